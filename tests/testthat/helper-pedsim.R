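# aliases for internal helpers exercised by the tests
norm3 <- pedsim:::norm3
unit3 <- pedsim:::unit3
rot_x <- pedsim:::rot_x
rot_y <- pedsim:::rot_y
rot_z <- pedsim:::rot_z
quat_identity <- pedsim:::quat_identity
quat_to_matrix <- pedsim:::quat_to_matrix
ellipsoid_level <- pedsim:::ellipsoid_level
BONE_NAMES <- pedsim:::BONE_NAMES
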