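#' Parametric synthetic foot skeleton
#'
#' Builds a 23-bone rigid skeleton (tibia, fibula, talus, calcaneus,
#' navicular, cuboid, three cuneiforms, five metatarsals, proximal and
#' distal hallucal phalanges, four fused lesser-ray phalanges, three
#' sesamoids) from an analytic template: every bone is an oriented
#' ellipsoid (sesamoids are spheres) carrying a watertight triangulated
#' surface, named landmarks, and the attachment sites used by the ligament,
#' plantar-aponeurosis, muscle, and soft-tissue-column inventories.
#'
#' Global axes at build time: x anterior, y medial, z superior; the floor
#' is the plane z = 0 and the skeleton is built plantigrade with the
#' plantar soft-tissue clearance under the heel and metatarsal heads.
#' Units are mm / g / ms throughout.
#'
#' @name foot_model
NULL

BONE_NAMES <- c(
  "tibia", "fibula", "talus", "calcaneus", "navicular", "cuboid",
  "cuneiform_medial", "cuneiform_intermediate", "cuneiform_lateral",
  "metatarsal_1", "metatarsal_2", "metatarsal_3", "metatarsal_4",
  "metatarsal_5",
  "phalanx_hallux_proximal", "phalanx_hallux_distal",
  "phalanx_2", "phalanx_3", "phalanx_4", "phalanx_5",
  "sesamoid_medial", "sesamoid_lateral", "sesamoid_distal")

# Template reference foot length (mm); build parameters rescale from here.
TEMPLATE_FOOT_LENGTH <- 255
TEMPLATE_ARCH_RATIO <- 0.16
TEMPLATE_PAD <- 12 # plantar soft-tissue clearance at heel, mm

#' Build parameters for the synthetic foot
#'
#' @param scale foot length, mm (> 0)
#' @param arch_ratio navicular-height-to-foot-length ratio in (0, 1)
#' @param seed integer seed for the (optional) template jitter
#' @param jitter standard deviation of attachment-point jitter, mm
#' @param side `"right"` or `"left"` (left mirrors the template about the
#'   sagittal plane, flipping y)
#' @return a `foot_build_params` list
#' @export
foot_build_params <- function(scale = 255, arch_ratio = 0.16, seed = 0L,
                              jitter = 0, side = c("right", "left")) {
  side <- match.arg(side)
  if (!is.numeric(scale) || scale <= 0) {
    stop("foot_build_params: 'scale' must be > 0")
  }
  if (arch_ratio <= 0 || arch_ratio >= 1) {
    stop("foot_build_params: 'arch_ratio' must be in (0, 1)")
  }
  if (jitter < 0) stop("foot_build_params: 'jitter' must be >= 0")
  list(scale = scale, arch_ratio = arch_ratio, seed = as.integer(seed),
       jitter = jitter, side = side)
}

# ---------------------------------------------------------------------------
# Template tables. Coordinates are for a 255 mm right foot with a 12 mm
# plantar pad; the arch warp and scaling map them to the requested build.
# ---------------------------------------------------------------------------

# Long bones: proximal tip T1, distal tip T2, shaft radius r.
.template_long_bones <- function() list(
  metatarsal_1 = list(t1 = c(152, 16, 38), t2 = c(205, 18, 19), r = 6.5),
  metatarsal_2 = list(t1 = c(150, 4, 42), t2 = c(210, 6, 17), r = 5.0),
  metatarsal_3 = list(t1 = c(148, -8, 38), t2 = c(205, -6, 16), r = 5.0),
  metatarsal_4 = list(t1 = c(146, -19, 33), t2 = c(198, -17, 15.5),
                      r = 4.5),
  metatarsal_5 = list(t1 = c(144, -30, 28), t2 = c(190, -28, 15), r = 4.5),
  phalanx_hallux_proximal = list(t1 = c(213, 18, 18), t2 = c(234, 18, 14),
                                 r = 6.0),
  phalanx_hallux_distal = list(t1 = c(238, 18, 14), t2 = c(250, 18, 12),
                               r = 4.5),
  phalanx_2 = list(t1 = c(214, 6, 15), t2 = c(240, 7, 12), r = 4.5),
  phalanx_3 = list(t1 = c(209, -6, 15), t2 = c(233, -5, 12), r = 4.5),
  phalanx_4 = list(t1 = c(202, -17, 14), t2 = c(224, -16, 12), r = 4.0),
  phalanx_5 = list(t1 = c(194, -28, 14), t2 = c(212, -27, 12), r = 4.0))

# Tarsals, leg bones: axis-aligned ellipsoids (center, semi-axes).
.template_round_bones <- function() list(
  tibia = list(center = c(75, 8, 170), semi = c(15, 15, 85)),
  fibula = list(center = c(70, -24, 165), semi = c(9, 8, 75)),
  talus = list(center = c(75, 4, 68), semi = c(27, 16, 13)),
  calcaneus = list(center = c(48, 0, 34), semi = c(42, 20, 22)),
  navicular = list(center = c(115, 10, 41), semi = c(12, 16, 13)),
  cuboid = list(center = c(108, -22, 28), semi = c(17, 13, 13)),
  cuneiform_medial = list(center = c(140, 16, 40), semi = c(12, 6, 11)),
  cuneiform_intermediate = list(center = c(138, 3, 42), semi = c(10, 5, 10)),
  cuneiform_lateral = list(center = c(136, -9, 36), semi = c(11, 6, 10)),
  sesamoid_medial = list(center = c(200, 22, 9), semi = c(4.5, 3.5, 3.5)),
  sesamoid_lateral = list(center = c(200, 14, 9), semi = c(4.5, 3.5, 3.5)),
  sesamoid_distal = list(center = c(235, 18, 9), semi = c(3.5, 3, 3)))

# Cartilage pairs: (proximal bone, distal bone, contact point J, proxy
# sphere radius, torsional stiffness N*mm/rad). The proxy spheres touch at
# J in the build posture. Torsional stiffness stands in for articular
# congruence and the short periarticular ligaments not modeled
# individually: large at the wedged midfoot articulations, small at the
# mobile ankle, subtalar and toe joints.
.template_cartilage <- function() {
  j <- function(a, b, x, y, z, r = 6, krot = 2000) {
    list(a = a, b = b, point = c(x, y, z), radius = r, rot_stiffness = krot)
  }
  list(
    j("tibia", "talus", 75, 8, 83, 8, krot = 4000),
    j("fibula", "talus", 72, -16, 79, 4, krot = 500),
    j("talus", "calcaneus", 60, 0, 53, 8, krot = 20000),
    j("talus", "navicular", 103, 8, 48, 6, krot = 50000),
    j("calcaneus", "cuboid", 91, -20, 28, 6, krot = 50000),
    j("navicular", "cuneiform_medial", 128, 14, 40, 4, krot = 80000),
    j("navicular", "cuneiform_intermediate", 127, 4, 42, 4, krot = 80000),
    j("navicular", "cuneiform_lateral", 126, -6, 38, 4, krot = 80000),
    j("cuboid", "metatarsal_4", 126, -19, 31, 4, krot = 60000),
    j("cuboid", "metatarsal_5", 126, -28, 26, 4, krot = 60000),
    j("cuneiform_medial", "metatarsal_1", 152, 16, 38, 4, krot = 60000),
    j("cuneiform_intermediate", "metatarsal_2", 150, 3, 42, 4,
      krot = 60000),
    j("cuneiform_lateral", "metatarsal_3", 148, -7, 37, 4, krot = 60000),
    j("cuneiform_medial", "cuneiform_intermediate", 139, 9, 41, 3,
      krot = 80000),
    j("cuneiform_intermediate", "cuneiform_lateral", 137, -3, 39, 3,
      krot = 80000),
    j("metatarsal_1", "phalanx_hallux_proximal", 209, 18, 19, 5,
      krot = 5000),
    j("phalanx_hallux_proximal", "phalanx_hallux_distal", 236, 18, 14, 3,
      krot = 1200),
    j("metatarsal_2", "phalanx_2", 212, 6, 16, 3.5, krot = 4000),
    j("metatarsal_3", "phalanx_3", 207, -6, 16, 3.5, krot = 4000),
    j("metatarsal_4", "phalanx_4", 200, -17, 15, 3, krot = 4000),
    j("metatarsal_5", "phalanx_5", 192, -28, 15, 3, krot = 4000),
    j("metatarsal_1", "sesamoid_medial", 202, 21, 13, 2.5, krot = 100),
    j("metatarsal_1", "sesamoid_lateral", 202, 15, 13, 2.5, krot = 100),
    j("phalanx_hallux_proximal", "sesamoid_distal", 233, 18, 10.5, 2,
      krot = 100))
}

# Ligament chains: origin/insertion attachment points (template global),
# category governs the slack rule, area is the total bundle area (mm^2).
.template_ligaments <- function() {
  lg <- function(name, category, ob, op, ib, ip, area, bundle = 1L,
                 n_spheres = 0L, hosts = character()) {
    list(name = name, category = category,
         origin_bone = ob, origin = op, insertion_bone = ib, insertion = ip,
         area = area, bundle_count = as.integer(bundle),
         n_spheres = as.integer(n_spheres), hosts = hosts)
  }
  list(
    # lateral hindfoot group: slack = reference length
    lg("atfl", "lateral_hindfoot", "fibula", c(68, -20, 92), "talus",
       c(88, -10, 72), 12, bundle = 10),
    lg("cfl", "lateral_hindfoot", "fibula", c(70, -22, 90), "calcaneus",
       c(62, -18, 40), 10, bundle = 10),
    lg("ptfl", "lateral_hindfoot", "fibula", c(63, -24, 94), "talus",
       c(52, -8, 66), 12, bundle = 10),
    lg("lateral_talocalcaneal", "lateral_hindfoot", "talus", c(70, -11, 60),
       "calcaneus", c(68, -18, 46), 6, bundle = 10),
    lg("lateral_calcaneocuboid", "lateral_hindfoot", "calcaneus",
       c(88, -14, 30), "cuboid", c(98, -26, 28), 6),
    lg("bifurcate_calcaneonavicular", "lateral_hindfoot", "calcaneus",
       c(86, -4, 44), "navicular", c(106, 2, 44), 8),
    lg("bifurcate_calcaneocuboid", "lateral_hindfoot", "calcaneus",
       c(86, -8, 42), "cuboid", c(98, -16, 36), 8),
    # hindfoot stabilizers (default slack rule)
    lg("deltoid_tibiotalar_anterior", "default", "tibia", c(72, 20, 95),
       "talus", c(88, 14, 70), 15, bundle = 10),
    lg("deltoid_tibiocalcaneal", "default", "tibia", c(70, 21, 92),
       "calcaneus", c(58, 16, 48), 15, bundle = 10),
    lg("deltoid_tibiotalar_posterior", "default", "tibia", c(64, 20, 95),
       "talus", c(54, 10, 68), 15, bundle = 10),
    lg("deltoid_tibionavicular", "default", "tibia", c(74, 21, 96),
       "navicular", c(108, 18, 45), 8, bundle = 10),
    lg("interosseous_talocalcaneal", "default", "talus", c(64, 2, 57),
       "calcaneus", c(62, 0, 52), 25, bundle = 10),
    lg("posterior_talocalcaneal", "default", "talus", c(52, 0, 62),
       "calcaneus", c(44, 0, 52), 8),
    lg("talonavicular_dorsal", "default", "talus", c(98, 8, 58),
       "navicular", c(110, 10, 52), 8),
    # plantar group: slack = reference length
    lg("spring_calcaneonavicular", "plantar", "calcaneus", c(82, 8, 28),
       "navicular", c(108, 12, 32), 20),
    lg("short_plantar", "plantar", "calcaneus", c(76, -10, 15),
       "cuboid", c(98, -20, 17), 15),
    lg("long_plantar", "plantar", "calcaneus", c(60, -5, 13),
       "metatarsal_3", c(150, -8, 32), 25, n_spheres = 4, hosts = "cuboid"),
    lg("plantar_cubonavicular", "plantar", "cuboid", c(110, -14, 24),
       "navicular", c(112, 4, 30), 6),
    lg("plantar_cuneonavicular_1", "plantar", "navicular", c(120, 12, 33),
       "cuneiform_medial", c(134, 14, 31), 6),
    lg("plantar_cuneonavicular_2", "plantar", "navicular", c(122, 6, 32),
       "cuneiform_intermediate", c(132, 3, 33), 6),
    lg("plantar_cuneonavicular_3", "plantar", "navicular", c(121, 0, 31),
       "cuneiform_lateral", c(130, -8, 28), 6),
    lg("plantar_cuneocuboid", "plantar", "cuboid", c(114, -16, 20),
       "cuneiform_lateral", c(132, -9, 27), 6),
    lg("plantar_intercuneiform_12", "plantar", "cuneiform_medial",
       c(138, 11, 31), "cuneiform_intermediate", c(137, 5, 33), 5),
    lg("plantar_intercuneiform_23", "plantar", "cuneiform_intermediate",
       c(136, 0, 33), "cuneiform_lateral", c(134, -6, 28), 5),
    lg("plantar_tarsometatarsal_1", "plantar", "cuneiform_medial",
       c(148, 15, 32), "metatarsal_1", c(158, 16, 31), 8),
    lg("plantar_tarsometatarsal_2", "plantar", "cuneiform_intermediate",
       c(145, 3, 34), "metatarsal_2", c(156, 4, 35), 8),
    lg("plantar_tarsometatarsal_3", "plantar", "cuneiform_lateral",
       c(144, -8, 28), "metatarsal_3", c(154, -8, 31), 8),
    lg("plantar_tarsometatarsal_4", "plantar", "cuboid", c(122, -19, 22),
       "metatarsal_4", c(152, -18, 27), 8),
    lg("plantar_tarsometatarsal_5", "plantar", "cuboid", c(120, -27, 20),
       "metatarsal_5", c(150, -29, 23), 8),
    lg("plantar_metatarsal_12", "plantar", "metatarsal_1", c(198, 20, 14),
       "metatarsal_2", c(203, 7, 12), 5),
    lg("plantar_metatarsal_23", "plantar", "metatarsal_2", c(203, 5, 12),
       "metatarsal_3", c(198, -5, 12), 5),
    lg("plantar_metatarsal_34", "plantar", "metatarsal_3", c(198, -7, 12),
       "metatarsal_4", c(192, -16, 12), 5),
    lg("plantar_metatarsal_45", "plantar", "metatarsal_4", c(192, -18, 12),
       "metatarsal_5", c(185, -27, 12), 5),
    # dorsal counterparts (default slack rule)
    lg("dorsal_calcaneocuboid", "default", "calcaneus", c(86, -12, 38),
       "cuboid", c(100, -20, 39), 5),
    lg("dorsal_cubonavicular", "default", "cuboid", c(110, -12, 38),
       "navicular", c(114, 2, 50), 4),
    lg("dorsal_cuneonavicular_1", "default", "navicular", c(122, 12, 48),
       "cuneiform_medial", c(133, 15, 49), 5),
    lg("dorsal_cuneonavicular_2", "default", "navicular", c(123, 5, 50),
       "cuneiform_intermediate", c(132, 3, 51), 5),
    lg("dorsal_cuneonavicular_3", "default", "navicular", c(122, -1, 48),
       "cuneiform_lateral", c(130, -8, 45), 5),
    lg("dorsal_intercuneiform_12", "default", "cuneiform_medial",
       c(139, 11, 49), "cuneiform_intermediate", c(138, 5, 51), 4),
    lg("dorsal_intercuneiform_23", "default", "cuneiform_intermediate",
       c(137, 0, 51), "cuneiform_lateral", c(135, -5, 45), 4),
    lg("dorsal_tarsometatarsal_1", "default", "cuneiform_medial",
       c(149, 16, 47), "metatarsal_1", c(159, 16, 44), 6),
    lg("dorsal_tarsometatarsal_2", "default", "cuneiform_intermediate",
       c(146, 3, 50), "metatarsal_2", c(157, 4, 48), 6),
    lg("dorsal_tarsometatarsal_3", "default", "cuneiform_lateral",
       c(145, -8, 44), "metatarsal_3", c(155, -8, 43), 6),
    lg("dorsal_tarsometatarsal_4", "default", "cuboid", c(122, -19, 36),
       "metatarsal_4", c(152, -18, 38), 6),
    lg("dorsal_tarsometatarsal_5", "default", "cuboid", c(120, -27, 33),
       "metatarsal_5", c(150, -29, 32), 6),
    # metatarsophalangeal / interphalangeal stabilizers
    lg("mtp_plantar_plate_1", "plantar", "metatarsal_1", c(202, 18, 13),
       "phalanx_hallux_proximal", c(216, 18, 13), 8),
    lg("mtp_plantar_plate_2", "plantar", "metatarsal_2", c(207, 6, 12),
       "phalanx_2", c(217, 6, 11), 8),
    lg("mtp_plantar_plate_3", "plantar", "metatarsal_3", c(202, -6, 11),
       "phalanx_3", c(212, -6, 11), 8),
    lg("mtp_plantar_plate_4", "plantar", "metatarsal_4", c(195, -17, 11),
       "phalanx_4", c(205, -17, 10), 8),
    lg("mtp_plantar_plate_5", "plantar", "metatarsal_5", c(187, -28, 11),
       "phalanx_5", c(197, -28, 10), 8),
    lg("mtp_dorsal_capsule_1", "default", "metatarsal_1", c(202, 18, 27),
       "phalanx_hallux_proximal", c(216, 18, 22), 4),
    lg("mtp_dorsal_capsule_2", "default", "metatarsal_2", c(207, 6, 23),
       "phalanx_2", c(217, 6, 19), 4),
    lg("mtp_dorsal_capsule_3", "default", "metatarsal_3", c(202, -6, 22),
       "phalanx_3", c(212, -6, 19), 4),
    lg("mtp_dorsal_capsule_4", "default", "metatarsal_4", c(195, -17, 21),
       "phalanx_4", c(205, -17, 18), 4),
    lg("mtp_dorsal_capsule_5", "default", "metatarsal_5", c(187, -28, 21),
       "phalanx_5", c(197, -28, 18), 4),
    lg("ip_hallux_plantar", "plantar", "phalanx_hallux_proximal",
       c(232, 18, 10), "phalanx_hallux_distal", c(240, 18, 10), 5),
    lg("ip_hallux_dorsal", "default", "phalanx_hallux_proximal",
       c(232, 18, 19), "phalanx_hallux_distal", c(240, 18, 17), 4),
    # sesamoid suspension
    lg("sesamoid_suspensory_medial", "plantar", "metatarsal_1",
       c(201, 21, 14), "sesamoid_medial", c(199, 22, 12), 6),
    lg("sesamoid_suspensory_lateral", "plantar", "metatarsal_1",
       c(201, 15, 14), "sesamoid_lateral", c(199, 14, 12), 6),
    lg("sesamoid_phalangeal_medial", "plantar", "sesamoid_medial",
       c(203, 22, 9), "phalanx_hallux_proximal", c(215, 19, 13), 6),
    lg("sesamoid_phalangeal_lateral", "plantar", "sesamoid_lateral",
       c(203, 14, 9), "phalanx_hallux_proximal", c(215, 17, 13), 6),
    lg("intersesamoid", "plantar", "sesamoid_medial", c(200, 19, 9),
       "sesamoid_lateral", c(200, 17, 9), 4),
    lg("sesamoid_distal_proximal_band", "plantar", "phalanx_hallux_proximal",
       c(230, 18, 9), "sesamoid_distal", c(233, 18, 8), 4),
    lg("sesamoid_distal_distal_band", "plantar", "sesamoid_distal",
       c(238, 18, 8), "phalanx_hallux_distal", c(242, 18, 10), 4))
}

# Plantar aponeurosis: 10 slips, common origin region on the calcaneal
# tuberosity, inserting on the proximal phalanx bases; slip 1 routes via
# the hallucal sesamoids, slips 2..10 wrap the metatarsal-head cylinders.
.template_pa <- function() {
  origin_y <- seq(8, -7, length.out = 10)
  ins <- list(
    c("phalanx_hallux_proximal", 215, 18, 12),
    c("phalanx_2", 216, 6, 11), c("phalanx_2", 217, 8, 11),
    c("phalanx_3", 211, -6, 11), c("phalanx_3", 212, -4, 11),
    c("phalanx_4", 204, -17, 10), c("phalanx_4", 205, -15, 10),
    c("phalanx_5", 196, -28, 10), c("phalanx_5", 197, -26, 10),
    c("phalanx_5", 198, -30, 10))
  wrap_ray <- c(NA, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 5L)
  lapply(seq_len(10), function(i) {
    list(index = i,
         origin_bone = "calcaneus",
         origin = c(52, origin_y[i], 13),
         insertion_bone = ins[[i]][1],
         insertion = as.numeric(ins[[i]][2:4]),
         via_sesamoid = (i == 1L),
         wrap_ray = wrap_ray[i])
  })
}

.template_muscles <- function() list(
  TS = list(points = list(
    list(bone = "tibia", p = c(60, 8, 220)),
    list(bone = "calcaneus", p = c(10, 0, 44)))),
  TA = list(points = list(
    list(bone = "tibia", p = c(86, 12, 220)),
    list(bone = "tibia", p = c(86, 14, 100)),
    list(bone = "cuneiform_medial", p = c(140, 20, 46)))),
  # long toe extensors route over the metatarsal dorsum (extensor hood):
  # the via point keeps the moment arm at the toe joints anatomically
  # small instead of a straight pull to the shank
  EDL = list(points = list(
    list(bone = "tibia", p = c(84, -2, 210)),
    list(bone = "tibia", p = c(84, 0, 98)),
    list(bone = "metatarsal_2", p = c(185, 5, 31)),
    list(bone = "phalanx_2", p = c(228, 7, 18)))),
  EHL = list(points = list(
    list(bone = "tibia", p = c(85, 6, 200)),
    list(bone = "tibia", p = c(85, 10, 98)),
    list(bone = "metatarsal_1", p = c(180, 17, 34)),
    list(bone = "phalanx_hallux_distal", p = c(243, 18, 16)))))

# Soft-tissue columns: plantar anchor neighborhoods (x, y) and areas. The
# anchor is snapped to the plantar surface of the host bone at build time
# and the reference thickness is the resulting plantigrade clearance.
.template_columns <- function() list(
  list(name = "heel_posterior", bone = "calcaneus", xy = c(34, 0),
       area = 500),
  list(name = "heel_anteromedial", bone = "calcaneus", xy = c(52, 9),
       area = 500),
  list(name = "heel_anterolateral", bone = "calcaneus", xy = c(52, -9),
       area = 500),
  list(name = "lateral_midfoot", bone = "cuboid", xy = c(108, -24),
       area = 300),
  list(name = "met1_head", bone = "metatarsal_1", xy = c(198, 18),
       area = 350),
  list(name = "met2_head", bone = "metatarsal_2", xy = c(202, 6), area = 250),
  list(name = "met3_head", bone = "metatarsal_3", xy = c(198, -6),
       area = 250),
  list(name = "met4_head", bone = "metatarsal_4", xy = c(191, -17),
       area = 200),
  list(name = "met5_head", bone = "metatarsal_5", xy = c(183, -28),
       area = 200),
  list(name = "hallux_pad", bone = "phalanx_hallux_distal", xy = c(245, 18),
       area = 220),
  list(name = "toe2_pad", bone = "phalanx_2", xy = c(234, 7), area = 100),
  list(name = "toe3_pad", bone = "phalanx_3", xy = c(227, -5), area = 100),
  list(name = "toe4_pad", bone = "phalanx_4", xy = c(218, -16), area = 80),
  list(name = "toe5_pad", bone = "phalanx_5", xy = c(207, -27), area = 80))

# Named landmarks (template global): marker sites and protocol anchors.
.template_landmarks <- function() list(
  medial_malleolus = list(bone = "tibia", p = c(72, 23, 90)),
  lateral_malleolus = list(bone = "fibula", p = c(70, -31, 95)),
  tibial_tuberosity = list(bone = "tibia", p = c(88, 10, 248)),
  calcaneal_tuberosity = list(bone = "calcaneus", p = c(10, 0, 40)),
  heel_plantar = list(bone = "calcaneus", p = c(40, 0, 12)),
  met1_head = list(bone = "metatarsal_1", p = c(205, 18, 20)),
  met2_head = list(bone = "metatarsal_2", p = c(210, 6, 17)),
  met3_head = list(bone = "metatarsal_3", p = c(205, -6, 16)),
  met4_head = list(bone = "metatarsal_4", p = c(198, -17, 16)),
  met5_head = list(bone = "metatarsal_5", p = c(190, -28, 15)),
  toe_tip = list(bone = "phalanx_hallux_distal", p = c(250, 18, 12)),
  ankle_center = list(bone = "talus", p = c(75, 4, 78)))

# ---------------------------------------------------------------------------

# Arch warp: scales height-above-pad by a smooth midfoot bump, then
# applies uniform scaling. Operates on template-global points.
.make_template_transform <- function(params) {
  s <- params$scale / TEMPLATE_FOOT_LENGTH
  gain <- params$arch_ratio / TEMPLATE_ARCH_RATIO - 1
  flip <- if (params$side == "left") -1 else 1
  function(p) {
    p <- as.numeric(p)
    w <- exp(-((p[1] - 125) / 40)^2)
    z <- TEMPLATE_PAD + (p[3] - TEMPLATE_PAD) * (1 + gain * w)
    c(p[1], flip * p[2], z) * s
  }
}

.ellipsoid_mass_props <- function(semi, density) {
  vol <- 4 / 3 * pi * prod(semi)
  m <- vol * density
  inertia_local <- m / 5 * diag(c(semi[2]^2 + semi[3]^2,
                                  semi[1]^2 + semi[3]^2,
                                  semi[1]^2 + semi[2]^2))
  list(mass = m, inertia = inertia_local)
}

.make_bone <- function(name, center, semi, R_ell, density, unit_mesh) {
  mp <- .ellipsoid_mass_props(semi, density)
  # inertia about centroid in the bone-local (= global at build) frame
  inertia <- R_ell %*% mp$inertia %*% t(R_ell)
  verts_local <- t(R_ell %*% (t(unit_mesh$vertices) * semi))
  list(name = name, mass = mp$mass, centroid = center,
       inertia = inertia, orientation = quat_identity(),
       semi = semi, R_ell = R_ell,
       surface = list(vertices = verts_local, faces = unit_mesh$faces),
       landmarks = list())
}

#' Build the synthetic foot model
#'
#' Deterministic for a fixed seed. Returns a `foot_model` containing the 23
#' bones (mass, inertia, oriented-ellipsoid surface mesh), cartilage contact
#' pairs, the ligament / plantar-aponeurosis / muscle / soft-tissue-column
#' inventories with all attachment sites snapped to their host surfaces,
#' named landmarks, and the material registry used to derive element
#' stiffnesses.
#'
#' @param params a [foot_build_params()] list
#' @param materials a [material_set()]; defaults to the standard registry
#' @return a `foot_model` object
#' @export
build_foot <- function(params = foot_build_params(),
                       materials = material_set()) {
  tf <- .make_template_transform(params)
  unit_mesh <- icosphere(2L)
  rho_bone <- materials$bone$density
  flip <- if (params$side == "left") -1 else 1

  rng <- NULL
  if (params$jitter > 0) {
    rng <- local({
      set.seed(params$seed)
      function(n) stats::rnorm(n, sd = params$jitter)
    })
  }

  bones <- list()
  for (nm in names(.template_round_bones())) {
    spec <- .template_round_bones()[[nm]]
    ctr <- tf(spec$center)
    semi <- spec$semi * params$scale / TEMPLATE_FOOT_LENGTH
    bones[[nm]] <- .make_bone(nm, ctr, semi, diag(3), rho_bone, unit_mesh)
  }
  for (nm in names(.template_long_bones())) {
    spec <- .template_long_bones()[[nm]]
    t1 <- tf(spec$t1); t2 <- tf(spec$t2)
    ctr <- (t1 + t2) / 2
    a <- norm3(t2 - t1) / 2
    r <- spec$r * params$scale / TEMPLATE_FOOT_LENGTH
    R_ell <- frame_from_axis(t2 - t1)
    bones[[nm]] <- .make_bone(nm, ctr, c(a, r, r), R_ell, rho_bone,
                              unit_mesh)
    bones[[nm]]$landmarks$base <- t1 - ctr
    bones[[nm]]$landmarks$head <- t2 - ctr
  }
  bones <- bones[BONE_NAMES]

  # landmarks (bone-local)
  for (nm in names(.template_landmarks())) {
    lm <- .template_landmarks()[[nm]]
    bones[[lm$bone]]$landmarks[[nm]] <- tf(lm$p) - bones[[lm$bone]]$centroid
  }

  # attachment registry: snap every attachment to the host surface mesh
  attachments <- list()
  add_attachment <- function(label, bone, p_template) {
    p <- tf(p_template)
    if (!is.null(rng)) p <- p + rng(3)
    b <- bones[[bone]]
    local <- p - b$centroid
    cp <- mesh_closest_point(local, b$surface$vertices, b$surface$faces)
    if (cp$distance > 1) local <- cp$point
    attachments[[label]] <<- list(bone = bone, local = local)
    label
  }

  lig_specs <- .template_ligaments()
  ligaments <- lapply(lig_specs, function(lg) {
    o <- add_attachment(paste0("lig_", lg$name, "_origin"), lg$origin_bone,
                        lg$origin)
    i <- add_attachment(paste0("lig_", lg$name, "_insertion"),
                        lg$insertion_bone, lg$insertion)
    list(name = lg$name, category = lg$category,
         bundle_count = lg$bundle_count,
         origin_bone = lg$origin_bone, origin_attachment = o,
         insertion_bone = lg$insertion_bone, insertion_attachment = i,
         E = materials$ligament$E, area = lg$area,
         sphere_radius = 0.5, n_spheres = lg$n_spheres, hosts = lg$hosts,
         slack_length = NA_real_)
  })
  names(ligaments) <- vapply(ligaments, `[[`, "", "name")

  pa_specs <- .template_pa()
  mets <- paste0("metatarsal_", 1:5)
  pa_slips <- lapply(pa_specs, function(sp) {
    o <- add_attachment(sprintf("pa_slip%02d_origin", sp$index),
                        sp$origin_bone, sp$origin)
    i <- add_attachment(sprintf("pa_slip%02d_insertion", sp$index),
                        sp$insertion_bone, sp$insertion)
    wrap <- NULL
    if (!is.na(sp$wrap_ray)) {
      met <- mets[sp$wrap_ray]
      b <- bones[[met]]
      head_local <- b$landmarks$head
      wrap <- list(bone = met,
                   point = head_local, # cylinder axis point, bone-local
                   axis = c(0, flip, 0),
                   # effective wrap surface: met head + cartilage +
                   # plantar plate, so the band stays engaged when the
                   # foot pitches over the forefoot
                   radius = 1.25 * b$semi[2])
    }
    list(index = sp$index,
         origin_bone = sp$origin_bone, origin_attachment = o,
         insertion_bone = sp$insertion_bone, insertion_attachment = i,
         via_sesamoid = sp$via_sesamoid,
         via_bone = if (sp$via_sesamoid) "sesamoid_medial" else NULL,
         via_attachment = if (sp$via_sesamoid) {
           add_attachment(sprintf("pa_slip%02d_via", sp$index),
                          "sesamoid_medial", c(200, 20, 7))
         } else NULL,
         wrap_cylinder = wrap,
         E = materials$plantar_aponeurosis$E, area = 50 / 10,
         slack_length = NA_real_)
  })

  muscle_specs <- .template_muscles()
  muscles <- lapply(names(muscle_specs), function(mn) {
    pts <- muscle_specs[[mn]]$points
    labs <- vapply(seq_along(pts), function(k) {
      add_attachment(sprintf("muscle_%s_p%d", mn, k), pts[[k]]$bone,
                     pts[[k]]$p)
    }, "")
    list(name = mn,
         bones = vapply(pts, `[[`, "", "bone"),
         attachments = labs,
         force_profile = NULL)
  })
  names(muscles) <- names(muscle_specs)

  col_specs <- .template_columns()
  columns <- lapply(col_specs, function(cs) {
    b <- bones[[cs$bone]]
    probe <- c(tf(c(cs$xy[1], cs$xy[2], 0))[1:2], -30) - b$centroid
    cp <- mesh_closest_point(probe, b$surface$vertices, b$surface$faces)
    anchor_local <- cp$point
    z0 <- (b$centroid + anchor_local)[3]
    list(name = cs$name, bone = cs$bone, anchor = anchor_local,
         reference_thickness = z0,
         area = cs$area * (params$scale / TEMPLATE_FOOT_LENGTH)^2,
         ogden = materials$soft_tissue,
         prony = materials$soft_tissue_prony)
  })
  names(columns) <- vapply(columns, `[[`, "", "name")

  cart_specs <- .template_cartilage()
  s <- params$scale / TEMPLATE_FOOT_LENGTH
  cartilage_pairs <- lapply(cart_specs, function(cp) {
    J <- tf(cp$point)
    r <- cp$radius * s
    ca <- bones[[cp$a]]$centroid
    cb <- bones[[cp$b]]$centroid
    u <- unit3(cb - ca)
    list(bone_a = cp$a, bone_b = cp$b,
         center_a = (J - r * u) - ca, # bone-local proxy sphere centers
         center_b = (J + r * u) - cb,
         radius = r, contact_point = J,
         # torsional congruence stands in for the short periarticular
         # ligaments, so it carries the ligament modulus
         rot_stiffness = cp$rot_stiffness * s^3 *
           materials$ligament$E / 260)
  })

  model <- structure(list(
    bones = bones,
    attachments = attachments,
    ligaments = ligaments,
    pa_slips = pa_slips,
    muscles = muscles,
    columns = columns,
    cartilage_pairs = cartilage_pairs,
    materials = materials,
    build_params = params,
    welds = list(list(parent = "tibia", child = "fibula"))
  ), class = "foot_model")

  # slack lengths from the build-posture reference lengths
  model <- assign_model_slack(model)
  model
}

#' @export
print.foot_model <- function(x, ...) {
  cat("<foot_model>\n")
  cat(sprintf("  %d bones, %d ligament chains, %d PA slips, %d muscles\n",
              length(x$bones), length(x$ligaments), length(x$pa_slips),
              length(x$muscles)))
  cat(sprintf("  %d soft-tissue columns, %d cartilage pairs\n",
              length(x$columns), length(x$cartilage_pairs)))
  cat(sprintf("  foot length %g mm, arch ratio %g, side %s\n",
              x$build_params$scale, x$build_params$arch_ratio,
              x$build_params$side))
  invisible(x)
}

# Global position of a named attachment in the build posture.
attachment_position <- function(model, label) {
  a <- model$attachments[[label]]
  if (is.null(a)) stop("unknown attachment: ", label)
  model$bones[[a$bone]]$centroid + a$local
}

#' Global position of a named landmark in the build posture
#' @param model a `foot_model`
#' @param name landmark name (see `model$bones[[b]]$landmarks`)
#' @param bone host bone; if omitted, all bones are searched
#' @return length-3 numeric, mm
#' @export
landmark_position <- function(model, name, bone = NULL) {
  if (is.null(bone)) {
    for (b in model$bones) {
      if (name %in% names(b$landmarks)) {
        return(b$centroid + b$landmarks[[name]])
      }
    }
    stop("unknown landmark: ", name)
  }
  b <- model$bones[[bone]]
  b$centroid + b$landmarks[[name]]
}

#' Validate a foot model
#'
#' Checks the structural invariants: the 23-name enumeration, positive
#' masses, symmetric positive-definite inertias, watertight outward
#' surfaces, no bone-bone penetration in the build posture, attachments
#' within 1 mm of their host surface, exactly 10 PA slips with slip 1
#' routed through the sesamoids, positive slack lengths, and plantigrade
#' coplanarity of the calcaneus / metatarsal-head plantar points.
#'
#' @param model a `foot_model`
#' @param coplanar_tol tolerance on plantigrade coplanarity, mm
#' @return data frame of violations (zero rows when the model is valid)
#' @export
validate_model <- function(model, coplanar_tol = 5) {
  bad <- list()
  note <- function(component, where, message) {
    bad[[length(bad) + 1]] <<- data.frame(component = component,
                                          where = where, message = message,
                                          stringsAsFactors = FALSE)
  }

  nms <- names(model$bones)
  if (!identical(sort(nms), sort(BONE_NAMES)) || length(nms) != 23) {
    note("bones", "model", sprintf(
      "bone name set mismatch (%d bones; missing: %s; extra: %s)",
      length(nms), paste(setdiff(BONE_NAMES, nms), collapse = ","),
      paste(setdiff(nms, BONE_NAMES), collapse = ",")))
  }

  for (b in model$bones) {
    if (!is.finite(b$mass) || b$mass <= 0) {
      note("mass", b$name, "non-positive mass")
    }
    Isym <- max(abs(b$inertia - t(b$inertia)))
    if (Isym > 1e-9 * max(abs(b$inertia))) {
      note("inertia", b$name, "inertia not symmetric")
    } else if (any(eigen(b$inertia, symmetric = TRUE,
                         only.values = TRUE)$values <= 0)) {
      note("inertia", b$name, "inertia not positive-definite")
    }
    ws <- .mesh_watertight(b$surface)
    if (!ws$watertight) note("surface", b$name, "surface not watertight")
    if (ws$volume <= 0) note("surface", b$name, "surface not outward-oriented")
  }

  # bone-bone penetration: vertices of one bone inside another's ellipsoid
  for (i in seq_along(model$bones)) {
    bi <- model$bones[[i]]
    verts_i <- sweep(bi$surface$vertices, 2, bi$centroid, "+")
    for (j in seq_along(model$bones)) {
      if (i == j) next
      bj <- model$bones[[j]]
      lv <- ellipsoid_level(verts_i, bj$centroid, bj$semi, bj$R_ell)
      if (any(lv < 1 - 1e-6)) {
        note("penetration", paste(bi$name, bj$name, sep = "/"),
             sprintf("surface of %s penetrates %s (min level %.3f)",
                     bi$name, bj$name, min(lv)))
      }
    }
  }

  for (lab in names(model$attachments)) {
    a <- model$attachments[[lab]]
    b <- model$bones[[a$bone]]
    cp <- mesh_closest_point(a$local, b$surface$vertices, b$surface$faces)
    if (cp$distance > 1 + 1e-9 &&
        !mesh_contains(a$local, b$surface$vertices, b$surface$faces)) {
      note("attachment", lab, sprintf(
        "attachment %.2f mm off the %s surface", cp$distance, a$bone))
    }
  }

  if (length(model$pa_slips) != 10) {
    note("pa", "model", sprintf("%d PA slips (need 10)",
                                length(model$pa_slips)))
  } else if (!isTRUE(model$pa_slips[[1]]$via_sesamoid)) {
    note("pa", "slip 1", "slip 1 must route through the sesamoids")
  }

  for (lg in model$ligaments) {
    if (!is.na(lg$slack_length) && lg$slack_length <= 0) {
      note("ligament", lg$name, "non-positive slack length")
    }
    if (lg$origin_bone == lg$insertion_bone) {
      note("ligament", lg$name, "origin and insertion on the same bone")
    }
  }

  # plantigrade coplanarity of the calcaneus and metatarsal-head pads
  zs <- vapply(model$columns[c("heel_posterior", "met1_head", "met2_head",
                               "met3_head", "met4_head", "met5_head")],
               function(cc) {
                 b <- model$bones[[cc$bone]]
                 (b$centroid + cc$anchor)[3]
               }, 0)
  if (diff(range(zs)) > coplanar_tol) {
    note("plantigrade", "columns", sprintf(
      "plantar clearance spread %.2f mm exceeds %g mm",
      diff(range(zs)), coplanar_tol))
  }

  if (length(bad) == 0) {
    return(data.frame(component = character(), where = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, bad)
}

# watertightness (every edge shared by exactly two faces) and signed volume
.mesh_watertight <- function(surface) {
  f <- surface$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  keys <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  counts <- table(keys)
  v <- surface$vertices
  vol <- 0
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; cc <- v[f[i, 3], ]
    vol <- vol + sum(a * cross3(b, cc)) / 6
  }
  list(watertight = all(counts == 2), volume = vol)
}

#' Write bone meshes to a Wavefront OBJ file
#'
#' One named object per bone, vertices in global build coordinates.
#'
#' @param model a `foot_model`
#' @param path output path
#' @return the path, invisibly
#' @export
write_model_obj <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  offset <- 0L
  for (b in model$bones) {
    writeLines(paste("o", b$name), con)
    v <- sweep(b$surface$vertices, 2, b$centroid, "+")
    writeLines(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
    f <- b$surface$faces + offset
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
    offset <- offset + nrow(v)
  }
  invisible(path)
}

#' Total model mass
#' @param model a `foot_model`
#' @param extra additional attached masses, g (e.g. a loading shaft)
#' @return total mass, g
#' @export
model_mass <- function(model, extra = 0) {
  sum(vapply(model$bones, `[[`, 0, "mass")) + extra
}
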