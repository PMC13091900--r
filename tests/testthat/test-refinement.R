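# GRF-tracking refinement: error statistics, polynomial fitting, and the
# closed-loop contraction on linear plants.

test_that("grf_error returns the pointwise error and closed-form MAE for
          a sinusoid", {
  a <- matrix(c(1, 2, 3), ncol = 1)
  out <- grf_error(a, a, body_weight = 700)
  expect_equal(out$error[, 1], c(0, 0, 0))
  expect_equal(out$mae_pct_bw, 0)

  out2 <- grf_error(a + 10, a, body_weight = 100)
  expect_equal(out2$error[, 1], rep(10, 3))
  expect_equal(out2$mae_pct_bw, 10)
  expect_equal(out2$sd_pct_bw, 0)

  # mean |sin| over one period = 2/pi of the amplitude
  s <- seq(0, 1, length.out = 20001)
  amp <- 37
  out3 <- grf_error(matrix(amp * sin(2 * pi * s)), matrix(0 * s),
                    body_weight = 100)
  expect_equal(out3$mae_pct_bw, 100 * amp * 2 / pi / 100,
               tolerance = 1e-3)

  expect_error(grf_error(matrix(1:3), matrix(1:4)), "length")
})

test_that("polynomial fitting recovers exact polynomials and respects
          model nesting", {
  s <- seq(0, 1, length.out = 60)
  cf <- fit_polynomial(s, rep(4.2, 60), order = 8)
  expect_equal(cf[1], 4.2, tolerance = 1e-9)
  expect_equal(max(abs(cf[-1])), 0, tolerance = 1e-8)

  set.seed(12)
  true_coef <- rnorm(9)
  y <- eval_polynomial(true_coef, s)
  rec <- fit_polynomial(s, y, order = 8)
  expect_equal(rec, true_coef, tolerance = 1e-6)

  # residual orthogonal to the basis
  noise <- rnorm(60)
  cf2 <- fit_polynomial(s, noise, order = 8)
  resid <- noise - eval_polynomial(cf2, s)
  X <- outer(s, 0:8, `^`)
  expect_lt(max(abs(crossprod(X, resid))), 1e-8)

  # nested models: higher order never fits worse
  r8 <- sum((noise - eval_polynomial(fit_polynomial(s, noise, 8), s))^2)
  r0 <- sum((noise - eval_polynomial(fit_polynomial(s, noise, 0), s))^2)
  expect_lte(r8, r0)

  expect_error(fit_polynomial(s[1:5], s[1:5], order = 8), "samples")
})

test_that("fitting is invariant to affine reparameterization of the
          stance window", {
  set.seed(8)
  y <- rnorm(40)
  s <- seq(0, 1, length.out = 40)
  t_raw <- 120 + 580 * s # ms
  s_re <- (t_raw - min(t_raw)) / diff(range(t_raw))
  expect_equal(fit_polynomial(s, y, 6), fit_polynomial(s_re, y, 6),
               tolerance = 1e-9)
})

test_that("displacement corrections are linear in the error with the
          lifting sign convention", {
  s <- seq(0, 1, length.out = 30)
  zero <- displacement_correction(list(rep(0, 9)), 0.1, s)
  expect_equal(max(abs(zero)), 0)

  const <- displacement_correction(list(c(5, rep(0, 8))), 0.2, s)
  expect_true(all(abs(const + 1) < 1e-12)) # -gain * error
  flipped <- displacement_correction(list(c(5, rep(0, 8))), -0.2, s)
  expect_equal(flipped, -const)
})

test_that("on a scalar linear plant the loop contracts at |1 - gG| and
          the auto-gain halves the error per iteration", {
  n <- 101
  s <- seq(0, 1, length.out = n)
  target <- matrix(300 + 80 * sin(2 * pi * s), ncol = 1)
  G <- 2.5 # N per mm of offset
  plant <- function(off) matrix(250 + G * off[, 1], ncol = 1)

  # explicit gain: contraction factor |1 - gG|
  g <- 0.25
  res <- refine(plant, target,
                refinement_config(gains = g, max_iterations = 5,
                                  tol = 1e-6), body_weight = 700)
  mae <- res$history[, 1]
  ratios <- mae[-1] / mae[-length(mae)]
  # the fit residual floors late iterations; check the first contractions
  expect_equal(ratios[1], abs(1 - g * G), tolerance = 0.05)
  expect_equal(ratios[2], abs(1 - g * G), tolerance = 0.05)

  # auto-gain: g = 0.5/G so each iteration halves the error; >= 50 %
  # total reduction within 5 iterations is comfortable
  res2 <- refine(plant, target,
                 refinement_config(max_iterations = 5, tol = 1e-9),
                 body_weight = 700)
  expect_equal(res2$gains[1], 0.5 / G, tolerance = 1e-6)
  expect_lt(res2$history[nrow(res2$history), 1],
            0.5 * res2$history[1, 1])
  # best-seen safeguard: the reported offsets never do worse than zero
  final <- plant(res2$offsets)
  expect_lte(mean(abs(final - target)), mean(abs(plant(0 * target) -
                                                 target)))

  # zero initial error: terminates immediately with zero corrections
  res3 <- refine(function(off) target, target,
                 refinement_config(max_iterations = 5, tol = 0.01))
  expect_equal(res3$iterations, 0L)
  expect_equal(max(abs(res3$offsets)), 0)

  # plant failure mid-iteration is reported, not raised
  calls <- 0
  flaky <- function(off) {
    calls <<- calls + 1
    if (calls > 3) stop("boom")
    matrix(250 + G * off[, 1], ncol = 1)
  }
  res4 <- refine(flaky, target,
                 refinement_config(gains = g, max_iterations = 8,
                                   tol = 1e-9))
  expect_true(res4$failed)
  expect_gte(nrow(res4$history), 1)
})
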