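test_that("predicted WLC peak forces reproduce the analytic reference row", {
  Fs <- predict_peak_forces(ref_params(), ref_wlc_family(), ref_velocities())
  expect_equal(round(Fs, 2), c(41.55, 58.61, 74.49, 89.81))
  expect_true(all(diff(Fs) > 0))
})

test_that("the linear family reduces to the closed-form peak across velocities", {
  bp <- ref_params()
  fam <- linear_family(coefficient = 10)   # r = 10 v pN/s
  v <- c(1, 5, 20)
  expect_equal(predict_peak_forces(bp, fam, v),
               vapply(v, function(vv) peak_force_linear(bp, 10 * vv)$F_star,
                      numeric(1)),
               tolerance = 1e-9)
})

test_that("the noise-free predict -> fit round trip recovers the parameters", {
  bp <- ref_params()
  fam <- ref_wlc_family()
  v <- ref_velocities()
  Fs <- predict_peak_forces(bp, fam, v)
  fit <- fit_parameters(v, Fs, fam)
  expect_true(fit$converged)
  expect_lt(abs(fit$xb_hat - bp$xb) / bp$xb, 1e-3)
  expect_lt(abs(fit$koff_hat - bp$koff_th) / bp$koff_th, 1e-3)
  expect_lt(fit$objective, 1e-8)
})

test_that("fitting the recorded 50-sample peak table recovers the published estimates", {
  # measured peaks 39.57 / 55.33 / 74.58 / 88.47 pN at the four velocities
  fit <- fit_parameters(ref_velocities(), c(39.57, 55.33, 74.58, 88.47),
                        ref_wlc_family())
  expect_true(fit$converged)
  expect_lt(abs(fit$xb_hat - 0.685) / 0.685, 0.01)
  expect_lt(abs(fit$koff_hat - 1.54e-4) / 1.54e-4, 0.05)
})

test_that("fitting is deterministic and validates its inputs", {
  fam <- ref_wlc_family()
  v <- ref_velocities()
  Fs <- c(41.5, 58.6, 74.5, 89.8)
  f1 <- fit_parameters(v, Fs, fam)
  f2 <- fit_parameters(v, Fs, fam)
  expect_identical(f1$xb_hat, f2$xb_hat)
  expect_identical(f1$koff_hat, f2$koff_hat)
  expect_error(fit_parameters(0.01, 41.5, fam), "at least 2")
  expect_error(fit_parameters(c(0.01, -1), c(40, 50), fam), "positive")
})

test_that("a small error study has coherent structure and reproducible seeds", {
  bp <- ref_params()
  st <- error_study(bp, ref_wlc_family(), ref_velocities(),
                    sample_sizes = c(40, 120), iterations = 12, sigma = 3,
                    seed = 99)
  s <- st$summary
  expect_equal(s$N, c(40, 120))
  expect_true(all(s$xb_q1 <= s$xb_median & s$xb_median <= s$xb_q3))
  expect_true(all(s$koff_q1 <= s$koff_median & s$koff_median <= s$koff_q3))
  expect_true(all(s$xb_mean_rel >= 0 & s$koff_mean_rel >= 0))
  expect_equal(nrow(st$peak_errors), 8)
  expect_true(all(st$peak_errors$peak_mean_rel >= 0))
  expect_equal(sum(s$iterations - s$n_used), st$failures)
  # bond length is always far better identified than the off-rate
  expect_true(all(s$xb_mean_rel < s$koff_mean_rel))
  st2 <- error_study(bp, ref_wlc_family(), ref_velocities(),
                     sample_sizes = c(40, 120), iterations = 12, sigma = 3,
                     seed = 99)
  expect_identical(st$summary, st2$summary)
})
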