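test_that("closed-form constant-rate peak force behaves as the log law requires", {
  bp <- ref_params()
  res <- peak_force_linear(bp, 100)
  expect_equal(signif(res$F_star, 3), 70.7)
  # doubling the rate adds (kBT/xb) ln 2
  expect_equal(peak_force_linear(bp, 200)$F_star - res$F_star,
               bp$kBT / bp$xb * log(2), tolerance = 1e-12)
  # rate making the log argument e gives exactly kBT/xb
  r_e <- exp(1) * bp$koff_th * bp$kBT / bp$xb
  expect_equal(peak_force_linear(bp, r_e)$F_star, bp$kBT / bp$xb,
               tolerance = 1e-12)
  expect_true(peak_force_linear(bp, 1000)$F_star > res$F_star)
})

test_that("a log argument at or below 1 reports the peak-at-zero condition", {
  bp <- ref_params()
  r_crit <- bp$koff_th * bp$kBT / bp$xb
  expect_error(peak_force_linear(bp, 0.99 * r_crit),
               class = "nldfs_peak_at_zero")
})

test_that("the implicit solver reduces exactly to the closed form for constant loading", {
  bp <- ref_params()
  for (r in c(10, 100, 5000)) {
    imp <- peak_force_nonlinear(bp, linear_protocol(r))
    expect_close(imp$F_star, peak_force_linear(bp, r)$F_star, tol = 1e-9)
    expect_lt(imp$residual, 1e-9)
  }
  # power-law n = 1 is the same reduction through the distance units
  p1 <- power_law_protocol(10, 1, 10)  # r = 100 pN/s
  expect_close(peak_force_nonlinear(bp, p1)$F_star,
               peak_force_linear(bp, 100)$F_star, tol = 1e-9)
})

test_that("implicit peaks for the quadratic and WLC drives hit the reference values", {
  bp <- ref_params()
  quad <- peak_force_nonlinear(bp, power_law_protocol(1e-3, 2, 10))
  expect_equal(signif(quad$F_star, 3), 52.3)
  wlc <- peak_force_nonlinear(bp, wlc_protocol(3, 10, 0.01))
  expect_equal(signif(wlc$F_star, 3), 41.6)
  # low-velocity WLC has two stationary points (bimodal spectrum);
  # the reported root is the density maximum, not the valley
  expect_gte(nrow(wlc$all_roots), 2)
  expect_equal(wlc$F_star, max(wlc$all_roots$force), tolerance = 1e-9)
})

test_that("implicit solver and density oracle agree within 0.05 pN", {
  bp <- ref_params()
  protos <- list(linear_protocol(100),
                 power_law_protocol(1e-3, 2, 10),
                 wlc_protocol(3, 10, 0.01),
                 wlc_protocol(3, 10, 10))
  for (p in protos) {
    a <- peak_force_nonlinear(bp, p)$F_star
    b <- peak_force_density_oracle(bp, p)$F_star
    expect_close(a, b, tol = 0.05)
  }
})

test_that("solver/oracle agreement holds over randomized bond parameters", {
  set.seed(7)
  for (i in 1:8) {
    bp <- bond_parameters(stats::runif(1, 0.1, 2), 10^stats::runif(1, -6, -2))
    p <- wlc_protocol(3, 10, 0.1)
    ok <- tryCatch({
      a <- peak_force_nonlinear(bp, p)$F_star
      b <- peak_force_density_oracle(bp, p)$F_star
      expect_close(a, b, tol = 0.05)
      TRUE
    }, nldfs_peak_at_zero = function(e) TRUE)  # degenerate draws are reported
    expect_true(ok)
  }
})

test_that("the WLC peak force increases with pulling velocity", {
  bp <- ref_params()
  Fs <- vapply(ref_velocities(),
               function(v) peak_force_nonlinear(bp, wlc_protocol(3, 10, v))$F_star,
               numeric(1))
  expect_true(all(diff(Fs) > 0))
})
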