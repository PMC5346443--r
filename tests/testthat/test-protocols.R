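test_that("wlc_force matches the interpolation formula and diverges at Lc", {
  expect_equal(wlc_force(3, 10, 0), 0)
  # at half extension the bracket is exactly 1.25
  expect_equal(wlc_force(3, 10, 5), (4.11 / 3) * 1.25, tolerance = 1e-12)
  expect_gt(wlc_force(3, 10, 10 * (1 - 1e-8)), 1e10)
  expect_error(wlc_force(3, 10, 10), "diverges")
  # strictly increasing
  L <- seq(0, 9.9, length.out = 200)
  expect_true(all(diff(wlc_force(3, 10, L)) > 0))
})

test_that("wlc_loading_rate has the analytic form and matches finite differences", {
  # t = 0: bracket is 3/2, rate = 1.5 kBT v / (lp Lc) with um -> nm ingest
  expect_equal(wlc_loading_rate(3, 10, 10, 0), 2.055, tolerance = 1e-12)
  v <- 10; lp <- 3; Lc <- 10
  for (t in c(0.1, 0.5, 0.9) * Lc / v) {
    h <- 1e-7 * Lc / v
    fd <- (wlc_force(lp, Lc, v * (t + h)) - wlc_force(lp, Lc, v * (t - h))) /
      (2 * h)
    expect_equal(wlc_loading_rate(lp, Lc, v, t), fd, tolerance = 1e-5)
  }
  expect_error(wlc_loading_rate(3, 10, 10, 1), "domain")
})

test_that("dlnr_dt is analytic per protocol and agrees with log-rate differences", {
  expect_equal(dlnr_dt(linear_protocol(100), c(0, 1, 7)), c(0, 0, 0))
  quad <- power_law_protocol(1e-3, 2, 10)
  expect_equal(dlnr_dt(quad, 10), 0.1)          # (n-1)/t
  expect_identical(dlnr_dt(quad, 0), Inf)       # singular sentinel at t = 0
  w <- wlc_protocol(3, 10, 0.01)
  for (t in c(0.2, 0.6, 0.95) * w$t_max) {
    h <- 1e-6 * w$t_max
    fd <- (log(loading_rate(w, t + h)) - log(loading_rate(w, t - h))) / (2 * h)
    expect_equal(dlnr_dt(w, t), fd, tolerance = 1e-5)
  }
})

test_that("all protocol types have increasing force and positive rate equal to dF/dt", {
  set.seed(42)
  protos <- list()
  for (i in 1:5) {
    protos <- c(protos,
      list(linear_protocol(10^stats::runif(1, 0, 3)),
           power_law_protocol(10^stats::runif(1, -4, 1),
                              sample(1:3, 1), 10^stats::runif(1, -1, 1)),
           wlc_protocol(stats::runif(1, 0.5, 50), stats::runif(1, 0.5, 20),
                        10^stats::runif(1, -2, 1))))
  }
  for (p in protos) {
    t_hi <- if (is.finite(p$t_max)) p$t_max * 0.99 else 10
    tt <- seq(t_hi / 50, t_hi, length.out = 50)
    f <- protocol_force(p, tt)
    r <- loading_rate(p, tt)
    expect_true(all(diff(f) > 0))
    expect_true(all(r > 0))
    h <- 1e-5 * t_hi
    fd <- (protocol_force(p, tt + h) - protocol_force(p, tt - h)) / (2 * h)
    expect_equal(r, fd, tolerance = 1e-4)
  }
})

test_that("tabulated protocols reproduce linear curves and the WLC pipeline", {
  L <- seq(0, 2, length.out = 60)
  p <- tabulated_protocol(L, 10 * L, velocity = 10)     # F = a1 L, a1 = 10
  tt <- seq(0.01, 0.18, length.out = 20)
  expect_equal(loading_rate(p, tt), rep(100, 20), tolerance = 1e-6)

  # 200 nodes off the WLC law: downstream peak within 1% of the analytic one
  L <- seq(0, 10 * 0.97, length.out = 200)
  ptab <- tabulated_protocol(L, wlc_force(3, 10, L), velocity = 0.01)
  bp <- ref_params()
  F_tab <- peak_force_nonlinear(bp, ptab)$F_star
  F_ana <- peak_force_nonlinear(bp, wlc_protocol(3, 10, 0.01))$F_star
  expect_lt(abs(F_tab - F_ana) / F_ana, 0.01)
})

test_that("tabulated protocols reject bad input with diagnostics", {
  expect_error(tabulated_protocol(c(0, 1, 2), c(0, 1, 2), 1), "4")
  expect_error(tabulated_protocol(c(0, 1, 1, 2), c(0, 1, 2, 3), 1),
               "strictly increasing")
  expect_error(tabulated_protocol(c(0, 1, 2, 3), c(0, 2, 1.5, 3), 1),
               "interval \\[1, 2\\]")
  # smoothing rescues a mildly noisy monotone curve
  set.seed(1)
  L <- seq(0, 5, length.out = 100)
  f <- 10 * L + stats::rnorm(100, sd = 0.3)
  p <- tabulated_protocol(L, f, velocity = 1, smooth_window = 11)
  expect_s3_class(p, "loading_protocol")
})
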