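test_that("sampling is deterministic under a seed and validates inputs", {
  bp <- ref_params()
  p <- linear_protocol(100)
  a <- sample_rupture_forces(bp, p, 200, seed = 11)
  b <- sample_rupture_forces(bp, p, 200, seed = 11)
  expect_identical(a$forces, b$forces)
  expect_false(identical(a$forces, sample_rupture_forces(bp, p, 200,
                                                         seed = 12)$forces))
  expect_error(sample_rupture_times(bp, p, 0, seed = 1), "n")
  expect_error(sample_rupture_times(bp, p, 10), "seed")
})

test_that("empirical moments match the analytic density for constant loading", {
  bp <- ref_params()
  p <- linear_protocol(100)
  n <- 5e4
  d <- sample_rupture_forces(bp, p, n, seed = 5)
  mean_an <- integrate(function(f) f * rupture_density_force(bp, p, f),
                       1e-9, 130, rel.tol = 1e-9)$value
  se <- stats::sd(d$forces) / sqrt(n)
  expect_lt(abs(mean(d$forces) - mean_an), 3 * se)
})

test_that("sampled forces pass a KS test against the analytic CDF", {
  bp <- ref_params()
  p <- linear_protocol(100)
  n <- 1e4
  x <- sort(sample_rupture_forces(bp, p, n, seed = 9)$forces)
  cdf <- 1 - survival(bp, p, time_at_force(p, x))
  D <- max(pmax(abs(cdf - seq_len(n) / n), abs(cdf - (seq_len(n) - 1) / n)))
  expect_lt(D, 1.63 / sqrt(n))  # alpha = 0.01
})

test_that("empirical survival tracks exp(-H) within binomial bands", {
  bp <- ref_params()
  p <- linear_protocol(100)
  n <- 2e4
  t_r <- sample_rupture_times(bp, p, n, seed = 21)
  for (t0 in c(0.3, 0.6, 0.75)) {
    S_hat <- mean(t_r > t0)
    S <- survival(bp, p, t0)
    expect_lt(abs(S_hat - S), 4 * sqrt(S * (1 - S) / n))
  }
})

test_that("low-velocity WLC ruptures include a small low-force shoulder", {
  bp <- ref_params()
  d <- sample_rupture_forces(bp, wlc_protocol(3, 10, 0.01), 2e4, seed = 3)
  frac_low <- mean(d$forces < 20)
  expect_gt(frac_low, 0.05)   # nonzero shoulder ...
  expect_lt(frac_low, 0.35)   # ... but a minority of events
})

test_that("the quadratic-drive empirical mode sits at the implicit prediction", {
  bp <- ref_params()
  p <- power_law_protocol(1e-3, 2, 10)
  d <- sample_rupture_forces(bp, p, 2e5, seed = 17)
  peak <- find_peak(kde_spectrum(d, sigma = 0.5))
  expect_close(as.numeric(peak), 52.3, tol = 0.5)
})

test_that("inverse-hazard draws match the time-stepping oracle for all protocol types", {
  bp <- ref_params()
  protos <- list(linear = linear_protocol(100),
                 quadratic = power_law_protocol(1e-3, 2, 10),
                 wlc = wlc_protocol(3, 10, 0.01))
  n <- 1e4
  for (nm in names(protos)) {
    p <- protos[[nm]]
    fast <- sample_rupture_forces(bp, p, n, seed = 31)$forces
    slow <- step_rupture_forces(bp, p, n, seed = 32)
    ks <- suppressWarnings(stats::ks.test(fast, slow))
    expect_gt(ks$p.value, 0.01)
  }
})
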