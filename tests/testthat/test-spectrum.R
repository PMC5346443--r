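test_that("a single-sample spectrum is one Gaussian kernel", {
  sp <- kde_spectrum(50, sigma = 1)
  pk <- find_peak(sp)
  expect_close(as.numeric(pk), 50, tol = 1e-6)
  expect_equal(max(sp$density), 1 / sqrt(2 * pi), tolerance = 1e-4)
  expect_equal(spectrum_mass(sp), 1, tolerance = 1e-6)
})

test_that("a dominating kernel width collapses the spectrum onto the sample mean", {
  x <- c(40, 45, 55, 60, 70)
  pk <- find_peak(kde_spectrum(x, sigma = 500, grid_to = 3000))
  expect_close(as.numeric(pk), mean(x), tol = 1)
})

test_that("spectra from simulated datasets carry unit mass", {
  bp <- ref_params()
  for (p in list(linear_protocol(100), wlc_protocol(3, 10, 0.01))) {
    d <- sample_rupture_forces(bp, p, 5e3, seed = 8)
    expect_equal(spectrum_mass(kde_spectrum(d, sigma = 0.5)), 1,
                 tolerance = 1e-2)
  }
})

test_that("exact and binned KDE paths agree at the handover size", {
  bp <- ref_params()
  d <- sample_rupture_forces(bp, linear_protocol(100), 5000, seed = 4)
  pk_exact <- find_peak(kde_spectrum(d, sigma = 1, exact_threshold = 10000))
  pk_fft <- find_peak(kde_spectrum(d, sigma = 1, exact_threshold = 10))
  expect_close(as.numeric(pk_exact), as.numeric(pk_fft), tol = 0.05)
})

test_that("kernel smoothing pushes the peak of a right-skewed density to lower force", {
  bp <- ref_params()
  p <- linear_protocol(100)
  d <- sample_rupture_forces(bp, p, 3e4, seed = 19)
  F_true <- peak_force_linear(bp, 100)$F_star
  pk_wide <- find_peak(kde_spectrum(d, sigma = 10))
  expect_lt(as.numeric(pk_wide), F_true)
})

test_that("the KDE peak converges to the analytic maximizer for large n, small sigma", {
  bp <- ref_params()
  d <- sample_rupture_forces(bp, linear_protocol(100), 1e6, seed = 2)
  pk <- find_peak(kde_spectrum(d, sigma = 0.5))
  expect_close(as.numeric(pk), peak_force_linear(bp, 100)$F_star, tol = 0.5)
})

test_that("bimodal WLC spectra report both maxima with the high peak global", {
  bp <- ref_params()
  d <- sample_rupture_forces(bp, wlc_protocol(3, 10, 0.01), 1e5, seed = 6)
  pk <- find_peak(kde_spectrum(d, sigma = 0.5))
  lm <- attr(pk, "local_maxima")
  expect_gte(nrow(lm), 2)
  expect_true(any(lm$force < 15))                 # low-force shoulder
  expect_close(as.numeric(pk), 41.55, tol = 1)    # global is the high peak
})

test_that("a misconfigured grid flags a boundary maximum and coverage gap", {
  sp <- kde_spectrum(c(50, 51, 52), sigma = 1, grid_from = 60, grid_to = 80)
  expect_true(sp$coverage_warning)
  expect_true(attr(find_peak(sp), "boundary"))
})

test_that("a 50-sample high-velocity WLC spectrum peaks in the high-80s band", {
  bp <- ref_params()
  p <- wlc_protocol(3, 10, 10)
  d <- sample_rupture_forces(bp, p, 50, seed = 14)
  pk <- find_peak(kde_spectrum(d, sigma = 3))
  expect_gt(as.numeric(pk), 80)
  expect_lt(as.numeric(pk), 100)
})
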