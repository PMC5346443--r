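# Shared fixtures and independent oracles for the test suite.
#
# Reference bond: xb = 0.70 nm, koff_th = 1e-4 /s, kBT = 4.11 pN nm --
# typical of noncovalent adhesion bonds. The worm-like chain tether is
# lp = 3 nm, Lc = 10 um, pulled at 10 .. 1e4 nm/s (0.01 .. 10 um/s).

ref_params <- function() bond_parameters(xb = 0.70, koff_th = 1e-4, kBT = 4.11)

ref_wlc_family <- function() wlc_family(persistence_length = 3,
                                        contour_length = 10)

ref_velocities <- function() c(0.01, 0.1, 1, 10)  # um/s

# Independent cumulative-hazard oracle: plain trapezoid rule on a very
# fine uniform grid (no adaptive quadrature shared with the implementation).
trapezoid_hazard <- function(params, protocol, t, n = 1e6 + 1) {
  tg <- seq(0, t, length.out = n)
  k <- params$koff_th * exp(protocol_force(protocol, tg) * params$xb /
                              params$kBT)
  sum((k[-1] + k[-n]) / 2) * (tg[2] - tg[1])
}

# Independent Monte Carlo oracle: explicit time-stepping Bernoulli rupture
# trials. Steps are chosen so that koff * dt <= p_step (<= 1e-3) AND the
# force advances by at most dF_step per step (so the hazard is resolved
# even where the off-rate is tiny); each surviving bond ruptures with
# probability koff(t) * dt in its step. Slow by construction;
# distributional ground truth for the inverse-hazard sampler.
step_rupture_forces <- function(params, protocol, n, seed, p_step = 1e-3,
                                dF_step = 0.05, hazard_cap = 30) {
  k_of <- function(t) params$koff_th *
    exp(min(protocol_force(protocol, t) * params$xb / params$kBT, 700))
  t_lim <- if (is.finite(protocol$t_max)) protocol$t_max * (1 - 1e-9) else Inf
  cap <- ceiling(hazard_cap / p_step) * 4L
  times <- numeric(cap); probs <- numeric(cap)
  t <- 0; H <- 0; m <- 0L
  while (H < hazard_cap && t < t_lim && m < cap) {
    k <- k_of(t)
    dt <- min(p_step / k, dF_step / loading_rate(protocol, t))
    if (t + dt > t_lim) dt <- t_lim - t
    m <- m + 1L
    times[m] <- t + dt
    probs[m] <- k * dt
    H <- H + k * dt
    t <- t + dt
  }
  times <- times[seq_len(m)]; probs <- probs[seq_len(m)]
  set.seed(seed)
  rupture_step <- rep_len(m, n)   # bonds surviving the grid get the last step
  alive <- seq_len(n)
  for (s in seq_len(m)) {
    u <- stats::runif(length(alive))
    hit <- u < probs[s]
    if (any(hit)) {
      rupture_step[alive[hit]] <- s
      alive <- alive[!hit]
    }
    if (length(alive) == 0) break
  }
  protocol_force(protocol, times[rupture_step])
}

expect_close <- function(x, y, tol) {
  expect_true(abs(x - y) <= tol,
              label = sprintf("|%.6g - %.6g| = %.3g <= %.3g",
                              x, y, abs(x - y), tol))
}
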