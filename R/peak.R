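#' @title Most probable rupture force
#' @description
#' The mode F* of the rupture-force density. For constant loading rate r it
#' has the classical closed form
#' \deqn{F^* = (k_B T / x_b) \ln[r x_b / (k_{off}^{th} k_B T)].}
#' For a general monotone protocol the peak condition becomes implicit:
#' \deqn{F^* = (k_B T / x_b) \ln[(r x_b / k_B T - d\ln r/dt)/k_{off}^{th}],}
#' with r and d ln r/dt evaluated at the peak time t*. For constant loading
#' the extra log-rate term vanishes and the implicit condition reduces
#' exactly to the closed form.
#' @name peak_force
NULL

new_peak_result <- function(F_star, t_star, method, residual = NA_real_,
                            iterations = NA_integer_, all_roots = NULL) {
  structure(list(F_star = F_star, t_star = t_star, method = method,
                 residual = residual, iterations = iterations,
                 all_roots = all_roots),
            class = "peak_force")
}

#' @export
print.peak_force <- function(x, ...) {
  cat(sprintf("Most probable rupture force: %.4f pN (method: %s)\n",
              x$F_star, x$method))
  if (is.finite(x$t_star)) cat(sprintf("  at time t* = %g s\n", x$t_star))
  if (is.finite(x$residual)) cat(sprintf("  residual   = %.2e pN\n", x$residual))
  if (!is.null(x$all_roots) && nrow(x$all_roots) > 1) {
    cat("  all stationary candidates:\n")
    print(x$all_roots, row.names = FALSE)
  }
  invisible(x)
}

peak_at_zero <- function(msg) {
  stop(structure(class = c("nldfs_peak_at_zero", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Closed-form peak force for constant loading rate
#'
#' @param params A [bond_parameters()] object.
#' @param rate Constant loading rate r in pN/s, positive.
#' @return A `peak_force` object (method `"closed_form"`).
#' @section Degenerate case: if `r*xb/(koff_th*kBT) <= 1` the density is
#'   maximal at zero force and an error of class `nldfs_peak_at_zero` is
#'   raised, distinct from numeric failure.
#' @examples
#' peak_force_linear(bond_parameters(0.70, 1e-4), rate = 100)  # 70.7 pN
#' @export
peak_force_linear <- function(params, rate) {
  stopifnot(inherits(params, "bond_parameters"),
            is.numeric(rate), length(rate) == 1L, rate > 0)
  arg <- rate * params$xb / (params$koff_th * params$kBT)
  if (arg <= 1)
    peak_at_zero(sprintf(
      "peak at zero force: r*xb/(koff_th*kBT) = %.3g <= 1", arg))
  F_star <- params$kBT / params$xb * log(arg)
  new_peak_result(F_star, t_star = F_star / rate, method = "closed_form",
                  residual = 0)
}

#' Implicit peak force for a general monotone protocol
#'
#' Solves the implicit peak condition for t*: the residual
#' `g(t) = F(t) - (kBT/xb) log[(r(t)xb/kBT - dlnr/dt(t))/koff_th]`
#' is scanned on `n_scan` nodes over the admissible sub-domain (where the
#' log argument is positive) and each sign change is refined by Brent root
#' finding. If several stationary points exist (e.g. the bimodal worm-like
#' chain spectrum at low velocity), the root with the largest analytic
#' density is returned and all roots are kept in the result.
#'
#' @param params A [bond_parameters()] object.
#' @param protocol A `loading_protocol`.
#' @param n_scan Number of scan nodes for bracketing (default 512).
#' @return A `peak_force` object (method `"implicit"`) with `all_roots`
#'   diagnostics.
#' @examples
#' bp <- bond_parameters(0.70, 1e-4)
#' peak_force_nonlinear(bp, power_law_protocol(1e-3, 2, 10))   # 52.3 pN
#' peak_force_nonlinear(bp, wlc_protocol(3, 10, 0.01))         # 41.6 pN
#' @export
peak_force_nonlinear <- function(params, protocol, n_scan = 512) {
  stopifnot(inherits(params, "bond_parameters"),
            inherits(protocol, "loading_protocol"))
  t_hi <- if (is.finite(protocol$t_max)) {
    protocol$t_max * (1 - 1e-9)
  } else {
    hazard_horizon(params, protocol, target = 60)
  }
  force_fn <- protocol$force_fn
  rate_fn <- protocol$rate_fn
  dlnr_fn <- protocol$dlnr_fn
  xk <- params$xb / params$kBT
  cF <- params$kBT / params$xb
  # convention: where the log argument is <= 0 the right-hand side tends to
  # -Inf, so the residual is +Inf; a huge finite stand-in keeps the
  # bracketing scan and Brent iterations warning-free
  g <- function(t) {
    arg <- (rate_fn(t) * xk - dlnr_fn(t)) / params$koff_th
    out <- rep_len(1e300, length(arg))
    ok <- which(is.finite(arg) & arg > 0)
    if (length(ok)) out[ok] <- force_fn(t[ok]) - cF * log(arg[ok])
    out
  }
  tt <- t_hi * seq(1e-9, 1, length.out = n_scan + 1)
  arg_tt <- rate_fn(tt) * xk - dlnr_fn(tt)
  if (!any(arg_tt > 0))
    peak_at_zero("no admissible region: r*xb/kBT <= dlnr/dt throughout")
  gg <- g(tt)
  sign_change <- which(diff(sign(gg)) != 0)
  if (length(sign_change) == 0)
    peak_at_zero("no interior peak: residual has no sign change on bracket")
  roots <- vapply(sign_change, function(j) {
    stats::uniroot(g, c(tt[j], tt[j + 1]),
                   f.lower = gg[j], f.upper = gg[j + 1],
                   tol = 1e-13 * max(tt[j + 1], 1))$root
  }, numeric(1))
  # admissibility-boundary artifacts refine to points where g jumps rather
  # than crosses; genuine stationary points have a tiny residual
  res_roots <- abs(g(roots))
  keep <- res_roots <= 1e-6 * (1 + abs(force_fn(roots)))
  if (!any(keep))
    peak_at_zero("no interior peak: residual has no admissible zero")
  roots <- roots[keep]
  res_roots <- res_roots[keep]
  F_roots <- force_fn(roots)
  if (length(roots) > 1) {
    # rank competing stationary points by density; a trapezoid hazard on
    # the scan grid is plenty for ranking and avoids per-root quadrature
    k_tt <- hazard_rate(params, protocol, tt)
    H_tt <- c(0, cumsum((k_tt[-1] + k_tt[-length(k_tt)]) / 2 * diff(tt)))
    dens <- hazard_rate(params, protocol, roots) *
      exp(-stats::approx(tt, H_tt, roots)$y) / rate_fn(roots)
  } else {
    dens <- NA_real_
  }
  best <- if (length(roots) > 1) which.max(dens) else 1L
  all_roots <- structure(list(t = roots, force = F_roots, density = dens),
                         class = "data.frame",
                         row.names = seq_along(roots))
  new_peak_result(F_roots[best], roots[best], method = "implicit",
                  residual = res_roots[best],
                  iterations = length(sign_change),
                  all_roots = all_roots)
}

#' Peak force by direct density maximization
#'
#' Independent verification path: evaluates the analytic rupture density
#' [rupture_density_force()] on a dense time grid (mapped to force),
#' locates its interior local maxima, and refines the highest one with
#' golden-section search on the exact density. The density may also decay
#' from a nonzero value at the starting force (the worm-like chain's
#' low-force shoulder); that boundary sliver is not a stationary peak and
#' is excluded. Exists to cross-validate the implicit solver; the two must
#' agree to well under 0.05 pN.
#'
#' @inheritParams peak_force_nonlinear
#' @param n_grid Number of grid nodes (default 4096).
#' @return A `peak_force` object (method `"density_oracle"`).
#' @export
peak_force_density_oracle <- function(params, protocol, n_grid = 4096) {
  stopifnot(inherits(params, "bond_parameters"),
            inherits(protocol, "loading_protocol"))
  t_hi <- hazard_horizon(params, protocol, target = 45)
  tg <- t_hi * seq(1e-9, 1, length.out = n_grid)
  k <- hazard_rate(params, protocol, tg)
  dt <- diff(tg)
  H <- c(0, cumsum((k[-1] + k[-length(k)]) / 2 * dt))
  dens <- k * exp(-H) / protocol$rate_fn(tg)
  if (!all(is.finite(dens)) || max(dens) <= 0)
    stop("degenerate (flat or invalid) rupture density")
  interior <- 2:(n_grid - 1)
  cand <- interior[dens[interior] > dens[interior - 1] &
                     dens[interior] >= dens[interior + 1]]
  if (length(cand) == 0)
    stop("no interior density maximum (degenerate parameters)")
  j <- cand[which.max(dens[cand])]
  neg_dens_t <- function(t) {
    -rupture_density_force(params, protocol, protocol$force_fn(t))
  }
  opt <- stats::optimize(neg_dens_t, c(tg[j - 1], tg[j + 1]),
                         tol = 1e-12 * max(tg[j + 1], 1))
  t_star <- opt$minimum
  new_peak_result(protocol$force_fn(t_star), t_star,
                  method = "density_oracle", residual = NA_real_)
}
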