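#' @title Survival and rupture-density machinery
#' @description
#' A bond loaded by a protocol F(t) ruptures as an inhomogeneous Poisson
#' process with hazard k_off(F(t)). The survival probability solves
#' -dP/dt = k_off P, i.e. P(t) = exp(-H(t)) with the cumulative hazard
#' H(t) = integral of k_off(F(t')) dt' from 0 to t. Expressed over force,
#' the rupture density is p(F) = k_off(F) P(t(F)) / r(t(F)).
#' @name kinetics
NULL

# hazard rate k_off(F(t)) with a soft cap used only inside horizon searches,
# where the integrand may be evaluated far beyond any physical force
hazard_rate <- function(params, protocol, t, cap = Inf) {
  ex <- protocol$force_fn(t) * params$xb / params$kBT
  pmin(params$koff_th * exp(pmin(ex, 700)), cap)
}

# smallest t with H(t) >= target (capped hazard; bisection). Used to bound
# searches/grids: beyond it survival is below exp(-target).
hazard_horizon <- function(params, protocol, target = 45) {
  H_to <- function(t) {
    stats::integrate(function(s) hazard_rate(params, protocol, s, cap = 1e12),
                     0, t, rel.tol = 1e-8, abs.tol = 1e-10,
                     stop.on.error = FALSE)$value
  }
  if (is.finite(protocol$t_max)) {
    hi <- protocol$t_max * (1 - 1e-9)
    if (H_to(hi) < target) return(hi)
  } else {
    hi <- 1
    while (H_to(hi) < target) {
      hi <- hi * 2
      if (hi > 1e15) return(hi)
    }
  }
  lo <- 0
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (H_to(mid) < target) lo <- mid else hi <- mid
  }
  hi
}

#' Cumulative hazard along a loading protocol
#'
#' H(t) = integral from 0 to t of k_off(F(t')) dt', evaluated by adaptive
#' quadrature (relative tolerance 1e-8, absolute 1e-10). For a constant
#' loading rate r this equals the closed form
#' `(koff_th*kBT)/(r*xb) * (exp(r*t*xb/kBT) - 1)`.
#'
#' @param params A [bond_parameters()] object.
#' @param protocol A `loading_protocol`.
#' @param t Time(s) in s within the protocol domain; vectorized.
#' @return Dimensionless cumulative hazard, 0 at t = 0, strictly increasing.
#' @examples
#' bp <- bond_parameters(0.70, 1e-4)
#' p <- linear_protocol(100)
#' cumulative_hazard(bp, p, 0.5)
#' @export
cumulative_hazard <- function(params, protocol, t) {
  stopifnot(inherits(params, "bond_parameters"),
            inherits(protocol, "loading_protocol"))
  check_time(protocol, t)
  vapply(t, function(tt) {
    if (tt == 0) return(0)
    stats::integrate(function(s) off_rate(params, protocol$force_fn(s)),
                     0, tt, rel.tol = 1e-8, abs.tol = 1e-10)$value
  }, numeric(1))
}

#' Survival probability of a loaded bond
#'
#' P(t) = exp(-H(t)) with H from [cumulative_hazard()].
#'
#' @inheritParams cumulative_hazard
#' @return Probability in (0, 1]; 1 at t = 0, non-increasing.
#' @export
survival <- function(params, protocol, t) {
  exp(-cumulative_hazard(params, protocol, t))
}

#' Tabulated survival curve
#'
#' Evaluates the survival probability and cumulative hazard on a time grid.
#'
#' @inheritParams cumulative_hazard
#' @param times Strictly increasing time grid starting at 0.
#' @return A data frame of class `survival_curve` with columns `time`,
#'   `cumulative_hazard`, `survival`; the protocol and parameters are kept
#'   as attributes.
#' @export
survival_curve <- function(params, protocol, times) {
  stopifnot(is.numeric(times), length(times) >= 1)
  if (times[1] != 0 || any(diff(times) <= 0))
    stop("`times` must be strictly increasing and start at 0")
  H <- cumulative_hazard(params, protocol, times)
  out <- data.frame(time = times, cumulative_hazard = H, survival = exp(-H))
  attr(out, "params") <- params
  attr(out, "protocol") <- protocol
  class(out) <- c("survival_curve", class(out))
  out
}

#' Analytic rupture-force probability density
#'
#' The density of the rupture force under a strictly increasing protocol:
#' \deqn{p(F) = k_{off}(F) P(t(F)) / r(t(F)),}
#' where t(F) inverts the force-time relation. It integrates to
#' 1 - P(t_end) over the attainable force range (to 1 when the protocol
#' drives survival to zero).
#'
#' @inheritParams cumulative_hazard
#' @param force Force(s) in pN within the protocol's attainable range.
#' @return Density value(s) in 1/pN.
#' @examples
#' bp <- bond_parameters(0.70, 1e-4)
#' p <- linear_protocol(100)
#' rupture_density_force(bp, p, c(50, 70.7, 90))
#' @export
rupture_density_force <- function(params, protocol, force) {
  stopifnot(inherits(params, "bond_parameters"),
            inherits(protocol, "loading_protocol"))
  t <- time_at_force(protocol, force)
  k <- off_rate(params, force)
  S <- survival(params, protocol, t)
  r <- protocol$rate_fn(t)
  if (any(r <= 0)) stop("protocol loading rate must be positive")
  k * S / r
}
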