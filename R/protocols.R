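#' @title Monotone loading protocols
#' @description
#' A loading protocol describes the force F(t) a bond experiences, together
#' with its loading rate r(t) = dF/dt and the logarithmic rate derivative
#' d ln r/dt. The theory requires F to be continuous and strictly increasing
#' with r(t) > 0 on the open domain, so every force value occurs exactly
#' once. Protocols carry their domain end `t_max` (finite for a worm-like
#' chain, where the force diverges as the extension approaches the contour
#' length; infinite for constant-rate and power-law loading).
#'
#' Canonical units are pN, nm and s internally; contour lengths, extensions
#' and pulling velocities are accepted in um at the interfaces and converted
#' on ingest.
#' @name loading_protocol
NULL

UM_TO_NM <- 1e3

new_loading_protocol <- function(type, force_fn, rate_fn, dlnr_fn, t_max,
                                 velocity = NA_real_, pars = list(),
                                 label = type) {
  structure(list(type = type, force_fn = force_fn, rate_fn = rate_fn,
                 dlnr_fn = dlnr_fn, t_max = t_max, velocity = velocity,
                 pars = pars, label = label),
            class = c(paste0(type, "_protocol"), "loading_protocol"))
}

check_time <- function(protocol, t, open_end = TRUE) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("time must be finite and >= 0")
  if (is.finite(protocol$t_max)) {
    bad <- if (open_end) t >= protocol$t_max else t > protocol$t_max
    if (any(bad))
      stop(sprintf("time outside protocol domain [0, %g)", protocol$t_max))
  }
  invisible(TRUE)
}

#' Evaluate a protocol's force, loading rate, or log-rate derivative
#'
#' @param protocol A `loading_protocol` object.
#' @param t Time(s) in s, within the protocol domain.
#' @return `protocol_force`: force in pN; `loading_rate`: dF/dt in pN/s;
#'   `dlnr_dt`: d ln r/dt in 1/s (`Inf` sentinel where r has an integrable
#'   singularity at t = 0, e.g. power-law exponents >= 2).
#' @examples
#' p <- linear_protocol(rate = 100)
#' protocol_force(p, 0.5)
#' loading_rate(p, 0.5)
#' dlnr_dt(p, 0.5)
#' @export
protocol_force <- function(protocol, t) {
  stopifnot(inherits(protocol, "loading_protocol"))
  check_time(protocol, t)
  protocol$force_fn(t)
}

#' @rdname protocol_force
#' @export
loading_rate <- function(protocol, t) {
  stopifnot(inherits(protocol, "loading_protocol"))
  check_time(protocol, t)
  protocol$rate_fn(t)
}

#' @rdname protocol_force
#' @export
dlnr_dt <- function(protocol, t) {
  stopifnot(inherits(protocol, "loading_protocol"))
  check_time(protocol, t)
  protocol$dlnr_fn(t)
}

#' @export
print.loading_protocol <- function(x, ...) {
  cat(sprintf("<%s loading protocol>\n", x$type))
  if (!is.na(x$velocity))
    cat(sprintf("  pulling velocity : %g um/s\n", x$velocity))
  for (nm in names(x$pars))
    cat(sprintf("  %-16s : %g\n", nm, x$pars[[nm]]))
  cat(sprintf("  domain           : [0, %s) s\n",
              if (is.finite(x$t_max)) format(x$t_max) else "Inf"))
  invisible(x)
}

#' Constant loading rate (linear DFS) protocol
#'
#' F(t) = r t, the classical dynamic force spectroscopy drive.
#'
#' @param rate Constant loading rate r in pN/s, positive.
#' @return A `loading_protocol`.
#' @export
linear_protocol <- function(rate) {
  stopifnot(is.numeric(rate), length(rate) == 1L, is.finite(rate), rate > 0)
  new_loading_protocol(
    "linear",
    force_fn = function(t) rate * t,
    rate_fn = function(t) rep_len(rate, length(t)),
    dlnr_fn = function(t) rep_len(0, length(t)),
    t_max = Inf,
    pars = list(rate_pN_s = rate))
}

#' Power-law distance-loading protocol
#'
#' F = a (v t)^n with the coefficient given in distance units (pN/um^n), as
#' produced by an elastic tether pulled at constant velocity. n = 1 is
#' linear DFS with r = a v; n = 2 is a reversible elastic (quadratic)
#' response.
#'
#' @param coefficient a in pN/um^n, positive.
#' @param exponent Integer n >= 1.
#' @param velocity Pulling velocity v in um/s, positive.
#' @return A `loading_protocol`.
#' @examples
#' p <- power_law_protocol(coefficient = 1e-3, exponent = 2, velocity = 10)
#' protocol_force(p, 10)  # 1e-3 * (10*10)^2 = 10 pN
#' @export
power_law_protocol <- function(coefficient, exponent, velocity) {
  stopifnot(is.numeric(coefficient), length(coefficient) == 1L, coefficient > 0,
            is.numeric(exponent), length(exponent) == 1L,
            exponent >= 1, exponent == round(exponent),
            is.numeric(velocity), length(velocity) == 1L, velocity > 0)
  a <- coefficient; n <- exponent; v <- velocity
  new_loading_protocol(
    "power_law",
    force_fn = function(t) a * (v * t)^n,
    rate_fn = function(t) {
      if (n == 1) rep_len(a * v, length(t)) else n * a * v^n * t^(n - 1)
    },
    dlnr_fn = function(t) {
      if (n == 1) rep_len(0, length(t)) else (n - 1) / t  # Inf at t = 0
    },
    t_max = Inf, velocity = v,
    pars = list(coefficient_pN_um_n = a, exponent = n))
}

#' Worm-like chain force-extension law
#'
#' Inelastic (Marko-Siggia interpolation) WLC force at end-to-end extension
#' L: \deqn{F = (k_B T / l_p) [\tfrac14 (1 - L/L_c)^{-2} - \tfrac14 + L/L_c].}
#'
#' @param persistence_length l_p in nm, positive.
#' @param contour_length L_c in um, positive.
#' @param extension End-to-end distance L in um, `0 <= L < Lc`; vectorized.
#' @param kBT Thermal energy in pN nm.
#' @return Force in pN.
#' @examples
#' wlc_force(3, 10, 5)  # = (4.11/3) * 1.25 at half extension
#' @export
wlc_force <- function(persistence_length, contour_length, extension,
                      kBT = 4.11) {
  stopifnot(persistence_length > 0, contour_length > 0, kBT > 0,
            is.numeric(extension))
  if (any(extension < 0) || any(extension >= contour_length))
    stop("extension must satisfy 0 <= L < Lc (force diverges at L = Lc)")
  u <- extension / contour_length
  (kBT / persistence_length) * (0.25 * (1 - u)^-2 - 0.25 + u)
}

#' Worm-like chain effective loading rate
#'
#' For a WLC pulled at constant velocity v (so L = v t) the loading rate is
#' \deqn{r(t) = (k_B T / l_p)(v / L_c) [\tfrac12 (1 - v t/L_c)^{-3} + 1].}
#' Velocity is converted to nm/s internally so the result is in pN/s.
#'
#' @inheritParams wlc_force
#' @param velocity v in um/s, positive.
#' @param t Time(s) in s, `0 <= t < Lc/v`.
#' @return Loading rate in pN/s.
#' @export
wlc_loading_rate <- function(persistence_length, contour_length, velocity, t,
                             kBT = 4.11) {
  stopifnot(persistence_length > 0, contour_length > 0, velocity > 0, kBT > 0)
  t_max <- contour_length / velocity
  if (any(t < 0) || any(t >= t_max))
    stop(sprintf("time outside WLC domain [0, %g)", t_max))
  u <- velocity * t / contour_length
  v_nm <- velocity * UM_TO_NM
  Lc_nm <- contour_length * UM_TO_NM
  (kBT / persistence_length) * (v_nm / Lc_nm) * (0.5 * (1 - u)^-3 + 1)
}

#' Worm-like chain loading protocol
#'
#' Constant-velocity extension of an inelastic WLC tether; the applied force
#' follows [wlc_force()] with L = v t. The domain ends at `t_max = Lc/v`
#' where the force diverges.
#'
#' @inheritParams wlc_force
#' @param velocity Pulling velocity v in um/s, positive.
#' @return A `loading_protocol` with fields `t_max = Lc/v`.
#' @examples
#' p <- wlc_protocol(persistence_length = 3, contour_length = 10,
#'                   velocity = 0.01)
#' loading_rate(p, 0)  # 1.5 kBT v / (lp Lc)
#' @export
wlc_protocol <- function(persistence_length, contour_length, velocity,
                         kBT = 4.11) {
  stopifnot(persistence_length > 0, contour_length > 0, velocity > 0, kBT > 0)
  lp <- persistence_length
  Lc_nm <- contour_length * UM_TO_NM
  v_nm <- velocity * UM_TO_NM
  t_max <- Lc_nm / v_nm
  C <- kBT / lp            # pN
  w <- v_nm / Lc_nm        # 1/s
  new_loading_protocol(
    "wlc",
    force_fn = function(t) {
      u <- w * t
      C * (0.25 * (1 - u)^-2 - 0.25 + u)
    },
    rate_fn = function(t) {
      u <- w * t
      C * w * (0.5 * (1 - u)^-3 + 1)
    },
    dlnr_fn = function(t) {
      u <- w * t
      1.5 * w * (1 - u)^-4 / (0.5 * (1 - u)^-3 + 1)
    },
    t_max = t_max, velocity = velocity,
    pars = list(persistence_length_nm = lp,
                contour_length_um = contour_length, kBT_pN_nm = kBT))
}

#' Loading protocol from a tabulated force-distance curve
#'
#' Builds a protocol from sampled (distance, force) points, e.g. a measured
#' tether force-extension curve. F(L) is interpolated with a monotone
#' piecewise-cubic (Fritsch-Carlson) spline after optional moving-average
#' pre-smoothing; the loading rate follows from r = (dF/dL) v and the
#' log-rate derivative from a central finite difference of log r.
#'
#' @param distance Sample distances in um, strictly increasing, >= 4 points.
#' @param force Sample forces in pN, same length; must be (after smoothing)
#'   strictly increasing.
#' @param velocity Pulling velocity v in um/s, positive.
#' @param smooth_window Optional odd integer width of a moving-average
#'   window applied to `force` before interpolation (for noisy measured
#'   curves). `NULL` (default) disables smoothing.
#' @return A `loading_protocol` with domain `[0, max(distance)/v)`.
#' @examples
#' L <- seq(0, 2, length.out = 50)
#' p <- tabulated_protocol(L, 10 * L, velocity = 10)  # reproduces F = 10 L
#' loading_rate(p, 0.05)  # ~ 100 pN/s
#' @export
tabulated_protocol <- function(distance, force, velocity,
                               smooth_window = NULL) {
  stopifnot(is.numeric(distance), is.numeric(force),
            length(distance) == length(force),
            is.numeric(velocity), length(velocity) == 1L, velocity > 0)
  if (length(distance) < 4)
    stop("at least 4 (distance, force) points are required")
  if (any(diff(distance) <= 0))
    stop("`distance` must be strictly increasing")
  f <- force
  if (!is.null(smooth_window)) {
    stopifnot(smooth_window >= 3, smooth_window %% 2 == 1)
    k <- (smooth_window - 1) / 2
    f <- vapply(seq_along(f), function(i) {
      mean(force[max(1, i - k):min(length(force), i + k)])
    }, numeric(1))
  }
  if (any(diff(f) <= 0)) {
    i <- which(diff(f) <= 0)[1]
    stop(sprintf(paste0("force not strictly increasing after smoothing on ",
                        "interval [%g, %g] um; increase `smooth_window` or ",
                        "clean the curve"), distance[i], distance[i + 1]))
  }
  sf <- stats::splinefun(distance, f, method = "monoH.FC")
  v <- velocity
  t_max <- max(distance) / v
  rate_fn <- function(t) sf(v * t, deriv = 1) * v  # pN/um * um/s
  new_loading_protocol(
    "tabulated",
    force_fn = function(t) sf(v * t),
    rate_fn = rate_fn,
    # d ln r/dt = v * F''(L)/F'(L), from the interpolant's own derivatives
    # (finite differences of log r across the spline's knots are too
    # noisy). The boundary cells inherit the adjacent interior curvature:
    # the spline's one-sided end derivatives make F'' unreliable there.
    dlnr_fn = function(t) {
      L <- pmin(pmax(v * t, distance[2]), distance[length(distance) - 1])
      v * sf(L, deriv = 2) / sf(L, deriv = 1)
    },
    t_max = t_max, velocity = v,
    pars = list(n_points = length(distance),
                distance_range_um = max(distance)))
}

#' Invert a protocol's force-time relation
#'
#' Finds the unique time at which the (strictly increasing) protocol force
#' equals `force`, by bracketed root finding.
#'
#' @param protocol A `loading_protocol`.
#' @param force Target force(s) in pN, within the attainable range.
#' @return Time(s) in s.
#' @export
time_at_force <- function(protocol, force) {
  stopifnot(inherits(protocol, "loading_protocol"), is.numeric(force))
  vapply(force, function(f) {
    f0 <- protocol$force_fn(0)
    if (f < f0) stop(sprintf("force %g pN below protocol start %g pN", f, f0))
    if (f == f0) return(0)
    if (is.finite(protocol$t_max)) {
      hi <- protocol$t_max * (1 - 1e-12)
      if (protocol$force_fn(hi) < f)
        stop(sprintf("force %g pN not attained within protocol domain", f))
    } else {
      hi <- 1
      while (protocol$force_fn(hi) < f) {
        hi <- hi * 2
        if (hi > 1e12) stop("force not attained within searchable horizon")
      }
    }
    stats::uniroot(function(t) protocol$force_fn(t) - f, c(0, hi),
                   tol = 1e-12 * max(hi, 1))$root
  }, numeric(1))
}
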