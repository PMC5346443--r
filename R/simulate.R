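#' @title Monte Carlo rupture simulation
#' @description
#' Rupture times are drawn exactly from the survival law P(t) = exp(-H(t))
#' by inverse-transform sampling on the cumulative hazard: draw
#' u ~ U(0,1) and solve H(t) = -log u. The hazard is precomputed on a dense
#' uniform time grid reaching the point where H = `hazard_cap` (survival
#' exp(-cap), far below double rounding of any realistic sample), and each
#' draw is refined inside its grid cell by solving the locally
#' linear-in-rate hazard model in closed form.
#' @name mc_simulator
NULL

#' Precompute an inverse-hazard sampler
#'
#' Builds the cumulative-hazard grid once so that repeated sampling calls
#' (e.g. inside an error study) are cheap.
#'
#' @param params A [bond_parameters()] object.
#' @param protocol A `loading_protocol`.
#' @param n_grid Number of grid nodes (default 2^16).
#' @param hazard_cap Grid reaches the time where the cumulative hazard
#'   equals this value (default 45; survival ~ 3e-20 there).
#' @return A `rupture_sampler` object.
#' @export
rupture_sampler <- function(params, protocol, n_grid = 65536,
                            hazard_cap = 45) {
  stopifnot(inherits(params, "bond_parameters"),
            inherits(protocol, "loading_protocol"))
  t_hi <- hazard_horizon(params, protocol, target = hazard_cap)
  tg <- seq(0, t_hi, length.out = n_grid)
  k <- hazard_rate(params, protocol, tg)
  H <- c(0, cumsum((k[-1] + k[-n_grid]) / 2 * diff(tg)))
  structure(list(params = params, protocol = protocol, t = tg, k = k, H = H),
            class = "rupture_sampler")
}

#' @export
print.rupture_sampler <- function(x, ...) {
  cat(sprintf("<rupture_sampler: %s protocol, %d nodes, H up to %.1f>\n",
              x$protocol$type, length(x$t), max(x$H)))
  invisible(x)
}

invert_hazard <- function(sampler, y) {
  H <- sampler$H
  n <- length(H)
  censored <- y >= H[n]
  y <- pmin(y, H[n] * (1 - 1e-12))
  i <- findInterval(y, H)
  i[i < 1] <- 1L
  i[i >= n] <- n - 1L
  h <- sampler$t[2] - sampler$t[1]
  k1 <- sampler$k[i]
  slope <- (sampler$k[i + 1] - k1) / h
  dy <- y - H[i]
  # solve k1*dt + slope*dt^2/2 = dy within the cell
  dt <- ifelse(abs(slope) < 1e-300,
               dy / k1,
               (-k1 + sqrt(pmax(k1^2 + 2 * slope * dy, 0))) / slope)
  t <- sampler$t[i] + pmin(pmax(dt, 0), h)
  attr(t, "censored") <- censored
  t
}

#' Sample rupture times or forces
#'
#' Draws i.i.d. rupture events with survival function exp(-H(t)) by
#' inverse-transform sampling (see [rupture_sampler()]); forces are the
#' protocol force evaluated at the rupture times. Identical `seed` and
#' inputs give identical output.
#'
#' @inheritParams rupture_sampler
#' @param n Number of draws, >= 1.
#' @param seed Integer RNG seed (required: reproducibility contract).
#' @param sampler Optional precomputed [rupture_sampler()]; built on the
#'   fly when `NULL`.
#' @return `sample_rupture_times`: numeric vector of times in s.
#'   `sample_rupture_forces`: a `rupture_dataset` (see
#'   [rupture_dataset()]).
#' @examples
#' bp <- bond_parameters(0.70, 1e-4)
#' d <- sample_rupture_forces(bp, linear_protocol(100), n = 500, seed = 1)
#' mean(d$forces)
#' @export
sample_rupture_times <- function(params, protocol, n, seed, sampler = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == round(n))
  if (missing(seed) || is.null(seed))
    stop("`seed` is required for reproducible sampling")
  if (is.null(sampler)) sampler <- rupture_sampler(params, protocol)
  set.seed(seed)
  u <- stats::runif(n)
  t <- invert_hazard(sampler, -log(u))
  if (any(attr(t, "censored")))
    warning(sprintf("%d draw(s) censored at the hazard-grid end",
                    sum(attr(t, "censored"))))
  as.numeric(t)
}

#' @rdname sample_rupture_times
#' @export
sample_rupture_forces <- function(params, protocol, n, seed, sampler = NULL) {
  if (is.null(sampler)) sampler <- rupture_sampler(params, protocol)
  t <- sample_rupture_times(params, protocol, n, seed, sampler = sampler)
  rupture_dataset(forces = sampler$protocol$force_fn(t),
                  velocity = protocol$velocity,
                  protocol_label = protocol$type,
                  params = params, seed = seed)
}

#' Rupture-force dataset
#'
#' Container for measured or simulated rupture forces with their
#' provenance (protocol, velocity, parameters, RNG seed where synthetic).
#'
#' @param forces Numeric vector of rupture forces in pN, all >= 0.
#' @param velocity Pulling velocity in um/s (NA if not applicable).
#' @param protocol_label Short protocol descriptor.
#' @param params Optional [bond_parameters()] used to generate the data.
#' @param seed Optional RNG seed used.
#' @return An object of class `rupture_dataset` with element `forces`.
#' @export
rupture_dataset <- function(forces, velocity = NA_real_,
                            protocol_label = NA_character_, params = NULL,
                            seed = NA_integer_) {
  stopifnot(is.numeric(forces), length(forces) >= 1)
  if (any(forces < 0)) stop("rupture forces must be non-negative")
  structure(list(forces = as.numeric(forces), n = length(forces),
                 velocity = velocity, protocol_label = protocol_label,
                 params = params, seed = seed),
            class = "rupture_dataset")
}

#' @export
print.rupture_dataset <- function(x, ...) {
  cat(sprintf("<rupture_dataset: n = %d, protocol = %s, v = %s um/s>\n",
              x$n, x$protocol_label,
              if (is.na(x$velocity)) "NA" else format(x$velocity)))
  cat(sprintf("  force range %.2f .. %.2f pN, mean %.2f pN\n",
              min(x$forces), max(x$forces), mean(x$forces)))
  invisible(x)
}
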