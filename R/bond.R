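#' Bond parameters for Bell-Evans rupture kinetics
#'
#' Bundles the kinetic identity of a single noncovalent bond: the bond length
#' `xb` (distance from the bound-state energy minimum to the transition
#' barrier along the pulling coordinate), the thermal off-rate `koff_th`
#' (spontaneous dissociation rate at zero force), and the thermal energy
#' `kBT`. The force-dependent off-rate is
#' \deqn{k_{off}(F) = k_{off}^{th} \exp(F x_b / k_B T).}
#'
#' @param xb Bond length in nm. Must be positive.
#' @param koff_th Thermal off-rate in 1/s. Must be positive.
#' @param kBT Thermal energy in pN nm. Defaults to 4.11 pN nm (room
#'   temperature).
#'
#' @return An object of class `bond_parameters`.
#' @examples
#' bp <- bond_parameters(xb = 0.70, koff_th = 1e-4)
#' off_rate(bp, force = 50)
#' @export
bond_parameters <- function(xb, koff_th, kBT = 4.11) {
  stopifnot(is.numeric(xb), length(xb) == 1L, is.finite(xb),
            is.numeric(koff_th), length(koff_th) == 1L, is.finite(koff_th),
            is.numeric(kBT), length(kBT) == 1L, is.finite(kBT))
  if (xb <= 0) stop("`xb` must be positive (nm)")
  if (koff_th <= 0) stop("`koff_th` must be positive (1/s)")
  if (kBT <= 0) stop("`kBT` must be positive (pN nm)")
  structure(list(xb = xb, koff_th = koff_th, kBT = kBT),
            class = "bond_parameters")
}

#' @export
print.bond_parameters <- function(x, ...) {
  cat("Bell-Evans bond parameters\n")
  cat(sprintf("  bond length xb      : %g nm\n", x$xb))
  cat(sprintf("  thermal off-rate    : %g 1/s\n", x$koff_th))
  cat(sprintf("  thermal energy kBT  : %g pN nm\n", x$kBT))
  invisible(x)
}

#' Force-dependent dissociation rate
#'
#' Evaluates the Bell off-rate `koff_th * exp(F * xb / kBT)`.
#'
#' @param params A [bond_parameters()] object.
#' @param force Applied force in pN; non-negative (the theory covers pulling
#'   only), vectorized.
#' @param exponent_cap Guard against silent overflow: if `F*xb/kBT` exceeds
#'   this cap an error is raised instead of returning `Inf`. Default 700
#'   (just under the double-precision `exp` limit).
#'
#' @return Dissociation rate(s) in 1/s.
#' @examples
#' bp <- bond_parameters(0.70, 1e-4)
#' off_rate(bp, 0)      # = koff_th
#' off_rate(bp, 70.7)   # ~ 17 /s
#' @export
off_rate <- function(params, force, exponent_cap = 700) {
  stopifnot(inherits(params, "bond_parameters"), is.numeric(force))
  if (any(force < 0, na.rm = TRUE))
    stop("negative force: the Bell model here covers pulling (F >= 0) only")
  ex <- force * params$xb / params$kBT
  if (any(ex > exponent_cap, na.rm = TRUE))
    stop(sprintf("off_rate overflow: F*xb/kBT = %.3g exceeds cap %g",
                 max(ex), exponent_cap))
  params$koff_th * exp(ex)
}
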