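#' @keywords internal
BOLTZMANN <- 1.380649e-23  # J/K, exact SI

#' Bending stiffness from the filament wobble half-angle
#'
#' For a semiflexible filament of length `L` with one end fixed and the
#' other free, the thermally driven deviation of the free end satisfies
#' `sin^2(theta) = 0.87 (kT / epsilon) L`, so the bending stiffness is
#' `epsilon = 0.87 k T L / sin^2(theta_half)`.
#'
#' @param theta_half Wobble half-angle in degrees, strictly inside (0, 90).
#' @param L Filament length in meters (default 1 micrometer).
#' @param T Absolute temperature in kelvin (default 293.15, room
#'   temperature).
#' @return An object of class `stiffness_context` with fields `epsilon`
#'   (N m^2), `epsilon_1e26` (in units of 1e-26 N m^2, the reporting unit),
#'   `theta_half`, `L`, `T`, `k`, and `at_boundary` (TRUE when
#'   `sin^2(theta) = 1`, i.e. theta at 90 degrees).
#' @export
stiffness_from_theta <- function(theta_half, L = 1e-6, T = 293.15) {
  stopifnot(L > 0, T > 0)
  if (theta_half <= 0 || theta_half >= 90)
    stop("theta_half must lie strictly inside (0, 90) degrees")
  s2 <- sin(deg2rad(theta_half))^2
  eps <- 0.87 * BOLTZMANN * T * L / s2
  structure(list(epsilon = eps, epsilon_1e26 = eps / 1e-26,
                 theta_half = theta_half, L = L, T = T, k = BOLTZMANN,
                 at_boundary = abs(s2 - 1) < 1e-12),
            class = "stiffness_context")
}

#' Wobble half-angle from bending stiffness
#'
#' Exact inverse of [stiffness_from_theta()]:
#' `theta = asin(sqrt(0.87 k T L / epsilon))`.
#'
#' @param epsilon Bending stiffness in N m^2 (SI), or a `stiffness_context`.
#' @param L,T As in [stiffness_from_theta()].
#' @return Wobble half-angle in degrees.
#' @export
theta_from_stiffness <- function(epsilon, L = 1e-6, T = 293.15) {
  if (inherits(epsilon, "stiffness_context")) {
    L <- epsilon$L; T <- epsilon$T; epsilon <- epsilon$epsilon
  }
  stopifnot(epsilon > 0, L > 0, T > 0)
  s2 <- 0.87 * BOLTZMANN * T * L / epsilon
  if (s2 > 1)
    stop(sprintf(
      "sin^2(theta) = %.4f > 1: filament too soft for the small-angle relation",
      s2))
  rad2deg(asin(sqrt(s2)))
}

#' @export
print.stiffness_context <- function(x, ...) {
  cat(sprintf(
    "<stiffness_context> epsilon = %.3g x 1e-26 N m^2 (theta_half = %.2f deg, L = %g m, T = %g K)%s\n",
    x$epsilon_1e26, x$theta_half, x$L, x$T,
    if (x$at_boundary) " [boundary]" else ""))
  invisible(x)
}

#' Actin-frame correction of the tropomyosin emission angle
#'
#' The emission angle observed for a tropomyosin probe is measured in the
#' lab frame; when calcium or myosin heads rotate the actin monomers, the
#' F-actin helix itself turns and the observed tropomyosin angle is offset.
#' Expressing tropomyosin relative to the rotating F-actin frame gives
#' `corrected = tpm_obs - (actin_obs - actin_ref)`, where `actin_ref` is the
#' actin emission angle in the chosen reference condition (by convention the
#' no-S1, low-calcium blocked state).
#'
#' The correction is invariant under adding a common constant to both
#' `actin_obs` and `actin_ref`.  A result outside \[0, 90\] degrees is
#' clamped with a warning and flagged via the `"clamped"` attribute.
#'
#' @param tpm_obs Observed tropomyosin emission angle, degrees.
#' @param actin_obs Observed actin emission angle in the same condition.
#' @param actin_ref Actin emission angle in the reference condition.
#' @return Corrected tropomyosin angle(s) in degrees.
#' @export
corrected_phi_e <- function(tpm_obs, actin_obs, actin_ref) {
  stopifnot(all(tpm_obs >= 0 & tpm_obs <= 90),
            all(actin_obs >= 0 & actin_obs <= 90),
            all(actin_ref >= 0 & actin_ref <= 90))
  corrected <- tpm_obs - (actin_obs - actin_ref)
  clamped <- corrected < 0 | corrected > 90
  if (any(clamped)) {
    warning("corrected phi_E outside [0, 90] degrees; value(s) clamped")
    corrected <- pmin(90, pmax(0, corrected))
  }
  attr(corrected, "clamped") <- clamped
  corrected
}
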