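#' Orientation state of a probe population
#'
#' Parameters of the helix-plus-isotropic model for one probe population on
#' oriented filaments: the absorption and emission dipole cone half-angles
#' `phi_a` and `phi_e` about the filament axis, the fraction `n` of
#' disorderly oriented (isotropic) probes, and the maximal deviation
#' `theta_half` of the filament axis from the fiber axis (wobble half-angle).
#'
#' `n` follows the reporting convention of the fluorescence-polarization
#' literature on ghost fibers: it is the *disordered* fraction, so `n = 0`
#' is a fully ordered population and `n = 1` is fully isotropic.
#'
#' When `phi_a` is omitted it is tied to `phi_e` through the probe angle
#' `gamma`: `phi_a = phi_e - gamma` for `phi_e >= gamma`, and
#' `phi_a = gamma - phi_e` otherwise.  Both choices keep the fixed molecular
#' angle `gamma` between the dipoles geometrically feasible, and the second
#' branch keeps the tie continuous in `phi_e`.
#'
#' @param phi_e Emission-cone half-angle, degrees, in \[0, 90\].
#' @param n Disordered-probe fraction, in \[0, 1\].
#' @param theta_half Filament wobble half-angle, degrees, in \[0, 90).
#' @param phi_a Absorption-cone half-angle, degrees; defaults to the tie
#'   described above (requires `gamma`).
#' @param gamma Probe dipole angle in degrees, used for the tie and for the
#'   feasibility check `|phi_a - phi_e| <= gamma <= phi_a + phi_e`.
#' @return An object of class `orientation_state`.
#' @export
orientation_state <- function(phi_e, n, theta_half, phi_a = NULL, gamma = NULL) {
  stopifnot(is.numeric(phi_e), is.numeric(n), is.numeric(theta_half))
  if (phi_e < 0 || phi_e > 90) stop("phi_e must lie in [0, 90] degrees")
  if (n < 0 || n > 1) stop("n (disordered fraction) must lie in [0, 1]")
  if (theta_half < 0 || theta_half >= 90) stop("theta_half must lie in [0, 90) degrees")
  if (is.null(phi_a)) {
    if (is.null(gamma)) stop("either phi_a or gamma must be supplied")
    phi_a <- tied_phi_a(phi_e, gamma)
  }
  if (phi_a < 0 || phi_a > 90) stop("phi_a must lie in [0, 90] degrees")
  if (!is.null(gamma)) check_dipole_feasible(phi_a, phi_e, gamma)
  structure(list(phi_a = phi_a, phi_e = phi_e, n = n, theta_half = theta_half),
            class = "orientation_state")
}

#' Tie the absorption cone to the emission cone
#'
#' @param phi_e Emission-cone half-angle, degrees.
#' @param gamma Probe dipole angle, degrees.
#' @return Absorption-cone half-angle in degrees:
#'   `phi_e - gamma` when `phi_e >= gamma`, else `gamma - phi_e`.
#' @export
tied_phi_a <- function(phi_e, gamma) {
  abs(phi_e - gamma)
}

# The two cones admit a dipole pair with fixed angle gamma iff an azimuthal
# offset delta exists with cos(gamma) = cosA cosE + sinA sinE cos(delta),
# i.e. |phi_a - phi_e| <= gamma <= phi_a + phi_e.
check_dipole_feasible <- function(phi_a, phi_e, gamma) {
  if (abs(phi_a - phi_e) > gamma + 1e-9)
    stop(sprintf(
      "infeasible dipole geometry: |phi_a - phi_e| = %.3f exceeds gamma = %.3f",
      abs(phi_a - phi_e), gamma))
  if (phi_a + phi_e < gamma - 1e-9)
    stop(sprintf(
      "infeasible dipole geometry: phi_a + phi_e = %.3f is below gamma = %.3f",
      phi_a + phi_e, gamma))
  invisible(TRUE)
}

#' @export
print.orientation_state <- function(x, ...) {
  cat(sprintf(
    "<orientation_state> phi_A = %.2f deg, phi_E = %.2f deg, n(disordered) = %.3f, theta_half = %.2f deg\n",
    x$phi_a, x$phi_e, x$n, x$theta_half))
  invisible(x)
}
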