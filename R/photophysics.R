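#' Quadrature and averaging settings for the forward model
#'
#' @param n_psi Number of equally spaced azimuth nodes used by the
#'   locked-azimuth variant (the azimuth integrand is a low-order
#'   trigonometric polynomial, so 64 nodes are far beyond exact).
#' @param n_theta Number of Gauss-Legendre nodes for the filament wobble
#'   polar angle.
#' @param rel_tol Relative tolerance for the internal convergence check
#'   (the rule is compared against one with half the nodes).
#' @param wobble Wobble distribution for the filament polar deviation
#'   `theta_f` on `[0, theta_half]`: `"uniform"` (uniform in the polar
#'   angle, the default reading of a "maximal deviation" half-angle) or
#'   `"solid_angle"` (uniform over the spherical cap).
#' @param azimuth `"independent"` (default) averages the absorption and
#'   emission azimuths independently on their cones; `"locked"` keeps a
#'   single spiral azimuth shared by both dipoles with the offset `delta`
#'   solved from the probe angle `gamma`.  See the package vignette for why
#'   `"independent"` is the default (it reproduces the magic-angle identity
#'   P_par = P_perp at 54.74 degrees).
#' @return A list of settings, class `quadrature_settings`.
#' @export
quadrature_settings <- function(n_psi = 64L, n_theta = 64L, rel_tol = 1e-6,
                                wobble = c("uniform", "solid_angle"),
                                azimuth = c("independent", "locked")) {
  wobble <- match.arg(wobble)
  azimuth <- match.arg(azimuth)
  stopifnot(n_psi >= 8L, n_theta >= 4L, rel_tol > 0)
  structure(list(n_psi = as.integer(n_psi), n_theta = as.integer(n_theta),
                 rel_tol = rel_tol, wobble = wobble, azimuth = azimuth),
            class = "quadrature_settings")
}

# Moments <cos^2 theta>, <cos^4 theta> of the wobble distribution on
# [0, theta_half] (radians); theta_half = 0 collapses to a delta at 0.
# Both built-in distributions integrate in closed form (trigonometric
# antiderivatives for the uniform polar angle, power sums of cos(theta_half)
# for the spherical cap), so the fitting hot path is pure arithmetic.  The
# numeric Gauss-Legendre route is kept for cross-validation.
wobble_moments <- function(theta_half, settings) {
  if (theta_half < 1e-12) return(c(m2 = 1, m4 = 1))
  t <- theta_half
  if (settings$wobble == "uniform") {
    c(m2 = 1 / 2 + sin(2 * t) / (4 * t),
      m4 = 3 / 8 + sin(2 * t) / (4 * t) + sin(4 * t) / (32 * t))
  } else {
    cc <- cos(t)
    c(m2 = (1 + cc + cc^2) / 3,
      m4 = (1 + cc + cc^2 + cc^3 + cc^4) / 5)
  }
}

# Gauss-Legendre evaluation of the same moments, with a half-node
# convergence check.  Used by the locked-azimuth rule and by tests that
# validate the closed forms.
wobble_moments_quadrature <- function(theta_half, settings) {
  if (theta_half < 1e-12) return(c(m2 = 1, m4 = 1))
  one <- function(n) {
    gl <- gauss_nodes(n, 0, theta_half)
    w <- if (settings$wobble == "uniform") gl$w else gl$w * sin(gl$x)
    w <- w / sum(w)
    c(m2 = sum(w * cos(gl$x)^2), m4 = sum(w * cos(gl$x)^4))
  }
  fine <- one(settings$n_theta)
  coarse <- one(max(4L, settings$n_theta %/% 2L))
  err <- max(abs(fine - coarse) / pmax(abs(fine), 1e-12))
  if (err > settings$rel_tol)
    stop(sprintf("non-convergent wobble quadrature: achieved %.3g, requested %.3g",
                 err, settings$rel_tol))
  fine
}

# Gauss-Legendre nodes on [a, b], with the reference nodes on [-1, 1]
# cached per order (pracma recomputes them on every call).
.gauss_cache <- new.env(parent = emptyenv())
gauss_nodes <- function(n, a, b) {
  key <- as.character(n)
  base <- .gauss_cache[[key]]
  if (is.null(base)) {
    base <- pracma::gaussLegendre(n, -1, 1)
    .gauss_cache[[key]] <- base
  }
  list(x = (b - a) / 2 * base$x + (a + b) / 2, w = (b - a) / 2 * base$w)
}

# Quadruple of a fully ordered population with independent cone azimuths.
# For a cone of half-angle phi about the filament axis w, the azimuth average
# of (d.e)^2 is a + b*(w.e)^2 with a = sin^2(phi)/2, b = cos^2(phi) - a.
# Averaging the product over the filament azimuth and polar wobble then needs
# only <cos^2>, <cos^4> of the wobble distribution.
ordered_quadruple_independent <- function(phi_a, phi_e, theta_half, settings) {
  m <- wobble_moments(theta_half, settings)
  m2 <- m[["m2"]]; m4 <- m[["m4"]]
  aA <- sin(phi_a)^2 / 2; bA <- cos(phi_a)^2 - aA
  aE <- sin(phi_e)^2 / 2; bE <- cos(phi_e)^2 - aE
  s2 <- 1 - m2                 # <sin^2 theta_f>
  s4 <- 1 - 2 * m2 + m4        # <sin^4 theta_f>
  c2s2 <- m2 - m4              # <cos^2 sin^2>
  c(I_pp = aA * aE + (aA * bE + aE * bA) * m2 + bA * bE * m4,
    I_pt = aA * aE + aA * bE * s2 / 2 + aE * bA * m2 + bA * bE * c2s2 / 2,
    I_tt = aA * aE + (aA * bE + aE * bA) * s2 / 2 + bA * bE * (3 / 8) * s4,
    I_tp = aA * aE + aE * bA * s2 / 2 + aA * bE * m2 + bA * bE * c2s2 / 2)
}

# Locked-azimuth variant: both dipoles share the spiral azimuth psi with a
# fixed offset delta solved from cos(gamma) = cA cE + sA sE cos(delta).
# The filament-azimuth (beta) average is analytic (<cos^4 beta> = 3/8 etc.);
# psi uses an equally spaced rule (exact for trigonometric polynomials of
# degree < n_psi) and theta_f a Gauss-Legendre rule.
ordered_quadruple_locked <- function(phi_a, phi_e, theta_half, gamma, settings) {
  cd_num <- cos(gamma) - cos(phi_a) * cos(phi_e)
  cd_den <- sin(phi_a) * sin(phi_e)
  cd <- if (abs(cd_den) < 1e-14) {
    if (abs(cd_num) > 1e-9)
      stop("infeasible dipole geometry: degenerate cones cannot realize gamma")
    1
  } else cd_num / cd_den
  if (cd > 1 + 1e-9 || cd < -1 - 1e-9)
    stop(sprintf("infeasible dipole geometry: cos(delta) = %.4f outside [-1, 1]", cd))
  delta <- acos(max(-1, min(1, cd)))

  psi <- (seq_len(settings$n_psi) - 0.5) * 2 * pi / settings$n_psi
  if (theta_half < 1e-12) {
    th <- 0; wth <- 1
  } else {
    gl <- gauss_nodes(settings$n_theta, 0, theta_half)
    th <- gl$x
    wth <- if (settings$wobble == "uniform") gl$w else gl$w * sin(gl$x)
    wth <- wth / sum(wth)
  }
  grid <- expand.grid(psi = psi, th = th)
  w <- rep(wth, each = length(psi)) / length(psi)

  comp <- function(phi, ps) {
    s <- sin(phi); cc <- cos(phi)
    z <- cc * cos(grid$th) - s * cos(ps) * sin(grid$th)
    P <- s * cos(ps) * cos(grid$th) + cc * sin(grid$th)
    Q <- s * sin(ps)
    list(z = z, P = P, Q = Q)
  }
  a <- comp(phi_a, grid$psi)
  e <- comp(phi_e, grid$psi + delta)
  # beta-averages: <X^2> = (P^2+Q^2)/2 ; <Xa^2 Xe^2> via 4th-order moments
  Itt_int <- (3 / 8) * (a$P^2 * e$P^2 + a$Q^2 * e$Q^2) +
    (1 / 8) * (a$P^2 * e$Q^2 + a$Q^2 * e$P^2 + 4 * a$P * a$Q * e$P * e$Q)
  c(I_pp = sum(w * a$z^2 * e$z^2),
    I_pt = sum(w * a$z^2 * (e$P^2 + e$Q^2) / 2),
    I_tt = sum(w * Itt_int),
    I_tp = sum(w * (a$P^2 + a$Q^2) / 2 * e$z^2))
}

#' Forward model: fully ordered probe population
#'
#' Computes the four polarized fluorescence components
#' `<(a . e_exc)^2 (e . e_em)^2>` for probes whose dipoles lie on cones of
#' half-angles `phi_a` (absorption) and `phi_e` (emission) about the
#' filament axis, with the filament axis itself wobbling about the fiber
#' axis up to `theta_half`.  Lab geometry: fiber along OZ, light propagating
#' along OY, polarizations along OZ (par) and OX (perp).
#'
#' @param state An [orientation_state()] (the disordered fraction `n` is
#'   ignored here; see [model_quadruple()] for the mixture).
#' @param probe A [probe_geometry()] or built-in probe name.
#' @param quadrature A [quadrature_settings()] list.
#' @return An [intensity_quadruple()], defined up to one common scale.
#' @export
ordered_quadruple <- function(state, probe, quadrature = quadrature_settings()) {
  probe <- as_probe(probe)
  check_dipole_feasible(state$phi_a, state$phi_e, probe$gamma)
  pa <- deg2rad(state$phi_a); pe <- deg2rad(state$phi_e)
  th <- deg2rad(state$theta_half); g <- deg2rad(probe$gamma)
  q <- if (quadrature$azimuth == "independent")
    ordered_quadruple_independent(pa, pe, th, quadrature)
  else
    ordered_quadruple_locked(pa, pe, th, g, quadrature)
  intensity_quadruple(q[["I_pp"]], q[["I_pt"]], q[["I_tt"]], q[["I_tp"]])
}

#' Forward model: isotropic (disordered) probe population
#'
#' Closed-form static average over rigid dipole pairs with the probe's fixed
#' inter-dipole angle `gamma`, uniformly distributed in orientation:
#' components with parallel excitation/emission polarizers are proportional
#' to `(1 + 2 cos^2 gamma) / 15`, crossed components to
#' `(2 - cos^2 gamma) / 15`.  Reproduces the fundamental anisotropy
#' `r0 = (3 cos^2 gamma - 1) / 5`.
#'
#' @inheritParams ordered_quadruple
#' @return An [intensity_quadruple()] with `I_pp = I_tt` and `I_pt = I_tp`.
#' @export
isotropic_quadruple <- function(probe) {
  probe <- as_probe(probe)
  cg2 <- cos(deg2rad(probe$gamma))^2
  par <- (1 + 2 * cg2) / 15
  crs <- (2 - cg2) / 15
  intensity_quadruple(par, crs, par, crs)
}

#' Forward model: helix-plus-isotropic mixture
#'
#' Component-wise mixture of the ordered and disordered populations,
#' `(1 - n) * ordered + n * isotropic`, with no per-population
#' renormalization (both populations share absorption cross-section and
#' quantum yield).  `n` is the disordered fraction carried by `state`.
#'
#' @inheritParams ordered_quadruple
#' @return An [intensity_quadruple()], defined up to one common scale.
#' @export
model_quadruple <- function(state, probe, quadrature = quadrature_settings()) {
  probe <- as_probe(probe)
  iso <- isotropic_quadruple(probe)
  if (state$n >= 1) return(iso)
  ord <- ordered_quadruple(state, probe, quadrature)
  intensity_quadruple((1 - state$n) * ord[1] + state$n * iso[1],
                      (1 - state$n) * ord[2] + state$n * iso[2],
                      (1 - state$n) * ord[3] + state$n * iso[3],
                      (1 - state$n) * ord[4] + state$n * iso[4])
}

#' Cone half-angle at which the polarization ratios cross
#'
#' For a fully ordered population with `phi_a = phi_e = Phi` and the given
#' wobble, finds the cone half-angle at which `P_par = P_perp` by bracketed
#' root search on `Phi` in (0, 90) degrees.  For collinear dipoles
#' (`gamma = 0`) and no wobble this is the magic angle 54.74 degrees.
#'
#' @param probe A [probe_geometry()] or built-in probe name.
#' @param theta_half Filament wobble half-angle, degrees.
#' @param quadrature A [quadrature_settings()] list.
#' @param tol Root tolerance in degrees (default 0.001, well under 0.01).
#' @return The crossing angle in degrees.
#' @export
magic_angle_solve <- function(probe, theta_half = 0,
                              quadrature = quadrature_settings(), tol = 1e-3) {
  probe <- as_probe(probe)
  f <- function(phi) {
    st <- orientation_state(phi_e = phi, n = 0, theta_half = theta_half,
                            phi_a = phi)
    pr <- polarization_ratios(ordered_quadruple(st, probe, quadrature))
    pr$P_par - pr$P_perp
  }
  # keep phi_a = phi_e = Phi feasible: gamma <= 2 Phi
  lo <- max(probe$gamma / 2, 1e-3) + 1e-6
  hi <- 90 - 1e-6
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop("no sign change of P_par - P_perp in the bracket (",
         sprintf("%.3f, %.3f)", lo, hi))
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}
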