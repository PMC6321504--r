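# Monte-Carlo oracles for the forward model, independent of the quadrature
# implementation.  All geometry is sampled directly: filament polar wobble
# theta_f (uniform in angle or uniform over the spherical cap), filament
# azimuth beta, and probe azimuth(s) psi on the cones -- independently for
# absorption and emission or locked with the offset delta solved from the
# probe angle gamma.  Draws are accumulated in chunks so large n stays in
# bounded memory; returns component means and standard errors.
mc_accumulate <- function(n, chunk, draw_fun) {
  s1 <- numeric(4); s2 <- numeric(4); done <- 0
  while (done < n) {
    m <- min(chunk, n - done)
    prods <- draw_fun(m)
    s1 <- s1 + colSums(prods)
    s2 <- s2 + colSums(prods^2)
    done <- done + m
  }
  mean <- s1 / n
  var <- pmax((s2 / n - mean^2) * n / (n - 1), 0)  # guard tiny cancellation
  list(mean = stats::setNames(mean, c("I_pp", "I_pt", "I_tt", "I_tp")),
       se = sqrt(var / n))
}

mc_ordered_quadruple <- function(phi_a, phi_e, theta_half, gamma = NULL,
                                 n = 1e6, wobble = "uniform",
                                 azimuth = "independent", chunk = 1e6) {
  d2r <- pi / 180
  pa <- phi_a * d2r; pe <- phi_e * d2r; th_max <- theta_half * d2r
  delta <- if (azimuth == "locked") {
    cd <- (cos(gamma * d2r) - cos(pa) * cos(pe)) / (sin(pa) * sin(pe))
    acos(max(-1, min(1, cd)))
  } else NA
  mc_accumulate(n, chunk, function(m) {
    th <- if (th_max > 0) {
      if (wobble == "uniform") stats::runif(m, 0, th_max)
      else acos(stats::runif(m, cos(th_max), 1))
    } else rep(0, m)
    be <- stats::runif(m, 0, 2 * pi)
    psa <- stats::runif(m, 0, 2 * pi)
    pse <- if (azimuth == "independent") stats::runif(m, 0, 2 * pi)
      else psa + delta
    lab_vec <- function(phi, ps) {
      x1 <- sin(phi) * cos(ps); y1 <- sin(phi) * sin(ps); z1 <- cos(phi)
      xp <- x1 * cos(th) + z1 * sin(th)
      zp <- -x1 * sin(th) + z1 * cos(th)
      list(X = xp * cos(be) - y1 * sin(be), Z = zp)
    }
    a <- lab_vec(pa, psa); e <- lab_vec(pe, pse)
    cbind(a$Z^2 * e$Z^2, a$Z^2 * e$X^2, a$X^2 * e$X^2, a$X^2 * e$Z^2)
  })
}

# Uniformly random rigid dipole pairs with fixed inter-dipole angle gamma.
mc_isotropic_quadruple <- function(gamma, n = 1e6, chunk = 1e6) {
  g <- gamma * pi / 180
  mc_accumulate(n, chunk, function(m) {
    z <- stats::runif(m, -1, 1); az <- stats::runif(m, 0, 2 * pi)
    a <- cbind(sqrt(1 - z^2) * cos(az), sqrt(1 - z^2) * sin(az), z)
    # emission dipole at angle gamma from a, random azimuth about a
    ref <- cbind(-a[, 2], a[, 1], 0)  # orthogonal to a except at the poles
    degen <- sqrt(ref[, 1]^2 + ref[, 2]^2) < 1e-12
    if (any(degen))
      ref[degen, ] <- matrix(c(1, 0, 0), sum(degen), 3, byrow = TRUE)
    u <- ref / sqrt(rowSums(ref^2))
    v <- cbind(a[, 2] * u[, 3] - a[, 3] * u[, 2],
               a[, 3] * u[, 1] - a[, 1] * u[, 3],
               a[, 1] * u[, 2] - a[, 2] * u[, 1])
    phi <- stats::runif(m, 0, 2 * pi)
    e <- cos(g) * a + sin(g) * (cos(phi) * u + sin(phi) * v)
    cbind(a[, 3]^2 * e[, 3]^2, a[, 3]^2 * e[, 1]^2,
          a[, 1]^2 * e[, 1]^2, a[, 1]^2 * e[, 3]^2)
  })
}

# Shared small fixtures
aedans <- probe_geometry("AEDANS-S1")
fitc <- probe_geometry("FITC-actin")
collinear <- probe_geometry("collinear", gamma = 0)

make_atpase_df <- function(variant, pCa50, seed, noise_sd = 0.03) {
  a <- generate_atpase_assay(pCa50, noise_sd = noise_sd, seed = seed)
  data.frame(variant = variant, pCa = a$pCa,
             replicate = rep(seq_len(3), each = 17),
             activity = a$activity, baseline = attr(a, "baseline"))
}
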