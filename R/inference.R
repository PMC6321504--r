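#' Fit settings for orientation inversion
#'
#' @param phi_e_starts,n_starts,theta_starts Grid of optimizer starting
#'   values (their Cartesian product, 54 starts by default).
#' @param theta_max Upper bound on the wobble half-angle, degrees.
#' @param rel_tol,abs_tol Optimizer tolerances (passed to [stats::nlminb()]).
#' @param ssr_window Solutions within this SSR of the best are inspected for
#'   degeneracy.
#' @param quadrature A [quadrature_settings()] list used for every forward
#'   evaluation.
#' @return A list of settings, class `fit_settings`.
#' @export
fit_settings <- function(phi_e_starts = seq(10, 85, by = 15),
                         n_starts = c(0.2, 0.5, 0.8),
                         theta_starts = c(5, 25, 45),
                         theta_max = 60,
                         rel_tol = 1e-12, abs_tol = 1e-14,
                         ssr_window = 1e-6,
                         quadrature = quadrature_settings()) {
  structure(list(phi_e_starts = phi_e_starts, n_starts = n_starts,
                 theta_starts = theta_starts, theta_max = theta_max,
                 rel_tol = rel_tol, abs_tol = abs_tol,
                 ssr_window = ssr_window, quadrature = quadrature),
            class = "fit_settings")
}

#' Invert the helix-plus-isotropic model for one fiber
#'
#' Minimizes the sum of squared residuals between the sum-normalized
#' observed and modelled quadruples over `(phi_e, n, theta_half)`, with the
#' absorption cone tied as `phi_a = |phi_e - gamma|` and the probe angle
#' `gamma` held fixed.  Bounds: `phi_e` in \[0, 90\] degrees, `n` in
#' \[0, 1\], `theta_half` in \[0, 60\] degrees.  A deterministic multi-start
#' grid (54 starts by default) followed by bounded quasi-Newton refinement
#' makes the fit reproducible bit-for-bit on identical input.
#'
#' @param q Observed intensity quadruple (any common scale).
#' @param probe A [probe_geometry()] or built-in probe name (`gamma` is
#'   never fitted).
#' @param options A [fit_settings()] list.
#' @return An object of class `orientation_fit` with fields
#'   `estimate` (an [orientation_state()]), `ssr`, `n_starts`, `n_converged`,
#'   `degenerate` (distinct minima tie within `ssr_window` but differ by
#'   more than 2 degrees in `phi_e` or 0.05 in `n`), and `disordered_only`
#'   (`n` fitted at ~1 so the ordered parameters are unidentifiable).
#' @export
fit_orientation <- function(q, probe, options = fit_settings()) {
  probe <- as_probe(probe)
  qn <- as.numeric(normalize_quadruple(q))
  g <- probe$gamma
  quad <- options$quadrature

  # inlined numeric forward model: the optimizer calls this tens of
  # thousands of times, so skip the S3 constructors and validation
  iso <- as.numeric(isotropic_quadruple(probe))
  uniform <- quad$wobble == "uniform"
  independent <- quad$azimuth == "independent"
  d2r <- pi / 180
  fwd_fast <- function(p) {
    if (!independent) {
      st <- list(phi_a = tied_phi_a(p[1], g), phi_e = p[1], n = p[2],
                 theta_half = p[3])
      class(st) <- "orientation_state"
      return(as.numeric(model_quadruple(st, probe, quad)))
    }
    pa <- abs(p[1] - g) * d2r; pe <- p[1] * d2r; t <- p[3] * d2r
    if (t < 1e-12) {
      m2 <- 1; m4 <- 1
    } else if (uniform) {
      m2 <- 1 / 2 + sin(2 * t) / (4 * t)
      m4 <- 3 / 8 + sin(2 * t) / (4 * t) + sin(4 * t) / (32 * t)
    } else {
      cc <- cos(t)
      m2 <- (1 + cc + cc^2) / 3
      m4 <- (1 + cc + cc^2 + cc^3 + cc^4) / 5
    }
    aA <- sin(pa)^2 / 2; bA <- cos(pa)^2 - aA
    aE <- sin(pe)^2 / 2; bE <- cos(pe)^2 - aE
    s2 <- 1 - m2; s4 <- 1 - 2 * m2 + m4; c2s2 <- m2 - m4
    ord <- c(aA * aE + (aA * bE + aE * bA) * m2 + bA * bE * m4,
             aA * aE + aA * bE * s2 / 2 + aE * bA * m2 + bA * bE * c2s2 / 2,
             aA * aE + (aA * bE + aE * bA) * s2 / 2 + bA * bE * (3 / 8) * s4,
             aA * aE + aE * bA * s2 / 2 + aA * bE * m2 + bA * bE * c2s2 / 2)
    (1 - p[2]) * ord + p[2] * iso
  }
  objective <- function(p) {
    m <- fwd_fast(p)
    sum((m / sum(m) - qn)^2)
  }

  starts <- expand.grid(phi_e = options$phi_e_starts, n = options$n_starts,
                        theta = options$theta_starts)
  lower <- c(0, 0, 0); upper <- c(90, 1, options$theta_max)
  sols <- vector("list", nrow(starts))
  diag_msgs <- character(0)
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::nlminb(as.numeric(starts[i, ]), objective, lower = lower,
                    upper = upper,
                    control = list(rel.tol = options$rel_tol,
                                   abs.tol = options$abs_tol,
                                   iter.max = 500, eval.max = 1000)),
      error = function(e) e)
    if (inherits(res, "error")) {
      diag_msgs <- c(diag_msgs, sprintf("start %d: %s", i, conditionMessage(res)))
      next
    }
    sols[[i]] <- res
  }
  sols <- Filter(Negate(is.null), sols)
  if (length(sols) == 0L)
    stop("all optimizer starts failed:\n", paste(diag_msgs, collapse = "\n"))

  ssrs <- vapply(sols, function(s) s$objective, numeric(1))
  best <- sols[[which.min(ssrs)]]
  p <- best$par

  disordered_only <- p[2] > 0.98
  degenerate <- FALSE
  if (!disordered_only) {
    near <- sols[ssrs <= best$objective + options$ssr_window]
    pars <- vapply(near, function(s) s$par, numeric(3))
    if (diff(range(pars[1, ])) > 2 || diff(range(pars[2, ])) > 0.05)
      degenerate <- TRUE
  }

  estimate <- orientation_state(phi_e = p[1], n = p[2], theta_half = p[3],
                                gamma = g)
  structure(list(estimate = estimate, ssr = best$objective,
                 n_starts = nrow(starts), n_converged = length(sols),
                 degenerate = degenerate, disordered_only = disordered_only,
                 probe = probe),
            class = "orientation_fit")
}

#' @export
print.orientation_fit <- function(x, ...) {
  cat(sprintf(
    "<orientation_fit> phi_E = %.2f deg, n = %.3f, theta_half = %.2f deg (ssr = %.3g)%s%s\n",
    x$estimate$phi_e, x$estimate$n, x$estimate$theta_half, x$ssr,
    if (x$degenerate) " [degenerate]" else "",
    if (x$disordered_only) " [disordered-only]" else ""))
  invisible(x)
}

#' Fit an ensemble of fibers
#'
#' Fits each fiber's quadruple independently and aggregates the parameter
#' estimates: mean and standard error of the mean (SEM) of `phi_e`, `n` and
#' `theta_half` over fibers.  Fibers whose fit raises an error are excluded
#' and counted; the SEM is flagged undefined for a single fiber.
#'
#' @param qs A list of intensity quadruples (one per fiber), or a numeric
#'   matrix with 4 columns.
#' @param probe A [probe_geometry()] or built-in probe name.
#' @param options A [fit_settings()] list.
#' @return An object of class `ensemble_fit` with `per_fiber` (list of
#'   `orientation_fit`), `summary` (data frame of mean and SEM per
#'   parameter), `n_fibers`, `n_failed`, `sem_defined`.
#' @export
fit_ensemble <- function(qs, probe, options = fit_settings()) {
  if (is.matrix(qs)) qs <- lapply(seq_len(nrow(qs)), function(i) qs[i, ])
  if (length(qs) < 1L) stop("at least one fiber is required")
  fits <- list(); failed <- 0L
  for (q in qs) {
    f <- tryCatch(fit_orientation(q, probe, options), error = function(e) e)
    if (inherits(f, "error")) failed <- failed + 1L else fits[[length(fits) + 1L]] <- f
  }
  if (length(fits) == 0L) stop("all ", length(qs), " fiber fits failed")
  par_mat <- t(vapply(fits, function(f)
    c(phi_e = f$estimate$phi_e, n = f$estimate$n,
      theta_half = f$estimate$theta_half), numeric(3)))
  n_ok <- nrow(par_mat)
  sem_defined <- n_ok >= 2L
  summ <- data.frame(
    parameter = colnames(par_mat),
    mean = colMeans(par_mat),
    sem = if (sem_defined) apply(par_mat, 2, stats::sd) / sqrt(n_ok) else NA_real_,
    row.names = NULL)
  structure(list(per_fiber = fits, summary = summ, n_fibers = n_ok,
                 n_failed = failed, sem_defined = sem_defined),
            class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf("<ensemble_fit> %d fibers (%d failed)\n", x$n_fibers, x$n_failed))
  print(x$summary)
  invisible(x)
}
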