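#' ATPase activity curve
#'
#' Actin-activated S1 ATPase activity as a function of pCa
#' (`-log10[Ca2+]`), with optional replicates (repeated pCa values) and a
#' baseline measured with S1 alone (no actin) in the same units.
#'
#' @param pCa Numeric vector of pCa values in \[4, 9\]; replicates are
#'   represented by repeated values.
#' @param activity Matched activity values, arbitrary units or normalized.
#' @param baseline S1-alone baseline activity (scalar, same units).
#' @return An object of class `atpase_curve`: a data frame with columns
#'   `pCa` and `activity`, plus attribute `baseline`.
#' @export
atpase_curve <- function(pCa, activity, baseline = 0) {
  stopifnot(length(pCa) == length(activity), is.finite(baseline))
  if (any(!is.finite(pCa)) || any(!is.finite(activity)))
    stop("pCa and activity must be finite")
  if (any(pCa < 4 | pCa > 9))
    stop("pCa values must lie within [4, 9]")
  out <- data.frame(pCa = pCa, activity = activity)
  attr(out, "baseline") <- baseline
  class(out) <- c("atpase_curve", "data.frame")
  out
}

#' Normalize an ATPase curve
#'
#' Subtracts the S1-alone baseline from all activities and divides by the
#' maximum of the baseline-subtracted values, so the output lies in
#' (approximately) \[0, 1\] with a maximum of exactly 1.  Replicates share
#' one post-subtraction maximum (the curve is normalized to its own maximal
#' activity, not per replicate).  Idempotent on already-normalized data
#' with zero baseline.
#'
#' @param curve An [atpase_curve()].
#' @return A normalized [atpase_curve()] with baseline 0.
#' @export
normalize_activity <- function(curve) {
  stopifnot(inherits(curve, "atpase_curve"))
  b <- attr(curve, "baseline")
  shifted <- curve$activity - b
  top <- max(shifted)
  if (top <= 0)
    stop("non-positive dynamic range after baseline subtraction")
  atpase_curve(curve$pCa, shifted / top, baseline = 0)
}

#' Hill equation for calcium activation
#'
#' `activity = floor + amplitude / (1 + 10^(n_h * (pCa - pCa50)))`.
#' Activity rises to `floor + amplitude` at high calcium (pCa well below
#' `pCa50`) and falls to `floor` at low calcium; it is strictly decreasing
#' in pCa for positive `amplitude` and `n_h`.
#'
#' @param pCa pCa value(s).
#' @param pCa50 Midpoint (pCa of half-maximal activation).
#' @param n_h Hill coefficient, must be positive.
#' @param floor,amplitude Lower asymptote and span.
#' @return Activity value(s).
#' @export
hill_model <- function(pCa, pCa50, n_h, floor = 0, amplitude = 1) {
  stopifnot(n_h > 0)
  floor + amplitude / (1 + 10^(n_h * (pCa - pCa50)))
}

#' Fit the Hill equation to a normalized ATPase curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]) over `pCa50` in \[4, 8\], `n_h` in (0, 6\],
#' `floor` in \[-0.2, 0.5\] and `amplitude` in (0, 1.5\], multi-started
#' from a pCa50 grid.  Replicates are fitted jointly (all points enter one
#' SSR).  Standard errors come from the Jacobian.
#'
#' @param curve A normalized [atpase_curve()] with at least 4 distinct pCa
#'   points.
#' @param pCa50_starts Starting grid for the midpoint.
#' @return An object of class `hill_fit` with fields `pCa50`, `n_h`,
#'   `floor`, `amplitude`, `se` (named vector incl. `se_pCa50`),
#'   `at_bound` (logical flag), `ssr`, `fit` (the underlying nls object).
#' @export
fit_hill <- function(curve, pCa50_starts = c(5, 6, 6.5, 7, 7.5)) {
  stopifnot(inherits(curve, "atpase_curve"))
  if (length(unique(curve$pCa)) < 4L)
    stop("at least 4 distinct pCa points are required")
  if (diff(range(curve$activity)) < 1e-8)
    stop("flat activity curve: Hill parameters are unidentifiable")

  lower <- c(pCa50 = 4, n_h = 1e-3, floor = -0.2, amplitude = 1e-3)
  upper <- c(pCa50 = 8, n_h = 6, floor = 0.5, amplitude = 1.5)
  best <- NULL
  for (p0 in pCa50_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        activity ~ floor + amplitude / (1 + 10^(n_h * (pCa - pCa50))),
        data = curve,
        start = list(pCa50 = p0, n_h = 1.5, floor = 0, amplitude = 1),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(stats::resid(fit)^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) stop("Hill fit failed from every start")

  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  at_bound <- any(abs(cf - lower) < 1e-6) || any(abs(cf - upper) < 1e-6)
  structure(list(pCa50 = unname(cf["pCa50"]), n_h = unname(cf["n_h"]),
                 floor = unname(cf["floor"]),
                 amplitude = unname(cf["amplitude"]),
                 se = c(se_pCa50 = unname(se["pCa50"]),
                        se_n_h = unname(se["n_h"])),
                 at_bound = at_bound, ssr = best$ssr, fit = best$fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> pCa50 = %.3f +/- %.3f, n_H = %.2f%s\n",
              x$pCa50, x$se[["se_pCa50"]], x$n_h,
              if (x$at_bound) " [at bound]" else ""))
  invisible(x)
}
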