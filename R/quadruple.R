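#' Intensity quadruple
#'
#' The four measured (or modelled) polarized fluorescence components for one
#' fiber and condition, in arbitrary common units.  The first subscript is
#' the excitation polarization, the second the emission polarization, both
#' relative to the fiber axis: `I_pp` = par/par, `I_pt` = par/perp,
#' `I_tt` = perp/perp, `I_tp` = perp/par.
#'
#' @param I_pp,I_pt,I_tt,I_tp Nonnegative intensities; at least one positive.
#' @return A named numeric vector of class `intensity_quadruple`.
#' @export
intensity_quadruple <- function(I_pp, I_pt, I_tt, I_tp) {
  q <- c(I_pp = I_pp, I_pt = I_pt, I_tt = I_tt, I_tp = I_tp)
  if (any(!is.finite(q))) stop("intensities must be finite")
  if (any(q < 0)) stop("intensities must be nonnegative")
  if (all(q == 0)) stop("at least one intensity must be positive")
  structure(q, class = "intensity_quadruple")
}

as_quadruple <- function(q) {
  if (inherits(q, "intensity_quadruple")) return(q)
  q <- as.numeric(q)
  if (length(q) != 4L) stop("an intensity quadruple has exactly 4 components")
  intensity_quadruple(q[1], q[2], q[3], q[4])
}

#' Sum-normalize an intensity quadruple
#'
#' Divides the four components by their sum.  The forward model is defined up
#' to one common positive scale, so all fitting is done on sum-normalized
#' quadruples.
#'
#' @param q An intensity quadruple (or length-4 numeric).
#' @return An `intensity_quadruple` with components summing to 1.
#' @export
normalize_quadruple <- function(q) {
  q <- as_quadruple(q)
  intensity_quadruple(q[1] / sum(q), q[2] / sum(q), q[3] / sum(q), q[4] / sum(q))
}

#' Polarization ratios
#'
#' Computes the two polarization ratios from the four intensity components:
#' `P_par = (I_pp - I_pt) / (I_pp + I_pt)` and
#' `P_perp = (I_tt - I_tp) / (I_tt + I_tp)`.
#' Both are scale invariant: multiplying all four intensities by a common
#' positive factor leaves them unchanged.
#'
#' @param q An intensity quadruple (or length-4 numeric in the order
#'   `I_pp, I_pt, I_tt, I_tp`).
#' @return A list with components `P_par` and `P_perp`, both in \[-1, 1\].
#' @examples
#' polarization_ratios(c(3, 1, 3, 1))  # P_par = P_perp = 0.5
#' @export
polarization_ratios <- function(q) {
  q <- as_quadruple(q)
  if (q[1] + q[2] <= 0) stop("zero denominator: I_pp + I_pt must be positive")
  if (q[3] + q[4] <= 0) stop("zero denominator: I_tt + I_tp must be positive")
  list(P_par  = unname((q[1] - q[2]) / (q[1] + q[2])),
       P_perp = unname((q[3] - q[4]) / (q[3] + q[4])))
}

#' @export
print.intensity_quadruple <- function(x, ...) {
  cat(sprintf("<intensity_quadruple> I_pp=%.4g I_pt=%.4g I_tt=%.4g I_tp=%.4g\n",
              x[1], x[2], x[3], x[4]))
  invisible(x)
}
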