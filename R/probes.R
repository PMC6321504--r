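#' Probe geometry
#'
#' Describes a fluorescent probe by the fixed molecular angle `gamma` between
#' its absorption and emission transition dipoles.  Three probes used on
#' reconstituted thin filaments are built in: 1,5-IAEDANS on the myosin head
#' (Cys707 of S1), FITC-phalloidin in the actin groove, and 5-IAF on Cys190 of
#' tropomyosin.
#'
#' @param name Probe identifier.  One of `"AEDANS-S1"`, `"FITC-actin"`,
#'   `"AF-Tpm"` (in which case `gamma` may be omitted) or any user-defined
#'   string.
#' @param gamma Angle between absorption and emission dipoles, degrees, in
#'   \[0, 90\].  Required for user-defined probes.
#' @return An object of class `probe_geometry` with fields `name` and `gamma`
#'   (degrees).
#' @examples
#' probe_geometry("AEDANS-S1")           # gamma = 20
#' probe_geometry("custom", gamma = 10)
#' @export
probe_geometry <- function(name, gamma = NULL) {
  builtin <- c("AEDANS-S1" = 20, "FITC-actin" = 14, "AF-Tpm" = 17)
  if (is.null(gamma)) {
    if (!name %in% names(builtin))
      stop("gamma must be given for user-defined probe '", name, "'")
    gamma <- unname(builtin[[name]])
  }
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  if (gamma < 0 || gamma > 90)
    stop("gamma must lie in [0, 90] degrees, got ", gamma)
  structure(list(name = name, gamma = gamma), class = "probe_geometry")
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf("<probe_geometry> %s (gamma = %g deg)\n", x$name, x$gamma))
  invisible(x)
}

as_probe <- function(probe) {
  if (inherits(probe, "probe_geometry")) return(probe)
  if (is.character(probe) && length(probe) == 1L) return(probe_geometry(probe))
  stop("probe must be a probe_geometry object or a built-in probe name")
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
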