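fiber_csv_header <- c("fiber_id", "variant", "probe_target", "ca",
                      "nucleotide", "s1_present", "I_pp", "I_pt", "I_tt", "I_tp")

#' Read a fiber intensity CSV
#'
#' Strict reader for the per-fiber polarized-intensity schema (header
#' exactly `fiber_id, variant, probe_target, ca, nucleotide, s1_present,
#' I_pp, I_pt, I_tt, I_tp`).  Malformed rows are rejected with their line
#' numbers: negative or non-finite intensities, unknown enum values
#' (`probe_target` in Tpm/actin/S1, `ca` in high/low, `nucleotide` in
#' none/ADP/ATP), an S1 probe without S1 present, or a nucleotide state
#' without S1 (nucleotide states are defined via the myosin head).
#'
#' @param path CSV file path.
#' @return A data frame of fiber records.
#' @export
read_fiber_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), fiber_csv_header))
    stop("bad fiber CSV header; expected exactly: ",
         paste(fiber_csv_header, collapse = ", "))
  df$s1_present <- as.logical(df$s1_present)
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- list()
  note <- function(cond, msg) {
    if (any(cond)) bad[[length(bad) + 1L]] <<- sprintf(
      "%s (line%s %s)", msg, if (sum(cond) > 1) "s" else "",
      paste(line[cond], collapse = ", "))
  }
  ints <- as.matrix(df[c("I_pp", "I_pt", "I_tt", "I_tp")])
  note(apply(!is.finite(ints) | ints < 0, 1, any),
       "negative or non-numeric intensity")
  note(!df$probe_target %in% c("Tpm", "actin", "S1"), "unknown probe_target")
  note(!df$ca %in% c("high", "low"), "unknown ca level")
  note(!df$nucleotide %in% c("none", "ADP", "ATP"), "unknown nucleotide")
  note(is.na(df$s1_present), "s1_present not TRUE/FALSE")
  note(!is.na(df$s1_present) & df$probe_target == "S1" & !df$s1_present,
       "S1 probe requires s1_present")
  note(!is.na(df$s1_present) & df$nucleotide %in% c("ADP", "ATP") & !df$s1_present,
       "nucleotide state requires s1_present")
  if (length(bad) > 0)
    stop("invalid fiber CSV rows:\n", paste(unlist(bad), collapse = "\n"))
  df
}

#' Write a fiber intensity CSV
#'
#' @param records Data frame in the fiber CSV schema (see
#'   [read_fiber_csv()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fiber_csv <- function(records, path) {
  if (!all(fiber_csv_header %in% names(records)))
    stop("records lack required columns")
  utils::write.csv(records[fiber_csv_header], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

atpase_csv_header <- c("variant", "pCa", "replicate", "activity", "baseline")

#' Read an ATPase assay CSV
#'
#' Schema: `variant, pCa, replicate, activity, baseline` (baseline constant
#' within a variant).
#'
#' @param path CSV file path.
#' @return A data frame of assay records.
#' @export
read_atpase_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), atpase_csv_header))
    stop("bad ATPase CSV header; expected exactly: ",
         paste(atpase_csv_header, collapse = ", "))
  if (any(!is.finite(df$pCa)) || any(df$pCa < 4 | df$pCa > 9))
    stop("pCa values must be finite and within [4, 9]")
  if (any(!is.finite(df$activity))) stop("activities must be finite")
  df
}

#' Write an ATPase assay CSV
#'
#' @param records Data frame in the ATPase CSV schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_atpase_csv <- function(records, path) {
  if (!all(atpase_csv_header %in% names(records)))
    stop("records lack required columns")
  utils::write.csv(records[atpase_csv_header], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Loads (from YAML or JSON) or builds the configuration used by
#' [run_pipeline()].  Unknown keys are rejected.
#'
#' @param path Optional path to a YAML or JSON config file.
#' @param ... Named overrides of the defaults: `L` (m), `T` (K), `alpha`,
#'   `probe_gammas` (named list), `wobble`, `azimuth`,
#'   `reference_condition` (list with `ca`, `s1_present`, `nucleotide`),
#'   `signature_matrix` (path or NULL for the shipped one), `seed`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  defaults <- list(
    L = 1e-6, T = 293.15, alpha = 0.05,
    probe_gammas = list(Tpm = 17, actin = 14, S1 = 20),
    wobble = "uniform", azimuth = "independent",
    reference_condition = list(ca = "low", s1_present = FALSE,
                               nucleotide = "none"),
    signature_matrix = NULL,
    seed = 1L)
  user <- list(...)
  if (!is.null(path)) {
    parsed <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    user <- utils::modifyList(parsed, user)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  if (!is.null(cfg$signature_matrix) && !file.exists(cfg$signature_matrix))
    stop("signature_matrix file does not exist: ", cfg$signature_matrix)
  class(cfg) <- "run_config"
  cfg
}
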