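#' Names of the trinary signature features
#'
#' The 14 condition columns of the mutation-effect matrix: calcium
#' sensitivity of the ATPase, tropomyosin stiffness, and six high/low
#' calcium pairs describing the tropomyosin shift toward the inner actin
#' domain (induced by troponin or by S1), actin switching-on (by
#' tropomyosin or by S1), and strong binding of the myosin heads (without
#' and with ATP).
#'
#' @return Character vector of length 14.
#' @export
signature_features <- function() {
  c("ca_sens", "tpm_stiffness",
    "tn_shift_high", "tn_shift_low",
    "s1_shift_high", "s1_shift_low",
    "actin_on_tpm_high", "actin_on_tpm_low",
    "actin_on_s1_high", "actin_on_s1_low",
    "strong_high", "strong_low",
    "strong_atp_high", "strong_atp_low")
}

trinary_levels <- c("up", "down", "norm", "missing")

#' Trinary sign call for a mutant-vs-WT comparison
#'
#' Two-sample two-sided Student's t-test (equal variance by default).  If
#' `p < alpha` the call is `"up"` or `"down"` by the sign of the mean
#' difference (mutant minus wild type), otherwise `"norm"`.  Two
#' zero-variance samples with equal means give `"norm"`; with unequal means
#' they give a sign call with p reported as 0.
#'
#' @param mutant_values,wt_values Numeric samples with at least 2 values
#'   each.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Use the pooled-variance t-test (default TRUE); set
#'   FALSE for Welch.
#' @return `"up"`, `"down"` or `"norm"`, with attributes `p_value` and
#'   `delta` (mean difference).
#' @export
sign_call <- function(mutant_values, wt_values, alpha = 0.05,
                      var_equal = TRUE) {
  stopifnot(length(mutant_values) >= 2L, length(wt_values) >= 2L,
            alpha >= 0, alpha <= 1)
  delta <- mean(mutant_values) - mean(wt_values)
  if (stats::sd(mutant_values) == 0 && stats::sd(wt_values) == 0) {
    p <- if (delta == 0) 1 else 0
  } else {
    p <- stats::t.test(mutant_values, wt_values, var.equal = var_equal)$p.value
  }
  sign <- if (p < alpha && delta != 0) (if (delta > 0) "up" else "down") else "norm"
  structure(sign, p_value = p, delta = delta)
}

delta_key_cols <- c("probe_target", "ca", "nucleotide", "s1_present")
delta_parameters <- c("phi_e", "epsilon", "n")

#' Mutant-vs-WT delta table
#'
#' Builds, for every condition shared by the two groups and every available
#' parameter (`phi_e`, `epsilon`, `n`), the mean difference mutant minus
#' wild type with standard errors, a t-test p-value and a trinary sign
#' call.  Conditions present in only one group are reported in the
#' `"unmatched"` attribute, never silently dropped.
#'
#' @param mutant,wt Data frames of per-fiber parameter estimates with the
#'   key columns `probe_target`, `ca`, `nucleotide`, `s1_present` and
#'   parameter columns among `phi_e`, `epsilon`, `n` (NA where a parameter
#'   does not apply).
#' @param alpha Significance level for the sign calls.
#' @param var_equal Passed to [sign_call()].
#' @return A data frame of class `delta_table` with one row per shared
#'   condition and parameter: key columns, `parameter`, `delta`,
#'   `sem_mutant`, `sem_wt`, `p_value`, `sign`.
#' @export
delta_table <- function(mutant, wt, alpha = 0.05, var_equal = TRUE) {
  for (col in delta_key_cols) {
    if (!col %in% names(mutant) || !col %in% names(wt))
      stop("missing key column: ", col)
  }
  key <- function(df) do.call(paste, c(df[delta_key_cols], sep = "|"))
  mk <- key(mutant); wk <- key(wt)
  shared <- intersect(unique(mk), unique(wk))
  unmatched <- c(setdiff(unique(mk), shared), setdiff(unique(wk), shared))
  if (length(shared) == 0L) stop("no shared condition keys between mutant and WT")

  rows <- list()
  for (k in shared) {
    msub <- mutant[mk == k, , drop = FALSE]
    wsub <- wt[wk == k, , drop = FALSE]
    for (par in intersect(delta_parameters, intersect(names(mutant), names(wt)))) {
      mv <- msub[[par]]; wv <- wsub[[par]]
      mv <- mv[is.finite(mv)]; wv <- wv[is.finite(wv)]
      if (length(mv) < 2L || length(wv) < 2L) next
      s <- sign_call(mv, wv, alpha = alpha, var_equal = var_equal)
      rows[[length(rows) + 1L]] <- data.frame(
        msub[1L, delta_key_cols, drop = FALSE],
        parameter = par,
        delta = attr(s, "delta"),
        sem_mutant = stats::sd(mv) / sqrt(length(mv)),
        sem_wt = stats::sd(wv) / sqrt(length(wv)),
        p_value = attr(s, "p_value"),
        sign = as.character(s),
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "unmatched") <- unmatched
  if (length(unmatched) > 0)
    message("conditions without a counterpart: ", paste(unmatched, collapse = ", "))
  class(out) <- c("delta_table", "data.frame")
  out
}

#' Construct a myopathy signature
#'
#' @param features Named character vector over [signature_features()] with
#'   values `"up"`, `"down"`, `"norm"` or `"missing"`.
#' @param label Group label (default `"unassigned"`).
#' @param conflicts Character vector of logged feature conflicts.
#' @return An object of class `myopathy_signature`.
#' @export
myopathy_signature <- function(features, label = "unassigned",
                               conflicts = character(0)) {
  want <- signature_features()
  if (!all(want %in% names(features)))
    stop("features must be named over all of signature_features()")
  features <- features[want]
  if (!all(features %in% trinary_levels))
    stop("feature values must be one of: ", paste(trinary_levels, collapse = ", "))
  structure(list(features = features, label = label, conflicts = conflicts),
            class = "myopathy_signature")
}

#' @export
print.myopathy_signature <- function(x, ...) {
  cat(sprintf("<myopathy_signature> label = %s\n", x$label))
  print(x$features)
  if (length(x$conflicts)) cat("conflicts:", paste(x$conflicts, collapse = "; "), "\n")
  invisible(x)
}

flip_sign <- function(s) {
  ifelse(s == "up", "down", ifelse(s == "down", "up", s))
}

lookup_sign <- function(records, probe, ca, nuc, s1, parameter) {
  hit <- records$probe_target == probe & records$ca == ca &
    records$nucleotide == nuc & records$s1_present == s1 &
    records$parameter == parameter
  if (!any(hit)) return("missing")
  records$sign[which(hit)[1L]]
}

#' Derive a trinary myopathy signature from a delta table
#'
#' Deterministic mapping from mutant-vs-WT deltas to the 14 signature
#' features:
#' \itemize{
#'   \item calcium sensitivity: up/down when `pCa50_mut - pCa50_wt` exceeds
#'     +/-0.1 pCa units (and the reported standard errors do not overlap,
#'     when given), else norm;
#'   \item tropomyosin stiffness: sign of the tropomyosin `epsilon` delta
#'     without S1 at high calcium;
#'   \item tropomyosin shifts toward the inner actin domain: the *negated*
#'     tropomyosin `phi_e` sign (a drop in angle is a shift inward),
#'     without S1 (by troponin) or in the nucleotide-free S1 state (by S1);
#'   \item actin switching-on: sign of the actin `phi_e` delta, without S1
#'     (by tropomyosin) or with S1 (by S1);
#'   \item strong binding of the myosin heads: negated `phi_e` and negated
#'     `n` signs of the S1 probe must agree (both parameters drop when
#'     heads bind strongly); discordant evidence yields `"missing"` with a
#'     logged conflict.  Evaluated in the nucleotide-free state and, for
#'     the with-ATP columns, in the ATP state.
#' }
#'
#' @param records A [delta_table()].
#' @param pCa50_mut,pCa50_wt Fitted midpoints for the calcium-sensitivity
#'   feature (NA gives a missing feature).
#' @param se_mut,se_wt Optional standard errors of the midpoints.
#' @return A [myopathy_signature()].
#' @export
signature_from_deltas <- function(records, pCa50_mut = NA, pCa50_wt = NA,
                                  se_mut = NA, se_wt = NA) {
  feats <- stats::setNames(rep("missing", 14L), signature_features())
  conflicts <- character(0)

  if (is.finite(pCa50_mut) && is.finite(pCa50_wt)) {
    d <- pCa50_mut - pCa50_wt
    separated <- if (is.finite(se_mut) && is.finite(se_wt))
      abs(d) > (se_mut + se_wt) else TRUE
    feats["ca_sens"] <- if (d > 0.1 && separated) "up"
      else if (d < -0.1 && separated) "down" else "norm"
  }

  feats["tpm_stiffness"] <- lookup_sign(records, "Tpm", "high", "none", FALSE, "epsilon")

  for (ca in c("high", "low")) {
    feats[paste0("tn_shift_", ca)] <-
      flip_sign(lookup_sign(records, "Tpm", ca, "none", FALSE, "phi_e"))
    feats[paste0("s1_shift_", ca)] <-
      flip_sign(lookup_sign(records, "Tpm", ca, "none", TRUE, "phi_e"))
    feats[paste0("actin_on_tpm_", ca)] <-
      lookup_sign(records, "actin", ca, "none", FALSE, "phi_e")
    feats[paste0("actin_on_s1_", ca)] <-
      lookup_sign(records, "actin", ca, "none", TRUE, "phi_e")
    for (nuc in c("none", "ATP")) {
      feat <- if (nuc == "none") paste0("strong_", ca) else paste0("strong_atp_", ca)
      s_phi <- flip_sign(lookup_sign(records, "S1", ca, nuc, TRUE, "phi_e"))
      s_n <- flip_sign(lookup_sign(records, "S1", ca, nuc, TRUE, "n"))
      if (s_phi == "missing" || s_n == "missing") {
        feats[feat] <- "missing"
      } else if (s_phi == s_n) {
        feats[feat] <- s_phi
      } else {
        feats[feat] <- "missing"
        conflicts <- c(conflicts, sprintf(
          "%s: phi_E evidence '%s' contradicts N evidence '%s'", feat, s_phi, s_n))
      }
    }
  }
  myopathy_signature(feats, conflicts = conflicts)
}

#' Reference signature matrix
#'
#' Loads the versioned matrix of mutation signatures shipped with the
#' package: twelve literature rows (mutations in alpha-, beta- and
#' gamma-tropomyosin with their trinary feature calls) and four group
#' consensus rows encoding the defining strong-binding behaviour of the
#' CFTD, Cap, NM and DA groups.  The E139del row is also known as E139X.
#'
#' @param file Optional path to an alternative CSV with the same columns.
#' @param include_consensus Include the consensus rows (default TRUE).
#' @return A data frame with id, mutation, gene, diagnosis, group,
#'   is_consensus and the 14 feature columns.
#' @export
myopathy_references <- function(file = NULL, include_consensus = TRUE) {
  if (is.null(file))
    file <- system.file("extdata", "tpm_mutation_signatures.csv",
                        package = "fiberpol")
  refs <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("id", "group", "is_consensus", signature_features())
  if (!all(need %in% names(refs)))
    stop("reference file lacks required columns")
  if (!include_consensus) refs <- refs[!refs$is_consensus, , drop = FALSE]
  refs
}

#' Classify a signature against the reference matrix
#'
#' Nearest reference by Hamming distance over the features that are
#' non-missing in both the query and the reference, normalized by the
#' number of compared features.  References sharing no feature with the
#' query are skipped.  The returned label is the group of the nearest
#' labelled reference; a tie flag is raised when the best references of two
#' different groups are within one feature (out of the 14) of each other.
#'
#' @param sig A [myopathy_signature()].
#' @param references A reference data frame from [myopathy_references()].
#' @param exclude Character vector of reference ids to leave out (e.g. to
#'   ask for the nearest *other* mutation).
#' @return A list with `label`, `distance` (normalized, of the winner),
#'   `tie` (logical) and `distances` (data frame sorted by distance with
#'   id, group, n_compared, mismatches, distance).
#' @export
classify_signature <- function(sig, references = myopathy_references(),
                               exclude = NULL) {
  stopifnot(inherits(sig, "myopathy_signature"))
  if (all(sig$features == "missing"))
    stop("cannot classify: all signature features are missing")
  refs <- references[!references$id %in% exclude, , drop = FALSE]
  if (nrow(refs) == 0L) stop("reference set is empty")

  res <- lapply(seq_len(nrow(refs)), function(i) {
    rv <- unlist(refs[i, signature_features()], use.names = FALSE)
    ok <- sig$features != "missing" & rv != "missing"
    n_cmp <- sum(ok)
    mism <- if (n_cmp == 0L) NA_integer_ else sum(sig$features[ok] != rv[ok])
    data.frame(id = refs$id[i], group = refs$group[i], n_compared = n_cmp,
               mismatches = mism,
               distance = if (n_cmp == 0L) NA_real_ else mism / n_cmp)
  })
  dist_df <- do.call(rbind, res)
  dist_df <- dist_df[!is.na(dist_df$distance), , drop = FALSE]
  if (nrow(dist_df) == 0L) stop("no reference shares a feature with the signature")
  dist_df <- dist_df[order(dist_df$distance, -dist_df$n_compared), , drop = FALSE]

  labelled <- dist_df[dist_df$group != "unassigned", , drop = FALSE]
  if (nrow(labelled) == 0L) stop("no labelled reference available")
  label <- labelled$group[1L]

  group_best <- stats::aggregate(distance ~ group, data = labelled, FUN = min)
  group_best <- group_best[order(group_best$distance), , drop = FALSE]
  tie <- nrow(group_best) >= 2L &&
    (group_best$distance[2L] - group_best$distance[1L]) * 14 <= 1

  list(label = label, distance = labelled$distance[1L], tie = tie,
       distances = dist_df)
}
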