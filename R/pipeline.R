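condition_label <- function(df) {
  paste(df$probe_target, df$ca, df$nucleotide,
        ifelse(df$s1_present, "S1", "noS1"), sep = "|")
}

# Per-fiber parameter table for one variant: orientation parameters per
# fiber plus epsilon for filament-attached probes (Tpm, actin).  theta_half
# estimates below 0.5 degrees give no usable stiffness (epsilon diverges)
# and are recorded as NA.
fit_variant_fibers <- function(fibers, cfg, log) {
  out <- list()
  keys <- unique(fibers[c("probe_target", "ca", "nucleotide", "s1_present")])
  for (i in seq_len(nrow(keys))) {
    key <- keys[i, ]
    sub <- merge(fibers, key)
    probe_name <- c(Tpm = "AF-Tpm", actin = "FITC-actin",
                    S1 = "AEDANS-S1")[[key$probe_target]]
    probe <- probe_geometry(probe_name,
                            gamma = cfg$probe_gammas[[key$probe_target]])
    qs <- lapply(seq_len(nrow(sub)), function(j)
      as.numeric(sub[j, c("I_pp", "I_pt", "I_tt", "I_tp")]))
    ens <- fit_ensemble(qs, probe,
                        fit_settings(quadrature = quadrature_settings(
                          wobble = cfg$wobble, azimuth = cfg$azimuth)))
    if (ens$n_failed > 0)
      log$add(sprintf("%s: %d fiber fit(s) failed and were excluded",
                      condition_label(key), ens$n_failed))
    for (f in ens$per_fiber) {
      if (f$degenerate)
        log$add(sprintf("%s: degenerate fit flagged", condition_label(key)))
    }
    pars <- t(vapply(ens$per_fiber, function(f)
      c(f$estimate$phi_e, f$estimate$n, f$estimate$theta_half), numeric(3)))
    eps <- rep(NA_real_, nrow(pars))
    if (key$probe_target %in% c("Tpm", "actin")) {
      ok <- pars[, 3] > 0.5
      if (any(!ok))
        log$add(sprintf("%s: %d fiber(s) with theta_half < 0.5 deg excluded from stiffness",
                        condition_label(key), sum(!ok)))
      eps[ok] <- vapply(pars[ok, 3], function(th)
        stiffness_from_theta(th, L = cfg$L, T = cfg$T)$epsilon_1e26, numeric(1))
    }
    out[[i]] <- data.frame(key, row.names = NULL,
                           fiber = seq_len(nrow(pars)),
                           phi_e = pars[, 1], n = pars[, 2],
                           theta_half = pars[, 3], epsilon = eps)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

summarize_conditions <- function(per_fiber) {
  keys <- unique(per_fiber[c("probe_target", "ca", "nucleotide", "s1_present")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- merge(per_fiber, keys[i, ])
    sem <- function(x) if (sum(is.finite(x)) >= 2)
      stats::sd(x, na.rm = TRUE) / sqrt(sum(is.finite(x))) else NA_real_
    data.frame(keys[i, ], row.names = NULL, n_fibers = nrow(sub),
               phi_e = mean(sub$phi_e), phi_e_sem = sem(sub$phi_e),
               n = mean(sub$n), n_sem = sem(sub$n),
               theta_half = mean(sub$theta_half),
               epsilon = mean(sub$epsilon, na.rm = TRUE),
               epsilon_sem = sem(sub$epsilon))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# Tropomyosin emission angles expressed in the rotating F-actin frame.
correct_tpm_angles <- function(summary_df, cfg, log) {
  ref_cond <- cfg$reference_condition
  ref_row <- summary_df$probe_target == "actin" &
    summary_df$ca == ref_cond$ca &
    summary_df$s1_present == ref_cond$s1_present &
    summary_df$nucleotide == ref_cond$nucleotide
  if (!any(ref_row)) {
    log$add("actin reference condition absent: corrected phi_E skipped")
    return(NULL)
  }
  actin_ref <- summary_df$phi_e[which(ref_row)[1L]]
  tpm <- summary_df[summary_df$probe_target == "Tpm", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(tpm))) {
    match_actin <- summary_df$probe_target == "actin" &
      summary_df$ca == tpm$ca[i] &
      summary_df$s1_present == tpm$s1_present[i] &
      summary_df$nucleotide == tpm$nucleotide[i]
    if (!any(match_actin)) {
      log$add(sprintf("no matching actin condition for %s: not corrected",
                      condition_label(tpm[i, ])))
      next
    }
    corr <- corrected_phi_e(tpm$phi_e[i],
                            summary_df$phi_e[which(match_actin)[1L]],
                            actin_ref)
    out[[length(out) + 1L]] <- data.frame(
      tpm[i, c("probe_target", "ca", "nucleotide", "s1_present")],
      row.names = NULL,
      phi_e_observed = tpm$phi_e[i], phi_e_corrected = as.numeric(corr),
      clamped = attr(corr, "clamped"))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the analysis on a fiber dataset (and optionally an ATPase
#' dataset): per-condition ensemble orientation fits for every variant,
#' bending stiffness for the filament-attached probes, actin-frame
#' correction of the tropomyosin angles, Hill fits of the ATPase curves,
#' mutant-versus-wild-type delta tables, trinary signatures and myopathy
#' classification.  Every decision (excluded fibers, flagged fits, feature
#' conflicts, skipped stages) is recorded in the report log.  The report
#' contains no timestamp, so identical inputs give byte-identical output.
#'
#' @param fiber_csv Path to a fiber CSV ([read_fiber_csv()] schema) or a
#'   data frame in that schema.
#' @param atpase_csv Optional path to an ATPase CSV
#'   ([read_atpase_csv()] schema) or a data frame.
#' @param config A [run_config()] (or NULL for defaults).
#' @param wt_variant Name of the wild-type variant (default "WT").
#' @param out_file Optional path: the report is written there as JSON.
#' @return The report, an object of class `fiberpol_report` (a list).
#' @export
run_pipeline <- function(fiber_csv, atpase_csv = NULL, config = NULL,
                         wt_variant = "WT", out_file = NULL) {
  cfg <- if (is.null(config)) run_config() else config
  fibers <- if (is.character(fiber_csv)) read_fiber_csv(fiber_csv) else fiber_csv
  log_lines <- character(0)
  log <- list(add = function(msg) log_lines <<- c(log_lines, msg))

  variants <- unique(fibers$variant)
  if (!wt_variant %in% variants)
    stop("pipeline stage 'fit': wild-type variant '", wt_variant,
         "' absent from fiber data")

  per_fiber <- list(); summaries <- list(); corrected <- list()
  for (v in variants) {
    pf <- tryCatch(
      fit_variant_fibers(fibers[fibers$variant == v, , drop = FALSE], cfg, log),
      error = function(e) stop("pipeline stage 'fit' (variant ", v, "): ",
                               conditionMessage(e)))
    per_fiber[[v]] <- pf
    summaries[[v]] <- summarize_conditions(pf)
    corrected[[v]] <- correct_tpm_angles(summaries[[v]], cfg, log)
  }

  hill <- NULL
  if (!is.null(atpase_csv)) {
    atp <- if (is.character(atpase_csv)) read_atpase_csv(atpase_csv) else atpase_csv
    hill <- list()
    for (v in unique(atp$variant)) {
      sub <- atp[atp$variant == v, , drop = FALSE]
      curve <- atpase_curve(sub$pCa, sub$activity,
                            baseline = sub$baseline[1L])
      hf <- tryCatch(fit_hill(normalize_activity(curve)),
                     error = function(e) {
                       log$add(sprintf("Hill fit failed for %s: %s", v,
                                       conditionMessage(e)))
                       NULL
                     })
      if (!is.null(hf) && hf$at_bound)
        log$add(sprintf("Hill fit for %s at a parameter bound", v))
      hill[[v]] <- hf
    }
  }

  mutants <- setdiff(variants, wt_variant)
  deltas <- list(); signatures <- list(); classifications <- list()
  if (length(mutants) == 0L) {
    log$add("only the wild type present: delta table empty, classification skipped")
  } else {
    refs <- myopathy_references(file = cfg$signature_matrix)
    for (v in mutants) {
      dt <- delta_table(per_fiber[[v]], per_fiber[[wt_variant]],
                        alpha = cfg$alpha)
      deltas[[v]] <- dt
      p_mut <- if (!is.null(hill[[v]])) hill[[v]]$pCa50 else NA
      p_wt <- if (!is.null(hill[[wt_variant]])) hill[[wt_variant]]$pCa50 else NA
      se_mut <- if (!is.null(hill[[v]])) hill[[v]]$se[["se_pCa50"]] else NA
      se_wt <- if (!is.null(hill[[wt_variant]]))
        hill[[wt_variant]]$se[["se_pCa50"]] else NA
      sig <- signature_from_deltas(dt, p_mut, p_wt, se_mut, se_wt)
      for (cf in sig$conflicts) log$add(sprintf("%s: %s", v, cf))
      signatures[[v]] <- sig
      classifications[[v]] <- classify_signature(sig, references = refs)
    }
  }

  report <- structure(list(
    config = unclass(cfg),
    variants = variants,
    ensembles = summaries,
    corrected_phi_e = corrected,
    hill = lapply(hill, function(h) if (is.null(h)) NULL else
      h[c("pCa50", "n_h", "floor", "amplitude", "se", "at_bound", "ssr")]),
    deltas = lapply(deltas, as.data.frame),
    signatures = lapply(signatures, function(s)
      list(features = as.list(s$features), label = s$label)),
    classifications = lapply(classifications, function(cl)
      list(label = cl$label, distance = cl$distance, tie = cl$tie,
           distances = cl$distances)),
    log = log_lines), class = "fiberpol_report")

  if (!is.null(out_file))
    jsonlite::write_json(unclass(report), out_file, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  report
}

#' @export
print.fiberpol_report <- function(x, ...) {
  cat("<fiberpol_report>\n variants:", paste(x$variants, collapse = ", "), "\n")
  for (v in names(x$classifications))
    cat(sprintf(" %s -> %s (distance %.3f%s)\n", v, x$classifications[[v]]$label,
                x$classifications[[v]]$distance,
                if (x$classifications[[v]]$tie) ", tie" else ""))
  if (length(x$log)) cat(" log entries:", length(x$log), "\n")
  invisible(x)
}
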