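probe_for_target <- function(target) {
  switch(target,
         Tpm = probe_geometry("AF-Tpm"),
         actin = probe_geometry("FITC-actin"),
         S1 = probe_geometry("AEDANS-S1"),
         stop("unknown probe target: ", target))
}

# Wild-type truth table for the default scenario.  Emission angles and
# bending stiffnesses anchor on the values printed for gamma-tropomyosin
# thin filaments (AF-Tpm corrected 54.2/54.7 and 56.7/58.6 degrees,
# epsilon 13.9 -> 16.1 -> 7.5 x 1e-26 N m^2; FITC-actin 48.4 -> 47.5
# degrees, 4.2 -> 5.5 x 1e-26; AEDANS-S1 44.7 -> 51.2 degrees with
# N 0.393/0.432 -> 0.576).  Values not printed (ADP intermediates, low-Ca
# actin stiffness, disordered fractions of the Tpm/actin probes) are
# realistic interpolations documented in the vignette.
wt_truth_states <- function() {
  df <- function(...) data.frame(..., stringsAsFactors = FALSE)
  rbind(
    # probe on tropomyosin (5-IAF, gamma 17): phi_e observed (lab frame)
    df(probe_target = "Tpm", ca = "high", nucleotide = "none", s1_present = FALSE,
       phi_e = 58.3, n = 0.20, epsilon_1e26 = 13.9, theta_half = NA),
    df(probe_target = "Tpm", ca = "low", nucleotide = "none", s1_present = FALSE,
       phi_e = 58.6, n = 0.20, epsilon_1e26 = 12.0, theta_half = NA),
    df(probe_target = "Tpm", ca = "high", nucleotide = "none", s1_present = TRUE,
       phi_e = 56.1, n = 0.20, epsilon_1e26 = 16.1, theta_half = NA),
    df(probe_target = "Tpm", ca = "low", nucleotide = "none", s1_present = TRUE,
       phi_e = 55.5, n = 0.20, epsilon_1e26 = 14.5, theta_half = NA),
    df(probe_target = "Tpm", ca = "high", nucleotide = "ADP", s1_present = TRUE,
       phi_e = 56.5, n = 0.20, epsilon_1e26 = 12.0, theta_half = NA),
    df(probe_target = "Tpm", ca = "low", nucleotide = "ADP", s1_present = TRUE,
       phi_e = 55.8, n = 0.20, epsilon_1e26 = 13.0, theta_half = NA),
    df(probe_target = "Tpm", ca = "high", nucleotide = "ATP", s1_present = TRUE,
       phi_e = 55.8, n = 0.20, epsilon_1e26 = 7.5, theta_half = NA),
    df(probe_target = "Tpm", ca = "low", nucleotide = "ATP", s1_present = TRUE,
       phi_e = 56.2, n = 0.20, epsilon_1e26 = 8.5, theta_half = NA),
    # probe on actin (FITC-phalloidin, gamma 14)
    df(probe_target = "actin", ca = "high", nucleotide = "none", s1_present = FALSE,
       phi_e = 48.0, n = 0.15, epsilon_1e26 = 4.6, theta_half = NA),
    df(probe_target = "actin", ca = "low", nucleotide = "none", s1_present = FALSE,
       phi_e = 46.5, n = 0.15, epsilon_1e26 = 5.4, theta_half = NA),
    df(probe_target = "actin", ca = "high", nucleotide = "none", s1_present = TRUE,
       phi_e = 48.4, n = 0.15, epsilon_1e26 = 4.2, theta_half = NA),
    df(probe_target = "actin", ca = "low", nucleotide = "none", s1_present = TRUE,
       phi_e = 47.3, n = 0.15, epsilon_1e26 = 4.8, theta_half = NA),
    df(probe_target = "actin", ca = "high", nucleotide = "ADP", s1_present = TRUE,
       phi_e = 48.0, n = 0.15, epsilon_1e26 = 4.7, theta_half = NA),
    df(probe_target = "actin", ca = "low", nucleotide = "ADP", s1_present = TRUE,
       phi_e = 47.0, n = 0.15, epsilon_1e26 = 5.0, theta_half = NA),
    df(probe_target = "actin", ca = "high", nucleotide = "ATP", s1_present = TRUE,
       phi_e = 47.5, n = 0.15, epsilon_1e26 = 5.5, theta_half = NA),
    df(probe_target = "actin", ca = "low", nucleotide = "ATP", s1_present = TRUE,
       phi_e = 46.8, n = 0.15, epsilon_1e26 = 5.6, theta_half = NA),
    # probe on the myosin head (1,5-IAEDANS, gamma 20); wobble fixed at 25 deg
    df(probe_target = "S1", ca = "high", nucleotide = "none", s1_present = TRUE,
       phi_e = 44.7, n = 0.393, epsilon_1e26 = NA, theta_half = 25),
    df(probe_target = "S1", ca = "low", nucleotide = "none", s1_present = TRUE,
       phi_e = 45.5, n = 0.432, epsilon_1e26 = NA, theta_half = 25),
    df(probe_target = "S1", ca = "high", nucleotide = "ADP", s1_present = TRUE,
       phi_e = 46.5, n = 0.45, epsilon_1e26 = NA, theta_half = 25),
    df(probe_target = "S1", ca = "low", nucleotide = "ADP", s1_present = TRUE,
       phi_e = 47.0, n = 0.48, epsilon_1e26 = NA, theta_half = 25),
    df(probe_target = "S1", ca = "high", nucleotide = "ATP", s1_present = TRUE,
       phi_e = 51.2, n = 0.576, epsilon_1e26 = NA, theta_half = 25),
    df(probe_target = "S1", ca = "low", nucleotide = "ATP", s1_present = TRUE,
       phi_e = 51.2, n = 0.576, epsilon_1e26 = NA, theta_half = 25))
}

# Per-mutant trinary effect structure (sign columns of the reference
# matrix) and illustrative magnitudes: tropomyosin phi_E shifts 1.5 deg,
# actin phi_E 1.2 deg, S1 phi_E 2 deg with N 0.06, tropomyosin epsilon
# 5 x 1e-26 N m^2 (the scale of the printed halving, 12.2 -> 6.8).
mutant_effect_table <- function() {
  list(
    E173A = list(pCa50 = 6.84, stiff = -1,
                 tn = c(high = 1, low = 1), s1s = c(high = 1, low = 1),
                 swt = c(high = 1, low = 1), sws = c(high = 1, low = 1),
                 sb = c(high = 1, low = 1), sba = c(high = 1, low = 1)),
    R90P = list(pCa50 = 6.92, stiff = 1,
                tn = c(high = 1, low = 1), s1s = c(high = -1, low = 1),
                swt = c(high = -1, low = 1), sws = c(high = -1, low = -1),
                sb = c(high = 1, low = 1), sba = c(high = -1, low = 1)),
    E150A = list(pCa50 = 7.33, stiff = -1,
                 tn = c(high = -1, low = 1), s1s = c(high = 1, low = 1),
                 swt = c(high = 1, low = 1), sws = c(high = 1, low = 1),
                 sb = c(high = 1, low = 1), sba = c(high = -1, low = 1)),
    A155T = list(pCa50 = 6.69, stiff = -1,
                 tn = c(high = 0, low = 0), s1s = c(high = 1, low = 1),
                 swt = c(high = 0, low = 0), sws = c(high = 1, low = 1),
                 sb = c(high = -1, low = 1), sba = c(high = -1, low = 1)))
}

apply_mutant_effects <- function(states, eff) {
  for (ca in c("high", "low")) {
    tpm_nos1 <- states$probe_target == "Tpm" & states$ca == ca & !states$s1_present
    tpm_s1 <- states$probe_target == "Tpm" & states$ca == ca & states$s1_present
    act_nos1 <- states$probe_target == "actin" & states$ca == ca & !states$s1_present
    act_s1 <- states$probe_target == "actin" & states$ca == ca & states$s1_present
    s1_rigor <- states$probe_target == "S1" & states$ca == ca &
      states$nucleotide %in% c("none", "ADP")
    s1_atp <- states$probe_target == "S1" & states$ca == ca &
      states$nucleotide == "ATP"
    # shift toward the inner actin domain = drop in tropomyosin phi_E
    states$phi_e[tpm_nos1] <- states$phi_e[tpm_nos1] - 1.5 * eff$tn[[ca]]
    states$phi_e[tpm_s1] <- states$phi_e[tpm_s1] - 1.5 * eff$s1s[[ca]]
    states$phi_e[act_nos1] <- states$phi_e[act_nos1] + 1.2 * eff$swt[[ca]]
    states$phi_e[act_s1] <- states$phi_e[act_s1] + 1.2 * eff$sws[[ca]]
    # more strongly bound heads = lower phi_E and lower N of the S1 probe
    states$phi_e[s1_rigor] <- states$phi_e[s1_rigor] - 2 * eff$sb[[ca]]
    states$n[s1_rigor] <- states$n[s1_rigor] - 0.06 * eff$sb[[ca]]
    states$phi_e[s1_atp] <- states$phi_e[s1_atp] - 2 * eff$sba[[ca]]
    states$n[s1_atp] <- states$n[s1_atp] - 0.06 * eff$sba[[ca]]
  }
  tpm <- states$probe_target == "Tpm"
  states$epsilon_1e26[tpm] <- states$epsilon_1e26[tpm] + 5 * eff$stiff
  states
}

#' Default synthetic scenario
#'
#' A fully specified synthetic experiment emulating the ghost-fiber study
#' design: for each tropomyosin variant, true orientation states for the
#' three probes (tropomyosin, actin, myosin head) across the condition grid
#' (high/low calcium; without S1; with S1 in the nucleotide-free, ADP and
#' ATP states), true bending stiffnesses, and a true pCa50 and Hill
#' coefficient for the ATPase assay.  Mutant variants perturb the wild-type
#' truth following the trinary effect structure of the reference matrix.
#'
#' @param variants Subset of `c("WT", "E173A", "R90P", "E150A", "A155T")`.
#' @param n_fibers Fibers per condition (default 10, the upper end of the
#'   8-10 fibers used per experimental condition).
#' @param cv Multiplicative noise coefficient of variation per intensity
#'   component (default 0.02).
#' @param L,T Filament length (m) and temperature (K) used to convert truth
#'   stiffness to wobble angles.
#' @return An object of class `scenario_table` with elements `states`
#'   (truth data frame), `atpase` (variant, pCa50, n_h), `n_fibers`, `cv`,
#'   `L`, `T`.
#' @export
default_scenario <- function(variants = c("WT", "E173A", "R90P", "E150A", "A155T"),
                             n_fibers = 10L, cv = 0.02, L = 1e-6, T = 293.15) {
  stopifnot(n_fibers >= 1L, cv >= 0)
  effects <- mutant_effect_table()
  known <- c("WT", names(effects))
  if (!all(variants %in% known))
    stop("unknown variant(s): ", paste(setdiff(variants, known), collapse = ", "))
  states <- list(); atp <- list()
  for (v in variants) {
    st <- wt_truth_states()
    p50 <- 6.5
    if (v != "WT") {
      st <- apply_mutant_effects(st, effects[[v]])
      p50 <- effects[[v]]$pCa50
    }
    st <- cbind(variant = v, st, stringsAsFactors = FALSE)
    states[[v]] <- st
    atp[[v]] <- data.frame(variant = v, pCa50 = p50, n_h = 1.5,
                           stringsAsFactors = FALSE)
  }
  states <- do.call(rbind, c(states, make.row.names = FALSE))
  # resolve wobble angles from truth stiffness where given
  need <- is.na(states$theta_half)
  states$theta_half[need] <- vapply(states$epsilon_1e26[need], function(e)
    theta_from_stiffness(e * 1e-26, L = L, T = T), numeric(1))
  structure(list(states = states,
                 atpase = do.call(rbind, c(atp, make.row.names = FALSE)),
                 n_fibers = as.integer(n_fibers), cv = cv, L = L, T = T),
            class = "scenario_table")
}

#' @export
print.scenario_table <- function(x, ...) {
  cat(sprintf("<scenario_table> %d truth states, %d variants, %d fibers/condition, CV %.3g\n",
              nrow(x$states), length(unique(x$states$variant)), x$n_fibers, x$cv))
  invisible(x)
}

#' Generate a synthetic fiber dataset
#'
#' For every truth state of the scenario, evaluates the forward model and
#' draws `n_fibers` intensity quadruples with independent multiplicative
#' lognormal noise per component (unit mean, coefficient of variation
#' `cv`).  Output is deterministic under (`scenario`, `seed`).
#'
#' @param scenario A [default_scenario()]-style `scenario_table`.
#' @param seed Integer seed controlling all randomness.
#' @param n_fibers,cv Optional overrides of the scenario values.
#' @return A list with `fibers` (data frame in the fiber CSV schema:
#'   fiber_id, variant, probe_target, ca, nucleotide, s1_present, I_pp,
#'   I_pt, I_tt, I_tp) and `truth` (the scenario state table).
#' @export
generate_fiber_dataset <- function(scenario, seed,
                                   n_fibers = scenario$n_fibers,
                                   cv = scenario$cv) {
  stopifnot(inherits(scenario, "scenario_table"))
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -sdlog^2 / 2  # unit-mean lognormal
  rows <- vector("list", nrow(scenario$states) * n_fibers)
  k <- 0L
  for (i in seq_len(nrow(scenario$states))) {
    st <- scenario$states[i, ]
    probe <- probe_for_target(st$probe_target)
    state <- tryCatch(
      orientation_state(phi_e = st$phi_e, n = st$n,
                        theta_half = st$theta_half, gamma = probe$gamma),
      error = function(e) stop(
        "infeasible truth state for condition ",
        paste(st$variant, st$probe_target, st$ca, st$nucleotide, sep = "/"),
        ": ", conditionMessage(e)))
    q0 <- as.numeric(normalize_quadruple(model_quadruple(state, probe))) * 1000
    for (f in seq_len(n_fibers)) {
      noise <- if (cv > 0) stats::rlnorm(4, meanlog, sdlog) else rep(1, 4)
      q <- q0 * noise
      k <- k + 1L
      rows[[k]] <- data.frame(
        fiber_id = sprintf("%s_%s_%s_%s_%s_f%02d", st$variant, st$probe_target,
                           st$ca, st$nucleotide,
                           if (st$s1_present) "S1" else "noS1", f),
        variant = st$variant, probe_target = st$probe_target, ca = st$ca,
        nucleotide = st$nucleotide, s1_present = st$s1_present,
        I_pp = q[1], I_pt = q[2], I_tt = q[3], I_tp = q[4],
        stringsAsFactors = FALSE)
    }
  }
  list(fibers = do.call(rbind, c(rows, make.row.names = FALSE)),
       truth = scenario$states)
}

#' Generate a synthetic ATPase assay
#'
#' Hill-shaped activity over the pCa grid 8 to 4 in steps of 0.25 (floor 0,
#' amplitude 1), replicated, with additive Gaussian noise and a constant
#' S1-alone baseline added so that the normalization step has real work to
#' do.  Deterministic under `seed`.
#'
#' @param pCa50 True midpoint, in \[4, 8\].
#' @param n_h True Hill coefficient (default 1.5, typical thin-filament
#'   cooperativity).
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0).
#' @param n_replicates Replicates per pCa point (default 3).
#' @param seed Integer seed.
#' @param baseline Constant baseline activity added to every measurement.
#' @return An [atpase_curve()] (un-normalized, baseline attribute set).
#' @export
generate_atpase_assay <- function(pCa50, n_h = 1.5, noise_sd = 0.03,
                                  n_replicates = 3L, seed = 1L,
                                  baseline = 0.1) {
  stopifnot(pCa50 >= 4, pCa50 <= 8, noise_sd >= 0, n_replicates >= 1L)
  set.seed(as.integer(seed))
  grid <- seq(8, 4, by = -0.25)
  pCa <- rep(grid, times = n_replicates)
  activity <- baseline + hill_model(pCa, pCa50, n_h) +
    stats::rnorm(length(pCa), 0, noise_sd)
  atpase_curve(pCa, activity, baseline = baseline)
}
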