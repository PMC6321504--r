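# Deterministic per-fiber parameter tables over the condition grid used by
# the signature map.  `effects` maps "probe|ca|nuc|s1" to named offsets
# applied to the mutant means; a fixed jitter vector gives every sample a
# small nonzero variance without randomness.
grid_conditions <- function() {
  rbind(
    expand.grid(probe_target = "Tpm", ca = c("high", "low"),
                nucleotide = "none", s1_present = c(FALSE, TRUE),
                stringsAsFactors = FALSE),
    expand.grid(probe_target = "actin", ca = c("high", "low"),
                nucleotide = "none", s1_present = c(FALSE, TRUE),
                stringsAsFactors = FALSE),
    expand.grid(probe_target = "S1", ca = c("high", "low"),
                nucleotide = c("none", "ATP"), s1_present = TRUE,
                stringsAsFactors = FALSE))
}

make_fiber_params <- function(effects = list(), n_fibers = 5) {
  conds <- grid_conditions()
  jitter <- seq(-0.02, 0.02, length.out = n_fibers)
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    key <- conds[i, ]
    base <- c(phi_e = 50, epsilon = if (key$probe_target == "S1") NA else 10,
              n = 0.4)
    tag <- paste(key$probe_target, key$ca, key$nucleotide, key$s1_present,
                 sep = "|")
    off <- effects[[tag]]
    for (nm in names(off)) base[nm] <- base[nm] + off[[nm]]
    data.frame(key, fiber = seq_len(n_fibers),
               phi_e = base[["phi_e"]] + jitter,
               epsilon = base[["epsilon"]] + jitter,
               n = base[["n"]] + jitter / 10, row.names = NULL)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
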