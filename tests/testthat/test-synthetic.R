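test_that("the generator is deterministic under (scenario, seed)", {
  sc <- default_scenario(c("WT", "A155T"), n_fibers = 3L)
  d1 <- generate_fiber_dataset(sc, seed = 42)
  d2 <- generate_fiber_dataset(sc, seed = 42)
  expect_identical(d1, d2)
  d3 <- generate_fiber_dataset(sc, seed = 43)
  expect_false(identical(d1$fibers$I_pp, d3$fibers$I_pp))

  a1 <- generate_atpase_assay(6.5, seed = 5)
  a2 <- generate_atpase_assay(6.5, seed = 5)
  expect_identical(a1, a2)
})

test_that("zero noise reproduces the forward model exactly", {
  sc <- default_scenario("WT", n_fibers = 2L, cv = 0)
  ds <- generate_fiber_dataset(sc, seed = 1)
  row <- ds$fibers[ds$fibers$probe_target == "S1" & ds$fibers$ca == "high" &
                     ds$fibers$nucleotide == "none", ][1, ]
  st <- orientation_state(44.7, 0.393, 25, gamma = 20)
  q <- as.numeric(normalize_quadruple(model_quadruple(st, aedans))) * 1000
  expect_equal(as.numeric(row[c("I_pp", "I_pt", "I_tt", "I_tp")]), q,
               tolerance = 1e-12)

  a <- generate_atpase_assay(6.69, noise_sd = 0, seed = 1)
  expect_equal(a$activity, 0.1 + hill_model(a$pCa, 6.69, 1.5))
})

test_that("empirical noise matches the configured coefficient of variation", {
  sc <- default_scenario("WT", n_fibers = 1L)
  sc$states <- sc$states[1, ]
  ds <- generate_fiber_dataset(sc, seed = 8, n_fibers = 10000L)
  for (comp in c("I_pp", "I_pt", "I_tt", "I_tp")) {
    x <- ds$fibers[[comp]]
    expect_lt(abs(sd(x) / mean(x) - 0.02) / 0.02, 0.05)
  }
})

test_that("the default scenario covers every condition the signature map reads", {
  sc <- default_scenario("WT")
  key <- with(sc$states, paste(probe_target, ca, nucleotide, s1_present))
  needed <- c(t(outer(c("Tpm|none|FALSE", "Tpm|none|TRUE", "actin|none|FALSE",
                        "actin|none|TRUE", "S1|none|TRUE", "S1|ATP|TRUE"),
                      c("high", "low"), paste, sep = "@")))
  needed <- vapply(strsplit(needed, "@"), function(x) {
    p <- strsplit(x[1], "|", fixed = TRUE)[[1]]
    paste(p[1], x[2], p[2], p[3])
  }, character(1))
  for (nd in needed) expect_true(nd %in% key, label = nd)
})

test_that("mutant scenarios preserve feasibility and shift the truth as declared", {
  sc <- default_scenario()
  expect_true(all(sc$states$n >= 0 & sc$states$n <= 1))
  expect_true(all(sc$states$phi_e > 0 & sc$states$phi_e < 90))
  expect_true(all(is.na(sc$states$epsilon_1e26) | sc$states$epsilon_1e26 > 0))
  wt <- sc$states[sc$states$variant == "WT", ]
  mt <- sc$states[sc$states$variant == "A155T", ]
  pick <- function(df, p, ca, nuc) df[df$probe_target == p & df$ca == ca &
                                        df$nucleotide == nuc & df$s1_present, ]
  # strong binding down at high calcium: S1 angle and N up
  expect_gt(pick(mt, "S1", "high", "none")$phi_e,
            pick(wt, "S1", "high", "none")$phi_e)
  # ... but up at low calcium: S1 angle and N down
  expect_lt(pick(mt, "S1", "low", "none")$n, pick(wt, "S1", "low", "none")$n)
  # troponin-induced tropomyosin shift unchanged
  expect_equal(mt$phi_e[mt$probe_target == "Tpm" & !mt$s1_present],
               wt$phi_e[wt$probe_target == "Tpm" & !wt$s1_present])
})

test_that("an infeasible truth state names the offending condition", {
  sc <- default_scenario("WT", n_fibers = 1L)
  sc$states$n[1] <- 2
  expect_error(generate_fiber_dataset(sc, seed = 1), "infeasible truth state")
})
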