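test_that("sign calls follow the two-sample t-test", {
  x <- c(54.2, 54.25, 54.15, 54.22)
  expect_identical(as.character(sign_call(x, x)), "norm")

  mut <- 51.2 + seq(-0.1, 0.1, length.out = 10)
  wt <- 54.2 + seq(-0.1, 0.1, length.out = 10)
  s <- sign_call(mut, wt)
  expect_identical(as.character(s), "down")
  expect_lt(attr(s, "p_value"), 1e-10)

  # borderline case checked against the textbook pooled-variance formulas
  a <- c(1.1, 1.3, 0.9, 1.2); b <- c(1.0, 0.8, 1.1, 0.95)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  p_hand <- 2 * pt(-abs(t_stat), df = length(a) + length(b) - 2)
  s2 <- sign_call(a, b)
  expect_equal(attr(s2, "p_value"), p_hand, tolerance = 1e-12)
  expect_identical(as.character(s2), if (p_hand < 0.05 && mean(a) > mean(b))
    "up" else "norm")
})

test_that("zero-variance samples resolve deterministically", {
  expect_identical(as.character(sign_call(rep(1, 3), rep(1, 4))), "norm")
  s <- sign_call(rep(2, 3), rep(1, 4))
  expect_identical(as.character(s), "up")
  expect_equal(attr(s, "p_value"), 0)
})

test_that("sign calls are monotone in alpha", {
  a <- c(1.1, 1.3, 0.9, 1.2); b <- c(1.0, 0.8, 1.1, 0.95)
  expect_identical(as.character(sign_call(a, b, alpha = 1e-12)), "norm")
  expect_identical(as.character(sign_call(a, b, alpha = 1)), "up")
  eq <- c(1, 2, 3); eq2 <- c(3, 2, 1)
  expect_identical(as.character(sign_call(eq, eq2, alpha = 1)), "norm")
})

test_that("delta table of identical groups is all norm with zero deltas", {
  wt <- make_fiber_params()
  dt <- delta_table(wt, wt)
  expect_true(all(dt$sign == "norm"))
  expect_true(all(dt$delta == 0))
})

test_that("a planted emission-angle offset is flagged in exactly one record", {
  wt <- make_fiber_params()
  mut <- make_fiber_params(list("S1|high|none|TRUE" = c(phi_e = 2)))
  dt <- delta_table(mut, wt)
  up <- dt[dt$sign == "up", ]
  expect_equal(nrow(up), 1L)
  expect_identical(up$probe_target, "S1")
  expect_identical(up$ca, "high")
  expect_identical(up$parameter, "phi_e")
  expect_equal(up$delta, 2, tolerance = 1e-9)
})

test_that("delta table is antisymmetric under swapping mutant and wild type", {
  wt <- make_fiber_params()
  mut <- make_fiber_params(list("Tpm|high|none|FALSE" = c(phi_e = -2, epsilon = -4),
                                "S1|low|ATP|TRUE" = c(phi_e = 2, n = 0.06)))
  fwd <- delta_table(mut, wt)
  rev <- delta_table(wt, mut)
  key <- function(d) paste(d$probe_target, d$ca, d$nucleotide, d$s1_present,
                           d$parameter)
  rev <- rev[match(key(fwd), key(rev)), ]
  expect_equal(rev$delta, -fwd$delta, tolerance = 1e-12)
  flip <- c(up = "down", down = "up", norm = "norm")
  expect_identical(unname(flip[fwd$sign]), rev$sign)
  expect_equal(rev$p_value, fwd$p_value, tolerance = 1e-12)
})

test_that("unshared conditions are reported, never dropped silently", {
  wt <- make_fiber_params()
  mut <- make_fiber_params()
  mut <- mut[mut$probe_target != "actin", ]
  expect_message(dt <- delta_table(mut, wt), "without a counterpart")
  expect_true(length(attr(dt, "unmatched")) > 0)
  expect_error(delta_table(mut[0, ], wt), "no shared condition keys")
})

e173a_effects <- list(
  "Tpm|high|none|FALSE" = c(phi_e = -2, epsilon = -5),
  "Tpm|low|none|FALSE" = c(phi_e = -2, epsilon = -5),
  "Tpm|high|none|TRUE" = c(phi_e = -2, epsilon = -5),
  "Tpm|low|none|TRUE" = c(phi_e = -2, epsilon = -5),
  "actin|high|none|FALSE" = c(phi_e = 2), "actin|low|none|FALSE" = c(phi_e = 2),
  "actin|high|none|TRUE" = c(phi_e = 2), "actin|low|none|TRUE" = c(phi_e = 2),
  "S1|high|none|TRUE" = c(phi_e = -2, n = -0.05),
  "S1|low|none|TRUE" = c(phi_e = -2, n = -0.05),
  "S1|high|ATP|TRUE" = c(phi_e = -2, n = -0.05),
  "S1|low|ATP|TRUE" = c(phi_e = -2, n = -0.05))

test_that("deltas with the CFTD-mutation semantics reproduce the reference row", {
  dt <- delta_table(make_fiber_params(e173a_effects), make_fiber_params())
  sig <- signature_from_deltas(dt, pCa50_mut = 6.84, pCa50_wt = 6.5,
                               se_mut = 0.04, se_wt = 0.03)
  refs <- myopathy_references()
  expected <- unlist(refs[refs$id == "E173A_TPM3", signature_features()])
  expect_identical(unname(sig$features), unname(expected))
})

test_that("all-norm deltas with equal midpoints give an all-norm signature", {
  wt <- make_fiber_params()
  sig <- signature_from_deltas(delta_table(wt, wt), 6.5, 6.5, 0.03, 0.03)
  expect_true(all(sig$features == "norm"))
})

test_that("signatures ignore a common shift of all emission angles", {
  mut <- make_fiber_params(e173a_effects)
  wt <- make_fiber_params()
  sig1 <- signature_from_deltas(delta_table(mut, wt), 6.84, 6.5)
  mut$phi_e <- mut$phi_e + 3; wt$phi_e <- wt$phi_e + 3
  sig2 <- signature_from_deltas(delta_table(mut, wt), 6.84, 6.5)
  expect_identical(sig1$features, sig2$features)
})

test_that("contradictory strong-binding evidence yields a missing feature and a logged conflict", {
  eff <- list("S1|high|none|TRUE" = c(phi_e = -2, n = 0.05))  # discordant
  dt <- delta_table(make_fiber_params(eff), make_fiber_params())
  sig <- signature_from_deltas(dt, 6.5, 6.5)
  expect_identical(unname(sig$features["strong_high"]), "missing")
  expect_true(any(grepl("strong_high", sig$conflicts)))
})

test_that("every reference mutation self-classifies at distance zero", {
  refs <- myopathy_references()
  rows <- refs[!refs$is_consensus, ]
  expect_equal(nrow(rows), 12L)
  for (i in seq_len(nrow(rows))) {
    sig <- myopathy_signature(
      stats::setNames(unlist(rows[i, signature_features()]), signature_features()))
    cl <- classify_signature(sig)
    self <- cl$distances[cl$distances$id == rows$id[i], ]
    expect_equal(self$distance, 0, label = rows$id[i])
    expect_equal(cl$distance, 0)
  }
})

test_that("the NM-diagnosed slow-muscle mutation clusters with the Cap group", {
  refs <- myopathy_references()
  row <- refs[refs$id == "A155T_TPM3", ]
  sig <- myopathy_signature(
    stats::setNames(unlist(row[, signature_features()]), signature_features()))
  cl <- classify_signature(sig, exclude = "A155T_TPM3")
  expect_identical(cl$label, "Cap")
})

test_that("classification matches a brute-force nearest-neighbour search", {
  withr::local_seed(606)
  refs <- myopathy_references()
  feats <- signature_features()
  ref_mat <- as.matrix(refs[, feats])
  for (k in seq_len(25)) {
    v <- sample(c("up", "down", "norm"), 14, replace = TRUE)
    v[sample(14, sample(0:3, 1))] <- "missing"
    sig <- myopathy_signature(stats::setNames(v, feats))
    cl <- classify_signature(sig)
    # brute force with the same comparison and ordering rules
    d <- apply(ref_mat, 1, function(rv) {
      ok <- v != "missing" & rv != "missing"
      if (!any(ok)) return(c(NA, 0))
      c(sum(v[ok] != rv[ok]) / sum(ok), sum(ok))
    })
    dist <- d[1, ]; ncmp <- d[2, ]
    ord <- order(dist, -ncmp)
    ord <- ord[!is.na(dist[ord])]
    ord <- ord[refs$group[ord] != "unassigned"]
    expect_identical(cl$label, refs$group[ord[1]])
  }
})

test_that("a fully missing signature cannot be classified", {
  sig <- myopathy_signature(stats::setNames(rep("missing", 14),
                                            signature_features()))
  expect_error(classify_signature(sig), "all signature features are missing")
})
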