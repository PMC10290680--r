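# Frozen expected values below were computed with an independent
# implementation of each statistic (scipy.stats pooled t and chi-square
# survival function) and are cross-checked at run time against the
# first-principles oracles in helper-fixtures.R.

test_that("per-line one-tailed pooled t behaves at, above and below the null", {
  lay <- small_layout()
  # symmetric null: line equals blanks
  rel <- c(C1 = 2, C2 = 2, C3 = 1, C4 = 1, B1 = 2, B2 = 2)
  r0 <- per_line_test(rel, lay, "hs")
  expect_equal(r0$log2fc, 0)
  expect_equal(r0$p, 0.5)
  # textbook case: line log2 {10, 10.2} vs blanks {8, 8.1} (df = 2 here);
  # the 2-vs-3 blank design is exercised on the 11-plex layout below
  a <- 2^c(10, 10.2); b <- 2^c(8, 8.1)
  rel1 <- c(C1 = a[1], C2 = a[2], C3 = 1, C4 = 1, B1 = b[1], B2 = b[2])
  r1 <- per_line_test(rel1, lay, "hs")
  orc <- pooled_t_oracle(c(10, 10.2), c(8, 8.1))
  expect_equal(r1$log2fc, 2.05)
  expect_equal(r1$t, orc$t, tolerance = 1e-12)
  expect_equal(r1$p, orc$p, tolerance = 1e-12)
  expect_identical(r1$df, 2L)
  # below the blanks: one-tailed p > 0.5
  rel2 <- c(C1 = 0.5, C2 = 0.6, C3 = 1, C4 = 1, B1 = 2, B2 = 2.2)
  expect_gt(per_line_test(rel2, lay, "hs")$p, 0.5)
})

test_that("2 replicates vs 3 blanks gives the df = 3 pooled t of the design", {
  lay <- layout_11plex()
  rel <- setNames(rep(1, 11), layout_channels(lay))
  rel[sample_channels(lay, "human1")] <- 2^c(10.0, 10.2)
  rel[blank_channels(lay)] <- 2^c(8.0, 8.1, 7.9)
  r <- per_line_test(rel, lay, "human1")
  expect_identical(r$df, 3L)
  expect_equal(r$log2fc, 2.1)
  # frozen from scipy.stats.ttest_ind(equal_var=True, alternative="greater")
  expect_equal(r$t, 19.92234925906086, tolerance = 1e-10)
  expect_equal(r$p, 1.3819549672684688e-04, tolerance = 1e-10)
  orc <- pooled_t_oracle(c(10.0, 10.2), c(8.0, 8.1, 7.9))
  expect_equal(r$p, orc$p, tolerance = 1e-12)
})

test_that("Fisher combination matches its closed-form oracle", {
  r <- fisher_combine(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(r$statistic, 12.064573083256473, tolerance = 1e-12)
  expect_identical(r$df, 8L)
  # frozen from scipy.stats.chi2.sf(12.064573, 8)
  expect_equal(r$p_value, 0.1483459622946296, tolerance = 1e-12)
  expect_equal(fisher_combine(rep(1, 4))$statistic, 0)
  expect_equal(fisher_combine(rep(1, 4))$p_value, 1)
  # dominance: one overwhelming p drives the combination
  expect_lt(fisher_combine(c(1e-12, 1, 1, 1))$p_value, 1e-8)
  expect_error(fisher_combine(numeric(0)), class = "ppb_contract_error")
  expect_error(fisher_combine(c(0.5, 1.2)), class = "ppb_contract_error")
  # p = 0 floors instead of producing -Inf
  expect_true(is.finite(fisher_combine(c(0, 0.5))$statistic))
})

test_that("Fisher and BH agree with brute-force oracles on random inputs", {
  set.seed(42)
  for (i in 1:50) {
    p <- runif(sample(2:8, 1), min = 1e-8)
    r <- fisher_combine(p)
    o <- fisher_oracle(p)
    expect_equal(r$statistic, o$statistic, tolerance = 1e-12)
    expect_equal(r$p_value, o$p_value, tolerance = 1e-12)
  }
  for (i in 1:50) {
    p <- runif(sample(c(1, 5, 50, 200), 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # hand step-up example and tie/monotonicity behaviour
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 3)), rep(1, 3))
  q <- bh_adjust(p <- runif(100))
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("the null model recovers a known replicate-ratio SD", {
  lay <- small_layout()
  set.seed(7)
  n <- 2500
  # build relative profiles whose replicate log2 ratios are N(0, 0.2):
  # each line's two replicates differ by half the ratio on the log2 scale
  half <- matrix(rnorm(2 * n, 0, 0.2 / 2), n)
  L2 <- cbind(half[, 1], -half[, 1], half[, 2], -half[, 2], 0, 0)
  R <- 2^L2
  R <- R / rowMeans(R)
  tab <- data.frame(protein = sprintf("P%04d", 1:n), n_psms_used = 1L)
  tab[paste0("rel_", layout_channels(lay))] <- as.data.frame(R)
  null <- estimate_null_model(tab, lay, "mle")
  expect_identical(null$n_ratios, as.integer(2 * n))
  expect_lt(abs(null$sigma0 / 0.2 - 1), 0.05)
  null_mad <- estimate_null_model(tab, lay, "mad")
  expect_lt(abs(null_mad$sigma0 / 0.2 - 1), 0.08)
  # identical replicates degenerate to sigma0 = 0
  Rc <- matrix(1, 5, 6)
  tabc <- data.frame(protein = sprintf("P%d", 1:5), n_psms_used = 1L)
  tabc[paste0("rel_", layout_channels(lay))] <- as.data.frame(Rc)
  expect_error(suppressWarnings(estimate_null_model(tabc, lay)),
               class = "ppb_degeneracy_error")
})

test_that("the candidate rule is FDR < threshold AND z > threshold", {
  lay <- layout_11plex()
  sim <- simulate_experiment(sim_config(n_proteins = 300, seed = 19), lay)
  run <- run_pipeline(sim$psms, lay)
  cand <- run$candidates
  expect_true(all(cand$q_value >= cand$combined_p))
  expect_true(all(cand$fisher_X2 >= 0))
  expect_true(all(cand$combined_p >= 0 & cand$combined_p <= 1))
  gate <- cand$q_value < attr(cand, "fdr_threshold") &
    cand$z_score > attr(cand, "z_threshold")
  expect_identical(cand$is_candidate, gate)
  # rule truth table at the default thresholds
  null <- run$null_model
  expect_true(all(cand$is_candidate[cand$q_value < 0.01 & cand$z_score > 3]))
  expect_false(any(cand$is_candidate[cand$q_value >= 0.01]))
  expect_false(any(cand$is_candidate[cand$z_score <= 3]))
  # z-score definition: (max per-line log2FC - mu0) / sigma0
  fc_max <- do.call(pmax, cand[paste0("log2fc_", cell_lines(lay))])
  expect_equal(cand$z_score, (fc_max - null$mu0) / null$sigma0)
})

test_that("per-line null p-values are uniform; Fisher is exact on independent inputs", {
  lay <- layout_11plex()
  # exact null for the t-test machinery: no binders, no loading bias, no
  # normalization, one PSM per protein so log2 profiles are exactly Gaussian
  # (estimated loading factors shift a run's p-values coherently, and
  # averaging PSMs makes log2 profiles slightly non-Gaussian; both conditional
  # effects are documented in the vignette)
  sim <- simulate_experiment(sim_config(n_proteins = 2000, binder_fraction = 0,
                                        loading_bias = c(1, 1),
                                        peptides_per_protein = c(1, 1),
                                        psms_per_peptide = c(1, 1),
                                        p_shared_peptide = 1, seed = 31), lay)
  run <- run_pipeline(sim$psms, lay, normalize = FALSE)
  for (line in cell_lines(lay)) {
    ks <- suppressWarnings(
      stats::ks.test(run$candidates[[paste0("p_", line)]], "punif"))
    expect_lt(unname(ks$statistic), 0.05)
  }
  # combining independent uniforms returns uniforms: the Fisher machinery
  # itself adds no distortion (the per-line tests of one protein share blank
  # channels, so full-pipeline combined p-values are *not* independent-input
  # uniforms; see the methods vignette)
  set.seed(1)
  U <- matrix(runif(4 * 2000), ncol = 4)
  comb <- apply(U, 1, function(p) fisher_combine(p)$p_value)
  expect_lt(unname(suppressWarnings(stats::ks.test(comb, "punif"))$statistic),
            0.05)
})

test_that("calling is invariant to protein row order and channel column order", {
  lay <- layout_11plex()
  sim <- simulate_experiment(sim_config(n_proteins = 120, seed = 23), lay)
  run <- run_pipeline(sim$psms, lay)
  # permute protein rows
  tab <- run$proteins
  set.seed(2)
  perm <- sample(nrow(tab))
  cand2 <- call_candidates(tab[perm, ], lay, run$null_model)
  reord <- cand2[match(run$candidates$protein, cand2$protein), ]
  expect_equal(reord$combined_p, run$candidates$combined_p, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(reord$is_candidate, run$candidates$is_candidate,
               ignore_attr = TRUE)
  # permute intensity columns of the PSM table: identity by label, not position
  psms_perm <- sim$psms[, c(PSM_META_COLS, rev(layout_channels(lay)))]
  run2 <- run_pipeline(psms_perm, lay)
  expect_equal(run2$candidates, run$candidates, ignore_attr = TRUE)
})
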