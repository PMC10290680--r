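test_that("identity correction is a no-op and the worked 3-channel example inverts", {
  lay <- small_layout()
  set.seed(4)
  X <- matrix(runif(36, 1e3, 1e5), 6)
  psms <- make_psms(X, lay)
  out <- correct_impurity(psms, diag(6), lay)
  expect_equal(intensity_matrix(out, lay), intensity_matrix(psms, lay),
               ignore_attr = TRUE)
  expect_false(any(out$impurity_clamped))

  # label 1 truly emits (1000, 0, 0): observed (918, 79, 3) must invert back.
  # Solved inside a 6-channel table whose upper 3x3 block carries the
  # distribution; remaining channels are left pure.
  M <- diag(6)
  M[1:3, 1] <- c(0.918, 0.079, 0.003)
  M[1, 1] <- 0.918
  obs <- c(918, 79, 3, 5000, 5000, 5000)
  true <- solve(M, obs)                      # independent solver route
  psms1 <- make_psms(matrix(obs, 1), lay)
  got <- intensity_matrix(correct_impurity(psms1, M, lay), lay)[1, ]
  expect_equal(unname(got[1:3]), c(1000, 0, 0), tolerance = 1e-9)
  expect_equal(unname(got), unname(true), tolerance = 1e-9)
})

test_that("correction round-trips random well-conditioned mixtures (invert and nnls)", {
  lay <- small_layout()
  set.seed(99)
  for (i in 1:20) {
    M <- diag(6) * 0.85
    off <- matrix(runif(36, 0, 0.1 / 6), 6)
    diag(off) <- 0
    M <- M + off
    M <- validate_impurity_matrix(M)
    true <- matrix(runif(30, 1e3, 1e6), 5)
    obs <- true %*% t(M)
    psms <- make_psms(obs, lay)
    rec <- intensity_matrix(correct_impurity(psms, M, lay, "invert"), lay)
    expect_equal(rec, true, tolerance = 1e-9, ignore_attr = TRUE)
  }
  # nnls agrees on a clean system and stays non-negative on a noisy one
  M <- validate_impurity_matrix(diag(6) * 0.9 + 0.01)
  true <- matrix(runif(12, 1e3, 1e5), 2)
  psms <- make_psms(true %*% t(M), lay)
  rec <- intensity_matrix(correct_impurity(psms, M, lay, "nnls"), lay)
  expect_equal(rec, true, tolerance = 1e-6, ignore_attr = TRUE)
  noisy <- make_psms(matrix(c(1000, 0, 0, 0, 0, 0), 1), lay)
  rec2 <- intensity_matrix(correct_impurity(noisy, M, lay, "nnls"), lay)
  expect_true(all(rec2 >= 0))
})

test_that("negative corrected intensities clamp to zero with a row flag", {
  lay <- small_layout()
  M <- validate_impurity_matrix(diag(6) * 0.9 + 0.01)
  # an observation impossible under M (zero where spill-over must appear)
  psms <- make_psms(matrix(c(1000, 0, 0, 0, 0, 0), 1), lay)
  out <- correct_impurity(psms, M, lay, "invert")
  expect_true(out$impurity_clamped[1])
  expect_true(all(intensity_matrix(out, lay) >= 0))
})

test_that("low-intensity exclusion applies inclusive min/median thresholds", {
  lay <- small_layout()
  rows <- rbind(
    c(900, rep(9000, 5)),          # min 900 < 1000 -> excluded
    c(1200, 1200, 1200, 4000, 9000, 9000),  # median 2600 < 5000 -> excluded
    c(1000, 5000, 5000, 5000, 5000, 5000),  # exactly at both -> retained
    rep(10000, 6))
  psms <- make_psms(rows, lay)
  kept <- filter_psms(psms, lay, quiet = TRUE)
  expect_identical(kept$psm_id, psms$psm_id[3:4])
  # idempotent; output never longer than input
  expect_identical(filter_psms(kept, lay, quiet = TRUE), kept)
  expect_lte(nrow(kept), nrow(psms))
})

test_that("mean-centering produces rows averaging exactly 1", {
  lay <- small_layout()
  psms <- make_psms(rbind(c(10, 20, 30, 10, 20, 30),
                          rep(7, 6)), lay)
  out <- mean_center(psms, lay)
  X <- intensity_matrix(out, lay)
  expect_equal(unname(X[1, 1:3]), c(0.5, 1.0, 1.5))
  expect_equal(unname(X[2, ]), rep(1, 6))
  set.seed(8)
  rand <- make_psms(matrix(runif(60, 1, 1e5), 10), lay)
  Xr <- intensity_matrix(mean_center(rand, lay), lay)
  expect_equal(rowMeans(Xr), rep(1, 10), tolerance = 1e-12,
               ignore_attr = TRUE)
  zero <- make_psms(matrix(0, 1, 6), lay)
  expect_error(mean_center(zero, lay), class = "ppb_internal_error")
})

test_that("protein summarization averages shared PSMs and drops shared-free proteins", {
  lay <- small_layout()
  X <- rbind(c(0.5, 1.5, 1, 1, 1, 1),
             c(1.5, 0.5, 1, 1, 1, 1),
             c(2.0, 0.5, 0.5, 1, 1, 1),
             c(1, 1, 1, 1, 1, 1))
  psms <- make_psms(X, lay, protein = c("Pa", "Pa", "Pb", "Pc"),
                    specificity = c("shared", "shared", "shared", "mouse"))
  tab <- summarize_proteins(psms, lay, quiet = TRUE)
  expect_identical(tab$protein, c("Pa", "Pb"))   # Pc mouse-only -> omitted
  expect_identical(tab$n_psms_used, c(2L, 1L))
  R <- protein_matrix(tab, lay)
  expect_equal(unname(R["Pa", ]), rep(1, 6))     # averaging
  expect_equal(unname(R["Pb", ]), X[3, ])        # single PSM passthrough
  # per-channel mean over channels stays 1 (inherits centering)
  expect_equal(unname(rowMeans(R)), rep(1, 2), tolerance = 1e-9)
  # with use_only_shared = FALSE the mouse-only protein appears
  tab2 <- summarize_proteins(psms, lay, use_only_shared = FALSE, quiet = TRUE)
  expect_true("Pc" %in% tab2$protein)
})

test_that("absolute scaling uses the top-min(3, n) PSM grand-mean per protein", {
  lay <- small_layout()
  mk <- function(means) t(vapply(means, function(m) rep(m, 6), numeric(6)))
  raw <- make_psms(mk(c(5000, 4000, 3000, 2000, 5000, 3000)), lay,
                   protein = c("Pa", "Pa", "Pa", "Pa", "Pb", "Pb"))
  centered <- mean_center(raw, lay)
  tab <- summarize_proteins(centered, lay, quiet = TRUE)
  tab <- scale_absolute(tab, raw, lay)
  expect_equal(tab$scale[tab$protein == "Pa"], 4000)  # mean of top 3
  expect_equal(tab$scale[tab$protein == "Pb"], 4000)  # mean of top min(3, 2)
  A <- protein_matrix(tab, lay, "absolute")
  R <- protein_matrix(tab, lay, "relative")
  expect_equal(A, R * tab$scale, ignore_attr = TRUE)
  # constant relative profile -> absolute equals the scale everywhere
  expect_equal(unname(A["Pa", ]), rep(4000, 6))
  # relative 1.5 in some channel would scale to 6000 (worked arithmetic)
  expect_equal(1.5 * tab$scale[1], 6000)
  # global mode applies one common scale
  tabg <- scale_absolute(summarize_proteins(centered, lay, quiet = TRUE),
                         raw, lay, per_protein = FALSE)
  expect_equal(unique(tabg$scale), mean(c(5000, 5000, 4000)))
  # a protein missing from the raw table is a consistency error
  expect_error(scale_absolute(tab, raw[raw$protein != "Pb", ], lay),
               class = "ppb_consistency_error")
})

test_that("quantification is invariant to PSM row order", {
  lay <- small_layout()
  sim <- simulate_experiment(sim_config(n_proteins = 60, seed = 13),
                             layout_11plex())
  lay11 <- layout_11plex()
  psms <- sim$psms
  set.seed(1)
  perm <- psms[sample(nrow(psms)), ]
  run1 <- run_pipeline(psms, lay11)
  run2 <- run_pipeline(perm, lay11)
  expect_equal(run1$proteins, run2$proteins, ignore_attr = TRUE)
  expect_equal(run1$candidates, run2$candidates, ignore_attr = TRUE)
})
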