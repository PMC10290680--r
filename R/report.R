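# End-to-end orchestration and QC summaries (channel distributions, PCA of
# log2 protein profiles with channels as observations, hierarchical
# clustering of channels).

#' Run the full pulldown analysis pipeline
#'
#' Executes, in order: reporter impurity correction (identity when
#' `impurity` is `NULL`), low-intensity PSM exclusion, loading-bias
#' estimation and correction from cross-species-specific peptides,
#' mean-centering, shared-peptide protein summarization, absolute scaling,
#' null-model estimation and candidate calling. Deterministic given fixed
#' inputs; each stage's parameters are recorded in the run log.
#'
#' @param psms PSM table (raw reporter intensities).
#' @param layout a `ppb_layout`.
#' @param impurity impurity matrix or `NULL`.
#' @param impurity_mode `"invert"` or `"nnls"`.
#' @param min_intensity,median_intensity PSM exclusion thresholds.
#' @param normalize apply the species-specific loading normalization.
#' @param min_support minimum PSM support per loading factor.
#' @param estimator null-model estimator, `"mle"` or `"mad"`.
#' @param fdr_threshold,z_threshold,fc_rule candidate-calling parameters,
#'   see [call_candidates()].
#' @param quiet suppress per-stage messages.
#' @return a `ppb_run` list: `proteins` (quant table), `candidates`,
#'   `factors`, `null_model`, `psms_normalized` (post-filter, normalized,
#'   pre-centering), and `log` (character).
#' @export
run_pipeline <- function(psms, layout, impurity = NULL,
                         impurity_mode = c("invert", "nnls"),
                         min_intensity = 1000, median_intensity = 5000,
                         normalize = TRUE, min_support = 10L,
                         estimator = c("mle", "mad"), fdr_threshold = 0.01,
                         z_threshold = 3, fc_rule = c("max", "mean", "all"),
                         quiet = TRUE) {
  impurity_mode <- match.arg(impurity_mode)
  estimator <- match.arg(estimator)
  fc_rule <- match.arg(fc_rule)
  validate_layout(layout)
  validate_psm_table(psms, layout)
  log <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, ppb_error = function(e) {
      stop(errorCondition(
        sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = c("ppb_pipeline_error", class(e))))
    })
  }
  if (!is.null(impurity)) {
    psms <- stage("correct_impurity",
                  correct_impurity(psms, impurity, layout, impurity_mode))
    log <- c(log, sprintf("correct_impurity: mode=%s rcond=%.3g",
                          impurity_mode, attr(validate_impurity_matrix(impurity), "rcond")))
  } else log <- c(log, "correct_impurity: skipped (identity)")
  n0 <- nrow(psms)
  psms <- stage("filter_psms",
                filter_psms(psms, layout, min_intensity, median_intensity,
                            quiet = quiet))
  log <- c(log, sprintf("filter_psms: min>=%g median>=%g kept %d/%d",
                        min_intensity, median_intensity, nrow(psms), n0))
  factors <- NULL
  if (normalize) {
    factors <- stage("compute_loading_factors",
                     compute_loading_factors(psms, layout, min_support))
    psms <- stage("apply_loading_factors",
                  apply_loading_factors(psms, factors, layout))
    log <- c(log, sprintf("species_norm: factors [%s]",
                          paste(sprintf("%.3g", factors$factor), collapse = ", ")))
  } else log <- c(log, "species_norm: skipped")
  centered <- stage("mean_center", mean_center(psms, layout))
  proteins <- stage("summarize_proteins",
                    summarize_proteins(centered, layout, quiet = quiet))
  proteins <- stage("scale_absolute", scale_absolute(proteins, psms, layout))
  log <- c(log, sprintf("summarize: %d proteins quantified", nrow(proteins)))
  null <- stage("estimate_null_model",
                estimate_null_model(proteins, layout, estimator))
  log <- c(log, sprintf("null model (%s): mu0=%.4g sigma0=%.4g n=%d",
                        estimator, null$mu0, null$sigma0, null$n_ratios))
  cand <- stage("call_candidates",
                call_candidates(proteins, layout, null, fdr_threshold,
                                z_threshold, fc_rule))
  log <- c(log, sprintf("call: FDR<%g z>%g rule=%s -> %d candidates",
                        fdr_threshold, z_threshold, fc_rule,
                        sum(cand$is_candidate)))
  structure(list(proteins = proteins, candidates = cand, factors = factors,
                 null_model = null, psms_normalized = psms, log = log),
            class = "ppb_run")
}

#' @export
print.ppb_run <- function(x, ...) {
  cat("ppb_run\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' QC summary of a protein quant table
#'
#' Emits per-channel distribution summaries of log2 relative intensities,
#' a PCA with channels as observations (first two component coordinates and
#' the full variance-fraction spectrum; component signs fixed so the
#' largest-magnitude loading is positive), and average-linkage hierarchical
#' clustering of channels on Euclidean distance between log2 profiles. On a
#' constant (degenerate) matrix the PCA is skipped with a warning.
#'
#' @param tab protein quant table (>= 2 proteins).
#' @param layout a `ppb_layout`.
#' @param linkage linkage method for [stats::hclust()].
#' @return a `ppb_qc` list: `channel_summary`, `pca` (`coords`,
#'   `variance_fraction`) or `NULL`, `clustering` (an `hclust`).
#' @export
qc_summary <- function(tab, layout, linkage = "average") {
  R <- protein_matrix(tab, layout, "relative")
  if (nrow(R) < 2L)
    ppb_stop("qc_summary needs at least 2 proteins", "ppb_contract_error")
  if (any(R <= 0))
    ppb_stop("relative intensities must be positive", "ppb_numeric_error")
  L2 <- log2(R)
  qs <- t(apply(L2, 2L, stats::quantile, probs = c(0, 0.25, 0.5, 0.75, 1)))
  channel_summary <- data.frame(channel = colnames(L2),
                                mean = colMeans(L2), qs,
                                check.names = FALSE, row.names = NULL,
                                stringsAsFactors = FALSE)
  X <- t(L2)  # channels as observations
  pca <- NULL
  if (any(apply(X, 2L, stats::sd) > 0)) {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    for (j in seq_len(min(2L, ncol(pc$rotation)))) {
      i_max <- which.max(abs(pc$rotation[, j]))
      if (pc$rotation[i_max, j] < 0) {
        pc$rotation[, j] <- -pc$rotation[, j]
        pc$x[, j] <- -pc$x[, j]
      }
    }
    vf <- pc$sdev^2 / sum(pc$sdev^2)
    nc <- min(2L, ncol(pc$x))
    pca <- list(coords = data.frame(channel = rownames(pc$x),
                                    pc$x[, seq_len(nc), drop = FALSE],
                                    row.names = NULL, stringsAsFactors = FALSE),
                variance_fraction = vf)
  } else warning("qc_summary: constant intensity matrix, PCA skipped")
  hc <- stats::hclust(stats::dist(X), method = linkage)
  structure(list(channel_summary = channel_summary, pca = pca,
                 clustering = hc), class = "ppb_qc")
}

#' @export
plot.ppb_qc <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (!is.null(x$pca)) {
    co <- x$pca$coords
    graphics::plot(co[[2]], co[[3]],
                   xlab = sprintf("PC1 (%.0f%%)", 100 * x$pca$variance_fraction[1]),
                   ylab = sprintf("PC2 (%.0f%%)", 100 * x$pca$variance_fraction[2]),
                   main = "Channel PCA", pch = 19)
    graphics::text(co[[2]], co[[3]], co$channel, pos = 3, cex = 0.7)
  }
  graphics::plot(x$clustering, main = "Channel clustering", xlab = "",
                 sub = "")
  invisible(x)
}

#' Attach subcellular-compartment composition to a candidate table
#'
#' Optional QC: given a user-supplied annotation (protein -> compartment),
#' tabulates the compartment composition of called candidates. No annotation
#' database is bundled.
#'
#' @param candidates a `ppb_candidates`.
#' @param annotation data frame with columns `protein`, `compartment`.
#' @return data frame of compartment counts and fractions among candidates.
#' @export
compartment_composition <- function(candidates, annotation) {
  if (!all(c("protein", "compartment") %in% names(annotation)))
    ppb_stop("annotation needs 'protein' and 'compartment' columns",
             "ppb_format_error")
  called <- candidates$protein[candidates$is_candidate]
  comp <- annotation$compartment[match(called, annotation$protein)]
  comp[is.na(comp)] <- "unannotated"
  tt <- sort(table(comp), decreasing = TRUE)
  data.frame(compartment = names(tt), n = as.integer(tt),
             fraction = as.integer(tt) / max(1L, length(called)),
             stringsAsFactors = FALSE)
}
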