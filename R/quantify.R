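# Reporter-ion quantification: isotope impurity correction, low-intensity
# PSM exclusion, mean-centering to relative intensities, protein
# summarization over human-mouse shared peptides, and absolute scaling by
# the grand-mean of each protein's three most abundant PSMs.

#' Correct reporter-ion isotope impurities
#'
#' Each label's reporter signal spills into neighbouring channels with known
#' fractions, so the observed per-PSM channel vector is `M %*% true`. This
#' solves for the true signal per PSM. In `invert` mode the linear system is
#' solved exactly and any negative solutions are clamped to 0, with a logical
#' `impurity_clamped` column flagging affected rows; in `nnls` mode the
#' system is solved under a non-negativity constraint instead.
#'
#' @param psms PSM table.
#' @param M impurity matrix, dimension = channel count.
#' @param layout a `ppb_layout`.
#' @param mode `"invert"` (exact solve, clamp) or `"nnls"`.
#' @return PSM table with corrected intensities.
#' @export
correct_impurity <- function(psms, M, layout, mode = c("invert", "nnls")) {
  mode <- match.arg(mode)
  M <- validate_impurity_matrix(M)
  labs <- layout_channels(layout)
  if (nrow(M) != length(labs))
    ppb_stop("impurity matrix dimension does not match channel count",
             "ppb_layout_error")
  X <- intensity_matrix(psms, layout)
  if (mode == "invert") {
    if (rcond(M) < 1e-12)
      ppb_stop("impurity matrix too ill-conditioned to invert; use mode = 'nnls'",
               "ppb_numeric_error")
    Y <- t(solve(M, t(X)))
    clamped <- apply(Y < 0, 1L, any)
    Y[Y < 0] <- 0
    psms <- set_intensities(psms, layout, Y)
    psms$impurity_clamped <- clamped
  } else {
    Y <- t(apply(X, 1L, function(x) pracma::lsqnonneg(M, x)$x))
    psms <- set_intensities(psms, layout, Y)
  }
  psms
}

#' Exclude very low-intensity PSMs
#'
#' Keeps a PSM iff its minimum intensity across channels is at least
#' `min_intensity` and its median is at least `median_intensity` (both
#' inclusive). Defaults follow the exclusion thresholds conventional for
#' reporter-ion data (minimum 1000, median 5000).
#'
#' @param psms PSM table.
#' @param layout a `ppb_layout`.
#' @param min_intensity,median_intensity inclusive thresholds.
#' @param quiet suppress the retained/excluded message.
#' @return the filtered PSM table (possibly empty).
#' @export
filter_psms <- function(psms, layout, min_intensity = 1000,
                        median_intensity = 5000, quiet = FALSE) {
  X <- intensity_matrix(psms, layout)
  if (nrow(X) == 0L) return(psms)
  mins <- apply(X, 1L, min)
  meds <- apply(X, 1L, stats::median)
  keep <- mins >= min_intensity & meds >= median_intensity
  if (!quiet)
    message(sprintf("filter_psms: retained %d / %d PSMs (excluded %d)",
                    sum(keep), length(keep), sum(!keep)))
  psms[keep, , drop = FALSE]
}

#' Mean-center PSM intensities to the relative scale
#'
#' Divides every intensity by its PSM's across-channel mean, so each row
#' averages exactly 1 and channel values become relative intensities.
#'
#' @param psms PSM table with strictly positive row means.
#' @param layout a `ppb_layout`.
#' @return PSM table on the relative scale.
#' @export
mean_center <- function(psms, layout) {
  X <- intensity_matrix(psms, layout)
  m <- rowMeans(X)
  if (any(m <= 0))
    ppb_stop("mean_center: non-positive row mean (all-zero PSM slipped past the filter?)",
             "ppb_internal_error")
  set_intensities(psms, layout, X / m)
}

#' Summarize PSM relative intensities to proteins
#'
#' Groups mean-centered PSMs by `canonical_protein` and averages their
#' relative intensities per channel. With `use_only_shared = TRUE` (the
#' default, and the rule appropriate to a pooled two-species plex) only
#' peptides shared between human and mouse contribute, so that quantification
#' is not biased by species-specific background; proteins with no eligible
#' PSM are omitted. Species-specific PSMs remain in the PSM table for
#' loading-bias estimation.
#'
#' @param psms mean-centered PSM table.
#' @param layout a `ppb_layout`.
#' @param use_only_shared restrict summarization to shared peptides.
#' @param quiet suppress the omitted-protein message.
#' @return a protein quant table: `protein`, `n_psms_used`, one relative
#'   intensity column per channel (`rel_<label>`), absolute columns filled by
#'   [scale_absolute()].
#' @export
summarize_proteins <- function(psms, layout, use_only_shared = TRUE,
                               quiet = FALSE) {
  eligible <- if (use_only_shared) psms$species_specificity == "shared"
              else rep(TRUE, nrow(psms))
  all_prot <- unique(psms$canonical_protein)
  use <- psms[eligible, , drop = FALSE]
  if (!quiet) {
    omitted <- setdiff(all_prot, unique(use$canonical_protein))
    if (length(omitted))
      message(sprintf("summarize_proteins: %d protein(s) without eligible PSMs omitted",
                      length(omitted)))
  }
  X <- intensity_matrix(use, layout)
  g <- factor(use$canonical_protein, levels = sort(unique(use$canonical_protein)))
  sums <- rowsum(X, g)
  counts <- as.integer(table(g))
  rel <- sums / counts
  tab <- data.frame(protein = levels(g), n_psms_used = counts,
                    stringsAsFactors = FALSE)
  rel_cols <- paste0("rel_", layout_channels(layout))
  tab[rel_cols] <- as.data.frame(rel)
  structure(tab, class = c("ppb_proteins", "data.frame"))
}

# Relative or absolute protein intensity matrix, channels in layout order.
protein_matrix <- function(tab, layout, which = c("relative", "absolute")) {
  which <- match.arg(which)
  pre <- if (which == "relative") "rel_" else "abs_"
  cols <- paste0(pre, layout_channels(layout))
  if (!all(cols %in% names(tab)))
    ppb_stop(sprintf("protein table lacks %s intensity columns", which),
             "ppb_format_error")
  X <- as.matrix(tab[, cols, drop = FALSE])
  dimnames(X) <- list(tab$protein, layout_channels(layout))
  X
}

#' Scale relative protein profiles to absolute intensities
#'
#' Per protein, ranks its eligible PSMs by a per-PSM abundance statistic over
#' channels of the post-filter, pre-centering intensities (default: the
#' across-channel mean) and takes the grand-mean of the top `min(3, n)` PSMs
#' as the protein's scale; absolute intensity = relative x scale. With
#' `per_protein = FALSE` a single global top-3 grand-mean scales every
#' protein instead.
#'
#' @param tab protein quant table from [summarize_proteins()].
#' @param psms_raw the post-filter, pre-centering PSM table the summary came
#'   from.
#' @param layout a `ppb_layout`.
#' @param rank_stat abundance statistic per PSM: `"mean"`, `"sum"` or
#'   `"max"` over channels.
#' @param use_only_shared rank only shared-specificity PSMs (must match the
#'   summarization).
#' @param per_protein per-protein scale (default) or one global scale.
#' @return the table with `scale` and `abs_<label>` columns added.
#' @export
scale_absolute <- function(tab, psms_raw, layout,
                           rank_stat = c("mean", "sum", "max"),
                           use_only_shared = TRUE, per_protein = TRUE) {
  rank_stat <- match.arg(rank_stat)
  eligible <- if (use_only_shared) psms_raw$species_specificity == "shared"
              else rep(TRUE, nrow(psms_raw))
  use <- psms_raw[eligible, , drop = FALSE]
  X <- intensity_matrix(use, layout)
  stat <- switch(rank_stat,
                 mean = rowMeans(X),
                 sum = rowSums(X),
                 max = apply(X, 1L, max))
  top3_mean <- function(v) mean(sort(v, decreasing = TRUE)[seq_len(min(3L, length(v)))])
  if (per_protein) {
    by_prot <- split(stat, use$canonical_protein)
    missing <- setdiff(tab$protein, names(by_prot))
    if (length(missing))
      ppb_stop(sprintf("protein(s) absent from raw PSM table: %s",
                       paste(utils::head(missing, 5L), collapse = ", ")),
               "ppb_consistency_error")
    scale <- vapply(by_prot, top3_mean, numeric(1))[tab$protein]
  } else {
    scale <- rep(top3_mean(stat), nrow(tab))
  }
  tab$scale <- unname(scale)
  rel <- protein_matrix(tab, layout, "relative")
  abs_cols <- paste0("abs_", layout_channels(layout))
  tab[abs_cols] <- as.data.frame(rel * tab$scale)
  tab
}
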