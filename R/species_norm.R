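# Loading-bias normalization by cross-species-specific peptides. In a plex
# that pools human and mouse lines, a mouse-specific peptide carries only
# background signal in a human-line channel — the same signal it carries in a
# blank — so the ratio of its median signal in that channel to its median in
# the reference blank estimates the channel's loading bias free of any
# probe-binding biology.

#' Estimate per-channel loading-bias factors from cross-species peptides
#'
#' For each human-line channel, the factor is
#' median(mouse-specific PSM intensities in that channel) /
#' median(the same PSMs' intensities in the first blank channel); mouse-line
#' channels use human-specific peptides symmetrically. Non-reference blank
#' channels are normalized with the union of all species-specific PSMs
#' (every one of them is background in every blank); the reference blank is
#' fixed at 1. Factors are computed on post-filter, pre-centering
#' intensities.
#'
#' @param psms post-filter, pre-centering PSM table.
#' @param layout a `ppb_layout`.
#' @param min_support channels whose factor rests on fewer PSMs than this are
#'   flagged `low_support` (medians of tiny sets are unstable).
#' @return a `ppb_factors` data frame: `channel`, `factor`, `n_psms`,
#'   `class` (peptide class used), `low_support`; attribute `reference`.
#' @examples
#' sim <- simulate_experiment(sim_config(n_proteins = 100), layout_11plex())
#' compute_loading_factors(sim$psms, layout_11plex())
#' @export
compute_loading_factors <- function(psms, layout, min_support = 10L) {
  validate_psm_table(psms, layout)
  ref <- layout$blank_reference
  X <- intensity_matrix(psms, layout)
  ch <- layout$channels
  spec_idx <- list(human = which(psms$species_specificity == "human"),
                   mouse = which(psms$species_specificity == "mouse"))

  one_factor <- function(idx, label) {
    den <- stats::median(X[idx, ref])
    if (!is.finite(den) || den <= 0)
      ppb_stop("zero median signal in the reference blank", "ppb_numeric_error")
    stats::median(X[idx, label]) / den
  }

  out <- data.frame(channel = ch$label, factor = NA_real_,
                    n_psms = NA_integer_, class = NA_character_,
                    low_support = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ch))) {
    lab <- ch$label[i]
    if (lab == ref) {
      out$factor[i] <- 1
      out$n_psms[i] <- length(spec_idx$human) + length(spec_idx$mouse)
      out$class[i] <- "reference"
      next
    }
    if (ch$role[i] == "sample") {
      cls <- opposite_species(line_species(layout, ch$cell_line[i]))
      idx <- spec_idx[[cls]]
    } else {
      cls <- "pooled"
      idx <- c(spec_idx$human, spec_idx$mouse)
    }
    if (length(idx) == 0L)
      ppb_stop(sprintf("no cross-species-specific PSMs available to normalize channel '%s'",
                       lab), "ppb_normalization_error")
    out$factor[i] <- one_factor(idx, lab)
    out$n_psms[i] <- length(idx)
    out$class[i] <- cls
  }
  out$low_support <- out$n_psms < min_support
  if (any(out$low_support))
    warning(sprintf("loading factor(s) for %s rest on fewer than %d PSMs",
                    paste(out$channel[out$low_support], collapse = ", "),
                    min_support))
  structure(out, class = c("ppb_factors", "data.frame"),
            reference = ref, min_support = min_support)
}

#' Apply loading-bias factors
#'
#' Divides every intensity in channel c by that channel's factor.
#' Re-estimating factors on the output returns 1 for every channel on
#' noise-free data (fixed point).
#'
#' @param psms PSM table.
#' @param factors a `ppb_factors` from [compute_loading_factors()].
#' @param layout a `ppb_layout`.
#' @return the normalized PSM table.
#' @export
apply_loading_factors <- function(psms, factors, layout) {
  labs <- layout_channels(layout)
  if (!all(labs %in% factors$channel))
    ppb_stop("factors do not cover every layout channel", "ppb_layout_error")
  f <- factors$factor[match(labs, factors$channel)]
  if (any(!is.finite(f)) || any(f <= 0))
    ppb_stop("loading factors must be positive and finite", "ppb_numeric_error")
  X <- intensity_matrix(psms, layout)
  set_intensities(psms, layout, sweep(X, 2L, f, "/"))
}

#' @rdname write_table_tsv
#' @param factors a `ppb_factors`.
#' @export
write_loading_factors <- function(factors, path) {
  write_table_tsv(as.data.frame(factors), path)
}
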