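# Synthetic two-species multiplexed pulldown experiments with known ground
# truth. The generator reproduces the statistical structure the analysis
# assumes: Gaussian noise on log2 intensities, per-channel loading-bias
# multipliers, species-specific peptides that carry blank-like background in
# the wrong-species channels and in blanks, binder effects per
# (protein, cell line), optional reporter isotope spill-over and
# low-intensity censoring.

#' Simulation configuration
#'
#' Defaults describe the study conditions the package targets: an 11-plex
#' with 1000 proteins, 5% true binders per cell line at a log2 effect of 3,
#' log-normal measurement noise of 0.15 on the log2 scale, and per-channel
#' loading-bias multipliers drawn uniformly from \[0.5, 2\]. Intensity scales
#' (protein abundance around 2^16 with SD 1.5 log2 units; blank-like
#' background around 2^13.8 with SD 0.8) are chosen so that typical reporter
#' signals sit well above the default low-intensity filter while its
#' exclusion path still fires for the low-abundance tail, as in real reporter
#' data. Censoring emulates the instrument noise floor.
#'
#' @param n_proteins number of simulated proteins.
#' @param fraction_shared_peptide_proteins fraction of proteins carrying at
#'   least one human-mouse shared peptide (only these are quantifiable under
#'   the shared-only summarization rule).
#' @param p_shared_peptide probability that each further peptide of such a
#'   protein is shared rather than species-specific.
#' @param peptides_per_protein integer range, peptides drawn per protein.
#' @param psms_per_peptide integer range, PSMs drawn per peptide.
#' @param species_split fraction of proteins assigned to human.
#' @param binder_fraction fraction of proteins that are true probe binders.
#'   Binding is a property of the protein (the quantified proteins are
#'   conserved between the species), so by default a binder is enriched in
#'   every cell line and each line carries `binder_fraction` binders.
#' @param line_specificity fraction of binders restricted to a single
#'   (random) cell line, emulating line-specific interactor clusters.
#'   Default 0.
#' @param effect_size log2 fold enrichment of a binder in its line's
#'   pulldown channels.
#' @param noise_sd SD of Gaussian noise added on log2 intensities.
#' @param loading_bias either a length-2 range (per-channel multipliers
#'   drawn uniformly) or one multiplier per channel.
#' @param base_intensity `c(meanlog2, sdlog2)` of protein abundance.
#' @param psm_jitter_sd SD (log2) of PSM-to-PSM abundance scatter within a
#'   protein.
#' @param blank_background `c(meanlog2, sdlog2)` of the background signal a
#'   species-specific peptide shows where its protein is absent.
#' @param censor_threshold intensities below this are set to 0.
#' @param impurity an impurity matrix to mix reporter signal through, or
#'   `NULL` for none.
#' @param seed integer seed; all draws flow from one generator.
#' @return a `ppb_sim_config` list.
#' @export
sim_config <- function(n_proteins = 1000L,
                       fraction_shared_peptide_proteins = 0.8,
                       p_shared_peptide = 0.6,
                       peptides_per_protein = c(2L, 4L),
                       psms_per_peptide = c(1L, 2L),
                       species_split = 0.5,
                       binder_fraction = 0.05,
                       line_specificity = 0,
                       effect_size = 3,
                       noise_sd = 0.15,
                       loading_bias = c(0.5, 2),
                       base_intensity = c(16, 1.5),
                       psm_jitter_sd = 0.5,
                       blank_background = c(13.8, 0.8),
                       censor_threshold = 200,
                       impurity = NULL,
                       seed = 17L) {
  cfg <- as.list(environment())
  fr <- c(cfg$fraction_shared_peptide_proteins, cfg$p_shared_peptide,
          cfg$species_split, cfg$binder_fraction, cfg$line_specificity)
  if (any(fr < 0 | fr > 1))
    ppb_stop("fractions must lie in [0, 1]", "ppb_config_error")
  if (cfg$noise_sd < 0)
    ppb_stop("noise_sd must be >= 0", "ppb_config_error")
  if (any(cfg$loading_bias <= 0))
    ppb_stop("loading_bias multipliers must be positive", "ppb_config_error")
  structure(cfg, class = "ppb_sim_config")
}

.draw_range <- function(n, range) {
  if (range[1L] == range[length(range)]) rep(range[1L], n)
  else sample(seq.int(range[1L], range[2L]), n, replace = TRUE)
}

#' Simulate a multiplexed two-species pulldown experiment
#'
#' Generates a PSM-level reporter table plus ground truth for a given
#' layout. Expected log2 intensity of a PSM in channel c is
#' `base + effect*I(binder in that line) + log2(bias_c) + noise` for shared
#' peptides; species-specific peptides get that full signal only in
#' same-species cell lines and a blank-like background level elsewhere and
#' in all blanks — the assumption that makes them usable as internal blanks
#' for loading normalization. Intensities are exponentiated, optionally
#' mixed through the impurity matrix, then censored to 0 below
#' `censor_threshold`.
#'
#' @param config a [sim_config()].
#' @param layout a `ppb_layout`; must contain both species if any
#'   normalization is to be possible.
#' @return a list with `psms` (validated PSM table) and `truth`
#'   (`ppb_truth`: per protein x line binder flags and effects, per-channel
#'   bias multipliers, seed and config echo).
#' @examples
#' sim <- simulate_experiment(sim_config(n_proteins = 50), layout_11plex())
#' head(sim$psms[, 1:6])
#' @export
simulate_experiment <- function(config = sim_config(), layout = layout_11plex()) {
  validate_layout(layout)
  labs <- layout_channels(layout)
  k <- length(labs)
  lines <- cell_lines(layout)
  present <- unique(vapply(lines, function(l) line_species(layout, l),
                           character(1)))
  if (length(present) < 2L)
    ppb_stop("layout holds a single species; cross-species normalization impossible",
             "ppb_config_error")
  set.seed(config$seed)

  n <- config$n_proteins
  prot_id <- sprintf("P%04d", seq_len(n))
  prot_species <- ifelse(stats::runif(n) < config$species_split,
                         "human", "mouse")
  has_shared <- stats::runif(n) < config$fraction_shared_peptide_proteins
  is_binder_prot <- stats::runif(n) < config$binder_fraction
  binder <- matrix(is_binder_prot, n, length(lines),
                   dimnames = list(prot_id, lines))
  if (config$line_specificity > 0) {
    restrict <- is_binder_prot & stats::runif(n) < config$line_specificity
    only_line <- sample.int(length(lines), n, replace = TRUE)
    for (j in seq_along(lines))
      binder[restrict & only_line != j, j] <- FALSE
  }
  effect <- matrix(0, n, length(lines), dimnames = list(prot_id, lines))
  effect[binder] <- config$effect_size
  prot_abund <- stats::rnorm(n, config$base_intensity[1L],
                             config$base_intensity[2L])

  bias <- if (length(config$loading_bias) == k) config$loading_bias
          else stats::runif(k, config$loading_bias[1L], config$loading_bias[2L])
  names(bias) <- labs

  # peptide layer
  n_pep <- .draw_range(n, config$peptides_per_protein)
  pep_prot <- rep.int(seq_len(n), n_pep)
  pep_rank <- sequence(n_pep)
  pep_shared <- has_shared[pep_prot] &
    (pep_rank == 1L | stats::runif(length(pep_prot)) < config$p_shared_peptide)
  pep_class <- ifelse(pep_shared, "shared", prot_species[pep_prot])

  # PSM layer
  n_psm <- .draw_range(length(pep_prot), config$psms_per_peptide)
  psm_pep <- rep.int(seq_along(pep_prot), n_psm)
  m <- length(psm_pep)
  psm_prot <- pep_prot[psm_pep]
  psm_class <- pep_class[psm_pep]
  psm_base <- prot_abund[psm_prot] + stats::rnorm(m, 0, config$psm_jitter_sd)
  psm_bg <- stats::rnorm(m, config$blank_background[1L],
                         config$blank_background[2L])

  # channel masks: where does each PSM carry full signal?
  ch <- layout$channels
  ch_line <- ch$cell_line                       # NA for blanks
  ch_line_species <- ifelse(is.na(ch_line), NA,
                            unname(layout$species[ch_line]))
  full <- matrix(FALSE, m, k)
  eff_mat <- matrix(0, m, k)
  for (j in seq_len(k)) {
    if (is.na(ch_line[j])) {          # blank: shared peptides at base level
      full[, j] <- psm_class == "shared"
    } else {
      full[, j] <- psm_class == "shared" | psm_class == ch_line_species[j]
      eff_mat[, j] <- effect[cbind(psm_prot, match(ch_line[j], lines))]
    }
  }
  # species-specific peptide of the wrong species in a sample channel, or any
  # specific peptide in a blank, sits at background level; binder effects only
  # apply where the protein is actually present.
  base_mat <- ifelse(full, psm_base, psm_bg)
  eff_mat[!full] <- 0
  L2 <- base_mat + eff_mat +
    matrix(log2(bias), m, k, byrow = TRUE) +
    matrix(stats::rnorm(m * k, 0, config$noise_sd), m, k)
  X <- 2^L2
  if (!is.null(config$impurity)) {
    M <- validate_impurity_matrix(config$impurity)
    if (nrow(M) != k)
      ppb_stop("impurity matrix dimension does not match layout",
               "ppb_config_error")
    X <- X %*% t(M)
  }
  X[X < config$censor_threshold] <- 0
  colnames(X) <- labs

  psms <- data.frame(
    psm_id = sprintf("%s.pep%02d.psm%d", prot_id[psm_prot],
                     pep_rank[psm_pep], sequence(n_psm)),
    peptide = sprintf("%s.pep%02d", prot_id[psm_prot], pep_rank[psm_pep]),
    protein = prot_id[psm_prot],
    canonical_protein = prot_id[psm_prot],
    species_specificity = psm_class,
    stringsAsFactors = FALSE)
  psms <- cbind(psms, as.data.frame(X))
  validate_psm_table(psms, layout)

  truth <- structure(list(
    proteins = data.frame(
      protein = rep(prot_id, each = length(lines)),
      species = rep(prot_species, each = length(lines)),
      cell_line = rep(lines, n),
      is_binder = as.vector(t(binder)),
      effect = as.vector(t(effect)),
      stringsAsFactors = FALSE),
    bias = data.frame(channel = labs, bias = unname(bias),
                      stringsAsFactors = FALSE),
    seed = config$seed,
    config = config), class = "ppb_truth")
  list(psms = psms, truth = truth)
}

# proteins that are a binder in at least one line
true_binders <- function(truth) {
  unique(truth$proteins$protein[truth$proteins$is_binder])
}

#' @rdname write_table_tsv
#' @param truth a `ppb_truth`.
#' @export
write_truth <- function(truth, path) {
  write_table_tsv(truth$proteins, path)
}
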