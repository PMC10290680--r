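# Interaction-candidate statistic: per-cell-line one-tailed pooled-variance
# t-tests against the blank channels, Fisher combination across lines,
# Benjamini-Hochberg FDR, and a fold-change gate in units of the null SD
# estimated from replicate log2 ratios.

P_FLOOR <- 1e-300  # avoids log(0) in Fisher's method

# Vectorized one-tailed pooled-t of line replicates vs blanks on a
# proteins x channels log2 matrix. Returns p, log2fc, t, df per protein.
.line_test_matrix <- function(L2, layout, line) {
  a <- L2[, sample_channels(layout, line), drop = FALSE]
  b <- L2[, blank_channels(layout), drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2L || n2 < 2L)
    ppb_stop("per-line test needs >= 2 replicates and >= 2 blanks",
             "ppb_config_error")
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  ss1 <- rowSums((a - m1)^2); ss2 <- rowSums((b - m2)^2)
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  fc <- m1 - m2
  tt <- fc / se
  p <- stats::pt(tt, df, lower.tail = FALSE)
  # degenerate: zero pooled variance
  zv <- sp2 == 0
  p[zv & fc == 0] <- 0.5
  p[zv & fc > 0] <- P_FLOOR
  p[zv & fc < 0] <- 1
  list(p = p, log2fc = fc, t = tt, df = df, degenerate = zv & fc != 0)
}

#' One-tailed t-test of a protein's line replicates against blanks
#'
#' Pooled-variance two-sample Student t (df = n1 + n2 - 2) on log2 relative
#' intensities, alternative: line > blanks. With duplicates against three
#' blanks this is a df = 3 test. log2FC is mean(line) - mean(blanks) on the
#' log2 scale.
#'
#' @param rel named numeric vector of one protein's relative intensities
#'   (names = channel labels), or a one-row protein quant table.
#' @param layout a `ppb_layout`.
#' @param line cell line id.
#' @return list with `p`, `log2fc`, `t`, `df`.
#' @export
per_line_test <- function(rel, layout, line) {
  if (is.data.frame(rel)) rel <- protein_matrix(rel, layout, "relative")[1L, ]
  if (any(rel <= 0))
    ppb_stop("relative intensities must be positive for the log2 test",
             "ppb_numeric_error")
  L2 <- matrix(log2(rel), 1L, dimnames = list(NULL, names(rel)))
  r <- .line_test_matrix(L2, layout, line)
  list(p = unname(r$p), log2fc = unname(r$log2fc), t = unname(r$t), df = r$df)
}

#' Combine per-line p-values by Fisher's method
#'
#' X2 = -2 * sum(ln p_i), referred to a chi-square distribution with 2L
#' degrees of freedom. Zero p-values are floored at 1e-300.
#'
#' @param p numeric vector of L p-values in (0, 1].
#' @return list with `statistic` (X2), `df`, `p_value`.
#' @examples
#' fisher_combine(c(0.1, 0.2, 0.3, 0.4))
#' @export
fisher_combine <- function(p) {
  if (length(p) == 0L)
    ppb_stop("fisher_combine needs at least one p-value", "ppb_contract_error")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    ppb_stop("p-values must lie in [0, 1]", "ppb_contract_error")
  p <- pmax(p, P_FLOOR)
  x2 <- -2 * sum(log(p))
  list(statistic = x2, df = 2L * length(p),
       p_value = stats::pchisq(x2, df = 2L * length(p), lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Converts a vector of p-values into BH-adjusted q-values (monotone in
#' p-rank, q >= p, ties preserved; ties and equal values resolve by stable
#' order, so results are deterministic).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    ppb_stop("p-values must lie in [0, 1]", "ppb_contract_error")
  stats::p.adjust(p, method = "BH")
}

#' Estimate the null model from replicate log2 ratios
#'
#' For every protein and cell line, forms log2(rep_i / rep_j) of the
#' relative intensities over all replicate pairs, pools the ratios across
#' proteins and lines, and fits a Gaussian: `mle` takes the sample mean and
#' SD, `mad` the median and 1.4826 x MAD (robust alternative). The fitted SD
#' is the "null SD" in whose units the fold-change z-score is expressed.
#'
#' @param tab protein quant table.
#' @param layout a `ppb_layout`.
#' @param estimator `"mle"` or `"mad"`.
#' @return a `ppb_null` list: `mu0`, `sigma0`, `n_ratios`, `estimator`,
#'   `low_support` (TRUE when fewer than 30 ratios).
#' @export
estimate_null_model <- function(tab, layout, estimator = c("mle", "mad")) {
  estimator <- match.arg(estimator)
  R <- protein_matrix(tab, layout, "relative")
  if (any(R <= 0))
    ppb_stop("relative intensities must be positive", "ppb_numeric_error")
  L2 <- log2(R)
  ratios <- numeric(0)
  for (line in cell_lines(layout)) {
    chans <- sample_channels(layout, line)
    prs <- utils::combn(length(chans), 2L)
    for (q in seq_len(ncol(prs)))
      ratios <- c(ratios, L2[, chans[prs[1L, q]]] - L2[, chans[prs[2L, q]]])
  }
  if (estimator == "mle") {
    mu0 <- mean(ratios); sigma0 <- stats::sd(ratios)
  } else {
    mu0 <- stats::median(ratios); sigma0 <- stats::mad(ratios)
  }
  if (!is.finite(sigma0) || sigma0 <= 0)
    ppb_stop("replicate ratios are degenerate (null SD = 0)",
             "ppb_degeneracy_error")
  low <- length(ratios) < 30L
  if (low)
    warning(sprintf("null model fitted on only %d replicate ratios",
                    length(ratios)))
  structure(list(mu0 = mu0, sigma0 = sigma0, n_ratios = length(ratios),
                 estimator = estimator, low_support = low),
            class = "ppb_null")
}

#' @export
print.ppb_null <- function(x, ...) {
  cat(sprintf("ppb_null (%s): mu0 = %.4g, sigma0 (null SD) = %.4g, n_ratios = %d\n",
              x$estimator, x$mu0, x$sigma0, x$n_ratios))
  invisible(x)
}

#' Call interaction candidates
#'
#' Runs the per-line one-tailed tests for every protein, combines the L
#' per-line p-values by Fisher's method, converts combined p-values to FDR
#' q-values by Benjamini-Hochberg, and gates on fold change expressed as a
#' z-score in null-SD units: `z = (fc_stat - mu0) / sigma0`, where `fc_stat`
#' is by default the maximum per-line log2FC (so a protein binding strongly
#' in a single line can qualify). A protein is a candidate iff
#' `q < fdr_threshold` and `z > z_threshold`; the full table is returned
#' regardless of the call.
#'
#' @param tab protein quant table (relative intensities).
#' @param layout a `ppb_layout`.
#' @param null a `ppb_null`; estimated from `tab` when `NULL`.
#' @param fdr_threshold FDR cut-off on the combined q-value (default 0.01).
#' @param z_threshold z cut-off in null-SD units (default 3).
#' @param fc_rule which per-line log2FC enters the z-score: `"max"`,
#'   `"mean"`, or `"all"` (minimum — every line must clear the gate).
#' @return a `ppb_candidates` data frame: per protein one `p_<line>` and
#'   `log2fc_<line>` column per cell line, `fisher_X2`, `combined_p`,
#'   `q_value`, `z_score`, `is_candidate`; the null model and thresholds are
#'   attached as attributes.
#' @examples
#' sim <- simulate_experiment(sim_config(n_proteins = 200), layout_11plex())
#' run <- run_pipeline(sim$psms, layout_11plex())
#' table(run$candidates$is_candidate)
#' @export
call_candidates <- function(tab, layout, null = NULL, fdr_threshold = 0.01,
                            z_threshold = 3, fc_rule = c("max", "mean", "all")) {
  fc_rule <- match.arg(fc_rule)
  if (is.null(null)) null <- estimate_null_model(tab, layout)
  R <- protein_matrix(tab, layout, "relative")
  if (any(R <= 0))
    ppb_stop("relative intensities must be positive", "ppb_numeric_error")
  L2 <- log2(R)
  lines <- cell_lines(layout)
  P <- FC <- matrix(NA_real_, nrow(L2), length(lines),
                    dimnames = list(rownames(L2), lines))
  for (line in lines) {
    r <- .line_test_matrix(L2, layout, line)
    P[, line] <- r$p
    FC[, line] <- r$log2fc
  }
  x2 <- -2 * rowSums(log(pmax(P, P_FLOOR)))
  comb <- stats::pchisq(x2, df = 2L * length(lines), lower.tail = FALSE)
  q <- bh_adjust(comb)
  fc_stat <- switch(fc_rule,
                    max = apply(FC, 1L, max),
                    mean = rowMeans(FC),
                    all = apply(FC, 1L, min))
  z <- (fc_stat - null$mu0) / null$sigma0
  out <- data.frame(protein = tab$protein, stringsAsFactors = FALSE)
  out[paste0("p_", lines)] <- as.data.frame(P)
  out[paste0("log2fc_", lines)] <- as.data.frame(FC)
  out$fisher_X2 <- x2
  out$combined_p <- comb
  out$q_value <- q
  out$z_score <- z
  out$is_candidate <- q < fdr_threshold & z > z_threshold
  structure(out, class = c("ppb_candidates", "data.frame"),
            null_model = null, fdr_threshold = fdr_threshold,
            z_threshold = z_threshold, fc_rule = fc_rule)
}
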