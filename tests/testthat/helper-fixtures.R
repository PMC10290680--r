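# Shared fixtures and independent oracles. Oracles are deliberately written
# from first principles (series expansions, explicit step-up loops, textbook
# formulas) so they share no code path with the package functions they check.

# minimal valid layout: 2 lines (one per species) x 2 reps + 2 blanks
small_layout <- function() {
  channel_layout(
    channels = c("C1", "C2", "C3", "C4", "B1", "B2"),
    role = c(rep("sample", 4), rep("blank", 2)),
    cell_line = c("hs", "hs", "mm", "mm", NA, NA),
    replicate = c(1, 2, 1, 2, NA, NA),
    blank_index = c(NA, NA, NA, NA, 1, 2),
    species = c(hs = "human", mm = "mouse"))
}

# PSM table from an intensity matrix (rows = PSMs)
make_psms <- function(X, layout, specificity = "shared",
                      protein = sprintf("P%02d", seq_len(nrow(X)))) {
  n <- nrow(X)
  tab <- data.frame(psm_id = sprintf("psm%03d", seq_len(n)),
                    peptide = sprintf("pep%03d", seq_len(n)),
                    protein = protein,
                    canonical_protein = protein,
                    species_specificity = rep_len(specificity, n),
                    stringsAsFactors = FALSE)
  colnames(X) <- layout_channels(layout)
  cbind(tab, as.data.frame(X))
}

# Fisher's combined p by the closed-form series for even df:
# P(X2 > x) = exp(-x/2) * sum_{k=0}^{L-1} (x/2)^k / k!
fisher_oracle <- function(p) {
  x <- -2 * sum(log(p))
  L <- length(p)
  terms <- vapply(0:(L - 1), function(k) exp(-x / 2 + k * log(x / 2) -
                                               lgamma(k + 1)), numeric(1))
  list(statistic = x, p_value = min(1, sum(terms)))
}

# brute-force BH step-up: q_(i) = min_{j >= i} min(1, p_(j) * n / j)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    cand <- vapply(i:n, function(j) min(1, ps[j] * n / j), numeric(1))
    q_sorted[i] <- min(cand)
  }
  out <- numeric(n)
  out[o] <- q_sorted
  out
}

# textbook pooled-variance one-tailed t-test, written out longhand
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 1 - stats::pt(t, n1 + n2 - 2), df = n1 + n2 - 2)
}
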