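# Readers/writers for the pipeline's on-disk artifacts. Everything is plain
# text (TSV/CSV/JSON); the pipeline begins after peptide-spectrum matching, so
# no raw mass-spec formats are touched.

# Extract the channel intensity columns of a PSM table as a numeric matrix,
# columns in layout order.
intensity_matrix <- function(psms, layout) {
  labs <- layout_channels(layout)
  as.matrix(psms[, labs, drop = FALSE])
}

set_intensities <- function(psms, layout, X) {
  psms[, layout_channels(layout)] <- X
  psms
}

#' Validate a PSM table against a layout
#'
#' A PSM table has one row per peptide-spectrum match with the metadata
#' columns `psm_id`, `peptide`, `protein`, `canonical_protein`,
#' `species_specificity` (one of `human`, `mouse`, `shared`) and one
#' intensity column per layout channel, finite and non-negative.
#'
#' @param psms data frame to validate.
#' @param layout a `ppb_layout`.
#' @return `psms`, invisibly, if valid.
#' @export
validate_psm_table <- function(psms, layout) {
  miss <- setdiff(PSM_META_COLS, names(psms))
  if (length(miss))
    ppb_stop(sprintf("missing required column(s): %s",
                     paste(miss, collapse = ", ")), "ppb_format_error")
  labs <- layout_channels(layout)
  miss <- setdiff(labs, names(psms))
  if (length(miss))
    ppb_stop(sprintf("intensity column(s) absent for layout channel(s): %s",
                     paste(miss, collapse = ", ")), "ppb_layout_error")
  bad <- !psms$species_specificity %in% c(SPECIES_LEVELS, "shared")
  if (any(bad))
    ppb_stop(sprintf("invalid species_specificity at row(s) %s",
                     paste(utils::head(which(bad), 5L), collapse = ", ")),
             "ppb_format_error")
  X <- intensity_matrix(psms, layout)
  if (nrow(X) > 0L && (!is.numeric(X) || any(!is.finite(X)) || any(X < 0))) {
    bad_row <- which(apply(!is.finite(X) | X < 0, 1L, any))
    ppb_stop(sprintf("non-finite or negative intensity at row(s) %s",
                     paste(utils::head(bad_row, 5L), collapse = ", ")),
             "ppb_format_error")
  }
  invisible(psms)
}

#' Read a PSM table
#'
#' Reads a tab-separated PSM table and validates it against `layout`.
#' Channel identity is by column label, not position: files whose intensity
#' columns are permuted relative to the layout are re-ordered. Unknown extra
#' columns are kept (with a warning) so flags survive round trips.
#'
#' @param path TSV file with a header row.
#' @param layout a `ppb_layout`.
#' @return a validated PSM data frame, metadata columns first, then intensity
#'   columns in layout order.
#' @export
read_psm_table <- function(path, layout) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = NA)
  miss <- setdiff(PSM_META_COLS, names(tab))
  if (length(miss))
    ppb_stop(sprintf("PSM file '%s' is missing column(s): %s", path,
                     paste(miss, collapse = ", ")), "ppb_format_error")
  labs <- layout_channels(layout)
  miss <- setdiff(labs, names(tab))
  if (length(miss))
    ppb_stop(sprintf("PSM file '%s' lacks intensity column(s) %s required by the layout",
                     path, paste(miss, collapse = ", ")), "ppb_layout_error")
  for (lab in labs) {
    v <- tab[[lab]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        ppb_stop(sprintf("intensity in column '%s' not parseable at line %d",
                         lab, bad[1L] + 1L), "ppb_format_error")
      tab[[lab]] <- vn
    }
  }
  extra <- setdiff(names(tab), c(PSM_META_COLS, labs))
  if (length(extra))
    warning(sprintf("ignoring extra column(s): %s",
                    paste(extra, collapse = ", ")))
  tab <- tab[, c(PSM_META_COLS, labs, extra), drop = FALSE]
  validate_psm_table(tab, layout)
  tab
}

# Deterministic numeric formatting: %.17g round-trips every double exactly.
.fmt_num <- function(x) {
  if (is.double(x)) {
    out <- sprintf("%.17g", x)
    short <- sprintf("%.15g", x)
    out[as.numeric(short) == x] <- short[as.numeric(short) == x]
    out
  } else x
}

#' Write a pipeline table as TSV
#'
#' Byte-stable output: fixed column order (as passed), doubles printed with
#' the shortest of 15/17 significant digits that round-trips exactly. Used
#' for PSM, protein, candidate, loading-factor and truth tables alike.
#'
#' @param tab data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(tab, path) {
  out <- tab
  for (j in seq_along(out)) out[[j]] <- .fmt_num(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_table_tsv
#' @param psms validated PSM table.
#' @param layout a `ppb_layout`.
#' @export
write_psm_table <- function(psms, layout, path) {
  validate_psm_table(psms, layout)
  write_table_tsv(psms, path)
}

#' Build a reporter-ion impurity matrix from an isotopic distribution
#'
#' Each isobaric label produces most of its reporter signal in its own
#' channel and small fractions in neighbouring channels (isotopologue
#' spill-over). Given the fractions at channel offsets (default: 91.8% in the
#' label's own channel, 7.9% one channel up, 0.3% two channels up, the
#' distribution reported for TMT126), builds the k x k mixing matrix M with
#' `M[i, j]` = fraction of label j's signal observed in channel i. Fractions
#' falling outside the plex are dropped, so edge columns sum to < 1.
#'
#' @param k number of channels.
#' @param distribution numeric fractions per offset.
#' @param offsets integer channel offsets, same length as `distribution`.
#' @return a `k x k` impurity matrix (validated).
#' @examples
#' M <- tmt_impurity_matrix(11)
#' M[1, 1] # 0.918
#' @export
tmt_impurity_matrix <- function(k = 11L,
                                distribution = c(0.918, 0.079, 0.003),
                                offsets = c(0L, 1L, 2L)) {
  stopifnot(length(distribution) == length(offsets))
  M <- matrix(0, k, k)
  for (j in seq_len(k)) {
    i <- j + offsets
    ok <- i >= 1L & i <= k
    M[cbind(i[ok], j)] <- distribution[ok]
  }
  validate_impurity_matrix(M)
}

#' Read / validate an impurity matrix
#'
#' `read_impurity_matrix()` reads a headerless k x k CSV of fractions
#' (column j = label j). Validation requires entries in \[0, 1\], column sums
#' <= 1 (isotopologues outside the plex go undetected), diagonal > 0.5, and
#' numerical nonsingularity; the reciprocal condition number is attached as
#' attribute `rcond`.
#'
#' @param path CSV path.
#' @return validated impurity matrix.
#' @examples
#' # a generated example matrix using the default isotopic distribution
#' path <- system.file("extdata", "impurity_11plex_synthetic.csv",
#'                     package = "ppbscreen")
#' M <- read_impurity_matrix(path)
#' attr(M, "rcond")
#' @export
read_impurity_matrix <- function(path) {
  M <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(M) <- NULL
  validate_impurity_matrix(M)
}

#' @rdname read_impurity_matrix
#' @param M numeric matrix.
#' @export
validate_impurity_matrix <- function(M) {
  if (!is.matrix(M) || !is.numeric(M) || nrow(M) != ncol(M))
    ppb_stop("impurity matrix must be square and numeric", "ppb_format_error")
  if (any(!is.finite(M)) || any(M < 0) || any(M > 1))
    ppb_stop("impurity entries must be fractions in [0, 1]", "ppb_format_error")
  if (any(colSums(M) > 1 + 1e-9))
    ppb_stop("impurity columns must sum to <= 1", "ppb_format_error")
  if (any(diag(M) <= 0.5))
    ppb_stop("impurity diagonal entries must exceed 0.5", "ppb_format_error")
  rc <- rcond(M)
  if (!is.finite(rc) || rc < 1e-12)
    ppb_stop("impurity matrix is numerically singular; use mode = 'nnls'",
             "ppb_numeric_error")
  attr(M, "rcond") <- rc
  M
}
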