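# Channel layout: which reporter channel holds which cell line / replicate /
# blank, and each cell line's species. All downstream comparisons are defined
# by this object.

ppb_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ppb_error", "error", "condition")))
}

PSM_META_COLS <- c("psm_id", "peptide", "protein", "canonical_protein",
                   "species_specificity")
SPECIES_LEVELS <- c("human", "mouse")

#' Construct a channel layout
#'
#' Describes a multiplexed pulldown design: an ordered set of reporter
#' channels, each holding either one replicate of one cell line or a blank
#' bead control, plus the species of every cell line. The reference blank
#' (blank index 1) anchors the loading-bias normalization.
#'
#' @param channels character vector of channel labels, in plex order.
#' @param role character vector, one of `"sample"` or `"blank"` per channel.
#' @param cell_line cell line id per channel (`NA` for blanks).
#' @param replicate integer replicate index per channel (`NA` for blanks).
#' @param blank_index integer blank index per channel (`NA` for samples);
#'   blank 1 is the reference blank.
#' @param species named character vector mapping each cell line id to
#'   `"human"` or `"mouse"`.
#'
#' @return A `ppb_layout` object: a list with a per-channel data frame
#'   (`channels`), the `species` map, and `blank_reference` (the label of
#'   blank 1).
#' @examples
#' layout_11plex()
#' @export
channel_layout <- function(channels, role, cell_line, replicate, blank_index,
                           species) {
  tab <- data.frame(label = as.character(channels),
                    role = as.character(role),
                    cell_line = as.character(cell_line),
                    replicate = as.integer(replicate),
                    blank_index = as.integer(blank_index),
                    stringsAsFactors = FALSE)
  layout <- structure(list(channels = tab,
                           species = species,
                           blank_reference = NA_character_),
                      class = "ppb_layout")
  is_blank <- tab$role == "blank"
  if (any(is_blank) && any(tab$blank_index[is_blank] == 1L, na.rm = TRUE)) {
    layout$blank_reference <- tab$label[is_blank & tab$blank_index == 1L][1L]
  }
  validate_layout(layout)
  layout
}

#' Validate a channel layout
#'
#' Checks the structural invariants every analysis assumes: at least 5
#' channels covering >= 2 cell lines, >= 2 replicates per line (equal across
#' lines), >= 2 blanks numbered 1..n with blank 1 as the reference, and a
#' known species for every cell line. Raises a `ppb_layout_error` on any
#' violation; never returns an invalid object.
#'
#' @param layout a `ppb_layout`.
#' @return `layout`, invisibly, if valid.
#' @export
validate_layout <- function(layout) {
  if (!inherits(layout, "ppb_layout"))
    ppb_stop("not a ppb_layout object", "ppb_layout_error")
  tab <- layout$channels
  if (anyDuplicated(tab$label))
    ppb_stop("duplicated channel labels", "ppb_layout_error")
  if (nrow(tab) < 5L)
    ppb_stop("layout needs at least 5 channels", "ppb_layout_error")
  if (!all(tab$role %in% c("sample", "blank")))
    ppb_stop("channel role must be 'sample' or 'blank'", "ppb_layout_error")
  smp <- tab[tab$role == "sample", ]
  blk <- tab[tab$role == "blank", ]
  if (any(is.na(smp$cell_line)) || any(is.na(smp$replicate)))
    ppb_stop("sample channels need cell_line and replicate", "ppb_layout_error")
  if (any(is.na(blk$blank_index)))
    ppb_stop("blank channels need blank_index", "ppb_layout_error")
  lines <- unique(smp$cell_line)
  if (length(lines) < 2L)
    ppb_stop("layout needs at least 2 cell lines", "ppb_layout_error")
  reps <- table(smp$cell_line)
  if (length(unique(as.integer(reps))) != 1L)
    ppb_stop("every cell line must have the same replicate count",
             "ppb_layout_error")
  if (reps[[1L]] < 2L)
    ppb_stop("each cell line needs at least 2 replicates", "ppb_layout_error")
  for (ln in lines) {
    ri <- sort(smp$replicate[smp$cell_line == ln])
    if (!identical(ri, seq_along(ri)))
      ppb_stop(sprintf("replicate indices of '%s' are not 1..r", ln),
               "ppb_layout_error")
  }
  if (nrow(blk) < 2L)
    ppb_stop("layout needs at least 2 blank channels", "ppb_layout_error")
  if (!identical(sort(blk$blank_index), seq_len(nrow(blk))))
    ppb_stop("blank indices must be 1..n_blanks", "ppb_layout_error")
  if (is.na(layout$blank_reference) ||
      layout$blank_reference != tab$label[tab$role == "blank" &
                                          tab$blank_index == 1L])
    ppb_stop("blank_reference must be blank 1", "ppb_layout_error")
  sp <- layout$species
  if (is.null(names(sp)) || !all(lines %in% names(sp)))
    ppb_stop("species missing for some cell line", "ppb_layout_error")
  if (!all(sp[lines] %in% SPECIES_LEVELS))
    ppb_stop("species must be 'human' or 'mouse'", "ppb_layout_error")
  invisible(layout)
}

#' Default 11-plex layout
#'
#' The study design this package targets: four cell lines (two human, two
#' mouse), duplicate pulldowns of each, and three blank bead controls, in an
#' 11-plex with standard TMT reporter labels. Which reporter held which sample
#' is run-specific, so the assignment here (samples first, blanks last) is a
#' convention, not a claim about any particular run.
#'
#' @param lines named character vector: cell line id -> species. Default two
#'   human and two mouse lines.
#' @param n_replicates replicates per line (default 2).
#' @param n_blanks number of blank channels (default 3).
#' @return a validated `ppb_layout`.
#' @export
layout_11plex <- function(lines = c(human1 = "human", human2 = "human",
                                    mouse1 = "mouse", mouse2 = "mouse"),
                          n_replicates = 2L, n_blanks = 3L) {
  tmt11 <- c("TMT126", "TMT127N", "TMT127C", "TMT128N", "TMT128C", "TMT129N",
             "TMT129C", "TMT130N", "TMT130C", "TMT131N", "TMT131C")
  k <- length(lines) * n_replicates + n_blanks
  labels <- if (k == 11L) tmt11 else sprintf("CH%02d", seq_len(k))
  ns <- length(lines) * n_replicates
  channel_layout(
    channels = labels,
    role = rep(c("sample", "blank"), c(ns, n_blanks)),
    cell_line = c(rep(names(lines), each = n_replicates), rep(NA, n_blanks)),
    replicate = c(rep(seq_len(n_replicates), length(lines)), rep(NA, n_blanks)),
    blank_index = c(rep(NA, ns), seq_len(n_blanks)),
    species = lines)
}

# channel labels, in layout order
layout_channels <- function(layout) layout$channels$label

# labels of one cell line's replicate channels, replicate order
sample_channels <- function(layout, line) {
  tab <- layout$channels
  sel <- tab[tab$role == "sample" & tab$cell_line == line, ]
  sel$label[order(sel$replicate)]
}

blank_channels <- function(layout) {
  tab <- layout$channels
  sel <- tab[tab$role == "blank", ]
  sel$label[order(sel$blank_index)]
}

cell_lines <- function(layout) {
  unique(layout$channels$cell_line[layout$channels$role == "sample"])
}

line_species <- function(layout, line) unname(layout$species[[line]])

opposite_species <- function(species) {
  setNames(c("mouse", "human"), SPECIES_LEVELS)[[species]]
}

#' @export
print.ppb_layout <- function(x, ...) {
  tab <- x$channels
  n_lines <- length(cell_lines(x))
  cat(sprintf("ppb_layout: %d channels, %d cell lines, %d blanks (reference %s)\n",
              nrow(tab), n_lines, sum(tab$role == "blank"), x$blank_reference))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Read / write a channel layout as JSON
#'
#' The on-disk form is a JSON object with a `channels` array (`label`,
#' `role`, and `cell_line` + `replicate` or `blank_index`), a `cell_lines`
#' map giving each line's species, and `blank_reference`.
#'
#' @param path file path.
#' @return `read_layout()` returns a validated `ppb_layout`.
#' @export
read_layout <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ch <- js$channels
  for (col in c("cell_line", "replicate", "blank_index"))
    if (is.null(ch[[col]])) ch[[col]] <- NA
  sp <- vapply(js$cell_lines, function(x) x$species, character(1))
  layout <- channel_layout(ch$label, ch$role, ch$cell_line, ch$replicate,
                           ch$blank_index, species = sp)
  if (!is.null(js$blank_reference) &&
      !identical(js$blank_reference, layout$blank_reference))
    ppb_stop("blank_reference in file is not blank 1", "ppb_layout_error")
  layout
}

#' @rdname read_layout
#' @param layout a `ppb_layout`.
#' @export
write_layout <- function(layout, path) {
  validate_layout(layout)
  sp <- lapply(layout$species, function(s) list(species = s))
  js <- list(channels = layout$channels,
             cell_lines = sp,
             blank_reference = layout$blank_reference)
  jsonlite::write_json(js, path, auto_unbox = TRUE, pretty = TRUE, na = "null",
                       digits = NA)
  invisible(path)
}
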