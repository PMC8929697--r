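#' Multiple sequence alignment container
#'
#' An `msa` object holds one aligned sequence family: a family name, a
#' character vector of row identifiers, and an equal-length character vector
#' of gapped sequences. All rows must have the same number of columns, and
#' identifiers must be unique. Gap characters are `-` and `.`.
#'
#' @param ids Character vector of row identifiers.
#' @param seqs Character vector of gapped sequences, same length as `ids`.
#' @param name Family name (free text).
#' @return An object of class `msa` with elements `name`, `ids`, `seqs`
#'   and `n_cols`.
#' @examples
#' aln <- msa(c("a", "b"), c("AC-D", "ACWD"))
#' aln$n_cols
#' @export
msa <- function(ids, seqs, name = "family") {
  ids <- as.character(ids)
  seqs <- as.character(seqs)
  if (length(ids) != length(seqs))
    stop("ids and seqs must have the same length")
  if (anyDuplicated(ids))
    stop("duplicate sequence identifiers in alignment '", name, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  widths <- nchar(seqs)
  if (length(seqs) > 0L && length(unique(widths)) > 1L)
    stop("alignment '", name, "' has rows of unequal length")
  structure(
    list(name = name, ids = ids, seqs = seqs,
         n_cols = if (length(seqs)) widths[[1L]] else 0L),
    class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %s: %d sequences x %d columns\n",
              x$name, length(x$ids), x$n_cols))
  invisible(x)
}

#' @export
length.msa <- function(x) length(x$ids)

#' Subset an alignment by row index
#'
#' @param aln An [msa] object.
#' @param i Integer vector of row indices.
#' @return An [msa] containing the selected rows, in the given order.
#'   Columns are never dropped, so column indices remain comparable to the
#'   parent alignment.
#' @export
msa_subset <- function(aln, i) {
  stopifnot(inherits(aln, "msa"))
  out <- aln
  out$ids <- aln$ids[i]
  out$seqs <- aln$seqs[i]
  out
}

.gap_chars <- c("-", ".")
.gap_regex <- "[-.]"

#' Ungapped sequence lengths of alignment rows
#'
#' Counts residues (characters other than `-` and `.`) per row.
#'
#' @param aln An [msa] object.
#' @return Integer vector of ungapped lengths.
#' @export
ungapped_lengths <- function(aln) {
  nchar(gsub(.gap_regex, "", aln$seqs))
}

#' Remove fragment sequences from an alignment
#'
#' Drops every row whose ungapped length is below `min_frac` times the mean
#' ungapped length of the input rows. The mean is computed once, on the
#' alignment as given; the filter is intended to be applied exactly once,
#' before splitting. Row order and column count are preserved (columns that
#' become all-gap are retained).
#'
#' @param aln An [msa] object with at least one row.
#' @param min_frac Minimum fraction of the mean ungapped length (default 0.7).
#' @return The filtered [msa].
#' @examples
#' aln <- msa(c("a", "b", "c"),
#'            c(strrep("A", 100), strrep("C", 100),
#'              paste0(strrep("G", 40), strrep("-", 60))))
#' length(fragment_filter(aln))  # row "c" (length 40 < 0.7 * 80) is removed
#' @export
fragment_filter <- function(aln, min_frac = 0.7) {
  stopifnot(inherits(aln, "msa"))
  if (length(aln) == 0L)
    stop("cannot fragment-filter an empty alignment")
  ul <- ungapped_lengths(aln)
  keep <- ul >= min_frac * mean(ul)
  msa_subset(aln, which(keep))
}
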