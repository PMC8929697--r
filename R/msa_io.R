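#' Read a (possibly multi-record) Stockholm alignment file
#'
#' Parses Stockholm 1.0 text into a list of [msa] objects, one per record.
#' Records are terminated by `//`; concatenated multi-MSA files in the
#' Pfam-A.seed dialect are supported. Sequence lines may be interleaved:
#' within a record, blocks are separated by blank lines and rows with the
#' same identifier across blocks are concatenated. A `#=GF ID` line, when
#' present, supplies the family name; otherwise a name is synthesized from
#' the record's position in the file. Other annotation lines (`#=GC`,
#' `#=GS`, `#=GR`) are ignored.
#'
#' @param file Path to a Stockholm file, or a connection.
#' @return A list of [msa] objects (empty list for empty input).
#' @details A record whose assembled rows have unequal lengths, or that
#'   repeats an identifier within one block, raises an error naming the
#'   offending record.
#' @examples
#' tf <- tempfile(fileext = ".sto")
#' writeLines(c("# STOCKHOLM 1.0", "seq1 AC-D", "seq2 ACWD", "//"), tf)
#' alns <- read_stockholm(tf)
#' alns[[1]]$n_cols
#' @export
read_stockholm <- function(file) {
  lines <- readLines(file)
  records <- list()
  rec_ids <- character(0)
  rec_seqs <- list()          # named list id -> accumulated string
  block_ids <- character(0)   # ids seen in current interleaved block
  rec_name <- NULL
  rec_index <- 0L
  saw_content <- FALSE

  finish <- function() {
    rec_index <<- rec_index + 1L
    name <- if (!is.null(rec_name)) rec_name else sprintf("record_%d", rec_index)
    seqs <- unlist(rec_seqs[rec_ids], use.names = FALSE)
    if (length(seqs) && length(unique(nchar(seqs))) > 1L)
      stop("malformed Stockholm record '", name,
           "': assembled rows have unequal lengths")
    records[[length(records) + 1L]] <<- msa(rec_ids, seqs, name = name)
    rec_ids <<- character(0)
    rec_seqs <<- list()
    block_ids <<- character(0)
    rec_name <<- NULL
  }

  header_seen <- FALSE
  for (raw in lines) {
    line <- sub("[\r\n]+$", "", raw)
    trimmed <- trimws(line)
    if (trimmed == "") {
      block_ids <- character(0)
      next
    }
    if (!header_seen) {
      if (!grepl("^#\\s*STOCKHOLM", trimmed))
        stop("not a Stockholm file: expected '# STOCKHOLM 1.0' header")
      header_seen <- TRUE
    }
    if (trimmed == "//") {
      finish()
      saw_content <- TRUE
      next
    }
    if (startsWith(trimmed, "#")) {
      if (grepl("^#=GF\\s+ID\\s+", trimmed))
        rec_name <- sub("^#=GF\\s+ID\\s+", "", trimmed)
      next
    }
    # sequence line: "<id> <gapped seq>"
    parts <- strsplit(trimmed, "\\s+")[[1L]]
    if (length(parts) < 2L)
      stop("malformed Stockholm sequence line: '", trimmed, "'")
    id <- parts[[1L]]
    seq <- paste(parts[-1L], collapse = "")
    if (id %in% block_ids) {
      nm <- if (!is.null(rec_name)) rec_name else sprintf("record_%d", rec_index + 1L)
      stop("duplicate identifier '", id, "' in Stockholm record '", nm, "'")
    }
    block_ids <- c(block_ids, id)
    if (is.null(rec_seqs[[id]])) {
      rec_ids <- c(rec_ids, id)
      rec_seqs[[id]] <- seq
    } else {
      rec_seqs[[id]] <- paste0(rec_seqs[[id]], seq)
    }
    saw_content <- TRUE
  }
  if (length(rec_ids) > 0L)  # trailing record without "//"
    finish()
  records
}

#' Write an alignment as a single Stockholm record
#'
#' Emits a non-interleaved record (one line per sequence) terminated by
#' `//`, with the family name on a `#=GF ID` line.
#'
#' @param aln An [msa] object.
#' @param file Path or connection to write to.
#' @param append Append to an existing file (for building multi-MSA files).
#' @return Invisibly, `aln`.
#' @export
write_stockholm <- function(aln, file, append = FALSE) {
  stopifnot(inherits(aln, "msa"))
  width <- max(nchar(aln$ids), 0L)
  body <- if (length(aln)) sprintf("%-*s %s", width, aln$ids, aln$seqs) else character(0)
  lines <- c("# STOCKHOLM 1.0",
             paste0("#=GF ID ", aln$name),
             body,
             "//")
  if (is.character(file)) {
    con <- file(file, if (append) "a" else "w")
    on.exit(close(con))
  } else con <- file
  writeLines(lines, con)
  invisible(aln)
}

#' Read an aligned FASTA file as an alignment
#'
#' @param file Path to an aligned FASTA file.
#' @param name Family name to assign (default: the file base name).
#' @return An [msa] object.
#' @export
read_fasta_msa <- function(file, name = NULL) {
  set <- Biostrings::readBStringSet(file)
  ids <- sub("\\s.*$", "", names(set))
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(file))
  msa(ids, as.character(set), name = name)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param file Output path.
#' @return Invisibly, `seqs`.
#' @export
write_fasta <- function(seqs, file) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, file)
  invisible(seqs)
}

#' Remove gap characters from sequences
#'
#' @param seqs Character vector of gapped sequences.
#' @return The sequences with `-` and `.` removed.
#' @export
degap <- function(seqs) gsub(.gap_regex, "", seqs)

#' Write a train/test split to disk
#'
#' The training set is written as one Stockholm record, preserving the
#' original alignment columns but with the row order randomly permuted
#' (profile builders should not see a systematic ordering). The test set is
#' written as unaligned FASTA, with gap characters removed, since test
#' sequences are consumed individually downstream.
#'
#' @param train An [msa] of training rows.
#' @param test Named character vector of test sequences (may be gapped;
#'   gaps are stripped). May be empty.
#' @param train_file,test_file Output paths.
#' @return Invisibly, a list with the permutation applied to the training rows.
#' @export
write_train_test <- function(train, test, train_file, test_file) {
  stopifnot(inherits(train, "msa"))
  perm <- sample.int(length(train))
  write_stockholm(msa_subset(train, perm), train_file)
  test <- degap(test)
  write_fasta(test, test_file)
  invisible(list(perm = perm))
}
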