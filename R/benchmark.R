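#' Background sequence database for decoy construction
#'
#' Wraps a set of protein sequences (UniProt in the intended use, but any
#' FASTA works) that supplies (a) the empirical length distribution from
#' which synthetic sequence lengths are drawn and (b) the raw material for
#' shuffled nonhomologous segments.
#'
#' @param x Named character vector of sequences, or a path to a FASTA file.
#' @return A `background_db` with elements `ids`, `seqs` and `lengths`.
#' @export
background_db <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x)) {
    set <- Biostrings::readBStringSet(x)
    x <- stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
  }
  stopifnot(is.character(x), length(x) >= 1L)
  if (is.null(names(x))) names(x) <- sprintf("db%d", seq_along(x))
  lens <- nchar(x)
  if (any(lens < 1L)) stop("background database entries must be nonempty")
  structure(list(ids = names(x), seqs = unname(x), lengths = unname(lens)),
            class = "background_db")
}

#' @export
print.background_db <- function(x, ...) {
  cat(sprintf("<background_db> %d sequences, lengths %d-%d\n",
              length(x$seqs), min(x$lengths), max(x$lengths)))
  invisible(x)
}

#' Down-sample a test set
#'
#' Uniform sample without replacement of at most `max_n` test identifiers,
#' guarding against over-representation of families with large test sets.
#'
#' @param test_ids Vector of test sequence identifiers (or indices).
#' @param max_n Maximum number to keep (default 10).
#' @return A subset of `test_ids`, in original order.
#' @export
downsample_test <- function(test_ids, max_n = 10) {
  stopifnot(max_n >= 0)
  if (length(test_ids) <= max_n) return(test_ids)
  keep <- sort(sample.int(length(test_ids), max_n))
  test_ids[keep]
}

#' Shuffled nonhomologous segment from the background database
#'
#' Picks a database entry uniformly among those long enough, extracts a
#' window of the requested length starting at a uniform position, and
#' returns a uniform permutation of the window's residues. The source
#' window is attached as attribute `"source"` so composition provenance can
#' be verified.
#'
#' @param db A [background_db].
#' @param length Segment length (0 gives an empty string).
#' @return Character scalar of `length` residues.
#' @export
shuffle_subsequence <- function(db, length) {
  stopifnot(inherits(db, "background_db"), length >= 0)
  if (length == 0) return(structure("", source = ""))
  feasible <- which(db$lengths >= length)
  if (base::length(feasible) == 0L)
    stop("no background entry is at least ", length, " residues long")
  entry <- feasible[[sample.int(base::length(feasible), 1L)]]
  start <- sample.int(db$lengths[[entry]] - length + 1L, 1L)
  window <- substr(db$seqs[[entry]], start, start + length - 1L)
  chars <- strsplit(window, "")[[1L]]
  structure(paste(chars[sample.int(length)], collapse = ""), source = window)
}

#' Embed a test domain in a synthetic nonhomologous sequence
#'
#' Builds one positive benchmark sequence: a total length is drawn from the
#' background length distribution conditioned on being at least the domain
#' length (rejection from the empirical distribution); the domain is placed
#' at a uniformly random position; the two flanking segments are filled with
#' independent shuffled background windows ([shuffle_subsequence]). Exactly
#' one domain is embedded per positive.
#'
#' @param domain Ungapped domain sequence (nonempty).
#' @param db A [background_db] containing at least one entry no shorter
#'   than the domain.
#' @param id Identifier for the record.
#' @param family Family name recorded alongside the positive.
#' @return A list with `id`, `family`, `full_seq`, `domain_start`,
#'   `domain_end` (1-based, inclusive; `substr(full_seq, domain_start,
#'   domain_end)` recovers the domain), `segment_lengths` (left, domain,
#'   right) and the flank source windows.
#' @export
make_positive <- function(domain, db, id = "pos1", family = NA_character_) {
  stopifnot(inherits(db, "background_db"))
  d <- nchar(domain)
  if (d < 1L) stop("test domain must be nonempty")
  feasible <- db$lengths[db$lengths >= d]
  if (!length(feasible))
    stop("test domain is longer than every background entry")
  total <- feasible[[sample.int(length(feasible), 1L)]]
  start <- sample.int(total - d + 1L, 1L)
  left <- shuffle_subsequence(db, start - 1L)
  right <- shuffle_subsequence(db, total - d - (start - 1L))
  list(id = id, family = family,
       full_seq = paste0(left, domain, right),
       domain_start = start,
       domain_end = start + d - 1L,
       segment_lengths = c(left = start - 1L, domain = d,
                           right = total - d - (start - 1L)),
       left_source = attr(left, "source"),
       right_source = attr(right, "source"))
}

#' Construct the shared negative decoy set
#'
#' Each decoy copies the (left, domain, right) segment-length triple of a
#' uniformly chosen positive and fills all three segments with independent
#' shuffled background windows, so decoys match the positives' length and
#' segment structure while containing no homologous content.
#'
#' @param positives List of positive records from [make_positive]
#'   (nonempty).
#' @param db A [background_db].
#' @param count Number of decoys (default 200000, the scale used for a
#'   full homology-search benchmark; tests use far fewer).
#' @return A list of records with `id`, `full_seq` and `segment_lengths`.
#' @export
make_negatives <- function(positives, db, count = 200000) {
  stopifnot(length(positives) >= 1L, count >= 0)
  lapply(seq_len(count), function(i) {
    pos <- positives[[sample.int(length(positives), 1L)]]
    sl <- pos$segment_lengths
    seq <- paste0(shuffle_subsequence(db, sl[["left"]]),
                  shuffle_subsequence(db, sl[["domain"]]),
                  shuffle_subsequence(db, sl[["right"]]))
    list(id = sprintf("decoy%06d", i), full_seq = seq, segment_lengths = sl)
  })
}

#' Build a full benchmark set from per-family test sequences
#'
#' Applies test-set down-sampling (at most `max_per_family` per family),
#' embeds each kept test domain as a positive, and constructs the shared
#' negative set.
#'
#' @param tests_by_family Named list: family name -> named character vector
#'   of ungapped test domain sequences.
#' @param db A [background_db].
#' @param max_per_family Down-sampling cap (default 10).
#' @param n_negatives Decoy count (default 200000).
#' @param seed Optional integer seed.
#' @return A `benchmark_set` list with `positives`, `negatives` and `seed`.
#' @export
build_benchmark <- function(tests_by_family, db, max_per_family = 10,
                            n_negatives = 200000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  positives <- list()
  for (fam in names(tests_by_family)) {
    seqs <- tests_by_family[[fam]]
    keep <- downsample_test(seq_along(seqs), max_per_family)
    for (i in keep) {
      positives[[length(positives) + 1L]] <-
        make_positive(unname(seqs[[i]]), db,
                      id = sprintf("%s/%s", fam, names(seqs)[[i]]),
                      family = fam)
    }
  }
  if (!length(positives)) stop("no test sequences to embed")
  negatives <- make_negatives(positives, db, n_negatives)
  structure(list(positives = positives, negatives = negatives, seed = seed),
            class = "benchmark_set")
}

#' @export
print.benchmark_set <- function(x, ...) {
  cat(sprintf("<benchmark_set> %d positives (%d families), %d decoys\n",
              length(x$positives),
              length(unique(vapply(x$positives, `[[`, "", "family"))),
              length(x$negatives)))
  invisible(x)
}

#' Write a benchmark set as FASTA files
#'
#' @param bm A `benchmark_set`.
#' @param pos_file,neg_file Output paths.
#' @return Invisibly, `bm`.
#' @export
write_benchmark <- function(bm, pos_file, neg_file) {
  pos <- stats::setNames(vapply(bm$positives, `[[`, "", "full_seq"),
                         vapply(bm$positives, `[[`, "", "id"))
  neg <- stats::setNames(vapply(bm$negatives, `[[`, "", "full_seq"),
                         vapply(bm$negatives, `[[`, "", "id"))
  write_fasta(pos, pos_file)
  write_fasta(neg, neg_file)
  invisible(bm)
}
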