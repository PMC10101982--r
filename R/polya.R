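#' Find the polyA run in a read
#'
#' Returns the longest maximal run of consecutive `A` with length at least
#' `min_len` (ties broken to the leftmost run), or `NULL` when no run
#' qualifies. Junction-spanning circNC reads must contain the circularized
#' transcript's polyA tail, so this run anchors all downstream junction
#' calling.
#'
#' @param seq A non-empty nucleotide string.
#' @param min_len Minimum run length (default 8).
#' @return A list with `start`, `end` (0-based half-open offsets in the read)
#'   and `length`, or `NULL`.
#' @examples
#' find_polya_run("CCAAAAAAAAGG")  # run [2, 10)
#' @export
find_polya_run <- function(seq, min_len = 8L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  m <- gregexpr("A+", seq)[[1L]]
  if (m[1L] == -1L) return(NULL)
  lens <- attr(m, "match.length")
  ok <- lens >= min_len
  if (!any(ok)) return(NULL)
  best <- which(ok)[which.max(lens[ok])]  # which.max takes the leftmost tie
  start <- as.integer(m[best]) - 1L
  list(start = start, end = start + lens[best], length = lens[best])
}

#' Filter reads for a polyA run, resolving orientation
#'
#' Keeps reads containing a run of at least `min_len` consecutive `A`.
#' Reads whose orientation is not yet resolved are also tested in reverse
#' complement (a long T run in sequencing orientation); such reads are
#' returned reverse-complemented and marked resolved.
#'
#' @param reads Tibble with columns `read_id`, `seq` and optionally
#'   `orientation_resolved` (defaults to `FALSE`).
#' @param min_len Minimum run length (default 8).
#' @return The passing subset, with `seq` in polyA orientation and
#'   `orientation_resolved = TRUE`.
#' @export
filter_polya <- function(reads, min_len = 8L) {
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  reads <- tibble::as_tibble(reads)
  if (!"orientation_resolved" %in% names(reads)) {
    reads$orientation_resolved <- FALSE
  }
  if (nrow(reads) == 0L) {
    reads$orientation_resolved <- logical(0)
    return(reads)
  }
  fwd <- vapply(reads$seq, function(s) !is.null(find_polya_run(s, min_len)),
                logical(1L), USE.NAMES = FALSE)
  flip <- logical(nrow(reads))
  todo <- which(!fwd & !reads$orientation_resolved)
  for (i in todo) {
    rc <- revcomp(reads$seq[i])
    if (!is.null(find_polya_run(rc, min_len))) {
      flip[i] <- TRUE
      reads$seq[i] <- rc
    }
  }
  out <- reads[fwd | flip, , drop = FALSE]
  out$orientation_resolved <- TRUE
  out
}

#' Rank unique read sequences by multiplicity
#'
#' Counts exact-duplicate sequences and returns the `k` most abundant
#' (ties broken by lexicographic order of the sequence), following the
#' top-most-abundant-unique-reads selection used for junction inspection.
#'
#' @param reads Character vector of sequences, or a tibble with a `seq`
#'   column.
#' @param k Maximum number of unique sequences to return (default 5).
#' @return Tibble with `seq`, `count`, `rank`, sorted by decreasing count.
#' @examples
#' rank_unique_reads(c("AA", "CC", "AA", "AA", "CC", "GG"), k = 2)
#' @export
rank_unique_reads <- function(reads, k = 5L) {
  stopifnot(k >= 1)
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  if (length(seqs) == 0L) {
    return(tibble::tibble(seq = character(), count = integer(),
                          rank = integer()))
  }
  tab <- table(seqs)
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  out <- tibble::tibble(seq = names(tab)[ord],
                        count = as.integer(tab)[ord])
  out <- head(out, k)
  out$rank <- seq_len(nrow(out))
  out
}
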