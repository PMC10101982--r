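#' Merge a read pair by best overlap
#'
#' Reverse-complements read 2 (supplied in sequencing orientation) and scans
#' every overlap in which the 3' end of read 1 matches the 5' end of the
#' reverse-complemented read 2. An overlap of length `o` compares the last
#' `o` bases of read 1 with the first `o` bases of read 2; it is admissible
#' when `o >= min_overlap` and its mismatch fraction is at most
#' `max_mismatch_frac`. Among admissible overlaps the one with the highest
#' matching score (matches minus mismatches) wins; ties go to the longer
#' overlap. Conflicting bases in the overlap take the read 1 call (reads
#' carry no per-base qualities in this pipeline).
#'
#' @param seq1 Read 1 sequence.
#' @param seq2 Read 2 sequence, sequencing orientation.
#' @param min_overlap Minimum admissible overlap length (default 12).
#' @param max_mismatch_frac Maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @return The merged sequence, or `NULL` when no admissible overlap exists.
#' @examples
#' merge_pair("ACGTACGTACGTAAAA", revcomp("ACGTAAAACCCCGGGG"))
#' @export
merge_pair <- function(seq1, seq2, min_overlap = 12L,
                       max_mismatch_frac = 0.1) {
  stopifnot(is.character(seq1), length(seq1) == 1L,
            is.character(seq2), length(seq2) == 1L)
  if (nchar(seq1) == 0L || nchar(seq2) == 0L) {
    stop("empty read sequence", call. = FALSE)
  }
  r2 <- revcomp(seq2)
  c1 <- strsplit(seq1, "", fixed = TRUE)[[1L]]
  c2 <- strsplit(r2, "", fixed = TRUE)[[1L]]
  n1 <- length(c1); n2 <- length(c2)
  if (min(n1, n2) < min_overlap) return(NULL)
  best <- NULL; best_score <- -Inf
  for (o in seq.int(min(n1, n2), min_overlap)) {
    a <- c1[(n1 - o + 1L):n1]
    b <- c2[1L:o]
    mm <- sum(a != b)
    if (mm / o > max_mismatch_frac) next
    score <- (o - mm) - mm
    # strict > keeps the longest admissible overlap on ties (scanned first)
    if (score > best_score) {
      best_score <- score
      best <- o
    }
  }
  if (is.null(best)) return(NULL)
  paste0(substr(seq1, 1L, n1), substr(r2, best + 1L, n2))
}

#' Merge many read pairs
#'
#' Applies [merge_pair()] across paired read tibbles.
#'
#' @param read1,read2 Tibbles with `read_id` and `seq`, paired by position.
#' @inheritParams merge_pair
#' @return Tibble of successfully merged reads (`read_id`, `seq`).
#' @export
merge_pairs <- function(read1, read2, min_overlap = 12L,
                        max_mismatch_frac = 0.1) {
  stopifnot(nrow(read1) == nrow(read2),
            all(read1$read_id == read2$read_id))
  merged <- vector("list", nrow(read1))
  for (i in seq_len(nrow(read1))) {
    m <- merge_pair(read1$seq[i], read2$seq[i], min_overlap,
                    max_mismatch_frac)
    if (!is.null(m)) merged[[i]] <- tibble::tibble(read_id = read1$read_id[i],
                                                   seq = m)
  }
  out <- dplyr::bind_rows(merged)
  if (nrow(out) == 0L) tibble::tibble(read_id = character(),
                                      seq = character()) else out
}
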