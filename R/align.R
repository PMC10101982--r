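#' Alignment scoring scheme
#'
#' Parameters for the affine-gap aligner. A gap of length L scores
#' `gap_open + L * gap_extend`; the match score must be positive and the
#' penalties non-positive.
#'
#' @param match Score for a matching base pair (> 0).
#' @param mismatch Score for a mismatching pair (<= 0). `N` always scores as
#'   a mismatch.
#' @param gap_open Gap opening score (<= 0), charged once per gap.
#' @param gap_extend Gap extension score (<= 0), charged per gapped base.
#' @return An object of class `scoring_scheme`.
#' @examples
#' scoring_scheme()
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L, gap_open = -5L,
                           gap_extend = -2L) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = as.numeric(match), mismatch = as.numeric(mismatch),
                 gap_open = as.numeric(gap_open),
                 gap_extend = as.numeric(gap_extend)),
            class = "scoring_scheme")
}

#' Semi-global pairwise alignment
#'
#' Optimal affine-gap alignment in which the query is aligned end to end
#' while leading and trailing reference bases are skipped for free
#' ("glocal" alignment). Used to place circNC junction flanks on their
#' reference transcript. Traceback is deterministic: on score ties the
#' diagonal (match/mismatch) move is preferred, then the query-consuming gap,
#' then the reference-consuming gap, and the end column with the smallest
#' reference offset wins.
#'
#' @param query,reference Nucleotide strings over A/C/G/T/N; any other
#'   character is an error.
#' @param scheme A [scoring_scheme()].
#' @return An object of class `alignment_result`: a list with `score`,
#'   `query_interval` and `ref_interval` (0-based half-open), `ops` (a tibble
#'   of run-length encoded edit operations: `M` match, `X` mismatch, `I`
#'   insertion in the query, `D` deletion of a reference base), `matches`,
#'   `columns` and `identity` (matches / alignment columns).
#' @examples
#' semiglobal_align("ACGT", "TTACGTTT")
#' @export
semiglobal_align <- function(query, reference, scheme = scoring_scheme()) {
  stopifnot(is.character(query), length(query) == 1L,
            is.character(reference), length(reference) == 1L)
  if (nchar(query) == 0L || nchar(reference) == 0L) {
    stop("query and reference must be non-empty", call. = FALSE)
  }
  check_alphabet(query, "query")
  check_alphabet(reference, "reference")
  raw <- .semiglobal_align_cpp(query, reference, scheme$match,
                               scheme$mismatch, scheme$gap_open,
                               scheme$gap_extend)
  structure(list(
    score = raw$score,
    query_interval = c(0L, nchar(query)),
    ref_interval = c(raw$ref_start, raw$ref_end),
    ops = tibble::tibble(op = unlist(raw$op), len = unlist(raw$len)),
    matches = raw$matches,
    columns = raw$columns,
    identity = if (raw$columns > 0L) raw$matches / raw$columns else 0
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> score %g, ref [%d, %d), identity %.3f\n",
              x$score, x$ref_interval[1L], x$ref_interval[2L], x$identity))
  cat(" ops:", paste0(x$ops$len, x$ops$op, collapse = ""), "\n")
  invisible(x)
}

#' Alignment scores for many query/reference pairs
#'
#' Score-only version of [semiglobal_align()], vectorized over pairs.
#'
#' @param queries,references Character vectors of equal length.
#' @inheritParams semiglobal_align
#' @return Numeric vector of optimal scores.
#' @export
semiglobal_scores <- function(queries, references, scheme = scoring_scheme()) {
  stopifnot(length(queries) == length(references))
  check_alphabet(queries, "queries")
  check_alphabet(references, "references")
  if (any(nchar(queries) == 0L) || any(nchar(references) == 0L)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  .semiglobal_scores_cpp(queries, references, scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend)
}

#' Re-score an alignment from its edit operations
#'
#' Recomputes the score of an [semiglobal_align()] result from its run-length
#' encoded operations under a scheme; used to assert internal consistency.
#'
#' @param aln An `alignment_result`.
#' @inheritParams semiglobal_align
#' @return Numeric score.
#' @export
rescore_alignment <- function(aln, scheme = scoring_scheme()) {
  sc <- 0
  for (k in seq_len(nrow(aln$ops))) {
    op <- aln$ops$op[k]
    len <- aln$ops$len[k]
    sc <- sc + switch(op,
      M = len * scheme$match,
      X = len * scheme$mismatch,
      I = scheme$gap_open + len * scheme$gap_extend,
      D = scheme$gap_open + len * scheme$gap_extend,
      stop("unknown op: ", op)
    )
  }
  sc
}
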