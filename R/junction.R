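base_at <- function(seq, pos0) substr(seq, pos0 + 1L, pos0 + 1L)

# extend a polyA-run boundary across single-base interruptions (candidate
# sequencing errors inside the tail). Each jump crosses one non-A base that is
# immediately followed (rightward) or preceded (leftward) by at least one A.
# Returns the candidate boundaries in jump order, starting with no jump.
run_boundary_candidates <- function(seq, pos, direction, max_jumps = 3L) {
  n <- nchar(seq)
  cands <- pos
  t <- pos
  for (j in seq_len(max_jumps)) {
    if (direction == "right") {
      if (t >= n || base_at(seq, t) == "A") break
      if (t + 1L >= n || base_at(seq, t + 1L) != "A") break
      t <- t + 1L
      while (t < n && base_at(seq, t) == "A") t <- t + 1L
    } else {
      if (t <= 0L || base_at(seq, t - 1L) == "A") break
      if (t - 2L < 0L || base_at(seq, t - 2L) != "A") break
      t <- t - 1L
      while (t > 0L && base_at(seq, t - 1L) == "A") t <- t - 1L
    }
    cands <- c(cands, t)
  }
  cands
}

# reference coordinate aligned to the first (edge = "first") or last
# (edge = "last") query base, extrapolating through unaligned edge bases
aligned_edge_ref <- function(aln, edge, ref_len) {
  ops <- rep(aln$ops$op, aln$ops$len)
  if (edge == "last") ops <- rev(ops)
  qoff <- 0L
  roff <- 0L
  for (op in ops) {
    if (op == "M" || op == "X") break
    if (op == "I") qoff <- qoff + 1L
    if (op == "D") roff <- roff + 1L
  }
  if (edge == "first") {
    pos <- aln$ref_interval[1L] + roff - qoff
  } else {
    pos <- aln$ref_interval[2L] - 1L - roff + qoff
  }
  min(max(pos, 0L), ref_len - 1L)
}

flank_stats <- function(aln) {
  aligned <- sum(aln$ops$len[aln$ops$op %in% c("M", "X")])
  list(aligned = aligned, identity = aln$identity)
}

#' Call a circNC junction at nucleotide precision
#'
#' Splits a polyA-filtered read at its polyA run, aligns the post-run segment
#' to the transcript 5' region and the pre-run segment to the 3' region, and
#' reports the cap-addition site (reference position aligned to the first
#' base after the run), the 3' end site (reference position aligned to the
#' last base before the run) and the tail length.
#'
#' Because a substitution error inside the tail splits the A run, the caller
#' considers boundary candidates that jump across single non-A interruptions
#' (up to `max_jumps` per side) and keeps the candidate whose flank alignment
#' scores best; ties keep the unextended run. A templated adenosine at the
#' junction edge is absorbed into the maximal run, so the called cap site is
#' the first post-run base and `alt_cap_sites` lists up to `max_alt`
#' alternative upstream positions where the reference continues in `A`.
#'
#' Confidence is `high` when both flanks have at least `min_flank` aligned
#' bases at identity `min_identity` or better, `low` when exactly one flank
#' qualifies (only the qualifying site is reported), `none` otherwise.
#'
#' @param seq Read sequence in polyA orientation (must contain a qualifying
#'   run; see [filter_polya()]).
#' @param model The [transcript_model()] the amplicon derives from.
#' @param scheme A [scoring_scheme()].
#' @param min_flank Minimum aligned flank length (nt).
#' @param min_identity Minimum flank alignment identity.
#' @param min_polya Minimum polyA run length (default 8).
#' @param max_jumps Maximum error-bridging extensions per run boundary.
#' @param max_alt Maximum alternative upstream cap sites reported.
#' @return An object of class `junction_call`: gene_id, `cap_site` and
#'   `three_prime_site` (0-based transcript coordinates, `NA` for a
#'   disqualified flank), `polya_len`, `confidence`, flank alignments,
#'   `alt_cap_sites`, and the run interval in the read.
#' @export
call_junction <- function(seq, model, scheme = scoring_scheme(),
                          min_flank = 15L, min_identity = 0.9,
                          min_polya = 8L, max_jumps = 3L, max_alt = 3L) {
  stopifnot(inherits(model, "transcript_model"))
  run <- find_polya_run(seq, min_polya)
  if (is.null(run)) {
    stop("no polyA run of length >= ", min_polya, " in read", call. = FALSE)
  }
  n <- nchar(seq)
  tx_len <- nchar(model$sequence)
  ref5 <- substr(model$sequence, 1L, model$primer_rev[2L])
  off3 <- model$primer_fwd[1L]
  ref3 <- substr(model$sequence, off3 + 1L, tx_len)

  pick_boundary <- function(cands, make_seg, ref) {
    aligns <- vector("list", length(cands))
    scores <- rep(-Inf, length(cands))
    for (i in seq_along(cands)) {
      seg <- make_seg(cands[i])
      if (nchar(seg) == 0L) next
      aligns[[i]] <- semiglobal_align(seg, ref, scheme)
      scores[i] <- aligns[[i]]$score
    }
    if (all(is.infinite(scores))) return(NULL)
    best <- which.max(scores)  # ties keep the fewest jumps (listed first)
    list(boundary = cands[best], aln = aligns[[best]],
         jumps = best - 1L)
  }

  right <- pick_boundary(
    run_boundary_candidates(seq, run$end, "right", max_jumps),
    function(t) substr(seq, t + 1L, n), ref5)
  left <- pick_boundary(
    run_boundary_candidates(seq, run$start, "left", max_jumps),
    function(s) substr(seq, 1L, s), ref3)

  cap_site <- NA_integer_
  three_prime_site <- NA_integer_
  ok5 <- FALSE
  ok3 <- FALSE
  if (!is.null(right)) {
    st <- flank_stats(right$aln)
    ok5 <- st$aligned >= min_flank && st$identity >= min_identity
    cap_site <- aligned_edge_ref(right$aln, "first", nchar(ref5))
  }
  if (!is.null(left)) {
    st <- flank_stats(left$aln)
    ok3 <- st$aligned >= min_flank && st$identity >= min_identity
    three_prime_site <- off3 + aligned_edge_ref(left$aln, "last", nchar(ref3))
  }
  confidence <- if (ok5 && ok3) "high" else if (ok5 || ok3) "low" else "none"
  if (!ok5) cap_site <- NA_integer_
  if (!ok3) three_prime_site <- NA_integer_

  run_start <- if (is.null(left)) run$start else left$boundary
  run_end <- if (is.null(right)) run$end else right$boundary

  alt <- integer()
  if (!is.na(cap_site)) {
    p <- cap_site - 1L
    while (p >= 0L && length(alt) < max_alt &&
           base_at(model$sequence, p) == "A") {
      alt <- c(alt, p)
      p <- p - 1L
    }
  }

  structure(list(
    gene_id = model$gene_id,
    cap_site = cap_site,
    three_prime_site = three_prime_site,
    polya_len = run_end - run_start,
    confidence = confidence,
    five_flank_alignment = if (is.null(right)) NULL else right$aln,
    three_flank_alignment = if (is.null(left)) NULL else left$aln,
    alt_cap_sites = alt,
    run_interval = c(run_start, run_end),
    jumps = c(left = if (is.null(left)) 0L else left$jumps,
              right = if (is.null(right)) 0L else right$jumps),
    seq = seq
  ), class = "junction_call")
}

#' @export
print.junction_call <- function(x, ...) {
  cat(sprintf(
    "<junction_call> %s: cap %s, 3' end %s, polyA %d nt, confidence %s\n",
    x$gene_id,
    ifelse(is.na(x$cap_site), "NA", x$cap_site + 1L),
    ifelse(is.na(x$three_prime_site), "NA", x$three_prime_site + 1L),
    x$polya_len, x$confidence))
  invisible(x)
}

#' Classify a cap-addition site against the reference base
#'
#' Looks up the sense-strand reference base at the called cap site. An `A`
#' is consistent with ab initio capping (the metabolite incorporated as the
#' initiating nucleotide in place of ATP); any other base implies the cap
#' was added post-transcriptionally.
#'
#' @param call A [call_junction()] result with confidence other than `none`
#'   and a reported cap site.
#' @param model The corresponding [transcript_model()].
#' @return Tibble with `gene_id`, `cap_site` (0-based), `ref_base`,
#'   `category` (`adenosine_consistent` or `non_adenosine`).
#' @export
classify_cap_site <- function(call, model) {
  stopifnot(inherits(call, "junction_call"),
            inherits(model, "transcript_model"))
  if (call$confidence == "none") {
    stop("cannot classify a confidence-none call", call. = FALSE)
  }
  if (is.na(call$cap_site)) {
    stop("call reports no cap site", call. = FALSE)
  }
  if (call$cap_site < 0L || call$cap_site >= nchar(model$sequence)) {
    stop("cap site outside transcript bounds", call. = FALSE)
  }
  ref_base <- base_at(model$sequence, call$cap_site)
  tibble::tibble(
    gene_id = call$gene_id, cap_site = call$cap_site, ref_base = ref_base,
    category = if (ref_base == "A") "adenosine_consistent" else
      "non_adenosine")
}

#' Call junctions for a set of filtered reads
#'
#' Deduplicates sequences, calls the junction once per unique sequence and
#' returns a flat table with support counts.
#'
#' @param reads Tibble with `seq` (already polyA-filtered and oriented).
#' @inheritParams call_junction
#' @return Tibble: `seq`, `count`, `cap_site`, `three_prime_site`,
#'   `polya_len`, `confidence`, `five_identity`, `three_identity`,
#'   `alt_cap_sites` (list column), `n_jumps`.
#' @export
call_junctions <- function(reads, model, scheme = scoring_scheme(),
                           min_flank = 15L, min_identity = 0.9,
                           min_polya = 8L, max_jumps = 3L) {
  uniq <- rank_unique_reads(reads, k = .Machine$integer.max)
  rows <- vector("list", nrow(uniq))
  for (i in seq_len(nrow(uniq))) {
    cl <- call_junction(uniq$seq[i], model, scheme, min_flank, min_identity,
                        min_polya, max_jumps)
    rows[[i]] <- tibble::tibble(
      gene_id = model$gene_id,
      seq = uniq$seq[i], count = uniq$count[i],
      cap_site = cl$cap_site, three_prime_site = cl$three_prime_site,
      polya_len = cl$polya_len, confidence = cl$confidence,
      five_identity = if (is.null(cl$five_flank_alignment)) NA_real_ else
        cl$five_flank_alignment$identity,
      three_identity = if (is.null(cl$three_flank_alignment)) NA_real_ else
        cl$three_flank_alignment$identity,
      alt_cap_sites = list(cl$alt_cap_sites),
      n_jumps = sum(cl$jumps))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(gene_id = character(), seq = character(),
                          count = integer(), cap_site = integer(),
                          three_prime_site = integer(), polya_len = integer(),
                          confidence = character(), five_identity = double(),
                          three_identity = double(), alt_cap_sites = list(),
                          n_jumps = integer())
  }
  out
}
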