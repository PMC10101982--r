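# truncated-normal polyA tail lengths, rounded to integer nt
draw_polya_len <- function(n, params) {
  mu <- params[["mean"]]; sd <- params[["sd"]]; lo <- params[["min"]]
  if (sd <= 0) return(rep(as.integer(max(round(mu), lo)), n))
  p_lo <- pnorm(lo - 0.5, mu, sd)
  u <- runif(n, p_lo, 1)
  pmax(as.integer(round(qnorm(u, mu, sd))), as.integer(lo))
}

sample_pos <- function(dist, n) {
  dist$pos[sample.int(nrow(dist), n, replace = TRUE, prob = dist$weight)]
}

count_edge_a <- function(seq, side = c("left", "right")) {
  side <- match.arg(side)
  pat <- if (side == "left") "^A*" else "A*$"
  attr(regexpr(pat, seq), "match.length")
}

add_substitutions <- function(seqs, error_rate) {
  if (error_rate == 0) {
    return(list(seqs = seqs, n_errors = integer(length(seqs))))
  }
  n_err <- rbinom(length(seqs), nchar(seqs), error_rate)
  for (i in which(n_err > 0L)) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(length(chars), n_err[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  list(seqs = seqs, n_errors = n_err)
}

#' Simulate circNC junction amplicon read pairs
#'
#' Builds circularization amplicons for one transcript and sequences them as
#' paired-end reads with uniform substitution errors. The circularized RNA
#' fuses the transcript 5' end (at the cap-addition site) to the 3' polyA
#' tail, so the amplicon reads, left to right:
#' `transcript[fwd_primer_start .. cleavage_site]` + `A x L` +
#' `transcript[cap_site .. rev_primer_end)`. Read 1 is the amplicon 5' prefix
#' and read 2 the reverse complement of its 3' suffix.
#'
#' When the reference base at the cap site is `A`, or the 3' flank ends in
#' `A`, those templated bases are indistinguishable from the tail; the truth
#' table records the homopolymer extensions (`ext5`, `ext3`) and
#' boundary-attributed coordinates (`cap_site_attr`, `three_prime_site_attr`,
#' `polya_len_attr`) that an exact junction caller can recover.
#'
#' @param model A [transcript_model()].
#' @param n_reads Number of read pairs.
#' @param cap_type `"NAD"` (uses the NAD cap-site distribution; circNC after
#'   Rai1 deNADding) or `"m7G"` (canonical decapping control).
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param read_len Read length in nt (reads are truncated at amplicon ends).
#' @param min_flank Flank length used to annotate whether each read spans the
#'   junction with usable flanks.
#' @param seed Integer seed.
#' @return List with `read1`, `read2` (tibbles: `read_id`, `seq`) and `truth`
#'   (one row per pair: planted coordinates, tail length, extensions,
#'   error and junction-spanning annotations).
#' @examples
#' tx <- simulate_transcriptome(1, seed = 1)
#' rd <- simulate_circ_reads(tx$models[[1]], 5, "NAD", seed = 2)
#' rd$truth
#' @export
simulate_circ_reads <- function(model, n_reads, cap_type = c("NAD", "m7G"),
                                error_rate = 0, read_len = 250L,
                                min_flank = 15L, seed = NULL) {
  cap_type <- match.arg(cap_type)
  stopifnot(inherits(model, "transcript_model"), n_reads >= 0,
            error_rate >= 0, error_rate < 1, read_len >= 1)
  dist <- if (cap_type == "NAD") model$cap_site_dist_nad else
    model$cap_site_dist_m7g
  if (nrow(dist) == 0L) stop("cap-site distribution is empty", call. = FALSE)

  with_seed(seed, {
    cap <- sample_pos(dist, n_reads)
    cleave <- sample_pos(model$cleavage_site_dist, n_reads)
    tail_len <- draw_polya_len(n_reads, model$polya_len_params)
    fwd <- model$primer_fwd[1L]
    rev_end <- model$primer_rev[2L]

    seg3 <- substr(rep(model$sequence, n_reads), fwd + 1L, cleave + 1L)
    seg5 <- substr(rep(model$sequence, n_reads), cap + 1L, rev_end)
    amplicon <- paste0(seg3, strrep("A", tail_len), seg5)
    alen <- nchar(amplicon)

    ext3 <- vapply(seg3, count_edge_a, 0L, side = "right", USE.NAMES = FALSE)
    ext5 <- vapply(seg5, count_edge_a, 0L, side = "left", USE.NAMES = FALSE)

    r1 <- substr(amplicon, 1L, pmin(read_len, alen))
    r2 <- vapply(substr(amplicon, pmax(1L, alen - read_len + 1L), alen),
                 revcomp, "", USE.NAMES = FALSE)
    e1 <- add_substitutions(r1, error_rate)
    e2 <- add_substitutions(r2, error_rate)

    run_start <- nchar(seg3) - ext3         # 0-based, attributed run
    run_end <- nchar(seg3) + tail_len + ext5
    ids <- sprintf("%s_%s_%06d", model$gene_id, cap_type, seq_len(n_reads))
    truth <- tibble::tibble(
      read_id = ids, gene_id = model$gene_id, cap_type = cap_type,
      true_cap_site = cap, true_3p_site = cleave, true_polya_len = tail_len,
      ext5 = ext5, ext3 = ext3,
      cap_site_attr = cap + ext5,
      three_prime_site_attr = cleave - ext3,
      polya_len_attr = tail_len + ext5 + ext3,
      amplicon_len = alen,
      n_errors = e1$n_errors + e2$n_errors,
      spans_r1 = pmin(read_len, alen) >= run_end + min_flank &
        run_start >= min_flank,
      spans_r2 = pmax(1L, alen - read_len + 1L) - 1L <= run_start - min_flank &
        alen - run_end >= min_flank,
      spans_merged = (2L * pmin(read_len, alen) - alen) >= 12L &
        run_start >= min_flank & alen - run_end >= min_flank)
    list(read1 = tibble::tibble(read_id = ids, seq = e1$seqs),
         read2 = tibble::tibble(read_id = ids, seq = e2$seqs),
         truth = truth)
  })
}
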