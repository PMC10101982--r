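#' Construct a transcript model
#'
#' A transcript model carries the reference sequence (sense strand, 5'->3'),
#' the segment lengths, weighted cap-addition-site and cleavage-site
#' distributions, polyA tail length parameters, and the primer intervals used
#' to build circularization (circNC) amplicons. All coordinates are 0-based
#' half-open transcript coordinates; `cleavage_site` positions index the last
#' templated base (inclusive) so that every cap site must lie strictly before
#' every cleavage site.
#'
#' @param gene_id Gene identifier.
#' @param sequence Nucleotide string (A/C/G/T).
#' @param utr5_len,cds_len,utr3_len Segment lengths in nt; must sum to
#'   `nchar(sequence)`.
#' @param cap_site_dist_m7g,cap_site_dist_nad Tibbles/data frames with columns
#'   `pos` (0-based transcript coordinate) and `weight` (non-negative, summing
#'   to 1).
#' @param cleavage_site_dist Same layout; positions of the last templated base.
#' @param polya_len_params Named numeric `c(mean=, sd=, min=)` in nt.
#' @param primer_fwd,primer_rev Integer `c(start, end)` half-open intervals in
#'   transcript coordinates: the forward primer anneals upstream of the
#'   cleavage sites (3' side of the amplicon), the reverse primer downstream
#'   of the cap sites (5' side).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, sequence, utr5_len, cds_len, utr3_len,
                             cap_site_dist_m7g, cap_site_dist_nad,
                             cleavage_site_dist,
                             polya_len_params = c(mean = 30, sd = 8, min = 12),
                             primer_fwd, primer_rev) {
  sequence <- toupper(sequence)
  check_alphabet(sequence, gene_id)
  len <- nchar(sequence)
  if (utr5_len + cds_len + utr3_len != len) {
    stop("segment lengths must sum to the sequence length", call. = FALSE)
  }
  norm_dist <- function(d, what) {
    d <- tibble::as_tibble(d)
    stopifnot(all(c("pos", "weight") %in% names(d)))
    if (nrow(d) == 0L) stop(what, " distribution is empty", call. = FALSE)
    if (any(d$weight < 0) || abs(sum(d$weight) - 1) > 1e-8) {
      stop(what, " weights must be non-negative and sum to 1", call. = FALSE)
    }
    if (any(d$pos < 0L | d$pos >= len)) {
      stop(what, " positions outside the transcript", call. = FALSE)
    }
    d
  }
  cap_m7g <- norm_dist(cap_site_dist_m7g, "m7G cap-site")
  cap_nad <- norm_dist(cap_site_dist_nad, "NAD cap-site")
  cleave <- norm_dist(cleavage_site_dist, "cleavage-site")
  if (max(cap_m7g$pos, cap_nad$pos) >= min(cleave$pos)) {
    stop("every cap site must precede every cleavage site", call. = FALSE)
  }
  stopifnot(all(c("mean", "sd", "min") %in% names(polya_len_params)),
            polya_len_params[["min"]] >= 0)
  stopifnot(length(primer_fwd) == 2L, length(primer_rev) == 2L,
            primer_fwd[1L] < primer_fwd[2L], primer_rev[1L] < primer_rev[2L],
            primer_fwd[1L] >= 0L, primer_rev[2L] <= len)
  structure(list(
    gene_id = gene_id, sequence = sequence,
    utr5_len = as.integer(utr5_len), cds_len = as.integer(cds_len),
    utr3_len = as.integer(utr3_len),
    cap_site_dist_m7g = cap_m7g, cap_site_dist_nad = cap_nad,
    cleavage_site_dist = cleave,
    polya_len_params = polya_len_params,
    primer_fwd = as.integer(primer_fwd), primer_rev = as.integer(primer_rev)
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s: %d nt (UTR5 %d | CDS %d | UTR3 %d)\n",
              x$gene_id, nchar(x$sequence), x$utr5_len, x$cds_len, x$utr3_len))
  invisible(x)
}

# random sequence whose A homopolymers are capped at max_a_run, so that the
# only long A run in a simulated amplicon is the planted polyA tail
random_sequence <- function(len, max_a_run = 6L) {
  s <- sample(DNA_BASES, len, replace = TRUE)
  r <- rle(s)
  idx <- which(r$values == "A" & r$lengths > max_a_run)
  if (length(idx)) {
    ends <- cumsum(r$lengths)
    for (k in idx) {
      run_start <- ends[k] - r$lengths[k] + 1L
      fix <- seq(run_start + max_a_run, ends[k], by = max_a_run + 1L)
      s[fix] <- sample(c("C", "G", "T"), length(fix), replace = TRUE)
    }
  }
  paste(s, collapse = "")
}

# weighted site distribution: k distinct positions, Dirichlet-like weights
# sorted so the first position is predominant
random_site_dist <- function(candidates, k) {
  k <- min(k, length(candidates))
  pos <- sort(sample(candidates, k))
  w <- rgamma(k, shape = 2)
  w <- sort(w / sum(w), decreasing = TRUE)
  # heaviest weight on a random one of the chosen positions
  pos <- pos[sample.int(length(pos))]
  tibble::tibble(pos = as.integer(pos), weight = w)
}

#' Simulate a reference transcriptome
#'
#' Generates `n_genes` transcript models with uniform-random sequences
#' (A-homopolymers capped at 6 nt so planted polyA tails stay unambiguous),
#' distinct predominant NAD and m7G cap sites inside the 5' UTR,
#' cleavage sites at the 3' end, and primer intervals that yield junction
#' amplicons of a few hundred bases.
#'
#' @param n_genes Number of transcripts (>= 0).
#' @param length_params List with integer ranges `utr5`, `cds`, `utr3`
#'   (`c(min, max)` each).
#' @param polya_len_params PolyA tail parameters, see [transcript_model()].
#' @param n_cap_sites Maximum number of alternative cap sites per cap class.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `models` (named list of `transcript_model`) and
#'   `annotation` (tibble: gene_id, lengths, primer coordinates, predominant
#'   cap sites).
#' @examples
#' tx <- simulate_transcriptome(2, seed = 1)
#' tx$annotation
#' @export
simulate_transcriptome <- function(n_genes,
                                   length_params = list(utr5 = c(20L, 100L),
                                                        cds = c(300L, 900L),
                                                        utr3 = c(50L, 300L)),
                                   polya_len_params = c(mean = 30, sd = 8,
                                                        min = 12),
                                   n_cap_sites = 3L,
                                   seed = NULL) {
  stopifnot(n_genes >= 0)
  for (nm in c("utr5", "cds", "utr3")) {
    rng <- length_params[[nm]]
    if (is.null(rng) || length(rng) != 2L || rng[1L] > rng[2L] || rng[1L] <= 0) {
      stop("invalid length range for ", nm, call. = FALSE)
    }
  }
  with_seed(seed, {
    models <- vector("list", n_genes)
    ann <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      gene_id <- sprintf("SYN%04d", g)
      pick <- function(nm) {
        rng <- length_params[[nm]]
        sample(seq(rng[1L], rng[2L]), 1L)
      }
      utr5 <- pick("utr5"); cds <- pick("cds"); utr3 <- pick("utr3")
      len <- utr5 + cds + utr3
      seqc <- random_sequence(len)

      # cap sites live in the 5' UTR; the two cap classes get distinct
      # predominant start sites (observed for NAD vs m7G caps)
      cap_cand <- 0:(utr5 - 1L)
      nad <- random_site_dist(cap_cand, sample(seq_len(n_cap_sites), 1L))
      repeat {
        m7g <- random_site_dist(cap_cand, sample(seq_len(n_cap_sites), 1L))
        if (m7g$pos[1L] != nad$pos[1L]) break
      }
      # cleavage at the transcript 3' end (last templated base)
      cl_cand <- (len - 6L):(len - 1L)
      cleave <- random_site_dist(cl_cand, sample(1:2, 1L))

      flank3 <- sample(120:180, 1L)
      fwd_start <- max(0L, min(cleave$pos) - flank3)
      flank5 <- sample(150:200, 1L)
      rev_end <- min(len, max(nad$pos, m7g$pos) + flank5)
      models[[g]] <- transcript_model(
        gene_id, seqc, utr5, cds, utr3,
        cap_site_dist_m7g = m7g, cap_site_dist_nad = nad,
        cleavage_site_dist = cleave,
        polya_len_params = polya_len_params,
        primer_fwd = c(fwd_start, fwd_start + 20L),
        primer_rev = c(rev_end - 20L, rev_end))
      ann[[g]] <- tibble::tibble(
        gene_id = gene_id, length = len, utr5_len = utr5, cds_len = cds,
        utr3_len = utr3, fwd_start = fwd_start, fwd_end = fwd_start + 20L,
        rev_start = rev_end - 20L, rev_end = rev_end,
        cap_site_nad = nad$pos[1L], cap_site_m7g = m7g$pos[1L],
        cleavage_site = cleave$pos[which.max(cleave$weight)])
    }
    names(models) <- vapply(models, `[[`, "", "gene_id")
    list(models = models,
         annotation = if (n_genes > 0) dplyr::bind_rows(ann) else
           tibble::tibble(gene_id = character(), length = integer(),
                          utr5_len = integer(), cds_len = integer(),
                          utr3_len = integer(), fwd_start = integer(),
                          fwd_end = integer(), rev_start = integer(),
                          rev_end = integer(), cap_site_nad = integer(),
                          cap_site_m7g = integer(), cleavage_site = integer()))
  })
}

#' Write a simulated transcriptome to FASTA and annotation TSV
#'
#' @param tx Result of [simulate_transcriptome()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (`fasta`, `annotation`).
#' @export
write_transcriptome <- function(tx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "reference.fa")
  seqs <- Biostrings::DNAStringSet(
    vapply(tx$models, `[[`, "", "sequence"))
  names(seqs) <- names(tx$models)
  Biostrings::writeXStringSet(seqs, fasta)
  ann <- file.path(dir, "annotation.tsv")
  readr::write_tsv(tx$annotation, ann)
  invisible(list(fasta = fasta, annotation = ann))
}
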