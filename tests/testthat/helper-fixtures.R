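# Hand-built transcript fixture with full control over the junction-edge
# bases, plus amplicon/read constructors mirroring the circNC geometry.

toy_sequence <- function(len = 400L, seed = 7L, forbid_a_at = integer()) {
  withr::with_seed(seed, {
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    # cap genomic A homopolymers at 4 nt so the planted tail is unambiguous
    r <- rle(s)
    ends <- cumsum(r$lengths)
    for (k in which(r$values == "A" & r$lengths > 4L)) {
      fix <- seq(ends[k] - r$lengths[k] + 5L, ends[k], by = 5L)
      s[fix] <- "G"
    }
    s[forbid_a_at + 1L] <- "G"
    paste(s, collapse = "")
  })
}

toy_model <- function(cap_nad = 8L, cap_m7g = 3L, cleave = 398L,
                      len = 400L, seq = NULL, polya_min = 12L) {
  if (is.null(seq)) {
    # junction-edge bases forced non-A so planted coordinates are exact
    seq <- toy_sequence(len, forbid_a_at = c(cap_nad, cap_m7g, cleave))
  }
  transcript_model(
    gene_id = "TOY1", sequence = seq,
    utr5_len = 40L, cds_len = len - 100L, utr3_len = 60L,
    cap_site_dist_m7g = data.frame(pos = cap_m7g, weight = 1),
    cap_site_dist_nad = data.frame(pos = cap_nad, weight = 1),
    cleavage_site_dist = data.frame(pos = cleave, weight = 1),
    polya_len_params = c(mean = 25, sd = 5, min = polya_min),
    primer_fwd = c(len - 160L, len - 140L),
    primer_rev = c(180L, 200L))
}

# amplicon exactly as the circularization produces it:
# 3' flank (forward primer .. cleavage site) + tail + 5' flank (cap .. reverse
# primer end)
toy_amplicon <- function(model, cap, cleave, polya_len) {
  paste0(substr(model$sequence, model$primer_fwd[1L] + 1L, cleave + 1L),
         strrep("A", polya_len),
         substr(model$sequence, cap + 1L, model$primer_rev[2L]))
}

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# enumerate all strings of the given lengths over an alphabet
all_strings <- function(max_len, alphabet = c("A", "C")) {
  unlist(lapply(seq_len(max_len), function(l) {
    grid <- do.call(expand.grid, rep(list(alphabet), l))
    apply(grid, 1L, paste, collapse = "")
  }), use.names = FALSE)
}
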