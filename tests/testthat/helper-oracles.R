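# Independent oracles used to validate the implementation.

# Top-down scoring of the semi-global alignment definition: best score over
# all alignments that consume the whole query, with free reference end gaps
# and affine run-scored gaps. Written as memoized recursion over
# (query used, reference used, last column type), independent of the
# package's dynamic program.
oracle_semiglobal_score <- function(q, r, match = 2, mismatch = -3,
                                    gopen = -5, gext = -2) {
  qc <- strsplit(q, "", fixed = TRUE)[[1L]]
  rc <- strsplit(r, "", fixed = TRUE)[[1L]]
  n <- length(qc); m <- length(rc)
  memo <- new.env(parent = emptyenv())
  # best(i, j, s): best score of an alignment suffix that still has to
  # consume query i..n, may use reference j..m (plus free skips), with the
  # previous column of type s ("M", "I", "D", or "S" at the start).
  best <- function(i, j, s) {
    if (i > n) return(0)  # trailing reference is free
    key <- paste(i, j, s)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- -Inf
    if (s == "S") {  # free leading reference skip
      for (j0 in j:(m + 1L)) out <- max(out, best(i, j0, "M"))
    } else {
      if (j <= m) {
        sc <- if (qc[i] == rc[j] && qc[i] != "N") match else mismatch
        out <- max(out, sc + best(i + 1L, j + 1L, "M"))
        dcost <- gext + if (s == "D") 0 else gopen
        out <- max(out, dcost + best(i, j + 1L, "D"))
      }
      icost <- gext + if (s == "I") 0 else gopen
      out <- max(out, icost + best(i + 1L, j, "I"))
    }
    memo[[key]] <- out
    out
  }
  best(1L, 1L, "S")
}

# Fully exhaustive enumeration of every alignment path (no memoization);
# tractable only for very short sequences.
oracle_enumerate_score <- function(q, r, match = 2, mismatch = -3,
                                   gopen = -5, gext = -2) {
  qc <- strsplit(q, "", fixed = TRUE)[[1L]]
  rc <- strsplit(r, "", fixed = TRUE)[[1L]]
  n <- length(qc); m <- length(rc)
  walk <- function(i, j, s) {
    if (i > n) return(0)
    out <- -Inf
    if (j <= m) {
      sc <- if (qc[i] == rc[j]) match else mismatch
      out <- max(out, sc + walk(i + 1L, j + 1L, "M"))
      out <- max(out, gext + (if (s == "D") 0 else gopen) + walk(i, j + 1L, "D"))
    }
    out <- max(out, gext + (if (s == "I") 0 else gopen) + walk(i + 1L, j, "I"))
    out
  }
  best <- -Inf
  for (j0 in 1:(m + 1L)) best <- max(best, walk(1L, j0, "M"))
  best
}

# brute-force best-overlap merge: try every admissible suffix/prefix overlap
oracle_merge <- function(seq1, seq2, min_overlap, max_mismatch_frac) {
  r2 <- nadcapr::revcomp(seq2)
  c1 <- strsplit(seq1, "", fixed = TRUE)[[1L]]
  c2 <- strsplit(r2, "", fixed = TRUE)[[1L]]
  n1 <- length(c1); n2 <- length(c2)
  cands <- list()
  for (o in seq_len(min(n1, n2))) {
    if (o < min_overlap) next
    mm <- sum(c1[(n1 - o + 1L):n1] != c2[1L:o])
    if (mm / o > max_mismatch_frac) next
    cands[[length(cands) + 1L]] <- list(o = o, score = o - 2L * mm)
  }
  if (length(cands) == 0L) return(NULL)
  scores <- vapply(cands, `[[`, 0, "score")
  os <- vapply(cands, `[[`, 0, "o")
  keep <- which(scores == max(scores))
  o <- max(os[keep])
  paste0(seq1, substr(r2, o + 1L, n2))
}

# brute-force BH step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- match(i, ord)
    cand <- vapply(rank_i:m, function(k) m * p[ord[k]] / k, 0)
    q[i] <- min(1, min(cand))
  }
  q
}

# brute-force median-of-ratios, normalized to geometric mean 1
oracle_size_factors <- function(counts) {
  geo <- apply(counts, 1L, function(x) exp(mean(log(x))))
  keep <- geo > 0
  sf <- vapply(seq_len(ncol(counts)), function(s) {
    median(counts[keep, s] / geo[keep])
  }, 0)
  sf / exp(mean(log(sf)))
}

# Iterative re-statement of the alignment optimum used for the exhaustive
# parameter sweeps (same mathematics as oracle_semiglobal_score, written as
# explicit score tables in R so large families of short pairs stay tractable)
oracle_semiglobal_dp <- function(q, r, match = 2, mismatch = -3,
                                 gopen = -5, gext = -2) {
  qc <- strsplit(q, "", fixed = TRUE)[[1L]]
  rc <- strsplit(r, "", fixed = TRUE)[[1L]]
  n <- length(qc); m <- length(rc)
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, ] <- 0
  for (i in 2L:(n + 1L)) {
    for (j in seq_len(m + 1L)) {
      if (j > 1L) {
        s <- if (qc[i - 1L] == rc[j - 1L] && qc[i - 1L] != "N") match else
          mismatch
        M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                       Y[i - 1L, j - 1L]) + s
      }
      X[i, j] <- max(M[i - 1L, j] + gopen, X[i - 1L, j],
                     Y[i - 1L, j] + gopen) + gext
      if (j > 1L) {
        Y[i, j] <- max(M[i, j - 1L] + gopen, Y[i, j - 1L],
                       X[i, j - 1L] + gopen) + gext
      }
    }
  }
  max(M[n + 1L, ], X[n + 1L, ], Y[n + 1L, ])
}
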