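#' Recalculate transcripts-per-million from counts
#'
#' `TPM_i = 1e6 * (c_i / L_i) / sum_j (c_j / L_j)` per sample column; an
#' all-zero column yields an all-zero TPM column.
#'
#' @param counts Non-negative count matrix (genes x samples) or a single
#'   column vector.
#' @param gene_lengths Positive lengths in nt, one per gene.
#' @return Matrix (or vector) of TPMs; positive columns sum to 1e6.
#' @examples
#' recalc_tpm(c(10, 20, 30), c(100, 200, 300))
#' @export
recalc_tpm <- function(counts, gene_lengths) {
  vec <- is.null(dim(counts))
  counts <- as.matrix(counts)
  stopifnot(length(gene_lengths) == nrow(counts), all(gene_lengths > 0),
            all(counts >= 0))
  rate <- counts / gene_lengths
  denom <- colSums(rate)
  tpm <- sweep(rate, 2L, ifelse(denom > 0, denom, 1), "/") * 1e6
  tpm[, denom == 0] <- 0
  if (vec) drop(tpm) else tpm
}

#' Median-of-ratios size factors
#'
#' The per-sample normalization factor is the median, over genes with a
#' positive geometric mean across samples, of the ratio of the sample's
#' count to that geometric mean. Factors are rescaled to geometric mean 1.
#'
#' @param counts Count matrix (genes x samples).
#' @return Numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  logg <- rowMeans(log(counts))
  keep <- is.finite(logg)
  if (!any(keep)) {
    stop("no gene has a nonzero count in every sample", call. = FALSE)
  }
  sf <- apply(counts, 2L, function(col) {
    exp(median(log(col[keep]) - logg[keep]))
  })
  sf / exp(mean(log(sf)))
}

#' Enrichment analysis configuration
#'
#' @param lfc_threshold Minimum log2 fold-change to call a gene capped
#'   (default 1, i.e. twofold; boundary inclusive).
#' @param q_threshold Maximum BH-adjusted p (default 0.01; inclusive).
#' @param min_total_count Genes with a smaller total count across samples are
#'   filtered before testing (default 10).
#' @param dispersion_mode `"common"` (default) pools a single
#'   method-of-moments dispersion across genes; `"per_gene_mom"` estimates
#'   each gene separately (noisy at triplicate depth and anticonservative;
#'   see the methods vignette).
#' @return An object of class `enrichment_config`.
#' @export
enrichment_config <- function(lfc_threshold = 1, q_threshold = 0.01,
                              min_total_count = 10,
                              dispersion_mode = c("common", "per_gene_mom")) {
  dispersion_mode <- match.arg(dispersion_mode)
  stopifnot(lfc_threshold > 0, q_threshold > 0, q_threshold < 1,
            min_total_count >= 0)
  structure(list(lfc_threshold = lfc_threshold, q_threshold = q_threshold,
                 min_total_count = min_total_count,
                 dispersion_mode = dispersion_mode),
            class = "enrichment_config")
}

# per-gene method-of-moments NB dispersion from normalized counts,
# averaged over the two condition groups, floored at 1e-8
mom_dispersion <- function(norm_counts, capture) {
  est <- function(m) {
    mu <- rowMeans(m)
    v <- apply(m, 1L, var)
    (v - mu) / mu^2
  }
  a <- (est(norm_counts[, !capture, drop = FALSE]) +
          est(norm_counts[, capture, drop = FALSE])) / 2
  a[!is.finite(a)] <- 0
  pmax(a, 1e-8)
}

# NB GLM group means with fixed dispersion and size-factor offsets,
# by per-group Newton iterations (vectorized over genes).
# Returns log-mean eta and the Fisher information of eta per gene.
nb_group_fit <- function(counts, sf, alpha, max_iter = 50L) {
  n <- ncol(counts)
  norm_mean <- as.vector(counts %*% (1 / sf)) / n
  # all-zero groups get a half-count shift instead of a degenerate MLE
  zero <- norm_mean == 0
  eta <- log(pmax(norm_mean, 0.5))
  for (it in seq_len(max_iter)) {
    mu <- exp(eta) %o% sf
    score <- rowSums((counts - mu) / (1 + alpha * mu))
    info <- rowSums(mu / (1 + alpha * mu))
    step <- pmax(pmin(score / pmax(info, 1e-12), 5), -5)
    step[zero] <- 0
    eta <- eta + step
    if (max(abs(step)) < 1e-10) break
  }
  mu <- exp(eta) %o% sf
  list(eta = eta, info = rowSums(mu / (1 + alpha * mu)))
}

#' Negative-binomial enrichment test (capture vs RNA-seq)
#'
#' Fits, per gene, a two-group NB log-linear model with size-factor offsets
#' and variance `mu + alpha * mu^2`, and tests the capture-vs-control
#' coefficient with a two-sided Wald statistic. This is a functional
#' stand-in for a full shrinkage-based differential pipeline: the scientific
#' output is the fold-change / q-value classification rule, not shrunken
#' effect estimates.
#'
#' @param counts Integer count matrix (genes x samples); no all-zero rows.
#' @param condition Character or factor per sample; `"rnaseq"` is the
#'   control, `"minus_adprc"` marks background-control libraries that are
#'   excluded from the test, and anything else is the capture condition.
#'   At least two replicates per tested group.
#' @param sf Size factors (default: [size_factors()] of `counts`).
#' @param dispersion_mode See [enrichment_config()].
#' @param dispersion Optional fixed dispersion (scalar or per gene) that
#'   bypasses estimation; `0` gives the Poisson limit.
#' @return Tibble: `gene_id`, `base_mean` (mean normalized count), `log2fc`
#'   (capture vs control), `se_log2fc`, `p_value`, and the dispersion used.
#' @export
nb_enrichment_test <- function(counts, condition, sf = NULL,
                               dispersion_mode = c("common",
                                                   "per_gene_mom"),
                               dispersion = NULL) {
  dispersion_mode <- match.arg(dispersion_mode)
  counts <- as.matrix(counts)
  # minus-ADPRC background controls are descriptive only, never tested
  use <- condition != "minus_adprc"
  counts <- counts[, use, drop = FALSE]
  if (!is.null(sf)) sf <- sf[use]
  condition <- condition[use]
  capture <- condition != "rnaseq"
  if (sum(capture) < 2L || sum(!capture) < 2L) {
    stop("need at least two replicates per condition", call. = FALSE)
  }
  if (any(rowSums(counts) == 0)) {
    stop("all-zero gene in the test input; filter first", call. = FALSE)
  }
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")

  if (!is.null(dispersion)) {
    stopifnot(all(dispersion >= 0))
    alpha <- rep_len(dispersion, nrow(counts))
  } else {
    alpha <- mom_dispersion(norm, capture)
    if (dispersion_mode == "common") {
      ok <- is.finite(alpha)
      alpha <- rep(max(mean(alpha[ok]), 1e-8), nrow(counts))
    }
  }

  f0 <- nb_group_fit(counts[, !capture, drop = FALSE], sf[!capture], alpha)
  f1 <- nb_group_fit(counts[, capture, drop = FALSE], sf[capture], alpha)
  beta <- f1$eta - f0$eta
  se <- sqrt(1 / f0$info + 1 / f1$info)
  wald <- beta / se
  p <- 2 * pnorm(-abs(wald))
  p[beta == 0] <- 1
  gene_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%05d", seq_len(nrow(counts)))
  tibble::tibble(
    gene_id = gene_ids,
    base_mean = unname(rowMeans(norm)),
    log2fc = unname(beta) / log(2),
    se_log2fc = unname(se) / log(2),
    p_value = unname(pmin(pmax(p, .Machine$double.xmin), 1)),
    dispersion = unname(alpha))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (the "q-value" of the twofold / q <= 0.01
#' classification rule).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Classify genes as capped by the fold-change / q-value rule
#'
#' A gene is called capped when it is enriched at least `2^lfc_threshold`
#' -fold over standard RNA-seq at `q <= q_threshold`; both boundaries are
#' inclusive.
#'
#' @param results Tibble with `log2fc` and `q_value` columns.
#' @param cfg An [enrichment_config()].
#' @return List with `results` (input plus `classified_capped`) and
#'   `summary` (tibble of class counts).
#' @export
classify_capped <- function(results, cfg = enrichment_config()) {
  stopifnot(all(c("log2fc", "q_value") %in% names(results)))
  results <- tibble::as_tibble(results)
  results$classified_capped <- results$log2fc >= cfg$lfc_threshold &
    results$q_value <= cfg$q_threshold
  list(results = results,
       summary = tibble::tibble(
         class = c("capped", "not_capped"),
         n = c(sum(results$classified_capped),
               sum(!results$classified_capped))))
}

#' Full enrichment analysis
#'
#' Filters low-count genes, computes size factors, runs the NB Wald test,
#' adjusts p-values and applies the capped classification.
#'
#' @param counts Integer count matrix (genes x samples, rownames = gene ids).
#' @param condition Condition per sample (`"rnaseq"` = control).
#' @param cfg An [enrichment_config()].
#' @return List: `results` (per tested gene: base_mean, log2fc, p, q,
#'   classified_capped), `summary`, `size_factors`, `n_filtered`.
#' @export
run_enrichment <- function(counts, condition, cfg = enrichment_config()) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts) >= cfg$min_total_count
  tested <- counts[keep, , drop = FALSE]
  sf <- size_factors(tested)
  res <- nb_enrichment_test(tested, condition, sf,
                            dispersion_mode = cfg$dispersion_mode)
  bg <- condition == "minus_adprc"
  if (any(bg)) {
    bg_norm <- sweep(tested[, bg, drop = FALSE], 2L, sf[bg], "/")
    res$mean_minus_adprc <- unname(rowMeans(bg_norm))
  }
  res$q_value <- bh_adjust(res$p_value)
  cls <- classify_capped(res, cfg)
  list(results = cls$results, summary = cls$summary, size_factors = sf,
       n_filtered = sum(!keep))
}

#' One-sided abundance-distribution comparison
#'
#' Welch one-sided t-test on log-transformed TPMs, testing whether the
#' first method's identified transcripts are less abundant than the
#' second's (capture methods that remove canonical-capped background can
#' reach into lower-abundance transcripts).
#'
#' @param tpm_a,tpm_b Numeric TPM vectors (length >= 2 each).
#' @param pseudocount Added before the log transform (default 1).
#' @return List with `statistic`, `p_value` and the group means on the log
#'   scale (alternative: mean(A) < mean(B)).
#' @export
compare_abundance <- function(tpm_a, tpm_b, pseudocount = 1) {
  if (length(tpm_a) < 2L || length(tpm_b) < 2L) {
    stop("need at least two observations per group", call. = FALSE)
  }
  la <- log(tpm_a + pseudocount)
  lb <- log(tpm_b + pseudocount)
  ht <- t.test(la, lb, alternative = "less")
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       mean_log_a = mean(la), mean_log_b = mean(lb))
}
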