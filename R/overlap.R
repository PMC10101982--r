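#' Permutation null for the overlap of two gene sets
#'
#' Keeps the set sizes fixed and randomizes the identity of the genes in
#' each set, drawing both sets independently and uniformly without
#' replacement from the universe, and recomputes the intersection size
#' `n_iter` times. The empirical upper-tail p uses the add-one rule
#' `(1 + #{perm >= observed}) / (n_iter + 1)` and is therefore never zero.
#'
#' @param set_a,set_b Character vectors of gene ids (subsets of `universe`).
#' @param universe Character vector of all eligible gene ids.
#' @param n_iter Number of randomizations (default 10000).
#' @param seed Integer seed; results are reproducible per seed.
#' @return List: `observed`, `perm_mean`, `perm_sd`, `empirical_p`,
#'   `n_iter`, `seed`.
#' @export
permutation_overlap <- function(set_a, set_b, universe, n_iter = 10000L,
                                seed = NULL) {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  stopifnot(n_iter >= 1)
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("sets must be subsets of the universe", call. = FALSE)
  }
  n1 <- length(set_a); n2 <- length(set_b); N <- length(universe)
  observed <- length(intersect(set_a, set_b))
  with_seed(seed, {
    member <- logical(N)
    perm <- integer(n_iter)
    for (i in seq_len(n_iter)) {
      sa <- sample.int(N, n1)
      sb <- sample.int(N, n2)
      member[sb] <- TRUE
      perm[i] <- sum(member[sa])
      member[sb] <- FALSE
    }
    list(observed = observed,
         perm_mean = mean(perm),
         perm_sd = stats::sd(perm),
         empirical_p = (1 + sum(perm >= observed)) / (n_iter + 1),
         n_iter = as.integer(n_iter),
         seed = seed)
  })
}

#' Hypergeometric expectation for a two-set overlap
#'
#' Closed-form counterpart of [permutation_overlap()]: when two sets of
#' sizes `n1`, `n2` are drawn independently from a universe of size `N`,
#' the intersection size is hypergeometric with mean `n1 * n2 / N` and
#' variance `n1 * n2 * (N - n1) * (N - n2) / (N^2 * (N - 1))`.
#'
#' @param n1,n2 Set sizes.
#' @param N Universe size (>= 1).
#' @param observed Optional observed overlap; when given, the upper-tail
#'   probability `P(overlap >= observed)` is returned.
#' @return List: `mean`, `sd`, and `p_upper` (NA when `observed` is NULL).
#' @export
hypergeom_overlap <- function(n1, n2, N, observed = NULL) {
  if (N < 1) stop("universe size must be positive", call. = FALSE)
  stopifnot(n1 >= 0, n2 >= 0, n1 <= N, n2 <= N)
  n1 <- as.numeric(n1); n2 <- as.numeric(n2); N <- as.numeric(N)
  m <- n1 * n2 / N
  v <- if (N > 1) n1 * n2 * (N - n1) * (N - n2) / (N^2 * (N - 1)) else 0
  p <- if (is.null(observed)) NA_real_ else
    phyper(observed - 1, n1, N - n1, n2, lower.tail = FALSE)
  list(mean = m, sd = sqrt(v), p_upper = p)
}

#' Chi-squared test of independence for a 2x2 table
#'
#' Pearson chi-squared without continuity correction by default, testing the
#' independence of two gene-set memberships.
#'
#' @param tab 2x2 matrix of non-negative counts with positive margins.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return List with `statistic` and `p_value` (reference chi-squared, 1 df).
#' @export
chi2_independence <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("table has a zero margin", call. = FALSE)
  }
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Overlap summary arithmetic
#'
#' Exact set arithmetic for a two-set comparison: intersection, exclusive
#' sets, and shared fractions as percentages.
#'
#' @param set_a,set_b Character vectors (duplicates ignored).
#' @param digits Rounding for the percentage fields (default 2).
#' @return List: `n_a`, `n_b`, `intersection`, `exclusive_a`, `exclusive_b`,
#'   `fraction_of_a_shared_pct`, `fraction_of_b_shared_pct`.
#' @examples
#' overlap_summary(letters[1:5], letters[4:10])
#' @export
overlap_summary <- function(set_a, set_b, digits = 2L) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  i <- length(intersect(set_a, set_b))
  list(n_a = length(set_a), n_b = length(set_b), intersection = i,
       exclusive_a = length(set_a) - i, exclusive_b = length(set_b) - i,
       fraction_of_a_shared_pct =
         if (length(set_a)) round(100 * i / length(set_a), digits) else NA_real_,
       fraction_of_b_shared_pct =
         if (length(set_b)) round(100 * i / length(set_b), digits) else NA_real_)
}

#' Combined overlap statistics
#'
#' Runs the permutation null, its analytic hypergeometric counterpart and the
#' chi-squared independence test for two gene sets over a universe.
#'
#' @inheritParams permutation_overlap
#' @param correct Continuity correction for the chi-squared test.
#' @return An object of class `overlap_result` collecting the observed
#'   overlap, permutation mean/SD and empirical p, analytic mean/SD and
#'   upper-tail p, the chi-squared statistic and p, and the summary
#'   arithmetic.
#' @export
overlap_test <- function(set_a, set_b, universe, n_iter = 10000L,
                         seed = NULL, correct = FALSE) {
  perm <- permutation_overlap(set_a, set_b, universe, n_iter, seed)
  ana <- hypergeom_overlap(length(unique(set_a)), length(unique(set_b)),
                           length(universe), observed = perm$observed)
  n1 <- length(unique(set_a)); n2 <- length(unique(set_b))
  N <- length(universe); i <- perm$observed
  tab <- matrix(c(i, n2 - i, n1 - i, N - n1 - n2 + i), 2L, 2L)
  chi <- chi2_independence(tab, correct = correct)
  structure(c(perm,
              list(analytic_mean = ana$mean, analytic_sd = ana$sd,
                   analytic_p_upper = ana$p_upper,
                   chi2 = chi$statistic, chi2_p = chi$p_value,
                   summary = overlap_summary(set_a, set_b))),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    paste0("<overlap_result> observed %d; permutation %0.2f +/- %0.2f ",
           "(p = %.3g, %d iterations); analytic %0.2f +/- %0.2f; ",
           "chi2 = %0.2f (p = %.3g)\n"),
    x$observed, x$perm_mean, x$perm_sd, x$empirical_p, x$n_iter,
    x$analytic_mean, x$analytic_sd, x$chi2, x$chi2_p))
  invisible(x)
}
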