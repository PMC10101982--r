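#' Configuration for the count-matrix simulator
#'
#' Defines a capture-versus-RNA-seq experiment in biological replicates with
#' a planted subset of enriched (NAD-capped) genes. Counts follow a negative
#' binomial with `var = mu + dispersion * mu^2`; `dispersion = 0` is the
#' Poisson limit.
#'
#' @param n_genes Number of genes.
#' @param replicates_per_condition Replicates in each condition (>= 2;
#'   default 3, matching biological triplicates).
#' @param planted_enriched Either an integer number of genes to plant or a
#'   character vector of gene ids (subset of `SYNg%04d` ids). When a count is
#'   given, planted genes are drawn from genes whose expected control-library
#'   count is at least `min_planted_mean`, since enrichment below the
#'   counting noise floor is not recoverable by any test.
#' @param planted_log2fc Log2 fold-change of planted genes in the capture
#'   condition.
#' @param dispersion NB dispersion alpha (>= 0).
#' @param mean_expression Named list `meanlog`, `sdlog` of the log-normal
#'   expression-level distribution across genes (relative levels; scaled to
#'   the library depth).
#' @param library_depth Expected total counts per sample.
#' @param min_planted_mean Minimum expected control count for planted genes
#'   when `planted_enriched` is a count.
#' @param seed Integer seed.
#' @return An object of class `count_sim_config`.
#' @export
count_sim_config <- function(n_genes, replicates_per_condition = 3L,
                             planted_enriched = 0L, planted_log2fc = 2,
                             dispersion = 0.05,
                             mean_expression = list(meanlog = log(300),
                                                    sdlog = 1),
                             library_depth = 1e6,
                             min_planted_mean = 100,
                             seed = NULL) {
  stopifnot(n_genes >= 1, replicates_per_condition >= 2, dispersion >= 0,
            library_depth > 0)
  ids <- sprintf("SYNG%04d", seq_len(n_genes))
  if (is.character(planted_enriched)) {
    if (!all(planted_enriched %in% ids)) {
      stop("planted_enriched ids outside the gene universe", call. = FALSE)
    }
  } else {
    stopifnot(planted_enriched >= 0, planted_enriched <= n_genes)
  }
  structure(list(n_genes = as.integer(n_genes), gene_ids = ids,
                 replicates_per_condition = as.integer(replicates_per_condition),
                 planted_enriched = planted_enriched,
                 planted_log2fc = planted_log2fc,
                 dispersion = dispersion, mean_expression = mean_expression,
                 library_depth = library_depth,
                 min_planted_mean = min_planted_mean, seed = seed),
            class = "count_sim_config")
}

#' Simulate a capture vs RNA-seq count matrix with planted enrichment
#'
#' Draws per-gene expression levels from a log-normal, scales each condition
#' to the library depth (so capture libraries exhibit the real compositional
#' shift that median-of-ratios normalization must undo), multiplies planted
#' genes by `2^planted_log2fc` in the capture condition, and samples NB (or
#' Poisson) counts for every replicate.
#'
#' @param cfg A [count_sim_config()].
#' @return List with `counts` (integer matrix, genes x samples),
#'   `sample_info` (tibble: sample_id, condition in rnaseq/nadcappro,
#'   replicate), `gene_lengths` (named integer, nt), and `truth` (tibble:
#'   gene_id, planted flag, expected control mean).
#' @examples
#' sim <- simulate_counts(count_sim_config(20, planted_enriched = 2, seed = 1))
#' head(sim$counts)
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "count_sim_config"))
  with_seed(cfg$seed, {
    G <- cfg$n_genes
    level <- exp(rnorm(G, cfg$mean_expression$meanlog,
                       cfg$mean_expression$sdlog))
    mu_ctrl <- level / sum(level) * cfg$library_depth

    if (is.character(cfg$planted_enriched)) {
      planted <- cfg$gene_ids %in% cfg$planted_enriched
    } else if (cfg$planted_enriched > 0L) {
      eligible <- which(mu_ctrl >= cfg$min_planted_mean)
      if (length(eligible) < cfg$planted_enriched) {
        stop("not enough genes above min_planted_mean to plant", call. = FALSE)
      }
      planted <- logical(G)
      planted[sample(eligible, cfg$planted_enriched)] <- TRUE
    } else {
      planted <- logical(G)
    }

    fc <- ifelse(planted, 2^cfg$planted_log2fc, 1)
    mu_cap <- (level * fc) / sum(level * fc) * cfg$library_depth

    nrep <- cfg$replicates_per_condition
    draw <- function(mu) {
      if (cfg$dispersion == 0) rpois(length(mu), mu)
      else rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
    }
    counts <- cbind(
      matrix(draw(rep(mu_ctrl, nrep)), nrow = G),
      matrix(draw(rep(mu_cap, nrep)), nrow = G))
    sample_info <- tibble::tibble(
      sample_id = c(sprintf("rnaseq_%d", seq_len(nrep)),
                    sprintf("nadcappro_%d", seq_len(nrep))),
      condition = rep(c("rnaseq", "nadcappro"), each = nrep),
      replicate = rep(seq_len(nrep), 2L))
    dimnames(counts) <- list(cfg$gene_ids, sample_info$sample_id)
    gene_lengths <- setNames(sample(300:3000, G, replace = TRUE),
                             cfg$gene_ids)
    list(counts = counts, sample_info = sample_info,
         gene_lengths = gene_lengths,
         truth = tibble::tibble(gene_id = cfg$gene_ids, planted = planted,
                                mu_control = mu_ctrl))
  })
}

#' Simulate two gene sets with an exact forced overlap
#'
#' Fixture generator for the overlap statistics: draws two sets of prescribed
#' sizes from a labeled universe such that their intersection has exactly
#' `forced_overlap` members.
#'
#' @param universe_size Number of genes in the universe.
#' @param n1,n2 Set sizes.
#' @param forced_overlap Exact intersection size.
#' @param seed Integer seed.
#' @return List with `universe`, `set_a`, `set_b` (character vectors).
#' @examples
#' gs <- simulate_gene_sets(100, 10, 20, 5, seed = 1)
#' length(intersect(gs$set_a, gs$set_b))
#' @export
simulate_gene_sets <- function(universe_size, n1, n2, forced_overlap,
                               seed = NULL) {
  stopifnot(universe_size >= 1)
  if (n1 > universe_size || n2 > universe_size) {
    stop("set sizes exceed the universe", call. = FALSE)
  }
  if (forced_overlap > min(n1, n2)) {
    stop("forced_overlap exceeds the smaller set", call. = FALSE)
  }
  if (n1 + n2 - forced_overlap > universe_size) {
    stop("universe too small for the requested disjointness", call. = FALSE)
  }
  with_seed(seed, {
    universe <- sprintf("GENE%05d", seq_len(universe_size))
    ord <- sample(universe)
    set_a <- ord[seq_len(n1)]
    shared <- if (forced_overlap > 0) set_a[seq_len(forced_overlap)] else
      character()
    set_b <- c(shared, ord[n1 + seq_len(n2 - forced_overlap)])
    list(universe = universe, set_a = sort(set_a), set_b = sort(set_b))
  })
}
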