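#!/usr/bin/env Rscript

# Stage 5: gene-set overlap statistics.
#
# Two comparisons:
#  (a) the capped sets identified by the two simulated capture designs in
#      stage 4, over the universe of genes tested in both;
#  (b) the published WT set sizes (268 SPAAC vs 769 NADcapPro, 63 shared,
#      universe 6000) as a worked arithmetic example.
# Each gets the 10,000-fold identity-randomization null, the analytic
# hypergeometric expectation, and the chi-squared independence test.
# Results go to results/overlap/.

suppressPackageStartupMessages(library(nadcapr))

ind <- "results/enrichment"
out <- "results/overlap"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

report <- function(label, res) {
  cat(sprintf("%s:\n", label))
  cat(sprintf("  observed overlap %d vs permutation %.2f +/- %.2f (p = %.3g)\n",
              res$observed, res$perm_mean, res$perm_sd, res$empirical_p))
  cat(sprintf("  analytic %.2f +/- %.2f; chi2 = %.1f (p = %.3g)\n",
              res$analytic_mean, res$analytic_sd, res$chi2, res$chi2_p))
  cat(sprintf("  %.1f%% of the larger set shared; %d exclusive to it\n",
              res$summary$fraction_of_b_shared_pct, res$summary$exclusive_b))
  write_json_summary(unclass(res), file.path(out, paste0(label, ".json")))
}

# (a) simulated designs
a <- read_gene_list(file.path(ind, "spaac_capped.txt"))
b <- read_gene_list(file.path(ind, "nadcappro_capped.txt"))
universe <- read_gene_list(file.path(ind, "universe.txt"))
report("simulated_designs",
       overlap_test(a, b, universe, n_iter = 10000, seed = 20260401))

# (b) published WT set sizes
gs <- simulate_gene_sets(6000, 268, 769, 63, seed = 20260402)
report("published_sizes",
       overlap_test(gs$set_a, gs$set_b, gs$universe, n_iter = 10000,
                    seed = 20260403))
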