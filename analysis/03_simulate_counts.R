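#!/usr/bin/env Rscript

# Stage 3: simulate the capture-sequencing count study.
#
# Two designs over the same 2,000-gene universe in biological triplicate:
#  - "nadcappro": 100 planted NAD-capped genes drawn across the expression
#    range (the capture chemistry is abundance-agnostic once canonical caps
#    are removed);
#  - "spaac": 100 planted genes biased to the most abundant transcripts,
#    mimicking a capture that only reaches highly expressed RNAs.
# Counts, sample sheets, gene lengths and truth go to results/counts/.

suppressPackageStartupMessages(library(nadcapr))

out <- "results/counts"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

n_genes <- 2000L
depth <- 1e6

write_design <- function(sim, label) {
  counts_tbl <- tibble::tibble(gene_id = rownames(sim$counts),
                               tibble::as_tibble(sim$counts))
  readr::write_tsv(counts_tbl, file.path(out, paste0(label, "_counts.tsv")))
  readr::write_tsv(sim$sample_info,
                   file.path(out, paste0(label, "_samples.tsv")))
  readr::write_tsv(sim$truth, file.path(out, paste0(label, "_truth.tsv")))
}

# unbiased planting (min_planted_mean keeps planted genes testable)
sim_nadcappro <- simulate_counts(count_sim_config(
  n_genes, planted_enriched = 100L, planted_log2fc = 2, dispersion = 0.05,
  library_depth = depth, seed = 20260301))
write_design(sim_nadcappro, "nadcappro")

# abundance-biased planting: the 100 planted genes are drawn from the top
# expression decile of the same baseline transcriptome
base <- simulate_counts(count_sim_config(
  n_genes, planted_enriched = 0L, dispersion = 0.05, library_depth = depth,
  seed = 20260301))
top_decile <- base$truth$gene_id[
  rank(-base$truth$mu_control) <= n_genes / 10]
spaac_planted <- withr::with_seed(20260302, sample(top_decile, 100L))
sim_spaac <- simulate_counts(count_sim_config(
  n_genes, planted_enriched = spaac_planted, planted_log2fc = 2,
  dispersion = 0.05, library_depth = depth, seed = 20260301))
write_design(sim_spaac, "spaac")

lens <- tibble::tibble(gene_id = names(sim_nadcappro$gene_lengths),
                       length = unname(sim_nadcappro$gene_lengths))
readr::write_tsv(lens, file.path(out, "gene_lengths.tsv"))

cat(sprintf("simulated %d genes x 3+3 replicates at depth %.0g, two designs\n",
            n_genes, depth))
cat(sprintf("planted: %d unbiased (nadcappro-like), %d abundance-biased (spaac-like), %d shared\n",
            sum(sim_nadcappro$truth$planted), sum(sim_spaac$truth$planted),
            length(intersect(
              sim_nadcappro$truth$gene_id[sim_nadcappro$truth$planted],
              sim_spaac$truth$gene_id[sim_spaac$truth$planted]))))
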