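#!/usr/bin/env Rscript

# Stage 1: build the synthetic study materials for the junction analysis.
#
# Generates a small reference transcriptome with distinct NAD and m7G
# cap-addition sites, then sequences circularization amplicons for each gene
# under both deNADding treatments (Rai1 -> NAD caps, MDE -> m7G caps) at a
# 1% substitution error rate. Reads, reference and ground truth go to
# results/simdata/.

suppressPackageStartupMessages(library(nadcapr))

out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

n_genes <- 5L
n_reads <- 500L
error_rate <- 0.01

tx <- simulate_transcriptome(n_genes, seed = 20260101)
write_transcriptome(tx, out)

truths <- list()
for (g in seq_along(tx$models)) {
  m <- tx$models[[g]]
  for (trt in c(Rai1 = "NAD", MDE = "m7G")) {
    label <- names(which(c(Rai1 = "NAD", MDE = "m7G") == trt))
    rd <- simulate_circ_reads(m, n_reads, trt, error_rate = error_rate,
                              seed = 20260200 + 10L * g +
                                (trt == "m7G"))
    stem <- file.path(out, sprintf("%s_%s", m$gene_id, label))
    write_fastq_pair(rd$read1, rd$read2, paste0(stem, "_1.fastq"),
                     paste0(stem, "_2.fastq"))
    rd$truth$treatment <- label
    truths[[paste0(m$gene_id, label)]] <- rd$truth
  }
}
truth <- dplyr::bind_rows(truths)
write_tables(list(truth = truth), out)

write_json_summary(list(n_genes = n_genes, reads_per_library = n_reads,
                        error_rate = error_rate,
                        treatments = c("Rai1", "MDE")),
                   file.path(out, "config.json"))

cat(sprintf("simulated %d genes x 2 treatments x %d read pairs (%.0f%% error)\n",
            n_genes, n_reads, 100 * error_rate))
cat(sprintf("planted NAD cap sites (1-based): %s\n",
            paste(tx$annotation$cap_site_nad + 1L, collapse = ", ")))
cat(sprintf("planted m7G cap sites (1-based): %s\n",
            paste(tx$annotation$cap_site_m7g + 1L, collapse = ", ")))
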