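test_that("transcriptome generation honours length ranges and invariants", {
  tx <- simulate_transcriptome(
    50, length_params = list(utr5 = c(20L, 100L), cds = c(300L, 900L),
                             utr3 = c(50L, 300L)), seed = 101)
  expect_equal(length(tx$models), 50L)
  ann <- tx$annotation
  expect_true(all(ann$utr5_len >= 20 & ann$utr5_len <= 100))
  expect_true(all(ann$cds_len >= 300 & ann$cds_len <= 900))
  expect_true(all(ann$utr3_len >= 50 & ann$utr3_len <= 300))
  for (m in tx$models) {
    expect_equal(m$utr5_len + m$cds_len + m$utr3_len, nchar(m$sequence))
    expect_equal(sum(m$cap_site_dist_nad$weight), 1)
    expect_equal(sum(m$cap_site_dist_m7g$weight), 1)
    expect_lt(max(m$cap_site_dist_nad$pos, m$cap_site_dist_m7g$pos),
              min(m$cleavage_site_dist$pos))
    # genomic A homopolymers stay below the polyA filter threshold
    expect_null(find_polya_run(m$sequence, 8L))
  }
})

test_that("transcriptome generation is deterministic and handles n = 0", {
  a <- simulate_transcriptome(5, seed = 7)
  b <- simulate_transcriptome(5, seed = 7)
  expect_identical(a, b)
  empty <- simulate_transcriptome(0, seed = 7)
  expect_equal(length(empty$models), 0L)
  expect_equal(nrow(empty$annotation), 0L)
  expect_error(
    simulate_transcriptome(2, length_params = list(utr5 = c(50L, 20L),
                                                   cds = c(300L, 900L),
                                                   utr3 = c(50L, 300L))),
    "invalid length range")
})

test_that("written FASTA and annotation round-trip the models", {
  dir <- withr::local_tempdir()
  tx <- simulate_transcriptome(4, seed = 8)
  paths <- write_transcriptome(tx, dir)
  seqs <- read_fasta(paths$fasta)
  expect_equal(unname(seqs[names(tx$models)]),
               unname(vapply(tx$models, `[[`, "", "sequence")))
  ann <- read_table_tsv(paths$annotation)
  expect_equal(ann$gene_id, tx$annotation$gene_id)
  expect_equal(as.data.frame(lapply(ann[-1], as.numeric)),
               as.data.frame(lapply(tx$annotation[-1], as.numeric)))
})

test_that("error-free amplicons carry one maximal A-run abutting the cap site", {
  m <- toy_model()
  rd <- simulate_circ_reads(m, 30, "NAD", error_rate = 0, read_len = 600L,
                            seed = 9)
  # read length 600 covers the whole amplicon: read 1 is the amplicon itself
  for (i in seq_len(30)) {
    amp <- rd$read1$seq[i]
    run <- find_polya_run(amp)
    expect_equal(run$length, rd$truth$true_polya_len[i])
    # right run boundary abuts the cap-site base
    expect_equal(substr(amp, run$end + 1, run$end + 20),
                 substr(m$sequence, rd$truth$true_cap_site[i] + 1,
                        rd$truth$true_cap_site[i] + 20))
  }
})

test_that("junction-edge adenosines are annotated, not silently shifted", {
  seq <- toy_sequence(400, seed = 77, forbid_a_at = c(9, 10, 398))
  chars <- strsplit(seq, "")[[1]]
  chars[8 + 1] <- "A"  # cap site base is A, next two are not
  seq <- paste(chars, collapse = "")
  m <- toy_model(cap_nad = 8L, cleave = 398L, seq = seq)
  rd <- simulate_circ_reads(m, 5, "NAD", error_rate = 0, seed = 10)
  expect_true(all(rd$truth$ext5 == 1L))
  expect_equal(rd$truth$cap_site_attr, rd$truth$true_cap_site + 1L)
  expect_equal(rd$truth$polya_len_attr,
               rd$truth$true_polya_len + 1L + rd$truth$ext3)
})

test_that("substitution errors occur at the configured rate", {
  m <- toy_model()
  rd <- simulate_circ_reads(m, 2000, "NAD", error_rate = 0.01,
                            read_len = 250L, seed = 11)
  n_bases <- sum(nchar(rd$read1$seq)) + sum(nchar(rd$read2$seq))
  rate <- sum(rd$truth$n_errors) / n_bases
  se <- sqrt(0.01 * 0.99 / n_bases)
  expect_lt(abs(rate - 0.01), 3 * se)
})

test_that("read simulation is deterministic and validates inputs", {
  m <- toy_model()
  a <- simulate_circ_reads(m, 20, "NAD", error_rate = 0.02, seed = 12)
  b <- simulate_circ_reads(m, 20, "NAD", error_rate = 0.02, seed = 12)
  expect_identical(a, b)
  empty_dist <- m
  empty_dist$cap_site_dist_nad <- empty_dist$cap_site_dist_nad[0, ]
  expect_error(simulate_circ_reads(empty_dist, 5, "NAD"), "empty")
  expect_error(simulate_circ_reads(m, 5, "NAD", error_rate = 1))
})

test_that("Poisson-limit counts have the configured mean", {
  cfg <- count_sim_config(1000, dispersion = 0,
                          mean_expression = list(meanlog = log(100),
                                                 sdlog = 0),
                          library_depth = 1e7, seed = 13)
  sim <- simulate_counts(cfg)
  # every gene has mu = depth / n_genes = 10000
  mu <- 1e7 / 1000
  xbar <- mean(sim$counts[, 1])
  se <- sqrt(mu / 1000)
  expect_lt(abs(xbar - mu), 3 * se)
})

test_that("null configuration plants nothing and centres log-ratios at zero", {
  cfg <- count_sim_config(500, planted_enriched = 0L, seed = 14)
  sim <- simulate_counts(cfg)
  expect_false(any(sim$truth$planted))
  norm <- sweep(sim$counts, 2, size_factors(sim$counts), "/")
  lr <- log2((rowMeans(norm[, 4:6]) + 0.5) / (rowMeans(norm[, 1:3]) + 0.5))
  expect_lt(abs(median(lr)), 0.1)
})

test_that("planted genes show the planted fold change after normalization", {
  cfg <- count_sim_config(2000, planted_enriched = 100L, planted_log2fc = 2,
                          dispersion = 0.05, library_depth = 1e6, seed = 15)
  sim <- simulate_counts(cfg)
  expect_equal(sum(sim$truth$planted), 100L)
  norm <- sweep(sim$counts, 2, size_factors(sim$counts), "/")
  lr <- log2(rowMeans(norm[, 4:6]) / rowMeans(norm[, 1:3]))
  expect_lt(abs(median(lr[sim$truth$planted]) - 2), 0.3)
  counts <- sim$counts
  expect_true(all(counts >= 0) && all(counts == round(counts)))
  expect_identical(simulate_counts(cfg)$counts, counts)
})

test_that("gene-set simulation hits exact sizes and rejects infeasible asks", {
  nested <- simulate_gene_sets(100, 10, 10, 10, seed = 16)
  expect_true(all(nested$set_a %in% nested$set_b))
  gs <- simulate_gene_sets(6000, 268, 769, 63, seed = 17)
  expect_equal(length(gs$set_a), 268L)
  expect_equal(length(gs$set_b), 769L)
  expect_equal(length(intersect(gs$set_a, gs$set_b)), 63L)
  expect_error(simulate_gene_sets(10, 5, 6, 0), "universe too small")
  expect_error(simulate_gene_sets(10, 5, 6, 6), "smaller set")
})
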