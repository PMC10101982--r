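test_that("TPM normalization follows the rate definition", {
  expect_equal(recalc_tpm(matrix(7), 1000), matrix(1e6))
  two <- recalc_tpm(c(10, 10), c(100, 200))
  expect_equal(two[1] / two[2], 2)
  expect_equal(sum(two), 1e6)
  counts <- c(10, 20, 30)
  lens <- c(100, 200, 300)
  rate <- counts / lens
  expect_equal(recalc_tpm(counts, lens), 1e6 * rate / sum(rate))
  # all-zero column stays zero while positive columns sum to 1e6
  m <- cbind(a = c(0, 0), b = c(5, 5))
  tpm <- recalc_tpm(m, c(50, 100))
  expect_equal(unname(tpm[, "a"]), c(0, 0))
  expect_equal(sum(tpm[, "b"]), 1e6)
})

test_that("size factors are symmetric, scale-equivariant and match oracles", {
  base <- matrix(rep(c(10, 40, 90, 25, 60), 3), ncol = 3)
  expect_equal(size_factors(base), rep(1, 3))
  scaled <- base
  scaled[, 2] <- base[, 2] * 2
  sf <- size_factors(scaled)
  expect_equal(sf[2] / sf[1], 2)
  withr::with_seed(51, {
    m <- matrix(rpois(15, 60) + 1, nrow = 5)
    expect_equal(size_factors(m), oracle_size_factors(m))
  })
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "nonzero")
})

test_that("size factors agree with the reference differential pipeline", {
  skip_if_not_installed("DESeq2")
  withr::with_seed(52, {
    m <- matrix(rnbinom(600, mu = 200, size = 10), ncol = 6)
    ours <- size_factors(m)
    ref <- DESeq2::estimateSizeFactorsForMatrix(m)
    ref <- ref / exp(mean(log(ref)))
    expect_equal(ours, unname(ref), tolerance = 1e-10)
  })
})

test_that("identical groups give zero fold change and p = 1", {
  k <- matrix(rep(c(30L, 60L, 10L, 90L), each = 6), ncol = 6, byrow = TRUE)
  rownames(k) <- paste0("g", 1:4)
  res <- nb_enrichment_test(k, rep(c("rnaseq", "nadcappro"), each = 3))
  expect_equal(res$log2fc, rep(0, 4))
  expect_equal(res$p_value, rep(1, 4))
})

test_that("the Poisson limit agrees with a Poisson GLM Wald test", {
  withr::with_seed(53, {
    cond <- rep(c("rnaseq", "nadcappro"), each = 3)
    for (rep_i in 1:10) {
      mu <- runif(1, 200, 2000)
      ratio <- sample(c(1, 1.15, 1.3), 1)
      k <- rbind(c(rpois(3, mu), rpois(3, mu * ratio)))
      rownames(k) <- "g1"
      ours <- nb_enrichment_test(k, cond, sf = rep(1, 6), dispersion = 0)
      fit <- stats::glm(k[1, ] ~ factor(cond, c("rnaseq", "nadcappro")),
                        family = stats::poisson())
      p_glm <- summary(fit)$coefficients[2, 4]
      b_glm <- summary(fit)$coefficients[2, 1]
      expect_equal(ours$log2fc, b_glm / log(2), tolerance = 1e-6)
      expect_equal(ours$p_value, p_glm, tolerance = 0.1)
    }
  })
})

test_that("planted fold changes are recovered by the NB test", {
  sim <- simulate_counts(count_sim_config(
    1500, planted_enriched = 120L, planted_log2fc = 2, dispersion = 0.05,
    library_depth = 1e6, seed = 54))
  keep <- rowSums(sim$counts) >= 10
  res <- nb_enrichment_test(sim$counts[keep, ],
                            sim$sample_info$condition)
  planted <- sim$truth$planted[keep]
  expect_gte(sum(planted), 100)
  expect_lt(abs(median(res$log2fc[planted]) - 2), 0.3)
})

test_that("scaling one sample rescales its factor but not the estimates", {
  sim <- simulate_counts(count_sim_config(400, planted_enriched = 20L,
                                          seed = 55))
  keep <- rowSums(sim$counts) >= 10
  k <- sim$counts[keep, ]
  cond <- sim$sample_info$condition
  base_sf <- size_factors(k)
  base <- nb_enrichment_test(k, cond, dispersion = 0.05)
  k2 <- k
  k2[, 4] <- k2[, 4] * 3L
  sf2 <- size_factors(k2)
  expect_equal(unname(sf2[4] / base_sf[4] / (sf2[1] / base_sf[1])), 3,
               tolerance = 0.02)
  scaled <- nb_enrichment_test(k2, cond, dispersion = 0.05)
  expect_equal(scaled$log2fc, base$log2fc, tolerance = 0.05)
})

test_that("degenerate test inputs are rejected", {
  k <- matrix(c(0L, 0L, 0L, 0L, 0L, 0L, 5L, 5L, 5L, 5L, 5L, 5L), nrow = 2,
              byrow = TRUE)
  cond <- rep(c("rnaseq", "nadcappro"), each = 3)
  expect_error(nb_enrichment_test(k, cond), "all-zero")
  expect_error(nb_enrichment_test(k[2, , drop = FALSE], c("rnaseq",
                                                          "nadcappro",
                                                          "nadcappro")),
               "replicates")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.01, 0.02, 0.03, 0.5)
  expect_equal(bh_adjust(p), oracle_bh(p))
  withr::with_seed(56, {
    for (rep_i in 1:20) {
      p <- runif(sample(1:30, 1))
      expect_equal(bh_adjust(p), oracle_bh(p))
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the capped classification applies both thresholds inclusively", {
  res <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    log2fc = c(1.0, 0.99, 5.0, 3.0),
    q_value = c(0.01, 1e-6, 0.02, 0.001))
  cls <- classify_capped(res)
  expect_equal(cls$results$classified_capped, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(cls$summary$n, c(2L, 2L))
})

test_that("abundance comparison is one-sided with Welch behaviour", {
  x <- c(10, 20, 30, 40)
  same <- compare_abundance(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 0.5)
  withr::with_seed(57, {
    b <- exp(rnorm(200, 5, 1))
    a <- exp(rnorm(200, 3, 1))
    expect_lt(compare_abundance(a, b)$p_value, 1e-6)
    expect_gt(compare_abundance(b, a)$p_value, 0.5)
  })
  expect_error(compare_abundance(5, c(1, 2)), "two observations")
})

test_that("run_enrichment filters, tests, adjusts and classifies coherently", {
  sim <- simulate_counts(count_sim_config(800, planted_enriched = 40L,
                                          planted_log2fc = 2, seed = 58))
  out <- run_enrichment(sim$counts, sim$sample_info$condition)
  expect_equal(nrow(out$results) + out$n_filtered, 800L)
  expect_true(all(out$results$q_value >= out$results$p_value))
  expect_equal(out$summary$n[1], sum(out$results$classified_capped))
  hits <- out$results$gene_id[out$results$classified_capped]
  planted_ids <- sim$truth$gene_id[sim$truth$planted]
  expect_gt(length(intersect(hits, planted_ids)) / length(planted_ids), 0.8)
})

test_that("background control samples are reported but never tested", {
  sim <- simulate_counts(count_sim_config(200, planted_enriched = 10L,
                                          seed = 59))
  k6 <- sim$counts
  withr::with_seed(60, {
    bg <- matrix(rpois(nrow(k6) * 2, rowMeans(k6) * 0.1), ncol = 2)
  })
  colnames(bg) <- c("bg_1", "bg_2")
  k8 <- cbind(k6, bg)
  cond8 <- c(sim$sample_info$condition, "minus_adprc", "minus_adprc")
  plain <- nb_enrichment_test(k6[rowSums(k6) >= 10, ],
                              sim$sample_info$condition)
  with_bg <- nb_enrichment_test(k8[rowSums(k6) >= 10, ], cond8)
  expect_equal(with_bg$log2fc, plain$log2fc)
  expect_equal(with_bg$p_value, plain$p_value)
  out <- run_enrichment(k8, cond8)
  expect_true("mean_minus_adprc" %in% names(out$results))
})
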