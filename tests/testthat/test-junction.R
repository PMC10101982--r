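test_that("error-free junction reads are called exactly at high confidence", {
  m <- toy_model()
  withr::with_seed(41, {
    for (rep in 1:15) {
      polya <- sample(12:40, 1)
      amp <- toy_amplicon(m, cap = 8L, cleave = 398L, polya_len = polya)
      cl <- call_junction(amp, m)
      expect_equal(cl$confidence, "high")
      expect_equal(cl$cap_site, 8L)
      expect_equal(cl$three_prime_site, 398L)
      expect_equal(cl$polya_len, polya)
      expect_equal(cl$gene_id, "TOY1")
    }
  })
})

test_that("calls recover the simulator truth on error-free reads", {
  tx <- simulate_transcriptome(2, seed = 42)
  for (m in tx$models) {
    rd <- simulate_circ_reads(m, 100, "NAD", error_rate = 0, seed = 43)
    mg <- merge_pairs(rd$read1, rd$read2)
    fp <- filter_polya(mg)
    cl <- call_junctions(fp, m)
    by_read <- cl[match(fp$seq, cl$seq), ]
    tr <- rd$truth[match(fp$read_id, rd$truth$read_id), ]
    hi <- by_read$confidence == "high"
    expect_gt(sum(hi), 0)
    expect_equal(by_read$cap_site[hi], tr$cap_site_attr[hi])
    expect_equal(by_read$three_prime_site[hi], tr$three_prime_site_attr[hi])
    expect_equal(by_read$polya_len[hi], tr$polya_len_attr[hi])
  }
})

test_that("a read without a polyA run is a junction error", {
  m <- toy_model()
  expect_error(call_junction(strrep("ACGT", 20), m), "polyA")
})

test_that("an unalignable post-run segment cannot yield a high-confidence cap", {
  m <- toy_model()
  withr::with_seed(44, {
    amp3 <- substr(m$sequence, m$primer_fwd[1] + 1, 399)
    read <- paste0(amp3, strrep("A", 20), random_seq(80))
    cl <- call_junction(read, m)
    expect_true(cl$confidence %in% c("low", "none"))
    expect_true(is.na(cl$cap_site))
  })
})

test_that("a short post-run segment disqualifies the 5' flank", {
  m <- toy_model()
  amp3 <- substr(m$sequence, m$primer_fwd[1] + 1, 399)
  read <- paste0(amp3, strrep("A", 20), substr(m$sequence, 9, 18))  # 10 nt
  cl <- call_junction(read, m, min_flank = 15L)
  expect_true(is.na(cl$cap_site))
  expect_equal(cl$confidence, "low")  # 3' flank still qualifies
  expect_equal(cl$three_prime_site, 398L)
})

test_that("single substitutions inside the tail are bridged by alignment", {
  m <- toy_model()
  amp <- toy_amplicon(m, cap = 8L, cleave = 398L, polya_len = 30L)
  run <- find_polya_run(amp)
  chars <- strsplit(amp, "")[[1]]
  chars[run$start + 10] <- "G"  # error in the middle of the tail
  cl <- call_junction(paste(chars, collapse = ""), m)
  expect_equal(cl$confidence, "high")
  expect_equal(cl$cap_site, 8L)
  expect_equal(cl$three_prime_site, 398L)
  expect_equal(cl$polya_len, 30L)
})

test_that("a templated junction A is absorbed and reported as ambiguous", {
  seq <- toy_sequence(400, seed = 78, forbid_a_at = c(7, 9, 10, 398))
  chars <- strsplit(seq, "")[[1]]
  chars[8 + 1] <- "A"
  m <- toy_model(cap_nad = 8L, seq = paste(chars, collapse = ""))
  amp <- toy_amplicon(m, cap = 8L, cleave = 398L, polya_len = 25L)
  cl <- call_junction(amp, m)
  expect_equal(cl$confidence, "high")
  expect_equal(cl$cap_site, 9L)       # first post-run base
  expect_equal(cl$polya_len, 26L)     # templated A absorbed into the run
  expect_equal(cl$alt_cap_sites, 8L)  # upstream A flagged as alternative
})

test_that("cap sites classify by the reference base, with bounds checking", {
  seq <- toy_sequence(400, seed = 79, forbid_a_at = c(3, 398))
  chars <- strsplit(seq, "")[[1]]
  chars[8 + 1] <- "A"; chars[9 + 1] <- "C"
  m <- toy_model(cap_nad = 8L, seq = paste(chars, collapse = ""))
  mk_call <- function(site, conf = "high") {
    structure(list(gene_id = "TOY1", cap_site = site, confidence = conf),
              class = "junction_call")
  }
  a <- classify_cap_site(mk_call(8L), m)
  expect_equal(a$category, "adenosine_consistent")
  expect_equal(a$ref_base, "A")
  g <- classify_cap_site(mk_call(9L), m)
  expect_equal(g$category, "non_adenosine")
  expect_error(classify_cap_site(mk_call(400L), m), "bounds")
  expect_error(classify_cap_site(mk_call(8L, conf = "none"), m), "none")
  expect_error(classify_cap_site(mk_call(NA_integer_), m), "no cap site")
})
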