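test_that("the 8-A threshold is applied at its boundary", {
  run <- find_polya_run("CCAAAAAAAAGG")
  expect_equal(run$start, 2L)
  expect_equal(run$end, 10L)
  expect_equal(run$length, 8L)
  expect_null(find_polya_run("CCAAAAAAAGG"))  # 7 As
})

test_that("the longest run wins, leftmost on ties", {
  seq <- paste0("G", strrep("A", 9), "C", strrep("A", 12), "G")
  run <- find_polya_run(seq)
  expect_equal(run$length, 12L)
  expect_equal(run$start, 11L)
  tie <- paste0("C", strrep("A", 9), "G", strrep("A", 9), "T")
  expect_equal(find_polya_run(tie)$start, 1L)
})

test_that("run selection matches a brute-force run scan on random reads", {
  scan_runs <- function(s, min_len) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
    ends <- cumsum(r$lengths)
    ok <- r$values == "A" & r$lengths >= min_len
    if (!any(ok)) return(NULL)
    len <- max(r$lengths[ok])
    k <- which(ok & r$lengths == len)[1L]
    list(start = ends[k] - len, end = ends[k], length = len)
  }
  withr::with_seed(31, {
    for (rep in 1:300) {
      s <- random_seq(sample(10:60, 1), alphabet = c("A", "A", "C", "G"))
      expect_identical(find_polya_run(s, 5L), scan_runs(s, 5L), info = s)
    }
  })
})

test_that("filtering keeps exactly the planted polyA reads", {
  withr::with_seed(32, {
    no_tail <- function() {
      s <- random_seq(60)
      while (!is.null(find_polya_run(s)) ||
             !is.null(find_polya_run(revcomp(s)))) s <- random_seq(60)
      s
    }
    with_tail <- function() {
      s <- no_tail()
      paste0(substr(s, 1, 30), strrep("A", sample(8:15, 1)),
             substr(s, 31, 60))
    }
    seqs <- c(replicate(40, with_tail()), replicate(60, no_tail()))
    reads <- tibble::tibble(read_id = sprintf("r%03d", 1:100),
                            seq = sample(seqs))
    expect_equal(nrow(filter_polya(reads)), 40L)
  })
})

test_that("unresolved reads are rescued and flipped via reverse complement", {
  tail_read <- paste0("CGCGTTGTGC", strrep("A", 10), "GTGCCTGTGC")
  flipped <- revcomp(tail_read)
  reads <- tibble::tibble(read_id = c("fwd", "rev"),
                          seq = c(tail_read, flipped))
  out <- filter_polya(reads)
  expect_equal(nrow(out), 2L)
  expect_equal(out$seq[out$read_id == "rev"], tail_read)
  expect_true(all(out$orientation_resolved))
  # already-resolved reads are not flipped
  resolved <- tibble::tibble(read_id = "rev", seq = flipped,
                             orientation_resolved = TRUE)
  expect_equal(nrow(filter_polya(resolved)), 0L)
})

test_that("lowering the run threshold never shrinks the passing set", {
  withr::with_seed(33, {
    reads <- tibble::tibble(read_id = sprintf("r%03d", 1:150),
                            seq = replicate(150, random_seq(
                              40, alphabet = c("A", "A", "A", "C", "G"))))
    pass8 <- filter_polya(reads, 8L)$read_id
    pass7 <- filter_polya(reads, 7L)$read_id
    expect_true(all(pass8 %in% pass7))
  })
})

test_that("all-A and empty inputs behave as specified", {
  expect_equal(nrow(filter_polya(tibble::tibble(read_id = "x",
                                                seq = strrep("A", 20)))), 1L)
  empty <- filter_polya(tibble::tibble(read_id = character(),
                                       seq = character()))
  expect_equal(nrow(empty), 0L)
  expect_error(find_polya_run(""), "empty")
})

test_that("unique-read ranking counts and orders exactly", {
  reads <- c(rep("TTTT", 5), rep("CCCC", 3), "GGGG")
  top2 <- rank_unique_reads(reads, k = 2)
  expect_equal(top2$seq, c("TTTT", "CCCC"))
  expect_equal(top2$count, c(5L, 3L))

  one <- rank_unique_reads(rep("ACGT", 17), k = 5)
  expect_equal(nrow(one), 1L)
  expect_equal(one$count, 17L)
})

test_that("ranking matches an independent hash count and conserves reads", {
  withr::with_seed(34, {
    templates <- replicate(20, random_seq(12))
    draws <- sample(templates, 1000, replace = TRUE)
    full <- rank_unique_reads(draws, k = length(unique(draws)))
    expect_equal(sum(full$count), 1000L)
    counts <- vapply(full$seq, function(s) sum(draws == s), 0L)
    expect_equal(full$count, unname(counts))
    expect_true(all(diff(full$count) <= 0))
    # ties are ordered lexicographically
    ties <- full$count == 50
    expect_equal(full$seq[ties], sort(full$seq[ties]))
  })
})
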