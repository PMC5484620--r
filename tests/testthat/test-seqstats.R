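test_that("pyrimidine and guanine fractions follow their definitions", {
  expect_equal(pyrimidine_fraction("CCTTCC"), 1.0)
  expect_equal(pyrimidine_fraction("GAGA"), 0.0)
  expect_equal(pyrimidine_fraction("CTGA"), 0.5)
  expect_equal(pyrimidine_fraction("CTNN"), 1.0) # N out of the denominator
  expect_equal(g_fraction("GGAT"), 0.5)
  expect_error(pyrimidine_fraction("NNN"), "all-N")
  expect_error(pyrimidine_fraction(""), "empty")
})

test_that("pyrimidine and purine fractions are complementary", {
  set.seed(15)
  seqs <- vapply(1:50, function(i) rand_seq(sample(20:80, 1)), "")
  purine <- function(s) base_fraction_purine(s)
  base_fraction_purine <- function(s) {
    nchar(gsub("[^AG]", "", s)) / nchar(s)
  }
  expect_equal(pyrimidine_fraction(seqs) + purine(seqs), rep(1, 50))
})

test_that("Welch test matches stats::t.test on random inputs to 1e-10", {
  set.seed(77)
  for (i in 1:200) {
    a <- rnorm(sample(3:30, 1), mean = runif(1), sd = runif(1, 0.1, 2))
    b <- rnorm(sample(3:30, 1), mean = runif(1), sd = runif(1, 0.1, 2))
    got <- welch_t_test(a, b)
    ref <- t.test(a, b) # Welch by default
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Welch test symmetry and degenerate conventions", {
  a <- c(0.8, 0.9, 0.85); b <- c(0.5, 0.55, 0.6)
  fwd <- welch_t_test(a, b); rev <- welch_t_test(b, a)
  expect_equal(rev$t, -fwd$t)
  expect_equal(rev$p, fwd$p)
  same <- welch_t_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_message(deg <- welch_t_test(c(1, 1), c(1, 1)), "convention")
  expect_equal(deg$p, 1)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("pyrimidine runs are found by linear scan", {
  expect_identical(max_pyrimidine_run("GGCCTTTCG"), 6L) # run CCTTTC
  expect_identical(max_pyrimidine_run("AAAA"), 0L)
  expect_identical(max_pyrimidine_run("CTCTCT"), 6L)
  rs <- summarize_runs(c("GGCCTTTCG", "CTCTTA", "AAAA"), k = 6)
  expect_equal(rs$fraction, 1 / 3)
})

test_that("5'TOP classification requires a C start and a pyrimidine run", {
  seqs <- c(T1 = "CTTTCTGGCAAA", T2 = "ATTTTCCCGGG", T3 = "CTAGGGAAA")
  tc <- classify_top(seqs, min_run = 4)
  expect_identical(tc$is_top, c(TRUE, FALSE, FALSE))
  expect_gte(tc$top_run_length[1], 5L)
  # overlap: site at the 3'-end of a long 5'UTR misses a TOP at the cap
  sites <- data.frame(transcript_id = "T1", start = 180L, end = 200L,
                      region = "UTR5", stringsAsFactors = FALSE)
  ov <- top_overlap(sites, tc)
  expect_equal(ov$fraction, 0)
  sites2 <- data.frame(transcript_id = "T1", start = 0L, end = 10L,
                       region = "UTR5", stringsAsFactors = FALSE)
  expect_equal(top_overlap(sites2, tc)$fraction, 1)
})

test_that("bound vs unbound composition detects a planted pure-PES signal", {
  spec <- simulation_spec(n_transcripts = 100, fraction_rp = 1,
                          fraction_tr_other = 0, pes_pyrimidine_rate = 1.0,
                          seed = 19)
  tx <- generate_transcriptome(spec)
  pes <- tx$truth$sites[tx$truth$sites$kind == "PES", ]
  sites <- data.frame(transcript_id = pes$transcript_id, start = pes$start,
                      end = pes$end, region = "UTR5",
                      stringsAsFactors = FALSE)
  res <- bound_vs_unbound_composition(sites, tx, "UTR5")
  expect_lt(res$p, 1e-6)
  expect_gt(mean(res$bound), mean(res$unbound))
  expect_error(bound_vs_unbound_composition(sites[1, ], tx, "UTR5"),
               "at least 2")
})

test_that("3'UTR G-content comparison flags the GA-rich footprints", {
  spec <- simulation_spec(n_transcripts = 80, seed = 23)
  tx <- generate_transcriptome(spec)
  ga <- tx$truth$sites[tx$truth$sites$kind == "GA", ]
  sites <- data.frame(transcript_id = ga$transcript_id, start = ga$start,
                      end = ga$end, region = "UTR3",
                      stringsAsFactors = FALSE)
  res <- bound_vs_unbound_composition(sites, tx, "UTR3")
  expect_lt(res$p, 1e-4)
  expect_gt(mean(res$bound), mean(res$unbound))
})

test_that("positional profile separates 3'-end PES groups, not 5' ends", {
  spec <- simulation_spec(n_transcripts = 200, seed = 29)
  tx <- generate_transcriptome(spec)
  rg <- tx$regions
  # TR_other carries a 3'-end PES but no 5'TOP; non_TR carries neither
  prof <- positional_pyrimidine_profile(
    tx, rg$transcript_id[rg$category == "TR_other"],
    rg$transcript_id[rg$category == "non_TR"], window = 25)
  expect_lt(prof$test_last$p, 0.01)
  expect_gt(prof$test_first$p, 0.05)
  # uniform all-pyrimidine composition: both windows read 1.0
  one <- list(
    sequences = c(U1 = paste(rep("C", 300), collapse = ""),
                  U2 = paste(rep("C", 300), collapse = "")),
    regions = data.frame(transcript_id = c("U1", "U2"),
                         gene_id = c("g1", "g2"),
                         category = "RP", utr5_len = 100L,
                         cds_len = 100L, utr3_len = 100L,
                         length = 300L))
  expect_message(
    p2 <- positional_pyrimidine_profile(one, c("U1", "U2"), c("U1", "U2"),
                                        window = 25),
    "convention")
  expect_equal(p2$group_a$first, c(1.0, 1.0))
  expect_equal(p2$group_a$last, c(1.0, 1.0))
  # too-short UTRs are excluded
  expect_error(
    positional_pyrimidine_profile(one, c("U1", "U2"), c("U1", "U2"),
                                  window = 60),
    "too short")
})

test_that("site sequence extension clips at transcript ends", {
  tx <- list(sequences = c(TX = paste(rep("ACGT", 10), collapse = "")),
             regions = data.frame(transcript_id = "TX", gene_id = "g",
                                  category = "RP", utr5_len = 10L,
                                  cds_len = 20L, utr3_len = 10L,
                                  length = 40L))
  sites <- data.frame(transcript_id = "TX", start = 5L, end = 15L)
  s <- site_sequences(sites, tx, extend = 15)
  expect_identical(s, substring(tx$sequences[["TX"]], 1, 30))
})

test_that("planted PES hexamers dominate the k-mer enrichment summary", {
  set.seed(41)
  seqs <- vapply(1:40, function(i) {
    paste0(rand_seq(10), paste(rep("CT", 6), collapse = ""), rand_seq(10))
  }, "")
  top <- enriched_kmers(seqs, k = 6, n_shuffle = 3, top = 5)
  expect_true(any(grepl("^[CT]{6}$", top$kmer)))
})
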