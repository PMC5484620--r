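test_that("read clustering merges by >= 1 nt overlap, half-open", {
  rd <- data.frame(start = c(10L, 25L, 100L), end = c(30L, 45L, 120L))
  cl <- cluster_reads(rd)$clusters
  expect_equal(cl$start, c(10L, 100L))
  expect_equal(cl$end, c(45L, 120L))
  # book-ended intervals do not overlap
  cl2 <- cluster_reads(data.frame(start = c(10L, 20L),
                                  end = c(20L, 30L)))$clusters
  expect_identical(nrow(cl2), 2L)
  # singleton
  cl3 <- cluster_reads(data.frame(start = 5L, end = 35L))$clusters
  expect_equal(cl3$start, 5L)
  expect_equal(cl3$end, 35L)
  expect_identical(nrow(cluster_reads(rd[0, ])$clusters), 0L)
})

test_that("clustering matches the O(n^2) transitive-overlap oracle", {
  set.seed(99)
  for (i in 1:500) {
    n <- sample(1:25, 1)
    s <- sample(0:200, n, replace = TRUE)
    w <- sample(5:40, n, replace = TRUE)
    got <- cluster_reads(data.frame(start = s, end = s + w))$clusters
    want <- oracle_cluster(s, s + w)
    expect_identical(nrow(got), nrow(want))
    expect_equal(got$start, as.integer(want[, 1]))
    expect_equal(got$end, as.integer(want[, 2]))
  }
})

test_that("Gaussian smoothing preserves mass and symmetry", {
  # mass conservation before trimming
  set.seed(31)
  cov <- runif(50)
  sm <- smooth_coverage(cov, sigma = 5)
  expect_equal(sum(sm$smoothed), sum(cov), tolerance = 1e-6)
  # a single spike smooths to a symmetric profile about the spike
  spike <- numeric(21); spike[11] <- 1
  sp <- smooth_coverage(spike, sigma = 3)$smoothed
  peak <- which.max(sp)
  k <- min(peak - 1, length(sp) - peak)
  expect_equal(sp[peak - seq_len(k)], sp[peak + seq_len(k)],
               tolerance = 1e-12)
})

test_that("sigma -> 0 trims to the raw cluster span", {
  rd <- data.frame(start = c(10L, 20L), end = c(25L, 40L), weight = 1)
  cl <- data.frame(start = 10L, end = 40L)
  out <- smooth_cluster(rd, cl, caller_params(smoothing_sigma = 0))
  expect_identical(out$start, 10L)
  expect_identical(out$end, 40L)
})

test_that("clusters entirely below the smoothing floor are dropped", {
  rd <- data.frame(start = 10L, end = 40L, weight = 0.1)
  cl <- data.frame(start = 10L, end = 40L)
  out <- smooth_cluster(rd, cl, caller_params(smoothing_floor = 0.5))
  expect_null(out)
})

test_that("site scoring follows the RPM and norm-score formulas", {
  cand <- data.frame(transcript_id = "TX", start = 0L, end = 50L,
                     read_count = 50, conversion_read_count = 3L)
  out <- filter_and_score(cand, 2e6)
  expect_equal(out$rpm, 25.0)
  expr <- data.frame(transcript_id = "TX", rpkm_mean = 50)
  out2 <- filter_and_score(cand, 2e6, expression = expr)
  expect_equal(out2$norm_score, 500.0)
  # all-zero-conversion clusters are dropped
  cand$conversion_read_count <- 0L
  expect_identical(nrow(filter_and_score(cand, 2e6)), 0L)
  # zero-RPKM transcripts keep the site, norm_score undefined
  cand$conversion_read_count <- 2L
  expr$rpkm_mean <- 0
  expect_message(out3 <- filter_and_score(cand, 2e6, expression = expr),
                 "without positive RPKM")
  expect_true(is.na(out3$norm_score))
})

test_that("called sites always contain a conversion read and pass the RPM bar", {
  spec <- tiny_spec()
  tx <- generate_transcriptome(spec)
  reads <- annotate_mismatches(simulate_parclip(tx, "mTOR_off"),
                               tx$sequences)
  reads <- distribute_multimappers(reads)
  params <- caller_params(rpm_threshold = 30)
  sites <- call_sites(reads, tx, params = params, condition = "mTOR_off")
  expect_gt(nrow(sites), 0)
  expect_true(all(sites$conversion_read_count >= 1))
  expect_true(all(sites$rpm >= 30))
})

test_that("raising the RPM threshold only shrinks the site set", {
  spec <- tiny_spec()
  tx <- generate_transcriptome(spec)
  reads <- annotate_mismatches(simulate_parclip(tx, "mTOR_off"),
                               tx$sequences)
  reads <- distribute_multimappers(reads)
  key <- function(s) paste(s$transcript_id, s$start, s$end)
  prev <- NULL
  for (thr in c(1, 20, 60, 200)) {
    cur <- call_sites(reads, tx,
                      params = caller_params(rpm_threshold = thr))
    if (!is.null(prev)) expect_true(all(key(cur) %in% prev))
    prev <- key(cur)
  }
})
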