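test_that("spec validation rejects out-of-range parameters", {
  expect_error(simulation_spec(conversion_rate = 1.5), "probabilities")
  expect_error(simulation_spec(fraction_rp = 0.7, fraction_tr_other = 0.5),
               "<= 1")
  expect_error(simulation_spec(utr5_len = c(200, 100)), "utr5_len")
  expect_error(simulation_spec(utr3_len = c(5, 10)), "UTR3")
  expect_error(simulation_spec(utr5_len = c(10, 12)), "UTR5")
})

test_that("category counts follow the rounding rule exactly", {
  spec <- simulation_spec(n_transcripts = 100, fraction_rp = 0.2,
                          fraction_tr_other = 0.1, seed = 3)
  tx <- generate_transcriptome(spec)
  expect_identical(sum(tx$regions$category == "RP"), 20L)
  expect_identical(sum(tx$regions$category == "TR_other"), 10L)
  expect_identical(sum(tx$regions$category == "non_TR"), 70L)
})

test_that("generation is deterministic given the seed, byte for byte", {
  spec <- tiny_spec()
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  dir.create(d1, showWarnings = FALSE); dir.create(d2, showWarnings = FALSE)
  for (d in c(d1, d2)) {
    tx <- generate_transcriptome(spec)
    write_transcript_fasta(tx, file.path(d, "t.fa"))
    write_region_tsv(tx$regions, file.path(d, "r.tsv"))
  }
  expect_identical(readLines(file.path(d1, "t.fa")),
                   readLines(file.path(d2, "t.fa")))
  expect_identical(readLines(file.path(d1, "r.tsv")),
                   readLines(file.path(d2, "r.tsv")))
})

test_that("planted footprints respect their declared structure", {
  spec <- simulation_spec(n_transcripts = 60, pes_pyrimidine_rate = 1.0,
                          seed = 5)
  tx <- generate_transcriptome(spec)
  ts <- tx$truth$sites
  b <- region_bounds(tx$regions, ts$transcript_id)
  # region containment, 0-based half-open
  lo <- ifelse(ts$region == "UTR5", 0L,
               ifelse(ts$region == "CDS", b[, "utr5_end"], b[, "cds_end"]))
  hi <- ifelse(ts$region == "UTR5", b[, "utr5_end"],
               ifelse(ts$region == "CDS", b[, "cds_end"], b[, "length"]))
  expect_true(all(ts$start >= lo & ts$end <= hi))
  # PES footprints abut the 5'UTR/CDS junction and are pure pyrimidine at
  # rate 1
  pes <- ts[ts$kind == "PES", ]
  expect_true(all(pes$end == b[ts$kind == "PES", "utr5_end"]))
  pes_seq <- substring(tx$sequences[pes$transcript_id], pes$start + 1,
                       pes$end)
  expect_true(all(pyrimidine_fraction(pes_seq) == 1.0))
  # RP transcripts start with a 5'TOP: C then >= top_run_len pyrimidines
  rp_seq <- tx$sequences[tx$regions$category == "RP"]
  tops <- classify_top(rp_seq, min_run = spec$top_run_len)
  expect_true(all(tops$is_top))
  # non_TR transcripts carry no 5'UTR footprint
  expect_false(any(ts$region == "UTR5" & ts$category == "non_TR"))
})

test_that("conversion signature appears at the specified rate", {
  spec <- simulation_spec(n_transcripts = 60, seed = 9)
  tx <- generate_transcriptome(spec)
  reads <- simulate_parclip(tx, "mTOR_off")
  est <- estimate_conversion_rate(reads, tx)
  expect_gte(est$n_covered_t, 1000)
  expect_lt(abs(est$estimate - spec$conversion_rate), 3 * est$se)
})

test_that("conversion_rate = 0 leaves footprint reads conversion-free", {
  spec <- simulation_spec(n_transcripts = 30, conversion_rate = 0,
                          seq_error_rate = 0, seed = 2)
  tx <- generate_transcriptome(spec)
  reads <- simulate_parclip(tx, "mTOR_off")
  reads <- annotate_mismatches(reads, tx$sequences)
  expect_true(all(reads$t_to_c == 0))
})

test_that("mTOR_on silences RP 5'UTR footprints", {
  spec <- simulation_spec(n_transcripts = 40, background_read_rate = 0,
                          seed = 4)
  tx <- generate_transcriptome(spec)
  reads <- simulate_parclip(tx, "mTOR_on")
  rp_u5 <- tx$truth$sites[tx$truth$sites$category == "RP" &
                            tx$truth$sites$region == "UTR5", ]
  mid <- (reads$start + reads$end) / 2
  in_fp <- vapply(seq_len(nrow(reads)), function(i) {
    any(rp_u5$transcript_id == reads$transcript_id[i] &
          mid[i] >= rp_u5$start & mid[i] < rp_u5$end)
  }, logical(1))
  expect_identical(sum(in_fp), 0L)
})

test_that("empty truth yields an empty SAM with a valid header", {
  occ <- default_occupancy()
  occ$mTOR_on <- 0; occ$mTOR_off <- 0
  spec <- simulation_spec(n_transcripts = 10, occupancy = occ,
                          background_read_rate = 0, seed = 6)
  tx <- generate_transcriptome(spec)
  reads <- simulate_parclip(tx, "mTOR_off")
  expect_identical(nrow(reads), 0L)
  p <- tempfile(fileext = ".sam")
  write_sam(reads, setNames(tx$regions$length, tx$regions$transcript_id), p)
  back <- read_sam(p)
  expect_identical(nrow(back), 0L)
  expect_length(attr(back, "seq_lengths"), 10L)
})

test_that("replicate mRNA-seq libraries are concordant and proportional", {
  spec <- simulation_spec(n_transcripts = 100, mrnaseq_depth = 5e5, seed = 8)
  tx <- generate_transcriptome(spec)
  reps <- simulate_mrnaseq(tx)
  et <- expression_table(reps, tx$regions)
  cc <- replicate_concordance(et$rpkm_rep1, et$rpkm_rep2)
  expect_gte(cc$r_squared, 0.99)
  expect_error(simulate_mrnaseq(tx, depth = 0), "depth")
})

test_that("a doubled abundance doubles the expected read count", {
  spec <- simulation_spec(n_transcripts = 2, utr5_len = c(100, 100),
                          cds_len = c(400, 400), utr3_len = c(200, 200),
                          multimap_fraction = 0, mrnaseq_depth = 2e5,
                          seed = 10)
  tx <- generate_transcriptome(spec)
  tx$truth$abundance$abundance <- c(2 / 3, 1 / 3) # equal lengths, 2:1
  reps <- simulate_mrnaseq(tx, n_replicates = 1)
  cnt <- table(reps[[1]]$transcript_id)
  ratio <- as.numeric(cnt["TX0001"] / cnt["TX0002"])
  expect_lt(abs(ratio - 2), 0.1)
})

test_that("single-transcript library puts all reads on it with defined RPKM", {
  spec <- simulation_spec(n_transcripts = 1, multimap_fraction = 0,
                          mrnaseq_depth = 1e4, seed = 12)
  tx <- generate_transcriptome(spec)
  reps <- simulate_mrnaseq(tx, n_replicates = 1)
  expect_true(all(reps[[1]]$transcript_id == "TX0001"))
  et <- expression_table(reps, tx$regions)
  expect_equal(et$count_rep1, 1e4)
  expect_true(is.finite(et$rpkm_rep1) && et$rpkm_rep1 > 0)
})

test_that("multimapping cassette produces k-way ambiguous reads", {
  spec <- simulation_spec(n_transcripts = 60, multimap_fraction = 0.1,
                          mrnaseq_depth = 1e5, seed = 13)
  tx <- generate_transcriptome(spec)
  k <- sum(!is.na(tx$regions$cassette_start))
  expect_identical(k, 6L)
  reps <- simulate_mrnaseq(tx, n_replicates = 1)
  amb <- reps[[1]][reps[[1]]$n_placements > 1, ]
  expect_gt(nrow(amb), 0)
  expect_true(all(table(amb$read_id) == k))
  w <- distribute_multimappers(reps[[1]])
  expect_equal(sum(w$weight), length(unique(reps[[1]]$read_id)))
})
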