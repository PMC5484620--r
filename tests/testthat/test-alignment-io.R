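test_that("T-to-C counting follows the definition", {
  expect_identical(count_t_to_c("ACCG", "ATTG"), 2L)
  expect_identical(count_t_to_c("ATTG", "ATTG"), 0L)
  expect_identical(count_t_to_c("GG", "TG"), 0L) # T->G is not a conversion
  expect_identical(count_t_to_c("CN", "TT"), 1L) # N never counts
  expect_error(count_t_to_c("ACG", "AC"), "lengths differ")
})

test_that("T-to-C counting matches a per-base diff oracle on random pairs", {
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(10:40, 1)
    ref <- rand_seq(n, c("A", "C", "G", "T", "N"))
    read <- rand_seq(n, c("A", "C", "G", "T", "N"))
    expect_identical(count_t_to_c(read, ref),
                     oracle_t_to_c(read, ref))
  }
})

test_that("mismatch tables report position, ref and read base", {
  mt <- mismatch_table("ACCG", "ATTG", offset = 10L)
  expect_equal(mt$position, c(11L, 12L))
  expect_equal(mt$ref_base, c("T", "T"))
  expect_equal(mt$read_base, c("C", "C"))
})

test_that("multimapper weights are even and conserved", {
  pl <- data.frame(read_id = c("a", "a", "a", "a", "b", "c", "c", "c"))
  w <- distribute_multimappers(pl)
  expect_equal(w$weight[w$read_id == "a"], rep(0.25, 4))
  expect_equal(w$weight[w$read_id == "b"], 1.0)
  expect_equal(sum(w$weight[w$read_id == "c"]), 1.0, tolerance = 1e-12)
  expect_equal(sum(w$weight), 3) # = number of placed reads
})

test_that("best-stratum placement reports the minimum-mismatch stratum", {
  txs <- c(T1 = "GGGACGTTCAAGGG", T2 = "GGGACGTTCTAGGG")
  # read matches T1 exactly at offset 3, T2 only with 1 mismatch
  hits <- best_stratum_place("ACGTTCA", txs)
  expect_identical(hits$transcript_id, "T1")
  expect_identical(hits$start, 3L)
  expect_identical(hits$n_mismatch, 0L)
  # a read nowhere within the mismatch bound returns empty
  none <- best_stratum_place("TTTTTTTT", txs)
  expect_identical(nrow(none), 0L)
  # max_hits truncation
  poly <- c(P = paste(rep("ACGT", 20), collapse = ""))
  many <- best_stratum_place("ACGTACGT", poly,
                             mapping_policy(max_hits = 5))
  expect_identical(nrow(many), 5L)
})

test_that("best-stratum placement agrees with a naive scan", {
  set.seed(7)
  for (i in 1:20) {
    txs <- setNames(vapply(1:3, function(j) rand_seq(80), ""),
                    paste0("T", 1:3))
    read <- rand_seq(12)
    pol <- mapping_policy(max_mismatches = 3)
    got <- best_stratum_place(read, txs, pol)
    # naive: loop every transcript and offset, count mismatches per base
    all_hits <- NULL
    for (tid in names(txs)) {
      tv <- strsplit(txs[[tid]], "")[[1]]
      rv <- strsplit(read, "")[[1]]
      for (off in 0:(length(tv) - length(rv))) {
        mm <- sum(tv[(off + 1):(off + length(rv))] != rv)
        all_hits <- rbind(all_hits,
                          data.frame(transcript_id = tid, start = off,
                                     n_mismatch = mm))
      }
    }
    best <- min(all_hits$n_mismatch)
    want <- if (best <= 3) all_hits[all_hits$n_mismatch == best, ] else
      all_hits[0, ]
    expect_identical(nrow(got), nrow(want))
    if (nrow(got)) {
      got_key <- sort(paste(got$transcript_id, got$start))
      want_key <- sort(paste(want$transcript_id, want$start))
      expect_identical(got_key, want_key)
      expect_true(all(got$n_mismatch == best))
    }
  }
})

test_that("annotate_mismatches recovers planted conversions from sequence", {
  seqs <- c(TX = "AATTGGCCTTAA")
  reads <- data.frame(transcript_id = "TX", start = 2L, end = 8L,
                      seq = "TCGGCC") # ref TTGGCC: one T->C at pos 3
  out <- annotate_mismatches(reads, seqs)
  expect_identical(out$n_mismatch, 1L)
  expect_identical(out$t_to_c, 1L)
  expect_error(
    annotate_mismatches(data.frame(transcript_id = "NOPE", start = 0L,
                                   end = 3L, seq = "AAA"), seqs),
    "NOPE")
})
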