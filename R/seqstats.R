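#' Pyrimidine fraction of a sequence
#'
#' `(#C + #T) / (length - #N)`; N is excluded from the denominator. An
#' all-N (or empty) sequence has no defined composition and is an error.
#'
#' @param seq character vector of sequences over `A/C/G/T/N`.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
pyrimidine_fraction <- function(seq) {
  base_fraction(seq, c("C", "T"))
}

#' Guanine fraction of a sequence (N excluded from the denominator)
#' @param seq character vector of sequences.
#' @return Numeric vector of fractions.
#' @export
g_fraction <- function(seq) {
  base_fraction(seq, "G")
}

base_fraction <- function(seq, bases) {
  if (any(!nzchar(seq))) stop("empty sequence")
  n_tot <- nchar(seq)
  n_n <- nchar(gsub("[^N]", "", seq))
  if (any(n_tot == n_n)) stop("all-N sequence: composition undefined")
  pat <- paste0("[^", paste(bases, collapse = ""), "]")
  nchar(gsub(pat, "", seq)) / (n_tot - n_n)
}

#' Welch's two-sample t-test (two-tailed)
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-tailed p from the t distribution. When both groups have zero
#' variance and equal means the test is degenerate and `p = 1` is returned
#' by convention (with a message).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return List of class `composition_test`: `t`, `df`, `p`, `mean_a`,
#'   `mean_b`, `n_a`, `n_b`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values")
  }
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      message("zero variance in both groups with equal means; p = 1 ",
              "by convention")
      return(structure(list(t = 0, df = NA_real_, p = 1, mean_a = mean(a),
                            mean_b = mean(b), n_a = na, n_b = nb),
                       class = "composition_test"))
    }
    stop("zero variance in both groups with unequal means")
  }
  se2 <- va / na + vb / nb
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(list(t = t_stat, df = df, p = p, mean_a = mean(a),
                 mean_b = mean(b), n_a = na, n_b = nb),
            class = "composition_test")
}

#' @export
print.composition_test <- function(x, ...) {
  cat(sprintf(
    "Welch two-tailed t-test: t = %.4g, df = %.2f, p = %.3g\n",
    x$t, x$df, x$p))
  cat(sprintf("  group means %.4g (n=%d) vs %.4g (n=%d)\n",
              x$mean_a, x$n_a, x$mean_b, x$n_b))
  invisible(x)
}

# union of site spans intersected with [rs, re), returned as a merged
# interval data.frame
merge_spans <- function(starts, ends, rs, re) {
  s <- pmax(starts, rs); e <- pmin(ends, re)
  keep <- s < e
  s <- s[keep]; e <- e[keep]
  if (!length(s)) return(data.frame(start = integer(), end = integer()))
  ord <- order(s, e)
  s <- s[ord]; e <- e[ord]
  out_s <- s[1]; out_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > out_e[length(out_e)]) {
      out_s <- c(out_s, s[i]); out_e <- c(out_e, e[i])
    } else {
      out_e[length(out_e)] <- max(out_e[length(out_e)], e[i])
    }
  }
  data.frame(start = out_s, end = out_e)
}

#' Compare composition of bound versus unbound parts of a region
#'
#' Per transcript with at least one binding site assigned to the scoped
#' region, the composition of the bound segment (union of site spans clipped
#' to the region) and of the unbound remainder of the same region are
#' computed; the two collections are compared with an unpaired Welch test.
#' Composition is the pyrimidine fraction for 5'UTR scope and the guanine
#' fraction for 3'UTR scope. Transcripts whose region is entirely bound
#' contribute no unbound value (logged).
#'
#' @param sites site table with `region` labels.
#' @param tx a `transcriptome` (needs `sequences` and `regions`).
#' @param scope `"UTR5"` or `"UTR3"`.
#' @return A `composition_test` with extra fields `bound`, `unbound`
#'   (per-transcript composition vectors) and `scope`.
#' @export
bound_vs_unbound_composition <- function(sites, tx, scope = c("UTR5", "UTR3")) {
  scope <- match.arg(scope)
  comp_fn <- if (scope == "UTR5") pyrimidine_fraction else g_fraction
  use <- sites[sites$region == scope, , drop = FALSE]
  tids <- unique(use$transcript_id)
  if (length(tids) < 2L) {
    stop("need at least 2 transcripts with a bound segment in ", scope)
  }
  bound <- numeric(0); unbound <- numeric(0)
  n_full <- 0L
  for (tid in tids) {
    b <- region_bounds(tx$regions, tid)
    rng <- switch(scope,
                  UTR5 = c(0L, b[, "utr5_end"]),
                  UTR3 = c(b[, "cds_end"], b[, "length"]))
    ss <- use[use$transcript_id == tid, , drop = FALSE]
    bs <- merge_spans(ss$start, ss$end, rng[1], rng[2])
    if (!nrow(bs)) next
    seqs <- substr0(rep(tx$sequences[[tid]], nrow(bs)), bs$start, bs$end)
    bound <- c(bound, comp_fn(paste(seqs, collapse = "")))
    # unbound remainder = region minus bound spans
    gaps_s <- c(rng[1], bs$end)
    gaps_e <- c(bs$start, rng[2])
    keep <- gaps_s < gaps_e
    if (any(keep)) {
      gseq <- substr0(rep(tx$sequences[[tid]], sum(keep)),
                      gaps_s[keep], gaps_e[keep])
      unbound <- c(unbound, comp_fn(paste(gseq, collapse = "")))
    } else {
      n_full <- n_full + 1L
    }
  }
  if (n_full > 0L) {
    message(n_full, " transcript(s) with the whole ", scope,
            " bound; excluded from the unbound group")
  }
  res <- welch_t_test(bound, unbound)
  res$bound <- bound
  res$unbound <- unbound
  res$scope <- scope
  res
}

#' Longest contiguous pyrimidine run
#' @param seq character vector of sequences.
#' @return Integer vector: maximum run length of consecutive `C`/`T`.
#' @export
max_pyrimidine_run <- function(seq) {
  if (any(!nzchar(seq))) stop("empty sequence")
  vapply(seq, function(s) {
    r <- rle(chars(s) %in% c("C", "T"))
    runs <- r$lengths[r$values]
    if (length(runs)) max(runs) else 0L
  }, integer(1), USE.NAMES = FALSE)
}

#' Fraction of site sequences containing a pyrimidine run of length >= k
#'
#' In-house pyrimidine-run motif summary (a stand-in for external motif
#' discovery): site sequences are expected to be pre-extended (±15 nt by
#' default elsewhere) before scanning.
#'
#' @param site_seqs character vector of site sequences.
#' @param k minimum run length (default 6, the "six consecutive
#'   pyrimidines" criterion).
#' @return List: `fraction`, `n_sites`, `run_lengths`.
#' @export
summarize_runs <- function(site_seqs, k = 6L) {
  runs <- max_pyrimidine_run(site_seqs)
  list(fraction = mean(runs >= k), n_sites = length(site_seqs),
       run_lengths = runs)
}

#' Extract (optionally extended) site sequences
#'
#' @param sites site table.
#' @param tx a `transcriptome`.
#' @param extend nt added up- and downstream (clipped at transcript ends);
#'   default 15.
#' @return Character vector of sequences, one per site.
#' @export
site_sequences <- function(sites, tx, extend = 15L) {
  lens <- stats::setNames(tx$regions$length, tx$regions$transcript_id)
  s <- pmax(0L, sites$start - extend)
  e <- pmin(unname(lens[sites$transcript_id]), sites$end + extend)
  unname(substr0(tx$sequences[sites$transcript_id], s, e))
}

#' Classify transcripts as 5'TOP
#'
#' Operational definition (configurable, reported in output): a transcript
#' is 5'TOP iff its first base is C and the following `min_run` bases are
#' all pyrimidines. `top_run_length` is the full length of the initial
#' C-led pyrimidine run.
#'
#' @param tx a `transcriptome` (or named character vector of sequences).
#' @param min_run minimum pyrimidine run after the initial C (default 4).
#' @return data.frame `transcript_id`, `is_top`, `top_run_length`.
#' @export
classify_top <- function(tx, min_run = 4L) {
  seqs <- if (inherits(tx, "transcriptome")) tx$sequences else tx
  run_len <- vapply(seqs, function(s) {
    v <- chars(s)
    if (v[1] != "C") return(0L)
    r <- rle(v %in% c("C", "T"))
    as.integer(r$lengths[1])
  }, integer(1), USE.NAMES = FALSE)
  data.frame(transcript_id = names(seqs),
             is_top = run_len >= 1L + min_run,
             top_run_length = run_len, stringsAsFactors = FALSE)
}

#' Fraction of 5'UTR binding sites overlapping the 5'TOP run
#'
#' @param sites site table (`region` labels present).
#' @param top_calls output of [classify_top()].
#' @return List: `fraction` (of 5'UTR sites with >= 1 nt intersection with
#'   the TOP run of a TOP transcript), `n_utr5_sites`, `n_overlapping`.
#' @export
top_overlap <- function(sites, top_calls) {
  u5 <- sites[sites$region == "UTR5", , drop = FALSE]
  if (!nrow(u5)) {
    return(list(fraction = NA_real_, n_utr5_sites = 0L, n_overlapping = 0L))
  }
  i <- match(u5$transcript_id, top_calls$transcript_id)
  run <- ifelse(top_calls$is_top[i], top_calls$top_run_length[i], 0L)
  hit <- interval_overlap(u5$start, u5$end, 0L, run) > 0L
  list(fraction = mean(hit), n_utr5_sites = nrow(u5),
       n_overlapping = sum(hit))
}

#' Positional pyrimidine profile of 5'UTRs and group comparison
#'
#' Per 5'UTR of length >= 2*window, computes the pyrimidine fraction of the
#' 5'-most and 3'-most `window` nt; shorter UTRs are excluded (logged). When
#' two transcript groups are given, each window's compositions are compared
#' between groups with [welch_t_test()].
#'
#' @param tx a `transcriptome`.
#' @param group_a,group_b character vectors of transcript ids.
#' @param window window size in nt (default 25).
#' @return List with per-group data.frames (`transcript_id`, `first`,
#'   `last`) and `test_first` / `test_last` Welch tests.
#' @export
positional_pyrimidine_profile <- function(tx, group_a, group_b,
                                          window = 25L) {
  one_group <- function(ids) {
    b <- region_bounds(tx$regions, ids)
    ok <- b[, "utr5_end"] >= 2L * window
    if (any(!ok)) {
      message(sum(!ok), " 5'UTR(s) shorter than 2*window excluded")
    }
    ids <- ids[ok]
    if (!length(ids)) return(NULL)
    u5 <- b[ok, "utr5_end"]
    first <- pyrimidine_fraction(substr0(tx$sequences[ids], 0L, window))
    last <- pyrimidine_fraction(substr0(tx$sequences[ids], u5 - window, u5))
    data.frame(transcript_id = ids, first = unname(first),
               last = unname(last), stringsAsFactors = FALSE)
  }
  a <- one_group(group_a)
  b <- one_group(group_b)
  if (is.null(a) || is.null(b)) stop("all 5'UTRs too short for this window")
  list(group_a = a, group_b = b,
       test_first = welch_t_test(a$first, b$first),
       test_last = welch_t_test(a$last, b$last),
       window = as.integer(window))
}

#' Enriched hexamer counts, bound versus shuffled background
#'
#' Simple k-mer enrichment stand-in for motif discovery: counts k-mers in
#' the given site sequences and in base-shuffled versions of the same
#' sequences, and reports the most enriched k-mers by log2 ratio (with a
#' +1 pseudocount).
#'
#' @param site_seqs character vector of (extended) site sequences.
#' @param k k-mer length (default 6).
#' @param n_shuffle shuffled background replicates (default 5).
#' @param top number of k-mers to report.
#' @return data.frame `kmer`, `bound_count`, `background_mean`,
#'   `log2_enrichment`, sorted by enrichment.
#' @export
enriched_kmers <- function(site_seqs, k = 6L, n_shuffle = 5L, top = 20L) {
  count_kmers <- function(seqs) {
    tab <- table(unlist(lapply(seqs, function(s) {
      n <- nchar(s)
      if (n < k) return(character())
      substring(s, 1:(n - k + 1L), k:n)
    })))
    tab
  }
  obs <- count_kmers(site_seqs)
  shuf <- lapply(seq_len(n_shuffle), function(i) {
    count_kmers(vapply(site_seqs,
                       function(s) paste(sample(chars(s)), collapse = ""),
                       "", USE.NAMES = FALSE))
  })
  kmers <- names(obs)
  bg <- vapply(kmers, function(km) {
    mean(vapply(shuf, function(tb) {
      v <- tb[km]; if (is.na(v)) 0 else as.numeric(v)
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(kmer = kmers, bound_count = as.numeric(obs[kmers]),
                    background_mean = bg,
                    log2_enrichment = log2((as.numeric(obs[kmers]) + 1) /
                                             (bg + 1)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$log2_enrichment, -out$bound_count), ]
  rownames(out) <- NULL
  utils::head(out, top)
}
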