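#' Site-caller parameters
#'
#' @param max_t_to_c_per_read reads with more T-to-C conversions than this
#'   are discarded before clustering (default 2, the 0-2-conversion rule).
#' @param min_conversion_reads minimum number of member reads carrying at
#'   least one conversion for a cluster to be kept as a binding site.
#' @param rpm_threshold minimum site RPM (reads per million mapped reads);
#'   the underlying study used an empirically derived, unpublished value, so
#'   the threshold is an explicit, configurable parameter here.
#' @param smoothing_sigma Gaussian smoothing sigma in nt.
#' @param smoothing_floor smoothed-coverage floor used to trim site
#'   boundaries.
#' @return A `caller_params` list.
#' @export
caller_params <- function(max_t_to_c_per_read = 2L,
                          min_conversion_reads = 1L,
                          rpm_threshold = 1.0,
                          smoothing_sigma = 5,
                          smoothing_floor = 0.5) {
  p <- list(max_t_to_c_per_read = as.integer(max_t_to_c_per_read),
            min_conversion_reads = as.integer(min_conversion_reads),
            rpm_threshold = rpm_threshold,
            smoothing_sigma = smoothing_sigma,
            smoothing_floor = smoothing_floor)
  if (any(unlist(p) < 0)) stop("caller parameters must be >= 0")
  class(p) <- "caller_params"
  p
}

#' Cluster reads into peaks by single-nucleotide overlap
#'
#' Reads on one transcript are clustered into maximal sets connected by
#' (pairwise or transitive) overlap of at least one nucleotide; the cluster
#' span is the union of member spans. Intervals are 0-based half-open, so
#' `(10,20)` and `(20,30)` do NOT overlap. Callers are expected to have
#' filtered reads to `t_to_c <= max_t_to_c_per_read` first.
#'
#' @param reads alignment data.frame for a single transcript with `start`,
#'   `end`.
#' @return List with `clusters` (data.frame `cluster_id`, `start`, `end`,
#'   `n_reads`) and `assignment` (cluster id per input row).
#' @export
cluster_reads <- function(reads) {
  n <- nrow(reads)
  if (!n) {
    return(list(clusters = data.frame(cluster_id = integer(),
                                      start = integer(), end = integer(),
                                      n_reads = integer()),
                assignment = integer()))
  }
  ord <- order(reads$start, reads$end)
  s <- reads$start[ord]; e <- reads$end[ord]
  cid <- integer(n)
  cur <- 1L
  cid[1L] <- 1L
  max_end <- e[1L]
  for (i in seq_len(n)[-1L]) {
    if (s[i] >= max_end) {
      cur <- cur + 1L
      max_end <- e[i]
    } else {
      max_end <- max(max_end, e[i])
    }
    cid[i] <- cur
  }
  assignment <- integer(n)
  assignment[ord] <- cid
  clusters <- data.frame(
    cluster_id = seq_len(cur),
    start = as.integer(tapply(s, cid, min)),
    end = as.integer(tapply(e, cid, max)),
    n_reads = as.integer(tabulate(cid, cur))
  )
  list(clusters = clusters, assignment = assignment)
}

#' Gaussian-smooth a coverage vector
#'
#' Discrete convolution with a unit-mass Gaussian kernel truncated at 4
#' sigma; the input is zero-padded by the kernel half-width so total mass is
#' preserved exactly. `sigma = 0` returns the input padded with zeros.
#'
#' @param coverage numeric per-base coverage.
#' @param sigma kernel sigma in nt.
#' @return List with `smoothed` (length `length(coverage) + 2*half`),
#'   `offset` (= half-width, bases prepended before position 1).
#' @export
smooth_coverage <- function(coverage, sigma) {
  if (sigma <= 0) {
    return(list(smoothed = coverage, offset = 0L))
  }
  half <- as.integer(ceiling(4 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  padded <- c(numeric(2L * half), coverage, numeric(2L * half))
  sm <- stats::filter(padded, kern, sides = 2)
  sm <- as.numeric(sm[(half + 1L):(length(padded) - half)])
  list(smoothed = sm, offset = half)
}

#' Smooth a read cluster and trim its boundaries
#'
#' Builds weighted per-base coverage over the cluster span, smooths it with
#' the Gaussian kernel, and trims the cluster to the maximal contiguous run
#' of smoothed coverage at or above `smoothing_floor` that contains the
#' smoothed maximum. If all smoothed coverage falls below the floor the
#' cluster is dropped (`NULL` return).
#'
#' @param reads member reads (data.frame with `start`, `end`, `weight`).
#' @param cluster one-row cluster (`start`, `end`).
#' @param params [caller_params()].
#' @param transcript_length optional clip bound for the trimmed span.
#' @return List with trimmed `start`, `end`, plus `smoothed` and its
#'   coordinate `origin`; or `NULL` when dropped.
#' @export
smooth_cluster <- function(reads, cluster, params = caller_params(),
                           transcript_length = NULL) {
  span <- cluster$end - cluster$start
  cov <- numeric(span)
  for (r in seq_len(nrow(reads))) {
    i <- (reads$start[r] - cluster$start + 1L):(reads$end[r] - cluster$start)
    cov[i] <- cov[i] + reads$weight[r]
  }
  sm <- smooth_coverage(cov, params$smoothing_sigma)
  origin <- cluster$start - sm$offset
  y <- sm$smoothed
  ok <- y >= params$smoothing_floor
  if (!any(ok)) return(NULL)
  peak <- which.max(y)
  if (!ok[peak]) return(NULL)
  lo <- peak
  while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- peak
  while (hi < length(y) && ok[hi + 1L]) hi <- hi + 1L
  start <- origin + lo - 1L
  end <- origin + hi
  start <- max(start, 0L)
  if (!is.null(transcript_length)) end <- min(end, transcript_length)
  list(start = as.integer(start), end = as.integer(end),
       smoothed = y, origin = as.integer(origin))
}

#' Filter clusters and score binding sites
#'
#' A cluster is retained as a binding site iff it has at least
#' `min_conversion_reads` member reads with a T-to-C conversion and its RPM
#' passes `rpm_threshold`. `rpm` is the weighted member read count per
#' million mapped reads; `norm_score = rpm / gene_RPKM * 1000` when
#' expression is available (sites on transcripts with zero/absent RPKM are
#' retained with `norm_score = NA`).
#'
#' @param site_df data.frame of candidate sites with `transcript_id`,
#'   `start`, `end`, `read_count` (weighted), `conversion_read_count`.
#' @param library_mapped_total total mapped reads (sum of weights) in the
#'   PAR-CLIP library.
#' @param expression optional expression table ([expression_table()]).
#' @param params [caller_params()].
#' @return The retained sites with `rpm` and `norm_score` columns.
#' @export
filter_and_score <- function(site_df, library_mapped_total,
                             expression = NULL, params = caller_params()) {
  if (library_mapped_total <= 0) stop("library_mapped_total must be > 0")
  site_df$rpm <- site_df$read_count / (library_mapped_total / 1e6)
  keep <- site_df$conversion_read_count >= params$min_conversion_reads &
    site_df$rpm >= params$rpm_threshold
  out <- site_df[keep, , drop = FALSE]
  out$norm_score <- rep(NA_real_, nrow(out))
  if (!is.null(expression) && nrow(out)) {
    rpkm <- expression$rpkm_mean[match(out$transcript_id,
                                       expression$transcript_id)]
    ok <- !is.na(rpkm) & rpkm > 0
    out$norm_score[ok] <- out$rpm[ok] / rpkm[ok] * 1000
    if (any(!ok)) {
      message(sum(!ok), " site(s) on transcripts without positive RPKM; ",
              "norm_score left undefined")
    }
  }
  rownames(out) <- NULL
  out
}

#' Call binding sites from PAR-CLIP alignments
#'
#' The full caller: annotates mismatches if needed, discards reads with more
#' than `max_t_to_c_per_read` conversions, distributes multimapper weights,
#' clusters reads per transcript, Gaussian-smooths and trims each cluster,
#' then filters and scores sites ([filter_and_score()]). Region labels are
#' attached via [assign_region()].
#'
#' @param reads PAR-CLIP alignments (`transcript_id`, `start`, `end`, `seq`).
#' @param tx a `transcriptome` (or list with `sequences` and `regions`).
#' @param expression optional expression table for norm_score.
#' @param params [caller_params()].
#' @param condition optional condition label stored on the output.
#' @param library_mapped_total denominator for RPM; defaults to the total
#'   placement weight of the conversion-filtered library.
#' @return data.frame of binding sites: `transcript_id`, `start`, `end`,
#'   `read_count`, `conversion_read_count`, `rpm`, `norm_score`, `region`,
#'   `condition`.
#' @export
call_sites <- function(reads, tx, expression = NULL,
                       params = caller_params(), condition = NA_character_,
                       library_mapped_total = NULL) {
  if (!"t_to_c" %in% names(reads)) {
    reads <- annotate_mismatches(reads, tx$sequences)
  }
  if (!"weight" %in% names(reads)) reads <- distribute_multimappers(reads)
  reads <- reads[reads$t_to_c <= params$max_t_to_c_per_read, , drop = FALSE]
  if (is.null(library_mapped_total)) {
    library_mapped_total <- sum(reads$weight)
  }
  empty <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), read_count = numeric(),
                      conversion_read_count = integer(), rpm = numeric(),
                      norm_score = numeric(), region = character(),
                      condition = character(), stringsAsFactors = FALSE)
  if (!nrow(reads)) return(empty)
  lens <- stats::setNames(tx$regions$length, tx$regions$transcript_id)
  pieces <- lapply(split(reads, reads$transcript_id), function(rd) {
    cl <- cluster_reads(rd)
    rows <- lapply(seq_len(nrow(cl$clusters)), function(ci) {
      members <- rd[cl$assignment == ci, , drop = FALSE]
      sm <- smooth_cluster(members, cl$clusters[ci, ], params,
                           transcript_length = lens[[rd$transcript_id[1]]])
      if (is.null(sm)) return(NULL)
      data.frame(
        transcript_id = rd$transcript_id[1],
        start = sm$start, end = sm$end,
        read_count = sum(members$weight),
        conversion_read_count = sum(members$t_to_c > 0L),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
  cand <- do.call(rbind, pieces)
  if (is.null(cand) || !nrow(cand)) return(empty)
  sites <- filter_and_score(cand, library_mapped_total, expression, params)
  if (!nrow(sites)) return(empty)
  sites$region <- assign_region(sites, tx$regions)
  sites$condition <- condition
  rownames(sites) <- NULL
  sites
}

#' Write binding sites as BED6+ and TSV
#'
#' @param sites site table from [call_sites()].
#' @param bed_path,tsv_path output paths (either may be `NULL`).
#' @export
write_sites <- function(sites, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = sites$transcript_id, start = sites$start,
                      end = sites$end,
                      name = sprintf("site%04d", seq_len(nrow(sites))),
                      score = round(ifelse(is.na(sites$norm_score), 0,
                                           sites$norm_score), 4),
                      strand = "+",
                      read_count = round(sites$read_count, 4),
                      conversion_read_count = sites$conversion_read_count,
                      rpm = round(sites$rpm, 4), region = sites$region,
                      condition = sites$condition, stringsAsFactors = FALSE)
    write_bed(bed, bed_path,
              extra_cols = c("read_count", "conversion_read_count", "rpm",
                             "region", "condition"))
  }
  if (!is.null(tsv_path)) {
    utils::write.table(sites, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(sites)
}
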