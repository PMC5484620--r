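#' Reads per kilobase per million mapped reads
#'
#' `RPKM = (count / (total_mapped/1e6)) / (length/1000)`. Vectorized over
#' `count` and `length_nt`. Counts may be fractional (weighted multimapper
#' placements).
#'
#' @param count weighted read count per transcript.
#' @param total_mapped total mapped reads in the library (sum of placement
#'   weights).
#' @param length_nt transcript length in nt.
#' @return RPKM value(s).
#' @export
compute_rpkm <- function(count, total_mapped, length_nt) {
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  if (any(length_nt <= 0)) stop("length_nt must be > 0")
  (count / (total_mapped / 1e6)) / (length_nt / 1000)
}

#' Per-transcript expression table from replicate libraries
#'
#' Sums placement weights per transcript and library ("total mapped reads" is
#' the sum of weights, consistent with even multimapper distribution),
#' computes per-library RPKM, the across-replicate mean, and an `expressed`
#' flag (nonzero count in at least one replicate) used as the enrichment
#' background rule.
#'
#' @param replicate_reads list of alignment data.frames (one per replicate);
#'   a `weight` column is added via [distribute_multimappers()] if absent.
#' @param regions `regions` data.frame (for transcript lengths; all its
#'   transcripts are reported, including unexpressed ones).
#' @return data.frame with `transcript_id`, `gene_id`, `length`,
#'   `count_rep<i>`, `rpkm_rep<i>`, `rpkm_mean`, `expressed`.
#' @export
expression_table <- function(replicate_reads, regions) {
  if (!length(replicate_reads)) stop("need at least one replicate library")
  out <- data.frame(transcript_id = regions$transcript_id,
                    gene_id = regions$gene_id,
                    length = regions$length, stringsAsFactors = FALSE)
  rpkm_cols <- character(length(replicate_reads))
  for (i in seq_along(replicate_reads)) {
    reads <- replicate_reads[[i]]
    if (!"weight" %in% names(reads)) reads <- distribute_multimappers(reads)
    w <- tapply(reads$weight, reads$transcript_id, sum)
    cnt <- as.numeric(w[out$transcript_id])
    cnt[is.na(cnt)] <- 0
    total <- sum(reads$weight)
    out[[paste0("count_rep", i)]] <- cnt
    out[[paste0("rpkm_rep", i)]] <- compute_rpkm(cnt, total, out$length)
    rpkm_cols[i] <- paste0("rpkm_rep", i)
  }
  out$rpkm_mean <- rowMeans(out[, rpkm_cols, drop = FALSE])
  count_cols <- paste0("count_rep", seq_along(replicate_reads))
  out$expressed <- rowSums(out[, count_cols, drop = FALSE] > 0) > 0
  out
}

#' Replicate RPKM concordance
#'
#' Pearson product-moment correlation between two replicate RPKM vectors,
#' reported as `r` and `r_squared`. Zero variance in either vector leaves the
#' correlation undefined (`NA`, with a warning); downstream averaging
#' proceeds regardless.
#'
#' @param rpkm1,rpkm2 equal-length numeric vectors, n >= 3.
#' @return List with `r`, `r_squared`, `n`.
#' @export
replicate_concordance <- function(rpkm1, rpkm2) {
  if (length(rpkm1) != length(rpkm2)) stop("vectors must have equal length")
  if (length(rpkm1) < 3L) stop("need at least 3 transcripts")
  if (stats::sd(rpkm1) == 0 || stats::sd(rpkm2) == 0) {
    warning("zero variance in an RPKM vector; correlation undefined")
    return(list(r = NA_real_, r_squared = NA_real_, n = length(rpkm1)))
  }
  r <- stats::cor(rpkm1, rpkm2)
  list(r = r, r_squared = r^2, n = length(rpkm1))
}
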