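#' Count T-to-C conversions between a read and its reference window
#'
#' Compares a read sequence to the reference window it aligns to and counts
#' positions where the reference is T and the read is C (the PAR-CLIP
#' crosslink signature). `N` in either sequence never counts.
#'
#' @param read_seq read sequence (single string, `A/C/G/T/N`).
#' @param ref_seq reference window of identical length.
#' @return Integer conversion count.
#' @export
count_t_to_c <- function(read_seq, ref_seq) {
  if (nchar(read_seq) != nchar(ref_seq)) {
    stop("read and reference window lengths differ (",
         nchar(read_seq), " vs ", nchar(ref_seq), ")")
  }
  rv <- chars(ref_seq); dv <- chars(read_seq)
  sum(rv == "T" & dv == "C")
}

# vectorized mismatch / T-to-C annotation of an alignment table against the
# reference sequences; adds n_mismatch and t_to_c columns
#' Annotate alignments with mismatch and T-to-C counts
#'
#' Recovers mismatches by comparing each read sequence to the reference
#' (rather than trusting alignment tags), then counts total mismatches and
#' the subset that are T-to-C conversions.
#'
#' @param reads alignment data.frame with `transcript_id`, `start`, `end`,
#'   `seq` (0-based half-open).
#' @param sequences named character vector of reference transcript sequences.
#' @return `reads` with added integer columns `n_mismatch` and `t_to_c`.
#' @export
annotate_mismatches <- function(reads, sequences) {
  stop_if_missing_cols(reads, c("transcript_id", "start", "end", "seq"),
                       "alignment table")
  missing <- setdiff(unique(reads$transcript_id), names(sequences))
  if (length(missing)) {
    stop("alignments reference unknown transcript(s): ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(reads)
  reads$n_mismatch <- integer(n)
  reads$t_to_c <- integer(n)
  if (!n) return(reads)
  refwin <- substr0(sequences[reads$transcript_id], reads$start, reads$end)
  for (r in seq_len(n)) {
    rv <- chars(refwin[[r]]); dv <- chars(reads$seq[r])
    diff <- rv != dv & rv != "N" & dv != "N"
    reads$n_mismatch[r] <- sum(diff)
    reads$t_to_c[r] <- sum(diff & rv == "T" & dv == "C")
  }
  reads
}

#' Mismatch list of one read against the reference
#'
#' @param read_seq,ref_seq equal-length sequences.
#' @param offset 0-based alignment start (added to reported positions).
#' @return data.frame with `position` (0-based transcript coordinate),
#'   `ref_base`, `read_base`.
#' @export
mismatch_table <- function(read_seq, ref_seq, offset = 0L) {
  if (nchar(read_seq) != nchar(ref_seq)) {
    stop("read and reference window lengths differ")
  }
  rv <- chars(ref_seq); dv <- chars(read_seq)
  i <- which(rv != dv & rv != "N" & dv != "N")
  data.frame(position = offset + i - 1L, ref_base = rv[i], read_base = dv[i],
             stringsAsFactors = FALSE)
}

#' Distribute multimapping reads evenly across their placements
#'
#' Each read with `k` retained placements gets weight `1/k` per placement, so
#' weights per read sum to one and total weight equals the number of placed
#' reads.
#'
#' @param placements data.frame with at least `read_id`.
#' @return `placements` with a `weight` column.
#' @export
distribute_multimappers <- function(placements) {
  stop_if_missing_cols(placements, "read_id", "placement table")
  k <- table(placements$read_id)
  placements$weight <- 1 / as.numeric(k[placements$read_id])
  placements
}

#' Mapping policy mirroring a mismatch-bounded best-stratum aligner
#'
#' @param max_mismatches maximum mismatches allowed (default 3).
#' @param max_hits report at most this many placements (default 100).
#' @param best_stratum_only keep only placements at the minimum observed
#'   mismatch count (default TRUE).
#' @return A `mapping_policy` list.
#' @export
mapping_policy <- function(max_mismatches = 3L, max_hits = 100L,
                           best_stratum_only = TRUE) {
  if (max_mismatches < 0L) stop("max_mismatches must be >= 0")
  if (max_hits < 1L) stop("max_hits must be >= 1")
  structure(list(max_mismatches = as.integer(max_mismatches),
                 max_hits = as.integer(max_hits),
                 best_stratum_only = isTRUE(best_stratum_only)),
            class = "mapping_policy")
}

#' Exhaustively place a read on a transcript set (best stratum)
#'
#' Desk-scale stand-in for an external short-read aligner: scans every
#' ungapped offset of every transcript, counts mismatches, and reports all
#' placements in the best stratum (minimum mismatch count), provided that
#' minimum does not exceed `policy$max_mismatches`; output is truncated to
#' `policy$max_hits` in positional order (transcript, then offset).
#'
#' @param read_seq read sequence.
#' @param sequences named character vector of transcript sequences.
#' @param policy a [mapping_policy()].
#' @return data.frame `transcript_id`, `start`, `end`, `n_mismatch` (possibly
#'   empty).
#' @export
best_stratum_place <- function(read_seq, sequences, policy = mapping_policy()) {
  m <- nchar(read_seq)
  readv <- charToRaw(read_seq)
  hits <- list()
  for (tid in names(sequences)) {
    refv <- charToRaw(sequences[[tid]])
    n_off <- length(refv) - m + 1L
    if (n_off < 1L) next
    idx <- outer(seq_len(m), seq_len(n_off) - 1L, "+")
    mm <- colSums(matrix(refv[idx], nrow = m) != readv)
    keep <- which(mm <= policy$max_mismatches)
    if (length(keep)) {
      hits[[tid]] <- data.frame(
        transcript_id = tid, start = keep - 1L, end = keep - 1L + m,
        n_mismatch = as.integer(mm[keep]), stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(transcript_id = character(), start = integer(),
               end = integer(), n_mismatch = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!nrow(out)) return(out)
  if (policy$best_stratum_only) {
    out <- out[out$n_mismatch == min(out$n_mismatch), , drop = FALSE]
  }
  out <- out[order(match(out$transcript_id, names(sequences)), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, policy$max_hits)
}
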