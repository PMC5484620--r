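#' Write alignments as SAM
#'
#' Minimal single-end, ungapped, forward-strand SAM (CIGAR `<len>M`, MAPQ
#' 255). Secondary placements of a multimapping read carry flag 256. Internal
#' 0-based half-open starts become 1-based `POS` per the SAM standard.
#'
#' @param reads alignment data.frame with `read_id`, `transcript_id`,
#'   `start`, `end`, optionally `seq`.
#' @param seq_lengths named integer vector of reference lengths for the
#'   `@SQ` header.
#' @param path output path.
#' @export
write_sam <- function(reads, seq_lengths, path) {
  missing <- setdiff(unique(reads$transcript_id), names(seq_lengths))
  if (length(missing)) {
    stop("alignments reference transcripts absent from header: ",
         paste(missing, collapse = ", "))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seq_lengths),
                     as.integer(seq_lengths)), con)
  if (nrow(reads)) {
    flag <- integer(nrow(reads))
    dup <- duplicated(reads$read_id)
    flag[dup] <- 256L
    seqs <- if ("seq" %in% names(reads)) reads$seq else "*"
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                       reads$read_id, flag, reads$transcript_id,
                       reads$start + 1L, reads$end - reads$start, seqs),
               con)
  }
  invisible(path)
}

#' Read a SAM file of transcript-space alignments
#'
#' Parses the minimal ungapped subset this pipeline emits. Reverse-strand
#' records are discarded with a warning (sense-strand libraries are assumed),
#' as are gapped alignments (CIGAR other than `<len>M`); unmapped records
#' (flag 4) are skipped. Records referencing transcripts absent from the
#' `@SQ` header are an error.
#'
#' @param path SAM path.
#' @return data.frame `read_id`, `transcript_id`, `start`, `end` (0-based
#'   half-open), `seq` (`NA` when the record stores `*`), plus attribute
#'   `seq_lengths`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  sq <- lines[grepl("^@SQ\t", lines)]
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  body <- lines[!hdr]
  empty <- data.frame(read_id = character(), transcript_id = character(),
                      start = integer(), end = integer(), seq = character(),
                      stringsAsFactors = FALSE)
  if (!length(body)) {
    attr(empty, "seq_lengths") <- stats::setNames(ln, sn)
    return(empty)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, "", i)
  flag <- as.integer(get(2L))
  rname <- get(3L)
  cigar <- get(6L)
  keep <- rep(TRUE, length(flag))
  unmapped <- bitwAnd(flag, 4L) > 0L
  keep[unmapped] <- FALSE
  rev <- bitwAnd(flag, 16L) > 0L & !unmapped
  if (any(rev)) {
    warning(sum(rev), " reverse-strand alignment(s) discarded ",
            "(sense-strand library assumed)")
    keep[rev] <- FALSE
  }
  gapped <- !grepl("^[0-9]+M$", cigar) & !unmapped
  if (any(gapped & keep)) {
    warning(sum(gapped & keep),
            " gapped/clipped alignment(s) discarded (ungapped model)")
    keep[gapped] <- FALSE
  }
  bad <- setdiff(unique(rname[keep]), sn)
  if (length(bad)) {
    stop("SAM records reference unknown transcript(s): ",
         paste(bad, collapse = ", "))
  }
  seq <- get(10L)
  seq[seq == "*"] <- NA_character_
  start <- as.integer(get(4L)) - 1L
  width <- rep(NA_integer_, length(cigar))
  width[keep] <- as.integer(sub("M$", "", cigar[keep]))
  out <- data.frame(read_id = get(1L), transcript_id = rname,
                    start = start, end = start + width, seq = seq,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seq_lengths") <- stats::setNames(ln, sn)
  out
}

#' Write intervals as BED6(+)
#'
#' BED is 0-based half-open, matching the internal convention. Any columns
#' beyond the standard six are appended as extra tab-separated fields.
#'
#' @param df data.frame with `chrom`, `start`, `end`; optional `name`,
#'   `score`, `strand` and extra columns.
#' @param path output path.
#' @param extra_cols character vector of extra column names to append.
#' @export
write_bed <- function(df, path, extra_cols = character()) {
  stop_if_missing_cols(df, c("chrom", "start", "end"), "BED table")
  out <- data.frame(
    chrom = df$chrom, start = df$start, end = df$end,
    name = if ("name" %in% names(df)) df$name else ".",
    score = if ("score" %in% names(df)) df$score else 0,
    strand = if ("strand" %in% names(df)) df$strand else "+",
    stringsAsFactors = FALSE
  )
  for (col in extra_cols) out[[col]] <- df[[col]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6(+) file
#' @param path BED path.
#' @param extra_cols names for columns beyond the standard six.
#' @return data.frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` and any extras.
#' @export
read_bed <- function(path, extra_cols = character()) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (length(extra_cols)) {
    names(df)[6L + seq_along(extra_cols)] <- extra_cols
  }
  df
}
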