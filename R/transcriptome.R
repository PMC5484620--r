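#' Generate a synthetic transcriptome with planted binding footprints
#'
#' Builds `spec$n_transcripts` single-isoform transcripts with 5'UTR/CDS/3'UTR
#' structure and gene categories (RP, TR_other, non_TR; counts are
#' `round(n * fraction)`, RP first, remainder non_TR). RP transcripts start
#' with a 5'TOP (a C followed by at least `top_run_len` pyrimidines); RP and
#' TR_other transcripts carry a pyrimidine-enriched (PES) footprint abutting
#' the 5'UTR/CDS junction and one GA-rich 3'UTR footprint; non_TR transcripts
#' carry CDS/3'UTR footprints only. A `multimap_fraction` of non_TR
#' transcripts share an identical CDS cassette so that reads from it are
#' ambiguous. Output is deterministic given the spec (which includes the
#' seed).
#'
#' @param spec a [simulation_spec()].
#' @return An object of class `transcriptome`: a list with `sequences` (named
#'   character vector), `regions` (one row per transcript: `transcript_id`,
#'   `gene_id`, `category`, `utr5_len`, `cds_len`, `utr3_len`, `length`,
#'   `cassette_start`), `truth` (list of `sites` and `abundance` data.frames;
#'   all coordinates 0-based half-open) and the `spec` itself.
#' @export
generate_transcriptome <- function(spec) {
  validate_simulation_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_transcripts
  n_rp <- as.integer(round(n * spec$fraction_rp))
  n_tr <- as.integer(round(n * spec$fraction_tr_other))
  if (n_rp + n_tr > n) stop("category fractions round to more than n_transcripts")
  category <- c(rep("RP", n_rp), rep("TR_other", n_tr),
                rep("non_TR", n - n_rp - n_tr))
  tid <- sprintf("TX%04d", seq_len(n))
  gid <- sprintf("GENE%04d", seq_len(n))

  sample_range <- function(rng, n) {
    if (rng[1] == rng[2]) rep(rng[1], n) else
      sample(rng[1]:rng[2], n, replace = TRUE)
  }
  u5 <- sample_range(spec$utr5_len, n)
  cd <- sample_range(spec$cds_len, n)
  u3 <- sample_range(spec$utr3_len, n)
  len <- u5 + cd + u3

  bg_comp <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  ga_comp <- c(A = 0.35, C = 0.10, G = 0.45, T = 0.10)
  cds_fp_comp <- c(A = 0.35, C = 0.25, G = 0.30, T = 0.10)

  seqs <- vapply(len, random_dna, "", probs = bg_comp)
  names(seqs) <- tid

  # shared multimapping cassette, planted into non_TR CDSs
  n_mm <- as.integer(round(n * spec$multimap_fraction))
  cassette_start <- rep(NA_integer_, n)
  if (n_mm > 0L) {
    carriers <- which(category == "non_TR")
    if (length(carriers) < n_mm) n_mm <- length(carriers)
    carriers <- carriers[seq_len(n_mm)]
    cassette <- random_dna(spec$cassette_len, bg_comp)
    for (i in carriers) {
      cs <- u5[i] + 10L
      substr0(seqs[i], cs, cs + spec$cassette_len) <- cassette
      cassette_start[i] <- cs
    }
  }

  pes_seq <- function(k) {
    is_pyr <- stats::runif(k) < spec$pes_pyrimidine_rate
    base <- ifelse(is_pyr,
                   ifelse(stats::runif(k) < spec$pes_c_bias, "C", "T"),
                   sample(c("A", "G"), k, replace = TRUE))
    paste(base, collapse = "")
  }

  sites <- vector("list", 3L * n)
  ns <- 0L
  fp <- spec$footprint_len
  for (i in seq_len(n)) {
    cat_i <- category[i]
    occ <- spec$occupancy[spec$occupancy$category == cat_i, , drop = FALSE]
    # 5'TOP start on RP transcripts
    if (cat_i == "RP") {
      run <- spec$top_run_len + stats::rpois(1L, 2)
      pyr <- ifelse(stats::runif(run) < 0.6, "C", "T")
      substr0(seqs[i], 0L, run + 1L) <- paste0("C", paste(pyr, collapse = ""))
    }
    for (j in seq_len(nrow(occ))) {
      rg <- occ$region[j]
      if (rg == "UTR5") {
        s <- u5[i] - spec$pes_len
        e <- u5[i]
        substr0(seqs[i], s, e) <- pes_seq(spec$pes_len)
        kind <- "PES"
      } else if (rg == "UTR3") {
        lo <- u5[i] + cd[i]
        hi <- len[i] - fp
        s <- if (hi > lo) sample(lo:hi, 1L) else lo
        e <- s + fp
        substr0(seqs[i], s, e) <- random_dna(fp, ga_comp)
        kind <- "GA"
      } else { # CDS, avoid the cassette
        lo <- u5[i]
        hi <- u5[i] + cd[i] - fp
        repeat {
          s <- if (hi > lo) sample(lo:hi, 1L) else lo
          e <- s + fp
          if (is.na(cassette_start[i]) ||
              interval_overlap(s, e, cassette_start[i],
                               cassette_start[i] + spec$cassette_len) == 0L) {
            break
          }
        }
        substr0(seqs[i], s, e) <- random_dna(fp, cds_fp_comp)
        kind <- "CDS_fp"
      }
      ns <- ns + 1L
      sites[[ns]] <- data.frame(
        transcript_id = tid[i], gene_id = gid[i], category = cat_i,
        region = rg, start = s, end = e, kind = kind,
        occupancy_mTOR_on = occ$mTOR_on[j],
        occupancy_mTOR_off = occ$mTOR_off[j],
        stringsAsFactors = FALSE
      )
    }
  }
  sites <- do.call(rbind, sites[seq_len(ns)])
  sites$site_id <- sprintf("FP%04d", seq_len(nrow(sites)))
  sites$active_mTOR_on <- sites$occupancy_mTOR_on > 0
  sites$active_mTOR_off <- sites$occupancy_mTOR_off > 0

  ab <- stats::rlnorm(n, spec$abundance_mu, spec$abundance_sigma)
  abundance <- data.frame(transcript_id = tid, abundance = ab / sum(ab),
                          stringsAsFactors = FALSE)

  regions <- data.frame(
    transcript_id = tid, gene_id = gid, category = category,
    utr5_len = u5, cds_len = cd, utr3_len = u3, length = len,
    cassette_start = cassette_start, stringsAsFactors = FALSE
  )
  structure(list(sequences = seqs, regions = regions,
                 truth = list(sites = sites, abundance = abundance),
                 spec = spec),
            class = "transcriptome")
}

#' @export
print.transcriptome <- function(x, ...) {
  cat("transcriptome:", length(x$sequences), "transcripts;",
      nrow(x$truth$sites), "planted footprints\n")
  print(table(x$regions$category))
  invisible(x)
}

#' Region boundaries of one transcript
#'
#' @param regions the `regions` data.frame of a transcriptome.
#' @param transcript_id transcript identifier.
#' @return Named integer vector `utr5_end`, `cds_end`, `length` (0-based
#'   half-open region ends).
#' @export
region_bounds <- function(regions, transcript_id) {
  i <- match(transcript_id, regions$transcript_id)
  if (any(is.na(i))) {
    stop("unknown transcript(s): ",
         paste(transcript_id[is.na(i)], collapse = ", "))
  }
  cbind(utr5_end = regions$utr5_len[i],
        cds_end = regions$utr5_len[i] + regions$cds_len[i],
        length = regions$length[i])
}

#' Write transcriptome FASTA
#' @param tx a `transcriptome` (or named character vector of sequences).
#' @param path output FASTA path.
#' @export
write_transcript_fasta <- function(tx, path) {
  seqs <- if (inherits(tx, "transcriptome")) tx$sequences else tx
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read transcript sequences from FASTA
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_transcript_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write region annotation as GFF3
#'
#' Emits transcript-space `five_prime_UTR` / `CDS` / `three_prime_UTR`
#' features (1-based closed coordinates, per the GFF standard).
#'
#' @param regions `regions` data.frame of a transcriptome.
#' @param path output GFF3 path.
#' @export
write_region_gff <- function(regions, path) {
  u5e <- regions$utr5_len
  cde <- regions$utr5_len + regions$cds_len
  gr <- GenomicRanges::GRanges(
    seqnames = rep(regions$transcript_id, 3L),
    ranges = IRanges::IRanges(
      start = c(rep(1L, nrow(regions)), u5e + 1L, cde + 1L),
      end = c(u5e, cde, regions$length)
    ),
    strand = "+",
    type = rep(c("five_prime_UTR", "CDS", "three_prime_UTR"),
               each = nrow(regions)),
    phase = rep(c(NA_integer_, 0L, NA_integer_), each = nrow(regions)),
    gene_id = rep(regions$gene_id, 3L),
    category = rep(regions$category, 3L)
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a transcript-space region annotation GFF3
#' @param path GFF3 path as written by [write_region_gff()].
#' @return A `regions` data.frame (lengths per region, 0-based internally).
#' @export
read_region_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    transcript_id = as.character(GenomicRanges::seqnames(gr)),
    type = gr$type,
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    gene_id = gr$gene_id,
    category = gr$category,
    stringsAsFactors = FALSE
  )
  wide <- split(df, df$transcript_id)
  out <- do.call(rbind, lapply(wide, function(d) {
    get_len <- function(tp) {
      i <- which(d$type == tp)
      if (!length(i)) 0L else sum(d$end[i] - d$start[i])
    }
    data.frame(
      transcript_id = d$transcript_id[1], gene_id = d$gene_id[1],
      category = d$category[1],
      utr5_len = get_len("five_prime_UTR"), cds_len = get_len("CDS"),
      utr3_len = get_len("three_prime_UTR"),
      stringsAsFactors = FALSE
    )
  }))
  out$length <- out$utr5_len + out$cds_len + out$utr3_len
  out <- out[match(unique(df$transcript_id), out$transcript_id), ]
  rownames(out) <- NULL
  out
}

#' Write the region annotation as a TSV
#' @param regions `regions` data.frame.
#' @param path output path.
#' @export
write_region_tsv <- function(regions, path) {
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV region annotation
#' @param path TSV path.
#' @return `regions` data.frame.
#' @export
read_region_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
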