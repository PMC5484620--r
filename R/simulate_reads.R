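#' Simulate a PAR-CLIP library over a synthetic transcriptome
#'
#' Footprint reads are drawn per planted site with Poisson counts at the
#' occupancy the condition allows (RP/TR 5'UTR footprints are silent under
#' `mTOR_on`), positioned so the read spans the footprint. Every reference T
#' inside the footprint that a read covers is converted to C independently
#' with probability `spec$conversion_rate` (crosslink signature). Background
#' reads are placed uniformly along each transcript at
#' `spec$background_read_rate` reads per kb and acquire conversions only
#' through per-base sequencing error; background reads falling entirely
#' inside a shared multimapping cassette are emitted once per carrier
#' transcript. Deterministic given the spec and `seed`.
#'
#' @param tx a `transcriptome` from [generate_transcriptome()].
#' @param condition `"mTOR_on"` or `"mTOR_off"`.
#' @param spec simulation spec (defaults to the one inside `tx`).
#' @param seed integer seed for this library (default derives from the spec
#'   seed and the condition).
#' @return data.frame of alignments: `read_id`, `transcript_id`, `start`,
#'   `end` (0-based half-open), `seq`, `source` (`footprint`/`background`),
#'   `footprint_id`, `n_placements`, `library_id`.
#' @export
simulate_parclip <- function(tx, condition = c("mTOR_on", "mTOR_off"),
                             spec = tx$spec, seed = NULL) {
  condition <- match.arg(condition)
  if (is.null(seed)) {
    seed <- spec$seed + if (condition == "mTOR_on") 101L else 202L
  }
  set.seed(seed)
  rl <- spec$read_len
  lib <- paste0("parclip_", condition)
  occ_col <- paste0("occupancy_", condition)
  sites <- tx$truth$sites
  seq_chars <- lapply(tx$sequences, chars)
  lens <- nchar(tx$sequences)

  out <- list()
  # footprint reads, one block per planted site
  for (k in seq_len(nrow(sites))) {
    occ <- sites[[occ_col]][k]
    if (occ <= 0) next
    n_k <- stats::rpois(1L, occ)
    if (n_k == 0L) next
    tid <- sites$transcript_id[k]
    L <- lens[[tid]]
    fs <- sites$start[k]; fe <- sites$end[k]
    # read spans the footprint when read_len >= footprint length, else sits
    # inside it
    lo <- max(0L, min(fs, fe - rl))
    hi <- min(L - rl, max(fs, fe - rl))
    starts <- if (hi > lo) sample(lo:hi, n_k, replace = TRUE) else
      rep(lo, n_k)
    tch <- seq_chars[[tid]]
    tpos <- fs + which(tch[(fs + 1L):fe] == "T") - 1L # 0-based T positions
    reads <- character(n_k)
    for (r in seq_len(n_k)) {
      s <- starts[r]
      v <- tch[(s + 1L):(s + rl)]
      cov <- tpos[tpos >= s & tpos < s + rl]
      if (length(cov)) {
        hit <- cov[stats::runif(length(cov)) < spec$conversion_rate]
        if (length(hit)) v[hit - s + 1L] <- "C"
      }
      reads[r] <- paste(v, collapse = "")
    }
    out[[length(out) + 1L]] <- data.frame(
      transcript_id = tid, start = starts, end = starts + rl, seq = reads,
      source = "footprint", footprint_id = sites$site_id[k],
      stringsAsFactors = FALSE
    )
  }

  # uniform background reads
  n_bg <- stats::rpois(length(lens), spec$background_read_rate * lens / 1000)
  bg_tid <- rep(names(lens), n_bg)
  if (length(bg_tid)) {
    bg_max <- rep(lens - rl, n_bg)
    bg_start <- as.integer(floor(stats::runif(length(bg_tid)) * (bg_max + 1)))
    bg_seq <- substr0(tx$sequences[bg_tid], bg_start, bg_start + rl)
    out[[length(out) + 1L]] <- data.frame(
      transcript_id = bg_tid, start = bg_start, end = bg_start + rl,
      seq = unname(bg_seq), source = "background",
      footprint_id = NA_character_, stringsAsFactors = FALSE
    )
  }
  reads <- do.call(rbind, out)
  if (is.null(reads)) {
    reads <- data.frame(transcript_id = character(), start = integer(),
                        end = integer(), seq = character(),
                        source = character(), footprint_id = character(),
                        stringsAsFactors = FALSE)
  }
  reads$read_id <- sprintf("%s_r%06d", lib, seq_len(nrow(reads)))

  reads <- apply_seq_errors(reads, spec$seq_error_rate)
  reads <- expand_cassette_placements(reads, tx, spec)
  reads$library_id <- rep(lib, nrow(reads))
  rownames(reads) <- NULL
  reads
}

# per-base sequencing errors: each base replaced by a uniform different base
apply_seq_errors <- function(reads, rate) {
  if (!nrow(reads) || rate <= 0) return(reads)
  rl <- nchar(reads$seq)
  n_err <- stats::rbinom(nrow(reads), rl, rate)
  for (r in which(n_err > 0L)) {
    v <- chars(reads$seq[r])
    pos <- sample.int(rl[r], n_err[r])
    for (p in pos) v[p] <- sample(setdiff(DNA_BASES, v[p]), 1L)
    reads$seq[r] <- paste(v, collapse = "")
  }
  reads
}

# reads lying fully inside the shared cassette are ambiguous: emit one
# placement per carrier transcript at the equivalent offset
expand_cassette_placements <- function(reads, tx, spec) {
  reads$n_placements <- rep(1L, nrow(reads))
  carriers <- tx$regions[!is.na(tx$regions$cassette_start), , drop = FALSE]
  if (!nrow(reads) || nrow(carriers) < 2L) return(reads)
  cs <- stats::setNames(carriers$cassette_start, carriers$transcript_id)
  own <- cs[reads$transcript_id]
  inside <- !is.na(own) & reads$start >= own &
    reads$end <= own + spec$cassette_len
  if (!any(inside)) return(reads)
  amb <- reads[inside, , drop = FALSE]
  extra <- do.call(rbind, lapply(seq_len(nrow(amb)), function(r) {
    off <- amb$start[r] - cs[[amb$transcript_id[r]]]
    others <- carriers$transcript_id[carriers$transcript_id !=
                                       amb$transcript_id[r]]
    data.frame(
      transcript_id = others,
      start = unname(cs[others]) + off,
      end = unname(cs[others]) + off + (amb$end[r] - amb$start[r]),
      seq = amb$seq[r], source = amb$source[r],
      footprint_id = amb$footprint_id[r], read_id = amb$read_id[r],
      n_placements = nrow(carriers), stringsAsFactors = FALSE
    )
  }))
  reads$n_placements[inside] <- nrow(carriers)
  rbind(reads, extra[names(reads)])
}

#' Simulate replicate mRNA-seq libraries
#'
#' Per-transcript read counts are a single multinomial draw with probability
#' proportional to true abundance times effective length; replicates are
#' independent draws from identical abundances. Reads are emitted as
#' perfect-match placements (only perfectly-mapping mRNA-seq reads enter the
#' quantification, so sequence-level errors are irrelevant here); reads fully
#' inside the shared multimapping cassette are emitted once per carrier.
#' Deterministic given spec and seeds.
#'
#' @param tx a `transcriptome`.
#' @param spec simulation spec (defaults to `tx$spec`).
#' @param n_replicates number of libraries (default from spec).
#' @param depth reads per library (default from spec).
#' @param library_prefix prefix for `library_id`.
#' @param seed base seed; replicate `r` uses `seed + r`.
#' @return A list of data.frames (one per replicate) with `read_id`,
#'   `transcript_id`, `start`, `end`, `n_placements`, `library_id`.
#' @export
simulate_mrnaseq <- function(tx, spec = tx$spec,
                             n_replicates = spec$n_replicates,
                             depth = spec$mrnaseq_depth,
                             library_prefix = "mrnaseq",
                             seed = spec$seed + 500L) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (depth < 1L) stop("requested sequencing depth must be >= 1 read")
  rl <- spec$read_len
  lens <- nchar(tx$sequences)
  eff <- pmax(1L, lens - rl + 1L)
  ab <- tx$truth$abundance
  prob <- ab$abundance[match(names(lens), ab$transcript_id)] * eff
  lapply(seq_len(n_replicates), function(rep_i) {
    set.seed(seed + rep_i)
    lib <- sprintf("%s_rep%d", library_prefix, rep_i)
    counts <- as.integer(stats::rmultinom(1L, depth, prob))
    tid <- rep(names(lens), counts)
    maxs <- rep(eff - 1L, counts)
    start <- as.integer(floor(stats::runif(length(tid)) * (maxs + 1L)))
    reads <- data.frame(
      read_id = sprintf("%s_r%07d", lib, seq_along(tid)),
      transcript_id = tid, start = start, end = start + rl,
      stringsAsFactors = FALSE
    )
    reads <- expand_cassette_mrnaseq(reads, tx, spec$cassette_len)
    reads$library_id <- rep(lib, nrow(reads))
    reads
  })
}

expand_cassette_mrnaseq <- function(reads, tx, cassette_len) {
  reads$n_placements <- rep(1L, nrow(reads))
  carriers <- tx$regions[!is.na(tx$regions$cassette_start), , drop = FALSE]
  if (!nrow(reads) || nrow(carriers) < 2L) return(reads)
  cs <- stats::setNames(carriers$cassette_start, carriers$transcript_id)
  own <- cs[reads$transcript_id]
  inside <- !is.na(own) & reads$start >= own & reads$end <= own + cassette_len
  if (!any(inside)) return(reads)
  k <- nrow(carriers)
  amb <- reads[inside, , drop = FALSE]
  off <- amb$start - cs[amb$transcript_id]
  extra <- do.call(rbind, lapply(seq_len(k), function(j) {
    other <- carriers$transcript_id[j]
    keep <- amb$transcript_id != other
    if (!any(keep)) return(NULL)
    data.frame(
      read_id = amb$read_id[keep], transcript_id = other,
      start = unname(cs[[other]] + off[keep]),
      end = unname(cs[[other]] + off[keep] + (amb$end - amb$start)[keep]),
      stringsAsFactors = FALSE
    )
  }))
  reads$n_placements[inside] <- k
  extra$n_placements <- k
  rbind(reads, extra[names(reads)])
}

#' Estimate the crosslink conversion rate from truth-matched reads
#'
#' Matches footprint reads back to their planted site and, per covered
#' reference T inside the footprint, counts how often the read shows a C.
#' Sequencing errors contribute negligibly at default rates.
#'
#' @param reads PAR-CLIP alignments from [simulate_parclip()].
#' @param tx the generating `transcriptome`.
#' @return List with `estimate`, `n_covered_t`, `n_converted`, and the
#'   binomial `se` of the estimate.
#' @export
estimate_conversion_rate <- function(reads, tx) {
  fp <- reads[reads$source == "footprint" & reads$n_placements == 1L, ,
              drop = FALSE]
  sites <- tx$truth$sites
  covered <- 0L; converted <- 0L
  for (r in seq_len(nrow(fp))) {
    k <- match(fp$footprint_id[r], sites$site_id)
    tid <- fp$transcript_id[r]
    s <- fp$start[r]; e <- fp$end[r]
    lo <- max(s, sites$start[k]); hi <- min(e, sites$end[k])
    if (hi <= lo) next
    refv <- chars(substr0(tx$sequences[[tid]], lo, hi))
    readv <- chars(substr(fp$seq[r], lo - s + 1L, hi - s))
    tpos <- refv == "T"
    covered <- covered + sum(tpos)
    converted <- converted + sum(tpos & readv == "C")
  }
  est <- if (covered > 0L) converted / covered else NA_real_
  list(estimate = est, n_covered_t = covered, n_converted = converted,
       se = if (covered > 0L) sqrt(est * (1 - est) / covered) else NA_real_)
}
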