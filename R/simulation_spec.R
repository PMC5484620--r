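#' Default footprint occupancy table
#'
#' Expected reads per planted footprint, by gene category, transcript region
#' and mTOR condition. The defaults encode the qualitative binding pattern the
#' pipeline is meant to recover: ribosomal-protein (RP) and other
#' translation-related (TR_other) transcripts gain 5'UTR binding only when
#' mTOR is inhibited, 3'UTR binding is present under both conditions, and
#' non-translation-related (non_TR) transcripts are bound only in CDS/3'UTR.
#'
#' @return A data.frame with columns `category`, `region`, `mTOR_on`,
#'   `mTOR_off` (expected reads per footprint).
#' @export
default_occupancy <- function() {
  data.frame(
    category = c("RP", "RP", "TR_other", "TR_other", "non_TR", "non_TR"),
    region   = c("UTR5", "UTR3", "UTR5", "UTR3", "CDS", "UTR3"),
    mTOR_on  = c(0, 60, 0, 50, 40, 40),
    mTOR_off = c(60, 50, 40, 45, 40, 40),
    stringsAsFactors = FALSE
  )
}

#' Build a simulation specification
#'
#' Parameterizes the synthetic transcriptome / PAR-CLIP / mRNA-seq generator.
#' All coordinates produced downstream are 0-based half-open in transcript
#' space.
#'
#' @param n_transcripts number of transcripts (one gene per transcript).
#' @param fraction_rp,fraction_tr_other proportions of transcripts assigned to
#'   the RP and other-translation-related categories; counts are
#'   `round(n * fraction)` and must sum to at most `n_transcripts`.
#' @param utr5_len,cds_len,utr3_len integer length ranges `c(min, max)` in nt.
#' @param pes_len length (nt) of the pyrimidine-enriched sequence (PES)
#'   footprint planted at the 3'-most end of RP/TR_other 5'UTRs.
#' @param pes_pyrimidine_rate probability that a PES base is a pyrimidine.
#' @param pes_c_bias probability that a PES pyrimidine is C rather than T;
#'   the C bias keeps the per-read T-to-C conversion load low enough that the
#'   0-2-conversion read filter treats all footprint classes alike.
#' @param top_run_len minimum number of pyrimidines following the initial C of
#'   a planted 5'TOP on RP transcripts.
#' @param footprint_len footprint length (nt) for all planted sites.
#' @param read_len PAR-CLIP / mRNA-seq read length (nt); RNase-trimmed
#'   PAR-CLIP fragments are short, hence the 30-nt default.
#' @param occupancy occupancy table as in [default_occupancy()].
#' @param conversion_rate probability that a crosslink-site T reads as C in a
#'   footprint read.
#' @param background_read_rate background PAR-CLIP reads per kb of transcript.
#' @param seq_error_rate per-base sequencing error probability.
#' @param multimap_fraction proportion of transcripts carrying the duplicated
#'   multimapping cassette.
#' @param cassette_len length (nt) of the duplicated cassette.
#' @param abundance_mu,abundance_sigma log-normal parameters of true
#'   transcript abundances.
#' @param n_replicates number of mRNA-seq replicate libraries per condition.
#' @param mrnaseq_depth reads per mRNA-seq library.
#' @param seed integer seed; all generator outputs are deterministic given the
#'   spec (including this seed).
#' @return An object of class `simulation_spec` (a validated list).
#' @export
simulation_spec <- function(n_transcripts = 300L,
                            fraction_rp = 0.2,
                            fraction_tr_other = 0.2,
                            utr5_len = c(80L, 220L),
                            cds_len = c(300L, 900L),
                            utr3_len = c(150L, 450L),
                            pes_len = 25L,
                            pes_pyrimidine_rate = 0.9,
                            pes_c_bias = 0.85,
                            top_run_len = 5L,
                            footprint_len = 25L,
                            read_len = 30L,
                            occupancy = default_occupancy(),
                            conversion_rate = 0.3,
                            background_read_rate = 0.5,
                            seq_error_rate = 0.001,
                            multimap_fraction = 0.05,
                            cassette_len = 60L,
                            abundance_mu = 1,
                            abundance_sigma = 1,
                            n_replicates = 2L,
                            mrnaseq_depth = 5e5,
                            seed = 1L) {
  spec <- list(
    n_transcripts = as.integer(n_transcripts),
    fraction_rp = fraction_rp,
    fraction_tr_other = fraction_tr_other,
    utr5_len = as.integer(utr5_len),
    cds_len = as.integer(cds_len),
    utr3_len = as.integer(utr3_len),
    pes_len = as.integer(pes_len),
    pes_pyrimidine_rate = pes_pyrimidine_rate,
    pes_c_bias = pes_c_bias,
    top_run_len = as.integer(top_run_len),
    footprint_len = as.integer(footprint_len),
    read_len = as.integer(read_len),
    occupancy = occupancy,
    conversion_rate = conversion_rate,
    background_read_rate = background_read_rate,
    seq_error_rate = seq_error_rate,
    multimap_fraction = multimap_fraction,
    cassette_len = as.integer(cassette_len),
    abundance_mu = abundance_mu,
    abundance_sigma = abundance_sigma,
    n_replicates = as.integer(n_replicates),
    mrnaseq_depth = as.integer(mrnaseq_depth),
    seed = as.integer(seed)
  )
  class(spec) <- "simulation_spec"
  validate_simulation_spec(spec)
  spec
}

#' Validate a simulation specification
#'
#' Checks probability bounds, category fractions, length ranges and that each
#' declared region can hold the footprints requested for it.
#'
#' @param spec a `simulation_spec`.
#' @return The spec, invisibly, if valid; otherwise an error.
#' @export
validate_simulation_spec <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  probs <- c(
    pes_pyrimidine_rate = spec$pes_pyrimidine_rate,
    pes_c_bias = spec$pes_c_bias,
    conversion_rate = spec$conversion_rate,
    seq_error_rate = spec$seq_error_rate,
    multimap_fraction = spec$multimap_fraction,
    fraction_rp = spec$fraction_rp,
    fraction_tr_other = spec$fraction_tr_other
  )
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad)) {
    stop("probabilities outside [0,1]: ", paste(bad, collapse = ", "))
  }
  if (spec$fraction_rp + spec$fraction_tr_other > 1) {
    stop("fraction_rp + fraction_tr_other must be <= 1")
  }
  for (nm in c("utr5_len", "cds_len", "utr3_len")) {
    rng <- spec[[nm]]
    if (length(rng) != 2L || any(rng <= 0L) || rng[1] > rng[2]) {
      stop(nm, " must be a positive range c(min, max)")
    }
  }
  if (spec$n_transcripts < 1L) stop("n_transcripts must be >= 1")
  if (any(spec$occupancy$mTOR_on < 0) || any(spec$occupancy$mTOR_off < 0)) {
    stop("occupancy values must be >= 0")
  }
  if (!all(spec$occupancy$region %in% c("UTR5", "CDS", "UTR3"))) {
    stop("occupancy regions must be UTR5/CDS/UTR3")
  }
  # every region asked to hold a footprint must be long enough for it
  min_len <- c(UTR5 = spec$utr5_len[1], CDS = spec$cds_len[1],
               UTR3 = spec$utr3_len[1])
  need <- unique(spec$occupancy$region)
  for (rg in need) {
    fp <- if (rg == "UTR5") max(spec$pes_len, spec$footprint_len) else
      spec$footprint_len
    if (min_len[[rg]] < fp) {
      stop("region ", rg, " length range too short to hold a ", fp,
           "-nt footprint (min length ", min_len[[rg]], ")")
    }
  }
  if (spec$cds_len[1] < spec$cassette_len && spec$multimap_fraction > 0) {
    stop("region CDS length range too short to hold the multimapping cassette")
  }
  invisible(spec)
}

condition_levels <- function() c("mTOR_on", "mTOR_off")

occupancy_lookup <- function(occupancy, category, region, condition) {
  col <- match.arg(condition, condition_levels())
  i <- which(occupancy$category == category & occupancy$region == region)
  if (!length(i)) return(0)
  occupancy[[col]][i[1]]
}
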