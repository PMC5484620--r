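# Call binding sites per condition: filter reads to 0-2 T-to-C conversions,
# cluster by single-nucleotide overlap, Gaussian-smooth, keep clusters with
# a conversion read passing the RPM threshold, score by RPM and
# expression-normalized RPM, and benchmark against the planted truth.

source("analysis/00_config.R")

tx <- analysis_transcriptome()
truth <- tx$truth$sites

overlap_frac <- function(a, b) {
  hit <- vapply(seq_len(nrow(a)), function(i) {
    any(b$transcript_id == a$transcript_id[i] &
          b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
  mean(hit)
}

for (cond in c("mTOR_on", "mTOR_off")) {
  sites <- analysis_sites(tx, cond)
  write_sites(sites,
              bed_path = file.path(RESULTS_DIR,
                                   paste0("sites_", cond, ".bed")),
              tsv_path = file.path(RESULTS_DIR,
                                   paste0("sites_", cond, ".tsv")))
  active <- truth[truth[[paste0("active_", cond)]], ]
  message(sprintf(
    "%s: %d sites (%s); sensitivity %.1f%%, precision %.1f%% vs %d active footprints",
    cond, nrow(sites),
    paste(names(table(sites$region)), table(sites$region),
          sep = "=", collapse = ", "),
    100 * overlap_frac(active, sites), 100 * overlap_frac(sites, active),
    nrow(active)))
}
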