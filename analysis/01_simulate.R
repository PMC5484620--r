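# Generate the synthetic study: a 300-transcript transcriptome with planted
# LARP1-style footprints, PAR-CLIP libraries for both mTOR conditions, and
# the ground-truth tables everything downstream is evaluated against.

source("analysis/00_config.R")

tx <- analysis_transcriptome()
print(tx)

write_transcript_fasta(tx, file.path(RESULTS_DIR, "transcripts.fa"))
write_region_gff(tx$regions, file.path(RESULTS_DIR, "regions.gff3"))
write_result(tx$regions, "regions.tsv")
write_result(tx$truth$sites, "truth_sites.tsv")
write_result(tx$truth$abundance, "abundance.tsv")

lens <- setNames(tx$regions$length, tx$regions$transcript_id)
for (cond in c("mTOR_on", "mTOR_off")) {
  reads <- simulate_parclip(tx, cond)
  write_sam(reads, lens, file.path(RESULTS_DIR,
                                   paste0("parclip_", cond, ".sam")))
  est <- estimate_conversion_rate(reads, tx)
  message(sprintf(
    "%s: %d read placements; conversion rate %.4f over %d covered Ts (planted %.2f)",
    cond, nrow(reads), est$estimate, est$n_covered_t,
    tx$spec$conversion_rate))
}
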