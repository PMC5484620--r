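# Sequence composition of bound regions: pyrimidine content of 5'UTR sites
# vs the rest of the same 5'UTRs (Welch), G content of 3'UTR sites vs the
# rest of the 3'UTR, pyrimidine-run motif summary on +/-15 nt-extended
# sites, 5'TOP classification and overlap, and the positional pyrimidine
# profile of 5'UTR ends.

source("analysis/00_config.R")

tx <- analysis_transcriptome()
rows <- list()
note <- function(metric, value) {
  rows[[length(rows) + 1L]] <<- data.frame(metric = metric, value = value)
  message(sprintf("  %-46s %.6g", metric, value))
}

for (cond in c("mTOR_on", "mTOR_off")) {
  message(cond, ":")
  sites <- analysis_sites(tx, cond)
  if (sum(sites$region == "UTR5") >= 2) {
    t5 <- bound_vs_unbound_composition(sites, tx, "UTR5")
    note(paste0(cond, ".utr5_pyrimidine_welch_p"), t5$p)
    note(paste0(cond, ".utr5_bound_mean"), mean(t5$bound))
    note(paste0(cond, ".utr5_unbound_mean"), mean(t5$unbound))
  }
  t3 <- bound_vs_unbound_composition(sites, tx, "UTR3")
  note(paste0(cond, ".utr3_g_welch_p"), t3$p)
  u5 <- sites[sites$region == "UTR5", ]
  if (nrow(u5)) {
    runs <- summarize_runs(site_sequences(u5, tx, extend = 15))
    note(paste0(cond, ".utr5_run6_fraction"), runs$fraction)
    ov <- top_overlap(sites, classify_top(tx, min_run = 4))
    note(paste0(cond, ".utr5_top_overlap_fraction"), ov$fraction)
  }
}

# positional profile: PES-bearing TR_other vs non_TR (no 5'TOP confound)
rg <- tx$regions
prof <- positional_pyrimidine_profile(
  tx, rg$transcript_id[rg$category == "TR_other"],
  rg$transcript_id[rg$category == "non_TR"], window = 25)
message("positional profile (TR_other vs non_TR):")
note("positional.first_window_welch_p", prof$test_first$p)
note("positional.last_window_welch_p", prof$test_last$p)

write_result(do.call(rbind, rows), "sequence_stats.tsv")
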