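# Where does binding sit on a transcript? Sum expression-normalized binding
# per region and gene category, and build normalized-length metagene
# profiles per category and condition. The headline pattern: RP and TR 5'UTR
# binding appears only under mTOR inhibition; non-TR 5'UTR binding stays ~0.

source("analysis/00_config.R")

tx <- analysis_transcriptome()
all_sites <- rbind(analysis_sites(tx, "mTOR_on"),
                   analysis_sites(tx, "mTOR_off"))

tab <- region_coverage_table(all_sites, tx$regions)
write_result(tab, "region_coverage.tsv")
for (cat in c("RP", "TR_other", "non_TR")) {
  for (cond in c("mTOR_on", "mTOR_off")) {
    pct <- tab$pct[tab$category == cat & tab$condition == cond &
                     tab$region == "UTR5"]
    message(sprintf("%-8s %-9s 5'UTR share: %5.1f%%", cat, cond,
                    if (length(pct)) pct else 0))
  }
}

for (cond in c("mTOR_on", "mTOR_off")) {
  sites <- all_sites[all_sites$condition == cond, ]
  for (cat in c("RP", "TR_other", "non_TR")) {
    prof <- metagene_profile(sites, tx$regions, cat)
    write_metagene_tsv(prof, file.path(
      RESULTS_DIR, paste0("metagene_", cat, "_", cond, ".tsv")))
  }
}
message("metagene junction marks (RP): ",
        paste(signif(unlist(metagene_profile(
          all_sites, tx$regions, "RP")[c("boundary_utr5_cds",
                                         "boundary_cds_utr3")]), 3),
          collapse = ", "))
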