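# Quantify transcript abundance from replicate mRNA-seq libraries (RPKM per
# replicate, replicate-averaged) and report replicate concordance; the
# expressed genes form the background universe for the enrichment analysis.

source("analysis/00_config.R")

tx <- analysis_transcriptome()
for (cond in c("mTOR_on", "mTOR_off")) {
  et <- analysis_expression(tx, cond)
  write_result(et, paste0("expression_", cond, ".tsv"))
  cc <- replicate_concordance(et$rpkm_rep1, et$rpkm_rep2)
  message(sprintf(
    "%s: %d/%d transcripts expressed; replicate RPKM r = %.5f (R^2 = %.5f)",
    cond, sum(et$expressed), nrow(et), cc$r, cc$r_squared))
}
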