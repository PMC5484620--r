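# Shared configuration for the numbered analysis scripts.
#
# Every script regenerates its inputs deterministically from this spec (the
# generator is seeded), so the scripts can be run independently or in order;
# tables land under results/.

library(larpclip)

ANALYSIS_SEED <- 7L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

analysis_spec <- function() {
  simulation_spec(n_transcripts = 300L, fraction_rp = 0.2,
                  fraction_tr_other = 0.2, seed = ANALYSIS_SEED)
}

analysis_transcriptome <- function() generate_transcriptome(analysis_spec())

# PAR-CLIP library for one condition: simulate, recover mismatches from the
# sequences, and weight multimappers
analysis_parclip_reads <- function(tx, condition) {
  reads <- simulate_parclip(tx, condition)
  reads <- annotate_mismatches(reads, tx$sequences)
  distribute_multimappers(reads)
}

analysis_expression <- function(tx, condition) {
  spec <- tx$spec
  reps <- simulate_mrnaseq(
    tx, spec, library_prefix = paste0("mrnaseq_", condition),
    seed = spec$seed + 500L + 10L * match(condition,
                                          c("mTOR_on", "mTOR_off")))
  expression_table(reps, tx$regions)
}

analysis_sites <- function(tx, condition,
                           expr = analysis_expression(tx, condition)) {
  call_sites(analysis_parclip_reads(tx, condition), tx, expression = expr,
             condition = condition)
}

write_result <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
  invisible(path)
}
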