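# GO term enrichment of 5'UTR-bound genes (Fisher exact, Bonferroni,
# p_adj < 0.001) with translation super-category grouping, and the
# cross-tabulation of binding against translation-efficiency change classes.

source("analysis/00_config.R")

tx <- analysis_transcriptome()
expr <- analysis_expression(tx, "mTOR_off")
sites <- analysis_sites(tx, "mTOR_off", expr)
ann <- simulate_go_annotation(tx)

background <- expr$gene_id[expr$expressed]
u5_genes <- tx$regions$gene_id[match(
  unique(sites$transcript_id[sites$region == "UTR5"]),
  tx$regions$transcript_id)]
study <- intersect(u5_genes, background)

enr <- group_supercategories(fisher_enrichment(study, background, ann))
write_result(enr, "enrichment_mTOR_off.tsv")
message(sprintf("%d/%d background genes in study; %d significant terms",
                length(study), length(background), sum(enr$significant)))
message("top term: ", enr$term_name[1], " (", enr$super_category[1],
        "), p_adj = ", signif(enr$p_adj[1], 3))

tr_genes <- translation_related_genes(ann)
message(sprintf("%d/%d bound genes are translation-related",
                sum(study %in% tr_genes), length(study)))

# TE cross-tab: 5'UTR-bound genes (the mTOR-sensitive binding mode) vs
# simulated TE fold changes; TE-decreased genes should be bound far more
# often than unchanged/increased ones
te <- simulate_te_table(tx)
tab <- te_cross_tab(te, study)
write_result(tab, "te_crosstab.tsv")
print(tab)
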