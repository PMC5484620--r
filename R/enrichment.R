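#' Fisher-exact GO term enrichment with Bonferroni correction
#'
#' One-sided (enrichment) Fisher exact p per annotated term from the 2x2
#' table (study hit / study miss / background hit / background miss),
#' computed as the hypergeometric upper tail; Bonferroni correction over the
#' number of terms tested; `significant` flags `p_adj < alpha` (0.001 by
#' default). The background set is expected to be the expressed-gene
#' universe.
#'
#' @param study character vector of study gene ids (must be a subset of the
#'   background).
#' @param background character vector of background gene ids.
#' @param annotation data.frame `gene_id`, `term_id` (optional `term_name`).
#' @param parents optional data.frame `term_id`, `parent_id`; when given,
#'   gene-term annotations are propagated transitively to ancestor terms
#'   before testing (else flat annotation is used).
#' @param alpha significance cutoff on the adjusted p (default 0.001).
#' @return data.frame sorted by `p_adj`: `term_id`, `term_name`,
#'   `study_hits`, `study_size`, `background_hits`, `background_size`, `p`,
#'   `p_adj`, `significant`.
#' @export
fisher_enrichment <- function(study, background, annotation, parents = NULL,
                              alpha = 0.001) {
  study <- unique(study); background <- unique(background)
  extra <- setdiff(study, background)
  if (length(extra)) {
    stop("study gene(s) absent from background: ",
         paste(extra, collapse = ", "))
  }
  if (!nrow(annotation)) stop("annotation is empty")
  stop_if_missing_cols(annotation, c("gene_id", "term_id"), "annotation")
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  if (!is.null(parents)) ann <- propagate_annotation(ann, parents)
  ann <- unique(ann[c("gene_id", "term_id")])
  terms <- unique(ann$term_id)
  N <- length(background)
  n <- length(study)
  in_study <- ann$gene_id %in% study
  K <- tapply(ann$gene_id, ann$term_id, function(g) length(unique(g)))
  k <- tapply(in_study, ann$term_id, sum)
  K <- as.integer(K[terms]); k <- as.integer(k[terms])
  k[is.na(k)] <- 0L
  # hypergeometric upper tail: P(X >= k)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  p_adj <- pmin(1, p * length(terms))
  nm <- if ("term_name" %in% names(annotation)) {
    stats::setNames(annotation$term_name, annotation$term_id)[terms]
  } else terms
  out <- data.frame(term_id = terms, term_name = unname(nm),
                    study_hits = k, study_size = n, background_hits = K,
                    background_size = N, p = p, p_adj = p_adj,
                    significant = p_adj < alpha, stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$p, out$term_id), ]
  rownames(out) <- NULL
  out
}

# transitive propagation of gene-term annotation up parent links
propagate_annotation <- function(ann, parents) {
  stop_if_missing_cols(parents, c("term_id", "parent_id"), "parent table")
  repeat {
    joined <- merge(ann, parents, by = "term_id")
    if (!nrow(joined)) break
    new <- unique(data.frame(gene_id = joined$gene_id,
                             term_id = joined$parent_id,
                             stringsAsFactors = FALSE))
    before <- nrow(unique(ann[c("gene_id", "term_id")]))
    ann <- unique(rbind(ann[c("gene_id", "term_id")], new))
    if (nrow(ann) == before) break
  }
  ann
}

#' Group enrichment results into super-categories
#'
#' Attaches a `super_category` label from a term-to-category mapping;
#' unmapped terms are labeled `"other"`.
#'
#' @param results output of [fisher_enrichment()].
#' @param mapping data.frame `term_id`, `super_category`, or a path to a
#'   two-column TSV (header required). The packaged default mapping
#'   (translation super-category terms) is at
#'   `system.file("extdata", "translation_supercategory.tsv",
#'   package = "larpclip")`.
#' @return `results` with a `super_category` column.
#' @export
group_supercategories <- function(results, mapping = default_supercategory()) {
  if (is.character(mapping)) mapping <- read_supercategory(mapping)
  stop_if_missing_cols(mapping, c("term_id", "super_category"),
                       "super-category mapping")
  m <- stats::setNames(mapping$super_category, mapping$term_id)
  sc <- unname(m[results$term_id])
  sc[is.na(sc)] <- "other"
  results$super_category <- sc
  results
}

#' Read a term-to-super-category mapping TSV
#' @param path two-column TSV with header `term_id`, `super_category`.
#' @return The mapping data.frame.
#' @export
read_supercategory <- function(path) {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, quote = ""),
    error = function(e) stop("malformed mapping file ", path, ": ",
                             conditionMessage(e))
  )
  if (!all(c("term_id", "super_category") %in% names(df))) {
    stop("malformed mapping file ", path,
         ": needs columns term_id, super_category (line 1)")
  }
  bad <- which(!nzchar(df$term_id) | !nzchar(df$super_category))
  if (length(bad)) {
    stop("malformed mapping file ", path, ": empty field at line ",
         bad[1] + 1L)
  }
  df
}

default_supercategory <- function() {
  read_supercategory(system.file("extdata", "translation_supercategory.tsv",
                                 package = "larpclip"))
}

#' Translation-related genes under a super-category mapping
#'
#' A gene is translation-related iff it is annotated to at least one term in
#' the translation super-category.
#'
#' @param annotation gene-term annotation data.frame.
#' @param mapping term-to-super-category mapping (default packaged).
#' @return Character vector of gene ids.
#' @export
translation_related_genes <- function(annotation,
                                      mapping = default_supercategory()) {
  if (is.character(mapping)) mapping <- read_supercategory(mapping)
  terms <- mapping$term_id[mapping$super_category == "translation"]
  unique(annotation$gene_id[annotation$term_id %in% terms])
}

#' Cross-tabulate translation-efficiency change classes by binding
#'
#' Genes are classed by TE fold change: `down` below 1/1.5, `up` above 1.5,
#' otherwise `unchanged`; for each class the table reports the total genes,
#' the number bound, and the bound fraction.
#'
#' @param te_table data.frame `gene_id`, `fold_change` (positive).
#' @param bound_genes character vector of bound gene ids.
#' @return data.frame `te_class`, `n_genes`, `n_bound`, `bound_fraction`.
#' @export
te_cross_tab <- function(te_table, bound_genes) {
  stop_if_missing_cols(te_table, c("gene_id", "fold_change"), "TE table")
  if (any(te_table$fold_change <= 0)) {
    stop("fold changes must be positive")
  }
  cls <- ifelse(te_table$fold_change < 1 / 1.5, "down",
                ifelse(te_table$fold_change > 1.5, "up", "unchanged"))
  cls <- factor(cls, levels = c("down", "unchanged", "up"))
  bound <- te_table$gene_id %in% bound_genes
  out <- data.frame(
    te_class = levels(cls),
    n_genes = as.integer(table(cls)),
    n_bound = as.integer(tapply(bound, cls, sum, default = 0L)),
    stringsAsFactors = FALSE
  )
  out$n_bound[is.na(out$n_bound)] <- 0L
  out$bound_fraction <- ifelse(out$n_genes > 0, out$n_bound / out$n_genes,
                               NA_real_)
  out
}

#' Simulate a gene-to-GO annotation for a synthetic transcriptome
#'
#' RP genes get ribosome/translation terms, TR_other genes translation
#' terms, and all genes draw from a pool of non-translation terms, so that a
#' bound set enriched for RP/TR genes yields translation-term enrichment
#' with known ground truth.
#'
#' @param tx a `transcriptome`.
#' @param n_other_terms size of the non-translation term pool.
#' @param terms_per_gene mean number of background terms per gene.
#' @param seed integer seed.
#' @return data.frame `gene_id`, `term_id`, `term_name`.
#' @export
simulate_go_annotation <- function(tx, n_other_terms = 30L,
                                   terms_per_gene = 3,
                                   seed = tx$spec$seed + 900L) {
  set.seed(seed)
  rg <- tx$regions
  translation_terms <- c(
    "GO:0006412" = "translation",
    "GO:0006413" = "translational initiation",
    "GO:0006414" = "translational elongation",
    "GO:0002181" = "cytoplasmic translation"
  )
  rp_terms <- c("GO:0003735" = "structural constituent of ribosome",
                "GO:0022626" = "cytosolic ribosome")
  other_terms <- stats::setNames(
    sprintf("biological process %02d", seq_len(n_other_terms)),
    sprintf("GO:9%06d", seq_len(n_other_terms))
  )
  rows <- list()
  add <- function(genes, ids) {
    if (!length(genes) || !length(ids)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = rep(genes, each = length(ids)),
      term_id = rep(ids, length(genes)), stringsAsFactors = FALSE)
  }
  rp <- rg$gene_id[rg$category == "RP"]
  tr <- rg$gene_id[rg$category == "TR_other"]
  add(rp, names(translation_terms))
  add(rp, names(rp_terms))
  add(tr, names(translation_terms)[1:2])
  for (g in rg$gene_id) {
    k <- stats::rpois(1L, terms_per_gene)
    if (k > 0L) {
      add(g, sample(names(other_terms), min(k, n_other_terms)))
    }
  }
  ann <- do.call(rbind, rows)
  all_names <- c(translation_terms, rp_terms, other_terms)
  ann$term_name <- unname(all_names[ann$term_id])
  unique(ann)
}

#' Simulate a translation-efficiency fold-change table
#'
#' TE fold changes upon mTOR inhibition: genes in the given
#' `sensitive_genes` set (typically RP/TR genes) draw log2 fold changes
#' centred below zero (TE decreases), others around zero.
#'
#' @param tx a `transcriptome`.
#' @param sensitive_genes gene ids whose TE decreases (default: RP genes).
#' @param seed integer seed.
#' @return data.frame `gene_id`, `fold_change`.
#' @export
simulate_te_table <- function(tx,
                              sensitive_genes =
                                tx$regions$gene_id[tx$regions$category ==
                                                     "RP"],
                              seed = tx$spec$seed + 901L) {
  set.seed(seed)
  g <- tx$regions$gene_id
  lfc <- stats::rnorm(length(g), 0, 0.35)
  hit <- g %in% sensitive_genes
  lfc[hit] <- stats::rnorm(sum(hit), -1.2, 0.4)
  data.frame(gene_id = g, fold_change = 2^lfc, stringsAsFactors = FALSE)
}
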