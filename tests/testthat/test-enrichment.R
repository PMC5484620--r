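make_universe <- function(n_bg = 100, n_terms = 8, seed = 1) {
  set.seed(seed)
  bg <- sprintf("g%03d", seq_len(n_bg))
  ann <- do.call(rbind, lapply(seq_len(n_terms), function(t) {
    data.frame(gene_id = sample(bg, sample(5:40, 1)),
               term_id = sprintf("T%02d", t), stringsAsFactors = FALSE)
  }))
  list(bg = bg, ann = ann)
}

test_that("Fisher enrichment p matches the hypergeometric tail", {
  # study 50 genes with 10 hits; background 1000 with 50 hits
  bg <- sprintf("g%04d", 1:1000)
  hit_genes <- bg[1:50]
  study <- c(bg[1:10], bg[51:90]) # 10 hits among 50 study genes
  ann <- data.frame(gene_id = hit_genes, term_id = "T1",
                    stringsAsFactors = FALSE)
  res <- fisher_enrichment(study, bg, ann)
  expect_equal(res$p, oracle_hyper_tail(10, 50, 1000, 50), tolerance = 1e-12)
  expect_equal(res$p,
               fisher.test(matrix(c(10, 40, 40, 910), 2),
                           alternative = "greater")$p.value,
               tolerance = 1e-9)
})

test_that("degenerate enrichment tables give p = 1", {
  bg <- sprintf("g%02d", 1:40)
  ann <- data.frame(gene_id = bg, term_id = "ALL",
                    stringsAsFactors = FALSE)
  res <- fisher_enrichment(bg[1:10], bg, ann)
  expect_equal(res$p, 1.0) # term annotates every background gene
  # study = background
  ann2 <- rbind(ann, data.frame(gene_id = bg[1:7], term_id = "SOME"))
  res2 <- fisher_enrichment(bg, bg, ann2)
  expect_true(all(res2$p == 1.0))
})

test_that("study genes outside the background are an error naming them", {
  u <- make_universe()
  expect_error(fisher_enrichment(c("gX", u$bg[1]), u$bg, u$ann), "gX")
})

test_that("Bonferroni adjustment is min(1, p * terms) and monotone", {
  u <- make_universe(n_bg = 80, n_terms = 6, seed = 2)
  study <- sample(u$bg, 20)
  res <- fisher_enrichment(study, u$bg, u$ann)
  expect_equal(res$p_adj, pmin(1, res$p * nrow(res)))
  expect_equal(sort(res$p_adj),
               sort(unname(pmin(1, p.adjust(res$p, "bonferroni") *
                                  (nrow(res) / nrow(res))))))
  # adding a tested term never decreases any adjusted p
  extra <- rbind(u$ann, data.frame(gene_id = sample(u$bg, 10),
                                   term_id = "T99"))
  res2 <- fisher_enrichment(study, u$bg, extra)
  common <- intersect(res$term_id, res2$term_id)
  expect_true(all(res2$p_adj[match(common, res2$term_id)] >=
                    res$p_adj[match(common, res$term_id)] - 1e-12))
})

test_that("annotation propagates through parent links when provided", {
  ann <- data.frame(gene_id = c("g1", "g2"), term_id = c("child", "child"))
  parents <- data.frame(term_id = c("child", "mid"),
                        parent_id = c("mid", "root"))
  res <- fisher_enrichment("g1", c("g1", "g2", "g3"), ann,
                           parents = parents)
  expect_setequal(res$term_id, c("child", "mid", "root"))
  expect_true(all(res$background_hits == 2))
})

test_that("null draws rarely reach the 0.001 Bonferroni bar", {
  set.seed(55)
  u <- make_universe(n_bg = 200, n_terms = 15, seed = 3)
  n_sig <- replicate(200, {
    study <- sample(u$bg, 30)
    sum(fisher_enrichment(study, u$bg, u$ann)$significant)
  })
  expect_lte(mean(n_sig), 0.02) # expectation bound, generous
})

test_that("super-category grouping labels mapped terms and defaults to other", {
  res <- data.frame(term_id = c("GO:0006412", "GO:9999999"),
                    p_adj = c(1e-5, 1e-4), stringsAsFactors = FALSE)
  out <- group_supercategories(res)
  expect_identical(out$super_category, c("translation", "other"))
  # malformed mapping errors with a line number
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("term_id\tsuper_category", "GO:1\ttranslation", "GO:2\t"), bad)
  expect_error(group_supercategories(res, bad), "line")
})

test_that("bound RP genes rank translation first in the synthetic universe", {
  spec <- tiny_spec()
  tx <- generate_transcriptome(spec)
  ann <- simulate_go_annotation(tx)
  bg <- tx$regions$gene_id
  study <- tx$regions$gene_id[tx$regions$category %in% c("RP", "TR_other")]
  res <- group_supercategories(fisher_enrichment(study, bg, ann))
  expect_identical(res$super_category[1], "translation")
  expect_true(res$significant[1])
  tr <- translation_related_genes(ann)
  expect_true(all(study %in% tr))
})

test_that("TE cross-tabulation classes by the 1.5-fold rule", {
  te <- data.frame(gene_id = c("a", "b", "c", "d"),
                   fold_change = c(0.5, 1.0, 1.6, 0.6),
                   stringsAsFactors = FALSE)
  tab <- te_cross_tab(te, bound_genes = c("a", "c"))
  expect_equal(tab$n_genes, c(2L, 1L, 1L)) # 0.5 and 0.6 fall below 1/1.5
  expect_equal(tab$n_bound, c(1L, 0L, 1L))
  expect_equal(tab$bound_fraction, c(0.5, 0, 1))
  expect_error(te_cross_tab(data.frame(gene_id = "x", fold_change = -1),
                            "x"), "positive")
})
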