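#' Assemble a pipeline run configuration
#'
#' Simulation-driven configuration: the synthetic generator defines the
#' inputs and every downstream stage runs from its outputs. Externally
#' supplied inputs (FASTA + GFF + SAM) can replace the simulation stage via
#' the `*_path` arguments.
#'
#' @param outdir output directory (created if missing).
#' @param spec a [simulation_spec()]; its seed drives every stage.
#' @param params a [caller_params()].
#' @param conditions conditions to run (`"mTOR_on"`, `"mTOR_off"` or both).
#' @param stats_window window (nt) for the positional pyrimidine profile.
#' @param top_min_run 5'TOP minimum pyrimidine run (see [classify_top()]).
#' @param transcriptome_fasta,regions_gff,parclip_sam_paths,mrnaseq_sam_paths
#'   optional external inputs; `parclip_sam_paths` is a named list
#'   (condition -> SAM path) and `mrnaseq_sam_paths` a named list
#'   (condition -> character vector of replicate SAM paths). All referenced
#'   paths must exist.
#' @param write_mrnaseq_sam also write mRNA-seq SAM files (off by default;
#'   they are large and the expression tables are the pipeline currency).
#' @return A validated `run_config` list.
#' @export
run_config <- function(outdir,
                       spec = simulation_spec(),
                       params = caller_params(),
                       conditions = c("mTOR_on", "mTOR_off"),
                       stats_window = 25L,
                       top_min_run = 4L,
                       transcriptome_fasta = NULL,
                       regions_gff = NULL,
                       parclip_sam_paths = NULL,
                       mrnaseq_sam_paths = NULL,
                       write_mrnaseq_sam = FALSE) {
  conditions <- match.arg(conditions, condition_levels(), several.ok = TRUE)
  cfg <- list(outdir = outdir, spec = spec, params = params,
              conditions = conditions, stats_window = as.integer(stats_window),
              top_min_run = as.integer(top_min_run),
              transcriptome_fasta = transcriptome_fasta,
              regions_gff = regions_gff,
              parclip_sam_paths = parclip_sam_paths,
              mrnaseq_sam_paths = mrnaseq_sam_paths,
              write_mrnaseq_sam = isTRUE(write_mrnaseq_sam))
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration (before any compute)
#' @param cfg a `run_config`.
#' @return The config, invisibly, or an error naming the problem.
#' @export
validate_run_config <- function(cfg) {
  validate_simulation_spec(cfg$spec)
  external <- !is.null(cfg$transcriptome_fasta)
  if (external && is.null(cfg$regions_gff)) {
    stop("config validation: external transcriptome given but annotation ",
         "path (regions_gff) is missing")
  }
  for (p in c(cfg$transcriptome_fasta, cfg$regions_gff,
              unlist(cfg$parclip_sam_paths),
              unlist(cfg$mrnaseq_sam_paths))) {
    if (!file.exists(p)) stop("config validation: path does not exist: ", p)
  }
  invisible(cfg)
}

run_stage <- function(name, log, expr) {
  log(paste0("stage ", name, ": start"))
  res <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e),
         " (partial outputs preserved)", call. = FALSE)
  })
  log(paste0("stage ", name, ": done"))
  res
}

#' Run the full pipeline
#'
#' Stage order: simulate (or load) -> parse alignments -> quantify
#' expression -> call sites -> annotate regions/metagene -> sequence
#' statistics -> enrichment -> manifest. Every output is a plain-text table
#' under `cfg$outdir`; the manifest lists each file with an md5 checksum and
#' the driving seed, so a re-run with the same config reproduces
#' byte-identical outputs.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress progress logging.
#' @return Invisibly, a list with the in-memory objects (`tx`, per-condition
#'   `reads`, `expression`, `sites`, `coverage`, `enrichment`, `manifest`).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  validate_run_config(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$outdir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  log <- function(msg) {
    writeLines(msg, log_con)
    if (!quiet) message(msg)
  }
  spec <- cfg$spec
  log(paste0("seed: ", spec$seed))
  outf <- function(...) file.path(cfg$outdir, paste0(...))

  tx <- run_stage("simulate", log, {
    if (is.null(cfg$transcriptome_fasta)) {
      tx <- generate_transcriptome(spec)
      write_transcript_fasta(tx, outf("transcripts.fa"))
      write_region_gff(tx$regions, outf("regions.gff3"))
      write_region_tsv(tx$regions, outf("regions.tsv"))
      ts <- tx$truth$sites
      write_bed(data.frame(chrom = ts$transcript_id, start = ts$start,
                           end = ts$end, name = ts$site_id, score = 0,
                           strand = "+", region = ts$region,
                           category = ts$category, kind = ts$kind,
                           stringsAsFactors = FALSE),
                outf("truth_sites.bed"),
                extra_cols = c("region", "category", "kind"))
      utils::write.table(ts, outf("truth_sites.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(tx$truth$abundance, outf("abundance.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tx
    } else {
      seqs <- read_transcript_fasta(cfg$transcriptome_fasta)
      regions <- read_region_gff(cfg$regions_gff)
      structure(list(sequences = seqs, regions = regions,
                     truth = NULL, spec = spec), class = "transcriptome")
    }
  })
  lens <- stats::setNames(tx$regions$length, tx$regions$transcript_id)

  result <- list(tx = tx, conditions = list())
  for (cond in cfg$conditions) {
    cres <- list()
    sam_path <- run_stage(paste0("parclip_", cond), log, {
      if (!is.null(cfg$parclip_sam_paths[[cond]])) {
        cfg$parclip_sam_paths[[cond]]
      } else {
        raw <- simulate_parclip(tx, cond, spec)
        p <- outf("parclip_", cond, ".sam")
        write_sam(raw, lens, p)
        p
      }
    })
    reads <- run_stage(paste0("parse_", cond), log, {
      rd <- read_sam(sam_path)
      rd <- annotate_mismatches(rd, tx$sequences)
      distribute_multimappers(rd)
    })
    log(sprintf("  %s: %d placements, %.0f reads", cond, nrow(reads),
                sum(reads$weight)))

    expr <- run_stage(paste0("quantify_", cond), log, {
      reps <- if (!is.null(cfg$mrnaseq_sam_paths[[cond]])) {
        lapply(cfg$mrnaseq_sam_paths[[cond]], read_sam)
      } else {
        if (is.null(tx$truth)) {
          stop("external transcriptome without mrnaseq_sam_paths: ",
               "no abundances to simulate from")
        }
        simulate_mrnaseq(
          tx, spec, library_prefix = paste0("mrnaseq_", cond),
          seed = spec$seed + 500L + 10L * match(cond, condition_levels()))
      }
      if (cfg$write_mrnaseq_sam) {
        for (i in seq_along(reps)) {
          write_sam(reps[[i]], lens,
                    outf("mrnaseq_", cond, "_rep", i, ".sam"))
        }
      }
      et <- expression_table(reps, tx$regions)
      utils::write.table(et, outf("expression_", cond, ".tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (spec$n_replicates >= 2L) {
        cc <- replicate_concordance(et$rpkm_rep1, et$rpkm_rep2)
        log(sprintf("  %s replicate RPKM: r = %.5f, R^2 = %.5f", cond,
                    cc$r, cc$r_squared))
      }
      et
    })

    sites <- run_stage(paste0("callsites_", cond), log, {
      s <- call_sites(reads, tx, expression = expr, params = cfg$params,
                      condition = cond)
      write_sites(s, outf("sites_", cond, ".bed"),
                  outf("sites_", cond, ".tsv"))
      s
    })
    log(sprintf("  %s: %d binding sites", cond, nrow(sites)))

    stats_tab <- run_stage(paste0("seqstats_", cond), log, {
      rows <- list()
      push <- function(metric, value) {
        rows[[length(rows) + 1L]] <<- data.frame(metric = metric,
                                                 value = value)
      }
      if (sum(sites$region == "UTR5") >= 2L) {
        t5 <- bound_vs_unbound_composition(sites, tx, "UTR5")
        push("utr5_bound_vs_unbound_pyrimidine_p", t5$p)
        push("utr5_bound_mean_pyrimidine", mean(t5$bound))
        push("utr5_unbound_mean_pyrimidine", mean(t5$unbound))
      }
      if (sum(sites$region == "UTR3") >= 2L) {
        t3 <- bound_vs_unbound_composition(sites, tx, "UTR3")
        push("utr3_bound_vs_unbound_g_p", t3$p)
      }
      u5_sites <- sites[sites$region == "UTR5", , drop = FALSE]
      if (nrow(u5_sites)) {
        runs <- summarize_runs(site_sequences(u5_sites, tx, extend = 15L))
        push("utr5_sites_with_pyrimidine_run6", runs$fraction)
        tops <- classify_top(tx, cfg$top_min_run)
        ov <- top_overlap(sites, tops)
        push("utr5_site_top_overlap_fraction", ov$fraction)
      }
      df <- do.call(rbind, rows)
      utils::write.table(df, outf("seqstats_", cond, ".tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      df
    })

    enr <- run_stage(paste0("enrich_", cond), log, {
      ann <- simulate_go_annotation(tx)
      background <- expr$gene_id[expr$expressed]
      bound_tx <- unique(sites$transcript_id)
      study <- intersect(
        tx$regions$gene_id[match(bound_tx, tx$regions$transcript_id)],
        background)
      res <- fisher_enrichment(study, background, ann)
      res <- group_supercategories(res)
      utils::write.table(res, outf("enrichment_", cond, ".tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      res
    })

    result$conditions[[cond]] <- list(reads = reads, expression = expr,
                                      sites = sites, seqstats = stats_tab,
                                      enrichment = enr)
  }

  result$coverage <- run_stage("annotate_metagene", log, {
    all_sites <- do.call(rbind, lapply(result$conditions, `[[`, "sites"))
    cov <- region_coverage_table(all_sites, tx$regions)
    utils::write.table(cov, outf("region_coverage.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (cond in cfg$conditions) {
      for (cat in unique(tx$regions$category)) {
        prof <- metagene_profile(result$conditions[[cond]]$sites,
                                 tx$regions, cat)
        write_metagene_tsv(prof, outf("metagene_", cat, "_", cond, ".tsv"))
      }
    }
    cov
  })

  if ("mTOR_off" %in% cfg$conditions && !is.null(tx$truth)) {
    result$te_crosstab <- run_stage("te_crosstab", log, {
      sites_off <- result$conditions[["mTOR_off"]]$sites
      # the mTOR-sensitive binding mode: genes gaining 5'UTR sites
      u5_tx <- unique(sites_off$transcript_id[sites_off$region == "UTR5"])
      bound <- unique(tx$regions$gene_id[match(u5_tx,
                                               tx$regions$transcript_id)])
      te <- simulate_te_table(tx)
      tt <- te_cross_tab(te, bound)
      utils::write.table(tt, outf("te_crosstab.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      tt
    })
  }

  # manifest covers every table; the (append-only) log and the manifest
  # itself are excluded so the checksums are reproducible
  log("stage manifest: start")
  files <- sort(setdiff(list.files(cfg$outdir),
                        c("manifest.tsv", "run.log")))
  md5 <- unname(tools::md5sum(file.path(cfg$outdir, files)))
  mf <- data.frame(file = files, md5 = md5, seed = spec$seed,
                   stringsAsFactors = FALSE)
  utils::write.table(mf, file.path(cfg$outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log("stage manifest: done")
  result$manifest <- mf
  invisible(result)
}
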