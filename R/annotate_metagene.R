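#' Assign binding sites to transcript regions
#'
#' The label is the region (5'UTR, CDS, 3'UTR) holding the largest share of
#' the site span; exact ties break in the order UTR5 > CDS > UTR3. Sites
#' outside transcript bounds are an error.
#'
#' @param sites data.frame with `transcript_id`, `start`, `end`.
#' @param regions `regions` data.frame.
#' @return Character vector of labels (`UTR5`/`CDS`/`UTR3`).
#' @export
assign_region <- function(sites, regions) {
  if (!nrow(sites)) return(character())
  b <- region_bounds(regions, sites$transcript_id)
  if (any(sites$start < 0L) || any(sites$end > b[, "length"]) ||
      any(sites$start >= sites$end)) {
    stop("site(s) outside transcript bounds")
  }
  ov <- cbind(
    UTR5 = interval_overlap(sites$start, sites$end, 0L, b[, "utr5_end"]),
    CDS = interval_overlap(sites$start, sites$end, b[, "utr5_end"],
                           b[, "cds_end"]),
    UTR3 = interval_overlap(sites$start, sites$end, b[, "cds_end"],
                            b[, "length"])
  )
  # which.max on each row honours the UTR5 > CDS > UTR3 tie order
  c("UTR5", "CDS", "UTR3")[apply(ov, 1L, which.max)]
}

#' Summed binding coverage per gene category and region
#'
#' Sums each site's score (expression-normalized `norm_score` when
#' available for every site, otherwise `rpm` with a message) per
#' (category, region, condition) cell and converts to percentages within
#' each category and condition, the quantity behind "fraction of binding in
#' the 5'UTR" style comparisons.
#'
#' @param sites site table with `region` and `condition` columns.
#' @param regions `regions` data.frame carrying `category` per transcript;
#'   transcripts missing a category are grouped as `non_TR` with a warning.
#' @return data.frame `category`, `condition`, `region`, `coverage`, `pct`.
#' @export
region_coverage_table <- function(sites, regions) {
  if (!nrow(sites)) {
    return(data.frame(category = character(), condition = character(),
                      region = character(), coverage = numeric(),
                      pct = numeric(), stringsAsFactors = FALSE))
  }
  score <- sites$norm_score
  if (any(is.na(score))) {
    message("using rpm as coverage currency (norm_score missing for ",
            sum(is.na(score)), " site(s))")
    score <- sites$rpm
  }
  cat_map <- stats::setNames(regions$category, regions$transcript_id)
  category <- unname(cat_map[sites$transcript_id])
  if (any(is.na(category))) {
    warning(sum(is.na(category)),
            " site(s) on uncategorized transcripts grouped as non_TR")
    category[is.na(category)] <- "non_TR"
  }
  agg <- stats::aggregate(
    score,
    by = list(category = category, condition = sites$condition,
              region = factor(sites$region,
                              levels = c("UTR5", "CDS", "UTR3"))),
    FUN = sum, drop = FALSE
  )
  names(agg)[4L] <- "coverage"
  agg$coverage[is.na(agg$coverage)] <- 0
  agg$region <- as.character(agg$region)
  tot <- stats::ave(agg$coverage,
                    paste(agg$category, agg$condition), FUN = sum)
  agg$pct <- ifelse(tot > 0, 100 * agg$coverage / tot, NA_real_)
  agg <- agg[order(agg$category, agg$condition,
                   match(agg$region, c("UTR5", "CDS", "UTR3"))), ]
  rownames(agg) <- NULL
  agg
}

#' Normalized-length metagene profile of binding coverage
#'
#' Each transcript's coordinate axis is rescaled to `[0, 1]`; each site's
#' score is spread over the bins it overlaps, proportional to overlap, and
#' summed over transcripts of the requested category. Region boundary marks
#' are the mean fractional 5'UTR/CDS and CDS/3'UTR junction positions of the
#' category's transcripts (the whole transcript is rescaled as one axis;
#' regions are not rescaled separately).
#'
#' @param sites site table (any conditions; filter beforehand).
#' @param regions `regions` data.frame.
#' @param category gene category to profile (`NULL` = all transcripts).
#' @param n_bins number of bins (>= 10).
#' @return List of class `metagene_profile`: `bin_weights`, `n_bins`,
#'   `boundary_utr5_cds`, `boundary_cds_utr3`, `category`, `total_coverage`.
#' @export
metagene_profile <- function(sites, regions, category = NULL, n_bins = 100L) {
  if (n_bins < 10L) stop("n_bins must be >= 10")
  keep_tx <- regions
  if (!is.null(category)) {
    keep_tx <- regions[regions$category == category, , drop = FALSE]
  }
  use <- sites[sites$transcript_id %in% keep_tx$transcript_id, ,
               drop = FALSE]
  w <- numeric(n_bins)
  if (nrow(use)) {
    score <- use$norm_score
    if (any(is.na(score))) score <- use$rpm
    b <- region_bounds(regions, use$transcript_id)
    f0 <- use$start / b[, "length"]
    f1 <- use$end / b[, "length"]
    for (i in seq_len(nrow(use))) {
      lo <- f0[i] * n_bins; hi <- f1[i] * n_bins
      bins <- floor(lo):min(ceiling(hi) - 1, n_bins - 1)
      ov <- pmin(hi, bins + 1) - pmax(lo, bins)
      ov[ov < 0] <- 0
      w[bins + 1L] <- w[bins + 1L] + score[i] * ov / (hi - lo)
    }
  }
  u5 <- keep_tx$utr5_len / keep_tx$length
  cd <- (keep_tx$utr5_len + keep_tx$cds_len) / keep_tx$length
  structure(list(bin_weights = w, n_bins = as.integer(n_bins),
                 boundary_utr5_cds = mean(u5),
                 boundary_cds_utr3 = mean(cd),
                 category = if (is.null(category)) "all" else category,
                 total_coverage = sum(w)),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("metagene profile (", x$category, "): ", x$n_bins, " bins, total ",
      signif(x$total_coverage, 5), "; junction marks at ",
      signif(x$boundary_utr5_cds, 3), " and ",
      signif(x$boundary_cds_utr3, 3), "\n", sep = "")
  invisible(x)
}

#' Write a metagene profile as TSV (bin, fraction midpoint, weight)
#' @param profile a `metagene_profile`.
#' @param path output path.
#' @export
write_metagene_tsv <- function(profile, path) {
  df <- data.frame(bin = seq_len(profile$n_bins),
                   position = (seq_len(profile$n_bins) - 0.5) /
                     profile$n_bins,
                   weight = profile$bin_weights)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
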