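#' TSS-anchored methylation metaplot
#'
#' Assigns every CpG to the gene with the nearest TSS (same chromosome,
#' ties broken toward the lexicographically smaller gene id), keeps CpGs
#' within `upstream` bp before and `downstream` bp after that TSS, and
#' returns the coverage-weighted mean methylation percent per
#' TSS-relative bin across the selected pools. A moving-average smoother
#' (window `smooth` bins) is provided in place of heavier model-based
#' smoothing. Empty bins are omitted.
#'
#' @param x A [cpg_counts()] object.
#' @param annotation Annotation tibble.
#' @param pool_ids Pools to average over; default all pools.
#' @param upstream,downstream Metaplot span (defaults 5000 / 1000).
#' @param bin Bin width in bp (default 25).
#' @param smooth Moving-average window in bins (default 5; 0 disables).
#' @return A tibble: `bin_start`, `bin_mid`, `n_sites`, `coverage`,
#'   `meth_pct`, `meth_pct_smooth`.
#' @export
metaplot <- function(x, annotation, pool_ids = NULL,
                     upstream = 5000, downstream = 1000,
                     bin = 25, smooth = 5) {
  stopifnot(inherits(x, "cpg_counts"))
  if (!is.null(pool_ids)) x <- subset_pools(x, pool_ids)
  idx <- nearest_tss(x$sites, annotation)
  ok <- !is.na(idx)
  rel <- tss_relative_position(
    x$sites$pos[ok], annotation$tss[idx[ok]], annotation$strand[idx[ok]]
  )
  inside <- rel >= -upstream & rel < downstream
  rows <- which(ok)[inside]
  rel <- rel[inside]
  meth <- rowSums(x$meth[rows, , drop = FALSE])
  cov <- meth + rowSums(x$unmeth[rows, , drop = FALSE])
  bin_start <- floor(rel / bin) * bin
  out <- tibble(bin_start = bin_start, meth = meth, cov = cov) |>
    group_by(.data$bin_start) |>
    summarise(
      n_sites = dplyr::n(),
      coverage = sum(.data$cov),
      meth_pct = 100 * sum(.data$meth) / sum(.data$cov),
      .groups = "drop"
    ) |>
    filter(.data$coverage > 0) |>
    arrange(.data$bin_start) |>
    mutate(bin_mid = .data$bin_start + bin / 2, .after = "bin_start")
  out$meth_pct_smooth <- if (smooth > 1) {
    moving_average(out$meth_pct, smooth)
  } else {
    out$meth_pct
  }
  out
}

moving_average <- function(v, k) {
  half <- floor(k / 2)
  n <- length(v)
  vapply(seq_len(n), function(i) {
    mean(v[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

# Nearest TSS per site (same chromosome); ties toward the smaller gene_id.
nearest_tss <- function(sites, annotation) {
  out <- rep(NA_integer_, nrow(sites))
  ann_ord <- annotation |>
    mutate(.row = dplyr::row_number()) |>
    arrange(.data$chrom, .data$tss, .data$gene_id)
  for (ch in unique(sites$chrom)) {
    ann_c <- ann_ord[ann_ord$chrom == ch, ]
    if (nrow(ann_c) == 0) next
    s_idx <- which(sites$chrom == ch)
    pos <- sites$pos[s_idx]
    right <- findInterval(pos, ann_c$tss) # last tss <= pos
    left <- pmax(right, 1)
    nxt <- pmin(right + 1, nrow(ann_c))
    d_left <- abs(pos - ann_c$tss[left])
    d_right <- abs(pos - ann_c$tss[nxt])
    d_left[right == 0] <- Inf
    pick_left <- d_left < d_right |
      (d_left == d_right &
         ann_c$gene_id[left] <= ann_c$gene_id[nxt])
    out[s_idx] <- ifelse(pick_left, ann_c$.row[left], ann_c$.row[nxt])
  }
  out
}

#' Per-gene promoter methylation percent
#'
#' Coverage-weighted percent methylation over all promoter CpGs of each
#' gene, pooled across the selected pools.
#'
#' @param x A filtered, normalized [cpg_counts()] object.
#' @param annotation Annotation tibble.
#' @param pool_ids Pools to pool over; default all.
#' @param upstream,downstream Promoter extent.
#' @return A tibble: `gene_id`, `meth_pct`, `n_cpg`, `coverage`. Genes
#'   without covered promoter CpGs are absent.
#' @export
promoter_methylation <- function(x, annotation, pool_ids = NULL,
                                 upstream = 2000, downstream = 200) {
  if (!is.null(pool_ids)) x <- subset_pools(x, pool_ids)
  rc <- aggregate_window_counts(x, annotation, size = "promoter",
                                upstream = upstream,
                                downstream = downstream)
  meth <- rowSums(rc$meth)
  cov <- meth + rowSums(rc$unmeth)
  tibble(
    gene_id = rc$units$gene_id,
    meth_pct = 100 * meth / cov,
    n_cpg = rc$units$n_cpg,
    coverage = cov
  ) |>
    filter(.data$coverage > 0)
}

#' Per-gene mean log2-CPM
#'
#' @param x An [expression_counts()] object with normalization factors.
#' @param pool_ids Pools to average over; default all.
#' @param prior Prior count for [log_cpm()].
#' @return A tibble: `gene_id`, `log2_cpm`.
#' @export
gene_log2_cpm <- function(x, pool_ids = NULL, prior = 2) {
  m <- log_cpm_matrix(x, prior)
  if (!is.null(pool_ids)) m <- m[, pool_ids, drop = FALSE]
  tibble(gene_id = rownames(m), log2_cpm = rowMeans(m))
}

#' Static methylation-expression association
#'
#' Ordinary least-squares regression of per-gene log2-CPM on promoter
#' methylation percent within one condition, quantifying the global
#' (static) inverse relationship between promoter methylation and
#' transcription. Only genes with both values are used.
#'
#' @param data A data frame with one row per gene.
#' @param meth_col,expr_col Column names of the methylation percent and
#'   log2-CPM values.
#' @return An object of class `meth_expr_fit` with [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()] methods.
#' @export
#' @examples
#' d <- tibble::tibble(meth_pct = c(0, 50, 100), log2_cpm = c(8, 4, 0))
#' generics::glance(static_association(d))
static_association <- function(data, meth_col = "meth_pct",
                               expr_col = "log2_cpm") {
  d <- data[stats::complete.cases(data[c(meth_col, expr_col)]), ]
  if (nrow(d) < 3) stop("static_association needs at least 3 genes")
  fit <- stats::lm(
    stats::reformulate(meth_col, expr_col),
    data = d
  )
  structure(
    list(fit = fit, data = as_tibble(d),
         meth_col = meth_col, expr_col = expr_col, n = nrow(d)),
    class = "meth_expr_fit"
  )
}

#' @export
print.meth_expr_fit <- function(x, ...) {
  g <- generics::glance(x)
  cat("<meth_expr_fit> n =", g$n,
      "| slope =", signif(g$slope, 4),
      "log2-CPM per percentage point | p =", format.pval(g$p.value), "\n")
  invisible(x)
}

#' @export
tidy.meth_expr_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @export
glance.meth_expr_fit <- function(x, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  tibble(
    n = x$n,
    slope = co[2, "Estimate"],
    intercept = co[1, "Estimate"],
    p.value = co[2, "Pr(>|t|)"],
    r.squared = s$r.squared
  )
}

#' Binned density of the static association
#'
#' 2-D binned gene counts over (methylation percent, log2-CPM), the table
#' behind density-style association plots.
#'
#' @param x A `meth_expr_fit` object.
#' @param meth_bin,expr_bin Bin widths.
#' @return A tibble: `meth_bin`, `expr_bin`, `n`.
#' @export
association_density <- function(x, meth_bin = 5, expr_bin = 0.5) {
  d <- x$data
  tibble(
    meth_bin = floor(d[[x$meth_col]] / meth_bin) * meth_bin,
    expr_bin = floor(d[[x$expr_col]] / expr_bin) * expr_bin
  ) |>
    count(.data$meth_bin, .data$expr_bin)
}

#' Window-wise association of methylation change with expression change
#'
#' For each promoter window position, ordinary least-squares regression of
#' per-gene expression log2 fold change on the gene's methylation change in
#' that window (percentage points, B minus A). Records the slope, its
#' direction and a significance tier (`p < 0.05`, `< 0.01`, `< 0.001`).
#' Windows with fewer than `min_genes` genes carrying both values, or with
#' a degenerate (constant) methylation change, are skipped. No
#' multiple-testing correction is applied across windows by default; set
#' `adjust = TRUE` to add BH-adjusted p-values.
#'
#' @param window_results A `"window"`-mode [window_dm()] result (its
#'   `meth_diff` column is the per-gene window methylation change).
#' @param de_results A [de_test()] result for the same comparison.
#' @param min_genes Minimum genes per window (default 10).
#' @param adjust Add a BH-adjusted p-value column (default `FALSE`).
#' @return A tibble per tested window: `window_index`, `rel_start`,
#'   `rel_end`, `n`, `slope`, `r`, `p_value`, `direction`, `tier`.
#' @export
delta_association <- function(window_results, de_results, min_genes = 10,
                              adjust = FALSE) {
  ca <- attr(window_results, "comparison")
  cb <- attr(de_results, "comparison")
  if (!is.null(ca) && !is.null(cb) && !identical(ca, cb)) {
    stop("comparison mismatch: '", ca, "' vs '", cb, "'")
  }
  d <- inner_join(
    window_results[c("gene_id", "window_index", "rel_start", "rel_end",
                     "meth_diff")],
    de_results[c("gene_id", "log2_fc")],
    by = "gene_id"
  )
  out <- d |>
    group_by(.data$window_index, .data$rel_start, .data$rel_end) |>
    summarise(
      n = dplyr::n(),
      sd_x = sd(.data$meth_diff),
      sd_y = sd(.data$log2_fc),
      r = if (dplyr::n() >= 3 && sd(.data$meth_diff) > 0 &&
              sd(.data$log2_fc) > 0) {
        cor(.data$meth_diff, .data$log2_fc)
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    filter(.data$n >= min_genes, !is.na(.data$r), .data$sd_x > 0) |>
    mutate(
      slope = .data$r * .data$sd_y / .data$sd_x,
      statistic = .data$r * sqrt(.data$n - 2) / sqrt(pmax(1 - .data$r^2, 1e-12)),
      p_value = 2 * stats::pt(abs(.data$statistic), df = .data$n - 2,
                              lower.tail = FALSE),
      direction = ifelse(.data$slope < 0, "negative", "positive"),
      tier = as.character(cut(
        .data$p_value, breaks = c(0, 0.001, 0.01, 0.05, 1),
        labels = c("p<0.001", "p<0.01", "p<0.05", "ns"),
        include.lowest = TRUE
      ))
    ) |>
    select(-"sd_x", -"sd_y") |>
    arrange(.data$window_index)
  if (adjust) out$p_adjusted <- adjust_pvalues(out$p_value)
  attr(out, "comparison") <- ca %||% cb
  out
}

#' Overlap of differentially expressed and differentially methylated genes
#'
#' A gene overlaps iff it is a DEG (called `up` or `down`) and has at least
#' one significant differential-methylation unit in the given mode. The
#' positional profile counts every significant window of an overlapping
#' gene at its window position (one DEG can contribute several windows).
#'
#' @param de_results A [de_test()] result.
#' @param dm_results A [window_dm()] result for the same comparison
#'   (promoter or window mode).
#' @return A list of class `deg_dmr_overlap`: `n_overlap` (genes),
#'   `genes` (tibble of overlapping gene ids), `positional` (tibble
#'   `rel_start`, `n` of significant windows of overlapping genes),
#'   `n_deg`, `n_dmr_genes`, `n_dmr_units`.
#' @export
overlap_deg_dmr <- function(de_results, dm_results) {
  ca <- attr(de_results, "comparison")
  cb <- attr(dm_results, "comparison")
  if (!is.null(ca) && !is.null(cb) && !identical(ca, cb)) {
    stop("comparison mismatch: '", ca, "' vs '", cb, "'")
  }
  degs <- de_results$gene_id[de_results$call != "ns"]
  sig <- dm_results[dm_results$significant, , drop = FALSE]
  overlap_genes <- intersect(degs, unique(sig$gene_id))
  pos <- sig |>
    filter(.data$gene_id %in% overlap_genes) |>
    count(.data$rel_start)
  structure(
    list(
      n_overlap = length(overlap_genes),
      genes = tibble(gene_id = overlap_genes),
      positional = pos,
      n_deg = length(degs),
      n_dmr_genes = dplyr::n_distinct(sig$gene_id),
      n_dmr_units = nrow(sig),
      comparison = ca %||% cb
    ),
    class = "deg_dmr_overlap"
  )
}

#' @export
print.deg_dmr_overlap <- function(x, ...) {
  cat("<deg_dmr_overlap>", x$n_overlap, "overlapping gene(s) of",
      x$n_deg, "DEGs and", x$n_dmr_genes, "DM genes (",
      x$n_dmr_units, "significant units )\n")
  invisible(x)
}

#' Derived percentages and ratios from summary count tables
#'
#' Recomputes, from integer count tables alone, every derived quantity of
#' the per-comparison summaries: percent of the transcript universe down-
#' and up-regulated and combined, percent up/down among DEGs,
#' hyper/hypo-methylation ratios (both directions) and the
#' percent hypo/hyper among differentially methylated CpGs, percent of
#' DEGs and of promoter DMRs overlapping, and the per-window-size DMR
#' overlap percentage. Percentages of the transcript universe are rounded
#' to 2 decimals, overlap percentages of DEGs and window DMRs to 1 decimal,
#' DMR overlap and composition percentages to the nearest integer, and
#' ratios to 1 decimal (each value's rule is in its `metric` name's
#' documentation below).
#'
#' @param tables A named list in the layout of [study_count_tables()]:
#'   `deg` (`comparison`, `down`, `up`), `dm_cpg` (`comparison`, `hypo`,
#'   `hyper`), `dm_promoter` (`comparison`, `hypo`, `hyper`),
#'   `overlap_promoter` (`comparison`, `overlap`), optional
#'   `window_overlap` (`window_size`, `dmr_count`, `overlap_count`), and
#'   `total_transcripts` (scalar).
#' @return A tibble: `metric`, `comparison`, `value`. Zero denominators
#'   yield `NA` values.
#' @export
#' @examples
#' derived_ratios(study_count_tables())
derived_ratios <- function(tables) {
  tt <- tables$total_transcripts
  if (is.null(tt) || tt == 0) stop("total_transcripts must be positive")
  safe <- function(num, den, digits) {
    den <- rep(den, length.out = length(num))
    out <- round(num / den, digits)
    out[den <= 0] <- NA_real_
    out
  }
  deg <- tables$deg
  rows <- list(
    tibble(metric = "pct_down", comparison = deg$comparison,
           value = safe(100 * deg$down, tt, 2)),
    tibble(metric = "pct_up", comparison = deg$comparison,
           value = safe(100 * deg$up, tt, 2)),
    tibble(metric = "pct_deg_combined", comparison = deg$comparison,
           value = safe(100 * (deg$down + deg$up), tt, 2)),
    tibble(metric = "pct_up_among_degs", comparison = deg$comparison,
           value = safe(100 * deg$up, deg$down + deg$up, 0)),
    tibble(metric = "pct_down_among_degs", comparison = deg$comparison,
           value = safe(100 * deg$down, deg$down + deg$up, 0))
  )
  if (!is.null(tables$dm_cpg)) {
    dm <- tables$dm_cpg
    rows <- c(rows, list(
      tibble(metric = "hyper_hypo_ratio", comparison = dm$comparison,
             value = safe(dm$hyper, dm$hypo, 1)),
      tibble(metric = "hypo_hyper_ratio", comparison = dm$comparison,
             value = safe(dm$hypo, dm$hyper, 1)),
      tibble(metric = "pct_hypo_among_dm_cpgs", comparison = dm$comparison,
             value = safe(100 * dm$hypo, dm$hypo + dm$hyper, 0)),
      tibble(metric = "pct_hyper_among_dm_cpgs", comparison = dm$comparison,
             value = safe(100 * dm$hyper, dm$hypo + dm$hyper, 0))
    ))
  }
  if (!is.null(tables$overlap_promoter)) {
    ov <- tables$overlap_promoter |>
      left_join(deg, by = "comparison")
    rows <- c(rows, list(
      tibble(metric = "pct_degs_overlapping", comparison = ov$comparison,
             value = safe(100 * ov$overlap, ov$down + ov$up, 1))
    ))
    if (!is.null(tables$dm_promoter)) {
      ovp <- tables$overlap_promoter |>
        left_join(tables$dm_promoter, by = "comparison")
      rows <- c(rows, list(
        tibble(metric = "pct_dmrs_overlapping", comparison = ovp$comparison,
               value = safe(100 * ovp$overlap, ovp$hypo + ovp$hyper, 0))
      ))
    }
  }
  if (!is.null(tables$window_overlap)) {
    w <- tables$window_overlap
    rows <- c(rows, list(
      tibble(metric = "pct_window_dmrs_overlapping",
             comparison = paste0(w$window_size, "bp windows"),
             value = safe(100 * w$overlap_count, w$dmr_count, 1))
    ))
  }
  bind_rows(rows)
}

#' Published summary count tables
#'
#' Integer summary tables from a growth-hormone-transgenic coho salmon
#' feed-deprivation and re-feeding study (two genotypes, three time
#' points, liver tissue; 27,856 transcripts assayed): per-comparison
#' counts of down/up-regulated transcripts, of hypo/hyper differentially
#' methylated CpGs, of differentially methylated whole promoters, of
#' DEG-DMR overlaps in the whole promoter, and the 100 bp-window DMR and
#' overlap totals. Shipped as plain TSVs under
#' `inst/extdata/summary_counts/`; all derived percentages and ratios are
#' recomputable from these integers via [derived_ratios()].
#'
#' @param dir Directory of the TSVs; default the installed copies.
#' @return A named list of tibbles plus `total_transcripts`.
#' @export
#' @examples
#' study_count_tables()$deg
study_count_tables <- function(dir = system.file("extdata", "summary_counts",
                                                 package = "promethex")) {
  rd <- function(f) {
    readr::read_tsv(file.path(dir, f), col_types = readr::cols(),
                    progress = FALSE)
  }
  info <- rd("study_info.tsv")
  list(
    deg = rd("deg_counts.tsv"),
    dm_cpg = rd("dm_cpg_counts.tsv"),
    dm_promoter = rd("dm_promoter_counts.tsv"),
    overlap_promoter = rd("deg_dmr_promoter_overlap.tsv"),
    window_overlap = rd("window_overlap_counts.tsv"),
    total_transcripts = info$total_transcripts[1]
  )
}
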