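#' TSS-relative position
#'
#' Signed distance of a genomic position from a TSS: negative upstream,
#' positive downstream, respecting strand (`pos - tss` on `+`,
#' `tss - pos` on `-`).
#'
#' @param pos,tss 0-based genomic positions (vectorised).
#' @param strand `"+"` or `"-"` (vectorised).
#' @return Signed bp offsets.
#' @export
#' @examples
#' tss_relative_position(4500, 5000, "+") # -500 (upstream)
#' tss_relative_position(4500, 5000, "-") # +500 (downstream)
tss_relative_position <- function(pos, tss, strand) {
  ifelse(strand == "+", pos - tss, tss - pos)
}

#' Define promoter intervals
#'
#' The promoter is the TSS-relative interval `[-upstream, +downstream)`
#' (half-open; the TSS base itself is relative position 0). In genomic
#' coordinates: `[tss - upstream, tss + downstream)` on `+` and
#' `[tss - downstream + 1, tss + upstream + 1)` on `-`. Intervals reaching
#' past the chromosome start (or `chrom_length`, if given) are clipped
#' with a warning.
#'
#' @param annotation Annotation tibble.
#' @param upstream,downstream Promoter extent in bp (defaults 2000 / 200).
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return A tibble: `gene_id`, `chrom`, `start`, `end` (0-based,
#'   half-open), `tss`, `strand`.
#' @export
define_promoter <- function(annotation, upstream = 2000, downstream = 200,
                            chrom_lengths = NULL) {
  start <- ifelse(annotation$strand == "+",
                  annotation$tss - upstream,
                  annotation$tss - downstream + 1)
  end <- ifelse(annotation$strand == "+",
                annotation$tss + downstream,
                annotation$tss + upstream + 1)
  clipped <- start < 0
  if (!is.null(chrom_lengths)) {
    lens <- chrom_lengths[annotation$chrom]
    clipped <- clipped | end > lens
    end <- pmin(end, lens)
  }
  if (any(clipped)) {
    warning(sum(clipped), " promoter(s) clipped at chromosome boundaries",
            call. = FALSE)
  }
  tibble(
    gene_id = annotation$gene_id,
    chrom = annotation$chrom,
    start = pmax(start, 0),
    end = end,
    tss = annotation$tss,
    strand = annotation$strand
  )
}

#' Tile the promoter into fixed-size windows
#'
#' Partitions the TSS-relative promoter `[-upstream, +downstream)` into
#' windows of `size` bp: window `k` spans
#' `[-upstream + k * size, -upstream + (k+1) * size)`, giving exactly
#' `(upstream + downstream) / size` windows (22 / 44 / 88 / 176 for the
#' standard sizes 100 / 50 / 25 / 12.5). A CpG at relative position `r`
#' belongs to window `floor((r + upstream) / size)`; for 12.5 bp windows
#' the boundaries are real-valued but the assignment remains exact because
#' `r` is an integer, and the genomic `abs_start` / `abs_end` columns carry
#' the integer positions the window actually covers. On the minus strand
#' increasing relative position corresponds to decreasing genomic
#' coordinate.
#'
#' @param annotation Annotation tibble.
#' @param size Window size in bp; must divide the promoter span exactly.
#' @param upstream,downstream Promoter extent.
#' @return A tibble of window specs: `gene_id`, `window_index`,
#'   `rel_start`, `rel_end`, `abs_start`, `abs_end`, `size`, `strand`.
#' @export
tile_windows <- function(annotation, size, upstream = 2000,
                         downstream = 200) {
  span <- upstream + downstream
  n_win <- span / size
  if (abs(n_win - round(n_win)) > 1e-9) {
    stop("window size ", size, " does not divide the promoter span ", span)
  }
  n_win <- as.integer(round(n_win))
  k <- rep(seq_len(n_win) - 1L, times = nrow(annotation))
  gene_row <- rep(seq_len(nrow(annotation)), each = n_win)
  rel_start <- -upstream + k * size
  rel_end <- rel_start + size
  # integer relative positions covered by the window
  int_start <- ceiling(rel_start)
  int_end <- ceiling(rel_end)  # half-open on the integer lattice
  tss <- annotation$tss[gene_row]
  strand <- annotation$strand[gene_row]
  abs_start <- ifelse(strand == "+", tss + int_start, tss - (int_end - 1))
  abs_end <- ifelse(strand == "+", tss + int_end, tss - int_start + 1)
  tibble(
    gene_id = annotation$gene_id[gene_row],
    window_index = k,
    rel_start = rel_start,
    rel_end = rel_end,
    abs_start = abs_start,
    abs_end = abs_end,
    size = size,
    strand = strand
  )
}

# Assign CpG sites to gene promoters (possibly to several overlapping
# promoters). Returns site_idx, gene_idx, rel.
promoter_site_pairs <- function(x, annotation, upstream, downstream) {
  prom <- define_promoter(annotation, upstream, downstream)
  q <- GenomicRanges::GRanges(
    x$sites$chrom, IRanges::IRanges(start = x$sites$pos + 1, width = 1)
  )
  s <- GenomicRanges::GRanges(
    prom$chrom, IRanges::IRanges(start = prom$start + 1, end = prom$end)
  )
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  site_idx <- S4Vectors::queryHits(hits)
  gene_idx <- S4Vectors::subjectHits(hits)
  rel <- tss_relative_position(
    x$sites$pos[site_idx], annotation$tss[gene_idx],
    annotation$strand[gene_idx]
  )
  list(site_idx = site_idx, gene_idx = gene_idx, rel = rel)
}

#' Aggregate CpG counts into promoter windows
#'
#' Sums methylated and unmethylated counts of all member CpGs per window
#' (or per whole promoter) per pool. Windows without any CpG are excluded
#' from testing (no unit row). Per gene and window size, the window sums
#' add up exactly to the whole-promoter aggregate. CpGs inside the
#' promoters of two overlapping genes are counted for both genes.
#'
#' @param x A filtered, normalized [cpg_counts()] object.
#' @param annotation Annotation tibble.
#' @param size Window size in bp, or `"promoter"` for one unit spanning the
#'   whole promoter.
#' @param upstream,downstream Promoter extent.
#' @return A `region_counts` object whose `units` tibble has `gene_id`,
#'   `window_index`, `rel_start`, `rel_end`, `n_cpg`.
#' @export
aggregate_window_counts <- function(x, annotation, size = "promoter",
                                    upstream = 2000, downstream = 200) {
  stopifnot(inherits(x, "cpg_counts"))
  pairs <- promoter_site_pairs(x, annotation, upstream, downstream)
  if (identical(size, "promoter")) {
    win <- rep(0L, length(pairs$rel))
    w_size <- upstream + downstream
  } else {
    size <- as.numeric(size)
    stopifnot(length(size) == 1, size > 0)
    win <- as.integer(floor((pairs$rel + upstream) / size))
    w_size <- size
  }
  key <- paste(pairs$gene_idx, win)
  fac <- factor(key, levels = unique(key))
  meth <- rowsum(x$meth[pairs$site_idx, , drop = FALSE], fac)
  unmeth <- rowsum(x$unmeth[pairs$site_idx, , drop = FALSE], fac)
  first <- !duplicated(key)
  gene_idx <- pairs$gene_idx[first]
  win_u <- win[first]
  units <- tibble(
    gene_id = annotation$gene_id[gene_idx],
    window_index = win_u,
    rel_start = if (identical(size, "promoter")) {
      rep(-upstream, length(win_u))
    } else {
      -upstream + win_u * w_size
    },
    rel_end = if (identical(size, "promoter")) {
      rep(downstream, length(win_u))
    } else {
      -upstream + (win_u + 1) * w_size
    },
    n_cpg = as.integer(table(fac)[levels(fac)])
  )
  ord <- order(match(units$gene_id, annotation$gene_id), units$window_index)
  region_counts(
    units[ord, ], meth[ord, , drop = FALSE], unmeth[ord, , drop = FALSE],
    x$pools, size = if (identical(size, "promoter")) "promoter" else size
  )
}

#' Per-window (or per-promoter) differential methylation
#'
#' Applies [dm_test()] to every aggregated unit of a comparison. In
#' `"promoter"` mode significance requires `q_value < q_cut` and
#' `|meth_diff| >= diff_cut` (the stringent dual threshold); in `"window"`
#' mode significance is `p_value < p_cut` with no q-value or effect-size
#' filter (the deliberately less stringent sub-window screen).
#'
#' @param rc A `region_counts` object from [aggregate_window_counts()].
#' @param group_a,group_b Character vectors of pool ids.
#' @param mode `"window"` or `"promoter"`; default matches `rc$size`.
#' @param q_cut,diff_cut,p_cut Thresholds (defaults 0.01, 25, 0.05).
#' @param label Optional comparison label stored as an attribute.
#' @return A tibble: unit columns plus [dm_test()] results, `q_value`,
#'   `significant`, `call`.
#' @export
window_dm <- function(rc, group_a, group_b, mode = NULL,
                      q_cut = 0.01, diff_cut = 25, p_cut = 0.05,
                      label = NULL) {
  stopifnot(inherits(rc, "region_counts"))
  if (is.null(mode)) {
    mode <- if (identical(rc$size, "promoter")) "promoter" else "window"
  }
  mode <- match.arg(mode, c("window", "promoter"))
  a <- subset_pools(rc, group_a)
  b <- subset_pools(rc, group_b)
  res <- dm_test(a$meth, a$unmeth, b$meth, b$unmeth)
  out <- bind_cols(rc$units, res)
  out <- out[!is.na(out$p_value), ]
  out$q_value <- adjust_pvalues(out$p_value)
  if (mode == "promoter") {
    out <- call_dm(out, q_cut = q_cut, diff_cut = diff_cut)
    out$significant <- out$call != "ns"
  } else {
    out$significant <- out$p_value < p_cut
    out$call <- dplyr::case_when(
      out$significant & out$meth_diff > 0 ~ "hyper",
      out$significant & out$meth_diff < 0 ~ "hypo",
      TRUE ~ "ns"
    )
  }
  attr(out, "comparison") <- label
  attr(out, "mode") <- mode
  attr(out, "size") <- rc$size
  out
}

#' Positional profile of significant windows
#'
#' Counts significant windows at each TSS-relative window start, the table
#' behind stacked-area DMR position plots. All window positions of the
#' tiling appear, zero-filled where nothing is significant; the counts sum
#' to the total number of significant windows.
#'
#' @param window_results A `"window"`-mode [window_dm()] result.
#' @param size Window size in bp; default taken from the result attribute.
#' @param upstream,downstream Promoter extent.
#' @return A tibble: `rel_start`, `n_hypo`, `n_hyper`, `n` per window
#'   position.
#' @export
positional_dmr_profile <- function(window_results, size = NULL,
                                   upstream = 2000, downstream = 200) {
  if (is.null(size)) size <- attr(window_results, "size")
  stopifnot(is.numeric(size))
  grid <- seq(-upstream, downstream - size, by = size)
  sig <- window_results[window_results$significant, , drop = FALSE]
  agg <- sig |>
    group_by(.data$rel_start) |>
    summarise(
      n_hypo = sum(.data$call == "hypo"),
      n_hyper = sum(.data$call == "hyper"),
      n = dplyr::n(),
      .groups = "drop"
    )
  out <- tibble(rel_start = grid) |>
    left_join(agg, by = "rel_start") |>
    mutate(across(c("n_hypo", "n_hyper", "n"),
                  ~ ifelse(is.na(.x), 0L, .x)))
  attr(out, "comparison") <- attr(window_results, "comparison")
  out
}
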