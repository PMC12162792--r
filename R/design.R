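#' Analysis thresholds and promoter geometry
#'
#' The fixed constants of the analysis: promoter extent around the TSS,
#' metaplot span, the window sizes used for promoter tiling, the minimum
#' per-pool CpG coverage, and the significance thresholds for differential
#' methylation (promoter and sub-window modes) and differential expression.
#'
#' @param promoter_upstream,promoter_downstream Promoter extent in bp
#'   upstream/downstream of the TSS. Defaults 2000 and 200.
#' @param metaplot_upstream,metaplot_downstream Metaplot span in bp around
#'   the TSS. Defaults 5000 and 1000.
#' @param window_sizes Window sizes (bp) used to tile the promoter; each must
#'   divide the promoter span exactly.
#' @param min_coverage Minimum total read coverage a CpG must reach in every
#'   pool to be retained.
#' @param q_cut_promoter,diff_cut Promoter-mode differential methylation
#'   thresholds: BH q-value cutoff and absolute methylation difference in
#'   percentage points.
#' @param p_cut_window Per-window (sub-promoter) differential methylation
#'   p-value cutoff; no effect-size filter is applied in window mode.
#' @param fdr_cut_de Differential expression FDR cutoff.
#'
#' @return A named list of constants.
#' @export
#' @examples
#' analysis_thresholds()$min_coverage
analysis_thresholds <- function(promoter_upstream = 2000,
                                promoter_downstream = 200,
                                metaplot_upstream = 5000,
                                metaplot_downstream = 1000,
                                window_sizes = c(100, 50, 25, 12.5),
                                min_coverage = 10,
                                q_cut_promoter = 0.01,
                                diff_cut = 25,
                                p_cut_window = 0.05,
                                fdr_cut_de = 0.05) {
  span <- promoter_upstream + promoter_downstream
  bad <- window_sizes[abs(span / window_sizes - round(span / window_sizes)) > 1e-9]
  if (length(bad) > 0) {
    stop("window sizes must divide the promoter span (", span, " bp) exactly: ",
         paste(bad, collapse = ", "))
  }
  list(
    promoter_upstream = promoter_upstream,
    promoter_downstream = promoter_downstream,
    metaplot_upstream = metaplot_upstream,
    metaplot_downstream = metaplot_downstream,
    window_sizes = window_sizes,
    min_coverage = min_coverage,
    q_cut_promoter = q_cut_promoter,
    diff_cut = diff_cut,
    p_cut_window = p_cut_window,
    fdr_cut_de = fdr_cut_de
  )
}

#' Pool layout of the two-genotype, three-time-point design
#'
#' Builds the pool (replicate sequencing library) table for a factorial
#' design of genotype (transgenic / non-transgenic) by time point
#' (Day0 fed, Day28 feed-deprived, Day41 re-fed), with `pools_per_cell`
#' replicate pools per cell.
#'
#' @param genotypes Character vector of genotype labels.
#' @param timepoints Character vector of time-point labels.
#' @param pools_per_cell Replicate pools per genotype x time-point cell.
#'
#' @return A tibble with columns `pool_id`, `genotype`, `timepoint`,
#'   `replicate`.
#' @export
#' @examples
#' experiment_pools()
experiment_pools <- function(genotypes = c("transgenic", "non_transgenic"),
                             timepoints = c("Day0", "Day28", "Day41"),
                             pools_per_cell = 2) {
  grid <- expand.grid(
    replicate = seq_len(pools_per_cell),
    timepoint = timepoints,
    genotype = genotypes,
    stringsAsFactors = FALSE
  )
  tibble(
    pool_id = sprintf(
      "%s_%s_r%d",
      ifelse(grid$genotype == "transgenic", "tg", "ntg"),
      tolower(grid$timepoint), grid$replicate
    ),
    genotype = grid$genotype,
    timepoint = grid$timepoint,
    replicate = grid$replicate
  )
}

#' The nine standard pairwise comparisons
#'
#' Three within-genotype time contrasts per genotype plus the
#' between-genotype contrast at each time point. In every comparison the
#' first-named group is group A and the second group B; differences
#' (methylation and expression log fold changes) are reported as B minus A,
#' so "hyper" / "up" mean higher in the second group.
#'
#' @param pools Pool table as returned by [experiment_pools()].
#'
#' @return A tibble with columns `label`, `group_a`, `group_b` (the latter
#'   two are list-columns of pool ids).
#' @export
#' @examples
#' standard_comparisons(experiment_pools())$label
standard_comparisons <- function(pools = experiment_pools()) {
  stopifnot(all(c("pool_id", "genotype", "timepoint") %in% names(pools)))
  sel <- function(g, t) pools$pool_id[pools$genotype == g & pools$timepoint == t]
  tp <- c("Day0", "Day28", "Day41")
  within <- purrr::map_dfr(c("transgenic", "non_transgenic"), function(g) {
    pairs <- list(c(1, 2), c(1, 3), c(2, 3))
    purrr::map_dfr(pairs, function(pr) {
      tibble(
        label = sprintf(
          "%s Day %s vs. Day %s",
          ifelse(g == "transgenic", "Transgenic", "Non-transgenic"),
          sub("Day", "", tp[pr[1]]), sub("Day", "", tp[pr[2]])
        ),
        group_a = list(sel(g, tp[pr[1]])),
        group_b = list(sel(g, tp[pr[2]]))
      )
    })
  })
  between <- purrr::map_dfr(tp, function(t) {
    tibble(
      label = sprintf("Transgenic vs. non-transgenic Day %s", sub("Day", "", t)),
      group_a = list(sel("transgenic", t)),
      group_b = list(sel("non_transgenic", t))
    )
  })
  out <- bind_rows(within, between)
  empty <- lengths(out$group_a) == 0 | lengths(out$group_b) == 0
  out[!empty, ]
}
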