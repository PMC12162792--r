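#' Simulation configuration
#'
#' Parameters of the joint WGBS + RNA-seq generator. Defaults emulate the
#' study conditions the analysis is designed for: a two-genotype by
#' three-time-point design with two replicate pools per cell, ~15x CpG
#' coverage, a promoter methylation profile with a high upstream plateau
#' (~80%) dipping to a trough (~15%) about 200 bp downstream of the TSS,
#' beta-binomial biological overdispersion from pooled individuals, and a
#' configurable subset of genes whose promoter methylation is inversely
#' coupled to expression.
#'
#' @param seed Integer seed; together with the other parameters it fully
#'   determines the output.
#' @param n_genes Number of genes on the synthetic chromosome.
#' @param intergenic_spacing Distance between consecutive TSSs (bp); must
#'   exceed twice the metaplot upstream extent so metaplot spans never
#'   overlap.
#' @param cpg_spacing_mean Mean CpG spacing (bp) inside gene metaplot spans
#'   (exponential inter-CpG gaps).
#' @param background_spacing Mean spacing of sparse background CpGs outside
#'   gene spans.
#' @param mean_coverage Mean per-pool read coverage (Poisson).
#' @param plateau_meth,trough_meth Upstream plateau and trough methylation
#'   fractions of the mean profile.
#' @param trough_offset Position of the trough, bp downstream of the TSS.
#' @param profile_width Gaussian width (bp) of the dip around the trough.
#' @param plateau_spread,trough_spread Between-gene methylation spread:
#'   each gene draws its own plateau and trough level uniformly within
#'   `plateau_meth +/- plateau_spread` and `trough_meth +/- trough_spread`.
#'   Uniform draws keep the population means exactly at the configured
#'   profile and keep site means strictly inside the unit interval (no
#'   boundary clipping).
#' @param biol_dispersion_meth Beta-binomial overdispersion rho in `[0, 1)`
#'   for per-pool biological noise.
#' @param expr_dispersion Negative-binomial dispersion phi of expression
#'   counts.
#' @param coupling_fraction Fraction of genes whose expression is coupled
#'   (inversely, for negative `coupling_slope`) to their promoter
#'   methylation.
#' @param coupling_slope Change in log2 expression per percentage point of
#'   regulatory methylation (negative for repression).
#' @param dm_fraction Fraction of genes given a differential-methylation
#'   shift at the feed-deprivation time point (Day28).
#' @param dm_effect Size of that shift in percentage points (sign random
#'   per gene, clipped to the unit interval).
#' @param dm_window_size Width (bp) of the shifted promoter window.
#' @param dm_window_rel Optional fixed `c(rel_start, rel_end)` of the
#'   shifted window (promoter-relative); default: random per gene on the
#'   `dm_window_size` grid.
#' @param de_fraction Fraction of uncoupled genes given an independent
#'   expression shift at Day28.
#' @param de_lfc Absolute log2 fold change of that shift (sign random).
#' @param mean_lib_size Mean RNA-seq library size.
#' @param baseline_log2_mean,baseline_log2_sd Between-gene distribution of
#'   baseline log2 expression (CPM-like scale).
#' @param pool_noise_sd Optional per-pool coverage noise inflation
#'   (log-normal sd on the coverage mean) emulating unequal pooled sample
#'   sizes; default off.
#' @param pools_per_cell Replicate pools per genotype x time-point cell.
#'
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 50)
sim_config <- function(seed = 1L,
                       n_genes = 2000,
                       intergenic_spacing = 12000,
                       cpg_spacing_mean = 30,
                       background_spacing = 1000,
                       mean_coverage = 15,
                       plateau_meth = 0.80,
                       trough_meth = 0.15,
                       trough_offset = 200,
                       profile_width = 600,
                       plateau_spread = 0.08,
                       trough_spread = 0.08,
                       biol_dispersion_meth = 0.02,
                       expr_dispersion = 0.1,
                       coupling_fraction = 0.50,
                       coupling_slope = -0.08,
                       dm_fraction = 0.05,
                       dm_effect = 30,
                       dm_window_size = 100,
                       dm_window_rel = NULL,
                       de_fraction = 0.05,
                       de_lfc = 2,
                       mean_lib_size = 3e6,
                       baseline_log2_mean = 5,
                       baseline_log2_sd = 1.5,
                       pool_noise_sd = 0,
                       pools_per_cell = 2) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(
      n_genes >= 0,
      trough_meth >= 0, trough_meth <= plateau_meth, plateau_meth <= 1,
      biol_dispersion_meth >= 0, biol_dispersion_meth < 1,
      expr_dispersion >= 0,
      coupling_fraction >= 0, coupling_fraction <= 1,
      dm_fraction >= 0, dm_fraction <= 1,
      de_fraction >= 0, de_fraction <= 1,
      mean_coverage > 0, pools_per_cell >= 1,
      dm_effect >= 0, dm_effect <= 100,
      plateau_spread >= 0, trough_spread >= 0
    )
  })
  if (cfg$plateau_meth > cfg$trough_meth &&
      cfg$plateau_meth - cfg$plateau_spread <
        cfg$trough_meth + cfg$trough_spread) {
    stop("plateau/trough spreads overlap: per-gene plateau could fall ",
         "below the per-gene trough")
  }
  th <- analysis_thresholds()
  if (cfg$n_genes > 0 &&
      cfg$intergenic_spacing <= 2 * th$metaplot_upstream) {
    stop("intergenic_spacing must exceed ", 2 * th$metaplot_upstream,
         " bp so metaplot spans of neighbouring genes cannot overlap")
  }
  cfg$chrom_length <- as.integer(
    2 * th$metaplot_upstream + 2000 +
      max(cfg$n_genes - 1, 0) * cfg$intergenic_spacing
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$n_genes, "genes |",
      "coverage ~Pois(", x$mean_coverage, ") | rho =",
      x$biol_dispersion_meth, "| phi =", x$expr_dispersion, "\n")
  invisible(x)
}

#' Mean methylation profile around the TSS
#'
#' The generator's mean methylation fraction as a function of signed
#' distance from the TSS (negative upstream): a plateau far upstream with a
#' Gaussian dip reaching its minimum `trough_meth` at `trough_offset` bp
#' downstream of the TSS, recovering further downstream. Monotone
#' decreasing on the upstream approach to the trough.
#'
#' @param rel_pos Signed bp from the TSS (vectorised).
#' @param cfg A [sim_config()].
#' @return Methylation fractions in `[0, 1]`.
#' @export
#' @examples
#' cfg <- sim_config()
#' mean_meth_profile(c(-5000, 0, 200), cfg)
mean_meth_profile <- function(rel_pos, cfg = sim_config()) {
  cfg$plateau_meth - (cfg$plateau_meth - cfg$trough_meth) *
    exp(-((rel_pos - cfg$trough_offset)^2) / (2 * cfg$profile_width^2))
}

#' Simulate a gene annotation
#'
#' Places `n_genes` genes with alternating random strand on one synthetic
#' chromosome, spaced so that metaplot spans (upstream 5 kb / downstream
#' 1 kb of each TSS) never overlap between genes.
#'
#' @param cfg A [sim_config()].
#' @return An annotation tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  tss = integer(), strand = character()))
  }
  withr::with_seed(cfg$seed, {
    tibble(
      gene_id = sprintf("g%05d", seq_len(cfg$n_genes)),
      chrom = "chrS",
      tss = as.integer(
        analysis_thresholds()$metaplot_upstream + 1000 +
          (seq_len(cfg$n_genes) - 1) * cfg$intergenic_spacing
      ),
      strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    )
  })
}

# Integer CpG offsets with exponential gaps covering [from, to).
exp_positions <- function(from, to, mean_gap) {
  n_guess <- ceiling((to - from) / mean_gap * 1.5) + 10
  gaps <- stats::rexp(n_guess, rate = 1 / mean_gap)
  pos <- from + cumsum(gaps)
  while (sum(gaps) < (to - from)) {
    extra <- stats::rexp(n_guess, rate = 1 / mean_gap)
    gaps <- c(gaps, extra)
    pos <- from + cumsum(gaps)
  }
  unique(as.integer(floor(pos[pos < to])))
}

#' Simulate CpG methylation counts
#'
#' Places CpG sites with exponential spacing across each gene's metaplot
#' span plus a sparse background, then draws per-site, per-pool counts:
#' coverage is Poisson with mean `mean_coverage`, the methylated fraction is
#' beta-distributed around the gene-adjusted mean profile with
#' overdispersion `biol_dispersion_meth`, and methylated reads are binomial.
#' For `dm_fraction` of genes, a window of the promoter is shifted by
#' `dm_effect` percentage points (random sign, clipped to the unit
#' interval) in all Day28 pools; the shifted genes, their windows and signs
#' are returned as the truth table.
#'
#' @param annotation Annotation tibble (non-empty).
#' @param cfg A [sim_config()].
#' @param pools Pool table; default [experiment_pools()] with
#'   `cfg$pools_per_cell` replicates.
#'
#' @return A list with elements `counts` (a [cpg_counts()]), and `truth`:
#'   `dm_genes` (tibble `gene_id`, `rel_start`, `rel_end`, `sign`,
#'   `timepoint`), `promoter_meth` (gene x pool matrix of true
#'   promoter-mean methylation percent, including the shift),
#'   `regulatory_meth` (gene x pool percent methylation of the focal
#'   regulatory element: promoter baseline plus the full window shift), and
#'   `gene_levels` (per-gene plateau/trough draws).
#' @export
simulate_methylation <- function(annotation, cfg,
                                 pools = experiment_pools(
                                   pools_per_cell = cfg$pools_per_cell
                                 )) {
  stopifnot(inherits(cfg, "sim_config"), nrow(annotation) > 0)
  th <- analysis_thresholds()
  n_pool <- nrow(pools)
  withr::with_seed(cfg$seed + 1L, {
    n_genes <- nrow(annotation)

    # per-gene plateau and trough levels (bounded uniform, means preserved)
    plateau_g <- pmin(pmax(
      stats::runif(n_genes, cfg$plateau_meth - cfg$plateau_spread,
                   cfg$plateau_meth + cfg$plateau_spread), 0.02), 0.98)
    trough_g <- pmin(pmax(
      stats::runif(n_genes, cfg$trough_meth - cfg$trough_spread,
                   cfg$trough_meth + cfg$trough_spread), 0.02), 0.98)
    gene_levels <- tibble(gene_id = annotation$gene_id,
                          plateau = plateau_g, trough = trough_g)

    # truth table of DM genes
    n_dm <- floor(cfg$dm_fraction * n_genes)
    dm_genes <- if (n_dm > 0) {
      idx <- sort(sample.int(n_genes, n_dm))
      n_win <- (th$promoter_upstream + th$promoter_downstream) /
        cfg$dm_window_size
      if (is.null(cfg$dm_window_rel)) {
        w0 <- -th$promoter_upstream +
          cfg$dm_window_size * (sample.int(n_win, n_dm, replace = TRUE) - 1)
        w1 <- w0 + cfg$dm_window_size
      } else {
        w0 <- rep(cfg$dm_window_rel[1], n_dm)
        w1 <- rep(cfg$dm_window_rel[2], n_dm)
      }
      tibble(
        gene_id = annotation$gene_id[idx],
        rel_start = w0, rel_end = w1,
        sign = sample(c(-1, 1), n_dm, replace = TRUE),
        timepoint = "Day28"
      )
    } else {
      tibble(gene_id = character(), rel_start = numeric(),
             rel_end = numeric(), sign = numeric(), timepoint = character())
    }

    # site layout: gene metaplot spans + sparse background
    gene_rel <- purrr::map(seq_len(n_genes), function(i) {
      exp_positions(-th$metaplot_upstream, th$metaplot_downstream,
                    cfg$cpg_spacing_mean)
    })
    gene_sites <- purrr::map_dfr(seq_len(n_genes), function(i) {
      rel <- gene_rel[[i]]
      pos <- if (annotation$strand[i] == "+") {
        annotation$tss[i] + rel
      } else {
        annotation$tss[i] - rel
      }
      tibble(pos = pos, gene = i, rel = rel)
    })
    bg_pos <- exp_positions(0, cfg$chrom_length, cfg$background_spacing)
    # background CpGs are strictly intergenic: drop any that fall inside a
    # gene's metaplot span (they would dilute the TSS profile)
    span_lo <- ifelse(annotation$strand == "+",
                      annotation$tss - th$metaplot_upstream,
                      annotation$tss - th$metaplot_downstream)
    span_hi <- ifelse(annotation$strand == "+",
                      annotation$tss + th$metaplot_downstream,
                      annotation$tss + th$metaplot_upstream)
    ord_span <- order(span_lo)
    span_lo <- span_lo[ord_span]
    span_hi <- span_hi[ord_span]
    k <- findInterval(bg_pos, span_lo)
    in_span <- k > 0 & bg_pos <= span_hi[pmax(k, 1)]
    bg_pos <- setdiff(bg_pos[!in_span], gene_sites$pos)
    sites <- bind_rows(
      gene_sites,
      tibble(pos = bg_pos, gene = NA_integer_, rel = NA_real_)
    )
    sites <- sites[sites$pos >= 0 & sites$pos < cfg$chrom_length, ]
    ord <- order(sites$pos)
    sites <- sites[ord, ]
    n_sites <- nrow(sites)

    # mean methylation per site: gene-specific plateau/trough through the
    # shared dip shape (no treatment shift yet)
    depth <- cfg$plateau_meth - cfg$trough_meth
    shape <- if (depth > 1e-12) {
      (cfg$plateau_meth - mean_meth_profile(sites$rel, cfg)) / depth
    } else {
      rep(0, nrow(sites))
    }
    shape[is.na(sites$rel)] <- 0
    g <- sites$gene
    p_site <- ifelse(is.na(g), cfg$plateau_meth, plateau_g[g])
    t_site <- ifelse(is.na(g), cfg$trough_meth, trough_g[g])
    mu0 <- p_site - (p_site - t_site) * shape

    # treatment shift: Day28 pools, window-local
    shifted_pool <- pools$timepoint == "Day28"
    site_shift <- numeric(n_sites)
    if (nrow(dm_genes) > 0) {
      dmi <- match(dm_genes$gene_id, annotation$gene_id)
      for (k in seq_len(nrow(dm_genes))) {
        in_win <- !is.na(sites$gene) & sites$gene == dmi[k] &
          sites$rel >= dm_genes$rel_start[k] & sites$rel < dm_genes$rel_end[k]
        site_shift[in_win] <- dm_genes$sign[k] * cfg$dm_effect / 100
      }
    }

    # site x pool mean, coverage, beta-binomial counts
    mu <- matrix(mu0, n_sites, n_pool)
    if (any(site_shift != 0)) {
      mu[, shifted_pool] <- pmin(pmax(mu[, shifted_pool] + site_shift,
                                      0.001), 0.999)
    }
    cov_mean <- rep(cfg$mean_coverage, n_pool)
    if (cfg$pool_noise_sd > 0) {
      cov_mean <- cov_mean * exp(stats::rnorm(n_pool, 0, cfg$pool_noise_sd))
    }
    coverage <- matrix(
      stats::rpois(n_sites * n_pool, rep(cov_mean, each = n_sites)),
      n_sites, n_pool
    )
    rho <- cfg$biol_dispersion_meth
    p <- if (rho > 0) {
      s <- (1 - rho) / rho
      matrix(stats::rbeta(n_sites * n_pool, mu * s, (1 - mu) * s),
             n_sites, n_pool)
    } else {
      mu
    }
    meth <- matrix(stats::rbinom(n_sites * n_pool, coverage, p),
                   n_sites, n_pool)
    unmeth <- coverage - meth
    colnames(meth) <- colnames(unmeth) <- pools$pool_id

    counts <- cpg_counts(
      tibble(chrom = annotation$chrom[1], pos = sites$pos),
      meth, unmeth, pools
    )

    # truth: promoter-mean methylation percent per gene x pool (with shift)
    in_prom <- !is.na(sites$gene) &
      sites$rel >= -th$promoter_upstream & sites$rel < th$promoter_downstream
    prom_group <- factor(sites$gene[in_prom], levels = seq_len(n_genes))
    prom_mean <- rowsum(mu[in_prom, , drop = FALSE], prom_group) /
      pmax(as.vector(table(prom_group)), 1)
    promoter_meth <- 100 * prom_mean
    rownames(promoter_meth) <- annotation$gene_id
    colnames(promoter_meth) <- pools$pool_id

    # regulatory element: promoter baseline + full window shift
    mu_base <- matrix(mu0, n_sites, n_pool)
    prom_base <- rowsum(mu_base[in_prom, , drop = FALSE], prom_group) /
      pmax(as.vector(table(prom_group)), 1)
    regulatory_meth <- 100 * prom_base
    if (nrow(dm_genes) > 0) {
      dmi <- match(dm_genes$gene_id, annotation$gene_id)
      regulatory_meth[dmi, shifted_pool] <-
        regulatory_meth[dmi, shifted_pool] + dm_genes$sign * cfg$dm_effect
      regulatory_meth <- pmin(pmax(regulatory_meth, 0), 100)
    }
    rownames(regulatory_meth) <- annotation$gene_id
    colnames(regulatory_meth) <- pools$pool_id

    list(
      counts = counts,
      truth = list(
        dm_genes = dm_genes,
        promoter_meth = promoter_meth,
        regulatory_meth = regulatory_meth,
        gene_levels = gene_levels
      )
    )
  })
}

#' Simulate gene expression counts
#'
#' Draws negative-binomial counts whose mean follows
#' `log2 mu = baseline_g + coupling_slope * regulatory methylation %` for
#' coupled genes (a `coupling_fraction` random subset) and `baseline_g`
#' alone for the rest; `de_fraction` of the uncoupled genes additionally
#' receive an independent log2 fold change of `de_lfc` (random sign) in
#' Day28 pools. Counts are scaled by per-pool library size offsets.
#'
#' @param annotation Annotation tibble.
#' @param meth_truth The `truth` element of [simulate_methylation()] (its
#'   `regulatory_meth` matrix supplies each gene's true regulatory
#'   methylation percent per pool).
#' @param cfg A [sim_config()].
#' @param pools Pool table matching `meth_truth`.
#'
#' @return A list with `counts` (an [expression_counts()]) and `truth`
#'   (tibble `gene_id`, `coupled`, `de`, `de_lfc`, `baseline_log2`).
#' @export
simulate_expression <- function(annotation, meth_truth, cfg,
                                pools = experiment_pools(
                                  pools_per_cell = cfg$pools_per_cell
                                )) {
  stopifnot(inherits(cfg, "sim_config"))
  n_genes <- nrow(annotation)
  reg <- meth_truth$regulatory_meth
  stopifnot(nrow(reg) == n_genes, ncol(reg) == nrow(pools))
  withr::with_seed(cfg$seed + 2L, {
    baseline <- stats::rnorm(n_genes, cfg$baseline_log2_mean,
                             cfg$baseline_log2_sd)
    coupled <- rep(FALSE, n_genes)
    n_coupled <- floor(cfg$coupling_fraction * n_genes)
    if (n_coupled > 0) coupled[sample.int(n_genes, n_coupled)] <- TRUE
    de <- rep(FALSE, n_genes)
    de_lfc <- rep(0, n_genes)
    uncoupled_idx <- which(!coupled)
    n_de <- floor(cfg$de_fraction * length(uncoupled_idx))
    if (n_de > 0) {
      de_idx <- sample(uncoupled_idx, n_de)
      de[de_idx] <- TRUE
      de_lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) * cfg$de_lfc
    }
    shifted_pool <- pools$timepoint == "Day28"

    log2mu <- matrix(baseline, n_genes, nrow(pools))
    # centred coupling: the mean methylation level is absorbed into the
    # baseline so coupled genes are not systematically offset; per-gene
    # slopes and all fold changes are unchanged
    log2mu[coupled, ] <- log2mu[coupled, , drop = FALSE] +
      cfg$coupling_slope * (reg[coupled, , drop = FALSE] - mean(reg))
    log2mu[de, shifted_pool] <- log2mu[de, shifted_pool, drop = FALSE] +
      de_lfc[de]

    lib <- cfg$mean_lib_size * stats::runif(nrow(pools), 0.7, 1.3)
    # fixed denominator so injected log fold changes are exact
    denom <- sum(2^baseline)
    mu <- sweep(2^log2mu, 2, lib, `*`) / denom
    counts <- if (cfg$expr_dispersion > 0) {
      matrix(stats::rnbinom(length(mu), mu = mu,
                            size = 1 / cfg$expr_dispersion),
             n_genes, nrow(pools))
    } else {
      matrix(stats::rpois(length(mu), mu), n_genes, nrow(pools))
    }
    rownames(counts) <- annotation$gene_id
    colnames(counts) <- pools$pool_id
    list(
      counts = expression_counts(counts, pools),
      truth = tibble(
        gene_id = annotation$gene_id,
        coupled = coupled,
        de = de,
        de_lfc = de_lfc,
        baseline_log2 = baseline
      )
    )
  })
}

#' Simulate a complete joint experiment
#'
#' Convenience wrapper running [simulate_annotation()],
#' [simulate_methylation()] and [simulate_expression()] under one
#' configuration.
#'
#' @param cfg A [sim_config()].
#' @return A list: `annotation`, `pools`, `comparisons`, `methylation`
#'   (a [cpg_counts()]), `expression` (an [expression_counts()]), and
#'   `truth` (methylation and expression truth tables).
#' @export
#' @examples
#' sim <- simulate_experiment(sim_config(seed = 1, n_genes = 20))
#' sim$methylation
simulate_experiment <- function(cfg = sim_config()) {
  pools <- experiment_pools(pools_per_cell = cfg$pools_per_cell)
  annotation <- simulate_annotation(cfg)
  meth <- simulate_methylation(annotation, cfg, pools)
  expr <- simulate_expression(annotation, meth$truth, cfg, pools)
  list(
    annotation = annotation,
    pools = pools,
    comparisons = standard_comparisons(pools),
    methylation = meth$counts,
    expression = expr$counts,
    truth = c(meth$truth, list(expression = expr$truth))
  )
}
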