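#' Filter lowly expressed genes
#'
#' Keeps genes whose counts-per-million reach `min_cpm` in at least
#' `min_pools` pools. `min_pools` defaults to the smallest group size of
#' the design (genotype x time-point cells if the pool table carries them,
#' otherwise 1). Deterministic.
#'
#' @param x An [expression_counts()] object.
#' @param min_cpm CPM threshold (default 1; 0 keeps everything).
#' @param min_pools Minimum number of pools reaching the threshold.
#' @return A filtered [expression_counts()] object. The pre-filter number
#'   of genes is kept in the `total_transcripts` attribute (used as the
#'   default percentage denominator by [summarize_de()]).
#' @export
filter_expressed <- function(x, min_cpm = 1, min_pools = NULL) {
  stopifnot(inherits(x, "expression_counts"))
  if (is.null(min_pools)) {
    min_pools <- if (all(c("genotype", "timepoint") %in% names(x$pools))) {
      min(table(paste(x$pools$genotype, x$pools$timepoint)))
    } else {
      1L
    }
  }
  cpm <- sweep(x$counts, 2, x$lib_sizes / 1e6, `/`)
  keep <- rowSums(cpm >= min_cpm) >= min_pools
  total <- nrow(x$counts)
  out <- expression_counts(x$counts[keep, , drop = FALSE], x$pools,
                           x$norm_factors)
  attr(out, "total_transcripts") <- total
  out
}

# Trimmed mean of M-values between one pool and the reference.
tmm_pair <- function(y, n, y_ref, n_ref,
                     logratio_trim = 0.3, sum_trim = 0.05) {
  pos <- y > 0 & y_ref > 0
  y <- y[pos]; y_ref <- y_ref[pos]
  if (length(y) == 0) return(1)
  m <- log2((y / n) / (y_ref / n_ref))
  a <- 0.5 * log2((y / n) * (y_ref / n_ref))
  # inverse asymptotic variance of M (delta method, binomial sampling)
  w <- 1 / ((n - y) / (n * y) + (n_ref - y_ref) / (n_ref * y_ref))
  if (max(abs(m)) < 1e-6) return(1)
  ng <- length(m)
  lo_l <- floor(ng * logratio_trim) + 1
  hi_l <- ng + 1 - lo_l
  lo_s <- floor(ng * sum_trim) + 1
  hi_s <- ng + 1 - lo_s
  keep <- rank(m, ties.method = "first") >= lo_l &
    rank(m, ties.method = "first") <= hi_l &
    rank(a, ties.method = "first") >= lo_s &
    rank(a, ties.method = "first") <= hi_s
  if (sum(keep) < 20) {
    warning("fewer than 20 genes survive TMM trimming; ",
            "using the untrimmed weighted mean", call. = FALSE)
    keep <- rep(TRUE, ng)
  }
  f <- 2^(sum(w[keep] * m[keep]) / sum(w[keep]))
  if (!is.finite(f) || f <= 0) 1 else f
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes between-pool composition normalization factors: the reference
#' pool is the one whose upper-quartile count rate is closest to the mean
#' upper quartile (smallest index on ties); for every other pool the factor
#' is two to the power of the weighted mean of gene-wise log2 rate ratios
#' (M values), computed over genes positive in both pools after trimming
#' the 30% tails of M and the 5% tails of average abundance A, with
#' inverse-asymptotic-variance weights. Factors are rescaled to geometric
#' mean 1.
#'
#' @param x An [expression_counts()] object (ideally after
#'   [filter_expressed()]).
#' @return `x` with `norm_factors` set.
#' @export
tmm_factors <- function(x) {
  stopifnot(inherits(x, "expression_counts"))
  f <- tmm_norm_factors(x$counts, x$lib_sizes)
  x$norm_factors <- f
  x
}

#' @rdname tmm_factors
#' @param counts Gene x pool count matrix.
#' @param lib_sizes Column sums (or externally supplied library sizes).
#' @return For `tmm_norm_factors`: a named numeric vector of factors.
#' @export
tmm_norm_factors <- function(counts, lib_sizes = colSums(counts)) {
  if (ncol(counts) < 2) stop("TMM needs at least two pools")
  uq <- vapply(seq_len(ncol(counts)), function(j) {
    stats::quantile(counts[, j] / lib_sizes[j], 0.75, names = FALSE)
  }, numeric(1))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    tmm_pair(counts[, j], lib_sizes[j], counts[, ref], lib_sizes[ref])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' log2 counts per million
#'
#' `log2( (count + prior * L_i / mean(L)) / (L_i + 2 * prior * L_i /
#' mean(L)) * 1e6 )` with `L_i` the effective library size (library size
#' times normalization factor). Monotone in the count; the prior keeps
#' zero counts finite.
#'
#' @param x An [expression_counts()] object with normalization factors set.
#' @param prior Prior count (default 2; must be positive).
#' @return A tibble: `gene_id` plus one log2-CPM column per pool.
#' @export
log_cpm <- function(x, prior = 2) {
  stopifnot(inherits(x, "expression_counts"), prior > 0)
  ll <- x$lib_sizes * x$norm_factors
  pr <- prior * ll / mean(ll)
  m <- log2(sweep(sweep(x$counts, 2, pr, `+`), 2, ll + 2 * pr, `/`) * 1e6)
  bind_cols(tibble(gene_id = rownames(x$counts)), as_tibble(m))
}

# gene x pool log2-CPM as a matrix (internal convenience)
log_cpm_matrix <- function(x, prior = 2) {
  d <- log_cpm(x, prior)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene_id
  m
}

# Negative-binomial profile log-likelihood (with Cox-Reid adjustment) of
# one dispersion value, per gene, given group-wise ratio-estimated means.
nb_profile_ll <- function(counts, mu, groups, phi) {
  size <- 1 / max(phi, 1e-8)
  ll <- rowSums(stats::dnbinom(counts, size = size, mu = pmax(mu, 1e-10),
                               log = TRUE))
  # Cox-Reid: -0.5 * log det of the mean-parameter information, block
  # diagonal by group: sum_j mu_ij / (1 + phi * mu_ij) within each group.
  adj <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    w <- mu[, idx, drop = FALSE] / (1 + phi * mu[, idx, drop = FALSE])
    sw <- rowSums(w)
    adj <- adj + 0.5 * log(pmax(sw, 1e-300)) * (rowSums(mu[, idx, drop = FALSE]) > 0)
  }
  ll - adj
}

#' Estimate negative-binomial dispersion
#'
#' Estimates a common dispersion by maximizing the Cox-Reid adjusted
#' negative-binomial profile log-likelihood, summed over genes, on a
#' 61-point log-spaced grid from 1e-4 to 10 followed by golden-section
#' refinement; gene-wise dispersions are maximized on the same grid and
#' shrunk toward the common value with a prior weight equivalent to 10
#' residual degrees of freedom. Group means are ratio estimates (group
#' total over group library total, scaled by library size), a simplified
#' stand-in for full GLM fits at each candidate dispersion.
#'
#' @param x An [expression_counts()] object.
#' @param groups Factor (or coercible) of length `ncol` assigning pools to
#'   groups; default: genotype x time-point cells from the pool table.
#' @return An object of class `nb_dispersion`: list with `common`,
#'   `tagwise` (named per gene), `prior_df`, `residual_df`.
#' @export
estimate_dispersion <- function(x, groups = NULL) {
  stopifnot(inherits(x, "expression_counts"))
  if (is.null(groups)) {
    groups <- if (all(c("genotype", "timepoint") %in% names(x$pools))) {
      paste(x$pools$genotype, x$pools$timepoint)
    } else {
      rep("all", ncol(x$counts))
    }
  }
  groups <- factor(groups)
  n <- ncol(x$counts)
  resid_df <- n - nlevels(groups)
  if (resid_df <= 0) {
    warning("no residual degrees of freedom; ",
            "falling back to default dispersion 0.1", call. = FALSE)
    return(structure(
      list(common = 0.1,
           tagwise = setNames(rep(0.1, nrow(x$counts)), rownames(x$counts)),
           prior_df = 10, residual_df = resid_df),
      class = "nb_dispersion"
    ))
  }
  offs <- x$lib_sizes * x$norm_factors
  counts <- x$counts
  mu <- matrix(0, nrow(counts), n)
  for (g in levels(groups)) {
    idx <- which(groups == g)
    rate <- rowSums(counts[, idx, drop = FALSE]) / sum(offs[idx])
    mu[, idx] <- outer(rate, offs[idx])
  }
  grid <- exp(seq(log(1e-4), log(10), length.out = 61))
  ll_mat <- vapply(grid, function(phi) nb_profile_ll(counts, mu, groups, phi),
                   numeric(nrow(counts)))
  tot <- colSums(ll_mat)
  k <- which.max(tot)
  lo <- grid[max(k - 1, 1)]
  hi <- grid[min(k + 1, length(grid))]
  common <- stats::optimize(
    function(lphi) sum(nb_profile_ll(counts, mu, groups, exp(lphi))),
    lower = log(lo), upper = log(hi), maximum = TRUE, tol = 1e-4
  )
  common <- exp(common$maximum)
  tag_mle <- grid[max.col(ll_mat, ties.method = "first")]
  prior_df <- 10
  tagwise <- (resid_df * tag_mle + prior_df * common) / (resid_df + prior_df)
  structure(
    list(common = common,
         tagwise = setNames(tagwise, rownames(counts)),
         prior_df = prior_df, residual_df = resid_df),
    class = "nb_dispersion"
  )
}

#' @export
print.nb_dispersion <- function(x, ...) {
  cat("<nb_dispersion> common =", signif(x$common, 4),
      "| tagwise median =", signif(stats::median(x$tagwise), 4),
      "| prior df =", x$prior_df, "\n")
  invisible(x)
}

# One-gene NB GLM likelihood-ratio test of the group effect.
nb_gene_lrt <- function(y, group01, log_off, theta) {
  fam <- MASS::negative.binomial(theta = theta)
  full <- stats::glm.fit(cbind(1, group01), y, offset = log_off,
                         family = fam)
  null <- stats::glm.fit(matrix(1, length(y)), y, offset = log_off,
                         family = fam)
  c(lrt = max(null$deviance - full$deviance, 0),
    log2_fc = full$coefficients[2] / log(2))
}

#' Two-group negative-binomial differential expression
#'
#' Per gene, fits the NB log-linear model with a group effect and
#' log-effective-library-size offsets at the gene's (shrunk tagwise)
#' dispersion and tests the group coefficient with a likelihood-ratio test
#' (chi-square, 1 df). P-values are BH-adjusted; genes are called `up` /
#' `down` at `fdr < fdr_cut` by the sign of the log2 fold change
#' (B versus A).
#'
#' @param x An [expression_counts()] object (filtered, with normalization
#'   factors).
#' @param group_a,group_b Character vectors of pool ids.
#' @param dispersion Optional [estimate_dispersion()] result; default:
#'   estimated on the two comparison groups.
#' @param fdr_cut FDR threshold for calls (default 0.05).
#' @param label Optional comparison label stored as an attribute.
#'
#' @return A tibble with one row per gene: `gene_id`, `log2_fc`,
#'   `log2_cpm_mean`, `lrt`, `p_value`, `fdr`, `call`. Genes with zero
#'   counts in every pool of both groups are skipped.
#' @export
de_test <- function(x, group_a, group_b, dispersion = NULL,
                    fdr_cut = 0.05, label = NULL) {
  stopifnot(inherits(x, "expression_counts"))
  pool_ids <- c(group_a, group_b)
  idx <- match(pool_ids, colnames(x$counts))
  if (anyNA(idx)) stop("unknown pool id(s)")
  counts <- x$counts[, idx, drop = FALSE]
  offs <- (x$lib_sizes * x$norm_factors)[idx]
  group01 <- rep(c(0, 1), c(length(group_a), length(group_b)))
  if (is.null(dispersion)) {
    sub <- expression_counts(counts, x$pools[idx, ],
                             x$norm_factors[idx])
    sub$lib_sizes <- x$lib_sizes[idx]  # keep original depths
    dispersion <- estimate_dispersion(sub, groups = group01)
  }
  phi <- dispersion$tagwise[rownames(counts)]
  phi[is.na(phi)] <- dispersion$common
  keep <- rowSums(counts) > 0
  log_off <- log(offs)
  fits <- t(vapply(which(keep), function(i) {
    nb_gene_lrt(counts[i, ], group01, log_off,
                theta = 1 / max(phi[i], 1e-8))
  }, c(lrt = 0, log2_fc = 0)))
  lcpm <- log_cpm_matrix(expression_counts(counts, x$pools[idx, ],
                                           x$norm_factors[idx]))
  p <- stats::pchisq(fits[, "lrt"], df = 1, lower.tail = FALSE)
  out <- tibble(
    gene_id = rownames(counts)[keep],
    log2_fc = fits[, "log2_fc"],
    log2_cpm_mean = rowMeans(lcpm[keep, , drop = FALSE]),
    lrt = fits[, "lrt"],
    p_value = p,
    fdr = adjust_pvalues(p)
  )
  out$call <- dplyr::case_when(
    out$fdr < fdr_cut & out$log2_fc > 0 ~ "up",
    out$fdr < fdr_cut & out$log2_fc < 0 ~ "down",
    TRUE ~ "ns"
  )
  attr(out, "comparison") <- label
  attr(out, "dispersion") <- dispersion
  out
}

#' Summarize differential expression calls
#'
#' Down/up-regulated counts and their percentages of the transcript
#' universe, rounded to two decimals as printed in per-comparison summary
#' tables.
#'
#' @param results A [de_test()] result.
#' @param total_transcripts Denominator; default: the pre-filter universe
#'   recorded by [filter_expressed()] if present, otherwise the number of
#'   tested genes.
#' @return A one-row tibble: `down`, `up`, `down_pct`, `up_pct`.
#' @export
summarize_de <- function(results, total_transcripts = NULL) {
  if (is.null(total_transcripts)) total_transcripts <- nrow(results)
  if (total_transcripts == 0) stop("total_transcripts must be positive")
  down <- sum(results$call == "down")
  up <- sum(results$call == "up")
  tibble(
    down = down, up = up,
    down_pct = round(100 * down / total_transcripts, 2),
    up_pct = round(100 * up / total_transcripts, 2)
  )
}
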