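#' Filter CpG sites on per-pool coverage
#'
#' Retains exactly the sites whose total read coverage is at least
#' `min_coverage` in every pool, so that all downstream units have adequate
#' coverage in all samples. Order is preserved; an empty result is allowed.
#'
#' @param x A [cpg_counts()] object.
#' @param min_coverage Minimum coverage per pool (default 10).
#' @return A filtered [cpg_counts()] object.
#' @export
filter_coverage <- function(x, min_coverage = 10) {
  stopifnot(inherits(x, "cpg_counts"))
  cov <- x$meth + x$unmeth
  keep <- rowSums(cov >= min_coverage) == ncol(cov)
  x$sites <- x$sites[keep, , drop = FALSE]
  x$meth <- x$meth[keep, , drop = FALSE]
  x$unmeth <- x$unmeth[keep, , drop = FALSE]
  x
}

#' Normalize coverage across pools
#'
#' Scales each pool's counts by
#' `s_i = median(pool median coverages) / (pool i median coverage)`,
#' rounding half-up, so pools sequenced deeper do not dominate aggregated
#' statistics. Methylation fractions are preserved up to rounding.
#'
#' @param x A [cpg_counts()] object (typically after [filter_coverage()]).
#' @return A [cpg_counts()] object with scaled counts.
#' @export
normalize_coverage <- function(x) {
  stopifnot(inherits(x, "cpg_counts"))
  if (nrow(x$sites) == 0) return(x)
  cov <- x$meth + x$unmeth
  med <- apply(cov, 2, stats::median)
  if (any(med == 0)) {
    stop("pool(s) with zero median coverage: ",
         paste(colnames(cov)[med == 0], collapse = ", "))
  }
  s <- stats::median(med) / med
  round_half_up <- function(v) floor(v + 0.5)
  x$meth <- round_half_up(sweep(x$meth, 2, s, `*`))
  x$unmeth <- round_half_up(sweep(x$unmeth, 2, s, `*`))
  storage.mode(x$meth) <- "integer"
  storage.mode(x$unmeth) <- "integer"
  x
}

#' Two-group differential methylation test with overdispersion correction
#'
#' For each unit (CpG site or aggregated window), fits the binomial
#' logistic regression `logit(p) = b0 + b1 * group` by maximum likelihood
#' over the pools' (methylated, coverage) observations and tests `b1 = 0`
#' with a likelihood-ratio statistic. Because group is the only covariate,
#' the fitted values are the coverage-pooled group proportions, which the
#' implementation exploits in closed form. Overdispersion is estimated per
#' unit as the Pearson chi-square of the full model divided by its residual
#' degrees of freedom, floored at 1; the corrected statistic is
#' LRT / phi-hat, referred to chi-square with 1 df. Fitted proportions are
#' clipped so the group-effect coefficient satisfies `|b1| <= 20`
#' (complete-separation guard).
#'
#' @param meth_a,unmeth_a Matrices (units x pools) of group-A counts;
#'   vectors are treated as single-pool matrices.
#' @param meth_b,unmeth_b Group-B counts, same layout.
#' @param correct Apply the overdispersion correction (default `TRUE`);
#'   with `FALSE` the uncorrected LRT p-value is reported in `p_value`.
#'
#' @return A tibble with one row per unit: `meth_percent_a`,
#'   `meth_percent_b` (coverage-weighted pooled percentages), `meth_diff`
#'   (B minus A, percentage points), `lrt` (uncorrected statistic),
#'   `overdispersion` (phi-hat), `statistic` (corrected), `p_value`,
#'   and `p_raw` (uncorrected p). Units with zero total coverage in either
#'   group get `NA` results (callers skip them with a log message).
#' @export
#' @examples
#' dm_test(matrix(c(8, 9), 1), matrix(c(2, 1), 1),
#'         matrix(c(2, 1), 1), matrix(c(8, 9), 1))
dm_test <- function(meth_a, unmeth_a, meth_b, unmeth_b, correct = TRUE) {
  as_mat <- function(m) if (is.matrix(m)) m else matrix(m, nrow = 1)
  meth_a <- as_mat(meth_a); unmeth_a <- as_mat(unmeth_a)
  meth_b <- as_mat(meth_b); unmeth_b <- as_mat(unmeth_b)
  cov_a <- meth_a + unmeth_a
  cov_b <- meth_b + unmeth_b
  ma <- rowSums(meth_a); ca <- rowSums(cov_a)
  mb <- rowSums(meth_b); cb <- rowSums(cov_b)
  testable <- ca > 0 & cb > 0

  p_a <- ifelse(ca > 0, ma / ca, NA_real_)
  p_b <- ifelse(cb > 0, mb / cb, NA_real_)
  p_0 <- (ma + mb) / pmax(ca + cb, 1)

  # clip fitted proportions: |logit| <= 20
  lo <- stats::plogis(-20); hi <- stats::plogis(20)
  clip <- function(p) pmin(pmax(p, lo), hi)
  pa_c <- clip(p_a); pb_c <- clip(p_b); p0_c <- clip(p_0)

  ll <- function(m, c, p) m * log(p) + (c - m) * log1p(-p)
  ll_full <- ll(ma, ca, pa_c) + ll(mb, cb, pb_c)
  ll_null <- ll(ma, ca, p0_c) + ll(mb, cb, p0_c)
  lrt <- pmax(2 * (ll_full - ll_null), 0)

  # Pearson X^2 of the full model over pools with coverage > 0
  pearson_x2 <- function(meth, cov, p_fit) {
    e <- cov * p_fit
    v <- cov * p_fit * (1 - p_fit)
    term <- (meth - e)^2 / v
    term[cov == 0] <- 0
    rowSums(term)
  }
  x2 <- pearson_x2(meth_a, cov_a, pa_c) + pearson_x2(meth_b, cov_b, pb_c)
  df <- rowSums(cov_a > 0) + rowSums(cov_b > 0) - 2
  phi <- ifelse(df > 0, pmax(x2 / df, 1), 1)

  stat <- if (correct) lrt / phi else lrt
  p_value <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p_raw <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  out <- tibble(
    meth_percent_a = 100 * p_a,
    meth_percent_b = 100 * p_b,
    meth_diff = 100 * (p_b - p_a),
    lrt = lrt,
    overdispersion = phi,
    statistic = stat,
    p_value = p_value,
    p_raw = p_raw
  )
  out[!testable, ] <- NA
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment (`stats::p.adjust`, method
#' `"BH"`): monotone in the p-value ranks and elementwise at least the raw
#' p-value. Computed across all tested units of a comparison (genome-wide).
#'
#' @param p Vector of p-values in `[0, 1]`; `NA`s are propagated.
#' @return Vector of q-values.
#' @export
adjust_pvalues <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  stats::p.adjust(p, method = "BH")
}

#' Call differential methylation
#'
#' Applies the dual threshold: a unit is significant iff `q_value < q_cut`
#' and `|meth_diff| >= diff_cut`; significant units are labelled `hyper`
#' (methylation higher in group B) or `hypo` by the sign of `meth_diff`,
#' all others `ns`.
#'
#' @param results Tibble with `meth_diff` and `q_value` columns.
#' @param q_cut q-value cutoff (default 0.01).
#' @param diff_cut Minimum absolute methylation difference in percentage
#'   points (default 25); set to 0 to disable the effect-size filter.
#' @return `results` with a `call` column added.
#' @export
call_dm <- function(results, q_cut = 0.01, diff_cut = 25) {
  sig <- !is.na(results$q_value) & results$q_value < q_cut &
    abs(results$meth_diff) >= diff_cut
  results$call <- dplyr::case_when(
    sig & results$meth_diff > 0 ~ "hyper",
    sig & results$meth_diff < 0 ~ "hypo",
    TRUE ~ "ns"
  )
  results
}

#' Per-CpG differential methylation for one comparison
#'
#' Runs [dm_test()] on every CpG site for the two pool groups of a
#' comparison, adjusts p-values genome-wide with [adjust_pvalues()], and
#' calls hyper-/hypomethylation with [call_dm()]. Sites with zero total
#' coverage in either group are skipped (their count is reported in a
#' message and in the `skipped` attribute).
#'
#' @param x A filtered, normalized [cpg_counts()] object.
#' @param group_a,group_b Character vectors of pool ids.
#' @param q_cut,diff_cut Thresholds passed to [call_dm()].
#' @param label Optional comparison label stored as an attribute.
#'
#' @return A tibble with one row per tested CpG: `chrom`, `pos`,
#'   `unit_id`, the [dm_test()] columns, `q_value` and `call`.
#' @export
diff_methylation <- function(x, group_a, group_b,
                             q_cut = 0.01, diff_cut = 25, label = NULL) {
  stopifnot(inherits(x, "cpg_counts"))
  a <- subset_pools(x, group_a)
  b <- subset_pools(x, group_b)
  res <- dm_test(a$meth, a$unmeth, b$meth, b$unmeth)
  keep <- !is.na(res$p_value)
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    message(n_skip, " unit(s) skipped: zero coverage in one group")
  }
  out <- bind_cols(
    tibble(
      chrom = x$sites$chrom,
      pos = x$sites$pos,
      unit_id = paste0(x$sites$chrom, ":", x$sites$pos)
    ),
    res
  )[keep, ]
  out$q_value <- adjust_pvalues(out$p_value)
  out <- call_dm(out, q_cut = q_cut, diff_cut = diff_cut)
  attr(out, "comparison") <- label
  attr(out, "skipped") <- n_skip
  out
}

#' Summarize differential methylation calls
#'
#' Counts of significant units split by direction, in the layout of a
#' per-comparison summary row (total, hypomethylated, hypermethylated).
#'
#' @param results A tibble with a `call` column ([call_dm()] output).
#' @return A one-row tibble: `total`, `hypo`, `hyper`.
#' @export
summarize_dm <- function(results) {
  tibble(
    total = sum(results$call != "ns"),
    hypo = sum(results$call == "hypo"),
    hyper = sum(results$call == "hyper")
  )
}
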