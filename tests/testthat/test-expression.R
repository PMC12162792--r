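make_expr <- function(counts) {
  rownames(counts) <- sprintf("g%04d", seq_len(nrow(counts)))
  colnames(counts) <- paste0("p", seq_len(ncol(counts)))
  expression_counts(counts, tibble::tibble(pool_id = colnames(counts)))
}

test_that("expression filtering keeps genes reaching min CPM in enough pools", {
  m <- rbind(
    c(0L, 0L),          # all zero -> removed
    c(150L, 2L),        # CPM (1500, 20) at lib ~1e5? depends; see below
    c(60L, 60L)
  )
  x <- make_expr(m)
  # min_cpm = 0 is the identity
  f0 <- filter_expressed(x, min_cpm = 0, min_pools = 1)
  expect_equal(nrow(f0$counts), 3)
  f <- filter_expressed(x, min_cpm = 1, min_pools = 2)
  expect_false("g0001" %in% rownames(f$counts))
  expect_equal(attr(f, "total_transcripts"), 3)

  # a gene above threshold in only one pool fails min_pools = 2
  m2 <- rbind(c(1000L, 0L), c(1000L, 1000L))
  x2 <- make_expr(m2)
  f2 <- filter_expressed(x2, min_cpm = 1, min_pools = 2)
  expect_equal(rownames(f2$counts), "g0002")
})

test_that("TMM factors are 1 for identical and depth-scaled columns", {
  set.seed(1)
  base <- as.integer(rnbinom(500, mu = exp(rnorm(500, 5, 1.5)), size = 10)) + 1L
  x <- make_expr(cbind(base, base))
  expect_equal(unname(tmm_norm_factors(x$counts)), c(1, 1), tolerance = 1e-12)
  # pure depth: column 2 = 2 x column 1 -> M identically 0 -> factors (1, 1)
  x2 <- make_expr(cbind(base, 2L * base))
  expect_equal(unname(tmm_norm_factors(x2$counts)), c(1, 1), tolerance = 1e-12)
})

test_that("TMM matches an independent brute-force trimmed weighted mean", {
  set.seed(5)
  mu <- exp(rnorm(2000, 5, 1.5))
  m <- matrix(rnbinom(2000 * 2, mu = rep(mu, 2), size = 10), 2000, 2)
  m[1:200, 2] <- m[1:200, 2] * 8L   # composition shift
  x <- make_expr(m)
  f <- tmm_norm_factors(x$counts)

  # brute force, written independently of the implementation
  n1 <- sum(m[, 1]); n2 <- sum(m[, 2])
  uq <- c(quantile(m[, 1] / n1, 0.75), quantile(m[, 2] / n2, 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  oth <- 3 - ref
  keep0 <- m[, 1] > 0 & m[, 2] > 0
  y <- m[keep0, oth]; yr <- m[keep0, ref]
  nn <- sum(m[, oth]); nr <- sum(m[, ref])
  M <- log2((y / nn) / (yr / nr))
  A <- 0.5 * log2((y / nn) * (yr / nr))
  w <- 1 / ((nn - y) / (nn * y) + (nr - yr) / (nr * yr))
  ng <- length(M)
  loL <- floor(ng * 0.3) + 1; hiL <- ng + 1 - loL
  loS <- floor(ng * 0.05) + 1; hiS <- ng + 1 - loS
  rM <- rank(M, ties.method = "first"); rA <- rank(A, ties.method = "first")
  keep <- rM >= loL & rM <= hiL & rA >= loS & rA <= hiS
  f_oth <- 2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  raw <- c(1, 1); raw[oth] <- f_oth
  expected <- raw / exp(mean(log(raw)))
  expect_equal(unname(f), unname(expected), tolerance = 1e-6)
})

test_that("TMM agrees with the reference implementation on clean data", {
  skip_if_not_installed("edgeR")
  set.seed(7)
  mu <- exp(rnorm(1500, 5, 1.5))
  m <- matrix(rnbinom(1500 * 4, mu = rep(mu, 4), size = 10), 1500, 4)
  m[1:150, 2] <- m[1:150, 2] * 8L
  x <- make_expr(m)
  f_ours <- tmm_norm_factors(x$counts)
  f_edger <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(unname(f_ours), unname(f_edger), tolerance = 1e-3)
})

test_that("log2 CPM follows the offset formula and is monotone", {
  m <- rbind(c(0L, 0L), c(1000L, 1000L), c(2000L, 2000L))
  x <- make_expr(m)
  lc <- log_cpm(x)
  v <- unname(as.matrix(lc[, -1]))
  # equal library sizes: zero counts give a constant value across pools
  expect_equal(v[1, 1], v[1, 2])
  # doubling a large count raises log2 CPM by ~1
  expect_equal(v[3, 1] - v[2, 1], 1, tolerance = 0.01)
  expect_error(log_cpm(x, prior = 0), "prior")

  # exact formula on one cell
  ll <- x$lib_sizes * x$norm_factors
  pr <- 2 * ll / mean(ll)
  expect_equal(v[2, 1],
               unname(log2((1000 + pr[1]) / (ll[1] + 2 * pr[1]) * 1e6)))
})

test_that("dispersion estimation recovers the simulation truth", {
  set.seed(11)
  mu <- exp(rnorm(2000, 5, 1))
  groups <- rep(c("a", "b"), each = 2)
  # Poisson data: common dispersion pushed to (near) zero
  mp <- matrix(rpois(2000 * 4, rep(mu, 4)), 2000, 4)
  xp <- make_expr(mp)
  dp <- estimate_dispersion(xp, groups)
  expect_lte(dp$common, 0.01)
  # NB with phi = 0.1 recovered within the stated window
  mn <- matrix(rnbinom(2000 * 4, mu = rep(mu, 4), size = 10), 2000, 4)
  xn <- make_expr(mn)
  dn <- estimate_dispersion(xn, groups)
  expect_gte(dn$common, 0.07)
  expect_lte(dn$common, 0.13)
  # duplicating every pool cannot increase the estimate
  xd <- make_expr(cbind(mn, mn))
  dd <- estimate_dispersion(xd, rep(groups, 2))
  expect_lte(dd$common, dn$common + 1e-6)
  # tagwise values are shrunk toward the common value
  expect_lt(stats::sd(dn$tagwise), 0.2)
  expect_true(all(dn$tagwise >= 0))
})

test_that("de_test is symmetric under group relabeling", {
  x <- small_expr()
  fwd <- de_test(x, grp_a, grp_b)
  rev <- de_test(x, grp_b, grp_a)
  expect_equal(fwd$log2_fc, -rev$log2_fc, tolerance = 1e-6)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-6)
  up_fwd <- sum(fwd$call == "up"); down_rev <- sum(rev$call == "down")
  expect_equal(up_fwd, down_rev)
})

test_that("de_test recovers an injected two-fold-per-unit log fold change", {
  # 2 vs 2 pools at ~1e6 depth, phi = 0.05, true |log2 fc| = 2
  cfg <- sim_config(seed = 15, n_genes = 400, dm_fraction = 0,
                    coupling_fraction = 0, de_fraction = 0.25, de_lfc = 2,
                    expr_dispersion = 0.05, mean_lib_size = 1e6)
  sim <- simulate_experiment(cfg)
  x <- tmm_factors(filter_expressed(sim$expression))
  de <- de_test(x, grp_a, grp_b)
  j <- dplyr::inner_join(de, sim$truth$expression, by = "gene_id")
  truth <- j[j$de, ]
  expect_gt(nrow(truth), 50)
  # typical estimation error within 0.3; with phi = 0.05 and two pools per
  # group the intrinsic sd of a per-gene log2 fc is ~ sqrt(phi)/ln 2 = 0.32
  # whatever the depth, so individual genes exceed 0.3 about a third of
  # the time by construction
  err <- abs(truth$log2_fc - truth$de_lfc)
  expect_lt(median(err), 0.3)
  well <- truth$log2_cpm_mean > 3
  expect_gt(sum(well), 30)
  expect_gt(mean(err[well] < 0.3), 0.55)
  expect_lt(mean(err[well]), 0.35)
})

test_that("summary percentages reproduce the printed table arithmetic", {
  res <- tibble::tibble(call = c(rep("down", 253), rep("up", 652)))
  s <- summarize_de(res, total_transcripts = 27856)
  expect_equal(s$down_pct, 0.91)
  expect_equal(s$up_pct, 2.34)
  s0 <- summarize_de(tibble::tibble(call = character()), 27856)
  expect_equal(c(s0$down_pct, s0$up_pct), c(0, 0))
  res2 <- tibble::tibble(call = c(rep("down", 829), rep("up", 1508)))
  s2 <- summarize_de(res2, 27856)
  expect_equal(round(100 * (829 + 1508) / 27856, 2), 8.39)
  expect_error(summarize_de(res, total_transcripts = 0), "positive")
})

test_that("de_test is invariant to gene and pool order", {
  x <- small_expr()
  de1 <- de_test(x, grp_a, grp_b)
  perm <- sample(nrow(x$counts))
  x2 <- expression_counts(x$counts[perm, ], x$pools, x$norm_factors)
  de2 <- de_test(x2, grp_a, grp_b)
  j <- dplyr::inner_join(de1, de2, by = "gene_id")
  expect_equal(j$p_value.x, j$p_value.y, tolerance = 1e-8)
  de3 <- de_test(x, rev(grp_a), rev(grp_b))
  expect_equal(de1$p_value, de3$p_value, tolerance = 1e-8)
})
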