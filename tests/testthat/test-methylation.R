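two_pools <- tibble::tibble(pool_id = c("p1", "p2"))

test_that("coverage filter requires the threshold in every pool", {
  x <- cpg_counts(
    tibble::tibble(chrom = "c", pos = c(10, 20, 30)),
    meth = cbind(p1 = c(6L, 5L, 20L), p2 = c(5L, 5L, 20L)),
    unmeth = cbind(p1 = c(6L, 5L, 0L), p2 = c(4L, 5L, 0L)),
    pools = two_pools
  )
  # coverages: site1 (12, 9) -> removed; site2 (10, 10) -> boundary kept
  f <- filter_coverage(x, 10)
  expect_equal(f$sites$pos, c(20, 30))
  # all-pass input is the identity
  f2 <- filter_coverage(x, 5)
  expect_identical(f2$sites, x$sites)
  expect_identical(f2$meth, x$meth)
})

test_that("coverage normalization follows the median-of-medians formula", {
  # pool medians 10 and 20 -> overall median 15 -> s = (1.5, 0.75)
  x <- cpg_counts(
    tibble::tibble(chrom = "c", pos = c(10, 20, 30)),
    meth = cbind(p1 = c(5L, 5L, 5L), p2 = c(10L, 10L, 10L)),
    unmeth = cbind(p1 = c(5L, 5L, 5L), p2 = c(10L, 10L, 10L)),
    pools = two_pools
  )
  n <- normalize_coverage(x)
  expect_equal(unname(n$meth[1, ]), c(8L, 8L))   # 5*1.5 = 7.5 -> 8 (half-up)
  expect_equal(unname(n$unmeth[1, ]), c(8L, 8L)) # 10*0.75 = 7.5 -> 8
  # fractions preserved
  expect_equal(unname(n$meth[1, ] / (n$meth[1, ] + n$unmeth[1, ])),
               c(0.5, 0.5))

  # identical distributions -> unchanged
  y <- flat_cpg(c(1, 2, 3), two_pools, coverage = 10, frac = 0.5)
  ny <- normalize_coverage(y)
  expect_identical(ny$meth, y$meth)

  # fraction distortion bounded by 1/coverage at every site
  z <- small_sim()$methylation |> filter_coverage()
  nz <- normalize_coverage(z)
  f_before <- z$meth / (z$meth + z$unmeth)
  f_after <- nz$meth / (nz$meth + nz$unmeth)
  bound <- 1 / (z$meth + z$unmeth)
  expect_true(all(abs(f_after - f_before) <= bound + 1e-12))

  # a pool with zero median coverage is an error
  bad <- cpg_counts(
    tibble::tibble(chrom = "c", pos = c(1, 2, 3)),
    meth = cbind(p1 = c(1L, 1L, 1L), p2 = c(0L, 0L, 0L)),
    unmeth = cbind(p1 = c(1L, 1L, 1L), p2 = c(0L, 0L, 1L)),
    pools = two_pools
  )
  expect_error(normalize_coverage(bad), "zero median")
})

test_that("identical groups give zero statistic and p = 1", {
  r <- dm_test(matrix(c(5, 5), 1), matrix(c(5, 5), 1),
               matrix(c(5, 5), 1), matrix(c(5, 5), 1))
  expect_equal(r$meth_diff, 0)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("dm_test matches a brute-force binomial logistic GLM", {
  set.seed(42)
  for (i in 1:40) {
    ca <- rpois(2, 20) + 5; cb <- rpois(2, 20) + 5
    ma <- rbinom(2, ca, runif(1, 0.1, 0.9))
    mb <- rbinom(2, cb, runif(1, 0.1, 0.9))
    r <- dm_test(matrix(ma, 1), matrix(ca - ma, 1),
                 matrix(mb, 1), matrix(cb - mb, 1))
    y <- cbind(c(ma, mb), c(ca - ma, cb - mb))
    g <- factor(c(0, 0, 1, 1))
    full <- glm(y ~ g, family = binomial)
    null <- glm(y ~ 1, family = binomial)
    lrt <- null$deviance - full$deviance
    expect_equal(r$lrt, lrt, tolerance = 1e-6)
    x2 <- sum(residuals(full, "pearson")^2)
    expect_equal(r$overdispersion, max(x2 / 2, 1), tolerance = 1e-6)
    # correction can only move p upward
    expect_gte(r$p_value, r$p_raw - 1e-12)
  }
  # a strongly separated worked contrast
  r <- dm_test(matrix(c(8, 9), 1), matrix(c(2, 1), 1),
               matrix(c(2, 1), 1), matrix(c(8, 9), 1))
  y <- cbind(c(8, 9, 2, 1), c(2, 1, 8, 9))
  g <- factor(c(0, 0, 1, 1))
  lrt <- glm(y ~ 1, family = binomial)$deviance -
    glm(y ~ g, family = binomial)$deviance
  expect_equal(r$lrt, lrt, tolerance = 1e-6)
  expect_equal(r$meth_diff, 100 * (3 / 20 - 17 / 20))
})

test_that("the statistic is monotone in information", {
  r1 <- dm_test(matrix(c(8, 9), 1), matrix(c(2, 1), 1),
                matrix(c(5, 5), 1), matrix(c(5, 5), 1))
  r10 <- dm_test(matrix(c(80, 90), 1), matrix(c(20, 10), 1),
                 matrix(c(50, 50), 1), matrix(c(50, 50), 1))
  expect_gt(r10$lrt, r1$lrt)
  expect_lt(pchisq(r10$lrt, 1, lower.tail = FALSE),
            pchisq(r1$lrt, 1, lower.tail = FALSE))
})

test_that("complete separation is handled via coefficient clipping", {
  r <- dm_test(matrix(c(10, 10), 1), matrix(c(0, 0), 1),
               matrix(c(0, 0), 1), matrix(c(10, 10), 1))
  expect_true(is.finite(r$lrt))
  expect_lt(r$p_raw, 1e-6)
  expect_equal(r$meth_diff, -100)
})

test_that("BH adjustment matches the hand computation", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  p <- runif(100)
  q <- adjust_pvalues(p)
  expect_true(all(q >= p))
  expect_true(all(q[order(p)] == cummax(q[order(p)])) ||
                all(diff(q[order(p)]) >= -1e-12))
})

test_that("calls require both the q-value and the effect-size threshold", {
  res <- tibble::tibble(
    meth_diff = c(30, 10, 40, -30),
    q_value = c(0.005, 0.005, 0.02, 0.005)
  )
  out <- call_dm(res)
  expect_equal(out$call, c("hyper", "ns", "ns", "hypo"))
})

test_that("relabeling the groups swaps hyper and hypo calls exactly", {
  x <- small_cpg()
  fwd <- suppressMessages(diff_methylation(x, grp_a, grp_b, diff_cut = 5,
                                           q_cut = 0.2))
  rev <- suppressMessages(diff_methylation(x, grp_b, grp_a, diff_cut = 5,
                                           q_cut = 0.2))
  sf <- summarize_dm(fwd)
  sr <- summarize_dm(rev)
  expect_equal(sf$total, sr$total)
  expect_equal(sf$hyper, sr$hypo)
  expect_equal(sf$hypo, sr$hyper)
  expect_equal(fwd$meth_diff, -rev$meth_diff)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)
})

test_that("zero-coverage units are skipped with a message", {
  x <- cpg_counts(
    tibble::tibble(chrom = "c", pos = c(1, 2)),
    meth = cbind(p1 = c(5L, 0L), p2 = c(5L, 3L)),
    unmeth = cbind(p1 = c(5L, 0L), p2 = c(5L, 3L)),
    pools = two_pools
  )
  expect_message(
    out <- diff_methylation(x, "p1", "p2"),
    "skipped"
  )
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "skipped"), 1)
})
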