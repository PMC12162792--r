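test_that("a flat methylation landscape gives a flat metaplot", {
  pools <- tibble::tibble(pool_id = c("p1", "p2"))
  ann <- tibble::tibble(gene_id = "g", chrom = "chrS", tss = 50000,
                        strand = "+")
  x <- flat_cpg(seq(45000, 51000, by = 40), pools, coverage = 10, frac = 0.5)
  mp <- metaplot(x, ann)
  expect_true(all(mp$meth_pct == 50))
  expect_true(all(mp$meth_pct_smooth == 50))
  # empty bins are omitted, not zero-filled
  sparse <- flat_cpg(c(49000, 50500), pools, coverage = 10, frac = 0.5)
  mp2 <- metaplot(sparse, ann)
  expect_equal(nrow(mp2), 2)
})

test_that("CpGs are assigned to the nearest TSS with deterministic ties", {
  pools <- tibble::tibble(pool_id = "p1")
  ann <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "chrS",
    tss = c(10000, 20000), strand = c("+", "+")
  )
  # CpG at 14000 nearer gA; at 16000 nearer gB; at 15000 tie -> gA
  x <- flat_cpg(c(14000, 15000, 16000), pools, coverage = 100, frac = 0.2)
  idx <- promethex:::nearest_tss(x$sites, ann)
  expect_equal(ann$gene_id[idx], c("gA", "gA", "gB"))
})

test_that("the static association recovers an exact line", {
  d <- tibble::tibble(meth_pct = c(0, 50, 100), log2_cpm = c(8, 4, 0))
  fit <- static_association(d)
  g <- glance(fit)
  expect_equal(g$slope, -0.08, tolerance = 1e-12)
  expect_equal(g$intercept, 8, tolerance = 1e-12)
  expect_lt(g$p.value, 1e-10)
  td <- tidy(fit)
  expect_equal(unname(td$estimate[td$term == "meth_pct"]), -0.08)
  expect_error(static_association(d[1:2, ]), "at least 3")
})

test_that("tidy/glance agree with the underlying linear model", {
  set.seed(3)
  d <- tibble::tibble(meth_pct = runif(50, 0, 100))
  d$log2_cpm <- 5 - 0.02 * d$meth_pct + rnorm(50)
  fit <- static_association(d)
  ref <- summary(lm(log2_cpm ~ meth_pct, data = d))
  expect_equal(glance(fit)$slope, ref$coefficients[2, 1])
  expect_equal(glance(fit)$p.value, ref$coefficients[2, 4])
  expect_equal(glance(fit)$r.squared, ref$r.squared)
  dens <- association_density(fit)
  expect_equal(sum(dens$n), 50)
})

test_that("delta association skips degenerate regressors and checks labels", {
  win <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:20), window_index = 0L,
    rel_start = -2000, rel_end = -1900, meth_diff = 0
  )
  de <- tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                       log2_fc = rnorm(20))
  out <- delta_association(win, de)
  expect_equal(nrow(out), 0)

  attr(win, "comparison") <- "A vs B"
  attr(de, "comparison") <- "C vs D"
  expect_error(delta_association(win, de), "mismatch")
})

test_that("overlap accounting follows the counting rule", {
  de <- tibble::tibble(gene_id = c("g1", "g2"), call = c("up", "ns"))
  dm <- tibble::tibble(
    gene_id = c("g1", "g1", "g1", "g3"),
    rel_start = c(-100, -200, -100, -300),
    significant = TRUE
  )
  ov <- overlap_deg_dmr(de, dm)
  expect_equal(ov$n_overlap, 1)          # one overlapping gene
  expect_equal(sum(ov$positional$n), 3)  # its three significant windows
  # disjoint sets -> zero
  dm2 <- dm
  dm2$gene_id <- c("g7", "g7", "g7", "g8")
  expect_equal(overlap_deg_dmr(de, dm2)$n_overlap, 0)
})

test_that("overlap counts tighten monotonically with the DE threshold", {
  x <- small_expr()
  rc <- aggregate_window_counts(small_cpg(), small_sim()$annotation, 100)
  win <- window_dm(rc, grp_a, grp_b, mode = "window")
  de_loose <- de_test(x, grp_a, grp_b, fdr_cut = 0.2)
  de_tight <- de_test(x, grp_a, grp_b, fdr_cut = 0.01)
  expect_gte(overlap_deg_dmr(de_loose, win)$n_overlap,
             overlap_deg_dmr(de_tight, win)$n_overlap)
})

test_that("derived ratios reproduce every printed percentage and ratio", {
  tabs <- study_count_tables()
  r <- derived_ratios(tabs)
  val <- function(metric, cmp) {
    r$value[r$metric == metric & grepl(cmp, r$comparison)]
  }
  # per-comparison transcript percentages (2 decimals)
  expect_equal(val("pct_down", "^Transgenic Day 0 vs. Day 28"), 0.91)
  expect_equal(val("pct_up", "^Transgenic Day 0 vs. Day 28"), 2.34)
  expect_equal(val("pct_deg_combined", "^Non-transgenic Day 0 vs. Day 28"),
               8.39)
  expect_equal(val("pct_deg_combined", "^Transgenic Day 0 vs. Day 41"), 0.08)
  # overlap shares
  expect_equal(val("pct_degs_overlapping", "^Non-transgenic Day 0 vs. Day 28"),
               0.3)
  expect_equal(val("pct_dmrs_overlapping", "^Non-transgenic Day 0 vs. Day 28"),
               28)
  expect_equal(val("pct_window_dmrs_overlapping", "100bp"), 3.6)
  # composition of calls
  expect_equal(val("pct_up_among_degs", "^Transgenic Day 28 vs. Day 41"), 19)
  expect_equal(val("pct_down_among_degs", "^Transgenic Day 28 vs. Day 41"), 81)
  expect_equal(val("pct_hypo_among_dm_cpgs", "^Transgenic Day 28 vs. Day 41"),
               43)
  # direction ratios
  expect_equal(val("hyper_hypo_ratio", "^Non-transgenic Day 0 vs. Day 28"), 1.5)
  expect_equal(val("hypo_hyper_ratio", "^Non-transgenic Day 28 vs. Day 41"), 1.6)
  # zero denominators yield NA
  tabs$deg$down[1] <- 0L; tabs$deg$up[1] <- 0L
  r2 <- derived_ratios(tabs)
  expect_true(is.na(r2$value[r2$metric == "pct_up_among_degs"][1]))
})

test_that("plot builders return ggplot objects", {
  mp <- metaplot(small_cpg(), small_sim()$annotation)
  expect_s3_class(plot_metaplot(mp), "ggplot")
  rc <- aggregate_window_counts(small_cpg(), small_sim()$annotation, 100)
  win <- window_dm(rc, grp_a, grp_b, mode = "window")
  prof <- positional_dmr_profile(win, 100)
  expect_s3_class(plot_positional_profile(prof), "ggplot")
  d <- tibble::tibble(meth_pct = runif(30, 0, 100),
                      log2_cpm = rnorm(30, 5))
  expect_s3_class(autoplot(static_association(d)), "ggplot")
  de <- de_test(small_expr(), grp_a, grp_b)
  da <- delta_association(win, de)
  if (nrow(da) > 0) {
    expect_s3_class(plot_window_associations(da), "ggplot")
  }
})
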