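test_that("TSS-relative positions respect strand", {
  expect_equal(tss_relative_position(5000, 5000, "+"), 0)
  expect_equal(tss_relative_position(5000, 5000, "-"), 0)
  expect_equal(tss_relative_position(4500, 5000, "+"), -500)
  expect_equal(tss_relative_position(4500, 5000, "-"), 500)
})

test_that("promoter intervals mirror correctly across strands", {
  ann <- tibble::tibble(
    gene_id = c("gp", "gm"), chrom = "c",
    tss = c(5000, 5000), strand = c("+", "-")
  )
  p <- define_promoter(ann)
  expect_equal(c(p$start[1], p$end[1]), c(3000, 5200))
  expect_equal(c(p$start[2], p$end[2]), c(4801, 7001))
  # clipping at the chromosome start warns
  ann2 <- tibble::tibble(gene_id = "g", chrom = "c", tss = 100, strand = "+")
  expect_warning(p2 <- define_promoter(ann2), "clipped")
  expect_equal(c(p2$start, p2$end), c(0, 300))
})

test_that("window tiling partitions the promoter exactly", {
  ann <- tibble::tibble(gene_id = "g", chrom = "c", tss = 50000,
                        strand = "+")
  for (size in c(100, 50, 25, 12.5)) {
    w <- tile_windows(ann, size)
    expect_equal(nrow(w), 2200 / size)
    expect_equal(w$rel_start[1], -2000)
    expect_equal(w$rel_end[nrow(w)], 200)
    # contiguous, non-overlapping
    expect_equal(w$rel_start[-1], w$rel_end[-nrow(w)])
  }
  expect_equal(sapply(c(100, 50, 25, 12.5),
                      function(s) nrow(tile_windows(ann, s))),
               c(22, 44, 88, 176))
  expect_error(tile_windows(ann, 30), "divide")

  # floor assignment rule: r = -1988 falls in window 0 at size 12.5
  expect_equal(floor((-1988 + 2000) / 12.5), 0)
  # r = +199 is the last window for every size
  for (size in c(100, 50, 25, 12.5)) {
    expect_equal(floor((199 + 2000) / size), 2200 / size - 1)
  }
})

test_that("minus-strand windows run against the genomic axis", {
  ann <- tibble::tibble(gene_id = "g", chrom = "c", tss = 50000,
                        strand = "-")
  w <- tile_windows(ann, 100)
  # increasing relative position = decreasing genomic coordinate
  expect_true(all(diff(w$abs_start) < 0))
  # first window (rel -2000..-1900) covers tss+1901 .. tss+2000
  expect_equal(w$abs_start[1], 50000 + 1901)
  expect_equal(w$abs_end[1], 50000 + 2001)
})

test_that("aggregation is additive and conserves promoter totals", {
  pools <- tibble::tibble(pool_id = c("p1", "p2"))
  ann <- tibble::tibble(gene_id = "g", chrom = "chrS", tss = 50000,
                        strand = "+")
  # two CpGs in the same 100 bp window: (3,1) and (2,2)
  x <- cpg_counts(
    tibble::tibble(chrom = "chrS", pos = c(48010, 48020)),
    meth = cbind(p1 = c(3L, 2L), p2 = c(1L, 1L)),
    unmeth = cbind(p1 = c(1L, 2L), p2 = c(1L, 1L)),
    pools = pools
  )
  rc <- aggregate_window_counts(x, ann, 100)
  expect_equal(nrow(rc$units), 1)
  expect_equal(unname(rc$meth[1, ]), c(5L, 2L))
  expect_equal(unname(rc$unmeth[1, ]), c(3L, 2L))
  expect_equal(rc$units$n_cpg, 2L)
})

test_that("tiling is a partition on simulated genomes and counts conserve", {
  sim <- small_sim()
  x <- small_cpg()
  ann <- sim$annotation
  prom <- aggregate_window_counts(x, ann, "promoter")
  for (size in c(100, 50, 25, 12.5)) {
    rc <- aggregate_window_counts(x, ann, size)
    expect_true(all(rc$units$window_index >= 0))
    expect_true(all(rc$units$window_index < 2200 / size))
    # conservation: per gene, window sums equal the whole-promoter sums
    per_gene <- rowsum(rowSums(rc$meth) + rowSums(rc$unmeth),
                       rc$units$gene_id)
    prom_tot <- rowsum(rowSums(prom$meth) + rowSums(prom$unmeth),
                       prom$units$gene_id)
    common <- intersect(rownames(per_gene), rownames(prom_tot))
    expect_equal(per_gene[common, 1], prom_tot[common, 1])
    # CpG membership: windows never hold more CpGs than the promoter
    n_by_gene <- rowsum(rc$units$n_cpg, rc$units$gene_id)
    expect_equal(n_by_gene[common, 1],
                 rowsum(prom$units$n_cpg, prom$units$gene_id)[common, 1])
  }
})

test_that("relative-position quantities are invariant under genome reflection", {
  sim <- small_sim()
  x <- small_cpg()
  ann <- sim$annotation
  L <- max(x$sites$pos) + 10000
  ann_m <- ann
  ann_m$tss <- L - 1 - ann$tss
  ann_m$strand <- ifelse(ann$strand == "+", "-", "+")
  x_m <- cpg_counts(
    tibble::tibble(chrom = x$sites$chrom, pos = L - 1 - x$sites$pos),
    x$meth, x$unmeth, x$pools
  )
  rc <- aggregate_window_counts(x, ann, 100)
  rc_m <- aggregate_window_counts(x_m, ann_m, 100)
  k <- paste(rc$units$gene_id, rc$units$window_index)
  k_m <- paste(rc_m$units$gene_id, rc_m$units$window_index)
  expect_setequal(k, k_m)
  idx <- match(k, k_m)
  expect_equal(rowSums(rc$meth), rowSums(rc_m$meth[idx, , drop = FALSE]))
  expect_equal(rc$units$n_cpg, rc_m$units$n_cpg[idx])
})

test_that("window and promoter modes apply their own thresholds", {
  rc <- aggregate_window_counts(small_cpg(), small_sim()$annotation, 100)
  win <- window_dm(rc, grp_a, grp_b, mode = "window")
  expect_true(all(win$significant == (win$p_value < 0.05)))
  prom_rc <- aggregate_window_counts(small_cpg(), small_sim()$annotation,
                                     "promoter")
  prom <- window_dm(prom_rc, grp_a, grp_b, mode = "promoter")
  expect_true(all(prom$significant ==
                    (prom$q_value < 0.01 & abs(prom$meth_diff) >= 25)))
  # q = 0.005 with diff = 10 is not significant in promoter mode
  fake <- tibble::tibble(meth_diff = 10, q_value = 0.005)
  expect_equal(call_dm(fake)$call, "ns")
  # identical groups: nothing is significant
  same <- window_dm(rc, grp_a, grp_a, mode = "promoter")
  expect_equal(sum(same$significant), 0)
})

test_that("positional profiles cover the grid and conserve totals", {
  rc <- aggregate_window_counts(small_cpg(), small_sim()$annotation, 100)
  win <- window_dm(rc, grp_a, grp_b, mode = "window")
  prof <- positional_dmr_profile(win, size = 100)
  expect_equal(prof$rel_start, seq(-2000, 100, by = 100))
  expect_equal(sum(prof$n), sum(win$significant))
  expect_equal(prof$n, prof$n_hypo + prof$n_hyper)
  # no significant windows -> all-zero profile
  none <- win
  none$significant <- FALSE
  prof0 <- positional_dmr_profile(none, size = 100)
  expect_true(all(prof0$n == 0))
})
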