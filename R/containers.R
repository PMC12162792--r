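#' CpG count container
#'
#' Holds per-CpG methylated/unmethylated read counts across pools: a sites
#' tibble (`chrom`, `pos`, 0-based cytosine positions on the plus strand
#' after strand merging) aligned row-wise with integer `meth` and `unmeth`
#' matrices (sites x pools), plus the pool metadata table. Sites are kept
#' sorted by (chrom, pos) without duplicates.
#'
#' @param sites Tibble with columns `chrom` (character) and `pos`
#'   (non-negative integer, 0-based).
#' @param meth,unmeth Integer matrices, one row per site, one column per
#'   pool; column names must equal `pools$pool_id`.
#' @param pools Pool table (see [experiment_pools()]); any tibble with a
#'   unique `pool_id` column is accepted.
#'
#' @return An object of class `cpg_counts`.
#' @export
cpg_counts <- function(sites, meth, unmeth, pools) {
  sites <- as_tibble(sites)
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  meth <- as.matrix(meth)
  unmeth <- as.matrix(unmeth)
  if (nrow(sites) != nrow(meth) || nrow(sites) != nrow(unmeth)) {
    stop("sites and count matrices disagree in length")
  }
  if (!identical(dim(meth), dim(unmeth))) stop("meth/unmeth dimensions differ")
  if (anyDuplicated(pools$pool_id)) stop("duplicate pool_id in pools")
  if (is.null(colnames(meth))) colnames(meth) <- pools$pool_id
  if (is.null(colnames(unmeth))) colnames(unmeth) <- pools$pool_id
  if (!identical(colnames(meth), pools$pool_id)) {
    stop("count matrix columns must match pools$pool_id")
  }
  if (any(meth < 0) || any(unmeth < 0)) stop("negative counts")
  if (any(sites$pos < 0)) stop("negative positions")
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  meth <- meth[ord, , drop = FALSE]
  unmeth <- unmeth[ord, , drop = FALSE]
  if (nrow(sites) > 1 &&
      anyDuplicated(paste(sites$chrom, sites$pos))) {
    stop("duplicate CpG sites")
  }
  structure(
    list(sites = sites, meth = meth, unmeth = unmeth, pools = as_tibble(pools)),
    class = "cpg_counts"
  )
}

#' @export
print.cpg_counts <- function(x, ...) {
  cat("<cpg_counts> ", nrow(x$sites), " CpG sites x ", nrow(x$pools),
      " pools\n", sep = "")
  cat("  chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  cov <- x$meth + x$unmeth
  cat("  median coverage per pool:",
      paste(apply(cov, 2, stats::median), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cpg_counts <- function(x) c(nrow(x$sites), nrow(x$pools))

#' Tidy long view of a CpG count container
#'
#' @param x A [cpg_counts()] object.
#' @param ... Unused.
#' @return A tibble with one row per site x pool: `chrom`, `pos`, `pool_id`,
#'   `meth`, `unmeth`, `coverage`.
#' @export
as_tibble.cpg_counts <- function(x, ...) {
  n <- nrow(x$sites)
  p <- nrow(x$pools)
  tibble(
    chrom = rep(x$sites$chrom, times = p),
    pos = rep(x$sites$pos, times = p),
    pool_id = rep(x$pools$pool_id, each = n),
    meth = as.vector(x$meth),
    unmeth = as.vector(x$unmeth)
  ) |>
    mutate(coverage = .data$meth + .data$unmeth)
}

# Subset a cpg_counts (or region_counts) object to the given pool ids.
subset_pools <- function(x, pool_ids) {
  idx <- match(pool_ids, x$pools$pool_id)
  if (anyNA(idx)) {
    stop("unknown pool id(s): ",
         paste(pool_ids[is.na(idx)], collapse = ", "))
  }
  x$meth <- x$meth[, idx, drop = FALSE]
  x$unmeth <- x$unmeth[, idx, drop = FALSE]
  x$pools <- x$pools[idx, , drop = FALSE]
  x
}

#' Expression count container
#'
#' Gene x pool integer counts with library sizes (column sums) and TMM
#' normalization factors (default 1, geometric mean 1 after
#' [tmm_factors()]).
#'
#' @param counts Integer matrix, genes in rows (rownames are gene ids),
#'   pools in columns.
#' @param pools Pool table; `pool_id` must match the count columns.
#' @param norm_factors Optional positive normalization factors, one per pool.
#'
#' @return An object of class `expression_counts`.
#' @export
expression_counts <- function(counts, pools, norm_factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must carry gene ids as rownames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (any(counts < 0)) stop("negative counts")
  if (any(counts != round(counts))) stop("non-integer expression counts")
  storage.mode(counts) <- "integer"
  if (is.null(colnames(counts))) colnames(counts) <- pools$pool_id
  if (!identical(colnames(counts), pools$pool_id)) {
    stop("count columns must match pools$pool_id")
  }
  if (is.null(norm_factors)) norm_factors <- rep(1, ncol(counts))
  if (any(norm_factors <= 0)) stop("normalization factors must be positive")
  structure(
    list(
      counts = counts,
      pools = as_tibble(pools),
      lib_sizes = colSums(counts),
      norm_factors = setNames(as.numeric(norm_factors), colnames(counts))
    ),
    class = "expression_counts"
  )
}

#' @export
print.expression_counts <- function(x, ...) {
  cat("<expression_counts> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " pools\n", sep = "")
  cat("  library sizes: ", paste(format(x$lib_sizes, big.mark = ","),
                                 collapse = ", "), "\n", sep = "")
  cat("  norm factors:  ", paste(round(x$norm_factors, 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_counts <- function(x) dim(x$counts)

#' Tidy long view of an expression count container
#'
#' @param x An [expression_counts()] object.
#' @param ... Unused.
#' @return A tibble with one row per gene x pool.
#' @export
as_tibble.expression_counts <- function(x, ...) {
  tibble(
    gene_id = rep(rownames(x$counts), times = ncol(x$counts)),
    pool_id = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.vector(x$counts)
  )
}

# Region (promoter window) count container: same layout as cpg_counts but
# keyed by aggregation units rather than single sites.
region_counts <- function(units, meth, unmeth, pools, size) {
  stopifnot(nrow(units) == nrow(meth), identical(dim(meth), dim(unmeth)))
  structure(
    list(units = as_tibble(units), meth = meth, unmeth = unmeth,
         pools = as_tibble(pools), size = size),
    class = "region_counts"
  )
}

#' @export
print.region_counts <- function(x, ...) {
  cat("<region_counts> ", nrow(x$units), " units (size = ",
      if (identical(x$size, "promoter")) "whole promoter" else paste0(x$size, " bp"),
      ") x ", nrow(x$pools), " pools\n", sep = "")
  invisible(x)
}

#' @export
dim.region_counts <- function(x) c(nrow(x$units), nrow(x$pools))

#' @export
as_tibble.region_counts <- function(x, ...) {
  n <- nrow(x$units)
  p <- nrow(x$pools)
  out <- x$units[rep(seq_len(n), times = p), ]
  out$pool_id <- rep(x$pools$pool_id, each = n)
  out$meth <- as.vector(x$meth)
  out$unmeth <- as.vector(x$unmeth)
  as_tibble(out)
}
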