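#' Read gene annotation (BED6 or GFF3)
#'
#' Parses gene records into the annotation table used for all promoter
#' anchoring: one row per gene with its chromosome, 0-based transcription
#' start site and strand. For BED6 the TSS is `start` on the plus strand and
#' `end - 1` on the minus strand (both 0-based). For GFF3 the TSS is the
#' 5' end of each feature of type `feature`, converted from 1-based to
#' 0-based. Records are deduplicated by gene id, keeping the first.
#'
#' @param path Path to a BED6 or GFF3 file.
#' @param format `"auto"` (by extension), `"bed6"`, or `"gff3"`.
#' @param feature GFF3 feature type to extract (default `"gene"`).
#'
#' @return A tibble with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_annotation <- function(path, format = c("auto", "bed6", "gff3"),
                            feature = "gene") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) {
      "gff3"
    } else {
      "bed6"
    }
  }
  ann <- if (format == "bed6") {
    read_bed6_annotation(path)
  } else {
    read_gff3_annotation(path, feature)
  }
  if (any(ann$tss < 0)) stop("negative TSS coordinate in ", path)
  dup <- duplicated(ann$gene_id)
  if (any(dup)) ann <- ann[!dup, , drop = FALSE]
  ann
}

read_bed6_annotation <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) stop("no records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 6)
  if (length(bad) > 0) {
    stop("malformed BED6 line ", bad[1], " in ", path,
         " (fewer than 6 tab-separated fields)")
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    stop("malformed BED6 line ", bad[1], " in ", path,
         " (non-numeric coordinates)")
  }
  strand <- m[, 6]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0) {
    stop("unknown strand '", strand[bad[1]], "' on line ", bad[1], " in ", path)
  }
  tibble(
    gene_id = m[, 4],
    chrom = m[, 1],
    tss = ifelse(strand == "+", start, end - 1),
    strand = strand
  )
}

read_gff3_annotation <- function(path, feature) {
  gff <- as.data.frame(rtracklayer::readGFF(path))
  gff <- gff[gff$type == feature, , drop = FALSE]
  if (nrow(gff) == 0) stop("no '", feature, "' features in ", path)
  strand <- as.character(gff$strand)
  if (any(!strand %in% c("+", "-"))) {
    stop("unknown strand '", strand[!strand %in% c("+", "-")][1],
         "' in ", path)
  }
  ids <- gff$ID
  if (is.null(ids) || all(is.na(ids))) ids <- gff$Name
  if (is.null(ids)) stop("GFF3 features lack ID/Name attributes in ", path)
  tibble(
    gene_id = as.character(ids),
    chrom = as.character(gff$seqid),
    # GFF3 is 1-based closed; 5' end -> 0-based
    tss = ifelse(strand == "+", gff$start - 1, gff$end - 1),
    strand = strand
  )
}

#' Read per-pool CpG methylation counts
#'
#' Reads one file per pool in Bismark coverage format (`chrom`, 1-based
#' `start`, `end`, percent methylation, methylated count, unmethylated
#' count) or a headerless TSV (`chrom`, 0-based `pos`, methylated count,
#' unmethylated count) and assembles the union of sites across pools.
#' Positions are stored 0-based. A site absent from a pool gets zero
#' coverage there (the coverage filter removes such sites later). In
#' `bismark_cov` files a percent-methylation field inconsistent with the
#' counts by more than 0.5 percentage points triggers a warning and the
#' counts win.
#'
#' @param paths Character vector of file paths, one per pool.
#' @param pools Pool table with one row per path (same order). Default:
#'   generic pool ids derived from the file names.
#' @param format `"bismark_cov"` or `"tsv"`.
#'
#' @return A [cpg_counts()] object.
#' @export
read_cpg_counts <- function(paths, pools = NULL,
                            format = c("bismark_cov", "tsv")) {
  format <- match.arg(format)
  if (is.null(pools)) {
    pools <- tibble(pool_id = make.unique(
      sub("\\.(cov|tsv)(\\.gz)?$", "", basename(paths))
    ))
  }
  if (length(paths) != nrow(pools)) stop("one path per pool required")
  per_pool <- purrr::map2(paths, pools$pool_id, function(p, id) {
    read_one_cpg_file(p, id, format)
  })
  all_sites <- dplyr::distinct(
    bind_rows(lapply(per_pool, function(d) d[c("chrom", "pos")]))
  )
  all_sites <- arrange(all_sites, .data$chrom, .data$pos)
  key <- paste(all_sites$chrom, all_sites$pos)
  n <- nrow(all_sites)
  meth <- matrix(0L, n, length(paths), dimnames = list(NULL, pools$pool_id))
  unmeth <- meth
  for (k in seq_along(per_pool)) {
    idx <- match(paste(per_pool[[k]]$chrom, per_pool[[k]]$pos), key)
    meth[idx, k] <- per_pool[[k]]$meth
    unmeth[idx, k] <- per_pool[[k]]$unmeth
  }
  cpg_counts(all_sites, meth, unmeth, pools)
}

read_one_cpg_file <- function(path, pool_id, format) {
  if (format == "bismark_cov") {
    d <- readr::read_tsv(
      path,
      col_names = c("chrom", "start", "end", "pct", "meth", "unmeth"),
      col_types = "ciiddd", progress = FALSE
    )
    if (any(d$meth < 0 | d$unmeth < 0)) {
      stop("negative counts in ", path)
    }
    cov <- d$meth + d$unmeth
    frac <- ifelse(cov > 0, 100 * d$meth / cov, NA_real_)
    off <- which(!is.na(frac) & abs(frac - d$pct) > 0.5)
    if (length(off) > 0) {
      warning(length(off), " site(s) in ", basename(path),
              " have a percent-methylation field inconsistent with the ",
              "counts; counts win", call. = FALSE)
    }
    tibble(chrom = d$chrom, pos = d$start - 1L,
           meth = as.integer(d$meth), unmeth = as.integer(d$unmeth))
  } else {
    d <- readr::read_tsv(
      path, col_names = c("chrom", "pos", "meth", "unmeth"),
      col_types = "ciii", progress = FALSE
    )
    if (any(d$meth < 0 | d$unmeth < 0)) stop("negative counts in ", path)
    tibble(chrom = d$chrom, pos = d$pos, meth = d$meth, unmeth = d$unmeth)
  }
}

#' Write per-pool CpG counts in Bismark coverage format
#'
#' Inverse of [read_cpg_counts()] (`bismark_cov` format): writes one file
#' per pool, 1-based positions, omitting zero-coverage sites of each pool.
#'
#' @param x A [cpg_counts()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths (named by pool id).
#' @export
write_cpg_counts <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- setNames(
    file.path(dir, paste0(x$pools$pool_id, ".cov")),
    x$pools$pool_id
  )
  for (k in seq_len(nrow(x$pools))) {
    cov <- x$meth[, k] + x$unmeth[, k]
    keep <- cov > 0
    d <- tibble(
      chrom = x$sites$chrom[keep],
      start = x$sites$pos[keep] + 1L,
      end = x$sites$pos[keep] + 1L,
      pct = round(100 * x$meth[keep, k] / cov[keep], 6),
      meth = x$meth[keep, k],
      unmeth = x$unmeth[keep, k]
    )
    readr::write_tsv(d, paths[k], col_names = FALSE, progress = FALSE)
  }
  invisible(paths)
}

#' Read a gene x pool expression count matrix
#'
#' Expects a TSV with a header of pool labels, a first column of gene ids,
#' and integer cells.
#'
#' @param path TSV path.
#' @param pools Optional pool table; default derives pool ids from the
#'   header.
#' @return An [expression_counts()] object.
#' @export
read_expression <- function(path, pools = NULL) {
  d <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (nrow(d) == 0 || ncol(d) < 2) stop("no genes in ", path)
  gene_ids <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)) || any(m != round(m))) {
    stop("non-integer expression cell in ", path)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- gene_ids
  if (is.null(pools)) pools <- tibble(pool_id = colnames(m))
  expression_counts(m, pools)
}

#' Write a gene x pool expression count matrix
#'
#' Inverse of [read_expression()]: `read_expression(write_expression(x))`
#' round-trips exactly.
#'
#' @param x An [expression_counts()] object.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(x, path) {
  d <- as.data.frame(x$counts)
  d <- cbind(gene_id = rownames(x$counts), d)
  readr::write_tsv(as_tibble(d), path, progress = FALSE)
  invisible(path)
}

#' Write an annotation table as BED6
#'
#' @param annotation Annotation tibble (`gene_id`, `chrom`, `tss`,
#'   `strand`).
#' @param path Output path.
#' @param gene_length Nominal feature length used for the BED interval; the
#'   TSS convention of [read_annotation()] is preserved on both strands.
#' @return Invisibly, `path`.
#' @export
write_annotation_bed <- function(annotation, path, gene_length = 1000) {
  start <- ifelse(annotation$strand == "+",
                  annotation$tss, annotation$tss - gene_length + 1)
  start <- pmax(start, 0)
  d <- tibble(
    chrom = annotation$chrom,
    start = as.integer(start),
    end = as.integer(start + gene_length),
    name = annotation$gene_id,
    score = 0L,
    strand = annotation$strand
  )
  # on '-' the TSS must be end - 1
  d$end[annotation$strand == "-"] <- annotation$tss[annotation$strand == "-"] + 1L
  d$start[annotation$strand == "-"] <-
    pmax(d$end[annotation$strand == "-"] - gene_length, 0L)
  readr::write_tsv(d, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a result table as TSV
#'
#' All result tables are written as TSV with their existing (documented)
#' column order; list-columns are collapsed to comma-separated strings.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.list(x[[j]])) {
      x[[j]] <- vapply(x[[j]], function(v) paste(v, collapse = ","), "")
    }
  }
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}
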