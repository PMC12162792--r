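#' Run the full analysis pipeline
#'
#' Orchestrates one reproducible run: obtain inputs (either simulated from
#' a [sim_config()] or read from files), filter and normalize CpG coverage,
#' filter and TMM-normalize expression, then per comparison run per-CpG
#' differential methylation, differential expression, whole-promoter and
#' windowed differential methylation, DEG-DMR overlap accounting and the
#' window-wise association regressions; plus the TSS metaplot and the
#' static association of the reference condition. Every stage's table is
#' written as TSV into `out_dir` together with a YAML copy of the
#' configuration and a log recording the seed, thresholds and MD5 digests
#' of all outputs. Re-running with the same configuration reproduces
#' byte-identical tables.
#'
#' @param inputs A [sim_config()] (simulated run), or a named list with
#'   `annotation` (path, BED6/GFF3), `cpg` (vector of bismark coverage
#'   paths), `expression` (TSV path), and `pools` (pool table with one row
#'   per cpg path).
#' @param out_dir Output directory (created; must not exist or be empty).
#' @param comparisons Comparison table as from [standard_comparisons()];
#'   default: the standard nine.
#' @param window_size Window size (bp) used for the windowed stages.
#' @param thresholds Constants from [analysis_thresholds()].
#' @param reference_pools Pools used for the metaplot and static
#'   association; default the fed (Day0) non-transgenic pools if present,
#'   otherwise all pools.
#' @param write_inputs Also write the (simulated) inputs as BED /
#'   bismark coverage / TSV files (default `FALSE`).
#'
#' @return Invisibly, a list with the in-memory results of every stage and
#'   `out_dir`.
#' @export
run_pipeline <- function(inputs = sim_config(), out_dir,
                         comparisons = NULL, window_size = 100,
                         thresholds = analysis_thresholds(),
                         reference_pools = NULL,
                         write_inputs = FALSE) {
  # validate before any compute
  if (inherits(inputs, "sim_config")) {
    simulated <- TRUE
  } else if (is.list(inputs)) {
    simulated <- FALSE
    for (f in c("annotation", "cpg", "expression")) {
      if (is.null(inputs[[f]])) stop("inputs$", f, " is required")
      missing <- !file.exists(inputs[[f]])
      if (any(missing)) {
        stop("input file(s) not found: ",
             paste(inputs[[f]][missing], collapse = ", "))
      }
    }
    if (is.null(inputs$pools)) stop("inputs$pools is required")
  } else {
    stop("inputs must be a sim_config or a list of file paths")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (simulated) {
    sim <- simulate_experiment(inputs)
    annotation <- sim$annotation
    cpg <- sim$methylation
    expr <- sim$expression
    pools <- sim$pools
    yaml::write_yaml(unclass(inputs), file.path(out_dir, "config.yaml"))
    if (write_inputs) {
      write_annotation_bed(annotation, file.path(out_dir, "annotation.bed"))
      write_cpg_counts(cpg, file.path(out_dir, "cpg"))
      write_expression(expr, file.path(out_dir, "expression_counts.tsv"))
      for (nm in names(sim$truth)) {
        tr <- sim$truth[[nm]]
        if (is.matrix(tr)) {
          tr <- bind_cols(tibble(gene_id = rownames(tr)), as_tibble(tr))
        }
        if (is.data.frame(tr)) {
          write_table(tr, file.path(out_dir, paste0("truth_", nm, ".tsv")))
        }
      }
    }
  } else {
    annotation <- read_annotation(inputs$annotation)
    cpg <- read_cpg_counts(inputs$cpg, pools = inputs$pools)
    expr <- read_expression(inputs$expression, pools = inputs$pools)
    pools <- inputs$pools
    yaml::write_yaml(
      lapply(inputs[c("annotation", "cpg", "expression")], as.character),
      file.path(out_dir, "config.yaml")
    )
  }
  if (is.null(comparisons)) comparisons <- standard_comparisons(pools)

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      manifest <- file.path(out_dir, "error_manifest.txt")
      cat(sprintf("stage %s failed: %s\n", name, conditionMessage(e)),
          file = manifest, append = TRUE)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  cpg_f <- run_stage("filter_coverage", function() {
    normalize_coverage(filter_coverage(cpg, thresholds$min_coverage))
  })
  expr_f <- run_stage("filter_expression", function() {
    tmm_factors(filter_expressed(expr))
  })
  total_tx <- attr(expr_f, "total_transcripts")

  if (is.null(reference_pools)) {
    ref <- pools$pool_id[pools$genotype == "non_transgenic" &
                           pools$timepoint == "Day0"]
    reference_pools <- if (length(ref) > 0) ref else pools$pool_id
  }

  meta <- run_stage("metaplot", function() {
    metaplot(cpg_f, annotation, pool_ids = reference_pools,
             upstream = thresholds$metaplot_upstream,
             downstream = thresholds$metaplot_downstream)
  })
  write_table(meta, file.path(out_dir, "metaplot.tsv"))

  static <- run_stage("static_association", function() {
    static_association(inner_join(
      promoter_methylation(cpg_f, annotation, pool_ids = reference_pools),
      gene_log2_cpm(expr_f, pool_ids = reference_pools),
      by = "gene_id"
    ))
  })
  write_table(generics::glance(static),
              file.path(out_dir, "static_association.tsv"))

  rc_prom <- aggregate_window_counts(cpg_f, annotation, "promoter",
                                     thresholds$promoter_upstream,
                                     thresholds$promoter_downstream)
  rc_win <- aggregate_window_counts(cpg_f, annotation, window_size,
                                    thresholds$promoter_upstream,
                                    thresholds$promoter_downstream)

  per_comparison <- purrr::map(seq_len(nrow(comparisons)), function(i) {
    lab <- comparisons$label[i]
    ga <- comparisons$group_a[[i]]
    gb <- comparisons$group_b[[i]]
    slug <- gsub("[^a-z0-9]+", "_", tolower(lab))
    run_stage(lab, function() {
      dm <- suppressMessages(diff_methylation(
        cpg_f, ga, gb, q_cut = thresholds$q_cut_promoter,
        diff_cut = thresholds$diff_cut, label = lab
      ))
      de <- de_test(expr_f, ga, gb, fdr_cut = thresholds$fdr_cut_de,
                    label = lab)
      prom <- window_dm(rc_prom, ga, gb, mode = "promoter",
                        q_cut = thresholds$q_cut_promoter,
                        diff_cut = thresholds$diff_cut, label = lab)
      win <- window_dm(rc_win, ga, gb, mode = "window",
                       p_cut = thresholds$p_cut_window, label = lab)
      profile <- positional_dmr_profile(win, size = window_size,
                                        upstream = thresholds$promoter_upstream,
                                        downstream = thresholds$promoter_downstream)
      ov <- overlap_deg_dmr(de, win)
      ov_prom <- overlap_deg_dmr(de, prom)
      assoc <- delta_association(win, de)
      write_table(dm, file.path(out_dir, paste0("dm_cpg_", slug, ".tsv")))
      write_table(de, file.path(out_dir, paste0("de_", slug, ".tsv")))
      write_table(prom, file.path(out_dir, paste0("dm_promoter_", slug, ".tsv")))
      write_table(win, file.path(out_dir, paste0("dm_window_", slug, ".tsv")))
      write_table(profile, file.path(out_dir, paste0("dmr_profile_", slug, ".tsv")))
      write_table(assoc, file.path(out_dir, paste0("delta_assoc_", slug, ".tsv")))
      list(label = lab, dm = dm, de = de, promoter = prom, window = win,
           profile = profile, overlap_window = ov, overlap_promoter = ov_prom,
           delta = assoc)
    })
  })

  summary_tables <- list(
    deg = purrr::map_dfr(per_comparison, function(r) {
      bind_cols(tibble(comparison = r$label),
                summarize_de(r$de, total_tx)[c("down", "up")])
    }),
    dm_cpg = purrr::map_dfr(per_comparison, function(r) {
      s <- summarize_dm(r$dm)
      tibble(comparison = r$label, hypo = s$hypo, hyper = s$hyper)
    }),
    dm_promoter = purrr::map_dfr(per_comparison, function(r) {
      s <- summarize_dm(r$promoter)
      tibble(comparison = r$label, hypo = s$hypo, hyper = s$hyper)
    }),
    overlap_promoter = purrr::map_dfr(per_comparison, function(r) {
      tibble(comparison = r$label, overlap = r$overlap_promoter$n_overlap)
    }),
    window_overlap = tibble(
      window_size = window_size,
      dmr_count = sum(purrr::map_int(per_comparison,
                                     ~ .x$overlap_window$n_dmr_units)),
      overlap_count = sum(purrr::map_int(
        per_comparison,
        ~ sum(.x$overlap_window$positional$n)
      ))
    ),
    total_transcripts = total_tx
  )
  for (nm in setdiff(names(summary_tables), "total_transcripts")) {
    write_table(summary_tables[[nm]],
                file.path(out_dir, paste0("summary_", nm, ".tsv")))
  }
  ratios <- derived_ratios(summary_tables)
  write_table(ratios, file.path(out_dir, "derived_ratios.tsv"))

  files <- list.files(out_dir, pattern = "\\.(tsv|yaml|bed|cov)$",
                      recursive = TRUE, full.names = TRUE)
  digests <- tools::md5sum(files)
  log_lines <- c(
    paste("seed:", if (simulated) inputs$seed else NA),
    paste("window_size:", window_size),
    paste("thresholds:", paste(names(thresholds),
                               vapply(thresholds, paste, "", collapse = "/"),
                               sep = "=", collapse = " ")),
    "output digests:",
    paste(" ", basename(names(digests)), digests)
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(
    out_dir = out_dir,
    annotation = annotation,
    cpg = cpg_f,
    expression = expr_f,
    metaplot = meta,
    static = static,
    comparisons = per_comparison,
    summary_tables = summary_tables,
    derived_ratios = ratios,
    truth = if (simulated) sim$truth else NULL
  ))
}
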