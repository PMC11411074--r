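#' Run the full screen analysis pipeline
#'
#' QC filtering, guide assignment, cis-window construction, partitioned
#' differential-expression testing, empirical-FDR hit calling and summary
#' tables, in the standard order. Output is bit-for-bit reproducible for a
#' fixed config (including its seed).
#'
#' Files written to `config$out_dir` (when set): `results.tsv` with the fixed
#' column order (guide_id, gene, n_test, n_control, log2fc, p_raw,
#' p_empirical, p_adj, hit), `hits.tsv`, `qq.tsv` (class, expected,
#' observed), `skip_log.tsv` and `run_log.txt`.
#'
#' @param config a [run_config()].
#' @param dataset optional [screen_dataset()]; when `NULL` the dataset is
#'   read from `config$data_dir`.
#' @return (invisibly) a `result_bundle` list: `table`, `hits`, `counts`,
#'   `qq`, `moi`, `sign`, `skip_log`, `log`.
#' @export
run_pipeline <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_msg("%s", line)
    log <<- c(log, line)
  }
  if (is.null(dataset)) {
    if (is.null(config$data_dir)) stop2("config has no data_dir and no dataset was given")
    dataset <- read_screen_dataset(config$data_dir)
  }
  note("input: %d cells, %d genes, %d guides", nrow(dataset$cell_meta),
       nrow(dataset$genes), nrow(dataset$guides))

  ds <- filter_cells(dataset, config$max_mito_fraction, config$min_total_umi)
  qc <- attr(ds, "qc")
  note("QC: %d -> %d cells (%d high-mito, %d low-UMI)",
       qc$n_before, qc$n_after, qc$n_fail_mito, qc$n_fail_umi)

  assignment <- assign_guides(ds$guide_counts, config$assign_min_umi)
  moi <- moi_summary(assignment)
  note("assignment at >= %d UMIs: %.1f%% of cells carry a guide, mean %.2f guides/cell, mean %.1f cells/guide",
       config$assign_min_umi, 100 * moi$fraction_assigned,
       moi$mean_guides_per_cell, moi$mean_cells_per_guide)

  guides <- locate_guide_sites(ds$guides)
  windows <- build_windows(guides, ds$genes, config$window_radius)
  note("windows: %d targeting guides, %d unique cis genes",
       length(windows),
       length(unique(unlist(lapply(windows, `[[`, "genes")))))

  table <- run_all_tests(ds, assignment, windows, config)
  skip_log <- attr(table, "skip_log")
  note("tests: %d emitted (%d targeting, %d NTC), %d skipped",
       nrow(table), sum(table$test_class == "targeting"),
       sum(table$test_class == "ntc"), nrow(skip_log))

  called <- call_hits(table, config$efdr_threshold, guides = guides)
  note("hits at EFDR < %g: %d", config$efdr_threshold, called$counts$n_hits)

  full <- called$table
  qq <- qq_data(full$p_raw[full$test_class == "targeting"],
                full$p_raw[full$test_class == "ntc"], seed = config$seed)

  intended <- full$test_class == "targeting" & full$intended
  sign <- if (any(intended) && any(full$test_class == "ntc")) {
    sign_proportion(full$log2fc[intended], full$log2fc[full$test_class == "ntc"])
  } else NULL
  if (!is.null(sign)) {
    note("sign: %d/%d intended-target tests with log2FC > 0 (%.1f%%)",
         sign$n_positive, sign$n_total, sign$percent)
  }

  bundle <- structure(list(table = full, hits = called$hits,
                           counts = called$counts, qq = qq, moi = moi,
                           sign = sign, skip_log = skip_log, log = log),
                      class = "result_bundle")
  if (!is.null(config$out_dir)) write_result_bundle(bundle, config$out_dir)
  invisible(bundle)
}

#' @rdname run_pipeline
#' @param bundle a `result_bundle`.
#' @param out_dir output directory.
#' @export
write_result_bundle <- function(bundle, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop2("cannot create output directory: ", out_dir)
  cols <- c("guide_id", "gene", "n_test", "n_control", "log2fc", "p_raw",
            "p_empirical", "p_adj", "hit")
  write_tsv_file(bundle$table[, cols], file.path(out_dir, "results.tsv"))
  write_tsv_file(bundle$hits[, cols], file.path(out_dir, "hits.tsv"))
  write_tsv_file(bundle$qq, file.path(out_dir, "qq.tsv"))
  write_tsv_file(bundle$skip_log, file.path(out_dir, "skip_log.tsv"))
  writeLines(bundle$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
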