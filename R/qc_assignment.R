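#' Quality-control filtering of cells
#'
#' Removes cells with a mitochondrial fraction strictly greater than
#' `max_mito_fraction` or a total UMI count strictly less than
#' `min_total_umi`; boundary values are retained. Both count matrices and the
#' metadata are subset consistently. Idempotent: filtering a filtered dataset
#' changes nothing.
#'
#' @param dataset a [screen_dataset()].
#' @param max_mito_fraction mitochondrial-fraction ceiling (default 0.10, the
#'   K562 setting; the neuron screen used 0.17).
#' @param min_total_umi total-UMI floor (default 4000; neurons used 1500).
#' @return the filtered `screen_dataset`, with attribute `qc` recording
#'   cells before/after and removal counts per rule.
#' @export
filter_cells <- function(dataset, max_mito_fraction = 0.10, min_total_umi = 4000) {
  stopifnot(inherits(dataset, "screen_dataset"),
            max_mito_fraction >= 0, min_total_umi >= 0)
  cm <- dataset$cell_meta
  fail_mito <- cm$mito_fraction > max_mito_fraction
  fail_umi <- cm$total_umi < min_total_umi
  keep <- !(fail_mito | fail_umi)
  if (!any(keep)) stop2("QC removed every cell (", sum(fail_mito), " failed mito, ",
                        sum(fail_umi), " failed UMI)")
  out <- screen_dataset(
    dataset$expr_counts[keep, , drop = FALSE],
    dataset$guide_counts[keep, , drop = FALSE],
    cm[keep, , drop = FALSE],
    dataset$genes, dataset$guides
  )
  log_msg("QC: %d of %d cells retained (%d failed mito > %.3g, %d failed UMI < %g)",
          sum(keep), nrow(cm), sum(fail_mito), max_mito_fraction,
          sum(fail_umi), min_total_umi)
  attr(out, "qc") <- list(n_before = nrow(cm), n_after = sum(keep),
                          n_fail_mito = sum(fail_mito), n_fail_umi = sum(fail_umi))
  out
}

#' Assign gRNAs to cells by a capture-UMI threshold
#'
#' Guide `g` is assigned to cell `c` exactly when the capture matrix entry is
#' `>= min_umi` (the global 5-UMI rule). A cell may carry zero or many
#' guides; unassigned cells remain part of every guide's control group.
#'
#' @param guide_counts cells x guides capture UMI matrix (or a
#'   [screen_dataset()], in which case its guide matrix is used).
#' @param min_umi assignment threshold (default 5).
#' @return an `assignment_table`: sparse logical cells x guides matrix in
#'   `$assigned` plus the threshold used.
#' @export
assign_guides <- function(guide_counts, min_umi = 5) {
  stopifnot(min_umi >= 1)
  if (inherits(guide_counts, "screen_dataset")) guide_counts <- guide_counts$guide_counts
  assigned <- guide_counts >= min_umi
  assigned <- as(as(assigned, "generalMatrix"), "CsparseMatrix")
  structure(list(assigned = assigned, min_umi = min_umi),
            class = "assignment_table")
}

#' Per-cell guide sets and per-guide carrier lists
#'
#' @param assignment an [assign_guides()] result.
#' @return `cell_guide_sets`: named list of guide-id vectors per cell;
#'   `guide_carriers`: integer row indices of the carrier cells of one guide.
#' @export
cell_guide_sets <- function(assignment) {
  tm <- Matrix::t(assignment$assigned)
  lapply(setNames(seq_len(ncol(tm)), colnames(tm)), function(ci) {
    rownames(tm)[tm[, ci] != 0]
  })
}

#' @rdname cell_guide_sets
#' @param guide_id guide identifier.
#' @export
guide_carriers <- function(assignment, guide_id) {
  m <- assignment$assigned
  which(m[, guide_id] != 0)
}

#' Multiplicity-of-integration summary
#'
#' Reports the fraction of cells with at least one assigned guide, mean and
#' median guides per cell, mean cells per guide (over guides with at least
#' one carrier), and histogram tables for both margins.
#'
#' @param assignment an [assign_guides()] result.
#' @return a `moi_summary` list.
#' @export
moi_summary <- function(assignment) {
  m <- assignment$assigned
  per_cell <- Matrix::rowSums(m)
  per_guide <- Matrix::colSums(m)
  covered <- per_guide[per_guide > 0]
  if (!any(per_cell > 0)) {
    warning("no cell has an assigned guide; means reported as 0", call. = FALSE)
  }
  structure(list(
    n_cells = nrow(m), n_guides = ncol(m),
    fraction_assigned = if (nrow(m)) mean(per_cell > 0) else 0,
    mean_guides_per_cell = if (nrow(m)) mean(per_cell) else 0,
    median_guides_per_cell = if (nrow(m)) median(per_cell) else 0,
    mean_cells_per_guide = if (length(covered)) mean(covered) else 0,
    guides_per_cell_hist = table(per_cell),
    cells_per_guide_hist = table(per_guide)
  ), class = "moi_summary")
}

#' @export
print.moi_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "MOI summary: %d cells, %d guides\n",
    "  fraction of cells with >=1 guide: %.3f\n",
    "  guides/cell: mean %.2f, median %g\n",
    "  cells/guide (covered guides):     mean %.1f\n"),
    x$n_cells, x$n_guides, x$fraction_assigned,
    x$mean_guides_per_cell, x$median_guides_per_cell, x$mean_cells_per_guide))
  invisible(x)
}
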