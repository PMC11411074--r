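#' Screen dataset container
#'
#' Bundles the two count matrices of a multiplex single-cell CRISPRa screen
#' (cells x genes expression UMIs and cells x guides capture UMIs) with
#' per-cell metadata, gene annotation and the guide library. All axes are
#' validated for consistency: matrix dimensions match the annotation tables,
#' counts are non-negative integers, and cell ids / gene symbols / guide ids
#' are unique.
#'
#' Gene coordinates are stored 0-based half-open throughout the package;
#' conversions to 1-based formats happen only at I/O boundaries.
#'
#' @param expr_counts cells x genes matrix of expression UMIs (coerced to
#'   sparse). Rows named by cell id, columns by gene symbol.
#' @param guide_counts cells x guides matrix of gRNA capture UMIs. Rows named
#'   by cell id, columns by guide id.
#' @param cell_meta data.frame with columns `cell`, `total_umi`,
#'   `mito_fraction`, `batch`, `context`, `sorted`.
#' @param genes data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `symbol` (0-based half-open intervals, strand "+" or "-").
#' @param guides guide library data.frame, see [validate_guide_library()].
#' @return an object of class `screen_dataset` (a validated list).
#' @export
screen_dataset <- function(expr_counts, guide_counts, cell_meta, genes, guides) {
  ds <- structure(
    list(
      expr_counts = as_count_matrix(expr_counts, "expr_counts"),
      guide_counts = as_count_matrix(guide_counts, "guide_counts"),
      cell_meta = as.data.frame(cell_meta, stringsAsFactors = FALSE),
      genes = as.data.frame(genes, stringsAsFactors = FALSE),
      guides = as.data.frame(guides, stringsAsFactors = FALSE)
    ),
    class = "screen_dataset"
  )
  validate_screen_dataset(ds)
}

as_count_matrix <- function(m, what) {
  m <- as(as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (length(m@x)) {
    if (any(m@x < 0)) stop2(what, ": negative counts are not allowed")
    if (any(m@x != round(m@x))) stop2(what, ": counts must be integers")
  }
  m
}

#' @rdname screen_dataset
#' @param x object to validate.
#' @export
validate_screen_dataset <- function(x) {
  stopifnot(inherits(x, "screen_dataset"))
  cm <- x$cell_meta
  need <- c("cell", "total_umi", "mito_fraction", "batch", "context", "sorted")
  miss <- setdiff(need, names(cm))
  if (length(miss)) stop2("cell_meta missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(cm$cell)) stop2("cell ids are not unique")
  if (any(cm$mito_fraction < 0 | cm$mito_fraction > 1)) {
    stop2("mito_fraction must lie in [0, 1]")
  }
  validate_gene_annotation(x$genes)
  validate_guide_library(x$guides)
  if (anyDuplicated(x$genes$symbol)) stop2("gene symbols are not unique (collapse duplicates first)")

  if (nrow(x$expr_counts) != nrow(cm)) {
    stop2("expression matrix has ", nrow(x$expr_counts), " rows but cell_meta has ",
          nrow(cm), " cells")
  }
  if (nrow(x$guide_counts) != nrow(cm)) {
    stop2("guide matrix has ", nrow(x$guide_counts), " rows but cell_meta has ",
          nrow(cm), " cells")
  }
  if (ncol(x$expr_counts) != nrow(x$genes)) {
    stop2("expression matrix has ", ncol(x$expr_counts), " columns but ",
          nrow(x$genes), " genes are annotated")
  }
  if (ncol(x$guide_counts) != nrow(x$guides)) {
    stop2("guide matrix has ", ncol(x$guide_counts), " columns but the library has ",
          nrow(x$guides), " guides")
  }
  rownames(x$expr_counts) <- cm$cell
  rownames(x$guide_counts) <- cm$cell
  colnames(x$expr_counts) <- x$genes$symbol
  colnames(x$guide_counts) <- x$guides$guide_id
  # canonical storage types so round-tripped datasets compare equal
  x$genes$start <- as.numeric(x$genes$start)
  x$genes$end <- as.numeric(x$genes$end)
  x$guides$site <- as.numeric(x$guides$site)
  x$cell_meta$total_umi <- as.numeric(x$cell_meta$total_umi)
  x$cell_meta$mito_fraction <- as.numeric(x$cell_meta$mito_fraction)
  x$cell_meta$sorted <- as.logical(x$cell_meta$sorted)
  x
}

validate_gene_annotation <- function(genes) {
  need <- c("chrom", "start", "end", "strand", "symbol")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop2("gene annotation missing columns: ", paste(miss, collapse = ", "))
  if (nrow(genes)) {
    if (any(genes$start >= genes$end)) stop2("gene annotation: start must be < end")
    if (!all(genes$strand %in% c("+", "-"))) stop2("gene strand must be '+' or '-'")
  }
  invisible(genes)
}

#' Validate a guide library table
#'
#' A guide library has one row per gRNA with columns `guide_id`, `spacer`
#' (20 nt, first base G, per the Pol III design rule), `category` (one of
#' `tss_positive_control`, `promoter`, `enhancer_hit`, `enhancer_nonhit`,
#' `ntc`), `chrom` and `site` (0-based target position; `NA` iff the guide is
#' a non-targeting control) and `target_gene` (programmed target symbol,
#' `NA` for NTCs).
#'
#' @param guides data.frame to validate.
#' @return the validated data.frame, invisibly.
#' @export
validate_guide_library <- function(guides) {
  need <- c("guide_id", "spacer", "category", "chrom", "site", "target_gene")
  miss <- setdiff(need, names(guides))
  if (length(miss)) stop2("guide library missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(guides)) return(invisible(guides))
  if (anyDuplicated(guides$guide_id)) stop2("guide ids are not unique")
  if (any(nchar(guides$spacer) != 20L)) stop2("spacers must be 20 nt")
  if (any(substr(guides$spacer, 1, 1) != "G")) stop2("spacers must start with G")
  cats <- c("tss_positive_control", "promoter", "enhancer_hit", "enhancer_nonhit", "ntc")
  bad <- setdiff(unique(guides$category), cats)
  if (length(bad)) stop2("unknown guide categories: ", paste(bad, collapse = ", "))
  is_ntc <- guides$category == "ntc"
  if (any(is_ntc & !is.na(guides$site))) stop2("NTC guides must have no target site")
  invisible(guides)
}

is_targeting <- function(guides) guides$category != "ntc"

#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf("screen_dataset: %d cells x %d genes, %d guides (%d targeting, %d NTC)\n",
              nrow(x$cell_meta), nrow(x$genes), nrow(x$guides),
              sum(is_targeting(x$guides)), sum(!is_targeting(x$guides))))
  invisible(x)
}

#' Pipeline run configuration
#'
#' Holds the thresholds and paths a full screen analysis needs. Defaults are
#' the K562-screen settings: cells with mitochondrial fraction above 10% or
#' fewer than 4000 total UMIs are removed, guides are assigned at 5 or more
#' capture UMIs, genes within 1 Mb of the target site are tested, tests need
#' detection in more than 0.2% of both groups, and hits are called at
#' empirical FDR < 0.1. The neuron screen used `max_mito_fraction = 0.17`
#' and `min_total_umi = 1500`.
#'
#' @param data_dir directory holding a screen dataset (see
#'   [read_screen_dataset()]); may be `NULL` when a dataset is passed
#'   directly to [run_pipeline()].
#' @param out_dir output directory for result tables.
#' @param max_mito_fraction QC ceiling on mitochondrial fraction.
#' @param min_total_umi QC floor on total UMIs per cell.
#' @param assign_min_umi minimum capture UMIs to assign a guide to a cell.
#' @param window_radius cis-window radius in bases around the target site.
#' @param detection_threshold minimum detection fraction (exclusive) in both
#'   groups for a test to be run.
#' @param efdr_threshold empirical FDR threshold for hit calling (strict `<`).
#' @param scale_factor normalization scale factor.
#' @param ntc_gene_subsample optional number of cis genes each NTC is tested
#'   against (seeded subsample); `NULL` tests the full union.
#' @param seed integer seed feeding every stochastic substream.
#' @return a `run_config` list.
#' @export
run_config <- function(data_dir = NULL, out_dir = NULL,
                       max_mito_fraction = 0.10, min_total_umi = 4000,
                       assign_min_umi = 5, window_radius = 1e6,
                       detection_threshold = 0.002, efdr_threshold = 0.1,
                       scale_factor = 1e4, ntc_gene_subsample = NULL,
                       seed = 1L) {
  stopifnot(
    max_mito_fraction >= 0, min_total_umi >= 0, assign_min_umi >= 1,
    window_radius > 0, detection_threshold >= 0, scale_factor > 0,
    efdr_threshold > 0, efdr_threshold < 1
  )
  structure(list(
    data_dir = data_dir, out_dir = out_dir,
    max_mito_fraction = max_mito_fraction, min_total_umi = min_total_umi,
    assign_min_umi = assign_min_umi, window_radius = window_radius,
    detection_threshold = detection_threshold, efdr_threshold = efdr_threshold,
    scale_factor = scale_factor, ntc_gene_subsample = ntc_gene_subsample,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path file path.
#' @param config a [run_config()] object.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop2("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}
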