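#' Read and write screen datasets
#'
#' A screen dataset directory holds the dominant sparse-matrix exchange
#' layout: MatrixMarket triplet files (1-based coordinates, features in rows,
#' cells in columns) with plain-text sidecars naming each axis, plus a cell
#' metadata TSV, a BED-like gene annotation (chrom, start, end, symbol,
#' strand; 0-based half-open, headerless) and the guide library TSV.
#'
#' Files written: `expression.mtx`, `genes.tsv`, `barcodes.tsv`,
#' `guide_capture.mtx`, `guide_ids.tsv`, `cell_meta.tsv`, `genes.bed`,
#' `guide_library.tsv`.
#'
#' On read, duplicate gene symbols are collapsed by summing their columns
#' (with a warning); the first annotation record of a duplicated symbol is
#' kept. Output is deterministic: writing the same dataset twice produces
#' byte-identical files.
#'
#' @param directory_path dataset directory.
#' @return `read_screen_dataset` returns a validated [screen_dataset()];
#'   `write_screen_dataset` returns `directory_path` invisibly.
#' @export
read_screen_dataset <- function(directory_path) {
  if (!dir.exists(directory_path)) stop2("dataset directory not found: ", directory_path)
  p <- function(f) {
    fp <- file.path(directory_path, f)
    if (!file.exists(fp)) stop2("missing dataset file: ", f, " (in ", directory_path, ")")
    fp
  }
  expr <- Matrix::t(read_count_mtx(p("expression.mtx")))
  guide <- Matrix::t(read_count_mtx(p("guide_capture.mtx")))
  symbols <- read_lines_sidecar(p("genes.tsv"))
  cells <- read_lines_sidecar(p("barcodes.tsv"))
  guide_ids <- read_lines_sidecar(p("guide_ids.tsv"))

  cell_meta <- read_tsv_file(p("cell_meta.tsv"),
    colClasses = c(cell = "character", batch = "character", context = "character"))
  genes <- read.table(p("genes.bed"), sep = "\t", header = FALSE,
                      col.names = c("chrom", "start", "end", "symbol", "strand"),
                      colClasses = c("character", "numeric", "numeric", "character", "character"))
  genes <- genes[, c("chrom", "start", "end", "strand", "symbol")]
  guides <- read_tsv_file(p("guide_library.tsv"),
    colClasses = c(guide_id = "character", spacer = "character",
                   category = "character", chrom = "character",
                   target_gene = "character"))

  if (ncol(expr) != length(symbols)) {
    stop2("expression.mtx has ", ncol(expr), " feature rows but genes.tsv lists ",
          length(symbols), " symbols")
  }
  if (nrow(expr) != length(cells) || nrow(guide) != length(cells)) {
    stop2("matrix cell axes (", nrow(expr), ", ", nrow(guide),
          ") do not match barcodes.tsv (", length(cells), ")")
  }
  if (ncol(guide) != length(guide_ids)) {
    stop2("guide_capture.mtx has ", ncol(guide), " feature rows but guide_ids.tsv lists ",
          length(guide_ids), " ids")
  }
  if (!identical(cells, as.character(cell_meta$cell))) {
    stop2("barcodes.tsv and cell_meta.tsv disagree on cell ids or order")
  }

  # order annotation tables by the matrix sidecars
  if (!setequal(symbols, genes$symbol)) stop2("genes.bed and genes.tsv disagree on symbols")
  genes <- genes[match(symbols, genes$symbol), , drop = FALSE]
  if (!setequal(guide_ids, guides$guide_id)) stop2("guide_library.tsv and guide_ids.tsv disagree")
  guides <- guides[match(guide_ids, guides$guide_id), , drop = FALSE]
  rownames(genes) <- rownames(guides) <- NULL

  if (anyDuplicated(symbols)) {
    dup <- unique(symbols[duplicated(symbols)])
    warning("collapsing ", length(dup), " duplicated gene symbol(s) by summing counts: ",
            paste(head(dup, 5), collapse = ", "), if (length(dup) > 5) ", ..." else "",
            call. = FALSE)
    expr <- collapse_columns(expr, symbols)
    genes <- genes[!duplicated(genes$symbol), , drop = FALSE]
    genes <- genes[match(colnames(expr), genes$symbol), , drop = FALSE]
  }
  # BED-like storage is already 0-based half-open: no coordinate shift on read
  screen_dataset(expr, guide, cell_meta, genes, guides)
}

#' @rdname read_screen_dataset
#' @param dataset a [screen_dataset()].
#' @export
write_screen_dataset <- function(dataset, directory_path) {
  dataset <- validate_screen_dataset(dataset)
  ok <- dir.exists(directory_path) || dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop2("cannot create dataset directory: ", directory_path)
  w <- function(f) file.path(directory_path, f)
  Matrix::writeMM(Matrix::t(dataset$expr_counts), w("expression.mtx"))
  Matrix::writeMM(Matrix::t(dataset$guide_counts), w("guide_capture.mtx"))
  writeLines(dataset$genes$symbol, w("genes.tsv"))
  writeLines(dataset$cell_meta$cell, w("barcodes.tsv"))
  writeLines(dataset$guides$guide_id, w("guide_ids.tsv"))
  write_tsv_file(dataset$cell_meta, w("cell_meta.tsv"))
  bed <- dataset$genes[, c("chrom", "start", "end", "symbol", "strand")]
  bed$start <- sprintf("%.0f", bed$start)  # never scientific notation
  bed$end <- sprintf("%.0f", bed$end)
  write.table(bed, w("genes.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_tsv_file(dataset$guides, w("guide_library.tsv"))
  invisible(directory_path)
}

read_count_mtx <- function(path) {
  m <- Matrix::readMM(path)
  if (is(m, "nMatrix") || is(m, "lMatrix")) m <- m * 1  # pattern file: all ones
  m <- as(as(m, "generalMatrix"), "CsparseMatrix")
  if (length(m@x)) {
    if (any(m@x < 0)) stop2(path, ": negative counts")
    if (any(m@x != round(m@x))) stop2(path, ": non-integer counts")
  }
  m
}

read_lines_sidecar <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

read_tsv_file <- function(path, colClasses = NA) {
  read.table(path, sep = "\t", header = TRUE, colClasses = colClasses,
             na.strings = "NA", stringsAsFactors = FALSE)
}

write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
}

# Sum columns of a cells x features sparse matrix that share a name.
collapse_columns <- function(m, names_vec) {
  f <- factor(names_vec, levels = unique(names_vec))
  ind <- Matrix::sparseMatrix(i = seq_along(names_vec), j = as.integer(f), x = 1,
                              dims = c(length(names_vec), nlevels(f)))
  out <- m %*% ind
  out <- as(as(out, "generalMatrix"), "CsparseMatrix")
  colnames(out) <- levels(f)
  rownames(out) <- rownames(m)
  out
}
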