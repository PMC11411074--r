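#' Locate guide target sites
#'
#' Guides whose library already records a target site pass through unchanged
#' (always the case for synthetic screens). Guides missing a site are located
#' by exact string search of the spacer and its reverse complement against a
#' genome sequence; exactly one genomic occurrence is required.
#'
#' @param guides guide library data.frame.
#' @param genome_sequence named character vector (or
#'   `Biostrings::DNAStringSet`) of chromosome sequences; only needed when
#'   targeting guides lack explicit sites.
#' @return guide library with `chrom` and `site` filled for all targeting
#'   guides; `site` is the 0-based position of the 5' end of the match.
#' @export
locate_guide_sites <- function(guides, genome_sequence = NULL) {
  validate_guide_library(guides)
  targeting <- is_targeting(guides)
  need <- targeting & is.na(guides$site)
  if (!any(need)) return(guides)
  if (is.null(genome_sequence)) {
    stop2("no genome sequence supplied but these guides lack sites: ",
          paste(guides$guide_id[need], collapse = ", "))
  }
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop2("Biostrings is required to search spacer sites")
  }
  if (!is(genome_sequence, "DNAStringSet")) {
    genome_sequence <- Biostrings::DNAStringSet(unlist(genome_sequence))
  }
  if (is.null(names(genome_sequence))) stop2("genome sequences must be named")
  for (i in which(need)) {
    spacer <- Biostrings::DNAString(guides$spacer[i])
    hits <- list()
    for (chr in names(genome_sequence)) {
      fwd <- Biostrings::matchPattern(spacer, genome_sequence[[chr]])
      rev <- Biostrings::matchPattern(Biostrings::reverseComplement(spacer),
                                      genome_sequence[[chr]])
      if (length(fwd)) {
        hits <- c(hits, lapply(Biostrings::start(fwd), function(s)
          list(chrom = chr, site = s - 1L)))
      }
      if (length(rev)) {
        hits <- c(hits, lapply(Biostrings::end(rev), function(e)
          list(chrom = chr, site = e - 1L)))
      }
    }
    if (length(hits) == 0) stop2("spacer of guide ", guides$guide_id[i],
                                 " has no genomic match")
    if (length(hits) > 1) stop2("spacer of guide ", guides$guide_id[i],
                                " matches the genome ", length(hits),
                                " times (ambiguous site)")
    guides$chrom[i] <- hits[[1]]$chrom
    guides$site[i] <- hits[[1]]$site
  }
  guides
}

#' Genes in the cis-window around a target site
#'
#' A gene belongs to the window when its 0-based half-open interval
#' `[start, end)` overlaps `[site - radius, site + radius]` on the same
#' chromosome. Symbols are deduplicated. Empty windows are allowed.
#'
#' @param chrom chromosome of the target site.
#' @param site 0-based target position.
#' @param genes gene annotation data.frame.
#' @param radius window radius in bases (default 1 Mb, i.e. a 2 Mb window).
#' @return a `cis_window` list: `chrom`, `site`, `lo`, `hi`, `genes`
#'   (unique member symbols).
#' @export
genes_in_window <- function(chrom, site, genes, radius = 1e6) {
  stopifnot(radius > 0)
  validate_gene_annotation(genes)
  inside <- genes$chrom == chrom &
    genes$start <= site + radius &
    genes$end > site - radius
  structure(list(chrom = chrom, site = site,
                 lo = site - radius, hi = site + radius,
                 genes = unique(genes$symbol[inside])),
            class = "cis_window")
}

#' Build cis-windows for every targeting guide
#'
#' @param guides guide library with located sites (see
#'   [locate_guide_sites()]).
#' @param genes gene annotation.
#' @param radius window radius in bases.
#' @return named list of [genes_in_window()] results, one per targeting
#'   guide.
#' @export
build_windows <- function(guides, genes, radius = 1e6) {
  targeting <- which(is_targeting(guides))
  if (any(is.na(guides$site[targeting]))) {
    stop2("targeting guides lack sites; run locate_guide_sites() first")
  }
  windows <- lapply(targeting, function(i) {
    genes_in_window(guides$chrom[i], guides$site[i], genes, radius)
  })
  names(windows) <- guides$guide_id[targeting]
  empties <- names(windows)[vapply(windows, function(w) length(w$genes) == 0, logical(1))]
  if (length(empties)) {
    log_msg("%d guide(s) have an empty cis-window: %s",
            length(empties), paste(head(empties, 5), collapse = ", "))
  }
  windows
}

#' Log-normalize an expression matrix
#'
#' `value = ln(1 + scale_factor * count / cell_total)` with totals taken over
#' the matrix rows. Doubling every count of a cell leaves its normalized
#' vector unchanged.
#'
#' @param expr_counts cells x genes count matrix.
#' @param scale_factor scale (default 10,000).
#' @param cell_totals optional per-cell totals to normalize by. Defaults to
#'   the matrix row sums; pass the metadata total UMIs when the matrix covers
#'   only a subset of the transcriptome (as the pipeline does), so that one
#'   strongly activated gene cannot distort its window mates.
#' @return sparse normalized matrix of the same shape.
#' @export
normalize_expression <- function(expr_counts, scale_factor = 1e4,
                                 cell_totals = NULL) {
  m <- as(as(Matrix::Matrix(expr_counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  totals <- cell_totals %||% Matrix::rowSums(m)
  if (length(totals) != nrow(m)) stop2("cell_totals length does not match cells")
  if (any(totals <= 0)) {
    stop2(sum(totals <= 0), " cell(s) have zero total counts; filter cells first")
  }
  m@x <- log1p(scale_factor * m@x / totals[m@i + 1L])
  m
}

#' Differential expression test for one (guide, gene) pair
#'
#' Partitions cells into carriers and controls, applies the detection filter
#' (the gene must be detected in strictly more than `detection_threshold` of
#' the cells of both groups), and runs the two-tailed rank-sum test on
#' normalized expression. The fold change is computed on de-logged group
#' means with a pseudocount:
#' `log2fc = log2(mean(expm1(x)) + 1) - log2(mean(expm1(y)) + 1)`.
#'
#' @param norm_expr normalized matrix from [normalize_expression()].
#' @param carrier_cells,control_cells disjoint row indices that together
#'   cover all cells.
#' @param gene gene symbol (a column of `norm_expr`).
#' @param detection_threshold exclusive detection floor (default 0.002).
#' @param exact_limit passed to [rank_sum_test()].
#' @return one-row data.frame, or a `skipped_test` object carrying the skip
#'   reason when the detection filter applies.
#' @export
test_guide_gene <- function(norm_expr, carrier_cells, control_cells, gene,
                            detection_threshold = 0.002, exact_limit = 12L) {
  if (length(carrier_cells) == 0) stop2("carrier cell set is empty")
  x <- norm_expr[carrier_cells, gene]
  y <- norm_expr[control_cells, gene]
  pct1 <- mean(x > 0)
  pct2 <- mean(y > 0)
  if (pct1 <= detection_threshold || pct2 <= detection_threshold) {
    return(structure(list(reason = "detection"), class = "skipped_test"))
  }
  ts <- rank_sum_test(x, y, exact_limit = exact_limit)
  log2fc <- log2(mean(expm1(x)) + 1) - log2(mean(expm1(y)) + 1)
  data.frame(gene = gene, n_test = ts$n_test, n_control = ts$n_control,
             pct_test = pct1, pct_control = pct2,
             log2fc = log2fc, p_raw = ts$p.value, stringsAsFactors = FALSE)
}

#' Run every cis differential-expression test of a screen
#'
#' For each targeting guide, every member gene of its cis-window is tested
#' (carriers of that guide versus all other post-QC cells). Each NTC guide is
#' tested against the union of all targeting windows' genes (optionally a
#' seeded subsample). Rows failing the detection filter, and guides without
#' carriers, are recorded in the skip log instead.
#'
#' @param dataset post-QC [screen_dataset()].
#' @param assignment an [assign_guides()] result on the same cells.
#' @param windows cis-windows from [build_windows()].
#' @param config a [run_config()] (detection threshold, scale factor, NTC
#'   subsample size, seed).
#' @return data.frame with columns guide_id, gene, n_test, n_control,
#'   pct_test, pct_control, log2fc, p_raw, test_class; sorted by guide then
#'   gene, with attribute `skip_log`.
#' @export
run_all_tests <- function(dataset, assignment, windows, config = run_config()) {
  stopifnot(inherits(dataset, "screen_dataset"))
  guides <- dataset$guides
  n <- nrow(dataset$cell_meta)
  if (nrow(assignment$assigned) != n) {
    stop2("assignment covers ", nrow(assignment$assigned), " cells but dataset has ", n)
  }
  norm <- normalize_expression(dataset$expr_counts, config$scale_factor,
                               cell_totals = dataset$cell_meta$total_umi)

  union_genes <- sort(unique(unlist(lapply(windows, `[[`, "genes"), use.names = FALSE)))
  ntc_genes <- union_genes
  if (!is.null(config$ntc_gene_subsample) &&
      config$ntc_gene_subsample < length(union_genes)) {
    ntc_genes <- with_substream(config$seed, "ntc_subsample",
                                sort(sample(union_genes, config$ntc_gene_subsample)))
    log_msg("NTC tests use a seeded subsample of %d of %d cis genes",
            length(ntc_genes), length(union_genes))
  }

  test_sets <- c(
    lapply(windows, `[[`, "genes"),
    setNames(rep(list(ntc_genes), sum(!is_targeting(guides))),
             guides$guide_id[!is_targeting(guides)])
  )
  test_sets <- test_sets[lengths(test_sets) > 0]
  needed <- sort(unique(unlist(test_sets, use.names = FALSE)))

  sub <- norm[, needed, drop = FALSE]
  exact <- n <= 12L
  if (!exact) {
    R <- apply(as.matrix(sub), 2, rank)
    tieT <- apply(R, 2, tie_term)
    E <- sub
    E@x <- expm1(E@x)
    det_total <- Matrix::colSums(sub > 0)
    sumE_total <- Matrix::colSums(E)
  }

  rows <- list()
  skips <- list()
  for (gid in names(test_sets)) {
    gset <- test_sets[[gid]]
    carriers <- guide_carriers(assignment, gid)
    cls <- if (guides$category[match(gid, guides$guide_id)] == "ntc") "ntc" else "targeting"
    if (length(carriers) == 0) {
      skips[[gid]] <- data.frame(guide_id = gid, gene = gset,
                                 reason = "no carrier cells", stringsAsFactors = FALSE)
      next
    }
    if (exact) {
      controls <- setdiff(seq_len(n), carriers)
      res <- lapply(gset, function(g) {
        r <- test_guide_gene(norm, carriers, controls, g,
                             detection_threshold = config$detection_threshold)
        if (inherits(r, "skipped_test")) {
          return(data.frame(guide_id = gid, gene = g, reason = r$reason,
                            stringsAsFactors = FALSE))
        }
        cbind(guide_id = gid, r, test_class = cls, stringsAsFactors = FALSE)
      })
      ok <- vapply(res, function(d) "p_raw" %in% names(d), logical(1))
      if (any(ok)) rows[[gid]] <- do.call(rbind, res[ok])
      if (any(!ok)) skips[[gid]] <- do.call(rbind, res[!ok])
      next
    }
    cols <- match(gset, needed)
    n1 <- length(carriers)
    n2 <- n - n1
    det1 <- Matrix::colSums(sub[carriers, cols, drop = FALSE] > 0)
    pct1 <- det1 / n1
    pct2 <- (det_total[cols] - det1) / n2
    keep <- pct1 > config$detection_threshold & pct2 > config$detection_threshold
    if (any(!keep)) {
      skips[[gid]] <- data.frame(guide_id = gid, gene = gset[!keep],
                                 reason = "detection", stringsAsFactors = FALSE)
    }
    if (!any(keep)) next
    kc <- cols[keep]
    W <- colSums(R[carriers, kc, drop = FALSE])
    mu <- n1 * (n + 1) / 2
    sigma2 <- rank_sum_sigma2(n1, n2, tieT[kc])
    p <- rank_sum_approx_p(W, mu, sigma2)
    sum1 <- Matrix::colSums(E[carriers, kc, drop = FALSE])
    log2fc <- log2(sum1 / n1 + 1) - log2((sumE_total[kc] - sum1) / n2 + 1)
    rows[[gid]] <- data.frame(
      guide_id = gid, gene = gset[keep], n_test = n1, n_control = n2,
      pct_test = pct1[keep], pct_control = pct2[keep],
      log2fc = log2fc, p_raw = p, test_class = cls, stringsAsFactors = FALSE
    )
  }

  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(guide_id = character(0), gene = character(0), n_test = integer(0),
               n_control = integer(0), pct_test = numeric(0), pct_control = numeric(0),
               log2fc = numeric(0), p_raw = numeric(0), test_class = character(0))
  out <- out[order(out$guide_id, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  if (!any(out$test_class == "ntc")) {
    stop2("no NTC tests were emitted; the empirical FDR is undefined")
  }
  skip_log <- if (length(skips)) do.call(rbind, skips) else
    data.frame(guide_id = character(0), gene = character(0), reason = character(0))
  rownames(skip_log) <- NULL
  attr(out, "skip_log") <- skip_log
  log_msg("DE testing: %d tests emitted (%d targeting, %d NTC), %d skipped",
          nrow(out), sum(out$test_class == "targeting"),
          sum(out$test_class == "ntc"), nrow(skip_log))
  out
}
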