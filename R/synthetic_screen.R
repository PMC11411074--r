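#' Synthetic screen configuration
#'
#' Parameters for generating a multiplex CRISPRa screen with known ground
#' truth. The generator emulates the statistical structure of a real screen:
#' a Poisson number of gRNA integrations per cell (including zeros), gene
#' expression drawn negative-binomially around log-normal baseline means with
#' per-cell size factors, a configurable fraction of near-silent genes
#' (baseline ~0.005 UMI/cell) that only respond under activation,
#' multiplicative fold effects applied to programmed target genes in carrier
#' cells, and gRNA capture UMIs whose lower tail straddles the assignment
#' threshold so that assignment is a real filter.
#'
#' @param n_cells number of cells.
#' @param moi_mean expected gRNA integrations per cell (Poisson mean).
#' @param n_guides named integer vector of guides per category
#'   (`tss_positive_control`, `promoter`, `enhancer_hit`, `enhancer_nonhit`,
#'   `ntc`).
#' @param n_genes,n_chroms,gene_length,gene_spacing synthetic genome layout:
#'   genes of `gene_length` bases placed every `gene_spacing` bases across
#'   `n_chroms` chromosomes.
#' @param enhancer_offset distance (bases) between an enhancer guide's site
#'   and its target TSS.
#' @param window_radius cis-window radius used to check layout feasibility.
#' @param base_mean_meanlog,base_mean_sdlog log-normal parameters of the
#'   baseline per-cell expression means.
#' @param near_silent_fraction,near_silent_mean fraction of genes forced to a
#'   tiny baseline mean, emulating genes not expressed in the assayed context.
#' @param nb_size negative-binomial size (inverse dispersion) of expression.
#' @param size_factor_sdlog log-normal sd of per-cell size factors.
#' @param n_hit_guides number of targeting guides given a real effect.
#' @param hit_fold multiplicative fold effect (scalar or one value per hit
#'   guide); 1 means no effect.
#' @param hit_target_min_mean optional floor on the baseline mean of genes
#'   targeted by hit guides (hit guides are drawn among eligible guides).
#' @param capture_mu,capture_size negative-binomial parameters of capture
#'   UMIs per true integration. The defaults put ~10% of true integrations
#'   below the 5-UMI assignment threshold.
#' @param mito_shape,lowq_mito_shape Beta shape pairs for the mitochondrial
#'   fraction of ordinary and low-quality cells.
#' @param lowq_fraction fraction of injected low-quality cells (high mito,
#'   low depth) to exercise QC.
#' @param background_umi_meanlog,background_umi_sdlog log-normal parameters
#'   of per-cell sequencing depth outside the simulated gene panel; total
#'   UMIs in the metadata are panel counts plus this background.
#' @param lowq_umi_scale depth multiplier for low-quality cells.
#' @param n_batches,context,sorted_fraction metadata labels.
#' @param seed integer seed; all draws flow through named substreams.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_cells = 2000, moi_mean = 2.5,
                       n_guides = c(tss_positive_control = 10, promoter = 30,
                                    enhancer_hit = 10, enhancer_nonhit = 10,
                                    ntc = 50),
                       n_genes = 60, n_chroms = 2,
                       gene_length = 1e4, gene_spacing = 3e5,
                       enhancer_offset = 5e4, window_radius = 1e6,
                       base_mean_meanlog = log(0.5), base_mean_sdlog = 1,
                       near_silent_fraction = 0.1, near_silent_mean = 0.005,
                       nb_size = 5, size_factor_sdlog = 0.3,
                       n_hit_guides = 20, hit_fold = 4,
                       hit_target_min_mean = NULL,
                       capture_mu = 20, capture_size = 2,
                       mito_shape = c(2, 38), lowq_mito_shape = c(12, 28),
                       lowq_fraction = 0.05,
                       background_umi_meanlog = log(8000),
                       background_umi_sdlog = 0.25, lowq_umi_scale = 0.15,
                       n_batches = 2, context = "synthetic",
                       sorted_fraction = 0, seed = 1L) {
  cats <- c("tss_positive_control", "promoter", "enhancer_hit", "enhancer_nonhit", "ntc")
  if (is.null(names(n_guides)) || !all(names(n_guides) %in% cats)) {
    stop2("n_guides must be named with guide categories")
  }
  full <- setNames(integer(length(cats)), cats)
  full[names(n_guides)] <- as.integer(n_guides)
  n_targeting <- sum(full[cats != "ntc"])
  stopifnot(
    n_cells >= 1, moi_mean > 0, n_genes >= 2, n_chroms >= 1,
    gene_length > 0, gene_spacing > gene_length, window_radius > 0,
    near_silent_fraction >= 0, near_silent_fraction <= 1,
    nb_size > 0, capture_mu > 0, capture_size > 0,
    n_hit_guides >= 0, n_hit_guides <= n_targeting, all(hit_fold >= 1),
    lowq_fraction >= 0, lowq_fraction < 1, n_batches >= 1
  )
  structure(list(
    n_cells = as.integer(n_cells), moi_mean = moi_mean, n_guides = full,
    n_genes = as.integer(n_genes), n_chroms = as.integer(n_chroms),
    gene_length = gene_length, gene_spacing = gene_spacing,
    enhancer_offset = enhancer_offset, window_radius = window_radius,
    base_mean_meanlog = base_mean_meanlog, base_mean_sdlog = base_mean_sdlog,
    near_silent_fraction = near_silent_fraction, near_silent_mean = near_silent_mean,
    nb_size = nb_size, size_factor_sdlog = size_factor_sdlog,
    n_hit_guides = as.integer(n_hit_guides), hit_fold = hit_fold,
    hit_target_min_mean = hit_target_min_mean,
    capture_mu = capture_mu, capture_size = capture_size,
    mito_shape = mito_shape, lowq_mito_shape = lowq_mito_shape,
    lowq_fraction = lowq_fraction,
    background_umi_meanlog = background_umi_meanlog,
    background_umi_sdlog = background_umi_sdlog,
    lowq_umi_scale = lowq_umi_scale,
    n_batches = as.integer(n_batches), context = context,
    sorted_fraction = sorted_fraction, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a synthetic genome layout and guide library
#'
#' Places genes deterministically (given the seed) on synthetic chromosomes
#' and builds a guide library in which every targeting guide's site is near
#' its programmed target's TSS (promoter/TSS guides just upstream, enhancer
#' guides `enhancer_offset` bases away), so the target always lies inside the
#' cis-window while at least one gene lies outside it.
#'
#' @param config a [sim_config()].
#' @return list with elements `genes` (annotation data.frame) and `guides`
#'   (guide library data.frame; NTC rows have `NA` site/target).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  per_chrom <- diff(round(seq(0, n, length.out = config$n_chroms + 1)))
  chrom <- rep(paste0("chrS", seq_len(config$n_chroms)), per_chrom)
  idx_on_chrom <- unlist(lapply(per_chrom, seq_len), use.names = FALSE)
  start <- idx_on_chrom * config$gene_spacing

  counts <- config$n_guides
  category <- rep(names(counts), counts)
  short <- c(tss_positive_control = "tss", promoter = "prom",
             enhancer_hit = "enh", enhancer_nonhit = "enhx", ntc = "ntc")
  guide_id <- unlist(lapply(names(counts), function(ct) {
    if (counts[[ct]] == 0) return(character(0))
    sprintf("%s_%03d", short[[ct]], seq_len(counts[[ct]]))
  }), use.names = FALSE)

  targeting <- category != "ntc"
  n_t <- sum(targeting)
  draws <- with_substream(config$seed, "layout", list(
    strand = sample(c("+", "-"), n, replace = TRUE),
    target_idx = if (n_t > 0) sample(n, n_t, replace = n_t > n) else integer(0),
    enh_sign = sample(c(-1, 1), max(n_t, 1), replace = TRUE)
  ))
  genes <- data.frame(
    chrom = chrom, start = start, end = start + config$gene_length,
    strand = draws$strand, symbol = sprintf("GENE%04d", seq_len(n)),
    stringsAsFactors = FALSE
  )
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  target_idx <- draws$target_idx
  enh_sign <- draws$enh_sign[seq_len(n_t)]
  site <- rep(NA_real_, length(guide_id))
  g_chrom <- rep(NA_character_, length(guide_id))
  target_gene <- rep(NA_character_, length(guide_id))
  if (n_t > 0) {
    up <- ifelse(genes$strand[target_idx] == "+", -1, 1)
    offset <- ifelse(category[targeting] == "enhancer_hit" |
                       category[targeting] == "enhancer_nonhit",
                     enh_sign * config$enhancer_offset,
                     up * ifelse(category[targeting] == "promoter", 200, 50))
    s <- pmax(0, tss[target_idx] + offset)
    if (any(abs(s - tss[target_idx]) > config$window_radius)) {
      stop2("layout infeasible: a guide site falls outside its target's cis-window")
    }
    site[targeting] <- s
    g_chrom[targeting] <- genes$chrom[target_idx]
    target_gene[targeting] <- genes$symbol[target_idx]
  }

  spacers <- with_substream(config$seed, "library", {
    vapply(seq_along(guide_id), function(i) {
      paste0("G", paste(sample(c("A", "C", "G", "T"), 19, replace = TRUE), collapse = ""))
    }, character(1))
  })
  guides <- data.frame(
    guide_id = guide_id, spacer = spacers, category = category,
    chrom = g_chrom, site = site, target_gene = target_gene,
    stringsAsFactors = FALSE
  )
  validate_guide_library(guides)

  # every window must exclude at least one gene
  if (n_t > 0) {
    for (i in which(targeting)) {
      out <- genes$chrom != guides$chrom[i] |
        genes$start > guides$site[i] + config$window_radius |
        genes$end <= guides$site[i] - config$window_radius
      if (!any(out)) {
        stop2("layout infeasible: guide ", guides$guide_id[i],
              " has every gene inside its cis-window; add genes or chromosomes")
      }
    }
  }
  list(genes = genes, guides = guides)
}

#' Simulate a full screen with ground truth
#'
#' Draws per-cell integration sets (Poisson multiplicity, guides sampled
#' without replacement), capture UMIs per true integration, and expression
#' counts with mean `size_factor(cell) * base_mean(gene) * prod(fold effects
#' of carried hit guides targeting the gene)`, negative-binomially dispersed.
#' Cell metadata (mitochondrial fraction, total UMIs including a depth
#' background, batch, context, sorted flag) is generated so QC thresholds are
#' exercisable, including a small injected low-quality population.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a [screen_dataset()]) and `truth`
#'   (`sim_truth`: per-guide programmed target and fold, per-cell true
#'   integration pattern, carrier counts, base means and size factors).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- simulate_genome(config)
  genes <- layout$genes
  guides <- layout$guides
  n_cells <- config$n_cells
  n_genes <- nrow(genes)
  n_guides <- nrow(guides)

  params <- with_substream(config$seed, "expression_params", {
    bm <- rlnorm(n_genes, config$base_mean_meanlog, config$base_mean_sdlog)
    n_silent <- floor(config$near_silent_fraction * n_genes)
    if (n_silent > 0) bm[sample(n_genes, n_silent)] <- config$near_silent_mean
    list(base_mean = bm, size_factor = rlnorm(n_cells, 0, config$size_factor_sdlog))
  })
  base_mean <- setNames(params$base_mean, genes$symbol)
  size_factor <- params$size_factor

  # programmed effects
  targeting_idx <- which(is_targeting(guides))
  fold <- rep(1, n_guides)
  if (config$n_hit_guides > 0) {
    eligible <- targeting_idx
    if (!is.null(config$hit_target_min_mean)) {
      eligible <- eligible[base_mean[guides$target_gene[eligible]] >= config$hit_target_min_mean]
    }
    if (length(eligible) < config$n_hit_guides) {
      stop2("only ", length(eligible), " guides eligible to carry a programmed effect, ",
            config$n_hit_guides, " requested")
    }
    hit_idx <- with_substream(config$seed, "effects",
                              sample(eligible, config$n_hit_guides))
    fold[hit_idx] <- rep_len(config$hit_fold, config$n_hit_guides)
  }

  # true integrations per cell
  integ <- with_substream(config$seed, "integrations", {
    k <- pmin(rpois(n_cells, config$moi_mean), n_guides)
    j <- unlist(lapply(k, function(ki) if (ki > 0) sample.int(n_guides, ki) else integer(0)),
                use.names = FALSE)
    list(i = rep.int(seq_len(n_cells), k), j = j)
  })
  true_integrations <- Matrix::sparseMatrix(
    i = integ$i, j = integ$j, x = 1, dims = c(n_cells, n_guides)
  )

  # capture UMIs per true integration
  cap <- with_substream(config$seed, "capture",
                        rnbinom(length(integ$i), mu = config$capture_mu,
                                size = config$capture_size))
  guide_counts <- Matrix::drop0(Matrix::sparseMatrix(
    i = integ$i, j = integ$j, x = cap, dims = c(n_cells, n_guides)
  ))

  # expression counts
  mu <- outer(size_factor, base_mean)
  for (g in which(fold > 1)) {
    carriers <- integ$i[integ$j == g]
    col <- match(guides$target_gene[g], genes$symbol)
    mu[carriers, col] <- mu[carriers, col] * fold[g]
  }
  expr <- with_substream(config$seed, "expression", {
    Matrix::Matrix(matrix(rnbinom(n_cells * n_genes, mu = as.vector(mu),
                                  size = config$nb_size),
                          nrow = n_cells), sparse = TRUE)
  })

  meta <- with_substream(config$seed, "qc_meta", {
    lowq <- runif(n_cells) < config$lowq_fraction
    mito <- ifelse(lowq,
                   rbeta(n_cells, config$lowq_mito_shape[1], config$lowq_mito_shape[2]),
                   rbeta(n_cells, config$mito_shape[1], config$mito_shape[2]))
    bg <- rlnorm(n_cells, config$background_umi_meanlog, config$background_umi_sdlog) *
      size_factor * ifelse(lowq, config$lowq_umi_scale, 1)
    data.frame(
      cell = sprintf("cell%06d", seq_len(n_cells)),
      total_umi = as.integer(round(bg)) + as.integer(Matrix::rowSums(expr)),
      mito_fraction = mito,
      batch = paste0("lane", sample.int(config$n_batches, n_cells, replace = TRUE)),
      context = config$context,
      sorted = runif(n_cells) < config$sorted_fraction,
      stringsAsFactors = FALSE
    )
  })

  dataset <- screen_dataset(expr, guide_counts, meta, genes, guides)
  truth <- structure(list(
    guide_effects = data.frame(guide_id = guides$guide_id,
                               category = guides$category,
                               target_gene = guides$target_gene,
                               fold = fold, stringsAsFactors = FALSE),
    true_integrations = true_integrations,
    carrier_counts = setNames(as.integer(Matrix::colSums(true_integrations)),
                              guides$guide_id),
    base_means = base_mean,
    size_factors = size_factor,
    config = config
  ), class = "sim_truth")
  list(dataset = dataset, truth = truth)
}

#' Fraction of true integrations expected to pass the assignment threshold
#'
#' Closed-form tail probability of the capture UMI distribution; used to
#' predict the detected multiplicity from the simulated one.
#'
#' @param config a [sim_config()].
#' @param min_umi assignment threshold.
#' @return probability a true integration yields `>= min_umi` capture UMIs.
#' @export
capture_detection_rate <- function(config, min_umi = 5) {
  1 - stats::pnbinom(min_umi - 1, size = config$capture_size, mu = config$capture_mu)
}
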