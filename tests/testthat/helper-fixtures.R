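# Shared fixtures and independent oracles, built in code at test time.

# 3 cells x 4 genes / 3 guides dataset with hand-placed counts
tiny_dataset <- function() {
  expr <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 3), x = c(2, 1),
                               dims = c(3, 4))
  guide <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(1, 2, 2), x = c(7, 5, 4),
                                dims = c(3, 3))
  cell_meta <- data.frame(
    cell = c("c1", "c2", "c3"), total_umi = c(5000, 6000, 7000),
    mito_fraction = c(0.05, 0.08, 0.02), batch = "lane1",
    context = "toy", sorted = FALSE, stringsAsFactors = FALSE
  )
  genes <- data.frame(
    chrom = "chrT", start = c(0, 1000, 2000, 3000),
    end = c(500, 1500, 2500, 3500), strand = c("+", "-", "+", "+"),
    symbol = paste0("g", 1:4), stringsAsFactors = FALSE
  )
  guides <- data.frame(
    guide_id = c("gd1", "gd2", "ntc1"),
    spacer = c(paste0("G", strrep("A", 19)), paste0("G", strrep("C", 19)),
               paste0("G", strrep("T", 19))),
    category = c("promoter", "enhancer_hit", "ntc"),
    chrom = c("chrT", "chrT", NA), site = c(10, 2100, NA),
    target_gene = c("g1", "g3", NA), stringsAsFactors = FALSE
  )
  screen_dataset(expr, guide, cell_meta, genes, guides)
}

# Exact two-tailed rank-sum P by bitmask enumeration over all labelings;
# independent of the combn-based path inside the package.
oracle_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  mu <- n1 * (n + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  masks <- 0:(2^n - 1)
  bits <- vapply(masks, function(m) as.integer(intToBits(m))[seq_len(n)],
                 integer(n))
  sel <- colSums(bits) == n1
  Ws <- as.vector(crossprod(r, bits[, sel, drop = FALSE]))
  mean(abs(Ws - mu) >= obs - 1e-9)
}

# small simulated screen reused by several tests
small_sim <- function(seed = 42, n_hit_guides = 6, ...) {
  simulate_screen(sim_config(
    n_cells = 400,
    n_guides = c(tss_positive_control = 4, promoter = 12, enhancer_hit = 4,
                 enhancer_nonhit = 4, ntc = 12),
    n_genes = 40, n_hit_guides = n_hit_guides, seed = seed, ...
  ))
}

# run_config suitable for synthetic data (QC thresholds on the synthetic
# depth scale)
sim_run_config <- function(...) {
  run_config(max_mito_fraction = 0.15, min_total_umi = 2000, ...)
}
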