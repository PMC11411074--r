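test_that("exact rank-sum P matches hand enumeration on the separation case", {
  r <- rank_sum_test(c(1.2, 1.5, 1.9), c(0.1, 0.4, 0.7))
  expect_true(r$exact)
  expect_equal(r$p.value, 2 / 20)
  # all values equal: P = 1
  expect_equal(rank_sum_test(rep(2, 3), rep(2, 5))$p.value, 1)
  expect_error(rank_sum_test(numeric(0), 1:3), "empty")
})

test_that("approximate path matches the tie/continuity-corrected reference", {
  set.seed(101)
  for (i in 1:20) {
    n1 <- sample(5:40, 1)
    n2 <- sample(20:200, 1)
    x <- rnorm(n1)
    y <- rnorm(n2, mean = runif(1, -1, 1))
    if (i %% 2 == 0) { x <- round(x); y <- round(y) }  # heavy ties
    mine <- rank_sum_test(x, y, exact_limit = 0L)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("window membership follows half-open interval overlap", {
  site <- 5e6
  genes2 <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(site + 999000, site + 1000001, 0, 10),
    end = c(site + 1001000, site + 1002000, 100, 500),
    strand = "+",
    symbol = c("in_overlap", "out_past_edge", "out_far", "other_chrom"),
    stringsAsFactors = FALSE
  )
  w <- genes_in_window("chr1", site, genes2, radius = 1e6)
  expect_true("in_overlap" %in% w$genes)
  expect_false("out_past_edge" %in% w$genes)
  expect_false("out_far" %in% w$genes)
  expect_false("other_chrom" %in% w$genes)
  # duplicated symbols inside the window appear once
  genes3 <- rbind(genes2, genes2[1, ])
  w3 <- genes_in_window("chr1", site, genes3, radius = 1e6)
  expect_equal(sum(w3$genes == "in_overlap"), 1L)
})

test_that("spacer search finds a unique 0-based site and flags ambiguity", {
  skip_if_not_installed("Biostrings")
  spacer <- "GATTACAGATTACAGATTAC"
  set.seed(7)
  bg <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE), collapse = "")
  seq1 <- paste0(substr(bg, 1, 1234), spacer, substr(bg, 1255, 10000))
  guides <- data.frame(
    guide_id = "gX", spacer = spacer, category = "promoter",
    chrom = NA_character_, site = NA_real_, target_gene = "gA",
    stringsAsFactors = FALSE
  )
  # brute-force oracle on the toy sequence
  oracle <- as.integer(regexpr(spacer, seq1, fixed = TRUE)) - 1L
  located <- locate_guide_sites(guides, c(toy = seq1))
  expect_equal(located$site, oracle)
  expect_equal(located$site, 1234)
  expect_equal(located$chrom, "toy")

  seq2 <- paste0(seq1, "TTTT", spacer)
  expect_error(locate_guide_sites(guides, c(toy = seq2)), "ambiguous")
  guides$spacer <- paste0("G", strrep("N", 19))
  guides$spacer <- paste0("G", strrep("A", 9), strrep("C", 10))
  expect_error(locate_guide_sites(guides, c(toy = "GGGG")), "no genomic match")
  # explicit sites pass through with no genome needed
  g2 <- data.frame(guide_id = "gY", spacer = spacer, category = "promoter",
                   chrom = "chr1", site = 55, target_gene = "gA",
                   stringsAsFactors = FALSE)
  expect_equal(locate_guide_sites(g2), g2)
})

test_that("normalization has the closed form and is depth-invariant", {
  m <- Matrix::Matrix(matrix(c(10, 0, 9990, 100), nrow = 2), sparse = TRUE)
  norm <- normalize_expression(m, scale_factor = 1e4)
  expect_equal(norm[1, 1], log(11))  # count 10 of total 10000
  expect_equal(norm[2, 2], 0 + log1p(1e4 * 100 / 100))
  expect_equal(norm[1, 2] == 0, FALSE)
  expect_equal(as.vector(normalize_expression(2 * m)), as.vector(normalize_expression(m)))
  m0 <- m
  m0[2, ] <- 0
  expect_error(normalize_expression(m0), "zero total")
})

test_that("detection filter and degenerate distributions behave as specified", {
  n <- 1000
  carriers <- 1:100
  controls <- 101:n
  counts <- Matrix::Matrix(0, n, 2, sparse = TRUE)
  counts[, 1] <- 5
  counts[101, 2] <- 3 # detected in ~0.11% of control cells
  colnames(counts) <- c("filler", "rare")
  norm <- normalize_expression(counts)
  skip <- test_guide_gene(norm, carriers, controls, "rare", detection_threshold = 0.002)
  expect_s3_class(skip, "skipped_test")

  flat <- Matrix::Matrix(matrix(5, n, 1, dimnames = list(NULL, "flat")), sparse = TRUE)
  normf <- normalize_expression(flat)
  res <- test_guide_gene(normf, carriers, controls, "flat")
  expect_equal(res$p_raw, 1)
  expect_equal(res$log2fc, 0)
  expect_error(test_guide_gene(normf, integer(0), controls, "flat"), "empty")
})

test_that("vectorized screen testing equals the scalar per-pair test", {
  sim <- small_sim(seed = 51)
  ds <- filter_cells(sim$dataset, 0.15, 2000)
  cfg <- sim_run_config(seed = 51)
  assignment <- assign_guides(ds$guide_counts, cfg$assign_min_umi)
  windows <- build_windows(ds$guides, ds$genes, cfg$window_radius)
  tab <- run_all_tests(ds, assignment, windows, cfg)
  n <- nrow(ds$cell_meta)
  expect_true(all(tab$n_test + tab$n_control == n))
  expect_true(all(tab$p_raw > 0 & tab$p_raw <= 1))
  expect_true(all(is.finite(tab$log2fc)))

  norm <- normalize_expression(ds$expr_counts, cfg$scale_factor, cell_totals = ds$cell_meta$total_umi)
  set.seed(1)
  for (i in sample(nrow(tab), 8)) {
    carriers <- guide_carriers(assignment, tab$guide_id[i])
    controls <- setdiff(seq_len(n), carriers)
    ref <- test_guide_gene(norm, carriers, controls, tab$gene[i],
                           detection_threshold = cfg$detection_threshold,
                           exact_limit = 0L)
    expect_equal(tab$p_raw[i], ref$p_raw, tolerance = 1e-12)
    expect_equal(tab$log2fc[i], ref$log2fc, tolerance = 1e-12)
    expect_equal(tab$n_test[i], ref$n_test)
  }
})

test_that("log2fc sign tracks the de-logged group mean difference", {
  sim <- small_sim(seed = 61)
  ds <- filter_cells(sim$dataset, 0.15, 2000)
  cfg <- sim_run_config(seed = 61)
  assignment <- assign_guides(ds$guide_counts, cfg$assign_min_umi)
  windows <- build_windows(ds$guides, ds$genes, cfg$window_radius)
  tab <- run_all_tests(ds, assignment, windows, cfg)
  norm <- normalize_expression(ds$expr_counts, cfg$scale_factor, cell_totals = ds$cell_meta$total_umi)
  E <- norm
  E@x <- expm1(E@x)
  n <- nrow(ds$cell_meta)
  set.seed(2)
  for (i in sample(nrow(tab), 10)) {
    carriers <- guide_carriers(assignment, tab$guide_id[i])
    m1 <- mean(E[carriers, tab$gene[i]])
    m0 <- mean(E[-carriers, tab$gene[i]])
    if (m1 != m0) expect_equal(sign(tab$log2fc[i]), sign(m1 - m0))
  }
})

test_that("NTC guides are tested against the union of cis genes", {
  genes <- data.frame(chrom = "chr1", start = c(0, 1500, 3000) * 1e3,
                      end = c(10, 1510, 3010) * 1e3, strand = "+",
                      symbol = c("A", "B", "C"), stringsAsFactors = FALSE)
  guides <- data.frame(
    guide_id = c("t1", "t2", "ntc1"),
    spacer = paste0("G", strrep("A", 19)),
    category = c("promoter", "promoter", "ntc"),
    chrom = c("chr1", "chr1", NA), site = c(7e5, 22e5, NA),
    target_gene = c("A", "B", NA), stringsAsFactors = FALSE
  )
  # windows: t1 -> {A, B}, t2 -> {B, C}
  w <- build_windows(guides, genes, radius = 1e6)
  expect_setequal(w$t1$genes, c("A", "B"))
  expect_setequal(w$t2$genes, c("B", "C"))
  n <- 60
  set.seed(3)
  expr <- Matrix::Matrix(matrix(rpois(n * 3, 5), n, 3,
                                dimnames = list(NULL, c("A", "B", "C"))),
                         sparse = TRUE)
  gm <- Matrix::Matrix(matrix(c(rep(5, 20), rep(0, n - 20),
                                rep(0, 20), rep(5, 20), rep(0, n - 40),
                                rep(0, 40), rep(5, n - 40)), n, 3), sparse = TRUE)
  meta <- data.frame(cell = paste0("c", 1:n), total_umi = 5000,
                     mito_fraction = 0.01, batch = "l1", context = "toy",
                     sorted = FALSE, stringsAsFactors = FALSE)
  ds <- screen_dataset(expr, gm, meta, genes, guides)
  cfg <- run_config(seed = 1)
  tab <- run_all_tests(ds, assign_guides(ds$guide_counts, 5), w, cfg)
  expect_setequal(tab$gene[tab$guide_id == "ntc1"], c("A", "B", "C"))
  expect_setequal(tab$gene[tab$guide_id == "t1"], c("A", "B"))
  # a guide with zero carriers is skipped with a logged reason
  gm2 <- gm
  gm2[, 1] <- 0
  ds2 <- screen_dataset(expr, gm2, meta, genes, guides)
  tab2 <- run_all_tests(ds2, assign_guides(ds2$guide_counts, 5), w, cfg)
  skip_log <- attr(tab2, "skip_log")
  expect_true(all(c("A", "B") %in% skip_log$gene[skip_log$guide_id == "t1"]))
  expect_equal(unique(skip_log$reason[skip_log$guide_id == "t1"]), "no carrier cells")
})

test_that("fold effects are recovered on the log2fc scale when means are well above the pseudocount", {
  for (f in c(2, 4)) {
    sim <- simulate_screen(sim_config(
      n_cells = 2500, moi_mean = 1.2,
      n_guides = c(promoter = 2, ntc = 2), n_genes = 30,
      n_hit_guides = 1, hit_fold = f,
      base_mean_meanlog = log(1), base_mean_sdlog = 0,
      near_silent_fraction = 0, seed = 90 + f
    ))
    eff <- sim$truth$guide_effects
    hit <- eff[eff$fold > 1, ]
    gidx <- match(hit$guide_id, sim$dataset$guides$guide_id)
    carriers <- which(sim$truth$true_integrations[, gidx] != 0)
    expect_gt(length(carriers), 300)
    # matrix treated as the whole transcriptome: totals are its row sums
    norm <- normalize_expression(sim$dataset$expr_counts)
    res <- test_guide_gene(norm, carriers,
                           setdiff(seq_len(nrow(sim$dataset$cell_meta)), carriers),
                           hit$target_gene)
    expect_lt(abs(res$log2fc - log2(f)), 0.3)
  }
})
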