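#' Sign proportion of fold changes, targeting vs NTC
#'
#' Counts positive log2 fold changes in the targeting and NTC test classes
#' and tests the 2x2 contingency (class x sign) with Fisher's exact test. A
#' one-sample binomial test of the targeting class against 0.5 is available
#' behind `method = "binomial"`.
#'
#' @param log2fc_targeting fold changes of targeting tests (typically
#'   restricted to intended guide-target pairs).
#' @param log2fc_ntc fold changes of NTC tests.
#' @param method `"fisher"` (default) or `"binomial"`.
#' @return list with per-class counts, `percent` (positive targeting share,
#'   one decimal, e.g. 70.6 for 276/391) and the test `p.value`.
#' @export
sign_proportion <- function(log2fc_targeting, log2fc_ntc,
                            method = c("fisher", "binomial")) {
  method <- match.arg(method)
  if (!length(log2fc_targeting)) stop2("no targeting fold changes supplied")
  if (method == "fisher" && !length(log2fc_ntc)) stop2("no NTC fold changes supplied")
  n_pos <- sum(log2fc_targeting > 0)
  n_tot <- length(log2fc_targeting)
  ntc_pos <- sum(log2fc_ntc > 0)
  ntc_tot <- length(log2fc_ntc)
  p <- if (method == "fisher") {
    fisher.test(matrix(c(n_pos, n_tot - n_pos, ntc_pos, ntc_tot - ntc_pos), 2))$p.value
  } else {
    stats::binom.test(n_pos, n_tot, p = 0.5)$p.value
  }
  list(n_positive = n_pos, n_total = n_tot,
       percent = round(100 * n_pos / n_tot, 1),
       ntc_positive = ntc_pos, ntc_total = ntc_tot,
       method = method, p.value = p)
}

#' Proximity enrichment of hits to their upregulated genes
#'
#' For each hit, the distance is `|guide site - TSS of the upregulated
#' gene|`, with the strand-aware TSS (interval start on "+", end on "-"). The
#' null distribution assigns each NTC test's guide a window drawn uniformly
#' (seeded) from the targeting guides' windows and a gene drawn uniformly
#' within that window, realising "a target randomly selected from the same
#' gene set" while keeping distances well-defined for guides with no genomic
#' site. A one-sided rank-sum test asks whether hit distances are smaller
#' than null distances.
#'
#' @param hits data.frame with `guide_id` and `gene` of each hit.
#' @param windows [build_windows()] output (provides site and members per
#'   targeting guide).
#' @param gene_annotations gene annotation data.frame.
#' @param ntc_results NTC rows of the DE table (one null draw per row's
#'   guide, deduplicated to guides).
#' @param seed seed for the null draw.
#' @return list with `hit_distances`, `null_distances` (data.frames) and
#'   `p.value`.
#' @export
proximity_enrichment <- function(hits, windows, gene_annotations, ntc_results,
                                 seed = 1L) {
  if (!nrow(hits)) stop2("hit table is empty")
  tss <- setNames(ifelse(gene_annotations$strand == "+",
                         gene_annotations$start, gene_annotations$end),
                  gene_annotations$symbol)
  dist_for <- function(guide_id, gene) {
    w <- windows[[guide_id]]
    if (is.null(w)) stop2("no window for guide ", guide_id)
    abs(w$site - tss[[gene]])
  }
  hit_d <- data.frame(
    guide_id = hits$guide_id, gene = hits$gene,
    distance = mapply(dist_for, hits$guide_id, hits$gene),
    stringsAsFactors = FALSE
  )
  ntc_ids <- unique(ntc_results$guide_id)
  if (!length(ntc_ids)) stop2("no NTC guides supplied for the null draw")
  null_d <- with_substream(seed, "proximity_null", {
    wins <- sample(names(windows), length(ntc_ids), replace = TRUE)
    gene <- vapply(wins, function(wn) {
      g <- windows[[wn]]$genes
      if (length(g) == 1) g else sample(g, 1)
    }, character(1))
    data.frame(guide_id = ntc_ids, window_of = wins, gene = gene,
               distance = mapply(dist_for, wins, gene),
               stringsAsFactors = FALSE)
  })
  p <- stats::wilcox.test(hit_d$distance, null_d$distance,
                          alternative = "less", exact = FALSE)$p.value
  list(hit_distances = hit_d, null_distances = null_d, p.value = p)
}

#' Correlation of fold changes across cellular contexts
#'
#' Pearson correlation of log2 fold changes for a set of (guide, gene) pairs
#' measured in two screens (e.g. two cell types). Pairs missing from either
#' table are excluded and logged.
#'
#' @param results_A,results_B DE tables with `guide_id`, `gene`, `log2fc`.
#' @param pair_set data.frame of `guide_id`, `gene` pairs to compare.
#' @return list with `r`, `n`, and the paired table.
#' @export
cross_context_correlation <- function(results_A, results_B, pair_set) {
  key <- function(d) paste(d$guide_id, d$gene, sep = "\r")
  ka <- match(key(pair_set), key(results_A))
  kb <- match(key(pair_set), key(results_B))
  ok <- !is.na(ka) & !is.na(kb)
  if (any(!ok)) {
    log_msg("cross-context: %d of %d pairs missing in one context, excluded",
            sum(!ok), nrow(pair_set))
  }
  if (sum(ok) < 3) stop2("fewer than 3 shared pairs; correlation undefined")
  paired <- data.frame(
    guide_id = pair_set$guide_id[ok], gene = pair_set$gene[ok],
    log2fc_A = results_A$log2fc[ka[ok]], log2fc_B = results_B$log2fc[kb[ok]],
    stringsAsFactors = FALSE
  )
  list(r = cor(paired$log2fc_A, paired$log2fc_B), n = nrow(paired),
       pairs = paired)
}

#' Singleton bulk-validation test
#'
#' Compares target-gene abundance in the replicate lines carrying one gRNA
#' (typically 3) against the remaining control lines (typically 21), exactly
#' as in the screen's bulk validation: a two-tailed rank-sum P computed by
#' exhaustive enumeration over all `choose(n, n_test)` label assignments
#' (2024 for 3 vs 21), and `log2fc = log2((mean test + 1)/(mean control +
#' 1))`. The validation passes when `P < alpha` and the fold change is
#' positive (the screen validates upregulation specifically).
#'
#' @param test_abundances abundances (e.g. TPM) of the gRNA-carrying lines.
#' @param control_abundances abundances of the control lines.
#' @param alpha significance threshold (default 0.1).
#' @param expected_lengths group sizes to enforce, default `c(3, 21)`; set to
#'   `NULL` to accept any sizes.
#' @return list with `log2fc`, `p.value` (exact), `pass`.
#' @export
singleton_validation_test <- function(test_abundances, control_abundances,
                                      alpha = 0.1, expected_lengths = c(3, 21)) {
  if (!is.null(expected_lengths)) {
    if (length(test_abundances) != expected_lengths[1] ||
        length(control_abundances) != expected_lengths[2]) {
      stop2("expected ", expected_lengths[1], " test and ", expected_lengths[2],
            " control abundances, got ", length(test_abundances), " and ",
            length(control_abundances))
    }
  }
  n <- length(test_abundances) + length(control_abundances)
  ts <- rank_sum_test(test_abundances, control_abundances, exact_limit = n)
  log2fc <- log2((mean(test_abundances) + 1) / (mean(control_abundances) + 1))
  list(log2fc = log2fc, p.value = ts$p.value,
       pass = ts$p.value < alpha && log2fc > 0)
}
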