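#' Empirical P-value against the NTC null
#'
#' `p_empirical = (#{NTC raw P strictly below p_raw} + 1) / (N_ntc + 1)`.
#' Ties between an NTC P-value and the tested P-value count as not-lower.
#' The achievable floor is `1/(N_ntc + 1)`: a small NTC set provably limits
#' significance, so a warning is logged when fewer than 100 NTC tests are
#' supplied.
#'
#' @param p_raw raw P-value(s) of targeting tests (vectorized).
#' @param ntc_pvalues raw P-values of all NTC tests (non-empty).
#' @return empirical P-values in `[1/(N+1), 1]`, non-decreasing in `p_raw`.
#' @export
empirical_pvalue <- function(p_raw, ntc_pvalues) {
  if (length(ntc_pvalues) == 0) stop2("empirical_pvalue: NTC P-value vector is empty")
  if (length(ntc_pvalues) < 100) {
    warning("only ", length(ntc_pvalues), " NTC tests: empirical P floor is ",
            signif(1 / (length(ntc_pvalues) + 1), 3), call. = FALSE)
  }
  s <- sort(ntc_pvalues)
  below <- findInterval(p_raw, s, left.open = TRUE)  # == #{s < p}, strict
  (below + 1) / (length(s) + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjustment (wraps [stats::p.adjust()]) with input validation; kept
#' as a named operation because the screen applies it to empirical P-values
#' of targeting tests only.
#'
#' @param pvalues values in (0, 1].
#' @return adjusted P-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues <= 0 | pvalues > 1)) stop2("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Call empirical-FDR hits
#'
#' Computes empirical P-values for the targeting rows of a DE result table
#' against its NTC rows, BH-adjusts them (targeting rows only; NTC rows are
#' the null material, not hypotheses), and flags hits where the adjusted
#' value falls strictly below the threshold.
#'
#' @param results table from [run_all_tests()].
#' @param efdr_threshold hit threshold (default 0.1, strict `<`).
#' @param guides optional guide library; when given, per-category hit counts
#'   and intended-target flags (`gene == programmed target`) are reported.
#' @return list with `table` (all rows with `p_empirical`, `p_adj`, `hit`
#'   columns; `NA` for NTC rows), `hits` (the flagged subset) and `counts`.
#' @export
call_hits <- function(results, efdr_threshold = 0.1, guides = NULL) {
  stopifnot(efdr_threshold > 0, efdr_threshold <= 1)
  is_ntc <- results$test_class == "ntc"
  if (!any(is_ntc)) stop2("result table has no NTC rows")
  if (!any(!is_ntc)) stop2("result table has no targeting rows")
  results$p_empirical <- NA_real_
  results$p_adj <- NA_real_
  results$hit <- NA
  results$p_empirical[!is_ntc] <- empirical_pvalue(results$p_raw[!is_ntc],
                                                   results$p_raw[is_ntc])
  results$p_adj[!is_ntc] <- bh_adjust(results$p_empirical[!is_ntc])
  results$hit[!is_ntc] <- results$p_adj[!is_ntc] < efdr_threshold

  hits <- results[!is_ntc & results$hit, , drop = FALSE]
  counts <- list(n_targeting_tests = sum(!is_ntc), n_ntc_tests = sum(is_ntc),
                 n_hits = nrow(hits))
  if (!is.null(guides)) {
    idx <- match(results$guide_id, guides$guide_id)
    results$category <- guides$category[idx]
    results$intended <- !is.na(guides$target_gene[idx]) &
      results$gene == guides$target_gene[idx]
    hits <- results[!is_ntc & results$hit, , drop = FALSE]
    counts$hits_by_category <- table(hits$category)
    counts$n_hits_intended <- sum(hits$intended)
    counts$n_hits_other_gene <- sum(!hits$intended)
  }
  log_msg("EFDR < %g: %d hits among %d targeting tests (%d NTC tests)",
          efdr_threshold, nrow(hits), counts$n_targeting_tests, counts$n_ntc_tests)
  list(table = results, hits = hits, counts = counts)
}

#' Quantile-quantile data for targeting vs NTC tests
#'
#' When the NTC vector is larger than the targeting one it is downsampled
#' without replacement (seeded) to the targeting count, matching how screen
#' QQ plots are drawn. Expected quantiles are `i/(n+1)`.
#'
#' @param targeting_p,ntc_p raw P-value vectors (non-empty).
#' @param seed seed for the downsample.
#' @return data.frame with columns `class`, `expected`, `observed`, sorted
#'   within class.
#' @export
qq_data <- function(targeting_p, ntc_p, seed = 1L) {
  if (!length(targeting_p) || !length(ntc_p)) stop2("both P-value vectors must be non-empty")
  if (length(ntc_p) > length(targeting_p)) {
    ntc_p <- with_substream(seed, "qq_downsample",
                            sample(ntc_p, length(targeting_p)))
  }
  one <- function(p, cls) {
    p <- sort(p)
    data.frame(class = cls, expected = seq_along(p) / (length(p) + 1),
               observed = p, stringsAsFactors = FALSE)
  }
  rbind(one(targeting_p, "targeting"), one(ntc_p, "ntc"))
}
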