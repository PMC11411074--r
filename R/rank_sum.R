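#' Two-tailed Wilcoxon rank-sum test
#'
#' The workhorse test of the screen: carrier cells versus control cells for
#' one gene. Small problems (pooled size at most `exact_limit`) are solved
#' exactly by enumerating every assignment of group labels and counting
#' rank sums at least as far from their expectation as the observed one; this
#' handles ties without approximation. Larger problems use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x numeric values of the test (carrier) group.
#' @param y numeric values of the control group.
#' @param exact_limit largest pooled size solved by exact enumeration.
#' @return list with `statistic` (rank sum of `x`), `p.value` (two-tailed,
#'   in (0, 1]), `exact` flag, and the group sizes.
#' @export
rank_sum_test <- function(x, y, exact_limit = 12L) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0) stop2("rank_sum_test: test group is empty")
  if (n2 == 0) stop2("rank_sum_test: control group is empty")
  n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (n <= exact_limit) {
    combs <- combn(n, n1)
    Ws <- colSums(matrix(r[combs], nrow = n1))
    p <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
    list(statistic = W, p.value = p, exact = TRUE, n_test = n1, n_control = n2)
  } else {
    sigma2 <- rank_sum_sigma2(n1, n2, tie_term(r))
    p <- rank_sum_approx_p(W, mu, sigma2)
    list(statistic = W, p.value = p, exact = FALSE, n_test = n1, n_control = n2)
  }
}

# sum over tied groups of (t^3 - t), from a midrank vector
tie_term <- function(r) {
  t <- tabulate(match(r, unique(r)))
  sum(t^3 - t)
}

rank_sum_sigma2 <- function(n1, n2, tie_t) {
  n <- n1 + n2
  (n1 * n2 / 12) * ((n + 1) - tie_t / (n * (n - 1)))
}

# vectorised two-tailed normal-approximation p with continuity correction
rank_sum_approx_p <- function(W, mu, sigma2) {
  p <- rep(1, length(W))
  ok <- sigma2 > 0
  z <- pmax(abs(W[ok] - mu) - 0.5, 0) / sqrt(sigma2[ok])
  p[ok] <- pmin(1, 2 * pnorm(-z))
  pmax(p, .Machine$double.xmin)
}
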