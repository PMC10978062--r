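#' Wilcoxon rank-sum (Mann-Whitney) two-sample test
#'
#' Compares two independent samples by the rank-sum statistic `W`: the sum
#' of the mid-ranks of `a` in the pooled sample. When both samples have at
#' most `exact_max_n` observations, the two-sided P is exact, obtained by
#' enumerating all `choose(n + m, n)` labelings of the pooled mid-ranks
#' (ties therefore handled exactly, conditional on the observed values).
#' Otherwise a tie-corrected normal approximation with continuity
#' correction is used. The two-sided exact P is twice the smaller tail
#' probability, capped at 1.
#'
#' @param a,b numeric samples (non-empty; `NA`s dropped).
#' @param exact_max_n per-sample size limit for exact enumeration
#'   (default 10).
#' @return A `rank_test` list: `W`, `p_value`, `method` (`"exact"` or
#'   `"normal"`), `n`, `m`.
#' @examples
#' wilcoxon_two_sample(c(1, 2), c(3, 4))  # exact P = 1/3
#' @export
wilcoxon_two_sample <- function(a, b, exact_max_n = 10) {
  a <- as.numeric(a[!is.na(a)]); b <- as.numeric(b[!is.na(b)])
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) stop("both samples must be non-empty")
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n)])
  N <- n + m
  if (n <= exact_max_n && m <= exact_max_n) {
    sums <- colSums(matrix(r[combn(N, n)], nrow = n))
    eps <- 1e-9
    p_le <- mean(sums <= W + eps)
    p_ge <- mean(sums >= W - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (N + 1) / 2
    ties <- as.numeric(table(r))
    sig2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal"
  }
  structure(list(W = W, p_value = p, method = method, n = n, m = m),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum test (%s): W = %g, two-sided P = %.4g (n = %d, m = %d)\n",
              x$method, x$W, x$p_value, x$n, x$m))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks, with the usual t approximation for the
#' two-sided P: `t = rho sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
#' freedom. Perfectly monotone data give `rho = +/-1` and `P = 0`
#' (degenerate t); constant input has no defined correlation and errors.
#'
#' @param x,y paired numeric vectors, n >= 3 complete pairs.
#' @return A list: `rho`, `p_value`, `n`.
#' @examples
#' spearman_rank(1:10, log(1:10))  # rho = 1
#' @export
spearman_rank <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3) stop("Spearman needs at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("constant input: rank correlation undefined")
  rho <- cor(rx, ry)
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}
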