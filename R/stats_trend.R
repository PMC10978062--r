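#' Mann-Kendall trend test
#'
#' Nonparametric test for a monotone trend in an ordered series.
#' `S = sum over i < j of sign(x_j - x_i)`; its variance uses the standard
#' tie correction
#' `var(S) = (n (n-1) (2n+5) - sum_g t_g (t_g - 1) (2 t_g + 5)) / 18`
#' over tie groups of size `t_g`. The normal deviate applies a +/-1
#' continuity correction, and the two-sided P comes from the normal
#' approximation. Kendall's tau is tie-adjusted
#' (`tau_b = S / sqrt((D - U) D)` with `D = n (n-1)/2` and
#' `U = sum t_g (t_g - 1)/2`; the time index is untied).
#'
#' An all-equal series is degenerate: it returns `tau = 0`, `P = 1` and is
#' flagged via the `degenerate` field.
#'
#' @param x numeric series in time order (`NA`s dropped); n >= 3.
#' @return A `trend_result`: `S`, `var_s`, `z`, `tau`, `p_value`, `n`,
#'   `degenerate`.
#' @examples
#' mann_kendall(c(1, 3, 2, 4, 6, 5, 7))
#' @export
mann_kendall <- function(x) {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("Mann-Kendall needs at least 3 observations")
  parts <- mk_parts(x)
  trend_from_parts(parts$S, parts$var_s, parts$denom, n,
                   degenerate = parts$var_s == 0)
}

# S, tie-corrected variance and the tau_b denominator for one season/series.
mk_parts <- function(x) {
  n <- length(x)
  d <- outer(x, x, "-")
  S <- sum(sign(d[lower.tri(d)]))
  t_g <- as.numeric(table(x))
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(t_g * (t_g - 1) * (2 * t_g + 5))) / 18
  D <- n * (n - 1) / 2
  U <- sum(t_g * (t_g - 1) / 2)
  list(S = S, var_s = var_s, denom = sqrt((D - U) * D))
}

trend_from_parts <- function(S, var_s, denom, n, degenerate = FALSE) {
  tau <- if (denom > 0) S / denom else 0
  if (var_s > 0) {
    z <- (S - sign(S)) / sqrt(var_s)  # continuity correction
    p <- 2 * pnorm(-abs(z))
  } else {
    z <- 0; p <- 1
  }
  structure(list(S = S, var_s = var_s, z = z, tau = tau, p_value = p,
                 n = n, degenerate = degenerate),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("%s trend test: S = %.0f, var(S) = %.3f, Z = %.3f, tau = %.4f, two-sided P = %.4g (n = %d)%s\n",
              if (!is.null(x$seasons)) "Seasonal Mann-Kendall" else "Mann-Kendall",
              x$S, x$var_s, x$z, x$tau, x$p_value, x$n,
              if (isTRUE(x$degenerate)) " [degenerate: all values tied]" else ""))
  invisible(x)
}

#' Seasonal Mann-Kendall trend test
#'
#' Removes seasonal confounding by comparing values only across years within
#' the same season: `S_total = sum_k S_k` over within-season year pairs,
#' `var_total = sum_k var_k` (seasonal statistics treated as independent),
#' with Z and two-sided P from the totals (continuity-corrected) and
#' `tau = S_total / sum_k D_k` where `D_k = n_k (n_k - 1) / 2`.
#'
#' Seasons are typically calendar months. At most one value per (year,
#' season) is allowed; seasons with fewer than two years are skipped, and at
#' least one season must have three or more years.
#'
#' @param series a data.frame with columns `year`, `season`, `value`
#'   (missing cells simply absent or `NA`).
#' @return A `trend_result` with an added `seasons` field (number of seasons
#'   contributing).
#' @examples
#' s <- expand.grid(year = 2000:2009, season = 1:12)
#' s$value <- -0.3 * (s$year - 2000) + sin(s$season) + rnorm(nrow(s), 0, 0.5)
#' seasonal_mann_kendall(s)
#' @export
seasonal_mann_kendall <- function(series) {
  stopifnot(all(c("year", "season", "value") %in% names(series)))
  series <- series[!is.na(series$value), , drop = FALSE]
  if (anyDuplicated(series[c("year", "season")]))
    stop("at most one value per (year, season) cell")
  S <- V <- Dsum <- 0
  n_total <- 0L
  used <- 0L
  max_years <- 0L
  for (k in unique(series$season)) {
    sub <- series[series$season == k, , drop = FALSE]
    sub <- sub[order(sub$year), , drop = FALSE]
    nk <- nrow(sub)
    if (nk < 2) next
    p <- mk_parts(sub$value)
    S <- S + p$S
    V <- V + p$var_s
    Dsum <- Dsum + nk * (nk - 1) / 2
    n_total <- n_total + nk
    used <- used + 1L
    max_years <- max(max_years, nk)
  }
  if (used == 0L || max_years < 3L)
    stop("need at least one season with >= 3 years")
  res <- trend_from_parts(S, V, Dsum, n_total, degenerate = V == 0)
  res$tau <- if (Dsum > 0) S / Dsum else 0
  res$seasons <- used
  res
}
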