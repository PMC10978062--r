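#' Two-way ANOVA with Tukey HSD on log10 settling velocities
#'
#' Settling velocities are log10-transformed (they are positive and
#' right-skewed; the transform brings them close to normal) and decomposed
#' by treatment, incubation time point, and their interaction. Sums of
#' squares are Type II, appropriate for the unbalanced layouts roller-tank
#' experiments produce: each main effect is tested against the model
#' containing the other main effect, and the interaction against the
#' additive model, via nested residual-sum-of-squares differences. F tests
#' use the residual mean square of the full model. When some
#' treatment-by-time cells are empty, the interaction is not estimable and
#' is dropped (reported in the result).
#'
#' Pairwise comparisons of the non-empty treatment-by-time cell means use
#' Tukey's honest significant difference on the studentized range.
#'
#' @param velocity positive settling velocities (m/day); zero or negative
#'   values are an error — exclude rising/stationary particles first (see
#'   [compare_treatments()]).
#' @param treatment,time_point factors (or coercible) with >= 2 levels each.
#' @return A `settling_anova` list: `table` (term, df, sum_sq, mean_sq,
#'   statistic F, p_value), `tukey` (data.frame of cell-mean pairs with
#'   difference, studentized q and adjusted P), `interaction_dropped`,
#'   `empty_cells`.
#' @examples
#' set.seed(1)
#' v <- rlnorm(40, log(20), 0.2) * rep(c(1, 10), each = 20)
#' tr <- rep(c("control", "gypsum"), each = 20)
#' tp <- rep(rep(c(3, 15), each = 10), 2)
#' anova_settling(v, tr, tp)
#' @export
anova_settling <- function(velocity, treatment, time_point) {
  velocity <- as.numeric(velocity)
  if (any(!is.finite(velocity)) || any(velocity <= 0))
    stop("all velocities must be positive and finite before log10 transform")
  A <- factor(treatment)
  B <- factor(time_point)
  if (nlevels(A) < 2 || nlevels(B) < 2)
    stop("need at least 2 levels per factor")
  y <- log10(velocity)
  cells <- table(A, B)
  empty <- sum(cells == 0)
  drop_int <- empty > 0
  f_a <- lm(y ~ A)
  f_b <- lm(y ~ B)
  f_ab <- lm(y ~ A + B)
  f_full <- if (drop_int) f_ab else lm(y ~ A * B)
  ss_a <- deviance(f_b) - deviance(f_ab)
  df_a <- df.residual(f_b) - df.residual(f_ab)
  ss_b <- deviance(f_a) - deviance(f_ab)
  df_b <- df.residual(f_a) - df.residual(f_ab)
  ss_int <- deviance(f_ab) - deviance(f_full)
  df_int <- df.residual(f_ab) - df.residual(f_full)
  ss_res <- deviance(f_full)
  df_res <- df.residual(f_full)
  if (df_res <= 0) stop("no residual degrees of freedom")
  mse <- ss_res / df_res
  terms <- data.frame(
    term = c("treatment", "time_point",
             if (!drop_int) "treatment:time_point", "residuals"),
    df = c(df_a, df_b, if (!drop_int) df_int, df_res),
    sum_sq = c(ss_a, ss_b, if (!drop_int) ss_int, ss_res))
  terms$mean_sq <- terms$sum_sq / terms$df
  terms$statistic <- c(terms$mean_sq[-nrow(terms)] / mse, NA)
  terms$p_value <- ifelse(is.na(terms$statistic), NA,
                          pf(terms$statistic, terms$df, df_res,
                             lower.tail = FALSE))
  structure(list(table = terms,
                 tukey = tukey_cells(y, A, B, mse, df_res),
                 interaction_dropped = drop_int,
                 empty_cells = empty,
                 df_residual = df_res, mse = mse),
            class = "settling_anova")
}

# Tukey HSD over the non-empty A-by-B cell means.
tukey_cells <- function(y, A, B, mse, df_res) {
  cell <- interaction(A, B, sep = ":", drop = TRUE)
  means <- tapply(y, cell, mean)
  ns <- tapply(y, cell, length)
  k <- length(means)
  if (k < 2) return(NULL)
  pairs <- combn(k, 2)
  diffs <- means[pairs[2, ]] - means[pairs[1, ]]
  se <- sqrt(mse / 2 * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
  q <- abs(diffs) / se
  data.frame(
    cell_1 = names(means)[pairs[1, ]],
    cell_2 = names(means)[pairs[2, ]],
    diff_log10 = as.numeric(diffs),
    q = as.numeric(q),
    p_adj = ptukey(as.numeric(q), nmeans = k, df = df_res,
                   lower.tail = FALSE),
    row.names = NULL)
}

#' @export
print.settling_anova <- function(x, ...) {
  cat("Two-way Type II ANOVA on log10 settling velocity\n")
  tab <- x$table
  tab$sum_sq <- signif(tab$sum_sq, 4)
  tab$mean_sq <- signif(tab$mean_sq, 4)
  tab$statistic <- signif(tab$statistic, 4)
  tab$p_value <- signif(tab$p_value, 4)
  print(tab, row.names = FALSE)
  if (x$interaction_dropped)
    cat(sprintf("interaction dropped: %d empty treatment-by-time cell(s)\n",
                x$empty_cells))
  if (!is.null(x$tukey))
    cat(sprintf("Tukey HSD over %d cell-mean pairs (smallest adjusted P = %.4g)\n",
                nrow(x$tukey), min(x$tukey$p_adj)))
  invisible(x)
}
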