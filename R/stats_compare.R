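#' Paired comparison with normality screening
#'
#' Shapiro-Wilk on the paired differences, then a paired t-test. When
#' normality is rejected at alpha = 0.05 a Wilcoxon signed-rank result is
#' attached alongside (never silently substituted). Zero-variance
#' differences are degenerate: `t = 0`, `p = 1` with a flag.
#'
#' @param x,y Paired measurements (same units, same length >= 3).
#' @param alternative Passed to [stats::t.test()] (`"two.sided"`,
#'   `"less"`, `"greater"`, for `x - y`).
#' @return A list of class `stat_report`: `test`, `statistic`, `df`,
#'   `p_value`, `shapiro_p`, `normality_rejected`, `wilcoxon` (or NULL),
#'   `degenerate`.
#' @export
paired_compare <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  d <- x - y
  if (stats::sd(d) == 0) {
    out <- list(test = "paired t", statistic = 0, df = length(d) - 1L,
                p_value = 1, shapiro_p = NA_real_,
                normality_rejected = FALSE, wilcoxon = NULL,
                degenerate = TRUE)
    class(out) <- "stat_report"
    return(out)
  }
  sw <- stats::shapiro.test(d)
  tt <- stats::t.test(x, y, paired = TRUE, alternative = alternative)
  rejected <- sw$p.value < 0.05
  wil <- NULL
  if (rejected) {
    wil <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, alternative = alternative))
    wil <- list(statistic = unname(wil$statistic), p_value = wil$p.value)
  }
  out <- list(test = "paired t", statistic = unname(tt$statistic),
              df = unname(tt$parameter), p_value = tt$p.value,
              shapiro_p = sw$p.value, normality_rejected = rejected,
              wilcoxon = wil, degenerate = FALSE)
  class(out) <- "stat_report"
  out
}

#' One-way repeated-measures ANOVA with Tukey post-hoc tests
#'
#' Within-subject one-way RM ANOVA (each unit measured under every
#' condition; balanced complete design required), followed by Tukey HSD on
#' the condition means using the RM error term. No sphericity correction is
#' applied by default (`gg_correction = TRUE` applies Greenhouse-Geisser).
#'
#' @param df Long data.frame with columns `unit`, `condition`, `value`.
#' @param gg_correction Apply the Greenhouse-Geisser epsilon correction to
#'   the ANOVA df and p.
#' @return A list of class `stat_report`: `test`, `F`, `df1`, `df2`,
#'   `p_value`, `ms_error`, `tukey` (pairwise table), `degenerate`,
#'   `gg_epsilon` (if corrected).
#' @export
rm_anova_tukey <- function(df, gg_correction = FALSE) {
  stopifnot(all(c("unit", "condition", "value") %in% names(df)))
  tab <- table(df$unit, df$condition)
  if (any(tab != 1L)) stop("unbalanced design: need one value per unit x condition")
  units <- unique(df$unit)
  conds <- unique(df$condition)
  n <- length(units); k <- length(conds)
  if (n < 3L || k < 2L) stop("need >= 3 units and >= 2 conditions")
  wide <- matrix(NA_real_, n, k, dimnames = list(units, conds))
  wide[cbind(match(df$unit, units), match(df$condition, conds))] <- df$value

  grand <- mean(wide)
  ss_cond <- n * sum((colMeans(wide) - grand)^2)
  ss_subj <- k * sum((rowMeans(wide) - grand)^2)
  ss_tot <- sum((wide - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  degenerate <- ms_err <= .Machine$double.eps * max(1, abs(ss_tot))
  Fval <- if (degenerate && ss_cond == 0) 0 else ms_cond / ms_err
  eps <- NULL
  if (gg_correction) {
    # Greenhouse-Geisser epsilon from the double-centred covariance matrix
    S <- stats::cov(wide)
    Sc <- S - outer(rowMeans(S), colMeans(S), "+") + mean(S)
    eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
    p <- stats::pf(Fval, eps * df1, eps * df2, lower.tail = FALSE)
  } else {
    p <- stats::pf(Fval, df1, df2, lower.tail = FALSE)
  }
  if (degenerate && ss_cond == 0) p <- 1

  pairs <- utils::combn(conds, 2)
  tukey <- data.frame(
    a = pairs[1L, ], b = pairs[2L, ],
    diff = colMeans(wide)[pairs[2L, ]] - colMeans(wide)[pairs[1L, ]],
    row.names = NULL)
  se <- sqrt(ms_err / n)
  tukey$q <- abs(tukey$diff) / se
  tukey$p_adj <- if (degenerate) rep(NA_real_, nrow(tukey)) else
    stats::ptukey(tukey$q, nmeans = k, df = df2, lower.tail = FALSE)
  out <- list(test = "one-way RM ANOVA + Tukey HSD",
              F = Fval, df1 = df1, df2 = df2, p_value = p,
              ms_error = ms_err, tukey = tukey,
              degenerate = degenerate, gg_epsilon = eps)
  class(out) <- "stat_report"
  out
}

#' @export
print.stat_report <- function(x, ...) {
  cat("<stat_report>", x$test, "\n")
  if (!is.null(x$F)) {
    cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n", x$df1, x$df2, x$F, x$p_value))
    if (!is.null(x$tukey)) {
      cat("  Tukey pairwise:\n")
      print(x$tukey, digits = 4)
    }
  } else {
    cat(sprintf("  t(%g) = %.4g, p = %.4g (Shapiro-Wilk p = %.3g)\n",
                x$df, x$statistic, x$p_value, x$shapiro_p))
    if (!is.null(x$wilcoxon)) {
      cat(sprintf("  normality rejected; Wilcoxon signed-rank p = %.4g\n",
                  x$wilcoxon$p_value))
    }
  }
  if (isTRUE(x$degenerate)) cat("  [degenerate input flagged]\n")
  invisible(x)
}
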