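# Cohort trend statistics: one-way repeated-measures ANOVA across the four
# NFR periods, paired t-tests of period 1 against each later period, and
# Bonferroni adjustment of the family-wise significance level.
#
# The sums of squares and the t statistic are computed from their defining
# formulas (only the t/F distribution tails come from stats::pt/pf) so the
# decomposition can be checked against an independent brute-force oracle.

#' Bonferroni-adjusted significance level
#'
#' @param family_alpha Family-wise level, in (0, 1) (default 0.05).
#' @param n_tests Number of pairwise tests, `>= 1`.
#' @return `family_alpha / n_tests` — e.g. `0.05 / 3 = 0.0167`, conventionally
#'   reported rounded as 0.017.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, n_tests) {
  if (length(family_alpha) != 1L || family_alpha <= 0 || family_alpha >= 1) {
    cpr_abort("family_alpha must lie strictly between 0 and 1")
  }
  if (length(n_tests) != 1L || n_tests < 1 || n_tests != round(n_tests)) {
    cpr_abort("n_tests must be a positive integer")
  }
  family_alpha / n_tests
}

#' Two-sided paired t-test
#'
#' Computes `t = mean(d) / (sd(d) / sqrt(n))` for the paired differences
#' `d = a - b` (sample standard deviation, `n - 1` denominator) with a
#' two-sided p-value from the t distribution on `n - 1` degrees of freedom.
#'
#' @param a,b Numeric vectors of equal length `n >= 2`.
#' @param alpha Optional significance level; when supplied, the result is
#'   flagged `significant` if `p < alpha` (used with [bonferroni_alpha()]).
#' @return A `cpr_paired_t`: list with `t_stat`, `df`, `p_value`,
#'   `mean_diff` and (if `alpha` given) `alpha` and `significant`.
#'   Identical vectors give `t = 0`, `p = 1`; zero difference variance with
#'   a nonzero mean difference is a degeneracy error.
#' @export
paired_t <- function(a, b, alpha = NULL) {
  if (length(a) != length(b)) cpr_abort("a and b must have equal length")
  n <- length(a)
  if (n < 2L) cpr_abort("paired t-test needs at least 2 pairs")
  d <- a - b
  if (anyNA(d)) cpr_abort("missing values in paired differences")
  s <- sd(d)
  if (s == 0) {
    if (all(d == 0)) {
      t_stat <- 0
      p <- 1
    } else {
      cpr_abort("paired differences have zero variance but nonzero mean",
                "cpr_degenerate_error")
    }
  } else {
    t_stat <- mean(d) / (s / sqrt(n))
    p <- 2 * pt(-abs(t_stat), df = n - 1)
  }
  out <- list(t_stat = t_stat, df = n - 1L, p_value = p, mean_diff = mean(d))
  if (!is.null(alpha)) {
    out$alpha <- alpha
    out$significant <- p < alpha
  }
  structure(out, class = "cpr_paired_t")
}

#' @export
print.cpr_paired_t <- function(x, ...) {
  cat(sprintf("<cpr_paired_t> t(%d) = %.3f, p = %.4g%s\n", x$df, x$t_stat,
              x$p_value,
              if (!is.null(x$significant))
                sprintf(", %ssignificant at %.4f",
                        if (x$significant) "" else "not ", x$alpha) else ""))
  invisible(x)
}

# Greenhouse-Geisser epsilon from the double-centred covariance matrix.
gg_epsilon <- function(x) {
  k <- ncol(x)
  S <- stats::cov(x)
  Sc <- sweep(sweep(S, 1L, rowMeans(S)), 2L, colMeans(S)) + mean(S)
  sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
}

#' One-way repeated-measures ANOVA
#'
#' Standard within-subject decomposition for an `n` subjects by `k`
#' conditions matrix:
#' `SS_total = sum((x - grand)^2)`, `SS_subjects = k * sum((rowmean - grand)^2)`,
#' `SS_conditions = n * sum((colmean - grand)^2)`,
#' `SS_error = SS_total - SS_subjects - SS_conditions`, and
#' `F = (SS_conditions / (k-1)) / (SS_error / ((k-1)(n-1)))` with the p-value
#' from the F distribution.  No sphericity correction is applied by default;
#' `sphericity_correction = TRUE` applies Greenhouse-Geisser
#' degrees-of-freedom scaling.
#'
#' @param x Numeric matrix, rows = subjects (`n >= 2`), columns = conditions
#'   (`k >= 2`), no missing values.
#' @param sphericity_correction Apply the Greenhouse-Geisser correction to
#'   the p-value (default `FALSE`).
#' @return A `cpr_rm_anova`: list with `f_stat`, `df_effect` (`k - 1`),
#'   `df_error` (`(k-1)(n-1)`), `p_value`, the `ss` components and, when
#'   corrected, `epsilon`.  An all-equal matrix is a zero-variance error.
#' @examples
#' set.seed(1)
#' rm_anova(matrix(rnorm(19 * 4), 19, 4))
#' @export
rm_anova <- function(x, sphericity_correction = FALSE) {
  x <- as.matrix(x)
  if (anyNA(x)) cpr_abort("missing values in the repeated-measures matrix")
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2L || k < 2L) cpr_abort("need at least 2 subjects and 2 conditions")
  grand <- mean(x)
  ss_total <- sum((x - grand)^2)
  if (ss_total == 0) {
    cpr_abort("all cells are identical: zero variance", "cpr_degenerate_error")
  }
  ss_subj <- k * sum((rowMeans(x) - grand)^2)
  ss_cond <- n * sum((colMeans(x) - grand)^2)
  ss_err <- ss_total - ss_subj - ss_cond
  df_effect <- k - 1L
  df_error <- (k - 1L) * (n - 1L)
  if (ss_cond <= 0) {
    # pure subject effects: no condition variance at all
    f_stat <- 0
  } else if (ss_err <= 0) {
    cpr_abort("zero within-subject error variance", "cpr_degenerate_error")
  } else {
    f_stat <- (ss_cond / df_effect) / (ss_err / df_error)
  }
  eps <- if (sphericity_correction) gg_epsilon(x) else 1
  p <- pf(f_stat, df1 = eps * df_effect, df2 = eps * df_error,
          lower.tail = FALSE)
  out <- list(f_stat = f_stat, df_effect = df_effect, df_error = df_error,
              p_value = p,
              ss = c(conditions = ss_cond, subjects = ss_subj,
                     error = ss_err, total = ss_total))
  if (sphericity_correction) out$epsilon <- eps
  structure(out, class = "cpr_rm_anova")
}

#' @export
print.cpr_rm_anova <- function(x, ...) {
  cat(sprintf("<cpr_rm_anova> F(%d, %d) = %.3f, p = %.4g\n",
              x$df_effect, x$df_error, x$f_stat, x$p_value))
  invisible(x)
}

#' No-flow trend analysis
#'
#' The trend machinery for the cohort window-NFR matrix: an overall
#' repeated-measures ANOVA across the periods, then paired t-tests of
#' period 1 against each later period, each flagged against the
#' Bonferroni-adjusted level `family_alpha / (k - 1)` (0.05 / 3 = 0.017 for
#' the four 3-minute periods).
#'
#' @param nfr_matrix Numeric matrix, attempts x periods (e.g.
#'   `cohort_nfr(cohort)$nfr_matrix`).
#' @param family_alpha Family-wise significance level (default 0.05).
#' @param sphericity_correction Passed to [rm_anova()].
#' @return A `cpr_nfr_trend`: list with `anova` ([rm_anova()] result),
#'   `pairwise` (list of [paired_t()] results named `"1v2"`, ... with a
#'   `periods` field) and `alpha_adjusted`.
#' @export
nfr_trend_analysis <- function(nfr_matrix, family_alpha = 0.05,
                               sphericity_correction = FALSE) {
  x <- as.matrix(nfr_matrix)
  k <- ncol(x)
  if (k < 2L) cpr_abort("need at least 2 periods")
  alpha_adj <- bonferroni_alpha(family_alpha, k - 1L)
  anova <- rm_anova(x, sphericity_correction = sphericity_correction)
  pairwise <- lapply(seq.int(2L, k), function(j) {
    res <- paired_t(x[, 1L], x[, j], alpha = alpha_adj)
    res$periods <- c(1L, j)
    res
  })
  names(pairwise) <- vapply(pairwise, function(p)
    sprintf("%dv%d", p$periods[1L], p$periods[2L]), character(1L))
  structure(list(anova = anova, pairwise = pairwise,
                 alpha_adjusted = alpha_adj, family_alpha = family_alpha),
            class = "cpr_nfr_trend")
}

#' @export
print.cpr_nfr_trend <- function(x, ...) {
  print(x$anova)
  cat(sprintf("  pairwise vs period 1 (Bonferroni-adjusted level %.4f):\n",
              x$alpha_adjusted))
  for (p in x$pairwise) {
    cat(sprintf("   periods %d vs %d: t(%d) = %.3f, p = %.4g%s\n",
                p$periods[1L], p$periods[2L], p$df, p$t_stat, p$p_value,
                if (isTRUE(p$significant)) " *" else ""))
  }
  invisible(x)
}

# JSON-ready representation of a trend report (used by run_analysis()).
trend_report_list <- function(trend) {
  list(
    anova = list(F = trend$anova$f_stat,
                 df = c(trend$anova$df_effect, trend$anova$df_error),
                 p = trend$anova$p_value),
    pairwise = lapply(unname(trend$pairwise), function(p) {
      list(periods = p$periods, t = p$t_stat, df = p$df, p = p$p_value,
           significant = p$significant)
    }),
    alpha_adjusted = trend$alpha_adjusted
  )
}
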