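#' Two-sample comparison result
#'
#' Container for one outcome variable's group comparison: test type,
#' statistic, degrees of freedom (t only), p-value, tail, Cohen's d and the
#' group summaries.
#'
#' @keywords internal
group_comparison <- function(variable, test, statistic, df = NA_real_, p,
                             alternative, cohens_d = NA_real_,
                             n1, m1 = NA_real_, s1 = NA_real_,
                             n2, m2 = NA_real_, s2 = NA_real_) {
  structure(list(variable = variable, test = test, statistic = statistic,
                 df = df, p = p,
                 tail = if (alternative == "two.sided") "two" else "one",
                 alternative = alternative, cohens_d = cohens_d,
                 n1 = n1, m1 = m1, s1 = s1, n2 = n2, m2 = m2, s2 = s2),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  dftxt <- if (is.na(x$df)) "" else sprintf("(%g)", x$df)
  cat(sprintf("%s: %s%s = %.3f, p = %.4g (%s-tailed), d = %.3f\n",
              x$variable, switch(x$test, student_t = "t", mann_whitney = "U", x$test),
              dftxt, x$statistic, x$p, x$tail, x$cohens_d))
  invisible(x)
}

#' @export
as.data.frame.group_comparison <- function(x, ...) {
  data.frame(variable = x$variable, test = x$test, statistic = x$statistic,
             df = x$df, p = x$p, tail = x$tail, cohens_d = x$cohens_d,
             n1 = x$n1, m1 = x$m1, s1 = x$s1, n2 = x$n2, m2 = x$m2, s2 = x$s2)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over [stats::shapiro.test] with the input checks this
#' pipeline needs; used to gate the choice between the pooled t-test and the
#' Mann-Whitney test.
#'
#' @param values numeric sample, `n >= 3`, non-constant.
#' @return A list with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) stop("Shapiro-Wilk needs n >= 3", call. = FALSE)
  if (sd(values) == 0) stop("Shapiro-Wilk undefined for constant input", call. = FALSE)
  res <- shapiro.test(values)
  list(W = unname(res$statistic), p = res$p.value)
}

#' Pooled-variance Student t-test from summary statistics
#'
#' Computes `t = (m1 - m2) / (sp * sqrt(1/n1 + 1/n2))` with the pooled
#' standard deviation `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`
#' and `df = n1 + n2 - 2`. This recovers published test statistics from a
#' table of group means and SDs alone.
#'
#' @param n1,m1,s1 size, mean, SD of group 1.
#' @param n2,m2,s2 size, mean, SD of group 2.
#' @param alternative `"two.sided"` (default), `"greater"` (m1 > m2) or
#'   `"less"`.
#' @param variable label carried on the result.
#' @return A `group_comparison`.
#' @export
pooled_t_from_summary <- function(n1, m1, s1, n2, m2, s2,
                                  alternative = c("two.sided", "greater", "less"),
                                  variable = NA_character_) {
  alternative <- match.arg(alternative)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (s1 < 0 || s2 < 0) stop("SDs must be nonnegative", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  if (sp2 <= 0) stop("pooled variance is zero; t undefined", call. = FALSE)
  t <- (m1 - m2) / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2))
  p <- switch(alternative,
              two.sided = 2 * pt(-abs(t), df),
              greater = pt(t, df, lower.tail = FALSE),
              less = pt(t, df))
  group_comparison(variable, "student_t", t, df, p, alternative,
                   cohens_d = (m1 - m2) / sqrt(sp2),
                   n1 = n1, m1 = m1, s1 = s1, n2 = n2, m2 = m2, s2 = s2)
}

#' Pooled-variance Student t-test on raw samples
#'
#' Equivalent to [pooled_t_from_summary] applied to the samples' summary
#' statistics (and cross-checked against [stats::t.test] with
#' `var.equal = TRUE`).
#'
#' @param values_a,values_b numeric samples (`NA` dropped), each `n >= 2`.
#' @inheritParams pooled_t_from_summary
#' @return A `group_comparison`.
#' @export
pooled_t <- function(values_a, values_b,
                     alternative = c("two.sided", "greater", "less"),
                     variable = NA_character_) {
  alternative <- match.arg(alternative)
  a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
  pooled_t_from_summary(length(a), mean(a), sd(a), length(b), mean(b), sd(b),
                        alternative, variable)
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (m1 - m2) / sp`, the standardized mean difference using the pooled
#' SD; `cohens_d_values` is the same on raw samples.
#'
#' @inheritParams pooled_t_from_summary
#' @return A single number.
#' @export
cohens_d <- function(n1, m1, s1, n2, m2, s2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("pooled SD is zero; d undefined", call. = FALSE)
  (m1 - m2) / sqrt(sp2)
}

#' @param values_a,values_b numeric samples (`NA` dropped).
#' @rdname cohens_d
#' @export
cohens_d_values <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
  cohens_d(length(a), mean(a), sd(a), length(b), mean(b), sd(b))
}

# exact Mann-Whitney p by enumerating all group assignments; handles ties
# (feasible for n1 + n2 <= ~14: choose(14, 7) = 3432 evaluations)
mw_exact_p <- function(a, b, alternative) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- combn(n, n1, u_of)
  eps <- 1e-9
  p_ge <- mean(us >= u_obs - eps)
  p_le <- mean(us <= u_obs + eps)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

#' Mann-Whitney U test
#'
#' Nonparametric two-sample comparison. The U statistic is reported for the
#' first sample (`U = #{a > b} + 0.5 #{a = b}`). For small samples
#' (`n1 + n2 <= 12`) the p-value comes from exact enumeration of all group
#' assignments (valid with ties); otherwise from the tie-corrected normal
#' approximation with continuity correction (via [stats::wilcox.test]).
#' Cohen's d on the raw samples is attached for comparability with the
#' t-test results.
#'
#' @param values_a,values_b numeric samples (`NA` dropped), both nonempty.
#' @inheritParams pooled_t_from_summary
#' @return A `group_comparison` with the U statistic.
#' @export
mann_whitney <- function(values_a, values_b,
                         alternative = c("two.sided", "greater", "less"),
                         variable = NA_character_) {
  alternative <- match.arg(alternative)
  a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be nonempty", call. = FALSE)
  u <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  p <- if (length(a) + length(b) <= 12L) {
    mw_exact_p(a, b, alternative)
  } else {
    suppressWarnings(
      wilcox.test(a, b, alternative = alternative, exact = FALSE,
                  correct = TRUE)$p.value)
  }
  d <- tryCatch(cohens_d_values(a, b), error = function(e) NA_real_)
  group_comparison(variable, "mann_whitney", u, NA_real_, p, alternative,
                   cohens_d = d,
                   n1 = length(a), m1 = mean(a), s1 = sd(a),
                   n2 = length(b), m2 = mean(b), s2 = sd(b))
}

#' Normality-gated two-sample comparison
#'
#' The decision rule of the analysis battery: test each group with
#' Shapiro-Wilk; if either group departs from normality (p < 0.05), compare
#' groups with the Mann-Whitney test, otherwise with the pooled t-test.
#'
#' @inheritParams mann_whitney
#' @param sw_alpha normality-gate level (default 0.05).
#' @return A `group_comparison` from the selected test.
#' @export
compare_groups <- function(values_a, values_b,
                           alternative = c("two.sided", "greater", "less"),
                           variable = NA_character_, sw_alpha = 0.05) {
  alternative <- match.arg(alternative)
  a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
  nonnormal <- function(v) {
    length(v) >= 3L && sd(v) > 0 && shapiro_wilk(v)$p < sw_alpha
  }
  if (nonnormal(a) || nonnormal(b)) {
    mann_whitney(a, b, alternative, variable)
  } else {
    pooled_t(a, b, alternative, variable)
  }
}

#' Impute missing questionnaire scores with the group mean
#'
#' Missing entries of `score` are replaced by the mean of the observed
#' values in the participant's own group; observed entries are untouched and
#' a `<score>_imputed` flag column records which rows were filled. The group
#' means are unchanged by the imputation.
#'
#' @param participants data frame with a `group` column and the score column.
#' @param score name of the score column.
#' @return The data frame with missing values filled and a flag column added.
#' @export
impute_group_mean <- function(participants, score) {
  if (!score %in% names(participants)) stop("no column '", score, "'", call. = FALSE)
  v <- participants[[score]]
  miss <- is.na(v)
  flag <- miss
  for (g in unique(participants$group)) {
    in_g <- participants$group == g
    obs <- v[in_g & !miss]
    if (length(obs) == 0L) {
      stop("group '", g, "' has no observed values for '", score, "'", call. = FALSE)
    }
    v[in_g & miss] <- mean(obs)
  }
  participants[[score]] <- v
  participants[[paste0(score, "_imputed")]] <- flag
  participants
}

#' Correlate synchrony with a questionnaire score
#'
#' Association between per-dyad synchrony and a score, by Spearman rank
#' correlation (default; robust to the skewed, bounded score scales) or
#' Pearson.
#'
#' @param ips numeric synchrony values.
#' @param score paired score values.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A list with `estimate`, `p`, `method`, `n`.
#' @export
correlate_scores <- function(ips, score, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  keep <- complete.cases(ips, score)
  x <- ips[keep]; y <- score[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector; correlation undefined", call. = FALSE)
  res <- suppressWarnings(cor.test(x, y, method = method))
  list(estimate = unname(res$estimate), p = res$p.value, method = method,
       n = length(x))
}
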