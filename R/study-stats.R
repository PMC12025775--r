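group_comparison <- function(parameter, test, statistic, df, p_value,
                             mean_difference = NA_real_,
                             groups = c(NA_character_, NA_character_)) {
  structure(list(parameter = parameter, test = test,
                 statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value),
                 mean_difference = unname(mean_difference), groups = groups),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s test%s: statistic = %.4f, df = %s, p = %s\n",
              x$test,
              if (!is.na(x$parameter)) paste0(" [", x$parameter, "]") else "",
              x$statistic,
              if (is.na(x$df)) "NA" else format(round(x$df, 2)),
              format_p(x$p_value)))
  if (!is.na(x$mean_difference))
    cat(sprintf("  mean difference: %.4f\n", x$mean_difference))
  invisible(x)
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of the sample against a normal distribution with the
#' sample's own mean and SD; the statistic is the supremum distance between
#' the empirical and reference CDFs and the p-value comes from the asymptotic
#' KS distribution. Because the reference parameters are estimated from the
#' same sample, the p-value is anti-conservative (the Lilliefors caveat); it
#' is used here only as a screen, as in the source protocol.
#'
#' @param x Numeric sample, n >= 3, finite, non-constant.
#' @param parameter Optional parameter label for the report.
#' @return A `group_comparison` with `test = "ks"`.
#' @export
ks_normality <- function(x, parameter = NA_character_) {
  x <- as.numeric(x)
  if (length(x) < 3) stop("KS normality screen needs n >= 3", call. = FALSE)
  if (any(!is.finite(x))) stop("sample contains non-finite values", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant sample: zero SD", call. = FALSE)
  res <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean(x), stats::sd(x), exact = FALSE))
  group_comparison(parameter, "ks", res$statistic, NA_real_, res$p.value)
}

#' Paired t test of pre vs post measurements
#'
#' Two-sided paired t test on the differences `d = post - pre`:
#' `t = mean(d) / (sd(d) / sqrt(n))`, `df = n - 1`.
#'
#' @param pre,post Numeric vectors of equal length, n >= 2.
#' @param parameter Optional parameter label.
#' @return A `group_comparison` with `test = "paired_t"` and
#'   `mean_difference = mean(post - pre)`.
#' @export
paired_t <- function(pre, post, parameter = NA_character_) {
  if (length(pre) != length(post))
    stop("pre and post must have equal length", call. = FALSE)
  if (length(pre) < 2) stop("paired t test needs n >= 2", call. = FALSE)
  d <- post - pre
  if (stats::sd(d) == 0)
    stop("zero variance of paired differences", call. = FALSE)
  res <- stats::t.test(post, pre, paired = TRUE)
  group_comparison(parameter, "paired_t", res$statistic, res$parameter,
                   res$p.value, mean_difference = mean(d))
}

#' Independent two-sample t test
#'
#' Two-sided comparison of two independent samples. The `"student"` variant
#' pools variances (`df = n_a + n_b - 2`), matching an unqualified
#' "independent t test"; `"welch"` uses the Satterthwaite approximation and
#' is exposed because the variant actually realised on the source data is
#' not verifiable from its summary tables.
#'
#' @param a,b Numeric samples, each n >= 2.
#' @param variant `"student"` (default) or `"welch"`.
#' @param parameter Optional parameter label.
#' @param groups Length-2 character vector of group labels.
#' @return A `group_comparison` with `test = "independent_t"` and
#'   `mean_difference = mean(a) - mean(b)`.
#' @export
independent_t <- function(a, b, variant = c("student", "welch"),
                          parameter = NA_character_,
                          groups = c("a", "b")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2)
    stop("independent t test needs n >= 2 per group", call. = FALSE)
  if (stats::sd(c(a, b)) == 0)
    stop("both samples are constant and equal", call. = FALSE)
  res <- stats::t.test(a, b, var.equal = variant == "student")
  group_comparison(parameter, "independent_t", res$statistic, res$parameter,
                   res$p.value, mean_difference = mean(a) - mean(b),
                   groups = groups)
}

#' Between-group comparison of pre-to-post change scores
#'
#' Applies [independent_t()] to the per-eye change `post - pre` of one
#' parameter, treatment vs control — the comparison underlying the study's
#' "after minus before" figure.
#'
#' @param cohort An `eye_cohort` long-format data frame
#'   (see [generate_cohort()] / [read_cohort()]).
#' @param parameter Parameter name to compare.
#' @param variant Passed to [independent_t()].
#' @param groups Length-2 character vector naming the two groups.
#' @return A `group_comparison`.
#' @export
change_score_comparison <- function(cohort, parameter,
                                    variant = c("student", "welch"),
                                    groups = c("CsA-CE", "control")) {
  sub <- cohort[cohort$parameter == parameter, , drop = FALSE]
  missing_groups <- setdiff(groups, unique(sub$group))
  if (length(missing_groups) > 0)
    stop("cohort has no rows for group(s): ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  ch <- function(g) {
    s <- sub[sub$group == g, , drop = FALSE]
    s$post - s$pre
  }
  independent_t(ch(groups[1]), ch(groups[2]), variant,
                parameter = parameter, groups = groups)
}

format_p <- function(p, digits = 3) {
  ifelse(p < 0.001, "<0.001", formatC(p, digits = digits, format = "f"))
}

#' Summarize a pre/post two-group cohort
#'
#' For every parameter and group: pre and post mean and SD and the
#' within-group paired-t p-value; and per parameter, the between-group
#' independent-t p-value on the change scores. Significance is flagged at
#' `alpha`. Output ordering is stable (parameters in order of first
#' appearance, groups in order of first appearance within parameter).
#'
#' @param cohort An `eye_cohort` long-format data frame.
#' @param variant Independent-test variant; see [independent_t()].
#' @param alpha Significance level. Default 0.05.
#' @return An object of class `study_report`: a data frame with one row per
#'   parameter-group combination and columns `parameter`, `group`, `n`,
#'   `pre_mean`, `pre_sd`, `post_mean`, `post_sd`, `p_within`,
#'   `p_between_change`, `significant_within`.
#' @export
summarize_study <- function(cohort, variant = c("student", "welch"),
                            alpha = 0.05) {
  variant <- match.arg(variant)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  pars <- unique(cohort$parameter)
  rows <- list()
  for (p in pars) {
    sub <- cohort[cohort$parameter == p, , drop = FALSE]
    grps <- unique(sub$group)
    p_between <- if (length(grps) == 2)
      change_score_comparison(cohort, p, variant, groups = grps)$p_value
    else NA_real_
    for (g in grps) {
      s <- sub[sub$group == g, , drop = FALSE]
      p_within <- paired_t(s$pre, s$post)$p_value
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, group = g, n = nrow(s),
        pre_mean = mean(s$pre), pre_sd = stats::sd(s$pre),
        post_mean = mean(s$post), post_sd = stats::sd(s$post),
        p_within = p_within, p_between_change = p_between,
        significant_within = p_within < alpha,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(parameter = character(), group = character(), n = integer(),
               pre_mean = numeric(), pre_sd = numeric(),
               post_mean = numeric(), post_sd = numeric(),
               p_within = numeric(), p_between_change = numeric(),
               significant_within = logical(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  attr(res, "variant") <- variant
  class(res) <- c("study_report", "data.frame")
  res
}

#' @export
print.study_report <- function(x, ...) {
  alpha <- attr(x, "alpha")
  cat(sprintf("Pre/post study report (%s independent test, alpha = %g)\n\n",
              attr(x, "variant"), alpha))
  if (nrow(x) == 0) {
    cat("  (no parameters)\n")
    return(invisible(x))
  }
  fmt <- function(m, s) sprintf("%.2f ± %.2f", m, s)
  tab <- data.frame(parameter = x$parameter, group = x$group, n = x$n,
                    pre = fmt(x$pre_mean, x$pre_sd),
                    post = fmt(x$post_mean, x$post_sd),
                    p = paste0(format_p(x$p_within),
                               ifelse(x$significant_within, " *", "")),
                    p_change = format_p(x$p_between_change),
                    stringsAsFactors = FALSE)
  print(tab, row.names = FALSE)
  cat(sprintf("\n  * within-group paired t significant at p < %g\n", alpha))
  invisible(x)
}

#' Write a study report to CSV
#'
#' Deterministic column order and float formatting; means and SDs to two
#' decimals, p-values to three with values below 0.001 rendered `<0.001`.
#'
#' @param report A `study_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_study_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  out <- data.frame(parameter = report$parameter, group = report$group,
                    n = report$n,
                    pre = sprintf("%.2f", report$pre_mean),
                    pre_sd = sprintf("%.2f", report$pre_sd),
                    post = sprintf("%.2f", report$post_mean),
                    post_sd = sprintf("%.2f", report$post_sd),
                    p_within = format_p(report$p_within),
                    p_between_change = format_p(report$p_between_change),
                    significant_within = report$significant_within)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}
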