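# Model-comparison protocol over DSC tables: Shapiro-Wilk-gated paired
# tests (Student t for normal paired differences, exact Wilcoxon
# signed-rank otherwise) and one-way ANOVA. Two-sided throughout;
# significance at p < 0.05.

#' Normality-gated paired comparison
#'
#' Runs a Shapiro-Wilk test on the paired differences; if normality is not
#' rejected at `alpha` a paired Student t-test is used, otherwise a
#' two-sided Wilcoxon signed-rank test (zero differences dropped, exact
#' null distribution for n <= 25 when there are no ties in the absolute
#' differences, normal approximation otherwise).
#'
#' @param x,y paired samples (equal length >= 3).
#' @param alpha gate and significance level in (0, 1).
#' @return a `scap_comparison`: `test_used` ("paired-t" or "wilcoxon"),
#'   `statistic`, `p_value`, `significant` (p < alpha), `direction` ("x",
#'   "y" or NA), `shapiro_p`, `degenerate`.
#' @export
gated_paired_compare <- function(x, y, alpha = 0.05) {
  .assert(length(x) == length(y), "paired samples must have equal length")
  .assert(length(x) >= 3, "need at least 3 pairs")
  .assert(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  d <- x - y
  if (stats::sd(d) == 0) {
    return(structure(list(test_used = NA_character_, statistic = NA_real_,
                          p_value = NA_real_, significant = FALSE,
                          direction = NA_character_, shapiro_p = NA_real_,
                          degenerate = TRUE, n = length(d)),
                     class = "scap_comparison"))
  }
  sw <- stats::shapiro.test(d)
  if (sw$p.value >= alpha) {
    tt <- stats::t.test(x, y, paired = TRUE)
    used <- "paired-t"
    stat <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    dz <- d[d != 0]
    exact <- length(dz) <= 25 && !anyDuplicated(abs(dz))
    wt <- suppressWarnings(stats::wilcox.test(dz, exact = exact,
                                              correct = !exact))
    used <- "wilcoxon"
    stat <- unname(wt$statistic)
    p <- wt$p.value
  }
  sig <- p < alpha
  structure(list(test_used = used, statistic = stat, p_value = p,
                 significant = sig,
                 direction = if (sig) if (mean(d) > 0) "x" else "y"
                             else NA_character_,
                 shapiro_p = sw$p.value, degenerate = FALSE, n = length(d)),
            class = "scap_comparison")
}

#' One-way analysis of variance
#'
#' Standard fixed-effects one-way decomposition (equal-variance F test)
#' across two or more groups.
#'
#' @param groups list of >= 2 numeric samples, each of length >= 2.
#' @param alpha significance level.
#' @return a `scap_comparison` with `test_used = "anova"`, the F statistic
#'   and p-value; degenerate when the within-group variance is zero.
#' @export
oneway_anova <- function(groups, alpha = 0.05) {
  .assert(is.list(groups) && length(groups) >= 2, "need at least 2 groups")
  .assert(all(vapply(groups, length, integer(1)) >= 2),
          "each group needs at least 2 observations")
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  within_var <- vapply(groups, stats::var, numeric(1))
  if (all(within_var == 0)) {
    return(structure(list(test_used = "anova", statistic = NA_real_,
                          p_value = NA_real_, significant = FALSE,
                          direction = NA_character_, shapiro_p = NA_real_,
                          degenerate = TRUE, n = length(values)),
                     class = "scap_comparison"))
  }
  res <- stats::oneway.test(values ~ fac, var.equal = TRUE)
  sig <- res$p.value < alpha
  structure(list(test_used = "anova", statistic = unname(res$statistic),
                 p_value = res$p.value, significant = sig,
                 direction = NA_character_, shapiro_p = NA_real_,
                 degenerate = FALSE, n = length(values)),
            class = "scap_comparison")
}

#' @export
print.scap_comparison <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<scap_comparison> degenerate (no variation); no test statistic\n")
  } else {
    cat(sprintf("<scap_comparison> %s: statistic %.4g, p = %.4g%s\n",
                x$test_used, x$statistic, x$p_value,
                if (x$significant) sprintf(" (significant; %s larger)",
                                           x$direction %||% "?") else ""))
  }
  invisible(x)
}
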