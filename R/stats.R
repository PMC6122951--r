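# The statistical decision tree used by every summary stage, with a
# full audit trail: normality gate (Shapiro-Wilk, alpha = 0.05) chooses
# parametric vs rank tests; a variance-homogeneity gate chooses pooled
# vs Welch t-tests; families of comparisons are Holm-Bonferroni
# corrected. Primitive statistics come from base R; the gating and
# bookkeeping live here.

.test_result <- function(test_name, statistic, p_raw, n,
                         gate_normality_p = NA_real_,
                         gate_variance_p = NA_real_,
                         p_adjusted = NULL) {
  structure(
    list(test_name = test_name, statistic = unname(statistic),
         p_raw = p_raw, p_adjusted = p_adjusted,
         gate_normality_p = gate_normality_p,
         gate_variance_p = gate_variance_p, n = n),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_raw))
  if (!is.null(x$p_adjusted))
    cat(sprintf("  Holm-adjusted p = %.4g\n", x$p_adjusted))
  if (!all(is.na(x$gate_normality_p)))
    cat("  normality gate p:",
        paste(signif(x$gate_normality_p, 3), collapse = ", "), "\n")
  if (!is.na(x$gate_variance_p))
    cat(sprintf("  variance gate p: %.3g\n", x$gate_variance_p))
  invisible(x)
}

# Shapiro-Wilk p; NA (treated as non-normal) for degenerate input
.shapiro_p <- function(x) {
  if (length(unique(x)) < 3L) return(NA_real_)
  stats::shapiro.test(x)$p.value
}

#' Two-group comparison via the normality-gated decision tree
#'
#' Both groups pass through a Shapiro-Wilk normality gate at alpha =
#' `alpha_gate`. If both pass: an F-test of variance homogeneity picks
#' the pooled t-test (gate p > alpha) or the Welch-corrected t-test
#' (paired data go straight to the paired t-test). If either group
#' fails the gate: the rank test — Wilcoxon signed-rank when paired,
#' Mann-Whitney/Wilcoxon rank-sum otherwise. All gate p-values are
#' reported with the result.
#'
#' @param x,y numeric samples, each of length >= 3 (equal lengths when
#'   paired).
#' @param paired logical.
#' @param alpha_gate significance level for both gates (default 0.05).
#' @return a `test_result`.
#' @export
compare_two_groups <- function(x, y, paired = FALSE, alpha_gate = 0.05) {
  if (length(x) < 3L || length(y) < 3L)
    stop("compare_two_groups: each group needs n >= 3 (normality gate ",
         "undefined below that)", call. = FALSE)
  if (paired && length(x) != length(y))
    stop("compare_two_groups: paired samples must have equal length",
         call. = FALSE)
  if (paired && all(x == y)) {
    # all differences zero: no evidence of any shift, whatever the branch
    return(.test_result("paired (degenerate)", 0, 1,
                        c(length(x), length(y))))
  }
  gate <- c(.shapiro_p(x), .shapiro_p(y))
  normal <- !anyNA(gate) && all(gate > alpha_gate)
  if (normal) {
    if (paired) {
      ht <- stats::t.test(x, y, paired = TRUE)
      return(.test_result("paired t-test", ht$statistic, ht$p.value,
                          c(length(x), length(y)),
                          gate_normality_p = gate))
    }
    var_p <- stats::var.test(x, y)$p.value
    equal_var <- var_p > alpha_gate
    ht <- stats::t.test(x, y, var.equal = equal_var)
    .test_result(if (equal_var) "two-sample t-test" else "Welch t-test",
                 ht$statistic, ht$p.value, c(length(x), length(y)),
                 gate_normality_p = gate, gate_variance_p = var_p)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                              exact = FALSE, correct = TRUE))
    .test_result(if (paired) "Wilcoxon signed-rank"
                 else "Mann-Whitney U-test",
                 ht$statistic, ht$p.value, c(length(x), length(y)),
                 gate_normality_p = gate)
  }
}

#' One-sample test against a reference value
#'
#' Normality-gated: one-sample t-test when the sample passes the
#' Shapiro-Wilk gate, Wilcoxon signed-rank otherwise. A constant sample
#' equal to `mu0` is degenerate (p = 1).
#'
#' @param x numeric sample, length >= 3.
#' @param mu0 reference value (default 0).
#' @param alpha_gate gate level (default 0.05).
#' @return a `test_result`.
#' @export
one_sample_test <- function(x, mu0 = 0, alpha_gate = 0.05) {
  if (length(x) < 3L)
    stop("one_sample_test: n >= 3 required", call. = FALSE)
  if (all(x == mu0))
    return(.test_result("one-sample (degenerate)", 0, 1, length(x)))
  gate <- .shapiro_p(x)
  if (!is.na(gate) && gate > alpha_gate) {
    ht <- stats::t.test(x, mu = mu0)
    .test_result("one-sample t-test", ht$statistic, ht$p.value, length(x),
                 gate_normality_p = gate)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, mu = mu0, exact = FALSE))
    .test_result("one-sample Wilcoxon signed-rank", ht$statistic,
                 ht$p.value, length(x), gate_normality_p = gate)
  }
}

#' Holm-Bonferroni step-down correction
#'
#' Step-down adjustment of a family of p-values with monotonicity
#' enforcement and capping at 1; the input order is preserved in the
#' output.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order and length.
#' @examples
#' holm_bonferroni(c(0.01, 0.04)) # 0.02, 0.04
#' @export
holm_bonferroni <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("holm_bonferroni: p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "holm")
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Supremum distance between the two empirical cumulative distribution
#' functions, with the asymptotic p-value.
#'
#' @param x,y non-empty numeric samples.
#' @return a `test_result`.
#' @export
ks_two_sample <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  ht <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  .test_result("two-sample Kolmogorov-Smirnov", ht$statistic, ht$p.value,
               c(length(x), length(y)))
}
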