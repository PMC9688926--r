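#' @rdname stat_result
#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %.4g, p = %.4g%s (n = %s)%s\n",
              x$test_name, x$statistic, x$p_value,
              if (x$adjusted) " (adjusted)" else "",
              paste(x$n_per_group, collapse = ", "),
              significance_stars(x$p_value)))
  invisible(x)
}

#' Container for a hypothesis-test result
#'
#' A small record shared by all tests of the statistical layer.
#'
#' @param test_name,statistic,p_value,n_per_group,alternative,adjusted
#'   fields; `extra` is an optional named list of method details.
#' @return An object of class `stat_result`.
#' @keywords internal
#' @export
stat_result <- function(test_name, statistic, p_value, n_per_group,
                        alternative = "two_sided", adjusted = FALSE,
                        extra = list()) {
  structure(c(list(test_name = test_name, statistic = statistic,
                   p_value = p_value, n_per_group = n_per_group,
                   alternative = alternative, adjusted = adjusted),
              extra), class = "stat_result")
}

significance_stars <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) " ***" else if (p < 0.01) " **"
  else if (p < 0.05) " *" else ""
}

alt_to_r <- function(alternative) {
  switch(alternative, two_sided = "two.sided", less = "less",
         greater = "greater",
         stop("unknown alternative '", alternative, "'"))
}

#' Shapiro-Wilk normality gate
#'
#' Tests a sample for normality and recommends the test family used
#' downstream: parametric (two-sample t) when normality is not rejected at
#' `alpha`, nonparametric (rank-based) otherwise.
#'
#' @param values numeric sample, `3 <= n <= 5000`.
#' @param alpha rejection level for the gate.
#' @return List with `result` (a `stat_result` with the W statistic) and
#'   `recommended_test` (`"parametric"` or `"nonparametric"`;
#'   `"degenerate"` when the sample has zero variance and W is undefined).
#' @export
shapiro_wilk_gate <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3) stop("Shapiro-Wilk requires at least 3 values")
  if (n > 5000) stop("Shapiro-Wilk is defined for n <= 5000")
  if (stats::sd(values) == 0) {
    return(list(
      result = stat_result("shapiro_wilk", NA_real_, NA_real_, n),
      recommended_test = "degenerate"))
  }
  sw <- stats::shapiro.test(values)
  list(result = stat_result("shapiro_wilk", unname(sw$statistic),
                            sw$p.value, n),
       recommended_test = if (sw$p.value < alpha) "nonparametric"
                          else "parametric")
}

#' Two-sample t test (pooled variance by default)
#'
#' @param a,b numeric samples with at least 2 values each.
#' @param alternative `"two_sided"`, `"less"` or `"greater"`.
#' @param var_equal pooled-variance t (default) or Welch.
#' @return A `stat_result`.
#' @export
two_sample_t <- function(a, b, alternative = "two_sided",
                         var_equal = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # zero pooled variance: equal means -> no evidence (p = 1); unequal
    # means -> degenerate (the statistic is unbounded)
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(stat_result("two_sample_t", 0, 1, c(length(a), length(b)),
                         alternative, extra = list(degenerate = FALSE)))
    return(stat_result("two_sample_t",
                       sign(mean(a) - mean(b)) * Inf, 0,
                       c(length(a), length(b)), alternative,
                       extra = list(degenerate = TRUE)))
  }
  tt <- stats::t.test(a, b, alternative = alt_to_r(alternative),
                      var.equal = var_equal)
  stat_result("two_sample_t", unname(tt$statistic), tt$p.value,
              c(length(a), length(b)), alternative,
              extra = list(df = unname(tt$parameter),
                           degenerate = FALSE))
}

#' Mann-Whitney U test
#'
#' U statistic of the first sample with an exact p value (enumeration of the
#' rank distribution) when both samples are small (`n <= exact_threshold`)
#' and tie-free, and the tie- and continuity-corrected normal approximation
#' otherwise.
#'
#' @param a,b numeric samples.
#' @param alternative `"two_sided"`, `"less"` or `"greater"`.
#' @param exact_threshold largest per-group n for which the exact
#'   distribution is used.
#' @return A `stat_result` with the U statistic; `$exact` records which
#'   path was taken.
#' @export
mann_whitney_u <- function(a, b, alternative = "two_sided",
                           exact_threshold = 8L) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !ties && length(a) <= exact_threshold &&
    length(b) <= exact_threshold
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alt_to_r(alternative),
                       exact = use_exact, correct = TRUE))
  stat_result("mann_whitney_u", unname(wt$statistic), wt$p.value,
              c(length(a), length(b)), alternative,
              extra = list(exact = use_exact, ties = ties))
}

#' Kruskal-Wallis rank test
#'
#' @param groups list of numeric samples (>= 2 groups, total n >= 3).
#' @return A `stat_result` with the tie-corrected H statistic and a
#'   chi-squared p value on k - 1 degrees of freedom.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, integer(1)) >= 1),
            sum(lengths(groups)) >= 3)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1)
    return(stat_result("kruskal_wallis", 0, 1, lengths(groups),
                       extra = list(df = length(groups) - 1L)))
  kw <- stats::kruskal.test(x, g)
  stat_result("kruskal_wallis", unname(kw$statistic), kw$p.value,
              lengths(groups), extra = list(df = unname(kw$parameter)))
}

#' Pairwise post-hoc comparisons with Bonferroni adjustment
#'
#' All pairwise group comparisons following a Kruskal-Wallis test, with raw
#' p values multiplied by the number of pairs (capped at 1). The default
#' method is Dunn's rank-based z test (pairwise mean-rank differences
#' against the pooled-rank variance with tie correction); plain pairwise
#' Mann-Whitney tests are a selectable alternative.
#'
#' @param groups named (or unnamed) list of numeric samples.
#' @param method `"dunn"` or `"pairwise_mw"`.
#' @return List of `stat_result`s, one per pair, each carrying both
#'   `p_value` (adjusted) and `$p_raw`.
#' @export
posthoc_bonferroni <- function(groups, method = c("dunn", "pairwise_mw")) {
  method <- match.arg(method)
  stopifnot(is.list(groups), length(groups) >= 2)
  k <- length(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)

  if (method == "dunn") {
    x <- unlist(groups, use.names = FALSE)
    g <- rep(seq_len(k), lengths(groups))
    N <- length(x)
    r <- rank(x)
    rbar <- tapply(r, g, mean)
    tie_tab <- table(x)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
    v <- N * (N + 1) / 12 - tie_corr
    res <- lapply(seq_len(m), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      se <- sqrt(v * (1 / lengths(groups)[i1] + 1 / lengths(groups)[i2]))
      z <- if (se > 0) (rbar[[i1]] - rbar[[i2]]) / se else 0
      p_raw <- 2 * stats::pnorm(-abs(z))
      stat_result(paste0("dunn:", nm[i1], " vs ", nm[i2]), z,
                  min(1, m * p_raw),
                  c(lengths(groups)[i1], lengths(groups)[i2]),
                  adjusted = TRUE,
                  extra = list(p_raw = p_raw, n_comparisons = m))
    })
  } else {
    res <- lapply(seq_len(m), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      mw <- mann_whitney_u(groups[[i1]], groups[[i2]])
      stat_result(paste0("mann_whitney:", nm[i1], " vs ", nm[i2]),
                  mw$statistic, min(1, m * mw$p_value),
                  mw$n_per_group, adjusted = TRUE,
                  extra = list(p_raw = mw$p_value, n_comparisons = m))
    })
  }
  res
}

#' Normalize viability-assay values to the untreated control
#'
#' Divides every absorbance by the mean of the control condition, so the
#' control's normalized mean is 1 and treated conditions read as relative
#' proliferation.
#'
#' @param values data frame with columns `condition` and `value`.
#' @param control name of the control condition.
#' @return The data frame with `value` replaced by normalized values.
#' @export
mts_normalize <- function(values, control) {
  stopifnot(is.data.frame(values),
            all(c("condition", "value") %in% names(values)))
  ctrl <- values$value[values$condition == control]
  if (!length(ctrl)) stop("control condition '", control, "' not present")
  cm <- mean(ctrl)
  if (!is.finite(cm) || cm <= 0)
    stop("control mean must be positive, got ", cm)
  values$value <- values$value / cm
  values
}

#' Percent marker-positive cells per visual field
#'
#' @param fields data frame with columns `positive_count` and
#'   `total_count` (one row per visual field); extra columns are kept.
#' @return The data frame with an added `percent_positive` column.
#' @export
ki67_percent <- function(fields) {
  stopifnot(is.data.frame(fields),
            all(c("positive_count", "total_count") %in% names(fields)))
  if (any(fields$total_count <= 0))
    stop("total_count must be positive in every field")
  if (any(fields$positive_count < 0 |
          fields$positive_count > fields$total_count))
    stop("positive_count must lie in [0, total_count]")
  fields$percent_positive <- 100 * fields$positive_count /
    fields$total_count
  fields
}
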