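#' Odds ratio with confidence interval for a 2x2 table
#'
#' The odds ratio is the cross-product `(a*d)/(b*c)` on the table
#' ```
#'            allele 1   allele 2
#'   group 1      a          b
#'   group 2      c          d
#' ```
#' The default interval is the Woolf log interval
#' `exp(log(OR) +- z * sqrt(1/a + 1/b + 1/c + 1/d))`; when any cell is zero
#' the Haldane-Anscombe correction adds 0.5 to every cell for both the OR
#' and the interval (recorded in `method`). `method = "exact"` keeps the
#' cross-product OR but takes the interval from the exact conditional
#' (Fisher) distribution.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @param level Confidence level, default 0.95.
#' @param method `"woolf"` (default) or `"exact"`.
#' @return One-row tibble: `odds_ratio`, `ci_low`, `ci_high`, `ci_level`,
#'   `or_method`.
#' @export
#' @examples
#' odds_ratio_ci(25, 4, 35, 24)   # OR = 4.286
odds_ratio_ci <- function(a, b, c, d, level = 0.95,
                          method = c("woolf", "exact")) {
  method <- match.arg(method)
  cells <- c(a, b, c, d)
  if (any(cells < 0)) abort("Cells must be non-negative.")
  or_raw <- if (b * c == 0 && a * d > 0) Inf else (a * d) / (b * c)
  if (method == "exact") {
    ft <- fisher.test(matrix(cells, 2, byrow = TRUE), conf.level = level)
    return(tibble(odds_ratio = or_raw, ci_low = ft$conf.int[1],
                  ci_high = ft$conf.int[2], ci_level = level,
                  or_method = "exact_conditional"))
  }
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  or <- (cc[1] * cc[4]) / (cc[2] * cc[3])
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(sum(1 / cc))
  tibble(
    odds_ratio = if (corrected) or else or_raw,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    ci_level = level,
    or_method = if (corrected) "woolf_haldane" else "woolf"
  )
}

#' Association test for a 2x2 allele-by-group table
#'
#' Pearson chi-square with 1 df and no continuity correction when all
#' expected cells are at least 5, otherwise Fisher's exact two-sided test;
#' the branch taken is recorded. The odds ratio and interval come from
#' [odds_ratio_ci()].
#'
#' @param a,b,c,d Cell counts, laid out as group-1 allele-1, group-1
#'   allele-2, group-2 allele-1, group-2 allele-2.
#' @param policy `"auto"` (expected-count rule, default), or force
#'   `"chi_square"` / `"fisher_exact"`.
#' @param level Confidence level for the odds-ratio interval.
#' @param or_method Interval method, see [odds_ratio_ci()].
#' @return One-row tibble of class `contingency_result`: cells, `test`,
#'   `statistic`, `p_value`, odds-ratio columns.
#' @export
#' @examples
#' two_by_two_test(25, 4, 35, 24)  # the G11914A-style table: p ~ 0.011
two_by_two_test <- function(a, b, c, d,
                            policy = c("auto", "chi_square", "fisher_exact"),
                            level = 0.95,
                            or_method = c("woolf", "exact")) {
  policy <- match.arg(policy)
  or_method <- match.arg(or_method)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || sum(cells) < 1) abort("Invalid 2x2 table.")
  m <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Degenerate table: empty row or column margin.")
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  use_chi <- switch(policy,
    auto = all(expected >= 5),
    chi_square = TRUE,
    fisher_exact = FALSE
  )
  if (use_chi) {
    ht <- suppressWarnings(chisq.test(m, correct = FALSE))
    test <- "chi_square"; statistic <- unname(ht$statistic)
  } else {
    ht <- fisher.test(m)
    test <- "fisher_exact"; statistic <- NA_real_
  }
  or <- odds_ratio_ci(a, b, c, d, level = level, method = or_method)
  out <- bind_cols(
    tibble(a = a, b = b, c = c, d = d, test = test,
           statistic = statistic, p_value = unname(ht$p.value)),
    or
  )
  class(out) <- c("contingency_result", class(out))
  out
}

#' @method tidy contingency_result
#' @export
tidy.contingency_result <- function(x, ...) as_tibble(x)

#' @method glance contingency_result
#' @export
glance.contingency_result <- function(x, ...) {
  as_tibble(x)[, c("test", "statistic", "p_value", "odds_ratio",
                   "ci_low", "ci_high")]
}

#' Per-site association tests over a delta scan
#'
#' Runs [two_by_two_test()] at selected positions of a `site_counts` table,
#' polarizing each site to major vs non-major allele mass per group (counts
#' of non-major alleles are pooled).
#'
#' @param counts A `site_counts` tibble.
#' @param positions Positions to test; default all polymorphic positions.
#' @param ... Passed to [two_by_two_test()].
#' @param p_adjust `"none"` (default, no multiple-testing correction),
#'   `"bonferroni"` (over the polymorphic-site count) or `"BH"`.
#' @return A tibble with one row per tested position: cells, test,
#'   statistic, p_value (+ `p_adjusted` unless `p_adjust = "none"`),
#'   odds-ratio columns. Rows of the 2x2 are the groups in alphabetical
#'   order; columns are (non-major, major) allele mass, so `a` is the
#'   first group's non-major count.
#' @export
site_association <- function(counts, positions = NULL,
                             p_adjust = c("none", "bonferroni", "BH"), ...) {
  p_adjust <- match.arg(p_adjust)
  groups <- attr(counts, "groups") %||% sort(unique(counts$group))
  if (length(groups) != 2) abort("Requires exactly 2 groups.")
  if (is.null(positions)) {
    positions <- sort(unique(counts$position[counts$polymorphic]))
  }
  sub <- filter(counts, .data$position %in% positions)
  tabs <- sub %>%
    group_by(.data$position, .data$group) %>%
    summarise(
      nonmajor = sum(.data$n[.data$allele != .data$major_allele[1]]),
      major = sum(.data$n[.data$allele == .data$major_allele[1]]),
      .groups = "drop"
    )
  res <- purrr::map(sort(unique(tabs$position)), function(p) {
    t1 <- tabs[tabs$position == p & tabs$group == groups[1], ]
    t2 <- tabs[tabs$position == p & tabs$group == groups[2], ]
    if (nrow(t1) == 0 || nrow(t2) == 0) return(NULL)
    r <- two_by_two_test(t1$nonmajor, t1$major, t2$nonmajor, t2$major, ...)
    bind_cols(tibble(position = p), as_tibble(r))
  }) %>% bind_rows()
  if (p_adjust != "none" && nrow(res)) {
    n_poly <- length(unique(counts$position[counts$polymorphic]))
    res$p_adjusted <- if (p_adjust == "bonferroni") {
      pmin(1, res$p_value * n_poly)
    } else stats::p.adjust(res$p_value, method = "BH")
  }
  res
}

#' Chi-square test on a lineage-by-group count table
#'
#' Pearson chi-square on an r x 2 table of simplified-lineage counts per
#' group (df = r - 1). Lineages with zero total count are dropped with a
#' warning.
#'
#' @param tab A matrix or data frame: rows = lineages, 2 columns = groups;
#'   or a tibble with columns `lineage`, `group`, `n` (long form).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n_lineages`.
#' @export
lineage_chi_square <- function(tab) {
  if (is_tibble(tab) || (is.data.frame(tab) && all(c("lineage", "group", "n") %in% names(tab)))) {
    tab <- tidyr::pivot_wider(tab, names_from = "group", values_from = "n",
                              values_fill = 0)
    m <- as.matrix(tab[, -1])
    rownames(m) <- tab$lineage
  } else {
    m <- as.matrix(tab)
  }
  if (ncol(m) != 2) abort("Expected a lineage x 2-group table.")
  zero <- rowSums(m) == 0
  if (any(zero)) {
    warn(sprintf("%d lineage(s) with zero total dropped.", sum(zero)))
    m <- m[!zero, , drop = FALSE]
  }
  if (nrow(m) < 2) abort("Degenerate: fewer than 2 surviving lineages.")
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value), n_lineages = nrow(m))
}

#' Two-sample or paired t-test from summary statistics
#'
#' Student's pooled-variance t with `df = n1 + n2 - 2` from per-group means,
#' SDs and sizes; or, with `kind = "paired"`, the one-sample t on the mean
#' and SD of within-pair differences (`df = n1 - 1`). Cohen's d (see
#' [cohens_d_summary()]) is attached for the two-sample case.
#'
#' @param mean1,sd1,n1 First group (or the differences, for paired).
#' @param mean2,sd2,n2 Second group (ignored for paired).
#' @param kind `"two_sample"` (default) or `"paired"`.
#' @param d_method Cohen's d denominator, see [cohens_d_summary()].
#' @return One-row tibble of class `summary_comparison`: inputs, `t`, `df`,
#'   `p_value`, `cohens_d`, `d_method`.
#' @export
#' @examples
#' t_from_summary(27.7, 4.2, 29, 28.6, 4.0, 59)
t_from_summary <- function(mean1, sd1, n1, mean2 = NULL, sd2 = NULL,
                           n2 = NULL, kind = c("two_sample", "paired"),
                           d_method = c("rms_sd", "pooled_df_weighted")) {
  kind <- match.arg(kind)
  d_method <- match.arg(d_method)
  if (sd1 <= 0 || (kind == "two_sample" && sd2 <= 0)) {
    abort("SDs must be positive.")
  }
  if (kind == "paired") {
    if (n1 < 2) abort("Need n >= 2.")
    df <- n1 - 1
    t <- mean1 / (sd1 / sqrt(n1))
    out <- tibble(mean1 = mean1, sd1 = sd1, n1 = n1,
                  mean2 = NA_real_, sd2 = NA_real_, n2 = NA_integer_,
                  t = t, df = df, p_value = 2 * pt(-abs(t), df),
                  cohens_d = abs(mean1) / sd1, d_method = "diff_sd",
                  kind = kind)
  } else {
    if (n1 < 2 || n2 < 2) abort("Need n >= 2 per group.")
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    out <- tibble(mean1 = mean1, sd1 = sd1, n1 = n1,
                  mean2 = mean2, sd2 = sd2, n2 = n2,
                  t = t, df = df, p_value = 2 * pt(-abs(t), df),
                  cohens_d = cohens_d_summary(mean1, sd1, mean2, sd2,
                                              n1 = n1, n2 = n2,
                                              method = d_method),
                  d_method = d_method, kind = kind)
  }
  class(out) <- c("summary_comparison", class(out))
  out
}

#' @method tidy summary_comparison
#' @export
tidy.summary_comparison <- function(x, ...) as_tibble(x)

#' @method glance summary_comparison
#' @export
glance.summary_comparison <- function(x, ...) {
  as_tibble(x)[, c("t", "df", "p_value", "cohens_d")]
}

#' Cohen's d from summary statistics
#'
#' `d = |mean1 - mean2| / denom`. The default denominator is the
#' root-mean-square of the two SDs, `sqrt((sd1^2 + sd2^2) / 2)`; the
#' alternative is the df-weighted pooled SD
#' `sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2))` (requires `n1`,
#' `n2`).
#'
#' @param mean1,sd1,mean2,sd2 Group summaries; SDs positive.
#' @param n1,n2 Group sizes (pooled method only).
#' @param method `"rms_sd"` (default) or `"pooled_df_weighted"`.
#' @return Non-negative numeric effect size.
#' @export
#' @examples
#' cohens_d_summary(27.7, 4.2, 28.6, 4.0)  # 0.219447
cohens_d_summary <- function(mean1, sd1, mean2, sd2, n1 = NULL, n2 = NULL,
                             method = c("rms_sd", "pooled_df_weighted")) {
  method <- match.arg(method)
  if (sd1 <= 0 || sd2 <= 0) abort("SDs must be positive.")
  denom <- if (method == "rms_sd") {
    sqrt((sd1^2 + sd2^2) / 2)
  } else {
    if (is.null(n1) || is.null(n2)) {
      abort("pooled_df_weighted needs n1 and n2.")
    }
    sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  }
  abs(mean1 - mean2) / denom
}
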