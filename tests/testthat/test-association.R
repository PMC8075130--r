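test_that("balanced tables show no association", {
  r <- two_by_two_test(10, 10, 10, 10)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$odds_ratio, 1)
})

test_that("the reconstructed G11914A table reproduces the printed stats", {
  r <- two_by_two_test(25, 4, 35, 24)
  expect_equal(r$test, "chi_square")        # all expected counts >= 5
  expect_equal(round(r$p_value, 3), 0.011)
  expect_equal(round(r$odds_ratio, 3), 4.286)
  expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
})

test_that("zero cells force the exact branch", {
  r <- two_by_two_test(0, 10, 10, 5)
  expect_equal(r$test, "fisher_exact")
  expect_equal(r$p_value, fisher_enum_p(0, 10, 10, 5), tolerance = 1e-9)
})

test_that("Fisher p equals exhaustive hypergeometric enumeration", {
  tabs <- withr::with_seed(3, {
    lapply(1:40, function(i) sample(0:15, 4, replace = TRUE))
  })
  for (tb in tabs) {
    if (sum(tb) == 0 || sum(tb[1:2]) == 0 || sum(tb[3:4]) == 0 ||
        sum(tb[c(1, 3)]) == 0 || sum(tb[c(2, 4)]) == 0) next
    r <- two_by_two_test(tb[1], tb[2], tb[3], tb[4], policy = "fisher_exact")
    expect_equal(r$p_value, fisher_enum_p(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-8)
  }
})

test_that("chi-square p tracks a fixed-margin Monte-Carlo null", {
  # the conditional (fixed-margin) null is discrete, so the asymptotic
  # chi-square p differs from the permutation p by a small systematic
  # amount even at large counts; agreement is asserted on that scale
  stat_of <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  for (cells in list(c(18, 12, 9, 21), c(70, 50, 55, 65),
                     c(130, 120, 120, 130))) {
    tb <- matrix(cells, 2, byrow = TRUE)
    r <- two_by_two_test(cells[1], cells[2], cells[3], cells[4])
    mc <- withr::with_seed(8, {
      sims <- stats::r2dtable(20000, rowSums(tb), colSums(tb))
      mean(vapply(sims, stat_of, numeric(1)) >= r$statistic - 1e-9)
    })
    expect_lt(abs(r$p_value - mc), 0.06)
  }
})

test_that("odds ratios follow the closed forms and symmetries", {
  expect_equal(round(odds_ratio_ci(25, 4, 35, 24)$odds_ratio, 3), 4.286)
  r1 <- odds_ratio_ci(1, 1, 1, 1)
  expect_equal(r1$odds_ratio, 1)
  expect_equal(log(r1$ci_low), -log(r1$ci_high))   # symmetric on log scale
  # Haldane-Anscombe correction with a zero cell
  rz <- odds_ratio_ci(5, 0, 5, 5)
  expect_equal(rz$odds_ratio, (5.5 * 5.5) / (0.5 * 5.5))
  expect_equal(rz$or_method, "woolf_haldane")
  # OR(swapped groups) = 1/OR; swap rows and columns leaves OR unchanged
  for (i in 1:10) {
    tb <- withr::with_seed(i, sample(1:30, 4))
    a <- odds_ratio_ci(tb[1], tb[2], tb[3], tb[4])$odds_ratio
    b <- odds_ratio_ci(tb[3], tb[4], tb[1], tb[2])$odds_ratio
    d <- odds_ratio_ci(tb[4], tb[3], tb[2], tb[1])$odds_ratio
    expect_equal(a, 1 / b)
    expect_equal(a, d)
  }
  # exact conditional interval is available and ordered
  re <- odds_ratio_ci(25, 4, 35, 24, method = "exact")
  expect_equal(re$or_method, "exact_conditional")
  expect_lt(re$ci_low, re$ci_high)
})

test_that("lineage chi-square follows the Pearson closed form", {
  # exact proportionality
  expect_equal(lineage_chi_square(matrix(c(5, 10, 10, 20, 15, 30),
                                         ncol = 2, byrow = TRUE))$statistic, 0)
  r <- lineage_chi_square(matrix(c(20, 10, 10, 20), 2, byrow = TRUE))
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-9)
  expect_equal(r$df, 1)
  expect_equal(round(r$p_value, 4), 0.0098)
  # zero-total categories are dropped with a warning
  expect_warning(
    r2 <- lineage_chi_square(matrix(c(20, 10, 0, 0, 10, 20), ncol = 2,
                                    byrow = TRUE)),
    "dropped")
  expect_equal(r2$n_lineages, 2)
  expect_error(
    suppressWarnings(lineage_chi_square(matrix(c(5, 5, 0, 0), 2,
                                               byrow = TRUE))),
    "Degenerate")
})

test_that("summary t-tests match the pooled closed form", {
  r0 <- t_from_summary(10, 2, 20, 10, 2, 20)
  expect_equal(r0$t, 0)
  expect_equal(r0$p_value, 1)
  # the cohort age comparison: rounded summaries give t ~ -0.976, df 86
  r <- t_from_summary(27.7, 4.2, 29, 28.6, 4.0, 59)
  expect_equal(r$df, 86)
  sp2 <- (28 * 4.2^2 + 58 * 4.0^2) / 86
  expect_equal(r$t, -0.9 / sqrt(sp2 * (1 / 29 + 1 / 59)), tolerance = 1e-12)
  expect_equal(round(r$t, 2), -0.98)
  # paired variant on summaries of differences
  rp <- t_from_summary(1.0, 1.0, 16, kind = "paired")
  expect_equal(rp$t, 4)
  expect_equal(rp$df, 15)
  expect_error(t_from_summary(1, 0, 10, 2, 1, 10), "positive")
})

test_that("Cohen's d follows the rms-SD and pooled denominators", {
  expect_equal(round(cohens_d_summary(27.7, 4.2, 28.6, 4.0), 6), 0.219447)
  expect_equal(cohens_d_summary(5, 1, 5, 2), 0)
  expect_equal(cohens_d_summary(0, 1, 1, 1), 1)
  dp <- cohens_d_summary(27.7, 4.2, 28.6, 4.0, n1 = 29, n2 = 59,
                         method = "pooled_df_weighted")
  expect_equal(dp, 0.9 / sqrt((28 * 4.2^2 + 58 * 4.0^2) / 86),
               tolerance = 1e-12)
})

test_that("per-site association reports the polarized tables", {
  mk <- function(base) paste0("T", base, "C")
  seqs <- make_seqs(c(rep(mk("G"), 25), rep(mk("A"), 4),
                      rep(mk("G"), 35), rep(mk("A"), 24)),
                    groups = c(rep("F", 29), rep("NF", 59)))
  counts <- build_site_counts(seqs, "TGC")
  res <- site_association(counts)
  expect_equal(nrow(res), 1)
  expect_equal(res$position, 2L)
  expect_equal(c(res$a, res$b, res$c, res$d), c(4, 25, 24, 35))
  expect_equal(round(res$odds_ratio, 3), round(1 / 4.2857143, 3))
  # Bonferroni over polymorphic sites
  res2 <- site_association(counts, p_adjust = "bonferroni")
  expect_equal(res2$p_adjusted, pmin(1, res2$p_value * 1))
})
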