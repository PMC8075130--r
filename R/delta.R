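#' Allele-frequency-difference (delta) scan with 3-SD outlier flagging
#'
#' Computes, at every reference position, the absolute allele-frequency
#' difference delta between the two groups after polarizing each site to the
#' cohort-wide major allele, then flags outlier sites whose delta exceeds a
#' threshold built from the standard deviation of delta over polymorphic
#' sites.
#'
#' At biallelic sites delta is `|p1 - p2|` for the non-major allele; at
#' multiallelic sites it is the total-variation distance (half the L1
#' distance between the allele-frequency vectors) by default, or the largest
#' non-major per-allele difference (`cfg$multiallelic_delta`). Monomorphic
#' sites have delta 0 and do not enter the SD.
#'
#' Two flagging rules are available: `"three_sd_about_zero"` (default)
#' flags `delta > 3 * sd(delta)`, reading "greater than three standard
#' deviations" literally about zero; `"mean_plus_three_sd"` flags
#' `delta > mean(delta) + 3 * sd(delta)`. The SD is the sample (n-1)
#' standard deviation over polymorphic sites. If that SD is zero nothing is
#' flagged and a warning is raised.
#'
#' @param counts A `site_counts` tibble from [build_site_counts()].
#' @param rule Outlier rule, see above.
#' @param cfg A [cohort_config()]; only `multiallelic_delta` is used here.
#' @return A tibble of class `delta_scan` with one row per scorable position:
#'   `position`, `major_allele`, `polymorphic`, one `freq_<group>` column per
#'   group (frequency of the non-major allele mass), `delta`, `outlier`.
#'   Attributes `sd_delta`, `threshold`, `rule`, `n_polymorphic`, `groups`.
#' @export
delta_scan <- function(counts,
                       rule = c("three_sd_about_zero", "mean_plus_three_sd"),
                       cfg = NULL) {
  rule <- match.arg(rule)
  cfg <- if (is.null(cfg)) attr(counts, "cfg") %||% cohort_config()
         else as_cohort_config(cfg)
  groups <- attr(counts, "groups") %||% sort(unique(counts$group))
  if (length(groups) != 2) abort("delta scan requires exactly 2 groups.")

  freqs <- counts %>%
    group_by(.data$position, .data$group) %>%
    mutate(freq = .data$n / sum(.data$n)) %>%
    ungroup()

  # sites where only one group has countable samples cannot be scored
  seen <- freqs %>% distinct(.data$position, .data$group) %>%
    count(.data$position)
  undef <- seen$position[seen$n < 2]
  if (length(undef)) {
    warn(sprintf("%d site(s) skipped: one group has no countable samples.",
                 length(undef)))
    freqs <- filter(freqs, !.data$position %in% undef)
  }

  wide <- freqs %>%
    select("position", "group", "allele", "freq",
           "major_allele", "polymorphic") %>%
    tidyr::pivot_wider(names_from = "group", values_from = "freq",
                       values_fill = 0)
  g1 <- groups[1]; g2 <- groups[2]

  per_site <- wide %>%
    group_by(.data$position, .data$major_allele, .data$polymorphic) %>%
    summarise(
      delta = if (cfg$multiallelic_delta == "total_variation") {
        sum(abs(.data[[g1]] - .data[[g2]])) / 2
      } else {
        nm <- .data$allele != .data$major_allele[1]
        if (any(nm)) max(abs(.data[[g1]][nm] - .data[[g2]][nm])) else 0
      },
      freq1 = 1 - sum(.data[[g1]][.data$allele == .data$major_allele[1]]),
      freq2 = 1 - sum(.data[[g2]][.data$allele == .data$major_allele[1]]),
      .groups = "drop"
    ) %>%
    arrange(.data$position)
  names(per_site)[names(per_site) == "freq1"] <- paste0("freq_", g1)
  names(per_site)[names(per_site) == "freq2"] <- paste0("freq_", g2)

  poly_delta <- per_site$delta[per_site$polymorphic]
  if (length(poly_delta) < 2) {
    abort("Scan error: need >= 2 polymorphic sites to estimate the SD.")
  }
  sd_delta <- sd(poly_delta)
  threshold <- switch(rule,
    three_sd_about_zero = 3 * sd_delta,
    mean_plus_three_sd = mean(poly_delta) + 3 * sd_delta
  )
  if (sd_delta == 0) {
    warn("sd(delta) is zero over polymorphic sites; no outliers flagged.")
    per_site$outlier <- FALSE
  } else {
    per_site$outlier <- per_site$delta > threshold
  }

  structure(
    per_site,
    sd_delta = sd_delta,
    threshold = if (sd_delta == 0) NA_real_ else threshold,
    rule = rule,
    n_polymorphic = sum(per_site$polymorphic),
    groups = groups,
    class = c("delta_scan", class(per_site))
  )
}

#' Delta at a single site from explicit group counts
#'
#' Convenience wrapper for one position: give per-group allele counts and
#' get the polarized delta. Used mostly for worked examples and tests; the
#' cohort path is [delta_scan()].
#'
#' @param counts_by_group Named list: group -> named numeric vector of
#'   allele counts, e.g. `list(F = c(G = 25, A = 4), NF = c(G = 35, A = 24))`.
#' @param multiallelic `"total_variation"` or `"max_nonmajor"`.
#' @return A one-row tibble: `major_allele`, `delta`, one `freq_<group>`
#'   column per group.
#' @export
#' @examples
#' site_delta(list(F = c(G = 25, A = 4), NF = c(G = 35, A = 24)))
site_delta <- function(counts_by_group,
                       multiallelic = c("total_variation", "max_nonmajor")) {
  multiallelic <- match.arg(multiallelic)
  groups <- sort(names(counts_by_group))
  if (length(groups) != 2) abort("Exactly 2 groups required.")
  alleles <- sort(unique(unlist(lapply(counts_by_group, names))))
  f <- vapply(groups, function(g) {
    v <- counts_by_group[[g]][alleles]
    v[is.na(v)] <- 0
    if (sum(v) == 0) abort(sprintf("Group '%s' has no counts.", g))
    v / sum(v)
  }, numeric(length(alleles)))
  rownames(f) <- alleles
  pooled <- rowSums(vapply(groups, function(g) {
    v <- counts_by_group[[g]][alleles]; v[is.na(v)] <- 0; v
  }, numeric(length(alleles))))
  major <- alleles[which.max(pooled)]
  delta <- if (multiallelic == "total_variation") {
    sum(abs(f[, 1] - f[, 2])) / 2
  } else {
    nm <- alleles != major
    if (any(nm)) max(abs(f[nm, 1] - f[nm, 2])) else 0
  }
  out <- tibble(major_allele = major, delta = delta)
  for (g in groups) out[[paste0("freq_", g)]] <- 1 - f[major, g]
  out
}

#' @method tidy delta_scan
#' @export
tidy.delta_scan <- function(x, outliers_only = FALSE, ...) {
  out <- as_tibble(x)
  if (outliers_only) {
    out <- out %>% filter(.data$outlier) %>% arrange(desc(.data$delta))
  }
  out
}

#' @method glance delta_scan
#' @export
glance.delta_scan <- function(x, ...) {
  tibble(
    n_sites = nrow(x),
    n_polymorphic = attr(x, "n_polymorphic"),
    n_outliers = sum(x$outlier),
    sd_delta = attr(x, "sd_delta"),
    threshold = attr(x, "threshold"),
    rule = attr(x, "rule")
  )
}

#' Manhattan-style plot of a delta scan
#'
#' @param object A `delta_scan` result.
#' @param ... Unused.
#' @return A ggplot: position vs delta, outliers highlighted, threshold line.
#' @method autoplot delta_scan
#' @export
autoplot.delta_scan <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$delta)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier), size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "mtDNA position", y = expression(delta),
                  colour = "> threshold") +
    ggplot2::theme_minimal()
  thr <- attr(object, "threshold")
  if (is.finite(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dashed")
  }
  p
}

#' @method print delta_scan
#' @export
print.delta_scan <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<delta_scan> %d sites, %d polymorphic, %d outlier(s); sd(delta)=%.5f, rule=%s, threshold=%.5f\n",
    g$n_sites, g$n_polymorphic, g$n_outliers, g$sd_delta, g$rule,
    ifelse(is.na(g$threshold), NA, g$threshold)))
  NextMethod()
}
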