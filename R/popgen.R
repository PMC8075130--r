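#' Wright's FST over haplogroup frequencies
#'
#' Treats haplogroups as alleles of one locus and computes the
#' heterozygosity-partition (GST-style) fixation index:
#' `H_T = 1 - sum(pbar_k^2)` with `pbar` the pooled haplogroup frequencies,
#' `H_S = sum_g w_g (1 - sum_k p_gk^2)` with `w_g = n_g / N`, and
#' `F_ST = (H_T - H_S) / H_T`. Significance comes from permuting sample
#' group labels and recomputing; `p = (b + 1) / (m + 1)` where `b` counts
#' permuted estimates at least as large as the observed one.
#'
#' @param counts Group -> haplogroup counts: either a tibble with columns
#'   `group`, `haplogroup`, `n`, or a named list of named vectors.
#' @param n_permutations Label permutations, default 10000.
#' @param seed Integer seed for the permutation stream.
#' @return One-row tibble of class `fst_result`: `flavor`, `estimate`,
#'   `p_value`, `n_permutations`, `seed`. The permuted estimates are kept
#'   in attribute `perm`.
#' @export
#' @examples
#' haplogroup_fst(list(F = c(H = 20, L3 = 9), NF = c(H = 40, L3 = 19)),
#'                n_permutations = 999, seed = 1)
haplogroup_fst <- function(counts, n_permutations = 10000L, seed = 1L) {
  tab <- hg_counts_matrix(counts)          # groups x haplogroups
  if (nrow(tab) < 2) abort("Need >= 2 groups.")
  if (sum(colSums(tab) > 0) < 2) {
    abort("Undefined FST: fewer than 2 haplogroups observed.")
  }
  obs <- gst_from_table(tab)
  # permutation: shuffle individual labels
  hap_of <- rep(colnames(tab), colSums(tab))
  sizes <- rowSums(tab)
  grp_of <- rep(rownames(tab), sizes)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      g <- sample(grp_of)
      gst_from_table(table(g, hap_of))
    }, numeric(1))
  })
  out <- tibble(
    flavor = "haplogroup_frequency",
    estimate = obs,
    p_value = (sum(perm >= obs) + 1) / (n_permutations + 1),
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed)
  )
  structure(out, perm = perm, class = c("fst_result", class(out)))
}

hg_counts_matrix <- function(counts) {
  if (is.list(counts) && !is.data.frame(counts)) {
    counts <- purrr::imap(counts, function(v, g) {
      tibble(group = g, haplogroup = names(v), n = as.numeric(v))
    }) %>% bind_rows()
  }
  wide <- tidyr::pivot_wider(counts, names_from = "haplogroup",
                             values_from = "n", values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$group
  m
}

gst_from_table <- function(tab) {
  tab <- as.matrix(unclass(tab))
  n_g <- rowSums(tab)
  N <- sum(n_g)
  pbar <- colSums(tab) / N
  h_t <- 1 - sum(pbar^2)
  if (h_t == 0) abort("Undefined FST: total heterozygosity is zero.")
  p_g <- tab / n_g
  h_s <- sum((n_g / N) * (1 - rowSums(p_g^2)))
  (h_t - h_s) / h_t
}

#' Pairwise mismatch distances between aligned sequences
#'
#' `d[i, j]` counts the positions at which both samples carry an
#' unambiguous base (A/C/G/T) and the bases differ; positions where either
#' sample has N, a gap or an ambiguity code are skipped for that pair
#' (pairwise deletion).
#'
#' @param seqs Tibble from [read_aligned_fasta()].
#' @return A symmetric numeric matrix with sample ids as dimnames and zero
#'   diagonal; attribute `usable_sites` holds the per-pair number of
#'   compared positions.
#' @export
pairwise_differences <- function(seqs) {
  M <- do.call(rbind, strsplit(seqs$bases, "", fixed = TRUE))
  if (length(unique(nchar(seqs$bases))) > 1) {
    abort("Alignment error: sequences differ in length.")
  }
  ok <- M %in% c("A", "C", "G", "T")
  dim(ok) <- dim(M)
  n <- nrow(M)
  d <- matrix(0, n, n, dimnames = list(seqs$sample_id, seqs$sample_id))
  usable <- matrix(ncol(M), n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- ok[i, ] & ok[j, ]
      d[i, j] <- d[j, i] <- sum(M[i, both] != M[j, both])
      usable[i, j] <- usable[j, i] <- sum(both)
    }
  }
  attr(d, "usable_sites") <- usable
  d
}

#' AMOVA-style PhiST from a pairwise distance matrix
#'
#' Two-level analysis of molecular variance on squared distances:
#' `SSD_total = (1/(2N)) * sum_ij d_ij^2`,
#' `SSD_within = sum_g (1/(2 n_g)) * sum_{i,j in g} d_ij^2`,
#' `SSD_among = SSD_total - SSD_within`; mean squares use `df_among = G - 1`
#' and `df_within = N - G`; the among-group variance component is
#' `(MS_among - MS_within) / n0` with `n0 = (N - sum(n_g^2)/N) / (G - 1)`,
#' and `PhiST = sigma2_a / (sigma2_a + sigma2_w)`. Significance by
#' permuting group labels over the distance matrix.
#'
#' @param dm Distance matrix from [pairwise_differences()] (or any labeled
#'   symmetric matrix).
#' @param groups Group label per sample, in matrix order, or a metadata
#'   tibble with `sample_id`, `group`.
#' @param n_permutations Default 10000 (minimum 99).
#' @param seed Integer seed.
#' @return One-row `fst_result` tibble with `flavor = "phi_st_pairwise"`.
#' @export
phi_st <- function(dm, groups, n_permutations = 10000L, seed = 1L) {
  if (n_permutations < 99) abort("Need n_permutations >= 99.")
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group),
                       groups$sample_id)[rownames(dm)]
  }
  groups <- as.character(groups)
  if (any(table(groups) < 2)) {
    abort("AMOVA error: every group needs >= 2 samples.")
  }
  d2 <- dm^2
  obs <- phi_from_d2(d2, groups)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      phi_from_d2(d2, sample(groups))
    }, numeric(1))
  })
  out <- tibble(
    flavor = "phi_st_pairwise",
    estimate = obs,
    p_value = (sum(perm >= obs) + 1) / (n_permutations + 1),
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed)
  )
  structure(out, perm = perm, class = c("fst_result", class(out)))
}

phi_from_d2 <- function(d2, groups) {
  N <- nrow(d2)
  g_levels <- unique(groups)
  G <- length(g_levels)
  ssd_total <- sum(d2) / (2 * N)
  n_g <- tabulate(factor(groups, levels = g_levels))
  ssd_within <- sum(vapply(seq_along(g_levels), function(k) {
    idx <- groups == g_levels[k]
    sum(d2[idx, idx]) / (2 * n_g[k])
  }, numeric(1)))
  ssd_among <- ssd_total - ssd_within
  ms_among <- ssd_among / (G - 1)
  sigma2_w <- ssd_within / (N - G)
  n0 <- (N - sum(n_g^2) / N) / (G - 1)
  sigma2_a <- (ms_among - sigma2_w) / n0
  sigma2_a / (sigma2_a + sigma2_w)
}

#' @method tidy fst_result
#' @export
tidy.fst_result <- function(x, ...) as_tibble(x)

#' @method glance fst_result
#' @export
glance.fst_result <- function(x, ...) {
  as_tibble(x)[, c("flavor", "estimate", "p_value")]
}

#' Permutation-null histogram for an FST/PhiST estimate
#'
#' @param object An `fst_result`.
#' @param ... Unused.
#' @return A ggplot of the permuted estimates with the observed value marked.
#' @method autoplot fst_result
#' @export
autoplot.fst_result <- function(object, ...) {
  perm <- attr(object, "perm")
  ggplot2::ggplot(tibble(perm = perm), ggplot2::aes(x = .data$perm)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$estimate, colour = "firebrick") +
    ggplot2::labs(x = sprintf("permuted %s", object$flavor), y = "count",
                  subtitle = sprintf("observed = %.4f, p = %.4f",
                                     object$estimate, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Neighbor-joining QC tree as a newick string
#'
#' A quick quality-control tree over the mismatch distance matrix (samples
#' should cluster by haplogroup); not a substitute for model-based
#' phylogenetics.
#'
#' @param dm Labeled distance matrix.
#' @return A newick string with branch lengths.
#' @export
nj_tree_newick <- function(dm) {
  if (nrow(dm) < 3) abort("Tree error: need >= 3 samples.")
  tree <- ape::nj(as.dist(dm))
  ape::write.tree(tree)
}
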