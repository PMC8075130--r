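#' Build the polarized per-site allele-count table
#'
#' Tabulates, at every reference position, how many samples of each group
#' carry each allele, after applying the heteroplasmy policy and the
#' homopolymer-indel mask. Each site is polarized to the cohort-wide major
#' allele (pooled argmax, alphabetical tie-break A<C<G<T). `N` and wide
#' ambiguity codes contribute no count; masked homopolymer deletions are
#' counted as the reference base.
#'
#' @param seqs Tibble from [read_aligned_fasta()].
#' @param reference Reference base string.
#' @param cfg A [cohort_config()].
#' @return A tibble of class `site_counts` with columns `position`, `group`,
#'   `allele`, `n` (only alleles observed at least once), plus per-position
#'   `major_allele` and `polymorphic`. Attributes: `groups`, `group_sizes`,
#'   `reference`, `cfg`.
#' @export
build_site_counts <- function(seqs, reference, cfg = cohort_config()) {
  cfg <- as_cohort_config(cfg)
  ref <- chars(reference)
  L <- length(ref)
  groups <- sort(unique(seqs$group))
  if (length(groups) < 2) abort("Need >= 2 groups.")

  M <- do.call(rbind, strsplit(seqs$bases, "", fixed = TRUE))
  if (ncol(M) != L) abort("Sequence length differs from reference length.")
  bad <- setdiff(unique(as.vector(M)), .valid_alpha)
  if (length(bad)) abort(sprintf("Alphabet error: '%s' in cohort.", bad[1]))

  # homopolymer rule: '-' runs anchored in long reference runs revert to ref
  run_len <- homopolymer_run_length(reference)
  for (i in seq_len(nrow(M))) {
    g <- M[i, ] == "-"
    if (!any(g)) next
    r <- rle(g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      if (run_len[starts[j]] >= cfg$homopolymer_min_run) {
        span <- starts[j]:ends[j]
        M[i, span] <- ref[span]
      }
    }
  }

  alleles <- c("A", "C", "G", "T", "-")
  amb_idx <- which(matrix(M %in% names(iupac2), nrow = nrow(M)), arr.ind = TRUE)

  # base counting on the unambiguous part
  M_plain <- M
  M_plain[M_plain %in% c(names(iupac2), iupac_many)] <- "N"
  counts <- array(0, dim = c(length(alleles), L, length(groups)),
                  dimnames = list(alleles, NULL, groups))
  for (gi in seq_along(groups)) {
    sub <- M_plain[seqs$group == groups[gi], , drop = FALSE]
    for (a in alleles) counts[a, , gi] <- colSums(sub == a)
  }

  # heteroplasmic cells per policy
  if (nrow(amb_idx) && cfg$heteroplasmy_policy != "exclude_site_sample") {
    pooled_plain <- apply(counts, c(1, 2), sum)
    for (k in seq_len(nrow(amb_idx))) {
      i <- amb_idx[k, 1]; p <- amb_idx[k, 2]
      two <- sort(iupac2[[M[i, p]]])
      gi <- match(seqs$group[i], groups)
      if (cfg$heteroplasmy_policy == "count_major") {
        pick <- two[which.max(pooled_plain[two, p])]
        counts[pick, p, gi] <- counts[pick, p, gi] + 1
      } else { # iupac: half a count to each base
        counts[two, p, gi] <- counts[two, p, gi] + 0.5
      }
    }
  }

  group_totals <- apply(counts, c(2, 3), sum)
  if (any(colSums(group_totals) == 0)) {
    abort("Degenerate cohort: a group has zero countable samples at every site.")
  }

  pooled <- apply(counts, c(1, 2), sum)
  major <- alleles[max.col(t(pooled), ties.method = "first")]
  polymorphic <- colSums(pooled > 0) >= 2

  long <- purrr::map(seq_along(groups), function(gi) {
    purrr::map(alleles, function(a) {
      nz <- which(counts[a, , gi] > 0)
      if (!length(nz)) return(NULL)
      tibble(position = nz, group = groups[gi], allele = a,
             n = counts[a, nz, gi])
    }) %>% bind_rows()
  }) %>% bind_rows()

  out <- long %>%
    arrange(.data$position, .data$group, .data$allele) %>%
    mutate(major_allele = major[.data$position],
           polymorphic = polymorphic[.data$position])
  structure(
    out,
    groups = groups,
    group_sizes = setNames(as.integer(table(seqs$group)[groups]), groups),
    reference = reference,
    cfg = cfg,
    class = c("site_counts", class(out))
  )
}

#' Build site counts from explicit variant calls
#'
#' Alternative entry point for VCF-derived calls: reconstructs each sample's
#' consensus by applying its calls to the reference (SNPs and deletions;
#' insertions cannot be represented in the fixed-coordinate matrix and are
#' ignored with a warning; heteroplasmic SNPs become IUPAC codes), then
#' counts with [build_site_counts()].
#'
#' @param calls Tibble of calls (see [read_vcf_variants()]).
#' @param metadata Tibble with `sample_id`, `group`; all samples listed here
#'   are counted, including call-free ones.
#' @param reference Reference base string.
#' @param cfg A [cohort_config()].
#' @return A `site_counts` tibble.
#' @export
site_counts_from_calls <- function(calls, metadata, reference,
                                   cfg = cohort_config()) {
  seqs <- sequences_from_calls(calls, metadata, reference)
  build_site_counts(seqs, reference, cfg)
}

# apply calls to the reference to rebuild consensus strings
sequences_from_calls <- function(calls, metadata, reference) {
  ref <- chars(reference)
  if (any(calls$kind == "insertion")) {
    warn("Insertions cannot be placed in the fixed-length matrix; ignored.")
  }
  code_of <- function(a, b) {
    two <- sort(c(a, b))
    names(iupac2)[purrr::map_lgl(iupac2, function(x) identical(sort(x), two))]
  }
  bases <- purrr::map_chr(metadata$sample_id, function(id) {
    b <- ref
    cc <- calls[calls$sample_id == id & !calls$masked, , drop = FALSE]
    if (nrow(cc)) {
      for (k in seq_len(nrow(cc))) {
        p <- cc$position[k]
        if (cc$kind[k] == "SNP") {
          b[p] <- if (isTRUE(cc$heteroplasmic[k])) {
            code_of(cc$ref_allele[k], cc$alt_allele[k])
          } else cc$alt_allele[k]
        } else if (cc$kind[k] == "deletion") {
          span <- p:(p + nchar(cc$ref_allele[k]) - 1L)
          b[span] <- "-"
        }
      }
    }
    paste(b, collapse = "")
  })
  tibble(sample_id = metadata$sample_id, group = metadata$group, bases = bases)
}
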