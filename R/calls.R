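#' Derive variant calls from aligned consensus sequences
#'
#' Compares each sample's consensus to the reference, column by column.
#' Plain base mismatches become SNP calls; runs of `-` become a single
#' deletion call anchored at the first gapped position; IUPAC two-base
#' ambiguity codes (R/Y/S/W/K/M) are read as consensus heteroplasmies and
#' yield a heteroplasmic SNP call for each non-reference base; `N` and
#' three/four-base ambiguity codes never produce a call.
#'
#' @param seqs Tibble from [read_aligned_fasta()] (columns `sample_id`,
#'   `group`, `bases`).
#' @param reference Reference base string (A/C/G/T only), same length as the
#'   sequences.
#' @return A tibble of calls (see [read_vcf_variants()] for columns).
#' @export
calls_from_alignment <- function(seqs, reference) {
  ref <- chars(reference)
  if (!all(ref %in% c("A", "C", "G", "T"))) {
    abort("Reference must contain only A, C, G, T.")
  }
  out <- purrr::map2(seqs$sample_id, seqs$bases, function(id, s) {
    b <- chars(s)
    if (length(b) != length(ref)) {
      abort(sprintf("Alignment error: sample '%s' length %d != reference %d.",
                    id, length(b), length(ref)))
    }
    bad <- setdiff(unique(b), .valid_alpha)
    if (length(bad)) {
      abort(sprintf("Alphabet error: sample '%s' contains '%s'.",
                    id, bad[1]))
    }
    rows <- list()
    # plain SNPs
    snp_pos <- which(b %in% c("A", "C", "G", "T") & b != ref)
    if (length(snp_pos)) {
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = id, position = snp_pos, ref_allele = ref[snp_pos],
        alt_allele = b[snp_pos], kind = "SNP", minor_fraction = NA_real_,
        heteroplasmic = FALSE, masked = FALSE
      )
    }
    # heteroplasmic IUPAC codes: one call per non-reference base
    amb_pos <- which(b %in% names(iupac2))
    for (p in amb_pos) {
      for (a in setdiff(iupac2[[b[p]]], ref[p])) {
        rows[[length(rows) + 1L]] <- tibble(
          sample_id = id, position = p, ref_allele = ref[p],
          alt_allele = a, kind = "SNP", minor_fraction = NA_real_,
          heteroplasmic = TRUE, masked = FALSE
        )
      }
    }
    # deletions: '-' runs anchored at the first gapped position
    if (any(b == "-")) {
      r <- rle(b == "-")
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        p <- starts[j]
        rows[[length(rows) + 1L]] <- tibble(
          sample_id = id, position = p,
          ref_allele = paste(ref[p:ends[j]], collapse = ""),
          alt_allele = "-", kind = "deletion", minor_fraction = NA_real_,
          heteroplasmic = FALSE, masked = FALSE
        )
      }
    }
    if (length(rows)) bind_rows(rows) else NULL
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) empty_calls() else arrange(res, .data$sample_id, .data$position)
}

#' Heteroplasmy acceptance rule
#'
#' A position with two nucleotides within one individual is accepted as
#' heteroplasmic when the minor:major ratio reaches the configured minimum
#' (default 1:4, i.e. 0.25).
#'
#' @param minor_count,major_count Non-negative read/molecule counts of the
#'   two nucleotides; not both zero.
#' @param cfg A [cohort_config()].
#' @return Logical: does the pair qualify as a heteroplasmy?
#' @export
#' @examples
#' heteroplasmy_flag(20, 80)  # exactly 1:4 -> TRUE
#' heteroplasmy_flag(19, 81)  # below      -> FALSE
heteroplasmy_flag <- function(minor_count, major_count, cfg = cohort_config()) {
  cfg <- as_cohort_config(cfg)
  if (any(minor_count < 0) || any(major_count < 0)) {
    abort("Counts must be non-negative.")
  }
  if (any(minor_count + major_count == 0)) {
    abort("Undefined ratio: both counts zero.")
  }
  lo <- pmin(minor_count, major_count)
  hi <- pmax(minor_count, major_count)
  lo / hi >= cfg$heteroplasmy_min_ratio
}

# run-length table of the reference: for each position, the length of the
# single-base run containing it
homopolymer_run_length <- function(reference) {
  r <- rle(chars(reference))
  rep(r$lengths, r$lengths)
}

#' Mask indels anchored in homopolymeric reference runs
#'
#' Insertions and deletions whose anchor position lies inside a single-base
#' reference run of length >= `homopolymer_min_run` are marked `masked` and
#' excluded from downstream allele counts (they are treated as variation
#' with no effect). SNPs are never masked.
#'
#' @param calls Tibble of variant calls.
#' @param reference Reference base string.
#' @param cfg A [cohort_config()].
#' @return The calls tibble with `masked` updated.
#' @export
mask_homopolymer_indels <- function(calls, reference, cfg = cohort_config()) {
  cfg <- as_cohort_config(cfg)
  if (nrow(calls) == 0) return(calls)
  run_len <- homopolymer_run_length(reference)
  is_indel <- calls$kind %in% c("insertion", "deletion")
  calls$masked <- is_indel & run_len[calls$position] >= cfg$homopolymer_min_run
  calls
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
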