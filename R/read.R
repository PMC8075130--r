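#' Read a single-record reference FASTA
#'
#' @param path Path to a FASTA file holding exactly one record (the
#'   mitochondrial reference the cohort was aligned to, e.g. an rCRS-length
#'   sequence).
#' @return A single uppercase string of A/C/G/T bases.
#' @export
read_reference_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1) {
    abort(sprintf("Reference FASTA must hold exactly 1 record, found %d.",
                  length(set)))
  }
  toupper(as.character(set[[1]]))
}

#' Read sample metadata (sample -> group)
#'
#' @param path Tab-separated file with header columns `sample_id` and
#'   `group`.
#' @return A tibble with columns `sample_id`, `group`.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(meta))) {
    abort("Metadata must have columns `sample_id` and `group`.")
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("Duplicate sample_id in metadata.")
  }
  meta[, c("sample_id", "group")]
}

#' Read an aligned cohort FASTA and attach group labels
#'
#' All records must have the same length as each other (one consensus
#' sequence per individual, aligned to a common reference), and every record
#' id must be present in the metadata.
#'
#' @param path Path to the cohort FASTA.
#' @param metadata A tibble/data frame with columns `sample_id`, `group`
#'   (see [read_sample_metadata()]).
#' @return A tibble with columns `sample_id`, `group`, `bases` (one sequence
#'   string per row), in file order.
#' @export
read_aligned_fasta <- function(path, metadata) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  lens <- Biostrings::width(set)
  if (length(unique(lens)) > 1) {
    modal <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
    bad_i <- which(lens != modal)[1]
    abort(sprintf(
      "Alignment error: record '%s' has length %d, others %d.",
      ids[bad_i], lens[bad_i], modal))
  }
  missing <- setdiff(ids, metadata$sample_id)
  if (length(missing)) {
    abort(sprintf("Metadata error: no group for sample(s): %s",
                  paste(missing, collapse = ", ")))
  }
  grp <- setNames(as.character(metadata$group), metadata$sample_id)
  tibble(
    sample_id = ids,
    group = unname(grp[ids]),
    bases = unname(toupper(as.character(set)))
  )
}

#' Read per-sample variant calls from a VCF
#'
#' Parses a VCF v4.x file with per-sample genotype columns into one call per
#' sample x ALT allele with a non-reference genotype. The allele fraction is
#' taken from a per-sample `AF` FORMAT field when present; genotypes written
#' as `0/1` (two alleles within one individual's mtDNA pool) are flagged
#' heteroplasmic.
#'
#' @param path Path to the VCF.
#' @param reference_length Optional integer; when given, positions outside
#'   `1..reference_length` raise a coordinate error.
#' @return A tibble of calls with columns `sample_id`, `position`,
#'   `ref_allele`, `alt_allele`, `kind` (`SNP`/`insertion`/`deletion`),
#'   `minor_fraction`, `heteroplasmic`, `masked` (all `FALSE`; see
#'   [mask_homopolymer_indels()]).
#' @export
read_vcf_variants <- function(path, reference_length = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0) return(empty_calls())
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    abort(sprintf("VCF parse error: non-integer POS at record %d.",
                  which(is.na(pos))[1]))
  }
  if (!is.null(reference_length) && any(pos < 1 | pos > reference_length)) {
    abort(sprintf("Coordinate error: POS %d outside 1..%d.",
                  pos[which(pos < 1 | pos > reference_length)[1]],
                  reference_length))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  af <- tryCatch(vcfR::extract.gt(v, element = "AF", as.numeric = TRUE),
                 error = function(e) NULL)
  samples <- colnames(gt)
  out <- vector("list", n_rec)
  for (i in seq_len(n_rec)) {
    alts <- strsplit(unname(fix[i, "ALT"]), ",", fixed = TRUE)[[1]]
    ref <- unname(fix[i, "REF"])
    rows <- list()
    for (s in samples) {
      g <- gt[i, s]
      if (is.na(g) || g %in% c(".", "./.", "0", "0/0", "0|0")) next
      alleles <- strsplit(g, "[/|]")[[1]]
      alt_idx <- unique(as.integer(alleles[alleles != "." & alleles != "0"]))
      het <- length(unique(alleles)) > 1
      for (k in alt_idx) {
        alt <- alts[k]
        kind <- variant_kind(ref, alt)
        frac <- if (!is.null(af)) af[i, s] else NA_real_
        rows[[length(rows) + 1L]] <- tibble(
          sample_id = s, position = pos[i], ref_allele = ref,
          alt_allele = alt, kind = kind,
          minor_fraction = if (het) min(frac, 1 - frac, na.rm = FALSE) else NA_real_,
          heteroplasmic = het, masked = FALSE
        )
      }
    }
    out[[i]] <- if (length(rows)) bind_rows(rows) else NULL
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) empty_calls() else res
}

variant_kind <- function(ref, alt) {
  if (nchar(ref) == nchar(alt) && nchar(ref) == 1) "SNP"
  else if (nchar(alt) > nchar(ref)) "insertion"
  else "deletion"
}

empty_calls <- function() {
  tibble(
    sample_id = character(), position = integer(), ref_allele = character(),
    alt_allele = character(), kind = character(), minor_fraction = double(),
    heteroplasmic = logical(), masked = logical()
  )
}
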