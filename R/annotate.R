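#' Read a mitochondrial gene model
#'
#' Tab-separated file with header columns `gene`, `start`, `end`, `strand`
#' (`+`/`-`), `phase_offset` (0/1/2), `coding` (TRUE/FALSE) and optionally
#' `wrap` (TRUE when the gene spans the circular origin, in which case
#' `start > end` and coordinates unroll past the genome length). Coordinates
#' are 1-based inclusive.
#'
#' @param path File path.
#' @param genome_length Genome length for validating wrap-around spans.
#' @return A tibble with the columns above (`wrap` filled with FALSE).
#' @export
read_gene_model <- function(path, genome_length = NULL) {
  gm <- readr::read_tsv(path, col_types = readr::cols(
    gene = "c", start = "i", end = "i", strand = "c",
    phase_offset = "i", coding = "l", .default = "c"
  ), progress = FALSE)
  if (!"wrap" %in% names(gm)) gm$wrap <- FALSE
  gm$wrap <- as.logical(gm$wrap)
  bad <- !gm$wrap & gm$start > gm$end
  if (any(bad)) {
    abort(sprintf("Gene '%s': start > end but wrap not set.",
                  gm$gene[bad][1]))
  }
  if (!is.null(genome_length)) {
    len <- gene_span_length(gm, genome_length)
    odd <- gm$coding & ((len - gm$phase_offset) %% 3 != 0)
    if (any(odd)) {
      abort(sprintf("Coding gene '%s' span not divisible by 3.",
                    gm$gene[odd][1]))
    }
  }
  gm
}

gene_span_length <- function(gm, genome_length) {
  ifelse(gm$wrap,
         genome_length - gm$start + 1L + gm$end,
         gm$end - gm$start + 1L)
}

# unrolled 1-based offset of `position` within the gene on the coding strand
gene_offset <- function(position, gene, genome_length = NULL) {
  pos <- position
  end <- gene$end
  if (isTRUE(gene$wrap)) {
    if (is.null(genome_length)) abort("Wrap-around gene needs genome_length.")
    if (pos < gene$start) pos <- pos + genome_length
    end <- gene$end + genome_length
  }
  if (pos < gene$start || pos > end) {
    abort(sprintf("Position %d outside gene '%s'.", position, gene$gene))
  }
  if (gene$strand == "+") pos - gene$start - gene$phase_offset
  else end - gene$phase_offset - pos
}

#' Locate the codon containing a position
#'
#' @param position 1-based reference position.
#' @param gene One row of a gene model (coding gene).
#' @param genome_length Needed only for wrap-around genes.
#' @return A list with `codon_index` (1-based) and `codon_position` (1-3,
#'   in reading-frame order).
#' @export
#' @examples
#' nd4 <- tibble::tibble(gene = "ND4", start = 10760, end = 12136,
#'                       strand = "+", phase_offset = 0L, coding = TRUE,
#'                       wrap = FALSE)
#' locate_codon(11914, nd4)  # codon 385, position 3
locate_codon <- function(position, gene, genome_length = NULL) {
  if (!isTRUE(gene$coding)) abort("Gene is non-coding.")
  off <- gene_offset(position, gene, genome_length)
  if (off < 0) abort(sprintf("Position %d precedes the reading frame.",
                             position))
  list(codon_index = off %/% 3 + 1L, codon_position = off %% 3 + 1L)
}

#' Read a genetic code table
#'
#' TSV with header `codon<TAB>aa` (64 rows; `aa` single letters, `*` for
#' stop). A vertebrate mitochondrial code table ships with the package:
#' `system.file("extdata", "vertebrate_mito_code.tsv", package = "mitoscan")`.
#'
#' @param path File path.
#' @return Named character vector codon -> amino acid.
#' @export
read_genetic_code <- function(path) {
  tab <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("codon", "aa") %in% names(tab)) || nrow(tab) != 64) {
    abort("Genetic code table needs 64 rows with columns codon, aa.")
  }
  setNames(tab$aa, toupper(tab$codon))
}

#' Read a codon usage table
#'
#' TSV with header `codon<TAB>per_thousand` (usage frequency per thousand
#' codons). A minimal human-mitochondrial fixture recording the ACA/ACG
#' values ships with the package (`codon_usage_mito.tsv`).
#'
#' @param path File path.
#' @return Tibble `codon`, `per_thousand`.
#' @export
read_codon_usage <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    codon = "c", per_thousand = "d", .default = "c"), progress = FALSE)
  if (!all(c("codon", "per_thousand") %in% names(tab))) {
    abort("Usage table needs columns codon, per_thousand.")
  }
  tab
}

complement <- c(A = "T", C = "G", G = "C", T = "A")

# codon (coding-strand, 5'->3') covering reading-frame offset `off0 = 3k`
codon_at <- function(gene, codon_index, ref, genome_length) {
  offs <- (codon_index - 1L) * 3L + 0:2
  pos <- if (gene$strand == "+") {
    gene$start + gene$phase_offset + offs
  } else {
    (if (isTRUE(gene$wrap)) gene$end + genome_length else gene$end) -
      gene$phase_offset - offs
  }
  pos_mod <- ((pos - 1L) %% genome_length) + 1L
  bases <- ref[pos_mod]
  if (gene$strand == "-") bases <- unname(complement[bases])
  list(bases = bases, positions = pos_mod)
}

#' Annotate a SNP's codon-level consequence
#'
#' Reads the reference codon containing the position, applies the
#' substitution, translates both under the supplied code table and flags
#' synonymous changes. Positions in non-coding genes are annotated with the
#' gene name only; positions outside all genes are `"intergenic"`.
#'
#' @param position 1-based position.
#' @param ref_allele,alt_allele Single bases (reference strand).
#' @param gene_model Gene-model tibble from [read_gene_model()].
#' @param reference Reference base string.
#' @param code Named vector from [read_genetic_code()].
#' @return One-row tibble: `position`, `gene`, `codon_index`,
#'   `codon_position`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `synonymous` (codon fields NA outside coding genes).
#' @export
classify_consequence <- function(position, ref_allele, alt_allele,
                                 gene_model, reference, code) {
  if (nchar(ref_allele) != 1 || nchar(alt_allele) != 1) {
    abort("Unsupported variant: annotation covers SNPs only.")
  }
  ref <- chars(reference)
  L <- length(ref)
  if (ref[position] != ref_allele) {
    abort(sprintf("Consistency error: reference has %s at %d, call says %s.",
                  ref[position], position, ref_allele))
  }
  hit <- gene_model[position_in_gene(position, gene_model, L), , drop = FALSE]
  na_row <- function(gene) tibble(
    position = position, gene = gene,
    codon_index = NA_integer_, codon_position = NA_integer_,
    ref_codon = NA_character_, alt_codon = NA_character_,
    ref_aa = NA_character_, alt_aa = NA_character_, synonymous = NA
  )
  if (nrow(hit) == 0) return(na_row("intergenic"))
  gene <- hit[1, ]
  if (!isTRUE(gene$coding)) return(na_row(gene$gene))
  loc <- locate_codon(position, gene, L)
  cod <- codon_at(gene, loc$codon_index, ref, L)
  ref_codon <- paste(cod$bases, collapse = "")
  alt_bases <- cod$bases
  slot <- loc$codon_position
  alt_base <- if (gene$strand == "+") alt_allele else unname(complement[alt_allele])
  alt_bases[slot] <- alt_base
  alt_codon <- paste(alt_bases, collapse = "")
  aa <- function(codon) {
    if (!codon %in% names(code)) abort(sprintf("Unknown codon '%s'.", codon))
    unname(code[codon])
  }
  tibble(
    position = position, gene = gene$gene,
    codon_index = loc$codon_index, codon_position = loc$codon_position,
    ref_codon = ref_codon, alt_codon = alt_codon,
    ref_aa = aa(ref_codon), alt_aa = aa(alt_codon),
    synonymous = aa(ref_codon) == aa(alt_codon)
  )
}

position_in_gene <- function(position, gm, genome_length) {
  plain <- !gm$wrap & position >= gm$start & position <= gm$end
  wrapped <- gm$wrap & (position >= gm$start | position <= gm$end)
  plain | wrapped
}

#' Codon usage (molar) ratio between two codons
#'
#' `usage(codon_a) / usage(codon_b)` on the per-thousand scale; the human
#' mitochondrial ACA/ACG ratio is 32.7 / 2.6 = 12.6 (1 dp).
#'
#' @param codon_a,codon_b Codon strings.
#' @param usage Tibble from [read_codon_usage()].
#' @return Numeric ratio.
#' @export
codon_usage_ratio <- function(codon_a, codon_b, usage) {
  u <- setNames(usage$per_thousand, toupper(usage$codon))
  for (cd in c(codon_a, codon_b)) {
    if (!toupper(cd) %in% names(u)) {
      abort(sprintf("Codon '%s' not in usage table.", cd))
    }
  }
  if (u[toupper(codon_b)] <= 0) abort("Ratio error: zero denominator.")
  unname(u[toupper(codon_a)] / u[toupper(codon_b)])
}

#' Annotate a set of SNPs, with usage ratios for synonymous changes
#'
#' @param variants Tibble with columns `position`, `ref_allele`,
#'   `alt_allele` (e.g. outlier sites joined back to calls).
#' @param gene_model,reference,code See [classify_consequence()].
#' @param usage Optional codon-usage tibble; when given, synonymous rows get
#'   `codon_usage_ratio = usage(alt_codon) / usage(ref_codon)`.
#' @return Tibble of per-variant annotations.
#' @export
annotate_variants <- function(variants, gene_model, reference, code,
                              usage = NULL) {
  out <- purrr::pmap(
    variants[, c("position", "ref_allele", "alt_allele")],
    function(position, ref_allele, alt_allele) {
      classify_consequence(position, ref_allele, alt_allele,
                           gene_model, reference, code)
    }
  ) %>% bind_rows()
  if (!is.null(usage)) {
    out$codon_usage_ratio <- purrr::pmap_dbl(
      out[, c("ref_codon", "alt_codon", "synonymous")],
      function(ref_codon, alt_codon, synonymous) {
        if (isTRUE(synonymous) &&
            all(c(ref_codon, alt_codon) %in% toupper(usage$codon))) {
          codon_usage_ratio(alt_codon, ref_codon, usage)
        } else NA_real_
      }
    )
  }
  out
}
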