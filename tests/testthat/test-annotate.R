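code_tab <- read_genetic_code(fixture_path("vertebrate_mito_code.tsv"))
usage_tab <- read_codon_usage(fixture_path("codon_usage_mito.tsv"))

gene_row <- function(start, end, strand = "+", phase = 0L, coding = TRUE,
                     wrap = FALSE, gene = "G1") {
  tibble::tibble(gene = gene, start = start, end = end, strand = strand,
                 phase_offset = phase, coding = coding, wrap = wrap)
}

test_that("codon location follows reading-frame arithmetic", {
  g <- gene_row(1L, 30L)
  expect_equal(locate_codon(3, g), list(codon_index = 1L, codon_position = 3L))
  # the ND4-like frame: 11914 sits at codon 385, third position
  nd4 <- gene_row(10760L, 12136L, gene = "ND4")
  expect_equal(locate_codon(11914, nd4),
               list(codon_index = 385L, codon_position = 3L))
  # minus strand: last base of the gene is codon 1, position 1
  gm <- gene_row(11L, 40L, strand = "-")
  expect_equal(locate_codon(40, gm), list(codon_index = 1L, codon_position = 1L))
  expect_error(locate_codon(5, gm), "outside")
})

test_that("codon index and position invert back to the genomic position", {
  for (g in list(gene_row(7L, 36L), gene_row(7L, 36L, strand = "-"),
                 gene_row(5L, 34L, phase = 2L))) {
    span <- (g$start + g$phase_offset):(g$end)
    if (g$strand == "-") span <- (g$start):(g$end - g$phase_offset)
    for (p in span) {
      loc <- locate_codon(p, g)
      off <- (loc$codon_index - 1) * 3 + loc$codon_position - 1
      back <- if (g$strand == "+") g$start + g$phase_offset + off
              else g$end - g$phase_offset - off
      expect_equal(back, p)
    }
  }
})

test_that("the ACG>ACA third-position change is synonymous threonine", {
  # reference with codon ACG at positions 4..6 of a + strand gene
  ref <- paste0("ATG", "ACG", "TGA", "C")
  gm <- gene_row(1L, 9L, gene = "toy")
  ann <- classify_consequence(6, "G", "A", gm, ref, code_tab)
  expect_equal(ann$ref_codon, "ACG")
  expect_equal(ann$alt_codon, "ACA")
  expect_equal(ann$ref_aa, "T")    # threonine
  expect_equal(ann$alt_aa, "T")
  expect_true(ann$synonymous)
  # ATG -> ATA: both methionine under the vertebrate mitochondrial code
  ann2 <- classify_consequence(3, "G", "A", gm, ref, code_tab)
  expect_equal(c(ann2$ref_aa, ann2$alt_aa), c("M", "M"))
  expect_true(ann2$synonymous)
  # intergenic position
  ann3 <- classify_consequence(10, "C", "T", gm, ref, code_tab)
  expect_equal(ann3$gene, "intergenic")
  expect_true(is.na(ann3$synonymous))
  # reference mismatch and indels are rejected
  expect_error(classify_consequence(6, "T", "A", gm, ref, code_tab),
               "Consistency")
  expect_error(classify_consequence(6, "GA", "A", gm, ref, code_tab),
               "SNP")
})

test_that("minus-strand and wrap-around genes translate correctly", {
  # gene on - strand occupying 1..6; coding sequence is revcomp
  ref <- "ATGACGTT"
  gm <- gene_row(1L, 6L, strand = "-")
  # coding strand reads CGTCAT; position 6 (T) is codon 1 pos 1 -> C... check
  ann <- classify_consequence(6, "G", "A", gm, ref, code_tab)
  expect_equal(ann$codon_index, 1L)
  expect_equal(ann$codon_position, 1L)
  expect_equal(ann$ref_codon, "CGT")
  expect_equal(ann$alt_codon, "TGT")   # G->A on + strand is C->T on coding
  # wrap-around gene: positions 6..8 then 1..3 (two codons)
  gmw <- gene_row(6L, 3L, wrap = TRUE, gene = "wrap")
  annw <- classify_consequence(2, "T", "C", gmw, ref, code_tab)
  expect_equal(annw$codon_index, 2L)
  expect_equal(annw$ref_codon, "ATG")
  expect_equal(annw$alt_codon, "ACG")
})

test_that("synonymous flags agree with whole-gene translation", {
  # brute-force oracle: translate the entire mutated gene with Biostrings
  set.seed(5)
  ref <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
  gm <- gene_row(1L, 60L)
  gcode <- Biostrings::getGeneticCode("2")
  translate_gene <- function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       genetic.code = gcode))
  }
  refc <- strsplit(ref, "")[[1]]
  for (p in seq(1, 60, by = 7)) {
    for (alt in setdiff(c("A", "C", "G", "T"), refc[p])) {
      mut <- refc; mut[p] <- alt
      ann <- classify_consequence(p, refc[p], alt, gm, ref, code_tab)
      brute <- translate_gene(ref) == translate_gene(paste(mut, collapse = ""))
      expect_equal(ann$synonymous, brute)
    }
  }
})

test_that("all 64 codons resolve and unknown codons error", {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(as.vector(outer(bases, bases, paste0)),
                            bases, paste0))
  expect_length(setdiff(codons, names(code_tab)), 0)
  expect_error(codon_usage_ratio("NNN", "ACG", usage_tab), "NNN")
})

test_that("codon usage ratios reproduce the ACA/ACG molar ratio", {
  r <- codon_usage_ratio("ACA", "ACG", usage_tab)
  expect_equal(round(r, 1), 12.6)
  expect_equal(codon_usage_ratio("ACA", "ACA", usage_tab), 1)
  expect_equal(codon_usage_ratio("ACA", "ACG", usage_tab) *
                 codon_usage_ratio("ACG", "ACA", usage_tab), 1,
               tolerance = 1e-12)
})

test_that("variant tables annotate in bulk with usage ratios attached", {
  ref <- paste0("ATG", "ACG", "TGA", "C")
  gm <- gene_row(1L, 9L, gene = "toy")
  vars <- tibble::tibble(position = c(6L, 10L), ref_allele = c("G", "C"),
                         alt_allele = c("A", "T"))
  ann <- annotate_variants(vars, gm, ref, code_tab, usage_tab)
  expect_equal(nrow(ann), 2)
  expect_equal(ann$gene, c("toy", "intergenic"))
  expect_equal(round(ann$codon_usage_ratio[1], 1), 12.6)
  expect_true(is.na(ann$codon_usage_ratio[2]))
})
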