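# shared in-code fixtures and independent oracles

`%||%` <- function(a, b) if (is.null(a)) b else a

make_seqs <- function(bases, groups = NULL, ids = NULL) {
  n <- length(bases)
  tibble::tibble(
    sample_id = ids %||% sprintf("s%d", seq_len(n)),
    group = groups %||% rep(c("F", "NF"), length.out = n),
    bases = bases
  )
}

write_fasta <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", seqs$sample_id), seqs$bases)), path)
  path
}

# small haplogroup tree: root L, two branches of different depth
toy_defs <- function() {
  tibble::tibble(
    name = c("L", "H", "H1", "L3", "L3e"),
    parent = c(NA, "L", "H", "L", "L3"),
    variants = list(character(0), c("10A", "20C"), c("30T"),
                    c("40G", "50A", "60T", "70C"), c("80G"))
  )
}

# independent Fisher oracle: exhaustive hypergeometric enumeration of all
# tables with the observed margins; two-sided p sums probabilities <= observed
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ak <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- stats::dhyper(ak, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# direct GST arithmetic oracle on a groups x haplogroups count matrix
gst_hand <- function(tab) {
  n_g <- rowSums(tab); N <- sum(n_g)
  pbar <- colSums(tab) / N
  h_t <- 1 - sum(pbar^2)
  h_s <- sum((n_g / N) * (1 - rowSums((tab / n_g)^2)))
  (h_t - h_s) / h_t
}

fixture_path <- function(...) {
  system.file("extdata", ..., package = "mitoscan")
}
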