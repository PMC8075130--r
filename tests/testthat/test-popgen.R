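test_that("haplogroup FST matches direct heterozygosity arithmetic", {
  # identical distributions: zero differentiation
  r0 <- haplogroup_fst(list(F = c(H = 10, L3 = 10), NF = c(H = 20, L3 = 20)),
                       n_permutations = 99, seed = 1)
  expect_equal(r0$estimate, 0)
  # fixed for different haplogroups: complete differentiation
  r1 <- haplogroup_fst(list(F = c(H = 10), NF = c(L3 = 10)),
                       n_permutations = 99, seed = 1)
  expect_equal(r1$estimate, 1)
  # near-identical spectra: tiny estimate, clearly non-significant
  tab <- rbind(F = c(H = 20, L3 = 9), NF = c(H = 40, L3 = 19))
  r2 <- haplogroup_fst(list(F = tab["F", ], NF = tab["NF", ]),
                       n_permutations = 10000, seed = 2)
  expect_equal(r2$estimate, gst_hand(tab), tolerance = 1e-12)
  expect_lt(r2$estimate, 0.001)
  expect_gt(r2$p_value, 0.3)
  # single-haplogroup cohorts are undefined
  expect_error(haplogroup_fst(list(F = c(H = 5), NF = c(H = 5)),
                              n_permutations = 99), "FST")
})

test_that("permutation p-values are seed-reproducible", {
  cc <- list(F = c(H = 12, L3 = 5, M = 3), NF = c(H = 9, L3 = 9, M = 7))
  r1 <- haplogroup_fst(cc, n_permutations = 500, seed = 42)
  r2 <- haplogroup_fst(cc, n_permutations = 500, seed = 42)
  r3 <- haplogroup_fst(cc, n_permutations = 500, seed = 43)
  expect_identical(r1$p_value, r2$p_value)
  expect_lt(abs(r1$p_value - r3$p_value),
            4 * sqrt(r1$p_value * (1 - r1$p_value) / 500) + 0.01)
})

test_that("pairwise distances count unambiguous mismatches only", {
  seqs <- make_seqs(c("ACGT", "ACGA", "ANGT", "ACCT"),
                    ids = c("a", "b", "c", "d"))
  d <- pairwise_differences(seqs)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], 1)
  expect_equal(d["c", "d"], 1)   # N position skipped, position 3 differs
  expect_equal(d, t(d))
  expect_equal(attr(d, "usable_sites")["c", "d"], 3)
})

test_that("PhiST equals hand-worked AMOVA variance components", {
  # 6 samples, 3 + 3: all within distances 0, all between 2 -> PhiST 1
  b <- matrix(2, 6, 6); b[1:3, 1:3] <- 0; b[4:6, 4:6] <- 0; diag(b) <- 0
  dimnames(b) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- rep(c("F", "NF"), each = 3)
  r <- phi_st(b, g, n_permutations = 99, seed = 1)
  expect_equal(r$estimate, 1)

  # hand-built asymmetric instance, spreadsheet-style arithmetic
  d <- matrix(0, 6, 6, dimnames = dimnames(b))
  vals <- c(1, 2, 2, 5, 6, 5, 4, 6, 5, 6, 1, 2, 5, 2, 1)
  k <- 1
  for (i in 1:5) for (j in (i + 1):6) { d[i, j] <- d[j, i] <- vals[k]; k <- k + 1 }
  d2 <- d^2
  ssd_total <- sum(d2) / (2 * 6)
  ssd_within <- sum(d2[1:3, 1:3]) / (2 * 3) + sum(d2[4:6, 4:6]) / (2 * 3)
  ms_among <- (ssd_total - ssd_within) / (2 - 1)
  s2w <- ssd_within / (6 - 2)
  n0 <- (6 - (9 + 9) / 6) / 1
  s2a <- (ms_among - s2w) / n0
  r2 <- phi_st(d, g, n_permutations = 99, seed = 1)
  expect_equal(r2$estimate, s2a / (s2a + s2w), tolerance = 1e-12)
})

test_that("exchangeable sequences give null PhiST and uniformish p", {
  ests <- ps <- numeric(60)
  for (i in 1:60) {
    seqs <- withr::with_seed(1000 + i, {
      pool <- replicate(12, paste(sample(c("A", "C", "G", "T"), 60,
                                         replace = TRUE), collapse = ""))
      make_seqs(pool, groups = rep(c("F", "NF"), each = 6))
    })
    d <- pairwise_differences(seqs)
    r <- phi_st(d, seqs$group, n_permutations = 199, seed = i)
    ests[i] <- r$estimate; ps[i] <- r$p_value
  }
  expect_lt(abs(mean(ests)), 0.05)       # centred near zero under the null
  expect_gt(mean(ps > 0.05), 0.80)       # rarely significant
})

test_that("group sizes below two are an AMOVA error", {
  b <- matrix(1, 3, 3); diag(b) <- 0
  dimnames(b) <- list(paste0("s", 1:3), paste0("s", 1:3))
  expect_error(phi_st(b, c("F", "NF", "NF"), n_permutations = 99), "AMOVA")
})

test_that("neighbor-joining recovers additive trees and haplogroup splits", {
  expect_error(nj_tree_newick(matrix(0, 2, 2)), "3")
  # additive 4-taxon distances from tree ((a:1,b:2):1,(c:3,d:4))
  dm <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, byrow = TRUE,
               dimnames = list(letters[1:4], letters[1:4]))
  nwk <- nj_tree_newick(dm)
  tree <- ape::read.tree(text = nwk)
  truth <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):0);")
  expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(truth)), 0,
               ignore_attr = TRUE)
  # pairwise path lengths reproduce the additive input
  expect_equal(ape::cophenetic.phylo(tree)[letters[1:4], letters[1:4]], dm,
               tolerance = 1e-9)

  # two founder haplotypes split cleanly in the tree
  co <- generate_cohort(sim_config(
    genome_length = 300L, n_group = c(F = 4L, NF = 4L),
    n_haplogroups = 2L, variants_per_edge = 6L,
    group_haplogroup_probs = list(F = c(1, 0), NF = c(0, 1)),
    planted_sites = tibble::tibble(position = integer(), allele = character(),
                                   p_F = double(), p_NF = double()),
    private_mutation_rate = 0.5, heteroplasmy_rate = 0,
    homopolymer_indel_rate = 0, seed = 6L))
  d <- pairwise_differences(co$sequences)
  tree <- ape::read.tree(text = nj_tree_newick(d))
  ids_f <- co$sequences$sample_id[co$sequences$group == "F"]
  # the F clade forms a bipartition of the unrooted tree
  parts <- ape::prop.part(ape::unroot(tree))
  labels <- attr(parts, "labels")
  sets <- lapply(parts, function(p) sort(labels[p]))
  want <- sort(ids_f)
  complement <- sort(setdiff(labels, ids_f))
  hit <- any(vapply(sets, identical, logical(1), want)) ||
    any(vapply(sets, identical, logical(1), complement))
  expect_true(hit)
})
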