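#' Simulation configuration for a synthetic mitogenome cohort
#'
#' Defaults mirror the cohort structure the analysis is designed for: a
#' 16,569-bp circular reference, two groups of unequal size (29 vs 59),
#' twenty-two haplogroups with a shared frequency spectrum in both groups,
#' one planted site whose non-reference allele is commoner in the larger
#' group (frequencies 4/29 vs 24/59), a handful of private mutations per
#' sample, occasional heteroplasmies and a poly-C homopolymer tract where
#' indels are injected.
#'
#' @param genome_length Reference length, default 16569.
#' @param n_group Named integer vector of group sizes, default
#'   `c(F = 29, NF = 59)`.
#' @param n_haplogroups Nodes in the simulated haplogroup tree, default 22.
#' @param variants_per_edge Defining variants on each tree edge, default 3.
#' @param group_haplogroup_probs Named list group -> probability vector over
#'   haplogroups; default NULL draws one shared spectrum from a symmetric
#'   Dirichlet(1) and uses it for both groups (no structure between groups).
#' @param planted_sites Tibble with columns `position`, `allele` and one
#'   `p_<group>` column per group (probability that a sample of that group
#'   carries the planted allele). Default: one site emulating a
#'   G-vs-A difference at frequencies 4/29 vs 24/59. Pass a zero-row tibble
#'   for a null cohort.
#' @param private_mutation_rate Poisson mean of private mutations per
#'   sample, default 5.
#' @param heteroplasmy_rate Per-sample probability of carrying one
#'   heteroplasmic position (emitted as an IUPAC code), default 0.05.
#' @param homopolymer_indel_rate Per-sample probability of a single-base
#'   deletion inside the homopolymer tract, default 0.05.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 16569L,
                       n_group = c(F = 29L, NF = 59L),
                       n_haplogroups = 22L,
                       variants_per_edge = 3L,
                       group_haplogroup_probs = NULL,
                       planted_sites = NULL,
                       private_mutation_rate = 5,
                       heteroplasmy_rate = 0.05,
                       homopolymer_indel_rate = 0.05,
                       seed = 1L) {
  if (is.null(planted_sites)) {
    planted_sites <- tibble(
      position = as.integer(round(genome_length * 11914 / 16569)),
      allele = "A",
      p_F = 4 / 29, p_NF = 24 / 59
    )
    names(planted_sites)[3:4] <- paste0("p_", names(n_group))
  }
  if (nrow(planted_sites)) {
    if (anyDuplicated(planted_sites$position)) {
      abort("Config error: planted positions collide.")
    }
    if (any(planted_sites$position > genome_length)) {
      abort("Planted position beyond genome length.")
    }
  }
  structure(
    list(
      genome_length = as.integer(genome_length),
      n_group = n_group,
      n_haplogroups = as.integer(n_haplogroups),
      variants_per_edge = as.integer(variants_per_edge),
      group_haplogroup_probs = group_haplogroup_probs,
      planted_sites = planted_sites,
      private_mutation_rate = private_mutation_rate,
      heteroplasmy_rate = heteroplasmy_rate,
      homopolymer_indel_rate = homopolymer_indel_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# realistic haplogroup names for trees up to 23 nodes; beyond that, generic
.hg_name_pool <- c("L0", "L1", "L2", "L3", "L3e", "M", "N", "R", "H", "H1",
                   "H1a", "U", "U5", "K", "J", "T", "T2", "V", "W", "X",
                   "A", "B", "C")

#' Generate a synthetic mitogenome cohort with ground truth
#'
#' Builds a seeded cohort: a uniform-random reference with an embedded
#' poly-C tract, haplogroup founders accumulated along a random tree, and
#' per-sample sequences with planted group-differential alleles, private
#' mutations, heteroplasmies and homopolymer-tract deletions. All draws
#' come from one seeded stream in a fixed order, so the same config yields
#' bit-identical cohorts.
#'
#' @param cfg A [sim_config()].
#' @return A list: `reference` (string), `sequences` (tibble `sample_id`,
#'   `group`, `bases`), `haplogroup_defs` (definition tibble usable by
#'   [classify_haplogroups()]), `truth` (list: per-sample haplogroups,
#'   planted-site realized counts, heteroplasmies, indels, tract span,
#'   seed), `cfg`.
#' @export
generate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, generate_cohort_impl(cfg))
}

generate_cohort_impl <- function(cfg) {
  L <- cfg$genome_length
  groups <- names(cfg$n_group)
  bases4 <- c("A", "C", "G", "T")

  ref <- sample(bases4, L, replace = TRUE)
  # embedded homopolymer tract (poly-C, length 8), away from planted sites
  tract_start <- max(2L, as.integer(L * 0.02))
  tract <- tract_start:(tract_start + 7L)
  ref[tract] <- "C"
  if (nrow(cfg$planted_sites) &&
      any(cfg$planted_sites$position %in% tract)) {
    abort("Planted site collides with the homopolymer tract.")
  }
  # a planted allele must be derived relative to the reference
  if (nrow(cfg$planted_sites)) {
    for (r in seq_len(nrow(cfg$planted_sites))) {
      p <- cfg$planted_sites$position[r]
      if (ref[p] == cfg$planted_sites$allele[r]) {
        ref[p] <- sample(setdiff(bases4, ref[p]), 1)
      }
    }
  }

  # haplogroup tree: node 1 is the root; others attach to a random earlier node
  K <- cfg$n_haplogroups
  hg_names <- if (K <= length(.hg_name_pool)) .hg_name_pool[seq_len(K)]
              else sprintf("HG%02d", seq_len(K))
  parent <- c(NA_integer_,
              if (K > 1) vapply(2:K, function(i) sample.int(i - 1L, 1),
                                integer(1)))
  reserved <- c(cfg$planted_sites$position, tract)
  free_pos <- setdiff(seq_len(L), reserved)
  n_edge_var <- cfg$variants_per_edge * max(K - 1L, 0L)
  edge_pos <- sample(free_pos, n_edge_var)
  defs <- tibble(
    name = hg_names,
    parent = ifelse(is.na(parent), NA_character_, hg_names[parent]),
    variants = vector("list", K)
  )
  used <- 0L
  for (i in seq_len(K)) {
    if (is.na(parent[i])) { defs$variants[[i]] <- character(0); next }
    pos <- edge_pos[used + seq_len(cfg$variants_per_edge)]
    used <- used + cfg$variants_per_edge
    alt <- vapply(pos, function(p) sample(setdiff(bases4, ref[p]), 1),
                  character(1))
    defs$variants[[i]] <- paste0(pos, alt)
  }

  # founders: reference + cumulative path variants
  founders <- lapply(hg_names, function(h) {
    s <- ref
    for (tok in hg_path_variants(defs, h)) {
      p <- as.integer(sub("[ACGT]$", "", tok))
      s[p] <- sub("^[0-9]+", "", tok)
    }
    s
  })
  names(founders) <- hg_names

  probs <- cfg$group_haplogroup_probs
  if (is.null(probs)) {
    shared <- {x <- stats::rexp(K); x / sum(x)}  # Dirichlet(1)
    probs <- setNames(rep(list(shared), length(groups)), groups)
  }

  planted <- cfg$planted_sites
  samples <- list(); truth_hg <- list(); het_log <- list(); indel_log <- list()
  planted_counts <- if (nrow(planted)) {
    matrix(0L, nrow(planted), length(groups),
           dimnames = list(NULL, groups))
  } else NULL

  idx <- 0L
  for (g in groups) {
    for (k in seq_len(cfg$n_group[[g]])) {
      idx <- idx + 1L
      id <- sprintf("%s%03d", g, k)
      hg <- sample(hg_names, 1, prob = probs[[g]])
      s <- founders[[hg]]
      if (nrow(planted)) {
        for (r in seq_len(nrow(planted))) {
          if (runif(1) < planted[[paste0("p_", g)]][r]) {
            s[planted$position[r]] <- planted$allele[r]
            planted_counts[r, g] <- planted_counts[r, g] + 1L
          }
        }
      }
      n_priv <- rpois(1, cfg$private_mutation_rate)
      if (n_priv > 0) {
        pp <- sample(free_pos, n_priv)
        for (p in pp) s[p] <- sample(setdiff(bases4, s[p]), 1)
      }
      if (runif(1) < cfg$heteroplasmy_rate) {
        p <- sample(free_pos, 1)
        other <- sample(setdiff(bases4, s[p]), 1)
        two <- sort(c(s[p], other))
        code <- names(iupac2)[vapply(iupac2, function(x)
          identical(sort(x), two), logical(1))]
        s[p] <- code
        het_log[[length(het_log) + 1L]] <-
          tibble(sample_id = id, position = p, bases = paste(two, collapse = "/"))
      }
      if (runif(1) < cfg$homopolymer_indel_rate) {
        p <- sample(tract, 1)
        s[p] <- "-"
        indel_log[[length(indel_log) + 1L]] <-
          tibble(sample_id = id, position = p)
      }
      samples[[idx]] <- tibble(sample_id = id, group = g,
                               bases = paste(s, collapse = ""))
      truth_hg[[idx]] <- tibble(sample_id = id, group = g, haplogroup = hg)
    }
  }

  truth <- list(
    haplogroups = bind_rows(truth_hg),
    planted = if (nrow(planted)) {
      bind_cols(planted,
                as_tibble(planted_counts) %>%
                  rlang::set_names(paste0("n_carriers_", groups)))
    } else planted,
    heteroplasmies = if (length(het_log)) bind_rows(het_log) else
      tibble(sample_id = character(), position = integer(), bases = character()),
    homopolymer_indels = if (length(indel_log)) bind_rows(indel_log) else
      tibble(sample_id = character(), position = integer()),
    tract = c(start = tract[1], end = tract[length(tract)]),
    seed = cfg$seed
  )

  list(reference = paste(ref, collapse = ""),
       sequences = bind_rows(samples),
       haplogroup_defs = defs,
       truth = truth,
       cfg = cfg)
}

#' Write a synthetic cohort to disk
#'
#' Emits `reference.fasta`, `cohort.fasta`, `cohort.vcf` (all non-reference
#' consensus calls, per-sample GT/AF), `metadata.tsv`, `haplogroups.tsv`
#' (the simulated definition tree) and `truth.json` into `outdir`. Files
#' are plain text and byte-stable for a fixed config.
#'
#' @param cohort Result of [generate_cohort()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named vector of file paths.
#' @export
write_cohort_files <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    reference = file.path(outdir, "reference.fasta"),
    fasta = file.path(outdir, "cohort.fasta"),
    vcf = file.path(outdir, "cohort.vcf"),
    metadata = file.path(outdir, "metadata.tsv"),
    haplogroups = file.path(outdir, "haplogroups.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  writeLines(c(">reference", cohort$reference), paths["reference"])
  writeLines(as.vector(rbind(paste0(">", cohort$sequences$sample_id),
                             cohort$sequences$bases)), paths["fasta"])
  readr::write_tsv(cohort$sequences[, c("sample_id", "group")],
                   paths["metadata"], progress = FALSE)
  defs_flat <- cohort$haplogroup_defs %>%
    mutate(parent = ifelse(is.na(.data$parent), "", .data$parent),
           variants = purrr::map_chr(.data$variants, paste, collapse = ","))
  readr::write_tsv(defs_flat, paths["haplogroups"], progress = FALSE)
  write_cohort_vcf(cohort, paths["vcf"])
  truth <- cohort$truth
  truth$tract <- as.list(truth$tract)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(paths)
}

# minimal VCF v4.2 writer for consensus-level calls
write_cohort_vcf <- function(cohort, path) {
  calls <- calls_from_alignment(cohort$sequences, cohort$reference)
  samples <- cohort$sequences$sample_id
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chrM,length=%d>", nchar(cohort$reference)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AF,Number=1,Type=Float,Description="Alt allele fraction">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  snps <- calls[calls$kind == "SNP", , drop = FALSE]
  body <- character(0)
  if (nrow(snps)) {
    keys <- unique(snps[, c("position", "ref_allele", "alt_allele")])
    keys <- keys[order(keys$position, keys$alt_allele), ]
    body <- vapply(seq_len(nrow(keys)), function(i) {
      k <- keys[i, ]
      carriers <- snps[snps$position == k$position &
                         snps$alt_allele == k$alt_allele, ]
      gt <- vapply(samples, function(s) {
        row <- carriers[carriers$sample_id == s, ]
        if (nrow(row) == 0) "0:."
        else if (row$heteroplasmic[1]) "0/1:0.5"
        else "1:1"
      }, character(1))
      paste(c("chrM", k$position, ".", k$ref_allele, k$alt_allele, ".",
              "PASS", ".", "GT:AF", gt), collapse = "\t")
    }, character(1))
  }
  writeLines(c(header, body), path)
}
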