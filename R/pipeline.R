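#' Read a pipeline configuration file
#'
#' YAML with keys: `inputs` (paths: `reference`, `fasta` and/or `vcf`,
#' `metadata`, and optionally `haplogroup_defs`, `lineage_map`,
#' `gene_model`, `code_table`, `usage_table`), `cohort` (arguments to
#' [cohort_config()]), `scan_rule`, `n_permutations`, `seed`, `out_dir`.
#' Relative input paths are resolved against the config file's directory.
#'
#' @param path Path to the YAML config.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  cfg$inputs <- lapply(cfg$inputs, function(p) {
    if (is.character(p) && !file.exists(p) && file.exists(file.path(base, p)))
      file.path(base, p) else p
  })
  cfg
}

#' Run the whole case-control scan pipeline
#'
#' Stages, in order: ingest (FASTA primary; when both FASTA and VCF are
#' given the FASTA wins with a warning) -> per-site allele counts ->
#' haplogroup calls -> simplified-lineage chi-square -> haplogroup FST and
#' pairwise-distance PhiST with permutation nulls -> delta scan ->
#' contingency test and odds ratio per flagged outlier -> codon annotation
#' of outlier SNPs -> report files. Optional stages whose inputs are
#' missing are skipped with a warning; every completed stage's tables are
#' written even if a later stage fails.
#'
#' @param config A config list (see [read_pipeline_config()]) or a path to
#'   a YAML file.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, a list of class `mitoscan_report` holding every
#'   stage's result plus `errors` (named list of stage failures, empty on
#'   full success).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  inp <- config$inputs
  out_dir <- out_dir %||% config$out_dir %||% "mitoscan_out"
  seed <- config$seed %||% 1L
  nperm <- config$n_permutations %||% 1000L
  rule <- config$scan_rule %||% "three_sd_about_zero"
  ccfg <- as_cohort_config(config$cohort)
  res <- list(seed = seed, errors = list())

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      warn(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
      res$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  # ingest
  reference <- read_reference_fasta(inp$reference)
  metadata <- read_sample_metadata(inp$metadata)
  if (!is.null(inp$fasta) && !is.null(inp$vcf)) {
    warn("Both FASTA and VCF supplied; FASTA wins, VCF ignored.")
  }
  if (!is.null(inp$fasta)) {
    seqs <- read_aligned_fasta(inp$fasta, metadata)
  } else if (!is.null(inp$vcf)) {
    calls_in <- read_vcf_variants(inp$vcf, nchar(reference))
    calls_in <- mask_homopolymer_indels(calls_in, reference, ccfg)
    seqs <- sequences_from_calls(calls_in, metadata, reference)
  } else {
    abort("Config must provide `fasta` or `vcf` input.")
  }
  res$sequences <- seqs

  res$counts <- run_stage("site_counts",
                          build_site_counts(seqs, reference, ccfg))
  res$calls <- run_stage("calls", {
    calls <- calls_from_alignment(seqs, reference)
    mask_homopolymer_indels(calls, reference, ccfg)
  })

  if (!is.null(inp$haplogroup_defs)) {
    res$haplogroup_calls <- run_stage("haplogroup_classify", {
      defs <- read_haplogroup_defs(inp$haplogroup_defs)
      classify_haplogroups(res$calls, defs, sample_ids = seqs$sample_id)
    })
    if (!is.null(res$haplogroup_calls)) {
      hg_tab <- res$haplogroup_calls %>%
        left_join(metadata, by = "sample_id") %>%
        count(.data$group, .data$haplogroup, name = "n")
      res$haplogroup_fst <- run_stage("haplogroup_fst",
        haplogroup_fst(hg_tab, n_permutations = nperm, seed = seed))
      if (!is.null(inp$lineage_map)) {
        res$lineage_test <- run_stage("lineage_chi_square", {
          lmap <- read_lineage_map(inp$lineage_map)
          lin <- res$haplogroup_calls %>%
            left_join(metadata, by = "sample_id") %>%
            mutate(lineage = simplify_lineage(.data$haplogroup, lmap)) %>%
            count(.data$lineage, .data$group, name = "n")
          lineage_chi_square(lin)
        })
      } else {
        inform("No lineage map supplied; lineage test skipped.")
      }
    }
  } else {
    inform("No haplogroup definitions supplied; haplogroup stages skipped.")
  }

  res$phi_st <- run_stage("phi_st", {
    dm <- pairwise_differences(seqs)
    res$distance_matrix <- dm
    res$nj_newick <- nj_tree_newick(dm)
    phi_st(dm, metadata, n_permutations = nperm, seed = seed)
  })

  res$scan <- run_stage("delta_scan",
                        delta_scan(res$counts, rule = rule, cfg = ccfg))
  if (!is.null(res$scan)) {
    outliers <- tidy(res$scan, outliers_only = TRUE)
    res$association <- run_stage("association", {
      if (nrow(outliers)) site_association(res$counts, outliers$position)
      else NULL
    })
    if (!is.null(inp$gene_model) && nrow(outliers)) {
      res$annotation <- run_stage("annotation", {
        gm <- read_gene_model(inp$gene_model, nchar(reference))
        code <- read_genetic_code(inp$code_table)
        usage <- if (!is.null(inp$usage_table))
          read_codon_usage(inp$usage_table) else NULL
        ref_chars <- chars(reference)
        vars <- outliers %>%
          mutate(ref_allele = ref_chars[.data$position]) %>%
          left_join(
            res$calls %>%
              filter(.data$kind == "SNP") %>%
              count(.data$position, .data$alt_allele) %>%
              group_by(.data$position) %>%
              slice_max(.data$n, n = 1, with_ties = FALSE) %>%
              ungroup() %>%
              select("position", "alt_allele"),
            by = "position"
          ) %>%
          filter(!is.na(.data$alt_allele),
                 .data$alt_allele != .data$ref_allele)
        annotate_variants(vars, gm, reference, code, usage)
      })
    } else if (is.null(inp$gene_model)) {
      warn("No gene model supplied; annotation stage skipped.")
    }
  }

  res$metadata <- metadata
  class(res) <- "mitoscan_report"
  write_report(res, out_dir)
  invisible(res)
}

#' Write pipeline report files
#'
#' One TSV per completed stage plus `summary.txt` with the headline shape:
#' polymorphic-site and outlier counts, the top outlier with its odds ratio
#' and interval, haplogroup count, and the differentiation estimates with
#' permutation p-values. The seed is echoed in every header.
#'
#' @param res A `mitoscan_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(x, name) {
    if (is.null(x)) return()
    p <- file.path(out_dir, name)
    readr::write_tsv(as_tibble(x), p, progress = FALSE)
    paths <<- c(paths, p)
  }
  put(res$counts, "site_counts.tsv")
  if (!is.null(res$scan)) put(tidy(res$scan), "delta_scan.tsv")
  put(res$association, "association.tsv")
  put(res$haplogroup_calls, "haplogroup_calls.tsv")
  if (!is.null(res$haplogroup_fst)) put(tidy(res$haplogroup_fst),
                                        "haplogroup_fst.tsv")
  if (!is.null(res$phi_st)) put(tidy(res$phi_st), "phi_st.tsv")
  put(res$lineage_test, "lineage_test.tsv")
  put(res$annotation, "annotation.tsv")
  if (!is.null(res$nj_newick)) {
    writeLines(res$nj_newick, file.path(out_dir, "nj_tree.nwk"))
    paths <- c(paths, file.path(out_dir, "nj_tree.nwk"))
  }

  lines <- c(sprintf("# mitoscan summary (seed %s)", res$seed))
  if (!is.null(res$scan)) {
    g <- glance(res$scan)
    lines <- c(lines, sprintf(
      "polymorphic sites: %d | outliers (%s): %d | sd(delta)=%.6f threshold=%.6f",
      g$n_polymorphic, g$rule, g$n_outliers, g$sd_delta, g$threshold))
    top <- tidy(res$scan, outliers_only = TRUE)
    if (nrow(top)) {
      t1 <- top[1, ]
      line <- sprintf("top outlier: position %d delta=%.4f", t1$position,
                      t1$delta)
      if (!is.null(res$association)) {
        a <- res$association[res$association$position == t1$position, ]
        if (nrow(a)) {
          line <- paste0(line, sprintf(
            " | %s P=%.4g OR=%.3f 95%%CI %.3f-%.3f", a$test[1], a$p_value[1],
            a$odds_ratio[1], a$ci_low[1], a$ci_high[1]))
        }
      }
      lines <- c(lines, line)
    } else {
      lines <- c(lines, "top outlier: none (0 outliers)")
    }
  }
  if (!is.null(res$haplogroup_calls)) {
    lines <- c(lines, sprintf("haplogroups observed: %d",
                              length(unique(res$haplogroup_calls$haplogroup))))
  }
  if (!is.null(res$haplogroup_fst)) {
    lines <- c(lines, sprintf("haplogroup FST = %.4f (perm p = %.4f, %d perms)",
                              res$haplogroup_fst$estimate,
                              res$haplogroup_fst$p_value,
                              res$haplogroup_fst$n_permutations))
  }
  if (!is.null(res$phi_st)) {
    lines <- c(lines, sprintf("PhiST = %.4f (perm p = %.4f, %d perms)",
                              res$phi_st$estimate, res$phi_st$p_value,
                              res$phi_st$n_permutations))
  }
  if (!is.null(res$lineage_test)) {
    lines <- c(lines, sprintf("lineage chi-square: X2=%.4f df=%d p=%.4f",
                              res$lineage_test$statistic,
                              res$lineage_test$df, res$lineage_test$p_value))
  }
  if (length(res$errors)) {
    lines <- c(lines, paste0("FAILED stage ", names(res$errors), ": ",
                             unlist(res$errors)))
  }
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(c(paths, file.path(out_dir, "summary.txt")))
}

#' @method print mitoscan_report
#' @export
print.mitoscan_report <- function(x, ...) {
  cat("<mitoscan_report>\n")
  cat(sprintf("  samples: %d in %d group(s)\n", nrow(x$sequences),
              length(unique(x$sequences$group))))
  if (!is.null(x$scan)) {
    g <- glance(x$scan)
    cat(sprintf("  delta scan: %d polymorphic, %d outlier(s)\n",
                g$n_polymorphic, g$n_outliers))
  }
  if (length(x$errors)) {
    cat("  failed stages:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
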