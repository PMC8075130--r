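#' Read a haplogroup definition table
#'
#' Tab-separated file with header `name<TAB>parent<TAB>variants`; `parent`
#' empty (or `.`) for the root, `variants` a comma-separated list of
#' `<pos><allele>` tokens (e.g. `3594T,10398G`) carried on the edge from the
#' parent. Defining variants are cumulative from root to node.
#'
#' @param path File path.
#' @return A tibble `name`, `parent` (NA at root), `variants` (list column
#'   of character vectors).
#' @export
read_haplogroup_defs <- function(path) {
  raw <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  if (!all(c("name", "parent", "variants") %in% names(raw))) {
    abort("Definition table needs columns name, parent, variants.")
  }
  defs <- raw %>%
    mutate(
      parent = ifelse(.data$parent %in% c("", "."), NA_character_,
                      .data$parent),
      variants = purrr::map(.data$variants, function(v) {
        if (is.na(v) || v == "") character(0)
        else strsplit(v, ",", fixed = TRUE)[[1]]
      })
    )
  validate_hg_tree(defs)
  defs
}

validate_hg_tree <- function(defs) {
  if (anyDuplicated(defs$name)) abort("Duplicate haplogroup names.")
  roots <- which(is.na(defs$parent))
  if (length(roots) != 1) abort("Tree must have exactly one root.")
  unknown <- setdiff(stats::na.omit(defs$parent), defs$name)
  if (length(unknown)) {
    abort(sprintf("Unknown parent(s): %s", paste(unknown, collapse = ", ")))
  }
  invisible(defs)
}

# cumulative defining variants along the root -> node path
hg_path_variants <- function(defs, name) {
  vars <- character(0)
  node <- name
  seen <- character(0)
  while (!is.na(node)) {
    if (node %in% seen) abort("Cycle in haplogroup tree.")
    seen <- c(seen, node)
    i <- match(node, defs$name)
    if (is.na(i)) abort(sprintf("Haplogroup '%s' not in tree.", node))
    vars <- c(defs$variants[[i]], vars)
    node <- defs$parent[i]
  }
  unique(vars)
}

#' Score a sample's variants against one haplogroup
#'
#' `expected` is the number of defining variants accumulated from the root
#' to the node; `matched` the overlap with the sample's variant set;
#' `score = matched / expected` (the root, with no defining variants,
#' scores 1 by convention).
#'
#' @param sample_variants Character vector of `<pos><allele>` tokens, e.g.
#'   `c("3594T", "11914A")`.
#' @param name Haplogroup name.
#' @param defs Definition tibble from [read_haplogroup_defs()].
#' @return One-row tibble: `haplogroup`, `matched`, `expected`, `score`.
#' @export
score_against_definition <- function(sample_variants, name, defs) {
  path <- hg_path_variants(defs, name)
  expected <- length(path)
  matched <- length(intersect(sample_variants, path))
  tibble(haplogroup = name, matched = matched, expected = expected,
         score = if (expected == 0) 1 else matched / expected)
}

#' Classify samples into haplogroups
#'
#' Each sample's variant set is scored against every node of the definition
#' tree; the best node maximizes the match fraction, with ties broken by
#' larger `expected` (deeper, more specific node) and then alphabetically.
#' Samples with empty variant sets are assigned the root with a warning.
#'
#' @param calls Tibble of variant calls (SNPs are used; masked calls and
#'   indels are ignored), or a named list sample_id -> token vector.
#' @param defs Definition tibble from [read_haplogroup_defs()].
#' @param sample_ids Samples to classify; defaults to those present in
#'   `calls` (pass explicitly to include call-free samples).
#' @return A tibble: `sample_id`, `haplogroup`, `score`, `matched`,
#'   `expected`, `private_variants` (variants off the winning path).
#' @export
classify_haplogroups <- function(calls, defs, sample_ids = NULL) {
  validate_hg_tree(defs)
  var_sets <- if (is.data.frame(calls)) {
    snp <- calls[calls$kind == "SNP" & !calls$masked, , drop = FALSE]
    split(paste0(snp$position, snp$alt_allele), snp$sample_id)
  } else calls
  if (is.null(sample_ids)) sample_ids <- names(var_sets)
  root <- defs$name[is.na(defs$parent)]
  paths <- setNames(lapply(defs$name, hg_path_variants, defs = defs),
                    defs$name)
  expected <- lengths(paths)
  purrr::map(sample_ids, function(id) {
    sv <- var_sets[[id]] %||% character(0)
    if (length(sv) == 0) {
      warn(sprintf("Sample '%s' has no variants; assigned root.", id))
      return(tibble(sample_id = id, haplogroup = root, score = 1,
                    matched = 0L, expected = 0L, private_variants = 0L))
    }
    matched <- vapply(paths, function(p) length(intersect(sv, p)), integer(1))
    score <- ifelse(expected == 0, 1, matched / pmax(expected, 1))
    ord <- order(-score, -expected, defs$name)
    best <- ord[1]
    tibble(
      sample_id = id,
      haplogroup = defs$name[best],
      score = unname(score[best]),
      matched = unname(matched[best]),
      expected = as.integer(unname(expected[best])),
      private_variants = length(setdiff(sv, paths[[best]]))
    )
  }) %>% bind_rows()
}

#' Collapse haplogroup names to simplified macro-lineages
#'
#' Longest-matching-prefix lookup against an ordered prefix table (e.g.
#' `L0, L1, L2, L3, M, N, R, H, ...`): `"L3e2b"` maps to `L3`, `"H1a"` to
#' `H`. Names matching no prefix map to `"OTHER"` with a warning.
#'
#' @param haplogroups Character vector of haplogroup names.
#' @param lineage_map Tibble with columns `prefix`, `lineage` (see the
#'   fixture `lineage_map.tsv` under `inst/extdata`).
#' @return Character vector of macro-lineage labels.
#' @export
#' @examples
#' lm <- tibble::tibble(prefix = c("L0", "L3", "H"),
#'                      lineage = c("L0", "L3", "H"))
#' simplify_lineage(c("L3e2b", "H1a"), lm)
simplify_lineage <- function(haplogroups, lineage_map) {
  if (any(!nzchar(haplogroups)) || anyNA(haplogroups)) {
    abort("Empty haplogroup name.")
  }
  pref <- lineage_map$prefix[order(-nchar(lineage_map$prefix))]
  lin <- lineage_map$lineage[order(-nchar(lineage_map$prefix))]
  out <- vapply(haplogroups, function(h) {
    hit <- which(startsWith(h, pref))
    if (length(hit)) lin[hit[1]] else NA_character_
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(out)) {
    warn(sprintf("%d haplogroup name(s) matched no prefix; mapped to OTHER.",
                 sum(is.na(out))))
    out[is.na(out)] <- "OTHER"
  }
  out
}

#' Read a lineage prefix map
#'
#' @param path TSV with header `prefix<TAB>lineage`.
#' @return Tibble `prefix`, `lineage`.
#' @export
read_lineage_map <- function(path) {
  m <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("prefix", "lineage") %in% names(m))) {
    abort("Lineage map needs columns prefix, lineage.")
  }
  m
}
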