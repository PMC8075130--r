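#' Cohort processing configuration
#'
#' Bundles the filtering and counting rules applied when turning aligned
#' consensus sequences (or variant calls) into the per-site allele-count
#' table that the delta scan consumes.
#'
#' @param heteroplasmy_min_ratio Minimum minor:major nucleotide ratio for a
#'   two-allele position within one individual to be accepted as a
#'   heteroplasmy rather than noise. Default `0.25`, i.e. a 1:4 ratio.
#' @param homopolymer_min_run Minimum length of a single-base reference run
#'   for the homopolymer rule to fire: insertions/deletions anchored inside
#'   such a run are masked (treated as having no effect). Default `5`.
#' @param heteroplasmy_policy How a heteroplasmic sample-site enters the
#'   allele counts: `"exclude_site_sample"` (default) drops that sample at
#'   that site; `"count_major"` resolves the ambiguity code to whichever of
#'   its two bases is more frequent among unambiguous samples at the site;
#'   `"iupac"` credits half a count to each of the two bases.
#' @param multiallelic_delta Definition of delta at sites with more than two
#'   alleles: `"total_variation"` (default), half the L1 distance between the
#'   two groups' allele-frequency vectors, or `"max_nonmajor"`, the largest
#'   per-allele frequency difference over non-major alleles. Both reduce to
#'   `|p1 - p2|` at biallelic sites.
#'
#' @return A list with class `"cohort_config"`.
#' @export
#' @examples
#' cohort_config()
#' cohort_config(heteroplasmy_policy = "iupac")
cohort_config <- function(heteroplasmy_min_ratio = 0.25,
                          homopolymer_min_run = 5L,
                          heteroplasmy_policy = c("exclude_site_sample",
                                                  "count_major", "iupac"),
                          multiallelic_delta = c("total_variation",
                                                 "max_nonmajor")) {
  heteroplasmy_policy <- match.arg(heteroplasmy_policy)
  multiallelic_delta <- match.arg(multiallelic_delta)
  if (!is.numeric(heteroplasmy_min_ratio) ||
      heteroplasmy_min_ratio <= 0 || heteroplasmy_min_ratio > 1) {
    abort("`heteroplasmy_min_ratio` must be in (0, 1].")
  }
  if (homopolymer_min_run < 2) {
    abort("`homopolymer_min_run` must be >= 2.")
  }
  structure(
    list(
      heteroplasmy_min_ratio = heteroplasmy_min_ratio,
      homopolymer_min_run = as.integer(homopolymer_min_run),
      heteroplasmy_policy = heteroplasmy_policy,
      multiallelic_delta = multiallelic_delta
    ),
    class = "cohort_config"
  )
}

as_cohort_config <- function(cfg) {
  if (is.null(cfg)) return(cohort_config())
  if (inherits(cfg, "cohort_config")) return(cfg)
  do.call(cohort_config, cfg)
}
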