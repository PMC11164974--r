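#' Estimate fold coverage from total sequenced bases
#'
#' @param total_bases numeric, bp sequenced (vectorized).
#' @param genome_size genome assembly size in bp (default 2.9e9).
#' @return total_bases / genome_size.
#' @export
#' @examples
#' estimate_fold_coverage(11.6e9)  # 4x
estimate_fold_coverage <- function(total_bases, genome_size = 2.9e9) {
  if (any(genome_size <= 0)) stop("genome_size must be positive")
  if (any(total_bases < 0)) stop("total_bases must be non-negative")
  total_bases / genome_size
}

#' Sex assignment from SRY read counts and coverage
#'
#' Classifies samples by the rule used for WGS cohorts with unknown sex:
#' a sample is called `male` when strictly more than `read_threshold` reads
#' match the SRY coding region (at >= 95 percent identity, counted upstream)
#' AND its fold coverage is at least `coverage_threshold`. Samples below the
#' coverage threshold are `insufficient-coverage` regardless of count; the
#' remainder are `not-male`.
#'
#' @param sry_read_count non-negative integer vector.
#' @param fold_coverage non-negative numeric vector.
#' @param read_threshold strict lower bound on the male read count (default 13).
#' @param coverage_threshold minimum usable fold coverage (default 4).
#' @return character vector in
#'   `c("male", "not-male", "insufficient-coverage")`.
#' @export
#' @examples
#' assign_sex(c(20, 13, 50), c(5, 10, 2))
assign_sex <- function(sry_read_count, fold_coverage,
                       read_threshold = 13, coverage_threshold = 4) {
  if (any(sry_read_count < 0) || any(fold_coverage < 0))
    stop("counts and coverage must be non-negative")
  n <- max(length(sry_read_count), length(fold_coverage))
  sry_read_count <- rep_len(sry_read_count, n)
  fold_coverage <- rep_len(fold_coverage, n)
  ifelse(fold_coverage < coverage_threshold, "insufficient-coverage",
         ifelse(sry_read_count > read_threshold, "male", "not-male"))
}

#' Run sex assignment over a sample table
#'
#' @param tab data.frame with columns `sample`, `sry_read_count`,
#'   `total_bases`.
#' @param config a [pipeline_config()] (supplies thresholds and genome size).
#' @return the table with `fold_coverage` and `call` columns appended.
#' @export
sex_assignment_table <- function(tab, config = pipeline_config()) {
  stopifnot(all(c("sample", "sry_read_count", "total_bases") %in% names(tab)))
  tab$fold_coverage <- estimate_fold_coverage(tab$total_bases, config$genome_size)
  tab$call <- assign_sex(tab$sry_read_count, tab$fold_coverage,
                         config$sry_read_threshold, config$coverage_threshold)
  tab
}
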