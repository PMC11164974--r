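#' Pipeline configuration
#'
#' Collects every tunable constant of the MSY pipeline in one list, with
#' defaults matching the published workflow the package implements:
#' candidate-contig regression cutoff, 50-bp windowing, window-model
#' probability cutoff, scY/mcY boundary, variant-filter conflict limits and
#' per-depth-group coverage ranges, sexing thresholds, and the molecular-clock
#' calibration constants.
#'
#' @param ... named overrides for any default listed below.
#'
#' @return A list of class `msy_config`. Fields:
#' \describe{
#'   \item{residual_cutoff}{raw-residual cutoff flagging Y-candidate contigs
#'     in the female-on-male coverage regression (default -35, percent scale).}
#'   \item{window_size}{classification window, bp (default 50).}
#'   \item{min_contig_length}{contig length floor, bp (default 300).}
#'   \item{autosomal_min_pct}{minimum percent covered in both sexes for a
#'     contig to count as autosomal (default 75).}
#'   \item{autosomal_ratio_tol}{maximum |male:female mean-coverage ratio - 1|
#'     for autosomal contigs (default 0.01).}
#'   \item{p_msy_cutoff}{windows with P(MSY) above this are MSY (default 0.5).}
#'   \item{mcy_bound}{mean normalized male depth separating scY from mcY
#'     (default 0.75, midpoint of the haploid and diploid expectations).}
#'   \item{sigma_m, sigma_f}{Gaussian spread of normalized depth in the window
#'     model, male and female (default 0.15 each).}
#'   \item{max_copies}{largest mcY copy number in the MSY mixture (default 10).}
#'   \item{discard_fraction}{contigs with more than this fraction of nonY
#'     window bp are dropped from the assembly (default 0.5).}
#'   \item{end_trim}{bp masked at each contig end for variant work (default 50).}
#'   \item{conflict_max_ascertainment, conflict_max_genotyping}{maximum
#'     samples showing both alleles before a site is dropped (2 and 5).}
#'   \item{ascertainment_ranges, genotyping_ranges}{per depth-group allowed
#'     coverage, as a named list of c(lo, hi).}
#'   \item{sry_read_threshold}{reads matching the SRY coding region above
#'     which a sample can be called male (default 13, strict >).}
#'   \item{coverage_threshold}{minimum fold coverage for a usable sample
#'     (default 4).}
#'   \item{genome_size}{genome size for fold-coverage estimation, bp
#'     (default 2.9e9).}
#'   \item{calibration_age}{calibration-node age, years (default 11000).}
#'   \item{generation_time}{years per generation (default 6; bounds 4 and 8).}
#'   \item{generation_time_bounds}{c(lower, upper) generation times.}
#'   \item{scan_length}{bp scanned for mutation counting (default 1234870:
#'     scY minus 50-bp contig end trims).}
#'   \item{theta_length}{bp for Watterson's theta (default 1360096, total scY).}
#'   \item{boot_reps}{bootstrap replicates for dating intervals (default 1000).}
#'   \item{seed}{base random seed (default 1).}
#' }
#' @export
#' @examples
#' cfg <- pipeline_config(seed = 42, boot_reps = 200)
#' cfg$scan_length
pipeline_config <- function(...) {
  cfg <- list(
    residual_cutoff      = -35,
    window_size          = 50L,
    min_contig_length    = 300L,
    autosomal_min_pct    = 75,
    autosomal_ratio_tol  = 0.01,
    p_msy_cutoff         = 0.5,
    mcy_bound            = 0.75,
    sigma_m              = 0.15,
    sigma_f              = 0.15,
    max_copies           = 10L,
    discard_fraction     = 0.5,
    end_trim             = 50L,
    conflict_max_ascertainment = 2L,
    conflict_max_genotyping    = 5L,
    ascertainment_ranges = list(vLowDP = c(1.5, 2.5),
                                LowDP  = c(3, 7),
                                ModDP  = c(10, 30)),
    genotyping_ranges    = list(vLowDP = c(2, 8),
                                LowDP  = c(3, 10),
                                ModDP  = c(8, 30)),
    sry_read_threshold   = 13L,
    coverage_threshold   = 4,
    genome_size          = 2.9e9,
    calibration_age      = 11000,
    generation_time      = 6,
    generation_time_bounds = c(4, 8),
    scan_length          = 1234870,
    theta_length         = 1360096,
    boot_reps            = 1000L,
    seed                 = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  stopifnot(cfg$window_size > 0, cfg$genome_size > 0,
            cfg$calibration_age > 0, cfg$generation_time > 0,
            cfg$scan_length > 0, cfg$theta_length > 0)
  class(cfg) <- "msy_config"
  cfg
}

#' @export
print.msy_config <- function(x, ...) {
  cat("MSY pipeline configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.list(v)) v <- paste(names(v), vapply(v, function(r) paste(r, collapse = "-"), ""), collapse = "; ")
    cat(sprintf("  %-28s %s\n", nm, paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
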