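#' A small dated example tree with the structure of a two-clade Y phylogeny
#'
#' A fixed 16-tip topology (plus optional outgroup) with branch lengths in
#' years: a 40,000-year root splitting a "NA-like" clade (deepest split
#' 20,900 y) from an "EB-like" clade whose deepest split (25,000 y) isolates
#' a two-tip island pair, an expansion polytomy at 13,900 y, a four-tip
#' calibration clade labeled `CP` at 11,000 y and a four-tip young clade at
#' 6,000 y. Useful as the default substrate for clock-dating simulations.
#'
#' @param include_outgroup attach an outgroup tip `out` on a long basal
#'   branch.
#' @param outgroup_branch outgroup branch length in years.
#' @return an [ape::phylo] with labeled internal nodes.
#' @export
example_dated_tree <- function(include_outgroup = FALSE,
                               outgroup_branch = 2e5) {
  eb <- paste0("((sv1:4200,nz1:4200)SVNZ:20800,",
               "((cp1:11000,cp2:11000,cp3:11000,cp4:11000)CP:2900,",
               "(df1:6000,df2:6000,df3:6000,df4:6000)DF1:7900,",
               "e1:13900,e2:13900)EXP:11100)EB:15000")
  na <- paste0("((na1:8500,na2:8500)NAB1:12400,",
               "(na3:8500,na4:8500)NAB2:12400)NAC:19100")
  core <- sprintf("(%s,%s)ROOT", eb, na)
  nwk <- if (include_outgroup)
    sprintf("(%s:%d,out:%d)TOP;", core, 0L, as.integer(outgroup_branch))
  else paste0(core, ";")
  ape::read.tree(text = nwk)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-data pipeline
#'
#' Executes the stages of the MSY workflow in dependency order on simulated
#' inputs: molecular sexing, Y-candidate contig discovery, window
#' classification, the variant filter cascade, parsimony tree building with
#' variant placement and imputation, haplotype collapsing and haplogroup
#' naming, strict-clock dating, and group-wise diversity. Every stage's
#' output table is written to `out_dir` together with a JSON manifest
#' recording configuration, seeds and per-stage record counts.
#'
#' @param config a [pipeline_config()]; `config$seed` drives every random
#'   draw, so reruns with the same config are identical.
#' @param out_dir output directory (created if needed).
#' @param coverage_params optional [coverage_sim_params()] override.
#' @param tree_params optional [tree_sim_params()] override; the default
#'   evolves SNPs down [example_dated_tree()] with an outgroup.
#' @param groups optional data.frame sample/group for the diversity stage;
#'   defaults to one group per basal clade of the example tree.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         coverage_params = NULL, tree_params = NULL,
                         groups = NULL) {
  if (missing(out_dir)) stop("out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  # -- stage 1: sexing -------------------------------------------------------
  if (is.null(coverage_params))
    coverage_params <- coverage_sim_params(seed = config$seed)
  n <- coverage_params$n_males + coverage_params$n_females
  sry <- simulate_sry_counts(n, rep(c("male", "female"),
                                    c(coverage_params$n_males,
                                      coverage_params$n_females)),
                             depth_range = c(4, 30),
                             genome_size = config$genome_size,
                             seed = config$seed + 1L)
  sexed <- sex_assignment_table(sry, config)
  write_tsv(sexed, file.path(out_dir, "sex_assignment.tsv"))
  counts$sexing <- c(n = nrow(sexed), male = sum(sexed$call == "male"))

  # -- stage 2: MSY discovery ------------------------------------------------
  sim <- simulate_coverage_dataset(coverage_params)
  summ <- contig_coverage_summary(sim$windows, sim$samples)
  cand <- classify_candidate_contigs(summ, config$residual_cutoff)
  autos <- select_autosomal_contigs(cand, config$autosomal_min_pct,
                                    config$autosomal_ratio_tol)
  ycand <- cand$contig[cand$candidate]
  if (!length(ycand)) stop("stage msy_discovery: no Y-candidate contig found")
  norm <- compute_normalization(sim$windows, sim$samples, autos, ycand)
  cls <- classify_windows(sim$windows[sim$windows$contig %in% ycand, ],
                          sim$samples, norm, config)
  contigs <- summarize_contigs(cls, config$discard_fraction)
  write_tsv(cand, file.path(out_dir, "contig_candidates.tsv"))
  write_tsv(cls, file.path(out_dir, "window_classes.bed"))
  write_tsv(contigs$contigs, file.path(out_dir, "contig_summary.tsv"))
  counts$msy_discovery <- c(contigs = nrow(summ), candidates = length(ycand),
                            autosomal = length(autos),
                            scY_bp = unname(contigs$totals["scY_bp"]))

  # -- stage 3: variant filters ---------------------------------------------
  if (is.null(tree_params))
    tree_params <- tree_sim_params(tree = example_dated_tree(TRUE),
                                   missing_rate = 0.02, conflict_rate = 0.01,
                                   seed = config$seed + 2L)
  snp <- simulate_tree_snps(tree_params)
  vt <- variant_table_from_sim(snp)
  L <- tree_params$L
  scan_windows <- data.frame(contig = "scY",
                             start = seq(0, L - 1, by = config$window_size))
  scan_windows$end <- pmin(scan_windows$start + config$window_size, L)
  scan_windows$class <- "scY"
  vt <- filter_variant_kind(vt)
  vt <- filter_by_region(vt, scan_windows, c(scY = L), config$end_trim)
  dgroups <- stats::setNames(rep("LowDP", nrow(vt$gt)), rownames(vt$gt))
  vt <- genotyped_set_filter(vt, dgroups, config$genotyping_ranges,
                             config$conflict_max_genotyping)
  write_variant_vcf(vt, file.path(out_dir, "filtered_variants.vcf"))
  counts$variant_filters <- c(input = nrow(snp$sites), surviving = n_sites(vt),
                              removed = nrow(snp$sites) - n_sites(vt))

  # -- stage 4: phylogeny ----------------------------------------------------
  outg <- if ("out" %in% rownames(vt$gt)) "out" else NULL
  tree <- build_parsimony_tree(vt, outgroup = outg)
  placement <- place_variants(vt, tree)
  imp <- impute_missing(vt, tree, placement)
  ht <- collapse_haplotypes(imp$gt[tree$ingroup, , drop = FALSE])
  hg <- assign_haplogroups(tree, scheme = list(prefix = "Y",
                                               basal = c("EB", "NA")))
  ape::write.tree(tree$phylo, file.path(out_dir, "haplotype_tree.nwk"))
  write_tsv(placement, file.path(out_dir, "variant_placement.tsv"))
  write_tsv(ht, file.path(out_dir, "haplotypes.tsv"))
  write_tsv(data.frame(node = names(hg), haplogroup = hg),
            file.path(out_dir, "haplogroups.tsv"))
  counts$phylogeny <- c(samples = length(tree$ingroup), haplotypes = nrow(ht),
                        placed = sum(!is.na(placement$branch)),
                        recurrent = sum(placement$label == "recurrent"),
                        unplaceable = sum(placement$label == "no-derived-call"),
                        score = tree$score)

  # -- stage 5: dating -------------------------------------------------------
  cal_node <- find_calibration_node(tree, tips_below = c("cp1", "cp2", "cp3", "cp4"))
  dates <- date_nodes(tree, cal_node,
                      calibration_age = config$calibration_age,
                      L_scan = tree_params$L, g = config$generation_time,
                      boot_reps = config$boot_reps, seed = config$seed + 3L)
  write_tsv(dates$nodes, file.path(out_dir, "node_dates.tsv"))
  counts$dating <- c(mu_year = dates$calibration$mu_year,
                     root_age = max(dates$nodes$age))

  # -- stage 6: diversity ----------------------------------------------------
  if (is.null(groups)) {
    tips <- tree$ingroup
    groups <- data.frame(sample = tips,
                         group = ifelse(grepl("^na", tips), "NA-like", "EB-like"),
                         stringsAsFactors = FALSE)
  }
  div <- diversity_by_group(imp$gt[tree$ingroup, , drop = FALSE], groups,
                            L = config$theta_length)
  write_tsv(div, file.path(out_dir, "diversity.tsv"))
  counts$diversity <- stats::setNames(div$theta_w, div$group)

  manifest <- list(package_version = as.character(utils::packageVersion("msytools")),
                   r_version = as.character(getRversion()),
                   config = unclass(config), counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Find the tree node subtending exactly a given tip set
#'
#' @param tree a [build_parsimony_tree()] result.
#' @param tips_below character vector of ingroup sample ids.
#' @return the internal node label whose clade equals the tip set.
#' @export
find_calibration_node <- function(tree, tips_below) {
  for (nm in names(tree$clades))
    if (setequal(tree$clades[[nm]], tips_below)) return(nm)
  stop("no node subtends exactly the given tip set")
}
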