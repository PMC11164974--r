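#' Simulation parameters for sex-stratified coverage data
#'
#' Describes a synthetic assembly (a plan of labeled contigs) and a sequencing
#' cohort (males and females with lognormally distributed diploid depth) from
#' which [simulate_coverage_dataset()] draws per-window mean depths.
#'
#' Window-level expectations, on the normalized scale where 1.0 is diploid:
#' autosomal contigs are 1.0 in both sexes; X-like contigs 0.5 in males and
#' 1.0 in females; single-copy Y (scY) 0.5 in males and `background` in
#' females; multi-copy Y with `copies = k` is `0.5 * k` in males and
#' `background` in females; unmapped non-Y sequence is 0 in both.
#'
#' @param n_males,n_females cohort sizes.
#' @param contig_plan data.frame with columns `contig`, `label` (one of
#'   `"autosomal"`, `"X"`, `"scY"`, `"mcY"`, `"unmapped"`), `length` (bp) and
#'   optionally `copies` (mcY copy number, >= 2). See [default_contig_plan()].
#' @param depth_meanlog,depth_sdlog location and scale of the lognormal
#'   distribution of per-sample diploid depth.
#' @param background female mean normalized depth on Y contigs, as a fraction
#'   of the haploid male signal's scale; must lie in [0, 0.2].
#' @param dispersion lognormal overdispersion of window depths. `0` gives
#'   noise-free expectations; positive values use a lognormal-scaled Poisson
#'   draw of window base counts (negative-binomial-like overdispersion).
#' @param window_size classification window, bp (default 50).
#' @param seed integer seed; identical seeds give identical output.
#' @return a list of class `coverage_sim_params`.
#' @export
coverage_sim_params <- function(n_males = 11, n_females = 5,
                                contig_plan = default_contig_plan(),
                                depth_meanlog = log(12), depth_sdlog = 0.4,
                                background = 0.02, dispersion = 0.1,
                                window_size = 50L, seed = 1L) {
  stopifnot(n_males >= 0, n_females >= 0, n_males + n_females > 0,
            is.data.frame(contig_plan),
            all(c("contig", "label", "length") %in% names(contig_plan)),
            all(contig_plan$length > 0),
            background >= 0, background <= 0.2,
            dispersion >= 0, window_size > 0)
  if (is.null(contig_plan$copies)) contig_plan$copies <- 1L
  contig_plan$copies[is.na(contig_plan$copies)] <- 1L
  bad <- setdiff(contig_plan$label, c("autosomal", "X", "scY", "mcY", "unmapped"))
  if (length(bad)) stop("unknown contig label(s): ", paste(unique(bad), collapse = ", "))
  if (any(contig_plan$label == "mcY" & contig_plan$copies < 2))
    stop("mcY contigs need copies >= 2")
  structure(list(n_males = n_males, n_females = n_females,
                 contig_plan = contig_plan,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 background = background, dispersion = dispersion,
                 window_size = as.integer(window_size), seed = as.integer(seed)),
            class = "coverage_sim_params")
}

#' Default synthetic contig plan
#'
#' A small assembly mixing autosomal background (used for normalization),
#' X-like sequence, single- and multi-copy Y, and unmapped windows.
#'
#' @param n_autosomal,n_scy number of autosomal and scY contigs.
#' @param autosomal_length,scy_length lengths in bp.
#' @return data.frame with columns contig, label, length, copies.
#' @export
default_contig_plan <- function(n_autosomal = 40, n_scy = 8,
                                autosomal_length = 5000L, scy_length = 2500L) {
  plan <- rbind(
    data.frame(contig = sprintf("auto%02d", seq_len(n_autosomal)),
               label = "autosomal", length = autosomal_length, copies = 1L),
    data.frame(contig = "chrX1", label = "X", length = 4000L, copies = 1L),
    data.frame(contig = sprintf("scY%02d", seq_len(n_scy)),
               label = "scY", length = scy_length, copies = 1L),
    data.frame(contig = c("mcY01", "mcY02"), label = "mcY",
               length = c(2000L, 1500L), copies = c(2L, 3L)),
    data.frame(contig = "junk01", label = "unmapped", length = 1000L, copies = 1L)
  )
  plan$length <- as.integer(plan$length)
  plan
}

expected_normalized_depth <- function(label, copies, sex, background) {
  male <- sex == "male"
  switch(label,
         autosomal = 1,
         X         = if (male) 0.5 else 1,
         scY       = if (male) 0.5 else background,
         mcY       = if (male) 0.5 * copies else background,
         unmapped  = 0)
}

#' Simulate a sex-stratified window coverage dataset
#'
#' Draws per-window mean sequencing depth for every sample over the contig
#' plan, returning the long-format window table the MSY discovery module
#' consumes, the per-window truth labels, and per-sample totals. Contigs are
#' split into `window_size`-bp windows (0-based half-open; the final window of
#' a contig may be shorter).
#'
#' With `dispersion = 0` every window's mean depth equals its expectation
#' exactly. Otherwise the window's base count is drawn Poisson with a
#' lognormal-scaled mean (mean-preserving overdispersion) and divided by the
#' window width.
#'
#' @param params a [coverage_sim_params()] object.
#' @return list with elements:
#'   \describe{
#'     \item{windows}{data.frame contig, start, end, sample, mean_depth.}
#'     \item{truth}{data.frame contig, start, end, label, copies.}
#'     \item{samples}{data.frame sample, sex, diploid_depth, total_bases.}
#'     \item{params}{the input parameters.}
#'   }
#' @export
#' @examples
#' sim <- simulate_coverage_dataset(coverage_sim_params(n_males = 2, n_females = 1,
#'   contig_plan = default_contig_plan(n_autosomal = 4, n_scy = 2), seed = 7))
#' head(sim$windows)
simulate_coverage_dataset <- function(params) {
  stopifnot(inherits(params, "coverage_sim_params"))
  set.seed(params$seed)
  plan <- params$contig_plan
  w <- params$window_size

  samples <- data.frame(
    sample = c(sprintf("M%02d", seq_len(params$n_males)),
               sprintf("F%02d", seq_len(params$n_females))),
    sex = rep(c("male", "female"), c(params$n_males, params$n_females)),
    stringsAsFactors = FALSE)
  samples$diploid_depth <- stats::rlnorm(nrow(samples),
                                         params$depth_meanlog, params$depth_sdlog)

  starts <- lapply(plan$length, function(L) seq(0L, L - 1L, by = w))
  truth <- data.frame(
    contig = rep(plan$contig, lengths(starts)),
    start  = unlist(starts),
    label  = rep(plan$label, lengths(starts)),
    copies = rep(plan$copies, lengths(starts)),
    stringsAsFactors = FALSE)
  truth$end <- pmin(truth$start + w, rep(plan$length, lengths(starts)))
  truth <- truth[, c("contig", "start", "end", "label", "copies")]
  nw <- nrow(truth)
  width <- truth$end - truth$start

  out <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    expect_norm <- mapply(expected_normalized_depth,
                          truth$label, truth$copies,
                          MoreArgs = list(sex = samples$sex[i],
                                          background = params$background))
    lambda <- expect_norm * samples$diploid_depth[i]
    if (params$dispersion == 0) {
      depth <- lambda
    } else {
      m <- exp(stats::rnorm(nw, -params$dispersion^2 / 2, params$dispersion))
      depth <- stats::rpois(nw, lambda * m * width) / width
    }
    out[[i]] <- data.frame(contig = truth$contig, start = truth$start,
                           end = truth$end, sample = samples$sample[i],
                           mean_depth = depth, stringsAsFactors = FALSE)
  }
  windows <- do.call(rbind, out)
  rownames(windows) <- NULL
  tb <- vapply(out, function(d) sum(d$mean_depth * (d$end - d$start)), 0)
  samples$total_bases <- tb
  list(windows = windows, truth = truth, samples = samples, params = params)
}

#' Simulation parameters for SNPs evolving down a dated tree
#'
#' Configures an infinite-sites mutation process on a time-calibrated tree:
#' each branch receives Poisson(mu_year * L * branch length) mutations, each
#' striking a previously unmutated site, so every derived allele is carried by
#' exactly the tips below its branch. Missing calls, allele-support conflicts
#' and recurrent (homoplastic) sites can be injected afterwards with their
#' truth recorded.
#'
#' @param tree an [ape::phylo] with branch lengths in years, or `NULL` to draw
#'   a coalescent topology with `n_tips` tips scaled to `root_age`.
#' @param n_tips,root_age used only when `tree` is `NULL`.
#' @param mu_year mutation rate per site per year.
#' @param L scanned sequence length, bp.
#' @param generation_time years per generation (metadata, default 6).
#' @param missing_rate,conflict_rate per-call artifact probabilities.
#' @param n_recurrent number of injected homoplastic sites (derived in two
#'   disjoint clades).
#' @param mean_read_depth mean per-call read depth for simulated AD support.
#' @param seed integer seed.
#' @return list of class `tree_sim_params`.
#' @export
tree_sim_params <- function(tree = NULL, n_tips = 16, root_age = 40000,
                            mu_year = 1.031e-9, L = 1234870,
                            generation_time = 6,
                            missing_rate = 0, conflict_rate = 0,
                            n_recurrent = 0L, mean_read_depth = 5,
                            seed = 1L) {
  stopifnot(mu_year > 0, L > 0, missing_rate >= 0, missing_rate < 1,
            conflict_rate >= 0, conflict_rate < 1, n_recurrent >= 0)
  if (!is.null(tree)) {
    stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
    if (any(tree$edge.length < 0)) stop("negative branch lengths")
  } else {
    stopifnot(n_tips >= 2, root_age > 0)
  }
  structure(list(tree = tree, n_tips = n_tips, root_age = root_age,
                 mu_year = mu_year, L = L, generation_time = generation_time,
                 missing_rate = missing_rate, conflict_rate = conflict_rate,
                 n_recurrent = as.integer(n_recurrent),
                 mean_read_depth = mean_read_depth, seed = as.integer(seed)),
            class = "tree_sim_params")
}

tips_below_edge <- function(tree, edge_idx) {
  ntip <- length(tree$tip.label)
  node <- tree$edge[edge_idx, 2]
  if (node <= ntip) return(tree$tip.label[node])
  desc <- node
  repeat {
    kids <- tree$edge[tree$edge[, 1] %in% desc & !(tree$edge[, 2] %in% desc), 2]
    if (!length(kids)) break
    desc <- c(desc, kids)
  }
  tree$tip.label[desc[desc <= ntip]]
}

#' Simulate a haploid genotype matrix down a dated tree
#'
#' Runs the infinite-sites process of [tree_sim_params()] and returns the true
#' dated tree, the samples-by-sites genotype matrix (0 ancestral, 1 derived,
#' NA missing) with read-support matrices, and a per-site truth ledger mapping
#' each site to the branch it mutated on (or marking it as an injected
#' artifact).
#'
#' @param params a [tree_sim_params()] object.
#' @return list with elements `tree` (ape phylo, branch lengths in years, plus
#'   `$edge_mutations` counts), `gt`, `gt_clean` (pre-artifact calls),
#'   `ref_reads`, `alt_reads`, `conflict` (logical matrix), `truth`
#'   (data.frame site, edge, type), `sites` (data.frame site, contig, pos,
#'   ref, alt) and `params`.
#' @export
simulate_tree_snps <- function(params) {
  stopifnot(inherits(params, "tree_sim_params"))
  set.seed(params$seed)
  tree <- params$tree
  if (is.null(tree)) {
    tree <- ape::rcoal(params$n_tips)
    tree$edge.length <- tree$edge.length * params$root_age /
      max(ape::node.depth.edgelength(tree))
  }
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)

  n_mut <- stats::rpois(nedge, params$mu_year * params$L * tree$edge.length)
  total <- sum(n_mut) + params$n_recurrent
  if (total > params$L)
    stop("site exhaustion: ", total, " mutations requested over L = ", params$L)
  pos <- sort(sample.int(params$L, total))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, total, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  site_id <- sprintf("scY:%d:%s>%s", pos, ref, alt)

  gt <- matrix(0L, nrow = ntip, ncol = total,
               dimnames = list(tree$tip.label, site_id))
  edge_of_site <- integer(total)
  k <- 0L
  for (e in seq_len(nedge)) {
    if (n_mut[e] == 0) next
    carriers <- tips_below_edge(tree, e)
    idx <- k + seq_len(n_mut[e])
    gt[carriers, idx] <- 1L
    edge_of_site[idx] <- e
    k <- k + n_mut[e]
  }
  type <- rep("clean", total)

  # homoplasy injection: derived allele on two disjoint clades
  if (params$n_recurrent > 0) {
    idx <- k + seq_len(params$n_recurrent)
    tipsets <- lapply(seq_len(nedge), tips_below_edge, tree = tree)
    all_tips <- tree$tip.label
    for (j in idx) {
      repeat {
        ee <- sample.int(nedge, 2)
        u <- union(tipsets[[ee[1]]], tipsets[[ee[2]]])
        # disjoint clades whose union fails the unrooted four-gamete test
        # against some true split, so the homoplasy is detectable however
        # the tree is later polarized
        if (!length(intersect(tipsets[[ee[1]]], tipsets[[ee[2]]])) &&
            length(u) < ntip &&
            any(vapply(tipsets, function(s) {
              uc <- setdiff(all_tips, u)
              sc <- setdiff(all_tips, s)
              length(intersect(u, s)) > 0 && length(intersect(u, sc)) > 0 &&
                length(intersect(uc, s)) > 0 && length(intersect(uc, sc)) > 0
            }, TRUE))) break
      }
      gt[c(tipsets[[ee[1]]], tipsets[[ee[2]]]), j] <- 1L
      edge_of_site[j] <- NA_integer_
      type[j] <- "recurrent"
    }
  }
  gt_clean <- gt

  depth <- matrix(pmax(1L, stats::rpois(ntip * total, params$mean_read_depth)),
                  ntip, total, dimnames = dimnames(gt))
  conflict <- matrix(FALSE, ntip, total, dimnames = dimnames(gt))
  if (params$conflict_rate > 0) {
    conflict[] <- stats::runif(ntip * total) < params$conflict_rate
    conflict[depth < 2] <- FALSE
  }
  alt_reads <- gt * depth
  minority <- matrix(0L, ntip, total)
  if (any(conflict)) {
    minority[conflict] <- pmax(1L, floor(depth[conflict] / 3))
    alt_reads <- gt * (depth - minority) + (1L - gt) * minority
  }
  ref_reads <- depth - alt_reads

  if (params$missing_rate > 0) {
    miss <- matrix(stats::runif(ntip * total) < params$missing_rate, ntip, total)
    gt[miss] <- NA_integer_
    ref_reads[miss] <- 0L
    alt_reads[miss] <- 0L
    conflict[miss] <- FALSE
  }

  list(tree = structure(tree, edge_mutations = n_mut),
       gt = gt, gt_clean = gt_clean,
       ref_reads = ref_reads, alt_reads = alt_reads, conflict = conflict,
       truth = data.frame(site = site_id, edge = edge_of_site, type = type,
                          stringsAsFactors = FALSE),
       sites = data.frame(site = site_id, contig = "scY", pos = pos,
                          ref = ref, alt = alt, stringsAsFactors = FALSE),
       params = params)
}

#' Simulate SRY-matching read counts for molecular sexing
#'
#' Males accumulate reads matching the SRY coding region in proportion to
#' their sequencing depth; females only through contamination (0 by default).
#'
#' @param n_samples number of samples.
#' @param sexes character vector of `"male"`/`"female"`; recycled if length 1.
#' @param depth_range fold-coverage range sampled uniformly.
#' @param reads_per_x expected SRY-matching reads per 1x coverage in a male.
#' @param contamination female rate as a fraction of the male rate.
#' @param genome_size bp, used to convert depth to total bases.
#' @param seed integer seed.
#' @return data.frame sample, true_sex, depth, sry_read_count, total_bases.
#' @export
simulate_sry_counts <- function(n_samples, sexes, depth_range = c(1, 30),
                                reads_per_x = 5, contamination = 0,
                                genome_size = 2.9e9, seed = 1L) {
  stopifnot(n_samples > 0, all(depth_range > 0), reads_per_x > 0,
            contamination >= 0)
  sexes <- rep_len(sexes, n_samples)
  stopifnot(all(sexes %in% c("male", "female")))
  set.seed(seed)
  depth <- stats::runif(n_samples, depth_range[1], depth_range[2])
  rate <- ifelse(sexes == "male", reads_per_x, contamination * reads_per_x)
  data.frame(sample = sprintf("S%03d", seq_len(n_samples)),
             true_sex = sexes, depth = depth,
             sry_read_count = stats::rpois(n_samples, rate * depth),
             total_bases = depth * genome_size,
             stringsAsFactors = FALSE)
}
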