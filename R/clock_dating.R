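as_count_tree <- function(tree) {
  phy <- if (inherits(tree, "haplotype_tree")) tree$phylo else tree
  stopifnot(inherits(phy, "phylo"), !is.null(phy$edge.length))
  phy
}

node_number <- function(phy, node) {
  if (is.character(node)) {
    ntip <- length(phy$tip.label)
    hit <- match(node, phy$node.label)
    if (is.na(hit)) {
      hit_tip <- match(node, phy$tip.label)
      if (is.na(hit_tip)) stop("node '", node, "' not found")
      return(hit_tip)
    }
    return(ntip + hit)
  }
  as.integer(node)
}

descendant_edges <- function(phy) {
  # for every node, the edge indices inside its subtree and tip counts per edge
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  reord <- ape::reorder.phylo(phy, "postorder")
  edge_match <- match(paste(reord$edge[, 1], reord$edge[, 2]),
                      paste(phy$edge[, 1], phy$edge[, 2]))
  sub_edges <- vector("list", nn)
  ntips_below <- integer(nn)
  ntips_below[seq_len(ntip)] <- 1L
  for (e in seq_len(nrow(reord$edge))) {
    par <- reord$edge[e, 1]; child <- reord$edge[e, 2]
    sub_edges[[par]] <- c(sub_edges[[par]], sub_edges[[child]], edge_match[e])
    ntips_below[par] <- ntips_below[par] + ntips_below[child]
  }
  list(sub_edges = sub_edges, ntips_below = ntips_below)
}

#' Mean mutations per root-to-tip path below a node
#'
#' Averages, over the tips descending from `node`, the summed branch mutation
#' counts on the path from the node down to each tip. This is the quantity a
#' calibration point converts into a mutation rate.
#'
#' @param tree a [build_parsimony_tree()] result or an [ape::phylo] whose
#'   branch lengths are mutation counts.
#' @param node internal node label (or number).
#' @return the mean path mutation count.
#' @export
mean_mutations_below <- function(tree, node) {
  phy <- as_count_tree(tree)
  v <- node_number(phy, node)
  if (v <= length(phy$tip.label)) stop("node is a leaf")
  d <- descendant_edges(phy)
  tipw <- d$ntips_below[phy$edge[, 2]]
  idx <- d$sub_edges[[v]]
  sum(phy$edge.length[idx] * tipw[idx]) / d$ntips_below[v]
}

#' Calibration-point mutation rate
#'
#' Converts the mean mutation count below a node of known age into per-site
#' rates: `mu_year = m_bar / (L_scan * T)` and `mu_gen = mu_year * g`. The
#' generation count is reported both as the floor integer and the exact
#' ratio T/g. Per-year bounds under alternative generation times are
#' `mu_gen / g` for each bound (holding the per-generation rate fixed).
#'
#' @param m_bar mean mutations per path below the calibration node.
#' @param L_scan scanned sequence length, bp.
#' @param T_cal calibration age in years.
#' @param g generation time in years.
#' @param g_bounds c(lower, upper) alternative generation times.
#' @return list of class `calibration_result`: m_bar, L_scan, T_cal, g,
#'   generations (floor), generations_exact, mu_year, mu_gen, and
#'   mu_year_bounds (named by generation time).
#' @export
#' @examples
#' r <- estimate_rate(14.01, 1234870, 11000, 6)
#' signif(r$mu_year, 4)   # 1.031e-09 per site per year
estimate_rate <- function(m_bar, L_scan, T_cal, g, g_bounds = c(4, 8)) {
  if (m_bar < 0) stop("negative mutation count")
  if (L_scan <= 0 || T_cal <= 0 || g <= 0) stop("non-positive calibration input")
  mu_year <- m_bar / (L_scan * T_cal)
  mu_gen <- mu_year * g
  structure(list(m_bar = m_bar, L_scan = L_scan, T_cal = T_cal, g = g,
                 generations = floor(T_cal / g),
                 generations_exact = T_cal / g,
                 mu_year = mu_year, mu_gen = mu_gen,
                 mu_year_bounds = stats::setNames(mu_gen / g_bounds,
                                                  paste0("g", g_bounds))),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration: m = %.4g mutations over %d y (%d generations at g = %g)\n",
              x$m_bar, round(x$T_cal), x$generations, x$g))
  cat(sprintf("  mu = %.4e /site/year = %.4e /site/generation\n",
              x$mu_year, x$mu_gen))
  invisible(x)
}

#' Strict-clock node dating with bootstrap intervals
#'
#' Estimates the rate from the calibration node, then dates every internal
#' node as `m_bar_node / (mu_year * L_scan)`. Uncertainty comes from a
#' parametric bootstrap: each branch count is resampled Poisson with mean
#' equal to its observed count, the rate is re-estimated from the resampled
#' calibration node, and ages are recomputed; the percentile interval over
#' the replicates is reported. The calibration node's age is the calibration
#' age exactly, in every replicate. Children dated older than their parent
#' (possible with noisy counts) are flagged, not clamped.
#'
#' @param tree a [build_parsimony_tree()] result or phylo with mutation-count
#'   branch lengths.
#' @param calibration_node internal node label or number.
#' @param calibration_age node age in years (default 11000).
#' @param L_scan scanned length in bp (default 1234870).
#' @param g generation time in years (metadata for the rate, default 6).
#' @param boot_reps bootstrap replicates (default 1000).
#' @param conf interval mass (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return list with `calibration` (a [estimate_rate()] result), `nodes`
#'   (data.frame node, n_tips, m_bar, age, lo, hi, parent_violation) and
#'   `phylo`.
#' @export
date_nodes <- function(tree, calibration_node, calibration_age = 11000,
                       L_scan = 1234870, g = 6, boot_reps = 1000,
                       conf = 0.95, seed = 1L) {
  phy <- as_count_tree(tree)
  ntip <- length(phy$tip.label)
  d <- descendant_edges(phy)
  tipw <- d$ntips_below[phy$edge[, 2]]
  counts <- phy$edge.length
  internal <- (ntip + 1):(ntip + phy$Nnode)

  # weight matrix: m_bar(v) = W[v, ] %*% counts
  W <- matrix(0, length(internal), length(counts))
  for (i in seq_along(internal)) {
    idx <- d$sub_edges[[internal[i]]]
    W[i, idx] <- tipw[idx] / d$ntips_below[internal[i]]
  }
  m_bar <- as.numeric(W %*% counts)

  cal <- node_number(phy, calibration_node)
  ci <- match(cal, internal)
  if (is.na(ci)) stop("calibration node must be internal")
  if (m_bar[ci] <= 0) stop("zero mutations below the calibration node; rate undefined")
  calres <- estimate_rate(m_bar[ci], L_scan, calibration_age, g)
  ages <- m_bar / (calres$mu_year * L_scan)

  set.seed(seed)
  boot <- matrix(NA_real_, boot_reps, length(internal))
  for (b in seq_len(boot_reps)) {
    cb <- stats::rpois(length(counts), counts)
    mb <- as.numeric(W %*% cb)
    if (mb[ci] <= 0) next  # degenerate resample; rate undefined
    mu_b <- mb[ci] / (L_scan * calibration_age)
    boot[b, ] <- mb / (mu_b * L_scan)
  }
  qs <- apply(boot, 2, stats::quantile,
              probs = c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)

  labs <- if (!is.null(phy$node.label)) phy$node.label else as.character(internal)
  parent_of <- phy$edge[match(internal, phy$edge[, 2]), 1]
  page <- ages[match(parent_of, internal)]
  violation <- !is.na(page) & ages > page + 1e-9

  list(calibration = calres,
       nodes = data.frame(node = labs, n_tips = d$ntips_below[internal],
                          m_bar = m_bar, age = ages,
                          lo = qs[1, ], hi = qs[2, ],
                          parent_violation = violation,
                          stringsAsFactors = FALSE),
       phylo = phy)
}
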