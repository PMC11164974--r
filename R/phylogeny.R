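#' @importFrom ape read.tree write.tree
NULL

as_gt_matrix <- function(x) {
  if (inherits(x, "variant_table")) x$gt
  else if (is.matrix(x)) x
  else stop("expected a variant_table or a samples-by-sites matrix")
}

set_key <- function(idx) paste(idx, collapse = ",")

# pairwise compatibility of two carrier sets (perfect phylogeny: nested or
# disjoint)
sets_compatible <- function(a, b) {
  i <- length(intersect(a, b))
  i == 0L || i == length(a) || i == length(b)
}

#' Build a maximum-parsimony haplotype tree by perfect-phylogeny construction
#'
#' Polarizes the haploid genotype matrix against the outgroup (sites where the
#' outgroup is missing are polarized by majority and flagged), groups sites by
#' their derived-carrier sets, and accepts carrier sets greedily (best
#' supported first) while they remain pairwise compatible - nested or
#' disjoint, the binary-character four-gamete condition. The accepted laminar
#' family IS the tree: each set becomes a clade whose subtending branch
#' carries the set's sites. Sites whose carrier set conflicts with the
#' accepted family are flagged recurrent and scored by exact minimum-change
#' (Sankoff) placement on the finished tree.
#'
#' Missing calls are wildcards: a site whose observed derived carriers fit
#' inside an already-accepted clade (and whose observed ancestral carriers
#' stay outside it) is placed on that clade's branch instead of proposing a
#' conflicting new one.
#'
#' @param x a [variant_table()] or samples-by-sites 0/1/NA matrix.
#' @param outgroup optional sample name used to root the tree and define the
#'   ancestral allele at every site.
#' @return an object of class `haplotype_tree`: list with
#'   \describe{
#'     \item{phylo}{rooted [ape::phylo]; branch lengths are mutation counts,
#'       internal nodes are labeled.}
#'     \item{branch_sites}{named list: child node/tip label -> site ids on
#'       the branch above it.}
#'     \item{clades}{named list: node label -> ingroup samples below it.}
#'     \item{recurrent_sites}{site ids that conflicted with the tree.}
#'     \item{score}{total parsimony score.}
#'     \item{majority_polarized}{sites polarized without outgroup information.}
#'   }
#' @export
build_parsimony_tree <- function(x, outgroup = NULL) {
  gt <- as_gt_matrix(x)
  samples <- rownames(gt)
  if (is.null(samples)) stop("matrix needs sample rownames")
  if (any(rowSums(!is.na(gt)) == 0)) stop("sample with all calls missing")
  if (!is.null(outgroup) && !outgroup %in% samples)
    stop("outgroup not among the samples")
  ingroup <- setdiff(samples, outgroup)
  if (length(ingroup) < 2) stop("need at least two ingroup samples")

  # polarize: ancestral = outgroup allele; majority when outgroup missing
  majority_polarized <- character(0)
  nsite <- ncol(gt)
  site_ids <- colnames(gt)
  if (is.null(site_ids)) site_ids <- colnames(gt) <- sprintf("site%04d", seq_len(nsite))
  pol <- gt
  for (j in seq_len(nsite)) {
    anc <- if (!is.null(outgroup)) gt[outgroup, j] else NA
    if (is.na(anc)) {
      obs <- gt[ingroup, j]
      anc <- if (sum(obs == 1L, na.rm = TRUE) > sum(obs == 0L, na.rm = TRUE)) 1L else 0L
      if (!is.null(outgroup)) majority_polarized <- c(majority_polarized, site_ids[j])
    }
    if (anc == 1L) pol[, j] <- 1L - gt[, j]
  }

  # derived/ancestral patterns over the ingroup (missing = wildcard)
  ing_idx <- match(ingroup, samples)
  ing_pol <- pol[ing_idx, , drop = FALSE]
  d_key <- apply(ing_pol, 2, function(col) set_key(which(!is.na(col) & col == 1L)))
  a_key <- apply(ing_pol, 2, function(col) set_key(which(!is.na(col) & col == 0L)))
  pair <- paste(d_key, a_key, sep = "|")
  empty <- d_key == ""
  keys <- unique(pair[!empty])
  parse_set <- function(k) if (nzchar(k)) as.integer(strsplit(k, ",")[[1]]) else integer(0)
  d_sets <- lapply(sub("\\|.*", "", keys), parse_set)
  a_sets <- lapply(sub(".*\\|", "", keys), parse_set)
  support <- vapply(keys, function(k) sum(pair == k), 0L)

  full <- seq_along(ingroup)
  full_key <- set_key(full)
  # base laminar family: the root clade and every singleton, always present
  base_sets <- c(stats::setNames(list(full), full_key),
                 stats::setNames(lapply(full, identity),
                                 vapply(full, set_key, "")))
  accepted <- list()       # internal clades proposed by the data
  branch_assign <- list()  # clade key -> site ids on the branch above it
  recurrent_keys <- character(0)

  ord <- order(-support, -lengths(d_sets),
               vapply(d_sets, function(s) ingroup[s[1]], ""))
  for (k in ord) {
    D <- d_sets[[k]]; A <- a_sets[[k]]
    fam <- c(accepted, base_sets)
    fits <- vapply(fam, function(C)
      all(D %in% C) && !any(A %in% C), TRUE)
    if (any(fits)) {
      cand <- fam[fits]
      key <- names(cand)[which.min(lengths(cand))]
    } else if (length(D) >= 2 &&
               all(vapply(accepted, sets_compatible, TRUE, a = D))) {
      key <- set_key(D)
      accepted[[key]] <- D
    } else {
      recurrent_keys <- c(recurrent_keys, keys[k])
      next
    }
    branch_assign[[key]] <- c(branch_assign[[key]],
                              site_ids[pair == keys[k]])
  }
  recurrent_sites <- site_ids[pair %in% recurrent_keys & !empty]

  internal <- accepted[names(accepted) != full_key]
  sites_of <- function(key) {
    s <- branch_assign[[key]]
    if (is.null(s)) character(0) else s
  }

  # parent lookup inside the laminar family
  family_sets <- c(list(root = full), internal)
  min_superset <- function(s, self_key = NULL) {
    best <- "root"; bestlen <- length(full)
    for (nm in names(internal)) {
      if (identical(nm, self_key)) next
      t <- internal[[nm]]
      if (length(t) > length(s) && all(s %in% t) && length(t) < bestlen) {
        best <- nm; bestlen <- length(t)
      }
    }
    best
  }
  node_label <- c(root = "rt")
  if (length(internal))
    node_label[names(internal)] <- sprintf("n%02d", seq_along(internal))

  children <- list()
  add_child <- function(parent, child) {
    children[[parent]] <<- c(children[[parent]], list(child))
  }
  for (nm in names(internal)) add_child(min_superset(internal[[nm]], nm),
                                        list(type = "node", key = nm))
  for (i in seq_along(ingroup)) {
    p <- min_superset(i)
    add_child(p, list(type = "tip", idx = i))
  }

  branch_sites <- list()
  clades <- list(rt = ingroup)
  render <- function(key) {
    kids <- children[[key]]
    stopifnot(length(kids) > 0)
    size_of <- function(kid) if (kid$type == "tip") 1L else length(internal[[kid$key]])
    name_of <- function(kid) if (kid$type == "tip") ingroup[kid$idx]
                             else ingroup[internal[[kid$key]][1]]
    ordk <- order(-vapply(kids, size_of, 0L), vapply(kids, name_of, ""))
    parts <- vapply(kids[ordk], function(kid) {
      if (kid$type == "tip") {
        tipname <- ingroup[kid$idx]
        s <- sites_of(set_key(kid$idx))
        branch_sites[[tipname]] <<- s
        sprintf("%s:%d", tipname, length(s))
      } else {
        lbl <- node_label[[kid$key]]
        s <- sites_of(kid$key)
        branch_sites[[lbl]] <<- s
        clades[[lbl]] <<- ingroup[internal[[kid$key]]]
        sprintf("%s%s:%d", render(kid$key), lbl, length(s))
      }
    }, "")
    sprintf("(%s)", paste(parts, collapse = ","))
  }
  core <- render("root")

  stem_sites <- sites_of(full_key)
  if (!is.null(outgroup)) {
    branch_sites[["rt"]] <- stem_sites
    nwk <- sprintf("(%srt:%d,%s:0)top;", core, length(stem_sites), outgroup)
  } else {
    branch_sites[["rt"]] <- stem_sites  # unplaceable above the root; kept visible
    nwk <- sprintf("%srt;", core)
  }
  phy <- ape::read.tree(text = nwk)

  score <- sum(lengths(branch_assign))
  for (s in recurrent_sites) {
    states <- pol[, s]; names(states) <- samples
    score <- score + sankoff_cost(phy, states)
  }

  structure(list(phylo = phy, branch_sites = branch_sites, clades = clades,
                 recurrent_sites = recurrent_sites, score = score,
                 outgroup = outgroup, ingroup = ingroup,
                 majority_polarized = majority_polarized,
                 polarized = pol),
            class = "haplotype_tree")
}

#' @export
print.haplotype_tree <- function(x, ...) {
  cat("haplotype_tree:", length(x$ingroup), "ingroup samples,",
      sum(lengths(x$branch_sites)), "placed sites,",
      length(x$recurrent_sites), "recurrent, parsimony score", x$score, "\n")
  invisible(x)
}

#' Exact minimum-change cost of a binary character on a fixed tree
#'
#' Sankoff dynamic programming over a rooted (possibly multifurcating) tree
#' with unit substitution cost; missing tips contribute either state freely.
#'
#' @param phy an [ape::phylo].
#' @param states named 0/1/NA vector over (a superset of) the tip labels.
#' @return the minimum number of state changes.
#' @export
sankoff_cost <- function(phy, states) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  cost <- matrix(Inf, ntip + nnode, 2)
  for (i in seq_len(ntip)) {
    s <- states[phy$tip.label[i]]
    if (is.na(s)) cost[i, ] <- c(0, 0) else cost[i, s + 1] <- 0
  }
  reord <- ape::reorder.phylo(phy, "postorder")
  done <- rep(FALSE, ntip + nnode)
  for (e in seq_len(nrow(reord$edge))) {
    par <- reord$edge[e, 1]; child <- reord$edge[e, 2]
    if (!done[par]) { cost[par, ] <- 0; done[par] <- TRUE }
    cost[par, 1] <- cost[par, 1] + min(cost[child, 1], cost[child, 2] + 1)
    cost[par, 2] <- cost[par, 2] + min(cost[child, 2], cost[child, 1] + 1)
  }
  root <- reord$edge[nrow(reord$edge), 1]
  min(cost[root, ])
}

#' Place variants on tree branches and label curation categories
#'
#' Maps each site to the branch whose clade exactly explains its derived
#' carriers: the clade must contain every observed derived call and exclude
#' every observed ancestral call (missing calls are wildcards). Sites with no
#' such branch are `recurrent`; sites derived in exactly one sample whose
#' call shows read support for both alleles are `single-sample-heterozygous`;
#' caller-supplied external annotation (assembly error, repetitive,
#' normalization failure) overrides the computed label.
#'
#' @param x a [variant_table()] (enables the read-support check) or matrix.
#' @param tree a [build_parsimony_tree()] result.
#' @param external_flags optional named character vector, site id -> label.
#' @return data.frame site, branch (node/tip label or NA), label.
#' @export
place_variants <- function(x, tree, external_flags = NULL) {
  gt <- as_gt_matrix(x)
  pol <- polarize_like(gt, tree)
  ingroup <- tree$ingroup
  conflict <- if (inherits(x, "variant_table")) conflicted_calls(x) else NULL

  clades <- c(tree$clades, stats::setNames(as.list(ingroup), ingroup))
  clade_sizes <- lengths(clades)
  ord <- order(clade_sizes)  # smallest explaining clade wins
  out <- data.frame(site = colnames(gt), branch = NA_character_,
                    label = "clean", stringsAsFactors = FALSE)
  for (j in seq_len(ncol(gt))) {
    col <- pol[ingroup, j]
    D <- ingroup[!is.na(col) & col == 1L]
    A <- ingroup[!is.na(col) & col == 0L]
    if (!length(D)) { out$label[j] <- "no-derived-call"; next }
    hit <- NA_character_
    for (k in ord) {
      C <- clades[[k]]
      if (all(D %in% C) && !any(A %in% C)) { hit <- names(clades)[k]; break }
    }
    if (is.na(hit)) {
      out$label[j] <- "recurrent"
    } else {
      out$branch[j] <- hit
      if (length(D) == 1L && !is.null(conflict) && conflict[D, j])
        out$label[j] <- "single-sample-heterozygous"
    }
  }
  if (!is.null(external_flags)) {
    m <- match(names(external_flags), out$site)
    ok <- !is.na(m)
    out$label[m[ok]] <- paste0("flagged-external:", external_flags[ok])
  }
  out
}

polarize_like <- function(gt, tree) {
  # reapply the tree's polarization to a (possibly different) matrix
  common <- intersect(colnames(gt), colnames(tree$polarized))
  pol <- gt
  for (s in common) {
    ref_col <- tree$polarized[, s]
    raw <- gt[rownames(tree$polarized), s]
    flipped <- any(!is.na(raw) & !is.na(ref_col) & raw != ref_col)
    if (flipped) pol[, s] <- 1L - gt[, s]
  }
  pol
}

#' Impute missing calls from the phylogeny
#'
#' A missing call becomes derived when the sample descends from the branch
#' the site is placed on, ancestral otherwise. Missing calls at unplaced
#' (recurrent) sites are left missing with a warning.
#'
#' @param x a [variant_table()] or matrix (polarized orientation, as used to
#'   build the tree).
#' @param tree a [build_parsimony_tree()] result.
#' @param placement optional [place_variants()] table; recomputed if absent.
#' @return list `gt` (completed matrix) and `imputed` (logical matrix
#'   flagging filled-in calls).
#' @export
impute_missing <- function(x, tree, placement = NULL) {
  gt <- as_gt_matrix(x)
  pol <- polarize_like(gt, tree)
  if (is.null(placement)) placement <- place_variants(x, tree)
  clades <- c(tree$clades, stats::setNames(as.list(tree$ingroup), tree$ingroup))
  imputed <- is.na(pol)
  unplaced <- 0L
  for (j in seq_len(ncol(pol))) {
    miss <- which(is.na(pol[, j]))
    if (!length(miss)) next
    br <- placement$branch[placement$site == colnames(pol)[j]]
    if (!length(br) || is.na(br)) {
      unplaced <- unplaced + length(miss)
      imputed[miss, j] <- FALSE
      next
    }
    C <- clades[[br]]
    pol[miss, j] <- ifelse(rownames(pol)[miss] %in% C, 1L, 0L)
  }
  if (unplaced > 0)
    warning(unplaced, " missing call(s) at unplaced sites left missing")
  list(gt = pol, imputed = imputed)
}

#' Collapse samples into haplotypes
#'
#' Samples with identical call strings share a haplotype. With missing calls
#' present, a sample merges into an existing haplotype only when every
#' non-missing call agrees (wildcard-consistent merge, first match wins in
#' sample order).
#'
#' @param x a [variant_table()] or samples-by-sites matrix.
#' @return data.frame haplotype, n_carriers, carriers (comma-separated),
#'   ordered by first carrier.
#' @export
collapse_haplotypes <- function(x) {
  gt <- as_gt_matrix(x)
  samples <- rownames(gt)
  reps <- list()   # haplotype representative call vectors (may hold NA)
  members <- list()
  for (s in samples) {
    v <- gt[s, ]
    hit <- 0L
    for (h in seq_along(reps)) {
      r <- reps[[h]]
      ok <- !any(!is.na(v) & !is.na(r) & v != r)
      if (ok) { hit <- h; break }
    }
    if (hit == 0L) {
      reps[[length(reps) + 1]] <- v
      members[[length(members) + 1]] <- s
    } else {
      r <- reps[[hit]]
      r[is.na(r)] <- v[is.na(r)]
      reps[[hit]] <- r
      members[[hit]] <- c(members[[hit]], s)
    }
  }
  data.frame(haplotype = sprintf("HT%02d", seq_along(members)),
             n_carriers = lengths(members),
             carriers = vapply(members, paste, "", collapse = ","),
             stringsAsFactors = FALSE)
}

#' Hierarchical haplogroup names
#'
#' Names the two basal clades of the rooted tree after `scheme$basal`
#' (assigned in order of clade size, largest first; ties broken by the
#' lexicographically smallest member), then walks down the tree alternating
#' letter and number levels: children of a basal clade get letters (A, B,
#' ...), their children numbers (A1, A2, ...), the next level opens a new
#' letter segment after a dot (A2.B), then numbers again (A2.B1), and so on.
#' Child order at every level is clade size descending, then smallest member
#' id - so names are deterministic given tree and scheme.
#'
#' @param tree a [build_parsimony_tree()] result.
#' @param scheme list with `prefix` (default `"Y"`) and `basal` (character
#'   names for the basal clades, default `c("A", "B")`).
#' @return named character vector: internal node label -> haplogroup name.
#' @export
assign_haplogroups <- function(tree, scheme = list(prefix = "Y",
                                                   basal = c("A", "B"))) {
  stopifnot(inherits(tree, "haplotype_tree"))
  phy <- tree$phylo
  clades <- tree$clades
  kids_of <- function(lbl) {
    C <- clades[[lbl]]
    direct <- character(0)
    for (nm in names(clades)) {
      if (nm == lbl) next
      S <- clades[[nm]]
      if (length(S) < length(C) && all(S %in% C)) {
        # direct child iff no intermediate clade
        inter <- FALSE
        for (mm in names(clades)) {
          if (mm %in% c(lbl, nm)) next
          M <- clades[[mm]]
          if (length(M) < length(C) && length(M) > length(S) &&
              all(M %in% C) && all(S %in% M)) { inter <- TRUE; break }
        }
        if (!inter) direct <- c(direct, nm)
      }
    }
    direct[order(-lengths(clades[direct]),
                 vapply(clades[direct], function(s) sort(s)[1], ""))]
  }

  names_out <- character(0)
  walk <- function(lbl, name, letter_level, sep) {
    names_out[lbl] <<- name
    kids <- kids_of(lbl)
    for (i in seq_along(kids)) {
      child_name <- if (letter_level) paste0(name, sep, LETTERS[i])
                    else paste0(name, i)
      walk(kids[i], child_name, !letter_level, if (letter_level) "." else sep)
    }
  }

  basal <- kids_of("rt")
  if (!length(basal)) stop("tree has no internal structure below the root")
  pre <- if (nzchar(scheme$prefix)) paste0(scheme$prefix, "-") else ""
  for (i in seq_along(basal)) {
    nm <- if (i <= length(scheme$basal)) scheme$basal[i] else LETTERS[i]
    walk(basal[i], paste0(pre, nm), TRUE, "-")
  }
  names_out
}
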