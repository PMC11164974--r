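# exhaustive maximum parsimony over all topologies (independent oracle)
oracle_min_parsimony <- function(gt) {
  trees <- phangorn::allTrees(nrow(gt), rooted = FALSE,
                              tip.label = rownames(gt))
  dat <- phangorn::phyDat(gt, type = "USER", levels = c(0, 1))
  min(vapply(trees, function(tr) phangorn::parsimony(tr, dat), 0))
}

# coalescent ingroup plus a distant outgroup, for simulation fixtures
coal_with_outgroup <- function(n, root_age = 20000, out_branch = 60000) {
  core <- ape::rcoal(n)
  core$edge.length <- core$edge.length * root_age /
    max(ape::node.depth.edgelength(core))
  txt <- sub(";$", "", ape::write.tree(core))
  ape::read.tree(text = sprintf("(%s:0,out:%d);", txt, as.integer(out_branch)))
}

test_that("identical samples collapse to a zero-length split", {
  gt <- clade_matrix(c("a", "b", "c"), list(c("a", "b")), per_clade = 3,
                     outgroup = "out")
  tree <- build_parsimony_tree(gt, outgroup = "out")
  phy <- tree$phylo
  pend <- phy$edge.length[match(match(c("a", "b"), phy$tip.label),
                                phy$edge[, 2])]
  expect_equal(pend, c(0, 0))
  expect_equal(nrow(collapse_haplotypes(gt[c("a", "b", "c"), ])), 2)
})

test_that("a 4-sample perfect matrix is recovered with score equal to its sites", {
  ids <- c("a", "b", "c", "d")
  gt <- clade_matrix(ids, list("a", "b", "c", "d", c("a", "b"), c("c", "d")),
                     outgroup = "out")
  tree <- build_parsimony_tree(gt, outgroup = "out")
  expect_equal(tree$score, 6)
  expect_equal(length(tree$recurrent_sites), 0)
  expect_setequal(vapply(tree$clades, paste, "", collapse = ","),
                  c("a,b,c,d", "a,b", "c,d"))
  expect_equal(tree$score, oracle_min_parsimony(gt))

  # one homoplastic site: it needs two changes on the (a,b)(c,d) topology,
  # and exhaustive search confirms no topology does better than 8 in total
  gt2 <- cbind(gt, hom = as.integer(rownames(gt) %in% c("a", "c")))
  tree2 <- build_parsimony_tree(gt2, outgroup = "out")
  expect_equal(tree2$recurrent_sites, "hom")
  expect_equal(tree2$score, oracle_min_parsimony(gt2))
  expect_equal(tree2$score, 8)
})

test_that("greedy construction matches exhaustive search on small noisy matrices", {
  set.seed(61)
  for (rep in 1:5) {
    core <- ape::rtree(6)
    core$edge.length <- runif(nrow(core$edge), 500, 3000)
    clades <- lapply(seq_len(nrow(core$edge)), function(e)
      msytools:::tips_below_edge(core, e))
    gt <- clade_matrix(core$tip.label, clades, per_clade = 2, outgroup = "out")
    # inject one homoplastic site across two disjoint cherries if available
    disj <- NULL
    for (i in seq_along(clades)) for (j in seq_along(clades)) {
      u <- union(clades[[i]], clades[[j]])
      if (i < j && !length(intersect(clades[[i]], clades[[j]])) &&
          length(u) < 6 && !any(vapply(clades, setequal, TRUE, y = u)))
        disj <- c(i, j)
    }
    if (!is.null(disj))
      gt <- cbind(gt, hom = as.integer(rownames(gt) %in%
                                         union(clades[[disj[1]]], clades[[disj[2]]])))
    tree <- build_parsimony_tree(gt, outgroup = "out")
    expect_equal(tree$score, oracle_min_parsimony(gt))
  }
})

test_that("artifact-free simulations are rebuilt exactly up to 64 tips", {
  set.seed(71)
  for (n in c(8, 16, 32, 64)) {
    phy <- coal_with_outgroup(n)
    sim <- simulate_tree_snps(tree_sim_params(tree = phy, mu_year = 2e-9,
                                              L = 1234870,
                                              seed = 1000 + n))
    tree <- build_parsimony_tree(sim$gt, outgroup = "out")
    expect_equal(length(tree$recurrent_sites), 0)
    # parsimony score equals the number of segregating sites
    expect_equal(tree$score, ncol(sim$gt))
    # the clade family equals the family of mutated true branches
    truth_clades <- unique(lapply(sim$truth$edge, function(e)
      sort(msytools:::tips_below_edge(sim$tree, e))))
    truth_clades <- Filter(function(s) length(s) >= 2 && !"out" %in% s,
                           truth_clades)
    got <- lapply(tree$clades[names(tree$clades) != "rt"], sort)
    expect_setequal(vapply(truth_clades, paste, "", collapse = ","),
                    vapply(got, paste, "", collapse = ","))
  }
})

test_that("the built topology matches the generating tree (RF = 0)", {
  phy <- example_dated_tree(include_outgroup = TRUE)
  sim <- simulate_tree_snps(tree_sim_params(tree = phy, mu_year = 2e-9,
                                            L = 1234870, seed = 5))
  tree <- build_parsimony_tree(sim$gt, outgroup = "out")
  ing <- ape::drop.tip(tree$phylo, "out")
  truth <- example_dated_tree(include_outgroup = FALSE)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(ing), ape::unroot(truth))), 0)
})

test_that("variant placement finds branches, flags recurrents, honors truth", {
  ids <- c("a", "b", "c", "d", "e", "f")
  clades <- list(c("a", "b"), c("c", "d"), c("a", "b", "c", "d"), "e", "f")
  gt <- clade_matrix(ids, clades, per_clade = 2, outgroup = "out")
  tree <- build_parsimony_tree(gt, outgroup = "out")
  pl <- place_variants(gt, tree)
  expect_true(all(pl$label == "clean"))
  # a site carried by one clade maps to that clade's branch
  ab_branch <- pl$branch[1]
  expect_setequal(tree$clades[[ab_branch]], c("a", "b"))
  # a site carried by two disjoint clades is recurrent
  gt2 <- cbind(gt, x = as.integer(rownames(gt) %in% c("a", "b", "e")))
  tree2 <- build_parsimony_tree(gt, outgroup = "out")
  pl2 <- place_variants(gt2, tree2)
  expect_equal(pl2$label[pl2$site == "x"], "recurrent")
})

test_that("injected recurrent sites are all and only the ones labeled", {
  sim <- simulate_tree_snps(tree_sim_params(tree = example_dated_tree(TRUE),
                                            mu_year = 2e-9, L = 1234870,
                                            n_recurrent = 12, seed = 19))
  tree <- build_parsimony_tree(sim$gt, outgroup = "out")
  pl <- place_variants(sim$gt, tree)
  injected <- sim$truth$site[sim$truth$type == "recurrent"]
  expect_setequal(pl$site[pl$label == "recurrent"], injected)
  # conservation: placed + recurrent = input sites
  expect_equal(sum(!is.na(pl$branch)) + sum(pl$label == "recurrent"),
               nrow(pl))
})

test_that("single-sample derived calls with allele conflict are flagged", {
  fxgt <- clade_matrix(c("a", "b", "c"), list(c("a", "b")), per_clade = 2,
                       outgroup = "out")
  fxgt <- cbind(fxgt, priv = c(1L, 0L, 0L, 0L))
  rr <- (fxgt == 0L) * 5L
  ar <- (fxgt == 1L) * 5L
  rr["a", "priv"] <- 2L   # both alleles supported in the only carrier
  vt <- variant_table(data.frame(contig = "c", pos = seq_len(ncol(fxgt)) + 60,
                                 ref = "A", alt = "T"), fxgt, rr, ar)
  tree <- build_parsimony_tree(vt, outgroup = "out")
  pl <- place_variants(vt, tree)
  expect_equal(pl$label[pl$site == "priv"], "single-sample-heterozygous")
  # external annotation overrides
  pl2 <- place_variants(vt, tree, external_flags = c(priv = "repetitive"))
  expect_equal(pl2$label[pl2$site == "priv"], "flagged-external:repetitive")
})

test_that("phylogeny-guided imputation restores injected missing calls exactly", {
  sim <- simulate_tree_snps(tree_sim_params(tree = example_dated_tree(TRUE),
                                            mu_year = 2e-9, L = 1234870,
                                            missing_rate = 0.10, seed = 23))
  tree <- build_parsimony_tree(sim$gt, outgroup = "out")
  pl <- place_variants(sim$gt, tree)
  imp <- suppressWarnings(impute_missing(sim$gt, tree, pl))
  # expected calls: the clean matrix, polarized the same way the tree was
  # (restrict to sites where the outgroup call survived, so the tree's
  # polarization is the outgroup's and not a majority vote)
  flip <- sim$gt_clean["out", ] == 1L
  expected <- sim$gt_clean
  expected[, flip] <- 1L - expected[, flip]
  # sites whose observed carriers identify the mutated branch exactly are
  # imputed perfectly; sites where missingness hides every carrier of a
  # nested clade are inherently ambiguous and excluded from the exact check
  true_carriers <- lapply(seq_len(nrow(sim$truth)), function(i)
    setdiff(msytools:::tips_below_edge(sim$tree, sim$truth$edge[i]), "out"))
  names(true_carriers) <- sim$truth$site
  exact <- vapply(colnames(sim$gt), function(s) {
    br <- pl$branch[pl$site == s]
    if (is.na(br) || is.na(sim$gt["out", s])) return(FALSE)
    clade <- if (br %in% names(tree$clades)) tree$clades[[br]] else br
    tc <- true_carriers[[s]]
    if (flip[s]) tc <- setdiff(tree$ingroup, tc)
    setequal(clade, tc)
  }, TRUE)
  got <- imp$gt[tree$ingroup, exact]
  expect_false(anyNA(got))
  expect_equal(got, expected[tree$ingroup, exact])
  expect_gt(mean(exact), 0.8)          # most sites are exactly identifiable
  expect_true(any(imp$imputed))
  # and overall, imputed calls almost always match the clean truth
  imputed_calls <- imp$imputed[tree$ingroup, ] & !is.na(imp$gt[tree$ingroup, ])
  agree <- imp$gt[tree$ingroup, ][imputed_calls] ==
    expected[tree$ingroup, ][imputed_calls]
  expect_gt(mean(agree), 0.95)
  # directional examples: inside the clade -> derived, outside -> ancestral
  site <- sim$truth$site[match(TRUE, !is.na(sim$truth$edge))]
  carriers <- msytools:::tips_below_edge(sim$tree, sim$truth$edge[1])
  inside <- intersect(tree$ingroup, carriers)[1]
  outside <- setdiff(tree$ingroup, carriers)[1]
  g <- sim$gt; g[inside, site] <- NA; g[outside, site] <- NA
  imp2 <- impute_missing(g, tree)
  expect_equal(unname(imp2$gt[inside, site]), 1L)
  expect_equal(unname(imp2$gt[outside, site]), 0L)
})

test_that("haplotype collapsing counts distinct call strings", {
  gt <- matrix(0L, 4, 3, dimnames = list(letters[1:4], NULL))
  expect_equal(nrow(collapse_haplotypes(gt)), 1)
  gt2 <- diag(4L); rownames(gt2) <- letters[1:4]
  expect_equal(nrow(collapse_haplotypes(gt2)), 4)
  # 55 samples built from a 50-haplotype truth with 5 known duplicates
  base <- diag(50L)
  rownames(base) <- sprintf("h%02d", 1:50)
  dup <- base[c(1, 10, 20, 30, 40), ]
  rownames(dup) <- sprintf("dup%d", 1:5)
  gt3 <- rbind(base, dup)
  ht <- collapse_haplotypes(gt3)
  expect_equal(nrow(ht), 50)
  expect_equal(sum(ht$n_carriers), 55)
})

test_that("haplogroup names follow the hierarchical letter/number scheme", {
  a <- sprintf("a%02d", 1:13)
  b <- c("b1", "b2")
  nn <- c("n1", "n2", "n3", "n4")
  ids <- c(a, b, nn)
  clades <- list(c(a, b),                    # EB basal
                 nn,                         # NA basal
                 a,                          # EB-A
                 b,                          # EB-B
                 a[1:7],                     # EB-A1
                 a[8:13],                    # EB-A2
                 a[8:10],                    # EB-A2.A
                 a[11:13],                   # EB-A2.B
                 a[11:12],                   # EB-A2.B1
                 c("n1", "n2"), c("n3", "n4"))
  gt <- clade_matrix(ids, clades, per_clade = 1, outgroup = "out")
  tree <- build_parsimony_tree(gt, outgroup = "out")
  hg <- assign_haplogroups(tree, scheme = list(prefix = "Y",
                                               basal = c("EB", "NA")))
  by_clade <- function(members) {
    for (nm in names(tree$clades))
      if (setequal(tree$clades[[nm]], members)) return(unname(hg[nm]))
    NA_character_
  }
  expect_equal(by_clade(c(a, b)), "Y-EB")
  expect_equal(by_clade(nn), "Y-NA")
  expect_equal(by_clade(a), "Y-EB-A")
  expect_equal(by_clade(b), "Y-EB-B")
  expect_equal(by_clade(a[1:7]), "Y-EB-A1")
  expect_equal(by_clade(a[8:13]), "Y-EB-A2")
  expect_equal(by_clade(a[11:13]), "Y-EB-A2.B")
  expect_equal(by_clade(a[11:12]), "Y-EB-A2.B1")

  # relabeling the samples changes leaf attachment, not the name structure
  ids2 <- setNames(sprintf("z%02d", seq_along(rownames(gt))), rownames(gt))
  gt2 <- gt; rownames(gt2) <- ids2[rownames(gt)]
  tree2 <- build_parsimony_tree(gt2, outgroup = ids2[["out"]])
  hg2 <- assign_haplogroups(tree2, scheme = list(prefix = "Y",
                                                 basal = c("EB", "NA")))
  expect_setequal(unname(hg2), unname(hg))
})
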