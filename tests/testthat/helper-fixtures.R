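# shared fixture builders; everything is generated in code, no files

# genotype matrix realizing a given clade structure: one site per clade,
# repeated `per_clade` times, over samples `ids`; optional outgroup row of 0s
clade_matrix <- function(ids, clades, per_clade = 1, outgroup = NULL) {
  rows <- c(ids, outgroup)
  cols <- list()
  nm <- character(0)
  for (i in seq_along(clades)) {
    for (r in seq_len(per_clade)) {
      v <- as.integer(rows %in% clades[[i]])
      cols[[length(cols) + 1]] <- v
      nm <- c(nm, sprintf("c%02d_%d", i, r))
    }
  }
  gt <- do.call(cbind, cols)
  rownames(gt) <- rows
  colnames(gt) <- nm
  gt
}

# the worked conflict/depth/region fixture used by the filter-oracle tests:
# 4 samples in known depth groups, 8 engineered sites whose fate under each
# filter is hand-computed in the tests
filter_fixture <- function() {
  samples <- c("s1", "s2", "s3", "s4")
  groups <- c(s1 = "vLowDP", s2 = "LowDP", s3 = "LowDP", s4 = "ModDP")
  nsite <- 8
  sites <- data.frame(contig = "ctg1", pos = c(60, 80, 100, 120, 140, 160, 180, 200),
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  gt <- matrix(0L, 4, nsite, dimnames = list(samples, NULL))
  # ascertainment in-range depths: vLow 2, Low 5, Mod 20
  ref_reads <- matrix(rep(c(2L, 5L, 5L, 20L), nsite), 4, nsite)
  alt_reads <- matrix(0L, 4, nsite)
  dimnames(ref_reads) <- dimnames(alt_reads) <- dimnames(gt)

  mk_conflict <- function(j, who) {
    ref_reads[who, j] <<- ref_reads[who, j] - 1L
    alt_reads[who, j] <<- 1L
    gt[who, j] <<- 1L
  }
  # site 1: clean, one derived call without conflict
  gt["s2", 1] <- 1L; ref_reads["s2", 1] <- 0L; alt_reads["s2", 1] <- 5L
  # site 2: 3 conflicted samples (> 2, still <= 5) plus one clean derived
  mk_conflict(2, c("s2", "s3", "s4"))
  gt["s1", 2] <- 1L; ref_reads["s1", 2] <- 0L; alt_reads["s1", 2] <- 2L
  # site 3: one missing call
  gt["s3", 3] <- NA_integer_; ref_reads["s3", 3] <- 0L
  # site 4: s1 depth 3 (outside vLow ascertainment 1.5-2.5, inside
  # genotyping 2-8)
  ref_reads["s1", 4] <- 3L
  # site 5: s4 depth 35 (outside Mod ranges in both policies)
  ref_reads["s4", 5] <- 35L
  # site 6: clean, derived in two samples
  gt[c("s2", "s4"), 6] <- 1L
  ref_reads[c("s2", "s4"), 6] <- 0L; alt_reads[c("s2", "s4"), 6] <- c(5L, 20L)
  # site 7: LowDP group mean depth 2.5 (s2 = 2, s3 = 3): below genotyping
  # lo = 3, below ascertainment lo = 3 too (per-sample: s2 = 2 out of range)
  ref_reads["s2", 7] <- 2L; ref_reads["s3", 7] <- 3L
  # site 8: boundary depths, all exactly at range edges: vLow 2.5, Low 7, Mod 30
  ref_reads[, 8] <- c(2L, 7L, 7L, 30L)
  # (2.5 not representable with integer reads; use 2 for s1: inside both)
  ref_reads["s1", 8] <- 2L

  list(vt = variant_table(sites, gt, ref_reads, alt_reads), groups = groups)
}

# independent OLS via normal equations, with hat-matrix studentization
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  H <- X %*% XtXi %*% t(X)
  r <- y - X %*% beta
  sigma2 <- sum(r^2) / (length(y) - 2)
  list(residual = as.numeric(r),
       std_residual = as.numeric(r / sqrt(sigma2 * (1 - diag(H)))))
}

# contig coverage fixture: 100 autosome-like points on the identity line
# (spread over 50-100% so the fit is anchored) and 10 Y-like points at
# (95, 3); deterministic
regression_fixture <- function() {
  set.seed(421)
  n_auto <- 100
  x <- runif(n_auto, 50, 100)
  data.frame(
    contig = c(sprintf("a%03d", 1:n_auto), sprintf("y%02d", 1:10)),
    length = 1000L,
    male_mean_pct = c(x, rep(95, 10)),
    female_mean_pct = c(x + runif(n_auto, -1, 1), rep(3, 10)),
    mf_depth_ratio = 1,
    stringsAsFactors = FALSE)
}
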