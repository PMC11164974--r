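test_that("autosomal selection applies the 75% and ratio-0.01 rules", {
  tab <- data.frame(contig = c("a", "b", "c", "d"),
                    male_mean_pct = c(100, 74.9, 100, 80),
                    female_mean_pct = c(100, 100, 100, 80),
                    mf_depth_ratio = c(1.000, 1.000, 1.02, 0.995))
  expect_setequal(select_autosomal_contigs(tab), c("a", "d"))
  none <- tab[tab$contig == "c", ]
  expect_error(select_autosomal_contigs(none), "normalization impossible")
})

test_that("candidate regression matches the closed-form OLS oracle", {
  tab <- regression_fixture()
  res <- classify_candidate_contigs(tab, residual_cutoff = -35)
  oracle <- ols_oracle(tab$male_mean_pct, tab$female_mean_pct)
  expect_equal(res$residual, oracle$residual, tolerance = 1e-9)
  expect_equal(res$std_residual, oracle$std_residual, tolerance = 1e-9)
  expect_setequal(res$contig[res$candidate], sprintf("y%02d", 1:10))
})

test_that("contigs on or above the fitted line are never candidates", {
  # identity-line contigs: all residuals zero, no candidate
  tab <- data.frame(contig = letters[1:6],
                    male_mean_pct = c(90, 92, 94, 96, 98, 100),
                    female_mean_pct = c(90, 92, 94, 96, 98, 100),
                    mf_depth_ratio = 1)
  res <- classify_candidate_contigs(tab)
  expect_true(all(!res$candidate))
  # a contig above the line has a positive residual: sign condition blocks it
  tab$female_mean_pct[3] <- 99.5
  res <- classify_candidate_contigs(tab)
  expect_false(res$candidate[3])
  expect_gt(res$residual[3], 0)
  expect_error(classify_candidate_contigs(tab[1:2, ]), "at least 3")
})

test_that("depth mode is exact on constant data and scale-equivariant", {
  expect_equal(depth_mode(rep(30, 100)), 30)
  x <- c(rep(10, 50), rep(11, 20), rep(30, 5))
  expect_equal(depth_mode(2 * x), 2 * depth_mode(x))
})

test_that("autosomal mode recovers the diploid depth within 5% under noise", {
  plan <- data.frame(contig = "a1", label = "autosomal", length = 500000L)
  p <- coverage_sim_params(n_males = 1, n_females = 1, contig_plan = plan,
                           depth_meanlog = log(30), depth_sdlog = 0,
                           dispersion = 0.1, seed = 41)
  sim <- simulate_coverage_dataset(p)   # 10^4 windows per sample
  norm <- compute_normalization(sim$windows, sim$samples, "a1", character(0))
  for (s in sim$samples$sample) {
    truth <- sim$samples$diploid_depth[sim$samples$sample == s]
    expect_lt(abs(norm$autosomal_mode[[s]] - truth) / truth, 0.05)
  }
})

test_that("normalized scY windows sit at 0.5 for a noise-free male", {
  plan <- data.frame(contig = c("a1", "y1"), label = c("autosomal", "scY"),
                     length = c(5000L, 1000L))
  p <- coverage_sim_params(n_males = 1, n_females = 1, contig_plan = plan,
                           depth_meanlog = log(30), depth_sdlog = 0,
                           dispersion = 0, background = 0, seed = 1)
  sim <- simulate_coverage_dataset(p)
  norm <- compute_normalization(sim$windows, sim$samples, "a1", "y1")
  male <- sim$samples$sample[sim$samples$sex == "male"]
  expect_equal(unname(norm$autosomal_mode[male]), 30)
  yw <- sim$windows[sim$windows$contig == "y1" & sim$windows$sample == male, ]
  r <- yw$mean_depth / norm$autosomal_mode[[male]]
  expect_equal(r, rep(0.5, length(r)))
})

# independent evaluation of the two-hypothesis window model
p_msy_oracle <- function(m, f, b, sigma = 0.15, cmax = 10) {
  lmsy <- sum(dnorm(m, (1:cmax) / 2, sigma)) / cmax * dnorm(f, b, sigma)
  lnon <- (dnorm(m, 1, sigma) * dnorm(f, 1, sigma) +
           dnorm(m, 0.5, sigma) * dnorm(f, 1, sigma) +
           dnorm(m, 0, sigma) * dnorm(f, 0, sigma)) / 3
  lmsy / (lmsy + lnon)
}

fake_windows <- function(m_bar, f_bar) {
  # one sample of each sex, already on the normalized scale (mode = 1)
  rbind(data.frame(contig = "y", start = seq_along(m_bar) * 50 - 50,
                   end = seq_along(m_bar) * 50, sample = "M01",
                   mean_depth = m_bar),
        data.frame(contig = "y", start = seq_along(m_bar) * 50 - 50,
                   end = seq_along(m_bar) * 50, sample = "F01",
                   mean_depth = f_bar))
}

test_that("window classification reproduces the depth-model decision boundary", {
  samples <- data.frame(sample = c("M01", "F01"), sex = c("male", "female"))
  norm <- list(autosomal_mode = c(M01 = 1, F01 = 1), background = 0.02)
  w <- fake_windows(c(0.5, 1.0, 1.5, 0.0), c(0.0, 1.0, 0.02, 0.0))
  cls <- classify_windows(w, samples, norm)
  expect_equal(cls$class, c("scY", "nonY", "mcY", "nonY"))
  expect_gt(cls$p_msy[1], 0.98)   # haploid male / absent female is unambiguous
  expect_equal(cls$copy_number[3], 3L)
  # probabilities agree with the independent oracle
  for (i in 1:4)
    expect_equal(cls$p_msy[i],
                 p_msy_oracle(cls$m_bar[i], cls$f_bar[i], 0.02),
                 tolerance = 1e-12)
})

test_that("classification is invariant to rescaling one sample's raw depths", {
  samples <- data.frame(sample = c("M01", "F01"), sex = c("male", "female"))
  w <- fake_windows(c(0.5, 1.0, 1.5), c(0.02, 1.0, 0.02))
  norm1 <- list(autosomal_mode = c(M01 = 1, F01 = 1), background = 0.02)
  w2 <- w
  w2$mean_depth[w2$sample == "M01"] <- w2$mean_depth[w2$sample == "M01"] * 7
  norm2 <- list(autosomal_mode = c(M01 = 7, F01 = 1), background = 0.02)
  expect_equal(classify_windows(w, samples, norm1),
               classify_windows(w2, samples, norm2))
})

test_that("window classes are accurate on synthetic data at default noise", {
  p <- coverage_sim_params(seed = 7)
  sim <- simulate_coverage_dataset(p)
  summ <- contig_coverage_summary(sim$windows, sim$samples)
  cand <- classify_candidate_contigs(summ)
  autos <- select_autosomal_contigs(cand)
  ycand <- cand$contig[cand$candidate]
  norm <- compute_normalization(sim$windows, sim$samples, autos, ycand)
  eval_contigs <- c(ycand, "junk01", autos[1:3])
  cls <- classify_windows(sim$windows[sim$windows$contig %in% eval_contigs, ],
                          sim$samples, norm)
  truth <- sim$truth[match(paste(cls$contig, cls$start),
                           paste(sim$truth$contig, sim$truth$start)), ]
  # scY vs nonY accuracy (nonY truth = autosomal/X/unmapped labels)
  is_scy_truth <- truth$label == "scY"
  is_nony_truth <- truth$label %in% c("autosomal", "X", "unmapped")
  acc <- (sum(cls$class == "scY" & is_scy_truth) +
          sum(cls$class == "nonY" & is_nony_truth)) /
    sum(is_scy_truth | is_nony_truth)
  expect_gte(acc, 0.99)
  # mcY copy-number accuracy
  mc <- truth$label == "mcY"
  expect_gte(mean(cls$class[mc] == "mcY" & cls$copy_number[mc] == truth$copies[mc]),
             0.95)
})

test_that("mostly-nonY contigs are discarded and bp totals add up", {
  cls <- data.frame(contig = rep(c("keep", "drop"), each = 10),
                    start = rep(seq(0, 450, 50), 2),
                    end = rep(seq(50, 500, 50), 2),
                    class = c(rep("scY", 10), rep("nonY", 6), rep("scY", 4)),
                    stringsAsFactors = FALSE)
  s <- summarize_contigs(cls)
  expect_true(s$contigs$retained[s$contigs$contig == "keep"])
  expect_false(s$contigs$retained[s$contigs$contig == "drop"])
  expect_equal(unname(s$totals["scY_bp"]), 500)
})

test_that("recovered scY length tracks the generator truth within 2%", {
  p <- coverage_sim_params(seed = 13)
  sim <- simulate_coverage_dataset(p)
  summ <- contig_coverage_summary(sim$windows, sim$samples)
  cand <- classify_candidate_contigs(summ)
  autos <- select_autosomal_contigs(cand)
  ycand <- cand$contig[cand$candidate]
  norm <- compute_normalization(sim$windows, sim$samples, autos, ycand)
  cls <- classify_windows(sim$windows[sim$windows$contig %in% ycand, ],
                          sim$samples, norm)
  got <- summarize_contigs(cls)$totals["scY_bp"]
  truth_bp <- sum((sim$truth$end - sim$truth$start)[sim$truth$label == "scY"])
  expect_lt(abs(got - truth_bp) / truth_bp, 0.02)
})
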