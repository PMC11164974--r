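#' Per-contig sex-stratified coverage summary
#'
#' Reduces a long window-depth table to one row per contig with the mean
#' percent of windows covered in males and in females, plus the
#' male-to-female relative-depth ratio used by the autosomal selection rule.
#' Percent covered counts windows whose mean depth reaches `min_depth`.
#' Before taking the sex ratio, each sample's per-contig mean depths are
#' divided by their median across contigs - the diploid level, since
#' autosomal contigs dominate any assembly - so that cohort depth
#' differences cancel.
#'
#' @param windows data.frame contig, start, end, sample, mean_depth.
#' @param samples data.frame with columns `sample` and `sex`
#'   (`"male"`/`"female"`).
#' @param min_depth window mean depth at which a window counts as covered.
#' @return data.frame contig, length, male_mean_pct, female_mean_pct,
#'   mf_depth_ratio.
#' @export
contig_coverage_summary <- function(windows, samples, min_depth = 1) {
  stopifnot(all(c("contig", "start", "end", "sample", "mean_depth") %in% names(windows)),
            all(c("sample", "sex") %in% names(samples)))
  sex <- samples$sex[match(windows$sample, samples$sample)]
  if (anyNA(sex)) stop("window table contains samples absent from the sample table")

  covered <- windows$mean_depth >= min_depth
  key <- paste(windows$contig, windows$sample, sep = "\r")
  pct <- 100 * tapply(covered, key, mean)
  md <- tapply(windows$mean_depth, key, mean)
  ks <- strsplit(names(pct), "\r", fixed = TRUE)
  per <- data.frame(contig = vapply(ks, `[`, "", 1),
                    sample = vapply(ks, `[`, "", 2),
                    pct = as.numeric(pct), mean_depth = as.numeric(md),
                    stringsAsFactors = FALSE)
  scale <- tapply(per$mean_depth, per$sample, stats::median)
  per$rel_depth <- per$mean_depth / scale[per$sample]
  per$sex <- samples$sex[match(per$sample, samples$sample)]

  agg <- function(v, s, f) tapply(v[per$sex == s], per$contig[per$sex == s], f)
  contigs <- sort(unique(per$contig))
  lens <- tapply(windows$end, windows$contig, max)
  out <- data.frame(
    contig = contigs,
    length = as.integer(lens[contigs]),
    male_mean_pct = as.numeric(agg(per$pct, "male", mean)[contigs]),
    female_mean_pct = as.numeric(agg(per$pct, "female", mean)[contigs]),
    stringsAsFactors = FALSE)
  md <- agg(per$rel_depth, "male", mean)[contigs]
  fd <- agg(per$rel_depth, "female", mean)[contigs]
  out$mf_depth_ratio <- as.numeric(md / fd)
  rownames(out) <- NULL
  out
}

#' Select autosomal contigs for depth normalization
#'
#' A contig qualifies as autosomal when it is covered at least `min_pct`
#' percent in both sexes and its male-to-female mean coverage ratio deviates
#' from 1 by at most `ratio_tol`.
#'
#' @param summary a [contig_coverage_summary()] table (columns
#'   `male_mean_pct`, `female_mean_pct`, `mf_depth_ratio`).
#' @param min_pct minimum percent covered in each sex (default 75).
#' @param ratio_tol allowed |ratio - 1| (default 0.01).
#' @return character vector of autosomal contig ids.
#' @export
select_autosomal_contigs <- function(summary, min_pct = 75, ratio_tol = 0.01) {
  keep <- summary$male_mean_pct >= min_pct &
    summary$female_mean_pct >= min_pct &
    abs(summary$mf_depth_ratio - 1) <= ratio_tol
  keep[is.na(keep)] <- FALSE
  if (!any(keep))
    stop("no contig passes the autosomal criteria; normalization impossible")
  summary$contig[keep]
}

#' Flag Y-candidate contigs by regression residuals
#'
#' Fits an ordinary least squares regression of female mean coverage percent
#' on male mean coverage percent over all contigs. Contigs far below the
#' fitted line - much less female coverage than their male coverage predicts -
#' are Y candidates: raw residual below `residual_cutoff` and internally
#' studentized residual negative.
#'
#' @param summary a [contig_coverage_summary()] table.
#' @param residual_cutoff raw-residual threshold (default -35, percent scale).
#' @param response which variable is the regression response; the default
#'   `"female"` regresses female on male.
#' @return the summary with `residual`, `std_residual` and `candidate`
#'   columns appended.
#' @export
classify_candidate_contigs <- function(summary, residual_cutoff = -35,
                                       response = c("female", "male")) {
  response <- match.arg(response)
  if (nrow(summary) < 3) stop("need at least 3 contigs to fit the regression")
  x <- if (response == "female") summary$male_mean_pct else summary$female_mean_pct
  y <- if (response == "female") summary$female_mean_pct else summary$male_mean_pct
  if (stats::var(x) == 0) stop("zero variance in the regression predictor")
  fit <- stats::lm(y ~ x)
  summary$residual <- as.numeric(stats::residuals(fit))
  summary$std_residual <- as.numeric(stats::rstandard(fit))
  summary$candidate <- summary$residual < residual_cutoff & summary$std_residual < 0
  summary
}

#' Histogram-mode estimate of a depth distribution
#'
#' Bins the values at fixed width and returns the midpoint of the fullest
#' bin. Deterministic and robust to the long right tail of window depth
#' distributions.
#'
#' @param x numeric values.
#' @param binwidth bin width in the units of `x` (1 depth unit for raw
#'   depths; use a finer width for normalized depths).
#' @return the mode estimate (midpoint of the argmax bin).
#' @export
depth_mode <- function(x, binwidth = 1) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite values")
  breaks <- seq(floor(min(x) / binwidth) * binwidth - binwidth / 2,
                ceiling(max(x) / binwidth) * binwidth + binwidth / 2,
                by = binwidth)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Per-sample normalization constants
#'
#' For every sample, the mode of its window mean depths over the autosomal
#' contigs estimates the diploid depth; dividing by it puts windows on a
#' scale where 1.0 is diploid. For each female, the mode of her normalized
#' depths over the Y-candidate contigs estimates the Y background; their
#' mean enters the window model as the female background level.
#'
#' @param windows long window-depth table.
#' @param samples sample table with `sample`, `sex`.
#' @param autosomal_contigs,y_contigs contig id vectors.
#' @param binwidth histogram bin width for the autosomal mode (depth units).
#' @param bg_binwidth bin width for the female background mode (normalized
#'   units, default 0.02).
#' @return list with `autosomal_mode` (named per-sample vector),
#'   `female_background` (named per-female vector) and `background` (scalar
#'   mean used by the window model).
#' @export
compute_normalization <- function(windows, samples, autosomal_contigs,
                                  y_contigs, binwidth = 1, bg_binwidth = 0.02) {
  if (!length(autosomal_contigs)) stop("empty autosomal contig set")
  aw <- windows[windows$contig %in% autosomal_contigs, ]
  if (!nrow(aw)) stop("no windows on the autosomal contigs")
  mode_by <- tapply(aw$mean_depth, aw$sample, depth_mode, binwidth = binwidth)
  autosomal_mode <- as.numeric(mode_by)
  names(autosomal_mode) <- names(mode_by)
  if (any(autosomal_mode <= 0)) stop("non-positive autosomal mode")

  females <- samples$sample[samples$sex == "female"]
  female_background <- numeric(0)
  if (length(females) && length(y_contigs)) {
    yw <- windows[windows$contig %in% y_contigs & windows$sample %in% females, ]
    if (nrow(yw)) {
      norm <- yw$mean_depth / autosomal_mode[yw$sample]
      fb <- tapply(norm, yw$sample, depth_mode, binwidth = bg_binwidth)
      female_background <- as.numeric(fb)
      names(female_background) <- names(fb)
    }
  }
  list(autosomal_mode = autosomal_mode,
       female_background = female_background,
       background = if (length(female_background)) mean(female_background) else 0)
}

# log-likelihood of one depth hypothesis; rows = windows
hypothesis_loglik <- function(male_mat, female_mat, e_m, e_f, sigma_m, sigma_f,
                              per_sample) {
  if (per_sample) {
    rowSums(stats::dnorm(male_mat, e_m, sigma_m, log = TRUE)) +
      rowSums(stats::dnorm(female_mat, e_f, sigma_f, log = TRUE))
  } else {
    stats::dnorm(rowMeans(male_mat), e_m, sigma_m, log = TRUE) +
      stats::dnorm(rowMeans(female_mat), e_f, sigma_f, log = TRUE)
  }
}

logsumexp <- function(m) {
  # rowwise log-sum-exp of a matrix of log terms
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Classify 50-bp windows into scY, mcY and nonY
#'
#' Computes, for every window on the Y-candidate contigs, the probability of
#' being male-specific (MSY) under a two-hypothesis Gaussian depth model, and
#' splits MSY windows into single-copy (scY) and multi-copy (mcY) by the male
#' normalized depth.
#'
#' The MSY likelihood mixes copy numbers c = 1..`max_copies` with male depth
#' centered on c/2 and female depth on the background level; the nonY
#' likelihood mixes the autosomal (1, 1), X-like (0.5, 1) and unmapped (0, 0)
#' male/female signatures, all components with uniform priors. A window is
#' MSY when P(MSY) exceeds `p_cutoff`; MSY windows with mean male normalized
#' depth below `mcy_bound` are scY, the rest mcY with copy number
#' `round(2 * male mean)`. Windows with zero depth in every sample are
#' classified nonY (unmapped) with their probability reported.
#'
#' @param windows long window-depth table restricted to the contigs to
#'   classify.
#' @param samples sample table with `sample`, `sex`; at least one of each sex.
#' @param norm output of [compute_normalization()].
#' @param config a [pipeline_config()]; supplies `sigma_m`, `sigma_f`,
#'   `max_copies`, `p_msy_cutoff`, `mcy_bound`.
#' @param per_sample if `TRUE`, evaluate the likelihood per sample instead of
#'   on cross-sample mean depths.
#' @return data.frame contig, start, end, m_bar, f_bar, p_msy, class
#'   (`"scY"`, `"mcY"`, `"nonY"`), copy_number (NA outside mcY).
#' @export
classify_windows <- function(windows, samples, norm,
                             config = pipeline_config(), per_sample = FALSE) {
  males <- samples$sample[samples$sex == "male"]
  females <- samples$sample[samples$sex == "female"]
  if (!length(males) || !length(females))
    stop("need at least one male and one female")

  keys <- unique(windows[, c("contig", "start", "end")])
  keys <- keys[order(keys$contig, keys$start), ]
  wid <- match(paste(windows$contig, windows$start, sep = "\r"),
               paste(keys$contig, keys$start, sep = "\r"))
  nw <- nrow(keys)

  norm_depth <- windows$mean_depth / norm$autosomal_mode[windows$sample]
  male_mat <- matrix(NA_real_, nw, length(males), dimnames = list(NULL, males))
  female_mat <- matrix(NA_real_, nw, length(females), dimnames = list(NULL, females))
  im <- windows$sample %in% males
  male_mat[cbind(wid[im], match(windows$sample[im], males))] <- norm_depth[im]
  ifm <- windows$sample %in% females
  female_mat[cbind(wid[ifm], match(windows$sample[ifm], females))] <- norm_depth[ifm]
  if (anyNA(male_mat) || anyNA(female_mat))
    stop("every window needs a depth for every sample")

  sm <- config$sigma_m; sf <- config$sigma_f
  b <- norm$background
  cmax <- config$max_copies
  ll_msy <- sapply(seq_len(cmax), function(cc)
    hypothesis_loglik(male_mat, female_mat, cc / 2, b, sm, sf, per_sample) -
      log(cmax))
  ll_non <- sapply(list(c(1, 1), c(0.5, 1), c(0, 0)), function(e)
    hypothesis_loglik(male_mat, female_mat, e[1], e[2], sm, sf, per_sample) -
      log(3))
  if (nw == 1) { ll_msy <- matrix(ll_msy, 1); ll_non <- matrix(ll_non, 1) }
  lm_tot <- logsumexp(ll_msy)
  ln_tot <- logsumexp(ll_non)
  p_msy <- 1 / (1 + exp(ln_tot - lm_tot))

  m_bar <- rowMeans(male_mat)
  f_bar <- rowMeans(female_mat)
  all_zero <- m_bar == 0 & f_bar == 0
  cls <- ifelse(p_msy > config$p_msy_cutoff, "MSY", "nonY")
  cls[all_zero] <- "nonY"
  copy <- rep(NA_integer_, nw)
  is_msy <- cls == "MSY"
  cls[is_msy & m_bar < config$mcy_bound] <- "scY"
  mc <- is_msy & m_bar >= config$mcy_bound
  cls[mc] <- "mcY"
  copy[mc] <- pmax(2L, as.integer(round(2 * m_bar[mc])))

  data.frame(contig = keys$contig, start = keys$start, end = keys$end,
             m_bar = m_bar, f_bar = f_bar, p_msy = p_msy, class = cls,
             copy_number = copy, stringsAsFactors = FALSE, row.names = NULL)
}

#' Contig-level summary and discard rule
#'
#' Totals scY/mcY/nonY base pairs per contig and discards contigs that are
#' mostly nonY (more than `discard_fraction` of their window bp).
#'
#' @param classification a [classify_windows()] table.
#' @param discard_fraction nonY bp fraction above which a contig is dropped.
#' @return list with `contigs` (per-contig bp by class, nonY fraction,
#'   retained flag) and `totals` (global bp per class over retained contigs).
#' @export
summarize_contigs <- function(classification, discard_fraction = 0.5) {
  if (!nrow(classification)) stop("no classified windows")
  bp <- classification$end - classification$start
  per <- do.call(rbind, lapply(split(seq_len(nrow(classification)),
                                     classification$contig), function(i) {
    cl <- classification$class[i]
    data.frame(scY_bp = sum(bp[i][cl == "scY"]),
               mcY_bp = sum(bp[i][cl == "mcY"]),
               nonY_bp = sum(bp[i][cl == "nonY"]))
  }))
  per$contig <- rownames(per)
  total <- per$scY_bp + per$mcY_bp + per$nonY_bp
  per$nonY_fraction <- per$nonY_bp / total
  per$retained <- per$nonY_fraction <= discard_fraction
  rownames(per) <- NULL
  per <- per[, c("contig", "scY_bp", "mcY_bp", "nonY_bp", "nonY_fraction", "retained")]
  kept <- per[per$retained, ]
  list(contigs = per,
       totals = c(scY_bp = sum(kept$scY_bp), mcY_bp = sum(kept$mcY_bp),
                  nonY_bp = sum(kept$nonY_bp)))
}
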