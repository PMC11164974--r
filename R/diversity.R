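#' Segregating sites within a sample group
#'
#' Counts sites showing at least two distinct non-missing calls among the
#' group's samples; sites with fewer than two non-missing calls are skipped.
#'
#' @param x a [variant_table()] or samples-by-sites 0/1/NA matrix.
#' @param group character vector of sample ids (length >= 2).
#' @return integer count of segregating sites.
#' @export
segregating_sites <- function(x, group) {
  gt <- as_gt_matrix(x)
  if (length(group) < 2) stop("group needs at least 2 samples")
  missing <- setdiff(group, rownames(gt))
  if (length(missing)) stop("unknown sample(s): ", paste(missing, collapse = ", "))
  sub <- gt[group, , drop = FALSE]
  seg <- apply(sub, 2, function(col) {
    v <- col[!is.na(col)]
    length(v) >= 2 && length(unique(v)) >= 2
  })
  sum(seg)
}

#' Harmonic number a_n = sum_{i=1}^{n-1} 1/i
#'
#' The Watterson correction factor for sample size n.
#'
#' @param n sample size (>= 2).
#' @return the (n-1)-th harmonic number.
#' @export
harmonic_a_n <- function(n) {
  if (n < 2) stop("n must be >= 2")
  sum(1 / seq_len(n - 1))
}

#' Watterson's theta per site
#'
#' `theta_W = S / (a_n * L)` with S segregating sites, a_n the (n-1)-th
#' harmonic number and L the surveyed sequence length in bp.
#'
#' @param S segregating sites.
#' @param n sample size (>= 2).
#' @param L surveyed length, bp.
#' @return theta_W per site.
#' @export
#' @examples
#' watterson_theta(15, 4, 1360096)
watterson_theta <- function(S, n, L) {
  if (n < 2) stop("n must be >= 2")
  if (L <= 0) stop("L must be positive")
  if (S < 0) stop("S must be non-negative")
  S / (harmonic_a_n(n) * L)
}

#' Group-wise diversity table
#'
#' Computes n, S, a_n and Watterson's theta for every group in a sample
#' grouping table; groups with fewer than two samples are skipped with a
#' message.
#'
#' @param x a [variant_table()] or matrix.
#' @param groups data.frame with columns `sample` and `group`.
#' @param L surveyed length, bp (default the scY total of
#'   [pipeline_config()]).
#' @return data.frame group, n, S, a_n, theta_w.
#' @export
diversity_by_group <- function(x, groups, L = pipeline_config()$theta_length) {
  stopifnot(all(c("sample", "group") %in% names(groups)))
  out <- lapply(split(groups$sample, groups$group), function(ss) {
    if (length(ss) < 2) return(NULL)
    S <- segregating_sites(x, ss)
    data.frame(n = length(ss), S = S, a_n = harmonic_a_n(length(ss)),
               theta_w = watterson_theta(S, length(ss), L))
  })
  keep <- !vapply(out, is.null, TRUE)
  if (any(!keep))
    message("skipping group(s) with < 2 samples: ",
            paste(names(out)[!keep], collapse = ", "))
  res <- do.call(rbind, out[keep])
  res <- cbind(group = names(out)[keep], res)
  rownames(res) <- NULL
  res
}
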