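#' Keep only biallelic SNPs
#'
#' Removes multiallelic records (comma in ALT), indels (REF/ALT of unequal
#' length) and MNP/complex records (equal length > 1); only single-base
#' biallelic substitutions survive. Removal reasons are appended to the
#' table's filter log.
#'
#' @param vt a [variant_table()].
#' @return the filtered table.
#' @export
filter_variant_kind <- function(vt) {
  ref <- vt$sites$ref; alt <- vt$sites$alt
  if (any(!nzchar(ref)) || any(!nzchar(alt))) stop("malformed alleles")
  kind <- ifelse(grepl(",", alt, fixed = TRUE), "multiallelic",
          ifelse(nchar(ref) != nchar(alt), "indel",
          ifelse(nchar(ref) > 1, "mnp_complex", "snp")))
  keep <- kind == "snp" & ref != alt
  kind[kind == "snp" & ref == alt] <- "malformed"
  vt <- log_stage(vt, "variant_kind", kind[!keep])
  subset_sites(vt, keep)
}

#' Restrict variants to trimmed scY regions
#'
#' Keeps sites that fall inside a window classified scY and lie strictly
#' more than `end_trim` bp from both ends of their contig; variants on mcY
#' or nonY windows and near contig ends are removed.
#'
#' @param vt a [variant_table()].
#' @param classification a [classify_windows()] table covering every contig
#'   that appears in `vt` (0-based half-open windows).
#' @param contig_lengths optional named vector; defaults to the maximum
#'   window end per contig.
#' @param end_trim bp excluded at each contig end (default 50).
#' @return the filtered table.
#' @export
filter_by_region <- function(vt, classification, contig_lengths = NULL,
                             end_trim = 50) {
  missing_ctg <- setdiff(unique(vt$sites$contig), unique(classification$contig))
  if (length(missing_ctg))
    stop("contig(s) absent from the window classification: ",
         paste(missing_ctg, collapse = ", "))
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(classification$end, classification$contig, max)
  }
  n <- nrow(vt$sites)
  reason <- character(n)
  for (i in seq_len(n)) {
    ctg <- vt$sites$contig[i]; pos <- vt$sites$pos[i]
    len <- contig_lengths[[ctg]]
    if (pos <= end_trim || pos > len - end_trim) { reason[i] <- "end_trim"; next }
    w <- classification[classification$contig == ctg &
                          classification$start < pos &
                          classification$end >= pos, ]
    if (!nrow(w)) { reason[i] <- "unclassified_window"; next }
    if (w$class[1] != "scY") reason[i] <- paste0(w$class[1], "_window")
  }
  keep <- reason == ""
  vt <- log_stage(vt, "region", reason[!keep])
  subset_sites(vt, keep)
}

range_of <- function(ranges, group) {
  r <- ranges[[group]]
  if (is.null(r)) stop("no depth range for group ", group)
  r
}

#' Stringent site filter for outgroup-private variant ascertainment
#'
#' Drops every site with more than `max_conflicts` conflicted samples, any
#' missing call, or any sample whose read depth falls outside its depth
#' group's ascertainment range. Used to distill a clean outgroup-private SNP
#' list from a joint ingroup+outgroup call set.
#'
#' @param vt a [variant_table()].
#' @param groups named character vector mapping every sample to a depth
#'   group (`"vLowDP"`, `"LowDP"`, `"ModDP"`).
#' @param ranges named list of c(lo, hi) per group; default the
#'   ascertainment ranges of [pipeline_config()].
#' @param max_conflicts maximum conflicted samples per surviving site
#'   (default 2).
#' @return the filtered table.
#' @export
outgroup_private_filter <- function(vt, groups,
                                    ranges = pipeline_config()$ascertainment_ranges,
                                    max_conflicts = 2) {
  samp <- rownames(vt$gt)
  if (!all(samp %in% names(groups)))
    stop("sample(s) without a depth-group assignment: ",
         paste(setdiff(samp, names(groups)), collapse = ", "))
  depth <- vt$ref_reads + vt$alt_reads
  conf <- colSums(conflicted_calls(vt))
  any_missing <- colSums(is.na(vt$gt)) > 0
  lo <- vapply(groups[samp], function(g) range_of(ranges, g)[1], 0)
  hi <- vapply(groups[samp], function(g) range_of(ranges, g)[2], 0)
  out_of_range <- colSums(depth < lo | depth > hi) > 0
  reason <- ifelse(conf > max_conflicts, "conflicts",
            ifelse(any_missing, "missing",
            ifelse(out_of_range, "depth_range", "")))
  keep <- reason == ""
  vt <- log_stage(vt, "outgroup_private", reason[!keep])
  subset_sites(vt, keep)
}

#' Genotyped-set site filter
#'
#' Applied after re-genotyping the merged SNP list: a site is discarded when
#' more than `max_conflicts` samples carry both alleles, or when its coverage
#' is outside the genotyping range - by default judged on the per-group mean
#' depth at the site (`depth_scope = "group_mean"`); `"per_sample"` instead
#' requires every sample in range. In surviving sites, conflicted samples'
#' calls are masked to missing so the tree never sees contradictory support.
#'
#' @inheritParams outgroup_private_filter
#' @param ranges default the genotyping ranges of [pipeline_config()].
#' @param max_conflicts default 5.
#' @param depth_scope `"group_mean"` or `"per_sample"`.
#' @return the filtered table with conflicted calls masked.
#' @export
genotyped_set_filter <- function(vt, groups,
                                 ranges = pipeline_config()$genotyping_ranges,
                                 max_conflicts = 5,
                                 depth_scope = c("group_mean", "per_sample")) {
  depth_scope <- match.arg(depth_scope)
  samp <- rownames(vt$gt)
  if (!all(samp %in% names(groups)))
    stop("sample(s) without a depth-group assignment: ",
         paste(setdiff(samp, names(groups)), collapse = ", "))
  depth <- vt$ref_reads + vt$alt_reads
  conf_mat <- conflicted_calls(vt)
  conf <- colSums(conf_mat)
  g <- groups[samp]
  if (depth_scope == "group_mean") {
    out_of_range <- rep(FALSE, ncol(vt$gt))
    for (gr in unique(g)) {
      r <- range_of(ranges, gr)
      mu <- colMeans(depth[g == gr, , drop = FALSE])
      out_of_range <- out_of_range | mu < r[1] | mu > r[2]
    }
  } else {
    lo <- vapply(g, function(x) range_of(ranges, x)[1], 0)
    hi <- vapply(g, function(x) range_of(ranges, x)[2], 0)
    out_of_range <- colSums(depth < lo | depth > hi) > 0
  }
  reason <- ifelse(conf > max_conflicts, "conflicts",
            ifelse(out_of_range, "depth_range", ""))
  keep <- reason == ""
  vt <- log_stage(vt, "genotyped_set", reason[!keep])
  vt <- subset_sites(vt, keep)
  mask <- conflicted_calls(vt)
  vt$gt[mask] <- NA_integer_
  vt
}

#' Consensus sequence from per-site base counts
#'
#' Emits, per position, the most frequent base when total depth reaches
#' `min_depth`, and `N` otherwise; ties between top bases also give `N`.
#'
#' @param counts numeric matrix, positions x 4, columns named A, C, G, T.
#' @param min_depth minimum total count to call a base (default 3).
#' @return a single consensus string.
#' @export
consensus_from_counts <- function(counts, min_depth = 3) {
  stopifnot(is.matrix(counts), ncol(counts) == 4)
  colnames(counts) <- toupper(colnames(counts))
  stopifnot(all(c("A", "C", "G", "T") %in% colnames(counts)))
  counts <- counts[, c("A", "C", "G", "T"), drop = FALSE]
  tot <- rowSums(counts)
  best <- max.col(counts, ties.method = "first")
  top <- counts[cbind(seq_len(nrow(counts)), best)]
  tie <- rowSums(counts == top) > 1
  base <- c("A", "C", "G", "T")[best]
  base[tot < min_depth | tie] <- "N"
  paste(base, collapse = "")
}

#' Remove an alignment region from all sequences
#'
#' Drops the columns `start..end` (1-based, inclusive) from every sequence of
#' an alignment, e.g. the hypervariable mitochondrial D-loop before tree
#' building.
#'
#' @param seqs character vector of aligned sequences, all the same length.
#' @param start,end region to excise, 1-based inclusive. `start > end` (an
#'   empty region) returns the input unchanged.
#' @return the shortened sequences.
#' @export
excise_region <- function(seqs, start, end) {
  n <- unique(nchar(seqs))
  if (length(n) != 1) stop("sequences differ in length")
  if (start > end) return(seqs)
  if (start < 1 || end > n) stop("region out of alignment bounds")
  if (start == 1 && end == n)
    warning("excising the whole alignment; empty sequences returned")
  vapply(seqs, function(s)
    paste0(substr(s, 1, start - 1), substr(s, end + 1, n)), "")
}

#' Extract a biallelic SNP matrix from an alignment
#'
#' Scans alignment columns for positions with exactly two non-N states and
#' encodes them 0/1 (0 = the majority base, or the outgroup base when an
#' outgroup is named); N becomes missing. Feeds consensus mtDNA sequences
#' into the same parsimony engine used for the Y.
#'
#' @param seqs named character vector of aligned sequences.
#' @param outgroup optional sequence name used to polarize alleles.
#' @return a [variant_table()] (contig `"aln"`, positions = alignment
#'   columns).
#' @export
snps_from_alignment <- function(seqs, outgroup = NULL) {
  stopifnot(!is.null(names(seqs)), length(unique(nchar(seqs))) == 1)
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  keep <- integer(0); ref <- character(0); alt <- character(0)
  gt_cols <- list()
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    obs <- col[col %in% c("A", "C", "G", "T")]
    al <- unique(obs)
    if (length(al) != 2) next
    a0 <- if (!is.null(outgroup) && col[outgroup] %in% al) col[outgroup]
          else names(sort(table(obs), decreasing = TRUE))[1]
    a1 <- setdiff(al, a0)
    g <- ifelse(col == a0, 0L, ifelse(col == a1, 1L, NA_integer_))
    keep <- c(keep, j); ref <- c(ref, a0); alt <- c(alt, a1)
    gt_cols[[length(gt_cols) + 1]] <- g
  }
  if (!length(keep)) stop("no biallelic site in the alignment")
  gt <- do.call(cbind, gt_cols)
  rownames(gt) <- names(seqs)
  variant_table(data.frame(contig = "aln", pos = keep, ref = ref, alt = alt,
                           stringsAsFactors = FALSE), gt)
}
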