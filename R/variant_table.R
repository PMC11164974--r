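#' Haploid variant table
#'
#' The container the filter cascade operates on: site metadata plus
#' samples-by-sites matrices of haploid calls and per-allele read support.
#' Calls are 0 (reference), 1 (alternative) or NA (missing). A sample is
#' *conflicted* at a site when both its reference and alternative read
#' counts are positive.
#'
#' @param sites data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`; one row per site.
#' @param gt integer matrix, samples x sites, values 0/1/NA.
#' @param ref_reads,alt_reads integer matrices of read support, same shape as
#'   `gt`. If omitted, unit support consistent with each call is assumed.
#' @return object of class `variant_table` with an attached `filter_log`
#'   (empty) recording later filter stages.
#' @export
variant_table <- function(sites, gt, ref_reads = NULL, alt_reads = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("contig", "pos", "ref", "alt") %in% names(sites)),
            is.matrix(gt), ncol(gt) == nrow(sites))
  if (is.null(rownames(gt))) stop("gt needs sample rownames")
  if (is.null(ref_reads)) ref_reads <- (gt == 0L) * 1L
  if (is.null(alt_reads)) alt_reads <- (gt == 1L) * 1L
  ref_reads[is.na(ref_reads)] <- 0L
  alt_reads[is.na(alt_reads)] <- 0L
  stopifnot(identical(dim(ref_reads), dim(gt)),
            identical(dim(alt_reads), dim(gt)))
  if (is.null(colnames(gt)))
    colnames(gt) <- sprintf("%s:%d:%s>%s", sites$contig, sites$pos,
                            sites$ref, sites$alt)
  dimnames(ref_reads) <- dimnames(alt_reads) <- dimnames(gt)
  structure(list(sites = sites, gt = gt,
                 ref_reads = ref_reads, alt_reads = alt_reads),
            filter_log = data.frame(stage = character(), reason = character(),
                                    n_removed = integer(),
                                    stringsAsFactors = FALSE),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$gt), "samples x", ncol(x$gt), "sites\n")
  lg <- attr(x, "filter_log")
  if (nrow(lg)) { cat("filter log:\n"); print(lg) }
  invisible(x)
}

#' Number of sites in a variant table
#' @param vt a [variant_table()].
#' @return integer site count.
#' @export
n_sites <- function(vt) ncol(vt$gt)

#' Per-sample allele conflicts
#'
#' @param vt a [variant_table()].
#' @return logical samples x sites matrix, TRUE where both alleles have read
#'   support.
#' @export
conflicted_calls <- function(vt) vt$ref_reads > 0 & vt$alt_reads > 0

log_stage <- function(vt, stage, reasons) {
  lg <- attr(vt, "filter_log")
  if (length(reasons)) {
    tab <- table(reasons)
    lg <- rbind(lg, data.frame(stage = stage, reason = names(tab),
                               n_removed = as.integer(tab),
                               stringsAsFactors = FALSE))
  }
  attr(vt, "filter_log") <- lg
  vt
}

subset_sites <- function(vt, keep) {
  out <- structure(list(sites = vt$sites[keep, , drop = FALSE],
                        gt = vt$gt[, keep, drop = FALSE],
                        ref_reads = vt$ref_reads[, keep, drop = FALSE],
                        alt_reads = vt$alt_reads[, keep, drop = FALSE]),
                   filter_log = attr(vt, "filter_log"),
                   class = "variant_table")
  rownames(out$sites) <- NULL
  out
}

#' Build a variant table from a tree-SNP simulation
#'
#' @param sim output of [simulate_tree_snps()].
#' @return a [variant_table()] carrying the simulated calls and read support.
#' @export
variant_table_from_sim <- function(sim) {
  variant_table(sim$sites[, c("contig", "pos", "ref", "alt")],
                sim$gt, sim$ref_reads, sim$alt_reads)
}

#' Read a haploid VCF into a variant table
#'
#' Uses vcfR to parse the file; the GT field supplies calls (0, 1, or .) and
#' the AD field, when present, the per-allele read support.
#'
#' @param path VCF file (plain or bgzipped).
#' @return a [variant_table()].
#' @export
read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  sites <- data.frame(contig = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  gtc <- vcfR::extract.gt(v, element = "GT")
  gt <- t(ifelse(gtc == "0", 0L, ifelse(gtc == "1", 1L, NA_integer_)))
  colnames(gt) <- NULL  # rebuilt as contig:pos:ref>alt by variant_table()
  ref_reads <- alt_reads <- NULL
  if ("AD" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    ad <- vcfR::extract.gt(v, element = "AD")
    split2 <- function(i) as.integer(vapply(strsplit(ad, ","), function(p)
      if (length(p) >= i) p[i] else "0", ""))
    ref_reads <- t(matrix(split2(1), nrow(ad), ncol(ad), dimnames = dimnames(ad)))
    alt_reads <- t(matrix(split2(2), nrow(ad), ncol(ad), dimnames = dimnames(ad)))
  }
  variant_table(sites, gt, ref_reads, alt_reads)
}

#' Write a variant table as a minimal haploid VCF
#'
#' @param vt a [variant_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(vt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read depth per allele\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(vt$gt)), collapse = "\t")), con)
  for (j in seq_len(ncol(vt$gt))) {
    g <- vt$gt[, j]
    cells <- sprintf("%s:%d,%d",
                     ifelse(is.na(g), ".", as.character(g)),
                     vt$ref_reads[, j], vt$alt_reads[, j])
    writeLines(paste(c(vt$sites$contig[j], vt$sites$pos[j], ".",
                       vt$sites$ref[j], vt$sites$alt[j], ".", "PASS", ".",
                       "GT:AD", cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write the calls of a variant table as TSV
#'
#' @param vt a [variant_table()].
#' @param path output file; sites as rows, samples as columns.
#' @return `path`, invisibly.
#' @export
write_variant_tsv <- function(vt, path) {
  df <- cbind(vt$sites, as.data.frame(t(vt$gt)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
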