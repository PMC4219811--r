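#' Read one group's variant records from a VCF
#'
#' Loads a single-sample VCF v4.2 (DP and AD FORMAT fields required) into
#' the flat record form used by [filter_variants()].
#'
#' @param path Path to a plain-text VCF.
#' @return Data frame with `contig`, `position`, `ref`, `alt`
#'   (comma-separated when multi-allelic), `depth`, `ad` (comma-separated
#'   per-allele counts), `quality`.
#' @export
read_group_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  dp <- suppressWarnings(
    as.integer(vcfR::extract.gt(vcf, element = "DP")[, 1]))
  ad <- vcfR::extract.gt(vcf, element = "AD")[, 1]
  data.frame(contig = fix[, "CHROM"],
             position = as.integer(fix[, "POS"]),
             ref = fix[, "REF"], alt = fix[, "ALT"],
             depth = dp, ad = unname(ad),
             quality = as.numeric(fix[, "QUAL"]),
             stringsAsFactors = FALSE)
}

.min_allele_fraction <- function(ad) {
  vapply(strsplit(ad, ",", fixed = TRUE), function(x) {
    counts <- as.numeric(x)
    tot <- sum(counts)
    if (tot == 0) return(0)
    min(counts) / tot
  }, numeric(1))
}

#' Screen two-group variant calls
#'
#' A site is retained only when: it is bi-allelic (exactly one alternate
#' allele) in both groups; it was discovered in both groups with identical
#' contig, position, reference and alternate allele; read depth is at
#' least `min_depth` in each group; the minor allele fraction
#' (`min(allele counts) / sum(allele counts)`, from the AD field) is at
#' least `min_maf` in each group; and the call quality is at least
#' `min_quality` in each group. All thresholds are inclusive ("at least").
#' Each removed site is logged once under its first failing rule, in that
#' order; a reference-allele mismatch between the groups at the same
#' coordinate is a consistency failure counted separately.
#'
#' @param group_a,group_b VCF paths or record data frames (see
#'   [read_group_vcf()]).
#' @param min_depth Minimum per-group read depth (default 5).
#' @param min_maf Minimum per-group minor allele fraction (default 0.20).
#' @param min_quality Minimum per-group Phred quality (default 30).
#' @return List with `retained` (merged data frame, one row per surviving
#'   site with per-group depth/MAF/quality) and `summary`, an object of
#'   class `"snp_summary"` carrying input/removal/retention counts and the
#'   transition/transversion classification of [classify_ts_tv()].
#' @export
filter_variants <- function(group_a, group_b, min_depth = 5L,
                            min_maf = 0.20, min_quality = 30) {
  if (is.character(group_a)) group_a <- read_group_vcf(group_a)
  if (is.character(group_b)) group_b <- read_group_vcf(group_b)
  key_a <- paste(group_a$contig, group_a$position)
  key_b <- paste(group_b$contig, group_b$position)
  if (anyDuplicated(key_a) || anyDuplicated(key_b)) {
    stop("duplicate (contig, position) records within a group")
  }
  all_keys <- union(key_a, key_b)
  ia <- match(all_keys, key_a)
  ib <- match(all_keys, key_b)
  multi_a <- grepl(",", group_a$alt[ia])
  multi_b <- grepl(",", group_b$alt[ib])
  multi <- (!is.na(ia) & multi_a) | (!is.na(ib) & multi_b)
  present_both <- !is.na(ia) & !is.na(ib)
  ref_mismatch <- present_both & group_a$ref[ia] != group_b$ref[ib]
  alt_mismatch <- present_both & !ref_mismatch &
    group_a$alt[ia] != group_b$alt[ib]
  reason <- rep(NA_character_, length(all_keys))
  reason[multi] <- "multi_allelic"
  reason[is.na(reason) & !present_both] <- "not_shared"
  reason[is.na(reason) & ref_mismatch] <- "ref_mismatch"
  reason[is.na(reason) & alt_mismatch] <- "not_shared"
  ok <- is.na(reason)
  dp_fail <- ok & (group_a$depth[ia] < min_depth |
                     group_b$depth[ib] < min_depth)
  reason[dp_fail] <- "depth"
  maf_a <- rep(NA_real_, length(all_keys))
  maf_b <- maf_a
  maf_a[!is.na(ia)] <- .min_allele_fraction(group_a$ad[ia[!is.na(ia)]])
  maf_b[!is.na(ib)] <- .min_allele_fraction(group_b$ad[ib[!is.na(ib)]])
  ok <- is.na(reason)
  maf_fail <- ok & (maf_a < min_maf | maf_b < min_maf)
  reason[maf_fail] <- "maf"
  ok <- is.na(reason)
  q_fail <- ok & (group_a$quality[ia] < min_quality |
                    group_b$quality[ib] < min_quality)
  reason[q_fail] <- "quality"
  keep <- is.na(reason)
  retained <- data.frame(
    contig = group_a$contig[ia[keep]],
    position = group_a$position[ia[keep]],
    ref = group_a$ref[ia[keep]], alt = group_a$alt[ia[keep]],
    depth_a = group_a$depth[ia[keep]], depth_b = group_b$depth[ib[keep]],
    maf_a = maf_a[keep], maf_b = maf_b[keep],
    quality_a = group_a$quality[ia[keep]],
    quality_b = group_b$quality[ib[keep]],
    stringsAsFactors = FALSE)
  removal <- table(factor(reason, levels = c("multi_allelic", "not_shared",
                                             "ref_mismatch", "depth", "maf",
                                             "quality")))
  cls <- classify_ts_tv(retained)
  summary <- structure(c(list(n_input = length(all_keys),
                              n_retained = nrow(retained)),
                         as.list(removal), cls),
                       class = "snp_summary")
  list(retained = retained, summary = summary,
       reasons = data.frame(key = all_keys[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE))
}

#' Classify bi-allelic variants into transitions and transversions
#'
#' A&lt;-&gt;G and C&lt;-&gt;T exchanges are transitions; the four other
#' unordered ref/alt pairs are transversions, counted per type.
#'
#' @param retained Data frame with `ref` and `alt` single-base columns.
#' @return List with `transitions`, `transversions` and `type_counts`
#'   (named counts for A/G, C/T, A/T, A/C, T/G, C/G).
#' @export
classify_ts_tv <- function(retained) {
  type_levels <- c("A/G", "C/T", "A/T", "A/C", "T/G", "C/G")
  pair_of <- c(AG = "A/G", GA = "A/G", CT = "C/T", TC = "C/T",
               AT = "A/T", TA = "A/T", AC = "A/C", CA = "A/C",
               GT = "T/G", TG = "T/G", CG = "C/G", GC = "C/G")
  if (nrow(retained) == 0L) {
    counts <- setNames(integer(length(type_levels)), type_levels)
    return(list(transitions = 0L, transversions = 0L, type_counts = counts))
  }
  keys <- paste0(retained$ref, retained$alt)
  bad <- !(keys %in% names(pair_of))
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-ACGT alleles skipped")
    keys <- keys[!bad]
  }
  types <- factor(pair_of[keys], levels = type_levels)
  counts <- table(types)
  ts <- sum(counts[c("A/G", "C/T")])
  list(transitions = as.integer(ts),
       transversions = as.integer(sum(counts) - ts),
       type_counts = setNames(as.integer(counts), type_levels))
}

#' SNP density in bases per SNP
#'
#' @param n_snps Number of retained SNPs (> 0).
#' @param total_bases Total bases surveyed (> 0).
#' @return `total_bases / n_snps` (bp per SNP); `NA` with a warning when
#'   `n_snps` is zero.
#' @examples
#' snp_density(182806, 130629 * 645)   # ~ one SNP per 461 bp
#' @export
snp_density <- function(n_snps, total_bases) {
  stopifnot(total_bases > 0)
  if (n_snps == 0) {
    warning("zero SNPs: density undefined")
    return(NA_real_)
  }
  total_bases / n_snps
}

#' @export
print.snp_summary <- function(x, ...) {
  cat("SNP screen summary\n")
  cat(sprintf("  input sites: %d, retained: %d\n", x$n_input, x$n_retained))
  cat(sprintf("  removed: multi-allelic %d, not shared %d, ref mismatch %d,\n",
              x$multi_allelic, x$not_shared, x$ref_mismatch))
  cat(sprintf("           depth %d, MAF %d, quality %d\n",
              x$depth, x$maf, x$quality))
  cat(sprintf("  transitions: %d, transversions: %d\n",
              x$transitions, x$transversions))
  tc <- x$type_counts
  cat("  types:", paste(sprintf("%s=%d", names(tc), tc), collapse = ", "), "\n")
  invisible(x)
}
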