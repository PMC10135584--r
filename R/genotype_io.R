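#' Read a multi-sample VCF and population map into a genotype matrix
#'
#' Parses diploid GT fields of a VCFv4.2 file into alternate-allele dosages:
#' `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`, `./. -> NA`. Phased
#' separators (`|`) are accepted and treated as unphased; half-missing calls
#' (`./1`) are treated as missing. Multiallelic records are dropped with a
#' warning giving their count. The INFO keys `TAG` and `REFN` carry the
#' restriction-tag identifier and the reference-N flag in files written by
#' this package; when absent, `tag_id` defaults to the locus id and
#' `ref_has_n` to `FALSE`.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param pop_map_path Path to a two-column TSV (sample, population) without
#'   header, or with a header line starting with `sample`.
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `populations` (a [population_map()]).
#' @export
read_vcf <- function(path, pop_map_path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = 7L,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    warning(sum(multi), " multiallelic record(s) dropped")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- matrix(gt, nrow = nrow(fix),
               dimnames = list(NULL, colnames(vcf@gt)[-1L]))
  info <- vcf@fix[, "INFO"]
  keep <- which(!multi)
  ids <- fix[keep, "ID"]
  blank <- is.na(ids) | ids == "." | ids == ""
  ids[blank] <- paste0(fix[keep, "CHROM"], "_", fix[keep, "POS"])[blank]
  tag <- info_field(info[keep], "TAG")
  refn <- grepl("(?:^|;)REFN(?:;|=|$)", info[keep])
  loci <- data.frame(
    locus_id = ids,
    linkage_group = fix[keep, "CHROM"],
    position = as.integer(fix[keep, "POS"]),
    ref_allele = fix[keep, "REF"],
    alt_allele = fix[keep, "ALT"],
    tag_id = ifelse(is.na(tag), ids, tag),
    ref_has_n = refn,
    stringsAsFactors = FALSE)
  dosage <- apply(gt[keep, , drop = FALSE], 2L, gt_to_dosage,
                  line = keep)
  dosage <- matrix(dosage, ncol = ncol(gt),
                   dimnames = list(loci$locus_id, colnames(gt)))
  g <- genotype_matrix(t(dosage), loci, colnames(gt))
  pops <- read_popmap(pop_map_path)
  pops <- match_popmap(g, pops)  # errors listing unmapped samples
  list(genotypes = g, populations = pops)
}

# Extract a single INFO key=value (returns NA where absent).
info_field <- function(info, key) {
  m <- regexpr(paste0("(?:^|;)", key, "=([^;]*)"), info, perl = TRUE)
  out <- rep(NA_character_, length(info))
  hit <- !is.na(m) & m > 0
  out[hit] <- sub(paste0("^;?", key, "="), "", regmatches(info, m))
  out
}

# GT string vector -> dosage vector; errors name the offending record.
gt_to_dosage <- function(gt, line = seq_along(gt)) {
  gt <- sub(":.*", "", gt)
  out <- rep(NA_integer_, length(gt))
  known <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "0|1" = 1L,
             "1/0" = 1L, "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  hit <- known[gt]
  missing_like <- grepl("^\\.?[/|]?\\.?$", gt) |
    grepl("\\.", gt) | is.na(gt)
  bad <- is.na(hit) & !missing_like
  if (any(bad))
    stop("unparsable GT '", gt[which(bad)[1L]], "' at record ",
         line[which(bad)[1L]])
  out[!is.na(hit)] <- hit[!is.na(hit)]
  out
}

#' Read a two-column sample-to-population TSV
#'
#' @param path TSV path; columns sample, population. A header line whose
#'   first field is `sample` is skipped.
#' @return A [population_map()].
#' @export
read_popmap <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "character",
                           col.names = c("sample", "population"))
  if (nrow(tab) && tolower(tab$sample[1L]) == "sample")
    tab <- tab[-1L, , drop = FALSE]
  population_map(tab)
}

#' Write a population map as TSV
#'
#' @param pops A [population_map()].
#' @param path Output path.
#' @export
write_popmap <- function(pops, path) {
  utils::write.table(
    data.frame(sample = names(pops), population = unclass(pops)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as plain-text VCFv4.2
#'
#' Emits one biallelic record per locus with GT fields reconstructed from
#' dosages (`NA -> ./.`) and the package's INFO keys `TAG` and `REFN`.
#' Round-trips exactly through [read_vcf()].
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=radpop",
    '##INFO=<ID=TAG,Number=1,Type=String,Description="Restriction tag identifier">',
    '##INFO=<ID=REFN,Number=0,Type=Flag,Description="Reference context contains N">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  d <- t(g$dosage)  # loci x samples
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_codes[d[ok] + 1L]
  info <- paste0("TAG=", g$loci$tag_id,
                 ifelse(g$loci$ref_has_n, ";REFN", ""))
  body <- paste(g$loci$linkage_group, g$loci$position, g$loci$locus_id,
                g$loci$ref_allele, g$loci$alt_allele, ".", "PASS", info,
                "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Alternate-allele frequency at one locus
#'
#' @param g A [genotype_matrix()].
#' @param locus Locus index or id.
#' @param samples Optional subset of samples (indices or names); default all.
#' @return A list with `p_alt` (alternate-allele frequency, `NA` when no
#'   genotype is called), `n_called` (non-missing genotypes) and `n_alleles`
#'   (`2 * n_called`).
#' @export
allele_frequency <- function(g, locus, samples = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.character(locus)) locus <- match(locus, g$loci$locus_id)
  d <- g$dosage[, locus]
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, g$samples)
    d <- d[samples]
  }
  if (!length(d)) stop("empty sample subset")
  n_called <- sum(!is.na(d))
  list(p_alt = if (n_called == 0L) NA_real_ else
         sum(d, na.rm = TRUE) / (2 * n_called),
       n_called = n_called,
       n_alleles = 2L * n_called)
}

#' Per-linkage-group SNP density summary
#'
#' For each linkage group reports the SNP count and the mean spacing between
#' successive SNPs in kb/SNP (positions sorted; groups with fewer than two
#' SNPs get `NA` spacing), plus the overall mean spacing across groups with
#' defined spacing.
#'
#' @param loci Data frame of locus records (see [genotype_matrix()]).
#' @param lg_lengths Optional named vector of linkage-group lengths in bp;
#'   when supplied, a `kb_per_snp_length` column (length / count / 1000) is
#'   added.
#' @return A list with `per_lg` (data frame: linkage_group, n_snps,
#'   kb_per_snp) and `overall_kb_per_snp`.
#' @export
snp_density_summary <- function(loci, lg_lengths = NULL) {
  if (!nrow(loci)) stop("at least one locus required")
  sp <- split(loci$position, loci$linkage_group)
  per <- data.frame(
    linkage_group = names(sp),
    n_snps = vapply(sp, length, 1L),
    kb_per_snp = vapply(sp, function(p) {
      if (length(p) < 2L) return(NA_real_)
      mean(diff(sort(p))) / 1000
    }, 1.0),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(lg_lengths))
    per$kb_per_snp_length <- unname(lg_lengths[per$linkage_group]) /
      per$n_snps / 1000
  list(per_lg = per,
       overall_kb_per_snp = mean(per$kb_per_snp, na.rm = TRUE))
}
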