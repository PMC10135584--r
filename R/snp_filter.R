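#' SNP quality-filter configuration
#'
#' Defaults mirror common RAD-seq practice: drop monomorphic loci, loci whose
#' reference context contains an N, tags carrying more than two SNPs, loci
#' duplicated at one genomic position, loci typable in fewer than 80% of all
#' samples, and loci with pooled minor allele frequency below 0.01.
#'
#' @param min_call_rate Minimum fraction of samples with a called genotype.
#' @param min_maf Minimum minor allele frequency over all samples pooled.
#' @param max_snps_per_tag Tags with more SNPs than this lose all their SNPs.
#' @param drop_monomorphic Drop loci with a single allele among called
#'   genotypes.
#' @param drop_ref_n Drop loci flagged `ref_has_n`.
#' @param drop_duplicate_positions Drop all loci sharing a (linkage group,
#'   position) coordinate.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_call_rate = 0.80, min_maf = 0.01,
                          max_snps_per_tag = 2L, drop_monomorphic = TRUE,
                          drop_ref_n = TRUE, drop_duplicate_positions = TRUE) {
  for (v in list(min_call_rate, min_maf, max_snps_per_tag))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("filter thresholds must be non-negative finite numbers")
  if (min_call_rate > 1) stop("min_call_rate must lie in [0, 1]")
  if (min_maf > 0.5) stop("min_maf must lie in [0, 0.5]")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 max_snps_per_tag = as.integer(max_snps_per_tag),
                 drop_monomorphic = isTRUE(drop_monomorphic),
                 drop_ref_n = isTRUE(drop_ref_n),
                 drop_duplicate_positions = isTRUE(drop_duplicate_positions)),
            class = "filter_config")
}

#' Minor allele frequency at one locus, all samples pooled
#'
#' @param g A [genotype_matrix()].
#' @param locus Locus index or id.
#' @return `min(p, 1 - p)` of the pooled alternate-allele frequency; `NA`
#'   when no genotype is called.
#' @export
maf <- function(g, locus) {
  p <- allele_frequency(g, locus)$p_alt
  if (is.na(p)) NA_real_ else min(p, 1 - p)
}

#' Apply the SNP quality-filter cascade
#'
#' Rules are evaluated on the *input* matrix and applied in a fixed order,
#' each locus attributed to the first rule that removes it:
#' 1. `monomorphic` — pooled alternate-allele frequency 0 or 1 (or no called
#'    genotype);
#' 2. `ref_n` — reference context contains an N;
#' 3. `excess_snps_per_tag` — the locus belongs to a tag with more than
#'    `max_snps_per_tag` SNPs (all SNPs of the tag are removed);
#' 4. `duplicate_position` — another locus shares its (linkage group,
#'    position) (all sharers are removed);
#' 5. `call_rate` — fraction of called genotypes below `min_call_rate`;
#' 6. `maf` — pooled minor allele frequency below `min_maf`.
#'
#' @param g A [genotype_matrix()].
#' @param cfg A [filter_config()].
#' @return A list with `genotypes` (the filtered matrix) and `report` (class
#'   `filter_report`: `n_input`, `n_output`, `removed_by_rule`).
#' @export
apply_filters <- function(g, cfg = filter_config()) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!inherits(cfg, "filter_config")) cfg <- do.call(filter_config, cfg)
  n <- nrow(g$loci)
  if (n == 0L) stop("empty genotype matrix")
  d <- g$dosage
  called <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * called)  # NaN when called == 0
  maf_all <- pmin(p, 1 - p)

  fails <- list(
    monomorphic = if (cfg$drop_monomorphic)
      called == 0L | (!is.na(p) & (p == 0 | p == 1)) else logical(n),
    ref_n = if (cfg$drop_ref_n) g$loci$ref_has_n else logical(n),
    excess_snps_per_tag = {
      tag_n <- table(g$loci$tag_id)
      g$loci$tag_id %in% names(tag_n)[tag_n > cfg$max_snps_per_tag]
    },
    duplicate_position = if (cfg$drop_duplicate_positions) {
      key <- paste(g$loci$linkage_group, g$loci$position)
      key %in% key[duplicated(key)]
    } else logical(n),
    call_rate = called / length(g$samples) < cfg$min_call_rate,
    maf = !is.na(maf_all) & maf_all < cfg$min_maf
  )
  removed_by <- rep(NA_character_, n)
  for (rule in names(fails)) {
    hit <- fails[[rule]] & is.na(removed_by)
    removed_by[hit] <- rule
  }
  keep <- is.na(removed_by)
  if (!any(keep)) warning("no locus survived the filter cascade")
  counts <- vapply(names(fails), function(r) sum(removed_by == r, na.rm = TRUE), 1L)
  report <- structure(list(n_input = n, n_output = sum(keep),
                           removed_by_rule = counts),
                      class = "filter_report")
  out <- if (any(keep)) subset_genotypes(g, loci = which(keep)) else {
    g0 <- g
    g0$dosage <- g$dosage[, 0, drop = FALSE]
    g0$loci <- g$loci[0, , drop = FALSE]
    g0
  }
  list(genotypes = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report: ", x$n_input, " -> ", x$n_output, " loci\n", sep = "")
  for (r in names(x$removed_by_rule))
    cat(sprintf("  %-22s %d\n", r, x$removed_by_rule[[r]]))
  invisible(x)
}
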