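#' Observed heterozygosity at one locus
#'
#' Fraction of called genotypes that are heterozygous (dosage 1).
#'
#' @param dosages Integer vector of dosages in `{0, 1, 2, NA}`.
#' @return Proportion of heterozygotes among called genotypes.
#' @export
observed_heterozygosity <- function(dosages) {
  called <- dosages[!is.na(dosages)]
  if (!length(called)) stop("no called genotype")
  mean(called == 1L)
}

#' Expected heterozygosity (2pq) at one locus
#'
#' @param p Alternate-allele frequency in `[0, 1]`.
#' @return `2 * p * (1 - p)`.
#' @export
expected_heterozygosity <- function(p) 2 * p * (1 - p)

#' Per-site nucleotide diversity
#'
#' The unbiased per-site heterozygosity `2pq * n / (n - 1)` with `n` the
#' number of sampled alleles; exceeds plain `2pq` by the small-sample factor.
#'
#' @param p Alternate-allele frequency.
#' @param n_alleles Number of non-missing allele copies (twice the called
#'   genotypes).
#' @return Per-site diversity; `NA` when `n_alleles < 2`.
#' @export
nucleotide_diversity_site <- function(p, n_alleles) {
  ifelse(n_alleles < 2, NA_real_,
         2 * p * (1 - p) * n_alleles / (n_alleles - 1))
}

#' Polymorphism information content of a biallelic locus
#'
#' Botstein's PIC, which for two alleles collapses to
#' `1 - (p^2 + q^2) - 2 p^2 q^2 = 2pq (1 - pq)`.
#'
#' @param p Alternate-allele frequency.
#' @return PIC in `[0, 0.375]`.
#' @export
pic_biallelic <- function(p) {
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' Effective number of alleles at one locus
#'
#' `1 / sum(p_i^2) = 1 / (1 - He)`: the number of equifrequent alleles giving
#' the same homozygosity.
#'
#' @param p Alternate-allele frequency.
#' @return Value in `[1, 2]` for a biallelic locus.
#' @export
effective_alleles <- function(p) 1 / (p^2 + (1 - p)^2)

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact p-value for a biallelic genotype table, conditioning on
#' the observed allele counts and enumerating all heterozygote counts of the
#' same parity. The p-value sums the probabilities of every outcome whose
#' conditional probability does not exceed that of the observed table
#' (probability-ordering rule). Monomorphic tables return 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (reference homozygotes,
#'   heterozygotes, alternate homozygotes).
#' @return Exact p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("at least one genotype required")
  n_a <- 2 * n_hom_ref + n_het    # reference allele copies
  n_b <- 2 * n_hom_alt + n_het
  if (n_a == 0 || n_b == 0) return(1.0)
  n_minor <- min(n_a, n_b)
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  # log P(het = h | n, n_a): multinomial over genotypes conditioned on alleles
  logp <- vapply(hets, function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- (max(n_a, n_b) - h) / 2
    lfactorial(n) - lfactorial(hom_minor) - lfactorial(h) -
      lfactorial(hom_major) + h * log(2) +
      lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  }, 1.0)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_het, hets)]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

# Vectorized HWE p-values for count triples; memoizes repeated tables.
hwe_exact_vec <- function(hom_ref, het, hom_alt) {
  key <- paste(hom_ref, het, hom_alt)
  uk <- !duplicated(key)
  pv <- mapply(hwe_exact_test, hom_ref[uk], het[uk], hom_alt[uk])
  unname(pv[match(key, key[uk])])
}

#' Per-population diversity summary
#'
#' For each population, computes per-locus observed and expected
#' heterozygosity, per-site nucleotide diversity, exact Hardy-Weinberg
#' p-value, PIC and effective allele number from that population's called
#' genotypes, then averages each statistic over loci with defined values.
#' Loci monomorphic within the population still contribute (He = 0, Ne = 1,
#' HW-P = 1) as long as they are present in the input matrix.
#'
#' @param g A (typically filtered) [genotype_matrix()].
#' @param pops A [population_map()].
#' @return Data frame with one row per population: `population`, `n_samples`,
#'   `Ho`, `He`, `Pi`, `HW_P`, `PIC`, `Ne`, `n_loci_used`, `low_n` (flag:
#'   fewer than two samples).
#' @export
population_summary <- function(g, pops) {
  stopifnot(inherits(g, "genotype_matrix"))
  pops <- match_popmap(g, pops)
  labels <- unique(unclass(pops))
  rows <- lapply(labels, function(lab) {
    idx <- which(unclass(pops) == lab)
    d <- g$dosage[idx, , drop = FALSE]
    hom_ref <- colSums(d == 0L, na.rm = TRUE)
    het     <- colSums(d == 1L, na.rm = TRUE)
    hom_alt <- colSums(d == 2L, na.rm = TRUE)
    nc <- hom_ref + het + hom_alt
    use <- nc >= 1L
    p <- (het[use] + 2 * hom_alt[use]) / (2 * nc[use])
    he <- expected_heterozygosity(p)
    pi <- nucleotide_diversity_site(p, 2 * nc[use])
    if (length(idx) < 2L)
      warning("population '", lab, "' has fewer than 2 samples")
    data.frame(
      population = lab,
      n_samples = length(idx),
      Ho = mean(het[use] / nc[use]),
      He = mean(he),
      Pi = mean(pi, na.rm = TRUE),
      HW_P = mean(hwe_exact_vec(hom_ref[use], het[use], hom_alt[use])),
      PIC = mean(pic_biallelic(p)),
      Ne = mean(effective_alleles(p)),
      n_loci_used = sum(use),
      low_n = length(idx) < 2L,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
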