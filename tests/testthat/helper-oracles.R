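# Independent oracles used to cross-check the package's estimators.

# Weir-Cockerham (1984) theta for two populations via the nested-ANOVA
# sums-of-squares route: allele-copy indicators nested in individuals nested
# in populations. Structurally independent of the implementation's direct
# a/b/c component formulas.
oracle_wc_theta <- function(da, db) {
  pops <- list(da, db)
  r <- 2L
  per_locus <- function(l) {
    cols <- lapply(pops, function(d) d[, l][!is.na(d[, l])])
    n_i <- lengths(cols)
    if (any(n_i < 2L)) return(NULL)
    p_ind <- lapply(cols, function(x) x / 2)      # individual allele freq
    p_i <- vapply(p_ind, mean, 1.0)
    S1 <- sum(n_i)
    pbar <- sum(n_i * p_i) / S1
    if (pbar <= 0 || pbar >= 1) return(NULL)
    SSP <- sum(2 * n_i * (p_i - pbar)^2)
    SSI <- sum(unlist(mapply(function(pi_j, pi) 2 * (pi_j - pi)^2,
                             p_ind, p_i, SIMPLIFY = FALSE)))
    # within-individual SS: each het contributes 0.5, homs 0
    SSG <- sum(vapply(cols, function(x) sum(x == 1L) / 2, 1.0))
    MSP <- SSP / (r - 1)
    MSI <- SSI / (S1 - r)
    MSG <- SSG / S1
    n_c <- (S1 - sum(n_i^2) / S1) / (r - 1)
    sg <- MSG
    si <- (MSI - MSG) / 2
    sp <- (MSP - MSI) / (2 * n_c)
    c(sp, si, sg)
  }
  comps <- Filter(Negate(is.null), lapply(seq_len(ncol(da)), per_locus))
  if (!length(comps)) return(NA_real_)
  tot <- Reduce(`+`, comps)
  tot[1L] / sum(tot)
}

# Exact HWE p-value by brute-force enumeration of all genotype tables with
# the observed sample size, under multinomial Hardy-Weinberg probabilities
# at an arbitrary allele frequency, conditioned on the observed allele
# count (the conditional law is frequency-free).
oracle_hwe_p <- function(n_hom_ref, n_het, n_hom_alt, p_arbitrary = 0.37) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_ref <- 2 * n_hom_ref + n_het
  if (n_ref == 0 || n_ref == 2 * n) return(1.0)
  tables <- expand.grid(aa = 0:n, ab = 0:n)
  tables$bb <- n - tables$aa - tables$ab
  tables <- tables[tables$bb >= 0, ]
  tables <- tables[2 * tables$aa + tables$ab == n_ref, ]
  p <- p_arbitrary
  lp <- with(tables, lfactorial(n) - lfactorial(aa) - lfactorial(ab) -
               lfactorial(bb) + aa * 2 * log(p) +
               ab * log(2 * p * (1 - p)) + bb * 2 * log(1 - p))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[tables$ab == n_het]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Small genotype_matrix from a dosage matrix (samples x loci).
toy_genotypes <- function(d, lg = NULL, pos = NULL, tag = NULL,
                          ref_n = NULL) {
  L <- ncol(d)
  loci <- data.frame(
    locus_id = paste0("L", seq_len(L)),
    linkage_group = if (is.null(lg)) "LG1" else lg,
    position = if (is.null(pos)) seq_len(L) * 1000L else pos,
    ref_allele = "A", alt_allele = "G",
    tag_id = if (is.null(tag)) paste0("L", seq_len(L)) else tag,
    ref_has_n = if (is.null(ref_n)) FALSE else ref_n,
    stringsAsFactors = FALSE)
  genotype_matrix(d, loci,
                  samples = if (is.null(rownames(d)))
                    paste0("s", seq_len(nrow(d))) else rownames(d))
}

# Two-population genotype_matrix drawn from explicit frequency vectors.
sim_two_pops <- function(pa, pb, n_per = 50L, seed = 1L) {
  set.seed(seed)
  L <- length(pa)
  da <- matrix(rbinom(n_per * L, 2, rep(pa, each = n_per)), n_per, L)
  db <- matrix(rbinom(n_per * L, 2, rep(pb, each = n_per)), n_per, L)
  g <- toy_genotypes(rbind(da, db))
  pops <- population_map(stats::setNames(
    rep(c("A", "B"), each = n_per), g$samples))
  list(g = g, pops = pops)
}

paper_fst <- c(zj_wh = 0.0335, zj_yz = 0.5656, zj_py = 0.0955,
               wh_yz = 0.4686, wh_py = 0.1333, yz_py = 0.7518)
paper_dr <- c(zj_wh = 0.0341, zj_yz = 0.8339, zj_py = 0.1004,
              wh_yz = 0.6323, wh_py = 0.1431, yz_py = 1.3935)
paper_nm <- c(zj_wh = 7.2127, zj_yz = 0.1920, zj_py = 2.3678,
              wh_yz = 0.2835, wh_py = 1.6255, yz_py = 0.0825)
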