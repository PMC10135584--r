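#' Simulation configuration for structured genotype data
#'
#' Describes a Balding-Nichols style generative model: ancestral allele
#' frequencies drawn uniformly, `K` ancestral components drifted from them
#' with per-component parameters `component_F`, and populations that mix the
#' components with fixed ancestry weights and add their own per-component
#' drift. An optional founder-effect bottleneck (binomial resampling of
#' frequencies across generations) can be applied to one population.
#'
#' @param n_loci Number of biallelic loci.
#' @param populations List of population descriptors, each a list with
#'   `label`, `n_samples`, `ancestry_weights` (length-K simplex vector) and
#'   `drift_F` (length-K per-component drift in `[0, 1)`).
#' @param component_F Length-K drift of each ancestral component from the
#'   shared ancestral frequency (0 means identical).
#' @param bottleneck Optional list: `population`, `founder_count`,
#'   `drift_generations`, `effective_size`.
#' @param lg_count Number of linkage groups loci are assigned to
#'   (round-robin, increasing positions).
#' @param missing_rate Probability a genotype call is missing.
#' @param maf_floor Ancestral frequencies are drawn from
#'   `Uniform(maf_floor, 1 - maf_floor)`.
#' @param seed Integer seed; the full output is reproducible from
#'   (config, seed).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_loci, populations, component_F,
                       bottleneck = NULL, lg_count = 24L,
                       missing_rate = 0.05, maf_floor = 0.05, seed = 1L) {
  stopifnot(n_loci >= 1L, lg_count >= 1L,
            missing_rate >= 0, missing_rate < 1,
            maf_floor >= 0, maf_floor < 0.5)
  K <- length(component_F)
  if (any(component_F < 0 | component_F >= 1))
    stop("component_F must lie in [0, 1)")
  for (p in populations) {
    stopifnot(!is.null(p$label), p$n_samples >= 1L,
              length(p$ancestry_weights) == K,
              length(p$drift_F) == K)
    if (abs(sum(p$ancestry_weights) - 1) > 1e-9)
      stop("ancestry weights of '", p$label, "' must sum to 1")
    if (any(p$drift_F < 0 | p$drift_F >= 1))
      stop("drift_F of '", p$label, "' must lie in [0, 1)")
  }
  if (!is.null(bottleneck))
    stopifnot(bottleneck$population %in%
                vapply(populations, `[[`, "", "label"),
              bottleneck$founder_count >= 1)
  structure(list(n_loci = as.integer(n_loci), populations = populations,
                 component_F = component_F, bottleneck = bottleneck,
                 lg_count = as.integer(lg_count),
                 missing_rate = missing_rate, maf_floor = maf_floor,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Balding-Nichols draw: Beta around p with dispersion F (F = 0 -> exact).
bn_draw <- function(p, F) {
  if (F == 0) return(p)
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Simulate ancestral, component and population allele frequencies
#'
#' @param cfg A [sim_config()].
#' @return A `sim_truth` list: `ancestral_freqs` (length L),
#'   `component_freqs` (K x L), `pop_freqs` (list per population: K x L,
#'   after population drift and any bottleneck), `Q_true` (samples x K),
#'   `pop_of` (population label per sample), `config`.
#' @export
simulate_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  L <- cfg$n_loci
  K <- length(cfg$component_F)
  anc <- stats::runif(L, cfg$maf_floor, 1 - cfg$maf_floor)
  comp <- t(vapply(cfg$component_F, function(F) bn_draw(anc, F),
                   numeric(L)))
  pop_freqs <- lapply(cfg$populations, function(p) {
    out <- comp
    for (k in seq_len(K)) out[k, ] <- bn_draw(comp[k, ], p$drift_F[k])
    out
  })
  names(pop_freqs) <- vapply(cfg$populations, `[[`, "", "label")
  if (!is.null(cfg$bottleneck)) {
    b <- cfg$bottleneck
    pop_freqs[[b$population]] <- apply_bottleneck(
      pop_freqs[[b$population]], b$founder_count, b$drift_generations,
      b$effective_size, seed = cfg$seed + 7L)
  }
  n_per <- vapply(cfg$populations, function(p) as.integer(p$n_samples), 1L)
  pop_of <- rep(names(pop_freqs), n_per)
  Q_true <- do.call(rbind, lapply(cfg$populations, function(p)
    matrix(p$ancestry_weights, p$n_samples, K, byrow = TRUE)))
  structure(list(ancestral_freqs = anc, component_freqs = comp,
                 pop_freqs = pop_freqs, Q_true = Q_true, pop_of = pop_of,
                 config = cfg),
            class = "sim_truth")
}

#' Drift allele frequencies through a founder-effect bottleneck
#'
#' The founding event resamples each frequency as a binomial draw of
#' `2 * founder_count` alleles; each subsequent generation resamples
#' `2 * effective_size` alleles. Fixed frequencies (0 or 1) are absorbing.
#' An infinite `founder_count` with zero generations leaves frequencies
#' unchanged.
#'
#' @param freqs Numeric vector or matrix of allele frequencies.
#' @param founder_count Number of founding diploid individuals (may be
#'   `Inf`).
#' @param generations Number of generations of drift after founding.
#' @param effective_size Diploid effective size during drift.
#' @param seed Integer seed.
#' @return Drifted frequencies, same shape as `freqs`.
#' @export
apply_bottleneck <- function(freqs, founder_count, generations,
                             effective_size, seed = 1L) {
  stopifnot(founder_count >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shape <- dim(freqs)
  f <- as.numeric(freqs)
  if (is.finite(founder_count))
    f <- stats::rbinom(length(f), 2 * founder_count, f) /
      (2 * founder_count)
  if (generations > 0)
    for (gen in seq_len(generations))
      f <- stats::rbinom(length(f), 2 * effective_size, f) /
        (2 * effective_size)
  if (!is.null(shape)) dim(f) <- shape
  f
}

#' Simulate genotypes from a frequency truth
#'
#' Individual `i` of population `P` with ancestry `q_i` has per-locus
#' success probability `pi_il = sum_k q_ik f^(P)_kl`; its dosage is
#' `Binomial(2, pi_il)`. Missingness is applied uniformly at the configured
#' rate. Loci are placed round-robin on the configured number of linkage
#' groups with increasing positions and two SNPs per restriction tag.
#'
#' @param truth A `sim_truth` from [simulate_frequencies()].
#' @return A list with `genotypes` (a [genotype_matrix()]) and
#'   `populations` (a [population_map()]).
#' @export
simulate_genotypes <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  cfg <- truth$config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1L)
  L <- cfg$n_loci
  n <- length(truth$pop_of)
  P <- matrix(0, n, L)
  for (i in seq_len(n)) {
    fp <- truth$pop_freqs[[truth$pop_of[i]]]
    P[i, ] <- as.numeric(truth$Q_true[i, , drop = FALSE] %*% fp)
  }
  d <- matrix(stats::rbinom(n * L, 2L, as.numeric(P)), n, L)
  if (cfg$missing_rate > 0)
    d[stats::runif(n * L) < cfg$missing_rate] <- NA_integer_
  lg <- rep_len(seq_len(cfg$lg_count), L)
  rank_in_lg <- stats::ave(seq_len(L), lg, FUN = seq_along)
  loci <- data.frame(
    locus_id = sprintf("snp%05d", seq_len(L)),
    linkage_group = paste0("LG", lg),
    position = rank_in_lg * 18000L,
    ref_allele = "A", alt_allele = "G",
    tag_id = sprintf("tag%05d", (seq_len(L) + 1L) %/% 2L),
    ref_has_n = FALSE, stringsAsFactors = FALSE)
  samples <- paste0(truth$pop_of, "_",
                    stats::ave(seq_len(n), truth$pop_of, FUN = seq_along))
  g <- genotype_matrix(d, loci, samples)
  pops <- population_map(stats::setNames(truth$pop_of, samples))
  list(genotypes = g, populations = pops)
}

#' Four-population study preset
#'
#' Emulates a two-ancestry design with four diploid populations: two closely
#' related farmed populations (ZJ, n = 40; WH, n = 30) and one connected
#' wild population (PY, n = 6) drawing at least 90% of their ancestry from
#' component 1, and one isolated wild population (YZ, n = 18) drawing from
#' component 2 with an additional founder-effect bottleneck. Defaults give
#' pairwise differentiation lowest between ZJ and WH, moderate between PY
#' and the farmed pair, and highest for all YZ pairs, with YZ showing the
#' lowest heterozygosity — the qualitative pattern the pipeline is expected
#' to recover.
#'
#' @param seed Integer master seed.
#' @param n_loci Number of loci (default 2000).
#' @return A list: `genotypes`, `populations`, `truth`.
#' @export
study_preset <- function(seed = 1L, n_loci = 2000L) {
  cfg <- sim_config(
    n_loci = n_loci,
    populations = list(
      list(label = "ZJ", n_samples = 40L,
           ancestry_weights = c(0.95, 0.05), drift_F = c(0.01, 0.01)),
      list(label = "WH", n_samples = 30L,
           ancestry_weights = c(0.95, 0.05), drift_F = c(0.01, 0.01)),
      list(label = "YZ", n_samples = 18L,
           ancestry_weights = c(0.03, 0.97), drift_F = c(0.02, 0.02)),
      list(label = "PY", n_samples = 6L,
           ancestry_weights = c(0.90, 0.10), drift_F = c(0.08, 0.08))),
    component_F = c(0.02, 0.35),
    bottleneck = list(population = "YZ", founder_count = 6,
                      drift_generations = 20L, effective_size = 30L),
    lg_count = 24L, missing_rate = 0.05, maf_floor = 0.05, seed = seed)
  truth <- simulate_frequencies(cfg)
  sim <- simulate_genotypes(truth)
  list(genotypes = sim$genotypes, populations = sim$populations,
       truth = truth)
}

#' Write simulation truth as JSON
#'
#' @param truth A `sim_truth`.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  cfg <- truth$config
  jsonlite::write_json(
    list(config = list(
           n_loci = cfg$n_loci, lg_count = cfg$lg_count,
           missing_rate = cfg$missing_rate, maf_floor = cfg$maf_floor,
           seed = cfg$seed, component_F = cfg$component_F,
           populations = cfg$populations, bottleneck = cfg$bottleneck),
         ancestral_freqs = truth$ancestral_freqs,
         component_freqs = truth$component_freqs,
         Q_true = truth$Q_true,
         pop_of = truth$pop_of),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
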