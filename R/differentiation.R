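#' Pairwise Weir-Cockerham fixation index
#'
#' Estimates theta between two populations as the ratio of summed per-locus
#' variance components a (among populations), b (among individuals within
#' populations) and c (within individuals), following the 1984 moment
#' estimator for r = 2 populations. Loci monomorphic across both populations
#' or with fewer than two called genotypes in either population are skipped.
#'
#' @param g A [genotype_matrix()].
#' @param pops A [population_map()].
#' @param a,b Population labels.
#' @return A list: `theta` (ratio of sums), `n_loci` (loci used), and
#'   `components` (data frame of per-locus a, b, c).
#' @export
wc_fst_pair <- function(g, pops, a, b) {
  idx_a <- pop_indices(g, pops, a)
  idx_b <- pop_indices(g, pops, b)
  comp <- wc_components(g$dosage[idx_a, , drop = FALSE],
                        g$dosage[idx_b, , drop = FALSE])
  if (!nrow(comp)) stop("no usable locus for pair ", a, "-", b)
  list(theta = sum(comp$a) / sum(comp$a + comp$b + comp$c),
       n_loci = nrow(comp), components = comp)
}

# Per-locus WC84 variance components for two dosage matrices (samples x loci).
wc_components <- function(da, db) {
  stat <- function(d) {
    nc <- colSums(!is.na(d))
    s <- colSums(d, na.rm = TRUE)
    list(n = nc, p = s / (2 * nc), h = colSums(d == 1L, na.rm = TRUE) / nc)
  }
  sa <- stat(da); sb <- stat(db)
  ok <- sa$n >= 2L & sb$n >= 2L
  n1 <- sa$n[ok]; n2 <- sb$n[ok]
  p1 <- sa$p[ok]; p2 <- sb$p[ok]
  h1 <- sa$h[ok]; h2 <- sb$h[ok]
  nbar <- (n1 + n2) / 2
  nsum <- n1 + n2
  nc <- nsum - (n1^2 + n2^2) / nsum          # (r*nbar - sum n^2/(r*nbar))/(r-1)
  pbar <- (n1 * p1 + n2 * p2) / nsum
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar   # (r-1) = 1 divisor
  hbar <- (n1 * h1 + n2 * h2) / nsum
  poly <- pbar > 0 & pbar < 1
  nbar <- nbar[poly]; nc <- nc[poly]; pbar <- pbar[poly]
  s2 <- s2[poly]; hbar <- hbar[poly]
  A <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  B <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  C <- hbar / 2
  data.frame(locus = which(ok)[poly], a = A, b = B, c = C)
}

#' Permutation significance of a pairwise Fst
#'
#' Shuffles individuals between the two populations (sizes preserved),
#' recomputes theta, and reports
#' `p = (1 + #(theta_perm >= theta_obs)) / (n_perm + 1)`.
#'
#' @param g A [genotype_matrix()].
#' @param pops A [population_map()].
#' @param a,b Population labels.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @return A list: `p_value`, `theta_obs`, `n_perm`.
#' @export
fst_significance <- function(g, pops, a, b, n_perm = 1000L, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  idx_a <- pop_indices(g, pops, a)
  idx_b <- pop_indices(g, pops, b)
  all_idx <- c(idx_a, idx_b)
  na <- length(idx_a)
  theta_of <- function(ia, ib)
    with(wc_components(g$dosage[ia, , drop = FALSE],
                       g$dosage[ib, , drop = FALSE]),
         sum(a) / sum(a + b + c))
  obs <- theta_of(idx_a, idx_b)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample(all_idx)
    t_i <- theta_of(perm[seq_len(na)], perm[-seq_len(na)])
    if (!is.na(t_i) && t_i >= obs) hits <- hits + 1L
  }
  list(p_value = (1 + hits) / (n_perm + 1), theta_obs = obs, n_perm = n_perm)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Reynolds' genetic distance from Fst
#'
#' `DR = -ln(1 - Fst)`; negative Fst is clamped to 0 before the transform.
#'
#' @param fst Fixation index, `< 1`.
#' @return Non-negative distance.
#' @export
reynolds_distance <- function(fst) {
  if (any(fst >= 1, na.rm = TRUE))
    stop("Reynolds' distance undefined for Fst >= 1")
  -log(1 - pmax(fst, 0))
}

#' Gene flow (effective migrants per generation) from Fst
#'
#' `Nm = (1 - Fst) / (4 Fst)` under the island model. `Fst <= 0` yields
#' `Inf` (unbounded exchange); `Fst >= 1` yields 0.
#'
#' @param fst Fixation index.
#' @return Migrants per generation.
#' @export
gene_flow <- function(fst) {
  out <- (1 - fst) / (4 * fst)
  out[fst <= 0] <- Inf
  out[fst >= 1] <- 0
  out
}

#' Categorical interpretation of a fixation index
#'
#' Bands: `< 0.05` low, `[0.05, 0.15)` moderate, `[0.15, 0.25)` large,
#' `>= 0.25` extremely large differentiation (boundaries assigned upward).
#'
#' @param fst Fixation index (finite).
#' @return Character vector of labels.
#' @export
classify_fst <- function(fst) {
  stopifnot(all(is.finite(fst)))
  as.character(cut(fst, breaks = c(-Inf, 0.05, 0.15, 0.25, Inf),
                   right = FALSE,
                   labels = c("low", "moderate", "large", "extremely_large")))
}

#' All pairwise differentiation statistics
#'
#' Computes Weir-Cockerham theta with permutation p-values for every
#' population pair, plus Reynolds' distance, gene flow and the categorical
#' label, each derived from theta (negatives clamped for the transforms).
#'
#' @param g A [genotype_matrix()].
#' @param pops A [population_map()].
#' @param n_perm Permutations per pair; 0 skips significance testing.
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `pairwise_stats`: list with `populations`,
#'   symmetric matrices `fst`, `fst_p`, `dr`, `nm`, character matrix
#'   `fst_class`, and `clamped` (logical matrix: theta was negative).
#' @export
pairwise_all <- function(g, pops, n_perm = 1000L, seed = 1L) {
  pops <- match_popmap(g, pops)
  labels <- unique(unclass(pops))
  if (length(labels) < 2L) stop("need at least two populations")
  k <- length(labels)
  mk <- function(init) matrix(init, k, k, dimnames = list(labels, labels))
  fst <- mk(NA_real_); fp <- mk(NA_real_); dr <- mk(NA_real_)
  nm <- mk(NA_real_); cls <- mk(NA_character_); clamped <- mk(FALSE)
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    a <- labels[i]; b <- labels[j]
    th <- tryCatch(wc_fst_pair(g, pops, a, b)$theta,
                   error = function(e) stop("pair ", a, "-", b, ": ",
                                            conditionMessage(e)))
    fst[i, j] <- fst[j, i] <- th
    if (n_perm > 0L)
      fp[i, j] <- fp[j, i] <-
        fst_significance(g, pops, a, b, n_perm,
                         seed = seed + i * 131L + j)$p_value
    dr[i, j] <- dr[j, i] <- reynolds_distance(th)
    nm[i, j] <- nm[j, i] <- gene_flow(th)
    cls[i, j] <- cls[j, i] <- classify_fst(th)
    clamped[i, j] <- clamped[j, i] <- th < 0
  }
  structure(list(populations = labels, fst = fst, fst_p = fp, dr = dr,
                 nm = nm, fst_class = cls, clamped = clamped),
            class = "pairwise_stats")
}

#' @export
print.pairwise_stats <- function(x, ...) {
  cat("pairwise_stats over", length(x$populations), "populations\n")
  cat("Fst (lower triangle) / Reynolds' DR (upper triangle):\n")
  print(round(combined_fst_dr(x), 4))
  invisible(x)
}

#' Combined Fst/DR matrix in the two-triangle layout
#'
#' Lower triangle carries pairwise Fst, upper triangle Reynolds' DR, the
#' conventional compact presentation of both statistics.
#'
#' @param ps A `pairwise_stats` object.
#' @return Numeric matrix with `NA` diagonal.
#' @export
combined_fst_dr <- function(ps) {
  m <- ps$fst
  m[upper.tri(m)] <- ps$dr[upper.tri(ps$dr)]
  diag(m) <- NA_real_
  m
}
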