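#' Fit the admixture model by expectation-maximization
#'
#' Each individual's two allele copies at each locus are drawn from `K`
#' ancestral components with individual ancestry fractions `Q` and component
#' allele frequencies `F`. The log-likelihood
#' `sum_il [ g_il log(pi_il) + (2 - g_il) log(1 - pi_il) ]` with
#' `pi_il = sum_k q_ik f_kl` (missing genotypes excluded) is maximized by
#' multiplicative EM updates, which never decrease it. Frequencies are
#' clipped to `[1e-6, 1 - 1e-6]`; `Q` rows stay on the simplex by
#' construction. Initialization is seeded: `Q` rows from a symmetric
#' Dirichlet, `F` from perturbed pooled frequencies.
#'
#' @param g A [genotype_matrix()] (LD-pruned input recommended).
#' @param K Number of ancestral components (>= 1).
#' @param seed Integer seed for the initialization.
#' @param tol Stop when the log-likelihood improves by less than this.
#' @param max_iter Iteration cap.
#' @return A list of class `admixture_fit`: `K`, `Q` (samples x K), `F`
#'   (K x loci), `loglik`, `loglik_trace`, `n_iter`, `converged`, `seed`.
#' @export
admixture_fit <- function(g, K, seed = 1L, tol = 1e-4, max_iter = 500L) {
  stopifnot(inherits(g, "genotype_matrix"), K >= 1L)
  d <- g$dosage
  n <- nrow(d); L <- ncol(d)
  called <- !is.na(d)
  Galt <- ifelse(called, d, 0)
  Gref <- ifelse(called, 2L - d, 0)
  L_i <- rowSums(called)
  if (any(L_i == 0L)) stop("sample with no called genotype")
  pooled <- colSums(Galt) / pmax(1, 2 * colSums(called))
  clip <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (K == 1L) {
    Q <- matrix(1, n, 1L)
    F_ <- matrix(clip(pooled), 1L, L)
  } else {
    Q <- matrix(stats::rexp(n * K), n, K)
    Q <- Q / rowSums(Q)
    F_ <- matrix(rep(pooled, each = K), K, L) +
      matrix(stats::runif(K * L, -0.1, 0.1), K, L)
    F_ <- clip(F_)
  }
  em <- .admixture_em_cpp(Galt, Gref, Q, F_, L_i, tol, as.integer(max_iter))
  Q <- em$Q
  F_ <- em$F
  trace <- as.numeric(em$trace)
  rownames(Q) <- g$samples
  colnames(F_) <- g$loci$locus_id
  structure(list(K = as.integer(K), Q = Q, F = F_,
                 loglik = trace[length(trace)], loglik_trace = trace,
                 n_iter = length(trace), converged = em$converged,
                 seed = as.integer(seed)),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("admixture_fit: K =", x$K, " loglik =", format(x$loglik),
      if (x$converged) "(converged," else "(iteration cap,",
      x$n_iter, "iterations)\n")
  invisible(x)
}

#' Cross-validation error for one choice of K
#'
#' Non-missing genotype entries are partitioned into `folds` folds; each
#' fold in turn is masked, the admixture model is refit on the remainder,
#' and the masked entries are scored by their mean binomial deviance against
#' the fitted expected dosage `2 * sum_k q_ik f_kl`. Loci left with no
#' training data in a fold are skipped in its scoring.
#'
#' Each fold's model is fit `n_starts` times from different seeded
#' initializations and the best training likelihood is kept, damping
#' local-optimum noise in the K comparison (the same multi-start practice
#' used when fitting admixture models for interpretation).
#'
#' @param g A [genotype_matrix()].
#' @param K Number of ancestral components.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed (fold assignment and EM initialization).
#' @param tol,max_iter Passed to [admixture_fit()].
#' @param n_starts EM restarts per fold; the best training fit is scored.
#' @return Mean deviance across folds (class-free scalar).
#' @export
cv_error <- function(g, K, folds = 5L, seed = 1L, tol = 1e-3,
                     max_iter = 200L, n_starts = 3L) {
  stopifnot(folds >= 2L)
  d <- g$dosage
  called <- which(!is.na(d))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), length(called)))
  dev_fold <- numeric(folds)
  for (f in seq_len(folds)) {
    mask <- called[fold_of == f]
    gtrain <- g
    gtrain$dosage[mask] <- NA_integer_
    trainable <- colSums(!is.na(gtrain$dosage)) > 0L
    # samples must keep >= 1 called genotype; EM requires it
    if (any(rowSums(!is.na(gtrain$dosage)) == 0L))
      stop("fold leaves a sample without training data; reduce folds")
    fits <- lapply(seq_len(n_starts), function(r)
      admixture_fit(gtrain, K, seed = seed + f + 1000L * (r - 1L),
                    tol = tol, max_iter = max_iter))
    fit <- fits[[which.max(vapply(fits, function(x) x$loglik, 1.0))]]
    mu <- 2 * (fit$Q %*% fit$F)
    keep <- mask[trainable[((mask - 1L) %/% nrow(d)) + 1L]]
    obs <- d[keep]
    mu_k <- pmin(pmax(mu[keep], 1e-9), 2 - 1e-9)
    term <- function(y, m) ifelse(y == 0, 0, y * log(y / m))
    dev_fold[f] <- mean(2 * (term(obs, mu_k) + term(2 - obs, 2 - mu_k)))
  }
  mean(dev_fold)
}

#' Align admixture replicates and measure agreement
#'
#' Replicate fits at the same K are label-aligned to the best-likelihood
#' replicate by greedily matching `Q` columns of maximum correlation. A
#' replicate agrees with the modal solution when its aligned `Q` differs by
#' less than `0.05` mean absolute entry-wise distance.
#'
#' @param results List of [admixture_fit()] objects with equal `K`.
#' @param agree_tol Mean absolute aligned-Q distance below which a replicate
#'   counts as matching.
#' @return A list: `Q_consensus` (mean aligned Q over agreeing replicates),
#'   `n_agree`, `n_total`, `distances`, `reference` (index of the
#'   best-likelihood replicate), `aligned` (list of permuted Q matrices).
#' @export
align_replicates <- function(results, agree_tol = 0.05) {
  stopifnot(length(results) >= 2L)
  Ks <- vapply(results, function(r) r$K, 1L)
  if (length(unique(Ks)) != 1L) stop("replicates have differing K")
  K <- Ks[1L]
  ref_i <- which.max(vapply(results, function(r) r$loglik, 1.0))
  Qref <- results[[ref_i]]$Q
  aligned <- lapply(results, function(r) {
    Q <- r$Q
    if (K == 1L) return(Q)
    cc <- suppressWarnings(stats::cor(Qref, Q))
    cc[!is.finite(cc)] <- -2
    perm <- integer(K)
    used <- logical(K)
    for (step in seq_len(K)) {
      best <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
      perm[best[1L]] <- best[2L]
      cc[best[1L], ] <- -Inf
      cc[, best[2L]] <- -Inf
    }
    Q[, perm, drop = FALSE]
  })
  distances <- vapply(aligned, function(Q) mean(abs(Q - Qref)), 1.0)
  agree <- distances < agree_tol
  list(Q_consensus = Reduce(`+`, aligned[agree]) / sum(agree),
       n_agree = sum(agree), n_total = length(results),
       distances = distances, reference = ref_i, aligned = aligned)
}

#' Scan K by cross-validation error
#'
#' @param g A [genotype_matrix()].
#' @param k_range Integer vector of K values to score.
#' @param folds,seed,tol,max_iter,n_starts Passed to [cv_error()].
#' @return Data frame with columns `K` and `cv_error`; the minimizing row is
#'   the selected model size.
#' @export
cv_scan <- function(g, k_range = 1:5, folds = 5L, seed = 1L, tol = 1e-3,
                    max_iter = 200L, n_starts = 3L) {
  data.frame(K = as.integer(k_range),
             cv_error = vapply(k_range, function(k)
               cv_error(g, k, folds = folds, seed = seed, tol = tol,
                        max_iter = max_iter, n_starts = n_starts), 1.0))
}
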