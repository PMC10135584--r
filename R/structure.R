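#' Sliding-window LD pruning
#'
#' Within windows of `window` loci advanced by `step`, greedily removes the
#' later locus of any pair whose squared Pearson correlation of dosages
#' (pairwise-complete) exceeds `r2`. Windows never span linkage groups; loci
#' are processed in (linkage group, position) order.
#'
#' @param g A [genotype_matrix()].
#' @param window Window size in loci.
#' @param step Window step in loci.
#' @param r2 Squared-correlation threshold above which the later locus is
#'   dropped.
#' @return A list: `kept_locus_ids`, `window`, `step`, `r2`.
#' @export
ld_prune <- function(g, window = 50L, step = 5L, r2 = 0.2) {
  stopifnot(inherits(g, "genotype_matrix"), window >= 2L, step >= 1L,
            r2 > 0, r2 <= 1)
  ord <- order(g$loci$linkage_group, g$loci$position)
  removed <- logical(nrow(g$loci))
  for (lg in unique(g$loci$linkage_group)) {
    idx <- ord[g$loci$linkage_group[ord] == lg]
    L <- length(idx)
    if (L < 2L) next
    d <- g$dosage[, idx, drop = FALSE]
    rem <- logical(L)
    for (start in seq.int(1L, max(1L, L - 1L), by = step)) {
      win <- start:min(start + window - 1L, L)
      act <- win[!rem[win]]
      if (length(act) < 2L) next
      cc <- suppressWarnings(
        stats::cor(d[, act, drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      for (jj in seq_along(act)[-1L]) {
        if (rem[act[jj]]) next
        for (ii in seq_len(jj - 1L)) {
          if (rem[act[ii]]) next
          if (!is.na(cc[ii, jj]) && cc[ii, jj] > r2) {
            rem[act[jj]] <- TRUE
            break
          }
        }
      }
      if (start + window - 1L >= L) break
    }
    removed[idx] <- rem
  }
  list(kept_locus_ids = g$loci$locus_id[ord][!removed[ord]],
       window = as.integer(window), step = as.integer(step), r2 = r2)
}

#' Principal component analysis of genotypes
#'
#' Missing dosages are mean-imputed per locus; loci are centered by `2p` and
#' scaled by `sqrt(2p(1-p))` (the drift-variance scaling standard for SNP
#' PCA); zero-variance loci are dropped. Scores come from the singular value
#' decomposition of the scaled matrix.
#'
#' @param g A [genotype_matrix()].
#' @param n_components Number of leading components to return (default all).
#' @return A list: `scores` (samples x components), `explained_fraction`
#'   (per returned component), `n_loci_used`.
#' @export
pca_genotypes <- function(g, n_components = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (length(g$samples) < 2L) stop("need at least two samples")
  d <- g$dosage
  cm <- colMeans(d, na.rm = TRUE)
  imp <- d
  nas <- which(is.na(imp), arr.ind = TRUE)
  if (nrow(nas)) imp[nas] <- cm[nas[, 2L]]
  p <- cm / 2
  keep <- !is.na(p) & p > 0 & p < 1 & apply(imp, 2L, stats::sd) > 0
  if (!any(keep)) stop("no polymorphic locus for PCA")
  x <- sweep(imp[, keep, drop = FALSE], 2L, 2 * p[keep])
  x <- sweep(x, 2L, sqrt(2 * p[keep] * (1 - p[keep])), "/")
  sv <- svd(x)
  ev <- sv$d^2
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  # deterministic sign: largest-magnitude loading positive per component
  for (k in seq_len(ncol(scores))) {
    v <- sv$v[, k]
    if (v[which.max(abs(v))] < 0) scores[, k] <- -scores[, k]
  }
  rownames(scores) <- g$samples
  nc <- if (is.null(n_components)) ncol(scores) else
    min(n_components, ncol(scores))
  list(scores = scores[, seq_len(nc), drop = FALSE],
       explained_fraction = (ev / sum(ev))[seq_len(nc)],
       n_loci_used = sum(keep))
}

#' Pairwise p-distance between two samples
#'
#' Mean over co-called loci of `|dosage_i - dosage_j| / 2`: the proportion
#' of allele differences between two diploid genotypes.
#'
#' @param g A [genotype_matrix()].
#' @param i,j Sample indices or names.
#' @return Value in `[0, 1]`; `NA` (with a warning) when the two samples
#'   share no called locus.
#' @export
p_distance <- function(g, i, j) {
  if (is.character(i)) i <- match(i, g$samples)
  if (is.character(j)) j <- match(j, g$samples)
  di <- g$dosage[i, ]; dj <- g$dosage[j, ]
  ok <- !is.na(di) & !is.na(dj)
  if (!any(ok)) {
    warning("no co-called locus for samples ", i, " and ", j)
    return(NA_real_)
  }
  mean(abs(di[ok] - dj[ok])) / 2
}

#' All-pairs p-distance matrix
#'
#' @param g A [genotype_matrix()].
#' @param loci Optional locus index vector (e.g. a bootstrap resample;
#'   indices may repeat).
#' @return Symmetric matrix of p-distances with zero diagonal.
#' @export
p_distance_matrix <- function(g, loci = NULL) {
  d <- g$dosage
  if (!is.null(loci)) d <- d[, loci, drop = FALSE]
  M <- !is.na(d)
  A0 <- (!is.na(d) & d == 0L) + 0
  A1 <- (!is.na(d) & d == 1L) + 0
  A2 <- (!is.na(d) & d == 2L) + 0
  co <- tcrossprod(M + 0)
  diff1 <- tcrossprod(A0, A1) + tcrossprod(A1, A0) +
    tcrossprod(A1, A2) + tcrossprod(A2, A1)
  diff2 <- tcrossprod(A0, A2) + tcrossprod(A2, A0)
  out <- (diff1 + 2 * diff2) / (2 * co)
  out[co == 0] <- NA_real_
  diag(out) <- 0
  dimnames(out) <- list(g$samples, g$samples)
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomerative neighbor joining with the rate-corrected selection
#' criterion `Q_ij = (m - 2) d_ij - R_i - R_j`; ties are broken by the
#' lexicographically smallest pair of node labels (internal nodes inherit
#' their smallest leaf label). Negative branch lengths are clamped to zero.
#' Three remaining nodes are joined in an unrooted trifurcation by the
#' three-point formulas; two taxa yield a single edge split evenly.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param labels Taxon labels (default from `d` dimnames).
#' @return A list of class `nj_tree`: `newick` (text) and `phylo`
#'   (an [ape::read.tree()] object).
#' @export
nj_tree <- function(d, labels = rownames(d)) {
  d <- as.matrix(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
    stop("distance matrix must be symmetric")
  if (any(is.na(d))) stop("distance matrix contains NA")
  m <- nrow(d)
  if (m < 2L) stop("need at least two taxa")
  nwk <- labels          # growing subtree strings
  lab <- labels          # tie-break label per active node
  while (m > 3L) {
    R <- rowSums(d)
    Q <- (m - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- apply(cand, 1L, function(ij)
      paste(sort(c(lab[ij[1L]], lab[ij[2L]])), collapse = "\r"))
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- max(0, d[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2)))
    lj <- max(0, d[i, j] - (d[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))))
    new_d <- (d[i, ] + d[j, ] - d[i, j]) / 2
    merged <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], li, nwk[j], lj)
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], new_d[keep]),
               c(new_d[keep], 0))
    nwk <- c(nwk[keep], merged)
    lab <- c(lab[keep], min(lab[c(i, j)]))
    m <- m - 1L
  }
  newick <- if (m == 2L) {
    sprintf("(%s:%.10g,%s:%.10g);", nwk[1L], d[1, 2] / 2, nwk[2L], d[1, 2] / 2)
  } else {
    l1 <- max(0, (d[1, 2] + d[1, 3] - d[2, 3]) / 2)
    l2 <- max(0, (d[1, 2] + d[2, 3] - d[1, 3]) / 2)
    l3 <- max(0, (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
            nwk[1L], l1, nwk[2L], l2, nwk[3L], l3)
  }
  structure(list(newick = newick, phylo = ape::read.tree(text = newick)),
            class = "nj_tree")
}

#' @export
print.nj_tree <- function(x, ...) {
  cat("nj_tree with", length(x$phylo$tip.label), "tips\n")
  if (!is.null(x$support))
    cat("bootstrap supports on", length(x$support), "internal splits\n")
  invisible(x)
}

# Canonical bipartition keys of a phylo's internal edges (side not
# containing the alphabetically first tip label).
tree_splits <- function(phy) {
  tips <- phy$tip.label
  ref <- sort(tips)[1L]
  parts <- ape::prop.part(phy)
  keys <- character(0)
  for (p in parts) {
    side <- tips[p]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2L && length(side) <= length(tips) - 2L)
      keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Neighbor-joining tree with locus-bootstrap support
#'
#' Builds the full-data p-distance NJ tree, then resamples loci with
#' replacement `n_boot` times, rebuilds the tree, and reports for each
#' internal bipartition of the full tree the fraction of replicates
#' containing it.
#'
#' @param g A [genotype_matrix()].
#' @param n_boot Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the resampling stream.
#' @return An `nj_tree` whose `support` element maps bipartition keys to
#'   support in `[0, 1]`, with `newick_support` carrying supports as
#'   internal node labels.
#' @export
nj_bootstrap <- function(g, n_boot = 1000L, seed = 1L) {
  stopifnot(n_boot >= 1L)
  full <- nj_tree(p_distance_matrix(g))
  obs <- tree_splits(full$phylo)
  count <- stats::setNames(numeric(length(obs)), obs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  L <- nrow(g$loci)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(L, L, replace = TRUE)
    bt <- nj_tree(p_distance_matrix(g, loci = idx))
    hit <- intersect(obs, tree_splits(bt$phylo))
    count[hit] <- count[hit] + 1
  }
  full$support <- count / n_boot
  full$n_boot <- n_boot
  full$newick_support <- annotate_supports(full$phylo, full$support)
  full
}

# Write supports as internal node labels of the full tree.
annotate_supports <- function(phy, support) {
  tips <- phy$tip.label
  ref <- sort(tips)[1L]
  parts <- ape::prop.part(phy)
  lab <- rep("", phy$Nnode)
  for (k in seq_along(parts)) {
    side <- tips[parts[[k]]]
    if (ref %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support))
      lab[k] <- format(support[[key]], digits = 3)
  }
  phy$node.label <- lab
  ape::write.tree(phy)
}
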