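#' Run configuration for the end-to-end pipeline
#'
#' All randomness flows from one master seed through named substreams
#' (simulation, permutation, bootstrap, EM) so a manifest reproduces every
#' numeric output.
#'
#' @param vcf,popmap Input paths (ignored when `genotypes` is supplied).
#' @param filter A [filter_config()].
#' @param n_perm Permutations per population pair (0 disables).
#' @param k_range K values scanned by cross-validation.
#' @param replicates Admixture replicates at the selected K.
#' @param n_boot Bootstrap replicates for the NJ tree (0 disables).
#' @param cv_folds Cross-validation folds.
#' @param prune Logical: LD-prune before structure analyses.
#' @param run_structure Logical: run the structure stage at all.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(vcf = NULL, popmap = NULL, filter = filter_config(),
                       n_perm = 1000L, k_range = 1:4, replicates = 10L,
                       n_boot = 100L, cv_folds = 5L, prune = TRUE,
                       run_structure = TRUE, seed = 1L, out_dir = ".") {
  structure(list(vcf = vcf, popmap = popmap, filter = filter,
                 n_perm = as.integer(n_perm), k_range = as.integer(k_range),
                 replicates = as.integer(replicates),
                 n_boot = as.integer(n_boot), cv_folds = as.integer(cv_folds),
                 prune = isTRUE(prune), run_structure = isTRUE(run_structure),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# Named seed substreams derived from the master seed (kept < 2^31).
derive_seeds <- function(seed) {
  list(sim = seed, perm = seed + 101L, boot = seed + 202L, em = seed + 303L)
}

#' Run the full analysis pipeline
#'
#' Filter -> per-population diversity -> pairwise differentiation ->
#' structure (LD pruning, PCA, cross-validated admixture, NJ tree with
#' bootstrap). Writes a report bundle mirroring the conventional table
#' layouts: `filter_report.tsv`, `table1.tsv` (diversity), `table2.tsv`
#' (Fst lower / DR upper triangle), `table3.tsv` (Nm lower triangle),
#' `classes.tsv`, `gene_flow_edges.tsv`, `pca_scores.tsv`,
#' `cv_errors.tsv`, `Q_K<k>.tsv`, `tree.nwk` and `manifest.json`. Any
#' stage failure aborts with the stage name; outputs of completed stages
#' persist.
#'
#' @param cfg A [run_config()].
#' @param genotypes,populations Optional in-memory inputs overriding the
#'   paths in `cfg`.
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(cfg, genotypes = NULL, populations = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- list()

  if (is.null(genotypes)) {
    io <- stage("genotype_io", read_vcf(cfg$vcf, cfg$popmap))
    genotypes <- io$genotypes
    populations <- io$populations
  }
  populations <- match_popmap(genotypes, populations)

  flt <- stage("snp_filter", apply_filters(genotypes, cfg$filter))
  g <- flt$genotypes
  out$filter <- flt$report
  write_filter_report(flt$report, file.path(cfg$out_dir, "filter_report.tsv"))
  if (nrow(g$loci) == 0L)
    stop("pipeline stage 'snp_filter' failed: no locus survived",
         call. = FALSE)

  out$diversity <- stage("diversity", population_summary(g, populations))
  tab1 <- out$diversity
  num <- vapply(tab1, is.numeric, TRUE) & names(tab1) != "n_samples" &
    names(tab1) != "n_loci_used"
  tab1[num] <- lapply(tab1[num], function(x) sprintf("%.4f", x))
  utils::write.table(tab1, file.path(cfg$out_dir, "table1.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  out$pairwise <- stage("differentiation",
                        pairwise_all(g, populations, n_perm = cfg$n_perm,
                                     seed = seeds$perm))
  write_pairwise_tables(out$pairwise, cfg$out_dir)

  if (cfg$run_structure) {
    gs <- g
    if (cfg$prune) {
      out$pruned <- stage("structure", ld_prune(g))
      gs <- subset_genotypes(g, loci = out$pruned$kept_locus_ids)
    }
    out$pca <- stage("structure", pca_genotypes(gs, n_components = 10L))
    utils::write.table(
      data.frame(sample = rownames(out$pca$scores),
                 population = unclass(populations)[rownames(out$pca$scores)],
                 round(out$pca$scores, 6)),
      file.path(cfg$out_dir, "pca_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)

    out$cv <- stage("structure",
                    cv_scan(gs, cfg$k_range, folds = cfg$cv_folds,
                            seed = seeds$em))
    utils::write.table(out$cv, file.path(cfg$out_dir, "cv_errors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    best_k <- out$cv$K[which.min(out$cv$cv_error)]
    out$best_k <- best_k

    out$replicates <- stage("structure", lapply(seq_len(cfg$replicates),
      function(r) admixture_fit(gs, best_k, seed = seeds$em + r)))
    out$alignment <- if (cfg$replicates >= 2L)
      stage("structure", align_replicates(out$replicates)) else NULL
    Qbest <- if (!is.null(out$alignment)) out$alignment$Q_consensus else
      out$replicates[[1L]]$Q
    utils::write.table(
      data.frame(sample = gs$samples,
                 population = unclass(populations)[gs$samples],
                 round(Qbest, 6)),
      file.path(cfg$out_dir, sprintf("Q_K%d.tsv", best_k)),
      sep = "\t", quote = FALSE, row.names = FALSE)

    out$tree <- stage("structure", if (cfg$n_boot > 0L)
      nj_bootstrap(gs, n_boot = cfg$n_boot, seed = seeds$boot) else
      nj_tree(p_distance_matrix(gs)))
    writeLines(if (!is.null(out$tree$newick_support))
      out$tree$newick_support else out$tree$newick,
      file.path(cfg$out_dir, "tree.nwk"))
  }

  manifest <- list(
    package = "radpop",
    version = as.character(utils::packageVersion("radpop")),
    r_version = as.character(getRversion()),
    seed = cfg$seed, seeds = seeds,
    filter = unclass(cfg$filter),
    n_perm = cfg$n_perm, k_range = cfg$k_range,
    replicates = cfg$replicates, n_boot = cfg$n_boot,
    cv_folds = cfg$cv_folds, prune = cfg$prune,
    run_structure = cfg$run_structure,
    inputs = list(vcf = cfg$vcf, popmap = cfg$popmap))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}

write_filter_report <- function(report, path) {
  utils::write.table(
    data.frame(rule = c("input", names(report$removed_by_rule), "output"),
               n = c(report$n_input, unname(report$removed_by_rule),
                     report$n_output)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# table2 (Fst lower / DR upper), table3 (Nm lower), classes, edge list.
write_pairwise_tables <- function(ps, out_dir) {
  fmt <- function(m, digits = 4) {
    x <- format(round(m, digits), nsmall = digits)
    x[is.na(m)] <- "-"
    x[is.infinite(m)] <- "Inf"
    data.frame(POP = rownames(m), x, check.names = FALSE)
  }
  t2 <- combined_fst_dr(ps)
  utils::write.table(fmt(t2), file.path(out_dir, "table2.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  t3 <- ps$nm
  t3[upper.tri(t3, diag = TRUE)] <- NA
  utils::write.table(fmt(t3), file.path(out_dir, "table3.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  k <- length(ps$populations)
  pairs <- which(lower.tri(ps$fst), arr.ind = TRUE)
  edges <- data.frame(
    pop_a = ps$populations[pairs[, 2L]],
    pop_b = ps$populations[pairs[, 1L]],
    fst = ps$fst[pairs], fst_p = ps$fst_p[pairs],
    dr = ps$dr[pairs], nm = ps$nm[pairs],
    class = ps$fst_class[pairs])
  utils::write.table(edges, file.path(out_dir, "gene_flow_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- ps$fst_class
  cl[upper.tri(cl, diag = TRUE)] <- "-"
  utils::write.table(data.frame(POP = rownames(cl), cl, check.names = FALSE),
                     file.path(out_dir, "classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
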