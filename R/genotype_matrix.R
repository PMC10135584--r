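#' Construct a genotype matrix
#'
#' The central container of the package: diploid alternate-allele dosages for
#' a set of samples at a set of biallelic SNP loci, together with per-locus
#' metadata. Dosages count copies of the alternate allele (0, 1, 2); missing
#' genotypes are `NA`.
#'
#' @param dosage Integer matrix, samples in rows, loci in columns; entries in
#'   `{0, 1, 2, NA}`. Row and column names, if absent, are taken from
#'   `samples` and `loci$locus_id`.
#' @param loci Data frame of locus records with columns `locus_id`,
#'   `linkage_group`, `position` (1-based bp), `ref_allele`, `alt_allele`,
#'   `tag_id` (restriction-tag identifier), `ref_has_n` (logical: reference
#'   context contains an N). Missing `tag_id` defaults to `locus_id`;
#'   missing `ref_has_n` defaults to `FALSE`.
#' @param samples Character vector of sample identifiers, one per row.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `loci`, `samples`.
#' @export
genotype_matrix <- function(dosage, loci, samples = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(samples)) stop("sample identifiers are required")
  samples <- as.character(samples)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (is.null(loci$tag_id)) loci$tag_id <- loci$locus_id
  if (is.null(loci$ref_has_n)) loci$ref_has_n <- FALSE
  required <- c("locus_id", "linkage_group", "position",
                "ref_allele", "alt_allele", "tag_id", "ref_has_n")
  miss <- setdiff(required, names(loci))
  if (length(miss)) stop("loci table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(dosage) != length(samples))
    stop("dosage has ", nrow(dosage), " rows but ", length(samples), " samples")
  if (ncol(dosage) != nrow(loci))
    stop("dosage has ", ncol(dosage), " columns but ", nrow(loci), " loci")
  if (anyDuplicated(loci$locus_id))
    stop("locus_id values must be unique")
  if (any(loci$position < 1)) stop("locus positions must be >= 1")
  same <- loci$ref_allele == loci$alt_allele
  if (any(same)) stop("ref and alt allele identical at locus ",
                      loci$locus_id[which(same)[1L]])
  bad <- dosage[!is.na(dosage) & !(dosage %in% 0:2)]
  if (length(bad)) stop("dosages must lie in {0, 1, 2, NA}")
  rownames(dosage) <- samples
  colnames(dosage) <- loci$locus_id
  structure(list(dosage = dosage, loci = loci, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$dosage))
  cat("genotype_matrix: ", length(x$samples), " samples x ",
      nrow(x$loci), " loci (",
      format(100 * nmiss / max(1L, length(x$dosage)), digits = 3),
      "% missing)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param g A [genotype_matrix()].
#' @param samples Indices or names of samples to keep (default all).
#' @param loci Indices or names of loci to keep (default all).
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(g, samples = NULL, loci = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  si <- if (is.null(samples)) seq_along(g$samples) else samples
  li <- if (is.null(loci)) seq_len(nrow(g$loci)) else loci
  if (is.character(si)) si <- match(si, g$samples)
  if (is.character(li)) li <- match(li, g$loci$locus_id)
  if (anyNA(si)) stop("unknown sample in selection")
  if (anyNA(li)) stop("unknown locus in selection")
  genotype_matrix(g$dosage[si, li, drop = FALSE],
                  g$loci[li, , drop = FALSE],
                  g$samples[si])
}

#' Construct a population map
#'
#' @param assignment Named character vector mapping sample id to population
#'   label, or a two-column data frame (sample, population).
#' @return An object of class `population_map`: a named character vector.
#' @export
population_map <- function(assignment) {
  if (is.data.frame(assignment)) {
    x <- as.character(assignment[[2L]])
    names(x) <- as.character(assignment[[1L]])
    assignment <- x
  }
  if (is.null(names(assignment)) || any(names(assignment) == ""))
    stop("every sample needs a name in the population map")
  if (anyDuplicated(names(assignment)))
    stop("duplicate sample in population map: ",
         names(assignment)[anyDuplicated(assignment)][1L])
  structure(as.character(stats::setNames(assignment, names(assignment))),
            names = names(assignment), class = "population_map")
}

#' @export
print.population_map <- function(x, ...) {
  tab <- table(unclass(x))
  cat("population_map: ", length(x), " samples in ", length(tab),
      " populations (", paste(names(tab), tab, sep = "=", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# Check that every sample of g is assigned; returns the map restricted and
# ordered to g$samples.
match_popmap <- function(g, pops) {
  missing <- setdiff(g$samples, names(pops))
  if (length(missing))
    stop("samples absent from population map: ",
         paste(missing, collapse = ", "))
  structure(unclass(pops)[g$samples], names = g$samples,
            class = "population_map")
}

# Sample indices for one population label.
pop_indices <- function(g, pops, label) {
  pops <- match_popmap(g, pops)
  idx <- which(unclass(pops) == label)
  if (!length(idx)) stop("no samples in population '", label, "'")
  idx
}
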