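# VCF fixture used across I/O tests: 3 samples, 2 biallelic loci plus one
# multiallelic record that must be dropped.
write_fixture_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=TAG,Number=1,Type=String,Description="tag">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM","POS","ID","REF","ALT","QUAL","FILTER","INFO","FORMAT",
            "ind1","ind2","ind3"), collapse = "\t"),
    "LG1\t100\tsnpA\tA\tG\t.\tPASS\tTAG=tag1\tGT\t0/0\t0/1\t1/1",
    "LG1\t200\tsnpB\tC\tT\t.\tPASS\tTAG=tag1;REFN\tGT\t./.\t1|0\t0/0",
    "LG2\t300\tsnpC\tG\tA,T\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2"), path)
  path
}

write_fixture_popmap <- function(path, samples = c("ind1","ind2","ind3")) {
  writeLines(paste(samples, c("P1","P1","P2"), sep = "\t"), path)
  path
}

test_that("read_vcf encodes dosages, missing calls and INFO keys", {
  vcf <- write_fixture_vcf(withr::local_tempfile(fileext = ".vcf"))
  pm <- write_fixture_popmap(withr::local_tempfile(fileext = ".tsv"))
  expect_warning(io <- read_vcf(vcf, pm), "multiallelic")
  g <- io$genotypes
  expect_equal(dim(g), c(3L, 2L))
  expect_equal(unname(g$dosage[, "snpA"]), c(0L, 1L, 2L))
  # ./. missing, phased 1|0 het
  expect_equal(unname(g$dosage[, "snpB"]), c(NA_integer_, 1L, 0L))
  expect_equal(g$loci$tag_id, c("tag1", "tag1"))
  expect_equal(g$loci$ref_has_n, c(FALSE, TRUE))
  expect_equal(unname(unclass(io$populations)), c("P1", "P1", "P2"))
})

test_that("read_vcf rejects unmapped samples and unparsable genotypes", {
  vcf <- write_fixture_vcf(withr::local_tempfile(fileext = ".vcf"))
  pm <- withr::local_tempfile(fileext = ".tsv")
  writeLines("ind1\tP1", pm)
  expect_error(suppressWarnings(read_vcf(vcf, pm)), "ind2")
  bad <- withr::local_tempfile(fileext = ".vcf")
  txt <- readLines(write_fixture_vcf(withr::local_tempfile(fileext = ".vcf")))
  txt[5] <- sub("0/1", "x/y", txt[5])
  writeLines(txt, bad)
  expect_error(suppressWarnings(read_vcf(bad, pm)), "unparsable GT")
})

test_that("write_vcf / read_vcf round-trips dosages and missingness", {
  set.seed(42)
  d <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 5, 12)
  g <- toy_genotypes(d, tag = rep(paste0("tag", 1:6), each = 2),
                     ref_n = rep(c(FALSE, TRUE), 6))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  pm <- withr::local_tempfile(fileext = ".tsv")
  write_vcf(g, vcf)
  write_popmap(population_map(stats::setNames(rep("P", 5), g$samples)), pm)
  g2 <- read_vcf(vcf, pm)$genotypes
  expect_equal(unname(g2$dosage), unname(g$dosage))
  expect_equal(g2$loci$tag_id, g$loci$tag_id)
  expect_equal(g2$loci$ref_has_n, g$loci$ref_has_n)
})

test_that("allele_frequency counts alleles and honors subsets", {
  g <- toy_genotypes(matrix(c(0, 0, 0,
                              0, 1, 2,
                              2, NA, NA), 3, 3))
  expect_equal(allele_frequency(g, 1)$p_alt, 0)
  expect_equal(allele_frequency(g, 1)$n_called, 3L)
  expect_equal(allele_frequency(g, 2)$p_alt, 0.5)
  af <- allele_frequency(g, 3)
  expect_equal(af$p_alt, 1.0)
  expect_equal(af$n_called, 1L)
  # all-missing subset is flagged, not silently zero
  expect_true(is.na(allele_frequency(g, 3, samples = 2:3)$p_alt))
})

test_that("allele frequencies are permutation-invariant and merge by
           allele-count weighting", {
  set.seed(7)
  for (rep in 1:20) {
    d <- matrix(sample(c(0:2, NA), 40, replace = TRUE,
                       prob = c(.3, .3, .3, .1)), 8, 5)
    if (all(is.na(d[, 3]))) next
    g <- toy_genotypes(d)
    perm <- sample(8)
    gp <- subset_genotypes(g, samples = perm)
    expect_equal(allele_frequency(gp, 3)$p_alt,
                 allele_frequency(g, 3)$p_alt)
    s1 <- 1:3; s2 <- 4:8
    a1 <- allele_frequency(g, 3, s1); a2 <- allele_frequency(g, 3, s2)
    tot <- allele_frequency(g, 3)
    if (tot$n_called > 0) {
      w <- sum(a1$p_alt * a1$n_alleles, a2$p_alt * a2$n_alleles,
               na.rm = TRUE) / tot$n_alleles
      expect_equal(tot$p_alt, w)
    }
  }
})

test_that("snp_density_summary reports per-LG spacing in kb", {
  loci <- data.frame(locus_id = paste0("L", 1:3), linkage_group = "LG1",
                     position = c(1000L, 11000L, 21000L),
                     ref_allele = "A", alt_allele = "G",
                     tag_id = paste0("L", 1:3), ref_has_n = FALSE)
  s <- snp_density_summary(loci)
  expect_equal(s$per_lg$kb_per_snp, 10.0)
  expect_equal(s$overall_kb_per_snp, 10.0)
  # single-SNP group: count reported, spacing undefined
  loci2 <- rbind(loci, within(loci[1, ], {
    locus_id <- "L4"; linkage_group <- "LG2"
  }))
  s2 <- snp_density_summary(loci2)
  expect_equal(s2$per_lg$n_snps, c(3L, 1L))
  expect_true(is.na(s2$per_lg$kb_per_snp[2]))
  # two LGs with 2 SNPs each
  loci3 <- loci[rep(1:2, 2), ]
  loci3$locus_id <- paste0("M", 1:4)
  loci3$linkage_group <- rep(c("LG1", "LG2"), each = 2)
  expect_equal(snp_density_summary(loci3)$per_lg$n_snps, c(2L, 2L))
})
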