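test_that("per-locus diversity statistics follow their closed forms", {
  expect_equal(observed_heterozygosity(c(1L, 1L, 1L)), 1.0)
  expect_equal(observed_heterozygosity(c(0L, 2L, 0L, 2L)), 0.0)
  expect_equal(observed_heterozygosity(c(0L, 1L, 2L, NA)), 1 / 3)
  expect_error(observed_heterozygosity(c(NA_integer_, NA_integer_)),
               "no called")

  expect_equal(expected_heterozygosity(0.5), 0.5)
  expect_equal(expected_heterozygosity(0), 0)
  expect_equal(expected_heterozygosity(0.25), 0.375)

  expect_equal(nucleotide_diversity_site(0.5, 2), 1.0)
  expect_equal(nucleotide_diversity_site(0, 10), 0)
  expect_equal(nucleotide_diversity_site(0.5, 60), 0.5 * 60 / 59)
  expect_true(is.na(nucleotide_diversity_site(0.5, 1)))

  expect_equal(pic_biallelic(0.5), 0.375)
  expect_equal(pic_biallelic(0), 0)
  expect_equal(pic_biallelic(0.1), 2 * 0.09 * (1 - 0.09))
  # PIC = 2pq(1 - pq) algebraic identity
  p <- seq(0, 1, by = 0.05)
  expect_equal(pic_biallelic(p), 2 * p * (1 - p) * (1 - p * (1 - p)))

  expect_equal(effective_alleles(0.5), 2.0)
  expect_equal(effective_alleles(0), 1.0)
  expect_equal(effective_alleles(0.2), 1 / 0.68)
})

test_that("HWE exact test matches enumeration oracle on frozen cases", {
  # frozen from the independent multinomial-enumeration oracle
  expect_equal(hwe_exact_test(5, 0, 5), 0.001363961, tolerance = 1e-6)
  expect_equal(hwe_exact_test(1, 2, 1), 1.0)
  expect_equal(hwe_exact_test(0, 0, 7), 1.0)  # monomorphic
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
  # spot equivalence on a few mixed tables
  for (tab in list(c(3, 1, 6), c(2, 8, 2), c(0, 5, 9), c(4, 4, 1)))
    expect_equal(hwe_exact_test(tab[1], tab[2], tab[3]),
                 oracle_hwe_p(tab[1], tab[2], tab[3]), tolerance = 1e-10)
})

test_that("population_summary matches a hand-computed 5-locus table", {
  # population P1: 3 samples, P2: 2 samples
  d <- rbind(
    a1 = c(0L, 1L, 2L, 0L, NA),
    a2 = c(0L, 1L, 1L, 0L, 1L),
    a3 = c(0L, 0L, 2L, 1L, 1L),
    b1 = c(0L, 2L, 2L, 0L, 0L),
    b2 = c(0L, 2L, 1L, 0L, 0L))
  g <- toy_genotypes(d)
  pops <- population_map(stats::setNames(c("P1", "P1", "P1", "P2", "P2"),
                                         rownames(d)))
  sm <- population_summary(g, pops)
  p1 <- sm[sm$population == "P1", ]
  # by hand, P1 per locus: p = 0, 1/3, 5/6, 1/6, 1/2(2 called)
  ps <- c(0, 1/3, 5/6, 1/6, 1/2)
  ns <- c(6, 6, 6, 6, 4)
  expect_equal(p1$Ho, mean(c(0, 2/3, 1/3, 1/3, 1)))
  expect_equal(p1$He, mean(2 * ps * (1 - ps)))
  expect_equal(p1$Pi, mean(2 * ps * (1 - ps) * ns / (ns - 1)))
  expect_equal(p1$PIC, mean(pic_biallelic(ps)))
  expect_equal(p1$Ne, mean(1 / (ps^2 + (1 - ps)^2)))
  expect_equal(p1$HW_P, mean(c(1, oracle_hwe_p(1, 2, 0),
                               oracle_hwe_p(0, 1, 2),
                               oracle_hwe_p(2, 1, 0),
                               oracle_hwe_p(0, 2, 0))))
  expect_equal(p1$n_loci_used, 5L)
})

test_that("an all-monomorphic population collapses to the fixed point", {
  d <- rbind(s1 = c(0L, 2L), s2 = c(0L, 2L), s3 = c(0L, 2L))
  g <- toy_genotypes(d)
  pops <- population_map(stats::setNames(rep("P", 3), rownames(d)))
  sm <- population_summary(g, pops)
  expect_equal(sm$Ho, 0); expect_equal(sm$He, 0); expect_equal(sm$Pi, 0)
  expect_equal(sm$PIC, 0); expect_equal(sm$Ne, 1); expect_equal(sm$HW_P, 1)
})

test_that("population with a single sample carries a low-n flag", {
  d <- rbind(s1 = c(0L, 1L), s2 = c(1L, 1L), s3 = c(2L, 0L))
  g <- toy_genotypes(d)
  pops <- population_map(stats::setNames(c("A", "A", "B"), rownames(d)))
  expect_warning(sm <- population_summary(g, pops), "fewer than 2")
  expect_true(sm$low_n[sm$population == "B"])
})

test_that("a bottlenecked population shows reduced heterozygosity", {
  lower <- vapply(1:10, function(s) {
    set.seed(s)
    p <- runif(400, 0.1, 0.9)
    pb <- apply_bottleneck(p, founder_count = 3, generations = 20,
                           effective_size = 30, seed = s)
    d_src <- matrix(rbinom(30 * 400, 2, rep(p, each = 30)), 30, 400)
    d_bn <- matrix(rbinom(30 * 400, 2, rep(pb, each = 30)), 30, 400)
    g <- toy_genotypes(rbind(d_src, d_bn))
    pops <- population_map(stats::setNames(rep(c("SRC", "BN"), each = 30),
                                           g$samples))
    sm <- population_summary(g, pops)
    sm$He[sm$population == "BN"] < sm$He[sm$population == "SRC"]
  }, TRUE)
  expect_true(all(lower))
})

test_that("structural inequalities hold for every simulated population", {
  sim <- study_preset(seed = 5, n_loci = 300)
  g <- apply_filters(sim$genotypes)$genotypes
  sm <- population_summary(g, sim$populations)
  expect_true(all(sm$Pi >= sm$He))
  expect_true(all(sm$PIC <= sm$He))
  expect_true(all(sm$Ne >= 1 / (1 - sm$He)))
})
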