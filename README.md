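# radpop

Population-genetic diversity and structure analysis for biallelic SNP
genotypes from reduced-representation (RAD-type) sequencing, written for
conservation-genetics studies that compare wild and farmed populations from
a few thousand to a few hundred thousand markers.

Starting from a multi-sample VCF and a sample-to-population map, the
package covers the standard analysis chain:

- **SNP quality filtering** — a fixed-order cascade removing monomorphic
  loci, loci whose reference context contains an N, restriction tags
  carrying more than two SNPs, duplicated genomic positions, loci typable
  in fewer than 80% of samples, and loci with pooled minor allele frequency
  below 0.01, with per-rule attrition reporting.
- **Per-population diversity** — observed heterozygosity
  ``Ho``, expected heterozygosity ``He = 2pq``, per-site nucleotide
  diversity ``Pi = 2pq·n/(n−1)`` (``n`` sampled alleles), an exact
  Hardy–Weinberg test by enumeration of heterozygote counts conditional on
  allele counts, Botstein's polymorphism information content
  ``PIC = 1 − p² − q² − 2p²q²``, and the effective allele number
  ``Ne = 1/(p² + q²)``, each computed per locus and averaged.
- **Pairwise differentiation** — the Weir–Cockerham (1984) fixation index
  ``θ`` as a ratio of summed variance components, permutation significance,
  Reynolds' genetic distance ``DR = −ln(1 − Fst)``, island-model gene flow
  ``Nm = (1 − Fst)/(4·Fst)``, and the conventional four-band categorical
  interpretation (low < 0.05 ≤ moderate < 0.15 ≤ large < 0.25 ≤ extremely
  large).
- **Population structure** — sliding-window LD pruning on genotype
  correlation, PCA with drift-variance scaling, neighbor-joining trees on
  p-distance with locus-bootstrap support, and an admixture model
  (ancestry fractions ``Q``, component frequencies ``F``) fit by an EM
  algorithm with a provable likelihood-ascent property, with the number of
  ancestral components ``K`` chosen by masked-genotype cross-validation.
- **Synthetic data with known truth** — a Balding–Nichols generator whose
  drift parameter ``F`` equals the pairwise ``Fst`` it induces, plus a
  founder-effect bottleneck model and a four-population study preset, so
  every estimator can be validated closed-loop.

## Worked example

Simulate the four-population study design (two closely related farmed
populations ZJ and WH, a connected wild population PY, and an isolated
bottlenecked wild population YZ; 94 individuals), then run the analysis:

```r
library(radpop)

sim <- study_preset(seed = 1, n_loci = 2000)
flt <- apply_filters(sim$genotypes)
flt$report
#> filter_report: 2000 -> 1991 loci
#>   monomorphic            1
#>   ref_n                  0
#>   excess_snps_per_tag    0
#>   duplicate_position     0
#>   call_rate              0
#>   maf                    8

g <- flt$genotypes
population_summary(g, sim$populations)
#>   population n_samples    Ho    He    Pi  HW_P   PIC   Ne
#> 1         ZJ        40 0.358 0.351 0.355 0.673 0.280 1.60
#> 2         WH        30 0.356 0.349 0.355 0.697 0.279 1.60
#> 3         YZ        18 0.170 0.163 0.168 0.888 0.131 1.27
#> 4         PY         6 0.335 0.306 0.336 0.878 0.244 1.53

pairwise_all(g, sim$populations, n_perm = 199, seed = 1)
#> pairwise_stats over 4 populations
#> Fst (lower triangle) / Reynolds' DR (upper triangle):
#>        ZJ     WH     YZ     PY
#> ZJ     NA 0.0075 0.2795 0.0324
#> WH 0.0074     NA 0.2988 0.0354
#> YZ 0.2438 0.2583     NA 0.3976
#> PY 0.0319 0.0348 0.3281     NA
```

The isolated population YZ shows the lowest diversity (`He` 0.16 against
0.31–0.35 elsewhere — the footprint of its founder effect) and by far the
strongest differentiation (`Fst` 0.24–0.33 against every other
population), while the farmed pair ZJ–WH is barely differentiated
(`Fst` 0.0074, "low"; gene flow `Nm` ≈ 33 migrants per generation). All
six pairwise tests are significant at the permutation resolution
(`p = 0.005` at 199 permutations). Scanning the number of ancestral
components by cross-validation on the LD-pruned matrix selects `K = 2`,
matching the two-ancestry design of the simulation:

```r
pruned <- subset_genotypes(g, loci = ld_prune(g)$kept_locus_ids)
cv_scan(pruned, 1:3, seed = 1)
#>   K cv_error
#> 1 1 1.195178
#> 2 2 1.083965
#> 3 3 1.106744
```

`run_pipeline()` (or the `inst/scripts/popgen` wrapper) chains every stage
and writes the report bundle: per-population diversity (`table1.tsv`), the
combined Fst/DR triangle (`table2.tsv`), gene flow (`table3.tsv`),
classification labels, PCA scores, cross-validation errors, ancestry
fractions, a bootstrap-annotated Newick tree, and a manifest that makes
the run bit-reproducible from one master seed.

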