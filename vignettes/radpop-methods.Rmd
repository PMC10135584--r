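---
title: "Models and methods behind radpop"
author: "radpop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind radpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models the package implements, the
conventions and tunable parameters behind each stage, the design of the
synthetic-data generator, and the numerical choices that affect results in
edge cases. It is the reference for *why* the code does what it does; the
README shows *what* a run looks like.

## Data model

The central object is a `genotype_matrix`: samples × loci alternate-allele
dosages in {0, 1, 2, `NA`}. Dosages count ALT alleles under the usual VCF
convention, so the minor allele frequency `min(p, 1 − p)` is symmetric in
the arbitrary choice of reference allele. Phase is irrelevant to every
statistic computed here, so phased separators are accepted and collapsed;
half-missing calls ("./1") are conservatively treated as missing rather
than as half a dosage. Restriction-tag membership and a reference-N flag —
metadata plain VCF has no column for — travel in the INFO keys `TAG` and
`REFN` in files the package writes, and default to one-locus-per-tag and
FALSE when absent.

Missing genotypes are handled pairwise-complete everywhere downstream:
every per-locus statistic uses the called genotypes at that locus, and
sample sizes enter the formulas per locus. The alternative — dropping any
locus with missingness — would discard most of a RAD dataset at typical
call rates. The one exception is PCA (below), which needs a complete
matrix and mean-imputes.

## Filter cascade

Six rules are applied in a fixed order, each evaluated on the *input*
matrix, and a removed locus is attributed to the first rule that fires:
monomorphic; reference-N; more than `max_snps_per_tag` (default 2) SNPs on
one tag (the whole tag is removed — excess SNP density on a uniform-length
tag indicates paralogy); duplicated (linkage group, position) coordinates
(all sharers removed); call rate below `min_call_rate` (default 0.80);
pooled MAF below `min_maf` (default 0.01). Call rate and MAF pool all
samples rather than being computed per population, matching the filtering
description the defaults come from. Single-pass evaluation keeps the
attrition report deterministic and auditable: rule counts always reconcile
exactly with the input/output dimensions, and re-filtering is idempotent.
Sequential re-evaluation after each rule would give the same survivor set
for these rules except in contrived cases (e.g. call-rate changes cannot
occur, as no samples are removed), and would make attribution
order-dependent.

## Diversity statistics

All statistics are computed per locus within each population from that
population's called genotypes, then averaged over loci; loci monomorphic
within a population still contribute their fixed-point values (He = 0,
Ne = 1, HW-P = 1) so that denominators are common across populations.

- `Ho`: fraction of called genotypes that are heterozygous.
- `He = 2p̂q̂`: plain expected heterozygosity.
- `Pi = 2p̂q̂ · n/(n − 1)` with `n` the number of sampled alleles: the
  unbiased per-site estimator. Using the corrected form for Pi and the
  uncorrected form for He is deliberate — it is the only pairing under
  which Pi slightly exceeds He at every sample size, the pattern expected
  of these two estimators when reported side by side.
- `PIC = 1 − p² − q² − 2p²q² = 2pq(1 − pq)`: Botstein's polymorphism
  information content; for two alleles it is bounded by 0.375 and never
  exceeds He (PIC = He·(1 − pq)).
- `Ne = 1/(p² + q²) = 1/(1 − He)`: effective allele number. Averaging the
  per-locus convex transform gives mean Ne ≥ 1/(1 − mean He) by Jensen's
  inequality, a structural property the tests assert.
- `HW-P`: a two-sided exact test. Conditional on the observed allele
  counts, all heterozygote counts of the same parity are enumerated with
  their conditional multinomial probabilities, and the p-value sums every
  outcome no more probable than the observed one (probability-ordering
  rule). Enumeration is exact at any sample size that occurs in practice;
  probabilities are computed in log space. The population-level `HW-P`
  figure is the *mean* of per-locus p-values. A single pooled test would
  be dominated by the most polymorphic loci and produce values near 0 or
  1, whereas a mean of approximately-uniform p-values sits in the 0.5–0.95
  range typical of published per-population tables; the aggregation is a
  package choice and the per-locus values remain available.

## Differentiation

Pairwise Fst is the Weir–Cockerham (1984) moment estimator for r = 2
populations: per-locus variance components `a` (among populations), `b`
(among individuals within populations) and `c` (within individuals) are
computed from per-population sample sizes, allele frequencies and observed
heterozygote frequencies, and θ is the ratio of sums Σa / Σ(a+b+c) across
loci. Ratio-of-sums rather than mean-of-ratios is the standard weighting:
it is robust to low-information loci whose per-locus ratios are wild. Loci
monomorphic across the pair, or with fewer than two called genotypes in
either population, carry no information about θ and are skipped. Small
negative θ estimates are expected under no differentiation (the estimator
is unbiased around zero) and are reported as-is, but clamped to zero —
with a flag — before the derived transforms.

The test suite checks the implementation against an independently coded
route to the same estimator (nested-ANOVA sums of squares over allele-copy
indicators) to 1e−10 on random instances, and checks parameter recovery on
Balding–Nichols simulations where the expected θ equals the generator's
drift parameter.

Significance is assessed by permutation: individuals are shuffled between
the two populations with sizes preserved, θ recomputed, and
`p = (1 + #{θ* ≥ θ}) / (n_perm + 1)`. A label permutation directly targets
the null "these two samples come from one population", which is the
question behind a pairwise Fst table; a locus bootstrap (the other common
convention) answers a different question (the sampling variance of θ over
loci) and is not what a p-value column in such a table reports.

Derived quantities are deterministic monotone transforms of θ: Reynolds'
distance `DR = −ln(1 − Fst)`, island-model gene flow
`Nm = (1 − Fst)/(4·Fst)` (infinite when Fst ≤ 0, zero when Fst ≥ 1, and
crossing Nm = 1 exactly at Fst = 0.2), and the four-band categorical
interpretation with boundaries assigned upward (0.05 → moderate, 0.15 →
large, 0.25 → extremely large; the conventional verbal bands use strict
inequalities that leave boundary points unassigned, so a deterministic
rule must pick a side, and upward is the conservative one for flagging
differentiation).

## Structure inference

**LD pruning** slides a window (default 50 loci, step 5, r² threshold 0.2
— the canonical defaults of the standard pruning tool) along each linkage
group and greedily removes the later locus of any pair whose squared
genotype correlation exceeds the threshold. Windows never span linkage
groups.

**PCA** mean-imputes missing dosages per locus, centers by `2p̂` and scales
by `sqrt(2p̂(1−p̂))` — the variance a locus would have under binomial
sampling, so that all loci contribute comparable drift signal — drops
zero-variance loci, and takes scores from the SVD. Component signs are
fixed by making the largest-magnitude loading positive, so runs are
reproducible; scores are otherwise invariant (up to sign) to sample order.
All leading components and their explained fractions are returned rather
than a fixed pair, since which components carry population signal is an
empirical question (published analyses sometimes plot non-consecutive
components).

**Trees** use p-distance — the mean over co-called loci of
`|dosage_i − dosage_j|/2`, a proper metric on complete data — and classic
neighbor joining with the rate-corrected selection criterion. Ties in the
criterion are broken by the lexicographically smallest pair of node labels
(internal nodes inherit their smallest leaf label), making the topology
deterministic. Negative branch lengths, which NJ can produce on noisy
distances, are clamped to zero. On additive distances NJ provably recovers
the generating tree; the tests exercise this on random trees. Bootstrap
support resamples loci with replacement, rebuilds the tree, and reports
for each internal bipartition of the full-data tree the fraction of
replicates containing it; output is unrooted Newick with supports as
internal node labels.

**Admixture** maximizes the binomial likelihood in which individual `i`'s
dosage at locus `l` is `Binomial(2, Σ_k q_ik f_kl)`, via the
multiplicative EM updates for `Q` and `F`. EM was chosen over the faster
quasi-Newton block relaxation used by the well-known genotype-clustering
tools because EM's likelihood-ascent guarantee is checkable — the test
suite asserts a non-decreasing log-likelihood trace on every fitted
instance (tolerance 1e−8). The update loop itself is compiled (Armadillo
matrix kernels); initialization, seeding and convergence control stay in
R. Frequencies are clipped to `[1e−6, 1 − 1e−6]` to keep the likelihood
finite at monomorphic loci; `Q` rows are renormalized each iteration to
absorb floating-point drift. Initialization is seeded: Dirichlet `Q`
rows, pooled frequencies perturbed by ±0.1 for `F`. Convergence is
declared when the log-likelihood improves by less than `tol` (default
1e−4, cap 500 iterations for interpretation fits).

**Choosing K** uses masked-genotype cross-validation: non-missing entries
are partitioned into folds (default 5); each fold is masked in turn, the
model refit, and the masked entries scored by mean binomial deviance
between the observed dosage and the fitted `2·Σ_k q_ik f_kl`. Deviance
rather than squared error keeps the score on the likelihood scale. Loci
left with no training data in a fold are skipped in that fold's scoring.
Because multiplicative EM crawls near flat optima and can stall in
K-dependent local maxima, each fold is fit from several seeded restarts
(default 3) with a 200-iteration cap and the best training likelihood is
scored; the restart maximum is what damps local-optimum noise in the K
comparison, while full convergence of the last likelihood decimals does
not change the K ranking and is not pursued inside the scan.
Replicate fits at the same K are label-aligned by greedy maximum
Q-column correlation to the best-likelihood replicate; a replicate counts
as reproducing the modal solution when its aligned ancestry matrix
differs by less than 0.05 mean absolute entry.

## Synthetic-data generator

The generator exists so that every stage can be tested against known
truth. Ancestral frequencies are uniform on `(maf_floor, 1 − maf_floor)`;
each of K ancestral components drifts from them by a Balding–Nichols Beta
draw with parameter `F_k`; each population takes its own further drifted
copy of each component (parameter per population and component) and mixes
them with fixed ancestry weights; genotypes are binomial in the mixed
frequency, with uniform missingness. Balding–Nichols was chosen because
its dispersion parameter *is* the Fst it induces: two populations drawn
with drift `F` have expected Weir–Cockerham θ equal to `F` (and `(F_a +
F_b)/2` for unequal drift), which turns estimator validation into a
closed-loop parameter-recovery test. The founder-effect bottleneck is
binomial resampling of frequencies: one draw of `2·founder_count` alleles,
then one draw of `2·effective_size` alleles per generation; fixation is
absorbing.

The study preset emulates a four-population, 94-individual design:
ZJ (n = 40) and WH (n = 30) with identical ancestry (95% component 1) and
small independent drift (F = 0.01 each), PY (n = 6) with 90% component 1
and stronger drift (F = 0.08), and YZ (n = 18) drawn from component 2
(97%) with a bottleneck of 6 founders followed by 20 generations at
effective size 30. Component drifts are 0.02 and 0.35. By the mean-drift
relation these choices put the expected pairwise Fst near 0.01 for
ZJ–WH, near 0.05 for the PY pairs and above 0.25 for the YZ pairs — the
ordering observed in the motivating scenario — and the bottleneck makes
YZ the lowest-heterozygosity population. The within-ancestry drifts are
kept deliberately small so that the preset is a genuinely two-ancestry
scenario at its default size: larger within-ancestry drift would itself
constitute third and fourth ancestral components that masked-genotype
cross-validation, correctly, would detect. The preset default of
2000 loci keeps a ten-seed structure-recovery run within minutes; the
generator scales to 10⁵ loci if desired. Missingness defaults to 5%,
typical of RAD genotype matrices after calling. PY's very small sample
(n = 6) is kept deliberately to exercise small-sample code paths (noisy
θ, low-information pairs).

What the generator does *not* emulate: linkage disequilibrium beyond
duplicated loci (loci are independent given the frequencies, so LD
pruning is exercised by engineered correlated columns rather than by the
preset), site-frequency spectra of real ascertained RAD data (the uniform
ancestral spectrum yields higher average heterozygosity than a real
low-polymorphism dataset — qualitative orderings transfer, absolute
diversity values do not), sequencing error, and non-random missingness.
Passing the closed-loop tests therefore demonstrates estimator
correctness under the stated model, not robustness to every artifact of
real data.

## Reproducibility and numerical choices

All stochastic operations take explicit seeds, save and restore the
global RNG state, and the pipeline derives named substreams (simulation,
permutation, bootstrap, EM) from one master seed recorded in the
manifest, so a manifest reproduces every numeric output bit-for-bit.
Degenerate inputs are handled explicitly rather than silently: an
all-missing locus subset yields a flagged-undefined frequency, never a
silent zero; monomorphic tables give HWE p = 1; populations below two
samples are summarized with a low-n warning; an empty post-filter matrix
aborts the pipeline naming the filtering stage.

Known limitations: the admixture model assumes Hardy–Weinberg within
components and free recombination between loci, so it should be run on
the pruned set; cross-validation at very small K-to-data ratios can be
nearly flat between adjacent K (the CV-error curve should be inspected,
not only its argmin); the exact HWE enumeration is quadratic in the minor
allele count and intended for per-locus sample sizes, not pooled
mega-samples; and the permutation p-value resolution is `1/(n_perm + 1)`.
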