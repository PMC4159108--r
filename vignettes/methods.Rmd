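---
title: "Models and methods in mirpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mirpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpopgen)
```

This vignette is the package's own account of its statistical machinery: the
models and estimators, the parameters that matter, the synthetic-data
generator's stated world, the numerical choices made where conventions
diverge, and what a green test suite does and does not establish.

## The data model

A **miRNA catalog** holds, per pre-miRNA hairpin, its genomic interval,
strand and one or two mature arms; the **seed** of each arm is bases 2–8
counted from the arm's 5' end (the lower genomic coordinate on `+`, the
higher on `-`, walking downward). Seeds are 7 nt and always derived, never
stored, so the three region classes — seed, mature-outside-seed, and the
remaining stem-loop — partition each hairpin exactly. That partition is a
tested invariant: it is what makes per-region variant densities comparable.

All coordinates, in memory and on disk, follow the 1-based closed GFF3/VCF
convention that the Bioconductor interval stack (IRanges/GenomicRanges) uses
natively. An earlier design sketch called for half-open 0-based internal
coordinates with conversion at the I/O boundary; we deliberately dropped the
conversion layer — in an R package the 0-based convention buys nothing and
adds an off-by-one surface. The conversion helpers (`coords_to_zero_based`,
`coords_to_one_based`) remain available and are property-tested as exact
inverses for interoperability with BED-style tools.

Genotypes are stored as an integer dosage matrix (variants × samples, values
0/1/2/NA). Multi-allelic VCF records split into one biallelic record per
alternate allele; within a split record, other alternate alleles count as
reference — the standard per-allele framing, matching an analysis that
treats each alternate allele as its own variant. `./.` and half-missing
calls become `NA` and leave the frequency denominator; this is a stated
choice, since upstream no-call handling in whole-genome pipelines is rarely
documented.

## Region classification

A variant occupies `[pos, pos + nchar(ref) - 1]`; an insertion sits at its
anchor base. For multi-base variants, any overlap with a higher-precedence
region wins, with precedence **seed > mature > stem-loop**: the per-region
counts are then disjoint, and seeds — the functional unit of target
recognition — absorb boundary-spanning indels. A variant under two
overlapping hairpins is reported once per hairpin (per-miRNA reporting needs
it); densities de-duplicate by default and expose the per-miRNA mode as an
option. Classification is tested against a brute-force per-base labelling
oracle on 1000 random variants.

**Singleton filtering.** Previously undescribed variants (absent from the
known-sites resource, allele-aware) carried by exactly one individual are
removed as possible somatic or sequencing artifacts. "One individual" means
one sample — a single homozygous carrier is still a singleton. Known
variants are never removed; the filter is idempotent.

## Diversity and differentiation

**Watterson's θ** per group and sequence class is S/(a_n · L): S segregating
sites within the group, n chromosomes, a_n the (n−1)-th harmonic number, L
the class's total bases in the catalog. θ halves when L doubles at fixed S —
a tested property.

**Weir–Cockerham F_ST** is implemented in the allele-frequency (haploid
sample) form: the 2N called chromosomes of each group are the sample and the
per-chromosome allele indicator the observation, omitting the
observed-heterozygosity component. This is the standard choice when only
unphased genotype counts per allele are analysed. With r = 2 groups the
among- and within-group components a and w reduce to closed forms in
(p₁, n₁, p₂, n₂) (see `?wc_fst`); algebraically a/(a+w) equals the ANOVA
form (MSA − MSW)/(MSA + (n_c − 1)·MSW), and the test suite pins the
implementation to an independently coded ANOVA oracle at 1e−12 over 10,000
random instances. Conventions:

* Both groups monomorphic for the same allele → the estimator is undefined;
  such records are representable, flagged, and excluded from percentile
  distributions.
* Negative raw θ̂ (no detectable differentiation) is truncated to 0 for
  reporting; the raw value is retained.
* Multi-locus summaries use the weighted combination Σa/Σ(a+w)
  (`wc_fst_global`), Weir and Cockerham's own prescription. The arithmetic
  mean of per-locus ratios is biased toward zero — each per-locus ratio is a
  noisy one-degree-of-freedom quantity — and in the drift-recovery test it
  underestimates a true F of 0.2 by ≈ 0.05, while the weighted form lands
  within ±0.005 across seeds. This is why the estimator-recovery acceptance
  check is phrased in terms of the weighted mean.

**The outlier scan.** F_ST is computed hierarchically: all population pairs,
all region pairs, and pooled African vs non-African samples. Admixed
populations join neither pool — with the default 69-sample panel the pools
are 32 and 25 individuals, and making pool membership explicit in the
manifest (rather than inferring it) is a deliberate interface choice. For
the pooled contrast a Welch two-sided t-test on per-individual dosages
(0, 0.5, 1; missing excluded) supplies a per-variant p-value; the dosage
reading is the only construction of "allele-frequency difference between
samples" that yields a two-sample t-test, and it is documented as a choice.
Degenerate inputs are explicit: both groups zero-variance with equal means
gives t = 0, p = 1; with different means p = 0 plus a `degenerate` flag
(base R's `t.test`, the test-suite oracle, refuses these inputs — one reason
the test is hand-coded and vectorised).

A variant is **PD** when its pooled θ̂ is at or above the 95th empirical
percentile *and* p < 0.05; **HPD** adds the 99th percentile. Both cutpoints
are inclusive (`≥`). Percentiles use linear interpolation between order
statistics (the type-7 quantile rule) — the rule is fixed, documented, and
the realised thresholds are written into output headers so alternative rules
are auditable. The miRNA-level label is the maximum over the miRNA's
variants.

**PSMAs** are alternate alleles present (frequency > 0) in exactly one
population; high-frequency means ≥ 50% within that population; density
divides the count by the population's sampled genomes. All 14 populations,
including admixed ones, participate — exclusivity is defined over the full
sampled panel.

## Enrichment analyses

Evidence QC retains a (miRNA, gene) pair when the expression correlation is
r < −0.5 — strictly; the boundary r = −0.5 fails — in at least two distinct
datasets. miRNAs with at least one validated target are flagged
high-confidence.

Three resampling analyses share one skeleton: compute an observed statistic
for a miRNA set, rebuild it for B random sets, and report the add-one
empirical p = (1 + #{null ≥ observed})/(B + 1). The add-one rule keeps p
strictly positive — standard resampling practice where the source analysis
only states "p < 0.05". Choices worth naming:

* Random miRNA *sets* are drawn without replacement (a set of 8 distinct
  miRNAs); the disease analysis is a bootstrap and draws with replacement.
  Both modes are switches.
* The null is one-sided (enrichment only).
* The candidate pool is all catalog miRNAs, not only high-confidence ones —
  configurable, and recorded in output.
* The process-level statistic counts annotated target genes per process; a
  presence/absence mode is provided since the source description is
  ambiguous between the two.
* Monotonicity holds by construction: with the same seed (hence the same
  null draws), raising a gene's observed count can only lower or keep its
  empirical p — tested.

The genomic GO stage is a plain upper-tail hypergeometric test with
Benjamini–Hochberg adjustment. It replaces an external tool whose internal
algorithm is out of scope, and outputs flag it as an approximation.

## The synthetic world

`bn_genotypes` draws ancestral frequencies p ~ Uniform(0.05, 0.95) — bounded
away from 0/1 so monomorphic loci do not dominate — population frequencies
from the Balding–Nichols Beta(p(1−F)/F, (1−p)(1−F)/F), and genotypes
Binomial(2, p_pop). Balding–Nichols was chosen over coalescent simulation
because it parameterises exactly the F that the Weir–Cockerham estimator
targets, giving a clean recovery test; the default F = 0.1 is typical of
global human differentiation. The default panel mirrors the analysed world:
69 individuals, 14 populations (six African, three of them hunter-gatherer;
two European; three Asian; three admixed), pools of 32/25.

Planted structure makes ground truth known: private alleles are forced to
carriers in exactly one population; PD loci are resampled until the realised
pooled frequency gap reaches 0.6 (target frequencies 0.95 vs 0.1, admixed
populations intermediate); the enrichment world plants a gene block targeted
by a designated 8-miRNA set with configurable effect (effect 0 is a pure
calibration world) and a QC pass-rate knob whose realised proportion is a
tested oracle.

What the generator does **not** emulate: linkage disequilibrium (loci are
independent), realistic site-frequency spectra or demographic history,
sequencing error, and sequence-level context. A green suite therefore
establishes estimator correctness and pipeline plumbing under the stated
model — not robustness to LD, ascertainment or coverage artifacts in real
data, and the real-data headline counts of the motivating analysis are not
reproducible from simulation.

## Numerical and interface choices

* Configs are JSON (a strict subset of YAML) since no YAML parser is in the
  supported dependency set; every output TSV carries a comment header with
  the package version, an md5 hash of the analytic config (output paths
  excluded) and the seed, so reruns are verifiably byte-identical — a tested
  property.
* Bootstrap functions save and restore the caller's RNG state; the pipeline
  derives stage seeds as seed, seed+1, seed+2 so stages are independently
  reproducible.
* Undefined F_ST records, empty percentile inputs, zero-base regions,
  single-member Welch groups and out-of-range quantiles all have explicit,
  tested behaviours (NA-with-flag or hard error, never silence).

## Known limitations

Indel handling is positional only (no re-normalisation/left-alignment);
haplotype-based statistics are out of scope; the GO stage is an
approximation of the external tool it stands in for; and the Welch test on
0/0.5/1 dosages is a large-sample approximation whose calibration at the
null is verified empirically (fraction of p < 0.05 ≈ 0.05 under F = 0)
rather than exact for small groups.
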