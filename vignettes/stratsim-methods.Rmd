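---
title: "Models and methods behind stratsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stratsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stratsim` studies how fine-scale population structure — the kind produced
by differential Khoe-San admixture into South-Eastern Bantu-speaking
groups sampled at a few study sites — distorts case-control association
statistics, and how well the standard corrections repair the damage.
Because the real cohorts that motivate this question are controlled-access,
everything here runs on synthetic cohorts whose structure is planted and
therefore known exactly. This vignette records the models, the defaults and
the numerical choices, and what the passing tests do and do not establish
about real data.

## The cohort simulator

### Allele frequencies: two Balding–Nichols layers

Each locus has a shared base frequency `p ~ Uniform(base_freq_range)`
(default 0.05–0.95). Ancestral component *k* receives

$$f_k \sim \mathrm{Beta}\!\left(p\frac{1-F_k}{F_k},\ (1-p)\frac{1-F_k}{F_k}\right),$$

so `E[f_k] = p` and `Var[f_k] = F_k\,p(1-p)`. The default `F_anc = (0.05,
0.20, 0.15)` for the Bantu-speaker-related, Khoe-San-related and
Eurasian-related components makes the Khoe-San component the most diverged,
matching its deep separation from the other two. A second layer drifts each
group's copy of every ancestral frequency by the group parameter `F_g`
(default 0.005), giving controllable between-group F_ST that is independent
of admixture differences: two groups with identical ancestry proportions
still differ by roughly `2 F_g` worth of drift variance, and
Weir–Cockerham θ̂ on such a pair estimates `F_g` itself (the basis of the
estimator-recovery test at `F = 0.05`). All frequencies are clipped to
[0.001, 0.999]; fixed loci would otherwise break downstream estimators
(PCA scaling, F_ST denominators, fold changes).

### Local ancestry and genotypes

Per haplotype and chromosome, ancestry switch points form a Poisson process
of rate `g` per Morgan (`g` = generations since admixture; defaults 24–45
per group, oldest for the Tsonga- and Venda-like groups). Ancestry is
redrawn iid from the proportion vector at the chromosome start and at every
switch point. Redrawing *from q* (rather than forcing a change) permits
silent same-ancestry switches; the observed switch rate is therefore
$g(1-\sum_k q_k^2)$ per Morgan and the mean tract length of ancestry *k* is
$1/(g(1-q_k))$ Morgans — both are property-tested. Alleles are Bernoulli
draws from the group's drifted frequency of the tract's ancestry, so the
only linkage disequilibrium in the data is admixture LD along tracts; there
is no background LD (see Limitations).

### The X chromosome and sex bias

Autosomal haplotypes use the group's proportions `q`; X haplotypes use
$H_X = (2 s_f + s_m)/3$, the equilibrium expectation for a single admixture
pulse with female contribution `s_f` and male contribution `s_m` per
ancestry (the autosomal expectation is $H_A = (s_f+s_m)/2 = q$). The
single-pulse equilibrium is this package's modelling choice — the
literature this setting draws on describes the X-vs-autosome comparison
without fixing a demographic model, and a continuous-gene-flow model would
give slightly different coefficients. The inversion
`invert_sex_contributions()` solves the same 2×2 system backwards
(`s_f = 3H_X − 2H_A`, `s_m = 4H_A − 3H_X`) and refuses solutions outside
[−0.02, 1.02], since those indicate the model does not fit. Males carry one
X haplotype; their X genotypes are haploid (and exported as haploid VCF
calls). The default chromosome layout (two 120 Mb autosomes plus a 150 Mb
X at 1–1.2 cM/Mb) deliberately over-represents the X relative to the human
genome so that X-ancestry means have usable precision at desk-scale
variant counts; analyses that should be autosomal (the GWAS suite) drop X
variants explicitly.

The default cohort (`seb_cohort_config()`) plants an eight-group design
with the reported mean ancestry proportions per group (Khoe-San from 1.6%
in Tsonga to 20.5% in Tswana), group sizes following the downsized
ethno-linguistically concordant design (23–80 per group, 462 total),
three sampling sites of mixed group composition (Tsonga- and Swazi-like
groups mostly at Agincourt, Pedi-like at Dikgale, Nguni- and
Sotho-Tswana-like at Soweto — approximate fractions, since the published
per-site table does not need to be reproduced exactly for the statistics
to behave), a 40% maternal bias on the Khoe-San contribution, and
language-majority-area medians as geographic anchors.

### Pedigree ethnicities and the EC filter

Each sample gets six relative labels (2 parents + 4 grandparents), each
independently mismatching the sample's own group with probability 0.2. At
that rate about a third of samples have two or more mismatching relatives
— matching the reported fluidity of self-identity — and the
ethno-linguistic concordance filter (≥ 5 of 6 matches) retains ~66% of
samples, the `P(Binomial(6, 0.2) ≤ 1)` closed form the tests check.

## Structure statistics

*F_ST.* Weir–Cockerham variance components `a, b, c` per locus; the overall
estimate is the ratio of averages `Σa / Σ(a+b+c)` (not the average of
per-locus ratios), the standard usage of this estimator; loci with zero
denominators are skipped, missing genotypes dropped per locus. Negative θ̂
is reported raw but floored at 0 when the matrix is used as a distance.

*UPGMA.* Hand-rolled average-linkage agglomeration so the contract is
explicit: merge heights are half the average distance, ties break toward
the lexicographically smallest pair of cluster labels, children are
ordered by smallest leaf label, and the output is an `ape::phylo` that is
ultrametric by construction. `stats::hclust(method = "average")` serves as
the independent oracle in tests, never as the implementation.

*PCA.* Variants are centred by `2p̂` and scaled by `sqrt(2p̂(1−p̂))`;
missing dosages are mean-imputed (i.e. contribute zero after centring);
monomorphic variants are excluded. For wide matrices the decomposition
runs on the n×n Gram matrix rather than a full SVD — identical up to
column sign, which is fixed by making each component's largest-magnitude
coordinate positive.

*Geography.* Weiszfeld's fixed-point iteration runs on a local
equirectangular projection about the weighted centroid (longitude scaled
by cos of the centroid latitude); at the sub-country scales involved the
projection error is far below the 1e-9-degree convergence tolerance.
Iterates landing exactly on a data point are nudged by 1e-9 degrees (the
standard perturbation rule). Great-circle distances are haversine on a
6371 km sphere.

*Mantel and Procrustes.* Both use one-sided permutation p-values with the
add-one estimator `p = (1 + #{stat_perm ≥ stat_obs}) / (n_perm + 1)`
(default 9999 permutations, seeded), so p can never drop below
`1/(n_perm+1)`. Mantel offers exact enumeration for ≤ 8 labels. Procrustes
centres and scales both configurations to unit sum of squares, finds the
optimal orthogonal map (reflections allowed by default; the proper
rotation is preferred when restricted) from the SVD of the cross-product,
and reports `m²`, `r = sqrt(1−m²)` and `r²` together — published
"Procrustes correlations" are sometimes r and sometimes r², so all three
are exposed.

## Ancestry statistics

*Supervised EM.* With truth ancestral frequencies available in simulation,
per-individual proportions are the MLE of the binomial admixture model,
found by the multiplicative EM update restricted to the Q coordinates.
The log-likelihood is non-decreasing (tested), convergence is
`max|Δq| < 1e-6` within 500 iterations, and non-convergence returns the
last iterate with a warning rather than failing the whole matrix. A
supervised estimator replaces unsupervised clustering deliberately: truth
panels exist here, which turns ancestry estimation into a testable
parameter-recovery problem (error shrinking as 1/√L is one of the tests).

*ΔAdmix.* The X-vs-autosome ratio `(Q̄_X − Q̄_A)/Q̄_A` on group means —
dimensionless, positive exactly when the X carries excess of that
ancestry, i.e. female-biased contribution. The bootstrap (50 resamples of
20 without replacement) reports the SD of resampled estimates as SE plus a
percentile CI. The normalization by Q̄_A is this package's choice of the
several "admixture difference ratio" variants in circulation; it preserves
the sign semantics (positive = maternal) that matter downstream.

*PBS.* `T = −log(1 − max(F_ST, 0))` — flooring first, because slightly
negative F_ST estimates would otherwise produce negative branch lengths —
and `PBS_A = (T_AB + T_AC − T_BC)/2`. `F_ST = 1` gives infinite T; such
variants are flagged and excluded from ranking rather than propagated.

*Enrichment scan.* Haplotype calls with posterior ≤ 0.8 are dropped, then
variants within 2 Mb of chromosome ends or the centromere; per-variant
mean dosage of the focal ancestry is compared with the genome-wide mean
and SD; variants beyond +3 SD (high tail by default — candidate regions
are defined by excess ancestry; a both-tails option covers depletion) are
merged into runs, and runs of ≥ 3 SNPs become regions, exported as BED
(converting the internal 1-based inclusive coordinates to 0-based
half-open). A constant-dosage genome has SD 0 and yields no regions rather
than dividing by zero.

*Fold-change scan.* `fold = max(f_i/f_j, f_j/f_i)` on alternate-allele
frequencies, ranked at ≥ 3-fold; pairs with a zero frequency are reported
in a separate "unbounded" table rather than dominating the ranking with
infinities. Bootstrap SEs use 50 subsamples of 30. (A frequency pair such
as 0.03 vs 0.18 is a literal 6-fold difference and is treated as such,
even though informal usage sometimes calls it "almost four-fold".)

## The simulated-trait GWAS suite

Four label-assignment schemes reproduce the confounding designs: cases
from one site vs controls from another (800/800); cases mixed across two
sites at 37.5/50/62.5% against single-site controls; within-site
assignment with one group excluded from cases (500/500); and random labels
within a site — the null. The raw test is the allelic 2×2 chi-square (the
basic association test of standard GWAS toolkits); corrected runs use
additive-coding logistic regression with Wald tests, since the
PC-correction procedure is defined in terms of logistic covariates. Rank
agreement between the two (Spearman ρ > 0.99) is property-tested.

λ is the median of the implied 1-df chi-squares divided by
`qchisq(0.5, 1) = 0.4549364` — the median-based genomic-control estimator.
GC deflation divides chi-squares by λ only when λ > 1 (deflating
well-calibrated scans would anti-conservatively inflate them on
re-inversion), making post-correction λ exactly 1 and the correction
idempotent. PC correction recomputes PCs per iteration on the analysis
samples from an LD-pruned subset (capped at 10 000 variants; structure
saturates far below that), then adds the first 3 PCs as covariates.

Logistic fits use a tight Newton IRLS warm-started from the covariate-only
null fit. Under strong structure the PC covariates can separate the
phenotype (quasi-)completely — the ML estimate then does not exist — so
the fitter falls back to Firth's Jeffreys-prior-penalized likelihood, the
standard separation-robust logistic used by current GWAS tooling; when the
null model itself is separated every variant goes straight to the Firth
path. Variants that still fail (singular information, no convergence) are
flagged invalid and excluded from λ and the tallies.

Significance is tallied at 5×10⁻⁸ and a suggestive threshold of 1×10⁻⁵;
5×10⁻⁵ — the other convention in circulation for "suggestive" — is
available via the `suggestive` argument rather than silently chosen.

## Pipeline and reproducibility

`run_pipeline()` wires simulate → structure → ancestry → gwas, each stage
consuming only serialized artifacts of earlier ones and writing VCF v4.2
(haploid male X calls as `0`/`1`, missing diploid calls as `./.`, genetic
positions preserved in `INFO/CM` so imports are lossless), TSV, newick,
BED and JSON stat blocks carrying `(statistic, p, n_perm, seed)`. One
global seed fans out through a stable per-stage/per-iteration derivation
(a small LCG-style hash kept below 2³¹), so identical configurations
produce byte-identical artifacts — tested by diffing two full runs.
Unknown configuration keys are rejected by name (typo guard). The manifest
is written atomically (temp file + rename).

## Problem sizes used by the tests

The acceptance-style tests and `scripts/acceptance.R` run at sizes chosen
to make every statistical claim decidable on a single CPU in minutes:
null calibration at 800 samples × 20 000 common variants (20 and 10 label
draws respectively); structured inflation at two 1000-sample groups ×
20 000 variants with 10 (tests) or 5 (script) case-control iterations;
F_ST recovery at 100+100 × 5000 × 20 replicates; topology recovery at
3 × 40 × 800 × 100 replicates; sex-bias recovery at 200 × 20 000 over 50
(tests) or 25 (script) seeds; enrichment scans at 500 haplotypes × 4000
variants over 20/10 seeds.

## Limitations

- **No background LD.** Only admixture LD exists, so LD pruning removes
  almost nothing here and haplotype-based methods (iHS-style scans,
  chromosome painting) cannot be exercised meaningfully.
- **No genotyping error, no relatedness.** Missingness is uniform; there
  are no pedigrees, cryptic relatedness or batch effects — all of which
  inflate real GWAS beyond what structure alone does. Passing the null
  calibration here says the statistics are correct, not that a real cohort
  with these sample sizes would be clean.
- **Single-pulse admixture.** Dates enter only through the tract-length
  scale; continuous or multi-wave gene flow, and the resulting ΔAdmix
  dynamics, are out of scope.
- **Supervised ancestry only.** The EM estimator consumes truth ancestral
  frequencies; it does not address the model-selection and label-switching
  problems of unsupervised clustering on real panels.
- **Geography is schematic.** Group anchors are fixed points; the
  Mantel/Procrustes machinery is exact, but the geographic realism of the
  default cohort is qualitative.
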