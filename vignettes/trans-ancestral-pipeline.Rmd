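---
title: "Trans-ancestral GWAS downstream analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trans-ancestral GWAS downstream analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transgwas)
```

# Scope

`transgwas` implements the downstream arc of a two-ancestry case-control
GWAS: per-cohort quality control and association, fixed-effect
meta-analysis with Cochran's Q heterogeneity classification,
approximate-Bayes-factor colocalization, single-causal-variant
trans-ancestral fine-mapping, Fst and EHH/iHS selection scans, clumping +
thresholding polygenic risk scores, and the small-sample contingency and
liability-variance statistics used to interpret ancestry-heterogeneous
loci. A synthetic two-ancestry generator provides cohorts with known truth
so that every stage can be tested by parameter recovery rather than by
fixture files.

This vignette records the models, the tunable parameters and their
defaults, the numerical conventions, and the design decisions that were
genuinely open — together with what the synthetic experiments do and do not
demonstrate about real cohort data.

# The synthetic cohort generator

## Haplotype panels

Ancestral derived-allele frequencies are drawn once per variant,
`p ~ Uniform(0.05, 0.95)` — a deliberately simple stand-in for a neutral
site-frequency spectrum that keeps most variants common enough to be
informative at the panel sizes used in testing. Each population then drifts
independently under the Balding–Nichols model: its frequency is Beta
distributed around `p` with variance `c·p(1−p)`, where `c` is the
per-population drift coefficient. The default `c = 0.05` reproduces the
genome-wide divergence typical of East Asian vs European comparisons
(mean Fst of the emitted panels ≈ 0.03 at the default pool sizes, with the
most-divergent tail reaching the 0.15+ range); experiments that need
stronger divergence pass `c = 0.1`.

Linkage disequilibrium comes from founder-mosaic copying: each population
has a founder pool (default 100 haplotypes) drawn i.i.d. from its drifted
frequencies, and each emitted haplotype copies one founder at a time,
switching to a random founder with probability `block_recomb` per site
(default 0.05) and always at block boundaries. Blocks are therefore
internally correlated and mutually independent. Two consequences shaped the
defaults:

- A *small* founder pool adds binomial sampling variance `p(1−p)/F` to each
  population's realized frequencies. With the ~20 founders one might first
  reach for, that alone puts a floor of roughly 1/40 under the panel Fst,
  which would contradict the requirement that zero drift yields
  near-identical populations. The default pool of 100 keeps that floor an
  order of magnitude below the default drift signal.
- Because founder columns are independent draws, mosaic LD is moderate: it
  is sufficient for clumping and EHH decay, but it rarely produces the
  near-perfect proxies (r² ≈ 1) that make real credible sets span tens of
  variants. The fine-mapping and colocalization experiments therefore
  generate their locus panels through a deep founder bottleneck (6 founders,
  switch probability 0.002), which yields haplotype "backbones" and groups
  of variants in near-perfect LD — the regime in which trans-ancestral
  fine-mapping has something to gain.

The generator does **not** model coalescent genealogy, recombination-rate
heterogeneity, mutation-age/frequency correlation, gene conversion, or any
demographic history beyond a single drift split. Panel frequencies are
exchangeable across the genome, so genome-wide empirical quantiles in the
tests are cleaner than they would be in real data.

## Sweeps

`impose_sweep()` creates an iHS-positive fixture: the derived-allele
frequency at a core variant is moved to a target, and every carrier of the
derived core allele has the window of `homozygosity_extension` bp around
the core replaced by one template carrier's segment, with small per-site
mutation noise (default 0.01). This produces the long, homogeneous
derived-allele haplotypes that a recent sweep leaves, without simulating
selection forward in time. The extension should be kept short relative to
the simulated contig; a window that covers most of the contig homogenizes
the background the scan is standardized against, and the core stops being
an outlier in its own scan.

## Case-control ascertainment

Disease follows a liability-threshold model: the genetic liability is the
sum over causal variants of centred derived-allele dosage times a
per-allele coefficient, standard-normal noise is added, and the threshold
is set so the population lifetime risk equals the configured prevalence
(defaults 1‰ for the East-Asian-like and 0.3‰ for the European-like
population — the SLE figures). Cases are oversampled to the requested
count; case-control sampling leaves logistic odds-ratio estimates
unbiased.

Causal effects are specified as per-allele log odds ratios, because those
are what the association stage estimates and what the truth manifest must
allow recovering. A probit liability model and a logistic model cannot
agree exactly, so the generator converts each log OR `β` into a liability
shift `β/λ(t)` with `λ(t) = φ(t)/(1 − Φ(t))` the inverse Mills ratio at
the threshold — the first-order rare-disease mapping. The residual
curvature bias is about 2 % of the effect at OR 1.35 and prevalence 1‰,
an order of magnitude below the sampling error of the cohorts used in
testing. The threshold itself is set from the normal approximation to the
genetic-liability distribution (exact in the null, very accurate for tens
of small effects).

Haplotype pairs are drawn with replacement by default, which admits any
cohort size but lets selected individuals share panel haplotypes —
harmless for association (and for the PRS and fine-mapping experiments),
but a cohort destined for relatedness QC would be full of PI_HAT ≈ 0.5
pairs. `replace = FALSE` uses each panel haplotype at most once (requiring
a panel of at least twice the cohort size), so selected individuals are
genuinely unrelated; the QC-stage analysis driver uses this mode.

For rare prevalences the sampler draws liabilities in bulk from
per-haplotype genetic scores, so reaching thousands of cases at prevalence
3e-4 costs a few million scalar draws, not a few million genotype-matrix
rows. The draw budget is capped (`max_draws`, default 2e7) and exceeding it
names the prevalence as the bottleneck.

All randomness flows from integer seeds through `withr::with_seed`, so no
function disturbs the caller's RNG state and identical configurations are
byte-identical.

# Quality control and association

The variant filters (call rate ≥ 0.90, MAF ≥ 0.005, Hardy–Weinberg exact
P ≥ 1e-4) and sample filters (missingness ≤ 0.05, pairwise PI_HAT ≤ 0.125,
|F| ≤ 0.05) use the standard GWAS thresholds; all variant filters are
evaluated on the input data rather than sequentially, which makes
`variant_qc()` idempotent. Two conventions the field leaves implicit had to
be fixed here: the Hardy–Weinberg test is applied in controls only
(configurable), and in a related pair the member with the higher
missingness is dropped, ties going to the later sample identifier.

The Hardy–Weinberg test enumerates all heterozygote counts compatible with
the allele-count margins and sums the probabilities of configurations no
more likely than the observed one, in log space. PI_HAT is the
method-of-moments estimator from identity-by-state counts and sample allele
frequencies, rescaled per pair for missingness and truncated to [0, 1]; the
small-sample correction factors some implementations add are omitted, which
costs a little accuracy for tens of variants but nothing at the ≥ 1000
variants the filters are meant for. PCA standardizes dosages as
`(g − 2p)/√(2p(1−p))` with mean imputation of missing genotypes (imputation
is used *only* for PCA; association is complete-case per variant), and each
component's sign is fixed by making its largest-magnitude loading positive.
The number of PCs is a free integer (default 4); a scree-plot elbow is
inherently subjective, so the choice is left to the caller.

`logistic_assoc()` is a maximum-likelihood logistic fit (IRLS via
`glm.fit`) of status on dosage plus covariates with Wald statistics.
Separation and non-convergence are flagged per variant (`converged =
FALSE`, statistics NA) rather than aborting a scan. λ_GC divides the median
association χ² by 0.4549364231 — the χ²₁ median fixed to ten digits so that
independent implementations agree exactly.

# Meta-analysis and the four-category classification

Fixed-effect inverse-variance pooling and Cochran's Q follow the closed
forms; no random-effects model is provided. Alleles are aligned by
effect/other pair with strand-complement resolution; A/T and C/G pairs that
do not match directly are ambiguous and dropped by default. When only
printed (OR, P) pairs are available, `se_from_or_p()` recovers
`se = |ln OR|/Φ⁻¹(1 − P/2)` — documented as approximate under rounding; on
two-decimal inputs, recomputed Q P-values should be trusted to order of
magnitude only.

The classification applies, in order: category 4 when the risk allele is
absent or rare (MAF < 0.01) in exactly one ancestry; category 3 when the
FDR-adjusted Q P < 0.05 (adjustment computed over the full lead-variant
batch, which is an explicit input); category 2 when the raw Q P < 0.05;
category 1 otherwise. Within category 3, a locus is ancestry-specific when
one ancestry has P < 5e-8, the other P > 0.01, and the Wald 95 % CIs of the
two odds ratios do not overlap. The Wald interval was chosen because the
interval type behind published ORs is rarely stated and Wald is the
convention of the association tools themselves. The default heterogeneity
test uses the two pooled ancestry group statistics (k = 2); testing all
cohorts jointly with k > 2 is supported but not the default.

# Colocalization and fine-mapping

Evidence is accumulated exclusively in log space (log-sum-exp; the H3 term
uses a guarded log-difference), and both PP0–PP4 and fine-mapping
posteriors are normalized to 1 within 1e-9. The Wakefield prior effect
standard deviation defaults to 0.2 on the log-odds scale (the usual
case-control choice) and the coloc priors to p1 = p2 = 1e-4, p12 = 1e-5;
none of these are stated by the analyses this package follows, so all are
configurable. Variants entering colocalization are expected to be common
(MAF > 1 %) in both groups; imputation INFO filtering is a no-op on fully
typed synthetic data.

Fine-mapping assumes a single causal variant per locus — the special case
in which the trans-ancestral model reduces to adding per-variant log Bayes
factors across ancestries. Multi-causal models and annotation priors are
out of scope; where a locus carries secondary signals, the supported
approximation is to residualize the lead variant's dosage and re-fit.

The 95 % credible set sorts posteriors in decreasing order and accumulates
until the mass reaches 0.95, including all posteriors tied (within 1e-12)
with the boundary variant. Under that tie rule a perfectly uniform locus
returns the whole locus, not an arbitrary 95 % subset — with identical
posteriors there is no principled way to exclude any variant. This is the
one place the package prefers determinism-with-meaning over hitting a
nominal set size.

Locus boundaries extend outward from the lead to the nearest
recombination-map point with rate ≥ 10 cM/Mb on each side. Hotspots are
high-rate intervals, so the boundary condition is `rate ≥ threshold`; a
hotspot sitting exactly on the lead produces a degenerate one-sided
interval, which is flagged rather than silently widened.

The unrelated-phenotype baseline summarizes an observed PP4 against PP4
values from colocalizing the same locus with phenotypes that have no true
relationship: the empirical P uses the add-one convention
`(1 + #{baseline ≥ observed})/(1 + n)`, and the "exceeds baseline" flag
fires when the observed PP4 tops every baseline run. With n baseline runs
that flag has a built-in false-positive rate of 1/(n + 1) per locus
(1/28 at the default 27 runs) — consumers of the flag must budget for it.

# Selection statistics

Fst is computed exactly as the two-population heterozygosity form:
`Ht = 2p̄(1−p̄)` at the sample-size-weighted pooled frequency,
`Hs` the sample-size-weighted mean of the subpopulation expected
heterozygosities, `Fst = (Ht − Hs)/Ht`, with a monomorphic pool flagged NA
rather than thrown. EHH uses the unbiased pair-counting homozygosity
`ΣC(n_k,2)/C(n,2)` over distinct extended haplotypes (not the plug-in
squared-frequency form), computed outward from the core until EHH < 0.05
(configurable); curves truncated by the panel edge are flagged and excluded
from standardization by default. iHH integrates the curve over physical
position by the trapezoid rule; raw iHS is `ln(iHH_A/iHH_D)`, negative when
derived-allele haplotypes are long. Standardization subtracts the mean and
divides by the SD within 50 equal-width derived-allele-frequency bins
(last bin right-closed). Fifty bins presuppose a genome-scale scan;
standardizing a few-hundred-variant scan this way leaves two or three
scores per bin, where the standardized score is bounded by construction
(|z| ≤ 0.707 at bin size two) — small scans should coarsen `n_bins`
accordingly. Empirical P-values use the add-one convention throughout.

# Polygenic risk scores

The score pipeline is clumping + thresholding: greedy clumping keeps the
smallest-P unclaimed variant and claims everything within 500 kb at
r² ≥ 0.1 (ties on P broken by position, then allele order), the P-threshold
grid {5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5, 1} is tuned by AUC on a
held-out tuning cohort, and scoring standardizes over the scored cohort,
cases and controls combined. A penalized-regression builder would be a
different estimator of the same transferability phenomenon; C+T was chosen
because it is fully specifiable and the cross-ancestry comparison is
method-agnostic. Scoring is invariant to variant order and to
strand-consistent allele re-encoding (effect alleles matching the cohort's
ancestral allele flip the dosage). AUC, its DeLong CI and the
Youden-optimal cutoff come from pROC; decile odds ratios are Woolf
intervals against the lowest decile with the Haldane–Anscombe 0.5
correction (flagged) for zero cells, remainders of n mod 10 going to the
lower deciles.

# Contingency and liability statistics

The 2×2 Fisher test uses the probability-mass two-sided rule (summing
hypergeometric probabilities ≤ the observed table's), which is the rule
behind the published values it is checked against. The odds ratio is the
conditional MLE under the noncentral hypergeometric distribution (solving
`E[a | margins, ψ] = a`), with a 95 % CI from inverting the one-sided
conditional tests; boundary tables return 0 or ∞ flagged, and degenerate
margins return P = 1 with the OR undefined.

Liability variance explained maps genotype penetrances — multiplicative
odds `odds₀·R^g` scaled so the average penetrance equals the lifetime risk
K — to mean liabilities `μ_g = t − Φ⁻¹(1 − pen_g)` at threshold
`t = Φ⁻¹(1 − K)`, and returns the between-genotype variance of those means.
Summation over variants assumes independent loci and says so in its output.

# Problem sizes and test design

The packaged experiments run at desk scale, chosen to keep each structural
finding individually demonstrable: 40 loci of ~60–80 common variants for
credible-set shrinkage (median single-ancestry set ≈ 6 variants shrinking
to 1 trans-ancestrally); 8 shared and 8 ancestry-specific loci against 27
baseline runs each for colocalization; 20 replicates of a 400-variant,
24-causal-effect genome with training cohorts of 700 + 700 for PRS
transferability (ancestry-matched AUC ≈ 0.63 vs mismatched ≈ 0.55); 5000
independent null variants for association calibration. These sizes are
deliberate package defaults; scaling any of them up changes precision, not
conclusions.

What passing these experiments shows is that the *statistical machinery*
behaves as designed under a generative model with known truth. What it
cannot show is robustness to the things the generator does not contain:
imputation error and INFO-score heterogeneity, population substructure
within an ancestry group, genotyping-platform batch effects beyond a random
binary covariate, long-range LD and major-histocompatibility-class
complexity, and real demographic history. Conclusions about real cohorts
inherit those caveats.

# Known limitations

- Single-causal-variant fine-mapping only; loci with several independent
  signals need the residualization workaround and lose calibration.
- The PI_HAT estimator omits finite-sample allele-frequency corrections.
- `se_from_or_p()` is only as good as the rounding of its inputs.
- The liability mapping of log odds ratios is first-order; simulated
  effects above OR ≈ 2 at very low prevalence will recover with visible
  curvature bias.
- The founder-mosaic LD model cannot reproduce fine-scale recombination
  maps; locus definition from hotspot maps is therefore exercised on
  constructed maps, not simulated ones.
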