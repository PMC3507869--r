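---
title: "Methods: simulating and screening a chemically hypomethylated population"
author: "epimsap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and screening a chemically hypomethylated population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimsap)
```

## The problem

5-azacytidine (5-AzaC) inhibits maintenance DNA methyltransferase, so seed
treatment produces plants with genome-wide, stochastic CG hypomethylation.
An epimutagenised population built this way is screened in two steps:
first a molecular screen asks *in which sib-lines did the treatment
actually take hold*, then a forward phenotypic screen asks what the
effective hypomethylation did to agronomic traits. `epimsap` implements
the full analytical chain for both steps, together with a synthetic-data
generator that reproduces the statistical structure each stage assumes, so
the pipeline is testable end to end without any external data.

## MSAP and the isoschizomer trick

Methylation-sensitive amplified polymorphism (MSAP) fingerprints CCGG
restriction sites with the isoschizomers HpaII and MspI. Both cut the
unmethylated site; HpaII is blocked by methylation of either cytosine,
while MspI still cuts when only the internal cytosine carries CG-context
methylation. Scoring amplified fragments as present/absent per sample
therefore converts the methylation state of each site into a pair of
binary band vectors:

| latent state | HpaII | MspI |
|---|---|---|
| unmethylated | 1 | 1 |
| internal CG (C^mCGG) | 0 | 1 |
| external CHG (^mCCGG) | 0 | 0 |
| fully methylated | 0 | 0 |

Only the internal-CG state makes the two digests disagree. In a normally
methylated line the HpaII and MspI profiles of the same seedlings are
therefore systematically divergent; if treatment erased CG methylation the
two profiles converge. That convergence is the screening signal.

Hemimethylated sites are not modelled: bands are scored only
present/absent, and a binary score cannot distinguish hemimethylation from
the full-methylation classes. The EcoRI partner site and fragment-size
selection are likewise abstracted away — every locus is treated as
amplifiable when cut — because the statistics start from the scored
matrix, not the chemistry.

## The synthetic population generator

`simulate_msap_population()` draws, for every sib-line, one founder state
vector over the loci from `state_frequencies`; maps states to the two band
profiles with the table above; and adds two layers of stochasticity:

* **Line-level treatment effectiveness.** The motivating screen found
  that only some treated lines (4 of 10 assayed) had effectively lost the
  enzyme-profile divergence, i.e. chemically induced hypomethylation is
  stochastic at the line level. Each treated line is therefore effective
  with probability `p_line_effective` (default 0.4), or an exact count can
  be fixed with `n_effective_treated`. The true labels are returned, which
  is what makes label-recovery experiments possible.
* **Locus-level demethylation.** In an effective line's founder, each
  methylated locus reverts to unmethylated with probability `p_demeth`.
  The default is 1 — complete erasure at the assayed sites — because
  flagged lines in the motivating screen showed essentially total loss of
  enzyme discrimination (PhiPT near 0); partial erasure is a parameter,
  not a different model.
* **Within-line noise.** Each sample resamples each locus state from
  `state_frequencies` with probability `p_epi_noise` (default 0.02). This
  models within-line epigenetic variability as independent per-sample
  flips rather than as a lineage process; it is the simplest mechanism
  that produces non-zero within-line sums of squares (SSWP), which the
  AMOVA denominator needs. Because resampling uses the same distribution,
  it leaves the marginal state frequencies of control lines untouched.

Default `state_frequencies` are (0.50, 0.30, 0.10, 0.10) over
(unmethylated, internal-CG, external-CHG, full): about half of CCGG sites
methylated, in the middle of published MSAP-based estimates for plant
genomes, with CG-context methylation dominating as expected for
gene-adjacent CCGG sites. The observed fraction of methylated sites in
this cultivar is not known; these are configurable defaults, not claims.

What the generator does **not** emulate: linkage or chromosomal structure
among loci (loci are independent), transgenerational remethylation
dynamics, lineage-structured within-line variation, fragment-size
homoplasy, and scoring error of electropherogram bin calling. Passing
tests therefore demonstrate the statistical machinery under the stated
model, not robustness to those real-data artefacts.

## Distances, PCoA

Squared Euclidean distance between binary band vectors equals the count
of discordant loci and is the quantity AMOVA sums of squares are built
from; ordinary Euclidean distance (its square root) is used for
ordination. Both metrics are exposed (`msap_dist()`), matching the
convention in the standard binary-marker software, where "Euclidean
analysis" means ordinary Euclidean for ordination and squared Euclidean
inside AMOVA. Whether the original ordination applied covariance
standardisation is not recoverable; plain Gower double-centring is used
and documented.

`pcoa()` double-centres −½d², eigendecomposes, scales eigenvectors by the
square root of their eigenvalues, and reports negative eigenvalues (which
arise for non-Euclidean inputs) without assigning them coordinates. Axis
orientation is made deterministic by forcing the largest-magnitude
loading of each axis positive. Missing band calls are handled by
pairwise-complete locus exclusion with a warning; the motivating design
has no missingness, so this path is a convenience, not a calibrated
imputation.

## AMOVA, PhiPT and the hypomethylation screen

For a grouping of N samples into G groups of sizes n_g:

* SS_total = (1/N) Σ_{i<j} d²_ij, SS_within = Σ_g (1/n_g) Σ_{i<j∈g} d²_ij,
  SS_among by difference;
* MS on (G−1) and (N−G) df; Vw = MS_within;
  Va = (MS_among − Vw)/n₀ with n₀ = (N − Σ n_g²/N)/(G−1);
* ΦPT = max(0, Va) / (max(0, Va) + Vw). Negative Va is clamped to zero
  before the ratio — the standard convention for the moment estimator.

Significance uses whole-sample label permutation preserving group sizes,
with the add-one convention p = (b+1)/(n_perm+1) counting ties as extreme
(b = #{permuted ΦPT ≥ observed}). At the default 9,999 permutations the
smallest attainable p is exactly 0.0001, which is the printed significance
of a line whose observed statistic exceeds every permuted one.

`screen_lines()` applies this per line with the two groups being the
line's HpaII samples and its MspI samples. The two digests of one
seedling are treated as two samples (the convention of the
binary-marker AMOVA software this mirrors), although they share a latent
state vector; the sharing makes between-enzyme pairs slightly closer than
exchangeability assumes, which pushes the permutation test toward
conservatism for converged lines — the safe direction for a screen whose
"hit" is a *non-significant* test. A line is flagged hypomethylated when
p > α, default α = 0.05. The motivating screen reported its four flagged
lines as spanning an internally inconsistent p interval without naming a
cut-off, so the classification is deliberately a pure function of p and a
configurable α, and both ΦPT and p are always reported so a reader can
apply a magnitude criterion instead. p-values are reported raw across
lines, without multiple-testing correction, as in the original screen.

## The dose-response model

Survival (or normal-phenotype) percentage against 5-AzaC concentration is
fitted with a declining log-logistic constrained to start at 100%:

y(x) = A + (100 − A) / (1 + (x/m)^b)

The original analysis names only "a logistic curve modified to start at
100%" with three parameters (rate, dose giving 50%, lower asymptote); this
form is adopted because it passes *exactly* through 100 at dose 0 and has
the half-reduction dose as the named parameter m: y(m) = (100+A)/2. With a
40% lower asymptote, 70% of the population is expected to survive at m —
a pure curve identity, independent of b and m. The dose at which absolute
survival reaches 50% solves y(x) = 50 and exists only when A < 50; when
A ≥ 50 it is reported as undefined rather than thrown.

Fitting is unweighted nonlinear least squares on percentages (a binomial
weighting mode exists behind a flag; the original weighting is unstated).
The optimiser is Levenberg–Marquardt with box constraints (A ∈ [0,99],
b ∈ [10⁻³, 50], m ∈ [10⁻⁶, 100·max dose]), multi-started over
b ∈ {0.5, 1, 2, 4} × m ∈ positive-dose quartiles, A started at the
minimum observed response; best converged start by residual SS wins, with
per-start diagnostics kept. Convergence tolerance is 10⁻¹⁰ on the
relative SS change, 500 iterations per start. A flat 100% response is
flagged non-identifiable instead of fitted. Two F-tests accompany the
fit: the extra-sum-of-squares test for needing the lower asymptote, and
lack-of-fit against pure replicate error (6 doses × 4 replicates gives 24
observations, 18 pure-error df and 3 lack-of-fit df).

The generator's default design matches the study design: doses 0, 0.01,
0.1, 0.5, 1.0, 1.5 mM, 4 replicates × 100 seedlings, binomial counts on
the true curve. Default true parameters A = 40, m = 0.32 mM reproduce the
reported survival-curve quantities; the rate is not printed anywhere and
b = 2 is chosen so the curve is near its floor by 1.5 mM, consistent with
the plotted shape. The printed decision doses (0.23 mM for the phenotype
curve, 0.32 mM for survival) derive from unavailable raw data, so they
are *recovery* targets for simulation experiments, not exact reproduction
targets.

## Trait statistics

The original analysis used REML with Wald and likelihood-ratio tests in a
commercial package whose exact model terms are not recoverable. The
package deliberately substitutes transparent method-of-moments machinery
of the same structure:

* `variance_components()`: one-way random-effects decomposition into
  between-line and within-line components, with the unbalanced-data
  average-group-size coefficient and clamping (flagged) at zero.
* `group_contrast()`: difference of treatment-group means with a
  line-clustered (CR0 sandwich) standard error and Wald χ²₁ statistic —
  seeds within a line are not independent, lines are.
* `trait_correlations()`: Pearson correlations on line means with
  Fisher-z 95% intervals, because the line mean is the replicate for
  composition traits.
* Likelihood-ratio tests of variance equality are out of scope; the
  printed variance components are treated as calibration magnitudes for
  the generator, not as values to reproduce exactly.

The trait generator uses those printed magnitudes as its defaults: seed
area 2.75 mm² (control) vs 2.61 mm² (treated) — the reported −0.14 mm²
shift — with between/within-line variances 0.009/0.083 and 0.125/0.122;
oil 48.9% vs 43.1%; protein 23.4% vs 27.2%; fatty acids (% of total oil)
palmitic 3.15/3.24, linoleic 18.82/19.45, erucic 57.56/54.19. The
absolute seed-area means are not printed anywhere; 2.75 mm² is a
realistic yellow-sarson seed profile area and only the difference and the
variance components matter to the analyses.

Fatty-acid line means load on a single latent "desaturation" factor per
line (biologically: lines where desaturase activity is up-regulated shift
C18:1 flux onward to linoleic and leave less for elongation to erucic).
Solving ρ_eρ_l = 0.88, ρ_pρ_l = 0.75, ρ_pρ_e = 0.74 gives loadings
(ρ_p, ρ_l, ρ_e) = (0.794, 0.944, −0.932), so one factor reproduces all
three reported pairwise line-mean correlations (−0.88 erucic:linoleic,
+0.75 palmitic:linoleic, −0.74 palmitic:erucic) exactly in expectation;
`latent_desaturation_effect` scales the loadings and 0 decouples the
acids.

## Population bookkeeping

`build_population_pedigree()` reproduces the accession arithmetic of the
population design: each E1 plant contributes three single-silique
accessions plus one pooled accession (so 473 E1 plants give 1,892 E2 seed
accessions), and advancing 100 selected lines at 10 seeds each gives
1,000 E2 plants. The ledger carries unique accession ids, parentage and
source type, and is the canonical line metadata input for the trait
generator.

## Reproducibility and problem sizes

Every stochastic operation takes one integer seed and draws from R's
generator in documented order, so identical spec + seed is bit-for-bit
reproducible; `run_pipeline()` derives per-stage seeds from one global
seed and writes an md5 manifest so reruns can be verified file by file.

Simulation experiments in the test suite use the study's own scales where
they are stated — the 14-line × 10-seedling × 500-locus MSAP cohort with
9,999 permutations, the 6-dose × 4-replicate × 100-seedling dose-response
design (200 replicate fits for midpoint recovery), 500 null replicates at
199 permutations for permutation-validity calibration — and modest
desk-scale instances (50–100 lines) for the trait-recovery and
correlation-coverage experiments. At 14 lines the trait contrasts are
illustrative only; the calibration experiments are where the estimators
are actually validated.

## Known limitations

* The screen's permutation test treats the two digests of a seedling as
  independent samples; the resulting conservatism is described above and
  is inherent to the mirrored convention, not removable without changing
  the test.
* The method-of-moments variance decomposition is not REML: on balanced
  data they coincide, on unbalanced data they differ slightly, and no
  attempt is made to reproduce the commercial REML output.
* The log-logistic is one of several curves passing through 100 at dose
  0; an alternative logistic-in-x form would differ in the tails. The
  choice is documented, not testable against the unavailable raw data.
* Generator defaults that the record does not pin down (methylated-site
  fraction, demethylation completeness, rate b, absolute seed-area mean)
  are single documented choices, deliberately not tuned further.
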