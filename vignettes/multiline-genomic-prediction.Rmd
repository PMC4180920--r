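---
title: "Multi-line genomic prediction: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-line genomic prediction: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multilineGP)
```

## The problem

Genomic prediction estimates the additive genetic merit (estimated breeding
value, EBV) of selection candidates from genome-wide SNP genotypes, using a
training set of genotyped and phenotyped relatives. When several breeding
lines are available — here two closely related brown layer-type lines and one
distant white line — the practical question is whether pooling lines in the
training set helps, and whether the answer depends on the prediction model.
Linear models differ mainly in how they shrink the `p >> n` marker effects:
uniformly (GBLUP / RRBLUP), by dimension reduction (ridge regression on
principal components, RRPCA), or adaptively per SNP (the Gibbs-sampling
variable-selection models BayesC and BSSVS). This package implements all of
these, a pedigree-BLUP baseline, the surrounding quality control and
evaluation machinery, and a calibrated multi-line simulator so that the whole
design can be exercised and tested without proprietary data.

## The simulator

`simulate_multiline()` generates the study conditions end to end:

* **Base population.** `n_founders` (default 100) unrelated individuals in
  Hardy–Weinberg proportions at `n_snps` unlinked SNPs; founder allele
  frequencies are uniform on (0.05, 0.5), matching a post-editing panel where
  rare alleles have been removed while still letting line-specific fixation
  emerge by drift.
* **Line divergence.** Each line samples `effective_size` (default 50)
  founders and drifts through `generations_since_split` discrete generations
  of random mating (gene dropping, recorded pedigree). The defaults — 14
  generations for the sibling pair, 150 for the distant line — were calibrated
  once so that the sibling lines' minor-allele-frequency (MAF) correlation is
  close to 0.35 and the distant line's close to 0.1, the relatedness pattern
  the design is about. Drift is the only divergence mechanism (no selection).
* **Study phase.** Three pedigreed generations holding ~1000 phenotyped
  training birds per line, then a youngest generation of ~240 validation
  birds. A validation bird's dam is drawn from the phenotyped training
  parents with probability `dam_overlap` (default 2/3, exposed as a knob
  because only the resulting overlap fraction, not the sampling mechanism
  that produced it, is identifiable from the study description) and otherwise
  from unphenotyped contemporaries.
* **Trait.** `n_qtl` (default 300) of the SNPs carry allele-substitution
  effects drawn from a multivariate normal across lines; the default
  effect correlations (0.8 between the sibling lines, 0.2 with the distant
  line) encode the hypothesis that QTL effects — and, in real data, the
  SNP–QTL linkage phase — are conserved between close lines but only weakly
  across distant ones. Since the simulator has no linkage map, this effect
  correlation is the single knob standing in for both mechanisms.
  Residual variance is set per line so that realized genetic variance over
  total variance equals the target heritability (0.41 / 0.41 / 0.51 by
  default); enforcing against *realized* rather than theoretical variance
  makes small simulations hit their target exactly. Hatch-week effects are a
  common normal shift per week class.

**What the simulator does not emulate:** within-chromosome linkage
disequilibrium and its decay, genotyping error, selection during divergence,
and maternal environment. Passing tests on these simulations therefore
establish correctness of the estimation machinery and the qualitative
relatedness logic, not quantitative transfer to any real panel.

Problem sizes (1500 SNPs, 300 QTL, ~3700 birds across three lines) are the
package's own desk-scale choice: large enough that the relationship matrices
and the seven-scenario grid behave as in practice, small enough that the full
replicate experiments run on a single CPU.

## Quality control

`filter_snps()` applies the four editing rules to the combined multi-line
data: call rate below 0.95, MAF below 0.02 (a SNP at exactly the threshold is
kept; "below" is read as strict), no observed homozygote, and a
Hardy–Weinberg chi-square above 600 (strictly). The Hardy–Weinberg statistic
is the 3-class goodness-of-fit chi-square with expectations from the observed
allele frequency and no continuity correction — the enormous threshold, whose
purpose is to catch assay artefacts such as paralogous loci rather than mild
disequilibrium, makes the correction irrelevant. All four rules are evaluated
for every SNP and all failed-rule tags recorded, so per-rule counts do not
depend on rule order. Missing genotypes surviving QC are mean-imputed per SNP
on the combined data before any matrix algebra; hatch-week pre-correction is
fitted by one-way least squares on training individuals only and applied to
all records, which avoids a leakage the original design did not need to
discuss.

## Relationship matrices

* `build_A()` — pedigree numerator relationship matrix by the recursive
  tabular method, founders unrelated and non-inbred. For deep simulated
  pedigrees `prune_pedigree()` truncates to a configurable number of ancestor
  generations (default 6 in `prepare_analysis()`), the usual practice when
  complete pedigrees are far deeper than the informative horizon.
* `build_G_vanraden()` — `G = MM' / (2 * sum(p_i q_i))` with columns centred
  by twice the allele frequency; frequencies come from the combined
  multi-line data and the matrix is built once and reused for all training
  sets.
* `build_G_identity_fraction()` — mean per-SNP allele-sharing score
  (identical homozygotes 1, opposite homozygotes 0, anything involving a
  heterozygote 0.5).
* `build_G_excess_hom()` — excess of identical over opposite homozygotes
  relative to the expectation under whole-population frequencies,
  `(O_id − O_op − E(H)) / (p − E(H))`. The exact expectation intended by the
  external utility this score originates from is not recoverable, so two
  variants are exposed and recorded in the matrix metadata: the default
  `"pairwise"` expectation for two independent Hardy–Weinberg individuals,
  `sum(p^4 + q^4 − 2 p^2 q^2)`, and the simpler `"individual"` expected
  homozygosity `sum(1 − 2pq)`.

**Conditioning.** The excess-homozygosity matrix on pooled multi-line data is
genuinely indefinite (the constant `E(H)` shift acts as a rank-one downdate,
and cross-line blocks are strongly negative), so it is not a valid covariance
as printed. `solve_mixed_model()` first tries a plain Cholesky factorization,
then a ridge of `1e-6` on the diagonal, and finally *bends* the training
block — eigenvalues below `1e-8` of the largest are raised to that floor —
the standard conditioning treatment for estimated relationship matrices. The
treatment used is reported in the fit.

## Predictors

All marker-based models centre genotype columns and scale them to unit
variance using constants estimated on the scenario's training rows and
re-applied verbatim to validation rows. With `sigma_w2 = sigma_a2 / p` for
the scaled design, RRBLUP solves the ridge system with
`alpha = sigma_e2 / sigma_w2`, and GBLUP with `K = ZZ'/p` is algebraically
identical to it — a property the test suite verifies to numerical precision
and a useful cross-check between the two independent code paths (dense ridge
solve versus animal-model mixed-model equations). The mixed model fits the
overall mean as the only fixed effect (phenotypes are pre-corrected) by
generalized least squares, and validation EBVs are obtained jointly with
their phenotypes treated as missing.

For RRPCA, the projection is the singular value decomposition of the centred
training design: rows of the projection matrix are the leading eigenvectors
of the genotype covariance, constrained to be orthonormal. (A unit-trace
constraint on `TT'` would identify only a single direction; the orthonormal
form is what makes a multi-hundred-component regression meaningful.) The
retained dimension is the smallest number of components explaining 97% of
the genotypic variance by default, and `pc_sweep()` traces accuracy across
the whole range of dimensions, with the PCA reference set (training lines
only, or all lines) chosen by the caller. The ridge coefficient on the
scores reuses `alpha = sigma_e2 / sigma_w2` from RRBLUP by default — whether
it should be re-derived for the rotated basis is not identifiable from the
design, so an override is provided.

When a training set contains several lines, `average_vc()` takes arithmetic
means of the additive and residual variances across member lines and
re-derives heritability and `alpha` from the means; the per-SNP variance is
the mean additive variance divided by the scenario's segregating SNP count.
Accuracies for a target line always use that line's own heritability.

## BayesC and BSSVS

Both are single-site Gibbs samplers over a two-component mixture per SNP.
BayesC sets the effect to exactly zero with prior probability `pi` in each
iteration; BSSVS always assigns an effect, drawn from a small-variance
component `sigma_w2 / c` with prior probability `pi` instead. Full
conditionals are the standard ones for this family: normal for each effect
given its component, Bernoulli for the component indicator from the marginal
likelihood of the SNP's right-hand side, scaled-inverse-chi-square for the
residual and common SNP variances (prior degrees of freedom 4.2, scales taken
from the supplied variance components with `sigma_w2` initialised as total
genetic variance over SNP count), and an unpenalised location for the mean.
Defaults: chain 10 000, burn-in 2 000, thinning 10, `pi` 0.9 (BayesC) or
0.999 (BSSVS), `c = 100` — the chain settings and `c` are field-conventional
choices, all configurable. `pi` is fixed, not estimated. Chains use R's RNG,
so a seed makes them bit-reproducible; summaries (posterior-mean effects,
inclusion probabilities, variance posteriors, an effective-sample-size
diagnostic) come from the kept post-burn-in, thinned iterations only.

One scale effect is worth knowing: the prior fractions 0.9 versus 0.999 were
chosen for a ~46k-SNP panel, where they imply thousands versus dozens of
large-effect slots and both models behave ridge-like on a polygenic trait,
with near-perfect agreement of their EBVs. At desk-scale panels of a few
hundred SNPs, `pi = 0.999` leaves about one large-effect slot and the two
posteriors genuinely diverge (EBV correlation around 0.9 in our replicates
regardless of chain length). The test suite therefore checks the
sampler-consistency property at matched sparsity, where the small BSSVS
component is negligible and the two mixtures describe the same model.

## Evaluation

Accuracy is the Pearson correlation between EBV and the (pre-corrected)
validation phenotypes divided by the square root of the trait heritability,
sign preserved. Its approximate standard error is
`sqrt((1 − rho^2)/(N − 2)) / sqrt(h2)` with `rho` the *raw* correlation —
the literal reading of the printed expression. `accuracy_se_from_accuracy()`
converts a tabulated accuracy back to the correlation scale first; applied to
the bundled `example_accuracy_grid()` (a published 6 x 7 accuracy grid for a
line with `h2 = 0.41` and 238 validation birds) it reproduces the reported
standard-error range 0.096–0.102 exactly. The analogous published range for
the higher-heritability line is not recovered by the formula under either
reading of `rho`; both readings are therefore exposed rather than silently
"fixed", and the validation count `N` (238–240 in the original design) is an
input. Dispersion bias is the least-squares slope of phenotypes on EBV with
a bootstrap standard error over resampled individuals (default 10 000
resamples; zero-variance resamples are redrawn and counted), and a slope is
flagged only when `|b1 − 1|` reaches twice that standard error.

## Scenario design

For three lines, `build_training_sets()` crosses every target line with all
seven non-empty line subsets as training sets; SNPs not segregating in a
scenario's training data are dropped from its design matrices. Pedigree BLUP
runs only in own-line scenarios — there are no pedigree links between lines,
and a multi-line A matrix is refused rather than silently block-built. The
VanRaden G is built once on all lines; a numerical failure of one model is
recorded and never aborts the remaining models of a scenario. The full
pipeline is deterministic given the configuration seed.

## Known limitations

* No linkage map: cross-line transfer is governed by the QTL-effect
  correlation knob alone, so the simulator cannot distinguish "different QTL
  effects" from "broken linkage phase".
* The Gibbs samplers are desk-scale (dense design in memory); they are not
  meant for hundreds of thousands of SNPs.
* Variance components are inputs (as in routine evaluations); no REML or
  Gibbs estimation of them is provided.
* The excess-homozygosity G requires bending before use in a mixed model;
  its results therefore depend mildly on the conditioning floor.
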