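---
title: "Genomic connectedness and prediction accuracy under non-additive gene action"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic connectedness and prediction accuracy under non-additive gene action}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Breeding programs compare estimated genetic values of animals kept in
different management units (herds, flocks, contemporary groups). Such
across-unit comparisons are only reliable when the units are
*genetically connected* — when enough relatives span the unit
boundary that a mixed model can separate genetic differences from
unit effects. `genoconnect` quantifies connectedness with the
coefficient of determination (CD) of the MU1-vs-MU2 contrast and
relates it to genomic prediction accuracy (PA) in two-fold
cross-validation, under additive *and* non-additive genetic
architectures.

The package's question is: when a trait carries dominance or
epistatic variation, do relationship kernels designed for those
components (the dominance kernel **D**, the Hadamard product **G#D**,
the Gaussian kernel **GK**) capture more connectedness and yield
better predictions than the additive **G** alone?

## The model

All analyses use the kernel mixed model

$$\mathbf{y} = \mathbf{X}\mathbf{b} + \mathbf{Z}\mathbf{u} +
\boldsymbol\varepsilon,\qquad
\mathrm{var}(\mathbf{u}) = \sum_k \mathbf{K}_k\,\sigma^2_k,\qquad
\mathrm{var}(\boldsymbol\varepsilon) = \mathbf{I}\sigma^2_\varepsilon ,$$

with kernels

* $\mathbf{G} = \mathbf{W}_a\mathbf{W}_a'/\,2\sum_k p_k q_k$ — VanRaden's
  additive genomic relationship matrix ($\mathbf{W}_a$ centered by $2p_k$);
* $\mathbf{D} = \mathbf{W}_d\mathbf{W}_d'/\sum_k (2p_kq_k)^2$ — Vitezica's
  dominance relationship matrix (codes $-2p^2, 2pq, -2q^2$);
* $\mathbf{G}\#\mathbf{D}$ — the Hadamard product, an
  additive-by-dominance epistatic kernel (PSD by the Schur product
  theorem);
* $\mathbf{GK}(i,j) = \exp(-\theta\, \tilde d^2_{ij})$ — a Gaussian
  kernel over marker dosages (an RKHS regression when fitted);
* $\mathbf{A}$ — Wright's pedigree numerator relationship matrix
  (tabular method), used to build the management units.

Variance components are estimated by average-information REML with EM
fallback steps whenever an AI update would leave the parameter space;
EM steps are monotone in the restricted likelihood, which the test
suite asserts. Multi-kernel models are collapsed for prediction and
CD by *kernel averaging*:
$\bar{\mathbf K} = \sum_k (\sigma^2_k/\sigma^2_u) \mathbf{K}_k$ with
$\sigma^2_u = \sum_k \sigma^2_k$; the phenotypic covariance
$\mathbf{V}$ is unchanged by this collapse.

The prediction error variance of the genetic values is
$\mathrm{PEV} = \mathbf{K}\sigma^2_u -
\sigma^2_u\mathbf{K}\mathbf{Z}'\mathbf{P}\mathbf{Z}\mathbf{K}\sigma^2_u$
with $\mathbf{P} = \mathbf{V}^{-1} -
\mathbf{V}^{-1}\mathbf{X}(\mathbf{X}'\mathbf{V}^{-1}\mathbf{X})^{-}
\mathbf{X}'\mathbf{V}^{-1}$, and the connectedness statistic is

$$\mathrm{CD} = 1 - \frac{\mathbf{x}'\,\mathrm{PEV}\,\mathbf{x}}
{\mathbf{x}'\mathbf{K}\mathbf{x}\,\sigma^2_u},$$

where $\mathbf{x}$ is the contrast with entries $1/n_{MU1}$,
$-1/n_{MU2}$. CD equals the squared correlation between predicted and
true unit differences (verified in the tests by direct Monte-Carlo
simulation of that definition), is 1 when the contrast is estimated
without error, and 0 when the data carry no information about it.
Its denominator also shrinks when the two units become genetically
similar, so CD deliberately penalizes designs with little across-unit
genetic variability.

## The simulator

Because the study design is fully simulated, the generator is
first-class, tested code:

1. **Historical population.** Wright–Fisher random mating with
   recombination (Haldane model: Poisson crossovers on the cM map, no
   interference), symmetric per-locus mutation ($2.5\times10^{-5}$ by
   default), and a linear census decline from 1000 to 220 over 100
   generations. The bottleneck builds linkage disequilibrium and
   spreads allele frequencies; neutral-drift behavior is checked
   against the closed form
   $\mathrm{var}(p_t) = pq\,(1-(1-\tfrac{1}{2N})^t)$.
2. **Recent population.** Founders (200 dams, 10 sires at full scale)
   are drawn from the last historical generation; each of five
   generations mates the dams (one random sire each) with two
   offspring per dam, giving 2000 pedigreed individuals. Offspring
   sex is an equal random split per generation rather than
   i.i.d. coin flips: the design needs 200 replacement dams out of
   400 offspring every generation, which a fair coin fails to supply
   about half the time, while the marginal sex probability remains
   one half.
3. **Genome.** 29 chromosomes of 100 cM; 1885 equally spaced SNPs per
   chromosome (a 54K-chip-like panel, the per-chromosome reading of
   the chip density) and 65 QTL per chromosome placed uniformly at
   random, *disjoint* from the marker panel. Kernels only ever see
   the markers.
4. **Trait architectures.** Additive magnitudes
   $|a_k| \sim \Gamma(0.42, 8.282)$ with random sign; degree of
   dominance $\delta_k \sim N(0,1)$ and $d_k = \delta_k |a_k|$;
   epistatic pair effects $\sim N(0.02, 0.03)$ over all
   $\binom{145}{2} = 10{,}440$ unordered pairs of the 145 epistatic
   QTL. Pair $(k, k')$ is coded additively at $k$ and as a dominance
   deviation at $k'$ (A$\times$D; an A$\times$A option exists), with
   $k < k'$ by map order fixing the direction.
5. **Variance targets.** Scenario AD splits the broad-sense target
   $H^2 \in \{0.4, 0.8\}$ as $(\tfrac34, \tfrac14, 0) H^2$ across
   (additive, dominance, epistasis), ADE as
   $(\tfrac12, \tfrac14, \tfrac14) H^2$, PE as $(0, 0, 1) H^2$;
   the residual variance is $1 - H^2$, giving unit phenotypic
   variance.

**Scaling choice.** Each effect class is rescaled by a single scalar
so that the *realized* variance of its genetic component across the
simulated individuals equals the target exactly: the additive
component is linear in $a$ (and $d = \delta|a|$ co-scales with $a$),
the dominance component is then linear in $\delta$, and the epistatic
component is linear in the pair effects, so one closed-form pass per
class suffices and the Table-style variance partition holds by
construction even under linkage disequilibrium. The textbook
equilibrium formulas
($\sigma^2_a = \sum 2p_kq_k\alpha_k^2$ with
$\alpha_k = a_k + d_k(q_k - p_k)$,
$\sigma^2_d = \sum (2p_kq_kd_k)^2$, and the pairwise A$\times$D sum)
are provided as diagnostics in `expected_variance_components()`; note
that the allele-substitution effect enters those formulas linearly
and is squared only inside $\sigma^2_a$.

## Management units and the scenario grid

Two units are formed by K-means (25 restarts) on the rows of the
pedigree numerator relationship matrix of the analysis individuals —
clustering on **G** or a combined matrix is equally supported. From
that base split (scenario S1, no exchange), scenarios S2–S6 swap 10,
20, 30, 40, 50% of MU1 individuals with equally many of MU2,
preserving unit sizes; the swapped sets are drawn independently per
scenario. A generation-based forward-validation split
(`forward_split()`) covers the supplementary design (generations 1–3
vs 4–5).

**CD design choice.** CD is computed from the full data at the
full-data REML variance components, under a fixed-effect design that
contains the management unit as a contemporary group. This is the
design under which across-unit comparisons are actually made, and it
is what gives CD its characteristic shape: with an intercept-only
design the prediction error of the contrast barely responds to
disconnection and CD simply tracks the shrinking denominator,
declining monotonically from S1; with the unit effect in the model,
poorly linked designs (S1) are penalized through the numerator, CD
rises to a peak at S3/S4 and then declines as exchange erodes
across-unit genetic variance. The intercept-only variant remains
available (`cd_unit_effect = FALSE`). Cross-validated prediction
always uses an intercept-only training model, since within a training
fold the unit label is confounded with the intercept.

## Prediction accuracy

Two-fold cross-validation treats MU1 as training and MU2 as test,
then reverses the roles. Variance components are re-estimated within
each training fold; test predictions use the train–test block of the
(averaged) kernel,
$\hat{\mathbf g}_{\mathrm{test}} = \sigma^2_u
\mathbf{K}_{\mathrm{test,train}}\mathbf{P}_{\mathrm{train}}
\mathbf{y}_{\mathrm{train}}$, which the tests show to be identical to
fitting the full kernel with the test phenotypes masked. PA is the
correlation between predicted and *total* true genetic values (the
sum of additive, dominance and epistatic components — the models
under comparison differ precisely in the non-additive part they can
capture); against phenotypes when no truth is available (real data).

## Numerical choices

* Dense Cholesky-based algebra throughout; the target sample sizes
  (hundreds to a few thousand) never need sparse machinery.
* REML convergence: relative parameter change below $10^{-6}$ or a
  restricted-log-likelihood change below $10^{-8}$ (the latter matters
  when a component sits on the boundary); variances floored at
  $10^{-8}\,\mathrm{var}(y)$; AI steps that would cross the floor are
  geometrically damped toward it.
* Kernels are checked for symmetry at construction; PSD repair
  (diagonal jitter $10^{-6}$, logged) is available via `ensure_psd()`
  but is not applied silently. The marker kernels are PSD by
  construction up to a $-10^{-8}$ eigenvalue floor, which the tests
  assert.
* Gaussian-kernel distances are divided by their across-pair mean by
  default, making $\theta$ dimensionless: the mean off-diagonal entry
  is then approximately $e^{-\theta}$ for any panel size, so the
  default bandwidths $\theta = 0.22, 0.5, 0.9, 1.6$ produce mean
  off-diagonals near 0.8, 0.6, 0.4, 0.2 — the stated calibration —
  without further tuning. Raw distances remain available, and
  `calibrate_theta()` solves the inverse problem by bisection.
* Monomorphic markers are dropped (with a message) from kernel
  denominators and designs; missing genotypes on input are imputed to
  the rounded mean dosage with a logged count.
* Seeding: one master seed per run; every stage receives a
  deterministically derived child seed, so whole experiment tables
  are bit-reproducible.

## Problem sizes

The default `"reduced"` profile keeps the population-genetic
conditions (bottleneck 1000 → 220 over 100 generations, 65 QTL and 5
epistatic QTL per chromosome, both heritability levels, the full
S1–S6 grid) but shrinks the genome to 10 chromosomes × 200 SNPs and
the analysis set to 600 individuals (60 dams × 2 offspring × 5
generations), which runs a full gene-action grid in a few minutes.
The `"full"` profile restores the complete 29 × 1885 panel and 2000
individuals. Replicate experiments at reduced scale reproduce the
qualitative structure of the full-scale design — the sharp PA rise
from S1 to S3 with a plateau beyond, the CD peak at S3/S4 with a
decline to S6, and the S1/G accuracy minimum — while absolute values
of cells that depend strongly on marker density and training-set size
(notably the ADE accuracy maximum and the high CD ceiling) sit below
their full-scale counterparts; the acceptance script reports exactly
what the reduced runs produce.

## What the generator does not emulate

Selection (the recent population mates at random), sex chromosomes,
non-equilibrium mutation models beyond symmetric flips, genotyping
error and missingness patterns of real chips, and QMSim's exact
random-number streams or file formats. Passing tests therefore speak
to the statistical structure the simulator encodes — LD from a
bottleneck, family structure from a sire-limited pedigree, the
designed variance partitions — not to every feature of commercial
livestock data.

## Known limitations

* CD values at reduced scale are systematically lower than full-scale
  ones (larger PEV with fewer records and markers); comparisons
  across scales should be qualitative.
* The A×D direction of each epistatic pair is a convention; nothing in
  the trait model pins it down, and the A×A option is the only
  alternative implemented. Reduced-scale comparisons of the two codings
  give similar prediction-accuracy ceilings.
* The dominance variance share of AD/ADE architectures is small at
  $H^2 = 0.4$, so REML frequently estimates $\sigma^2_d$ near the
  boundary in reduced-scale folds; the kernel-averaged model then
  collapses toward **G**, which is the statistically honest outcome,
  not a defect.
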