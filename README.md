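# genoconnect

Genomic connectedness and prediction accuracy under additive and
non-additive gene action.

## What this package is for

Genetic evaluations compare estimated genetic values of animals kept
in different management units (herds, contemporary groups, or the
reference/validation split of a genomic prediction scheme). Those
comparisons are only trustworthy when the units are *genetically
connected*. `genoconnect` measures connectedness with the
coefficient of determination (CD) of the between-unit contrast and
relates it to genomic prediction accuracy (PA) under two-fold
cross-validation, for traits whose architecture includes dominance
and epistasis — the case where purely additive relationship matrices
can miss part of the usable signal.

For the kernel mixed model `y = Xb + Zu + e` with `var(u) = K σ²u`,
the prediction error variance of the genetic values is

    PEV = K σ²u − σ²u K Z' P Z K σ²u ,   P = V⁻¹ − V⁻¹X(X'V⁻¹X)⁻X'V⁻¹

and the connectedness of the contrast `x` (entries `1/n_MU1`,
`−1/n_MU2`) is

    CD = 1 − (x' PEV x) / (x' K x · σ²u) ,

the squared correlation between the predicted and the true unit
difference: 1 when the contrast is perfectly estimable, 0 when the
data say nothing about it.

The package provides:

* a forward-in-time simulator (bottlenecked historical population,
  structured sire/dam pedigree, SNP panels with disjoint QTL, AD /
  ADE / PE trait architectures with exact variance partitions);
* relationship kernels: pedigree numerator `A`, additive `G`
  (VanRaden), dominance `D` (Vitezica), Hadamard `G#D`, Gaussian `GK`
  with bandwidth calibration, and variance-weighted kernel averaging;
* average-information REML (EM fallback), BLUP, and dense PEV
  matrices;
* management-unit construction by K-means on a relationship matrix,
  the S1–S6 exchange-rate grid, contrasts, and forward validation;
* a scenario-grid driver (`run_experiment()`) and replicate
  summaries, plus plain-text readers/writers (PLINK `.raw`, VCF,
  pedigree CSV, TSV) for running the same pipeline on real data.

## Worked example

Simulate a small population with an additive-plus-dominance trait
(broad-sense heritability 0.4, split 0.3 additive / 0.1 dominance),
split it into two management units, exchange 20% of individuals
(scenario S3), and measure CD and cross-validated accuracy with a
`G + D` multi-kernel model:

```r
library(genoconnect)

map  <- genome_map(n_chromosomes = 5, n_snp_per_chrom = 100,
                   n_qtl_per_chrom = 20, seed = 1)
pool <- simulate_historical_population(map, n0 = 400, n_final = 150,
                                       n_generations = 40, seed = 2)
pop  <- simulate_recent_population(pool, n_dams = 30, n_sires = 5,
                                   n_generations = 4, seed = 3)
ids  <- pop$pedigree$id[pop$pedigree$generation >= 1]
geno <- subset_genotypes(pop$genotypes, ids = ids)

arch <- sample_qtl_architecture(map, geno, "AD", qtl_per_chrom = 20,
                                epi_qtl_per_chrom = 3, seed = 4)
arch <- draw_qtl_effects(arch, seed = 5)
arch <- scale_to_target_variances(arch, geno, H2 = 0.4)
phe  <- simulate_phenotypes(geno, arch, seed = 6)
phe
#> <phenotype_set> n=240; var(y)=0.974, var(g)=0.374, sigma2_eps=0.600

markers <- marker_matrix(geno)          # QTL never reach the kernels
G <- additive_kernel(markers)
D <- dominance_kernel(markers)
A <- numerator_relationship(pop$pedigree)

units <- cluster_units(subset_kernel(A, ids), seed = 7)
units
#> <unit_assignment> MU1: 116, MU2: 124; exchange rate 0%
s3 <- apply_exchange(units, rate = 0.2, seed = 8)

spec <- model_spec(phe$y, list(G, D))
vc <- reml_estimate(spec)
vc
#> <variance_components>
#>   G          0.33999
#>   D          0.01981
#>   residual   0.64870
#>   logLik -109.4814 after 5 iterations (ai)

# CD of the unit contrast, with the unit as contemporary group
Xu   <- cbind(1, as.numeric(s3$unit[ids] == "MU2"))
spec_cd <- model_spec(phe$y, list(G, D), X = Xu)
fit  <- fit_blup(spec_cd, vc)
PEV  <- prediction_error_variance(fit, spec_cd)
cd_of_contrast(contrast_vector(s3), fit$K, PEV, fit$sigma2_u)
#> <connectedness> CD = 0.7551 (PEVD = 0.0085843 / x'Kx sigma2_u = 0.035054)

cv <- twofold_cv(spec, s3, truth = phe)
cv$pa
#> 0.348   (folds 0.457 / 0.240)
```

Reading the output: REML attributes most of the marked genetic
variance to the additive kernel (σ²G ≈ 0.34 against the simulated
0.3; the small dominance share is hard to separate at n = 240), the
20%-exchange design is well connected (CD ≈ 0.76), and the true
genetic values of held-out individuals are predicted with accuracy
≈ 0.35 on average over the two folds.

The full study grid — gene actions × heritabilities × S1–S6 × kernel
configurations × replicates — runs through one call:

```r
res <- run_experiment(experiment_config("reduced", gene_action = "AD",
                                        replicates = 3), seed = 1)
summarize_replicates(res)
```

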