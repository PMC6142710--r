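# Simulator: map construction, drift, pedigree expansion, trait
# architectures, variance scaling, phenotypes.

test_that("genome map places loci strictly increasing within chromosomes", {
  map <- genome_map(4, 100, 50, 7, seed = 1)
  expect_equal(nrow(map$loci), 4 * 57)
  for (chr in 1:4) {
    pos <- map$loci$pos_cM[map$loci$chrom == chr]
    expect_true(all(diff(pos) > 0))
    expect_true(all(pos >= 0 & pos <= 100))
  }
  snp <- map$loci[map$loci$chrom == 2 & map$loci$type == "snp", ]
  expect_equal(diff(snp$pos_cM), rep(100 / 51, 49), tolerance = 1e-12)
})

test_that("historical trajectory shrinks to n_final; zero generations is identity", {
  map <- genome_map(2, 100, 30, 0, seed = 2)
  pool <- simulate_historical_population(map, 100, 40, 10, seed = 3)
  expect_equal(pool$generation_sizes[1], 100)
  expect_equal(pool$generation_sizes[11], 40)
  expect_equal(nrow(pool$haplotypes), 80)

  pool0 <- simulate_historical_population(map, 50, 50, 0, p0 = 0.3, seed = 4)
  expect_equal(pool0$generation_sizes, 50)
  expect_equal(mean(pool0$haplotypes), 0.3, tolerance = 0.05)
})

test_that("neutral drift variance matches the Wright-Fisher closed form", {
  # 2N = 100 constant, t = 20, p0 = 0.5, no mutation:
  # var(p_t) = p q (1 - (1 - 1/(2N))^t)
  map <- genome_map(5, 100, 100, 0, seed = 5)
  pool <- simulate_historical_population(map, 50, 50, 20,
                                         mutation_rate = 0, seed = 6)
  expected <- 0.25 * (1 - (1 - 1 / 100)^20)
  observed <- mean((pool$allele_freqs - 0.5)^2)
  expect_equal(observed, expected, tolerance = 0.25)
})

test_that("recent population has the designed counts and structure", {
  fx <- tiny_population()
  ped <- as.data.frame(fx$pop$pedigree)
  expect_equal(sum(ped$generation == 0), 25)       # 20 dams + 5 sires
  expect_equal(sum(ped$generation > 0), 3 * 20 * 2)
  expect_true(all(ped$sex[ped$sire != "0"] %in% c("F", "M")))
  # parents precede offspring and sires are male, dams female
  idx <- match(ped$id, ped$id)
  for (i in which(ped$sire != "0")) {
    s <- match(ped$sire[i], ped$id)
    d <- match(ped$dam[i], ped$id)
    expect_true(s < i && d < i)
    expect_equal(ped$sex[s], "M")
    expect_equal(ped$sex[d], "F")
  }
})

test_that("gamete transmission is Mendelian-consistent at every locus", {
  fx <- tiny_population()
  ped <- as.data.frame(fx$pop$pedigree)
  dos <- fx$pop$genotypes$dosage
  off <- which(ped$sire != "0")
  for (i in off) {
    do <- dos[ped$id[i], ]
    ps <- dos[ped$sire[i], ]
    pd <- dos[ped$dam[i], ]
    bad <- (do == 0 & (ps == 2 | pd == 2)) |
      (do == 2 & (ps == 0 | pd == 0)) |
      (do == 1 & ps == 0 & pd == 0) |
      (do == 1 & ps == 2 & pd == 2)
    expect_equal(sum(bad), 0)
  }
})

test_that("zero recent generations returns founders without parent links", {
  fx <- tiny_population()
  out <- simulate_recent_population(fx$pool, n_dams = 10, n_sires = 3,
                                    n_generations = 0, seed = 1)
  ped <- as.data.frame(out$pedigree)
  expect_equal(nrow(ped), 13)
  expect_true(all(ped$sire == "0" & ped$dam == "0"))
})

test_that("epistatic pair enumeration is exhaustive", {
  fx <- tiny_population()
  arch <- sample_qtl_architecture(fx$map, fx$geno, "ADE",
                                  qtl_per_chrom = 8, epi_qtl_per_chrom = 3,
                                  seed = 7)
  expect_equal(length(arch$qtl_index), 24)
  expect_equal(length(arch$epi_qtl_index), 9)
  expect_equal(nrow(arch$pairs), choose(9, 2))   # 36, by direct enumeration
  expect_true(all(arch$pairs[, 1] < arch$pairs[, 2]))
  expect_true(all(arch$epi_qtl_index %in% arch$qtl_index))
  # QTL drawn from QTL-role loci only
  expect_true(all(fx$geno$map$loci$type[arch$qtl_index] == "qtl"))
  g1 <- random_genotypes(30, 10, seed = 8)
  g1$map$loci$type <- "qtl"
  arch1 <- sample_qtl_architecture(g1$map, g1, "ADE", qtl_per_chrom = 3,
                                   epi_qtl_per_chrom = 2, seed = 9)
  expect_equal(nrow(arch1$pairs), 1)
  expect_error(sample_qtl_architecture(fx$map, fx$geno, "ADE", 5, 6),
               "epi_qtl_per_chrom")
})

test_that("effect distributions have the designed moments", {
  arch <- structure(list(scenario = "ADE", qtl_index = seq_len(1e5),
                         pairs = cbind(k = rep(1L, 1e5), k2 = rep(2L, 1e5))),
                    class = "trait_architecture")
  arch <- draw_qtl_effects(arch, seed = 9)
  # |a| ~ Gamma(0.42, 8.282): mean = 3.47844, and signs are symmetric
  expect_equal(mean(abs(arch$a)), 0.42 * 8.282, tolerance = 0.06 / 3.478)
  expect_lt(abs(mean(arch$a)), 3 * sd(arch$a) / sqrt(1e5))
  expect_equal(mean(arch$delta), 0, tolerance = 0.02)
  expect_equal(arch$d, arch$delta * abs(arch$a))
  # pair effects ~ N(0.02, 0.03)
  expect_equal(mean(arch$ad_effects), 0.02, tolerance = 3 * sqrt(0.03 / 1e5) / 0.02)
  expect_equal(var(arch$ad_effects), 0.03, tolerance = 3 * sqrt(2 / 1e5))
})

test_that("variance partitions follow the gene-action table", {
  expect_equal(unname(heritability_targets("AD", 0.4)), c(0.3, 0.1, 0))
  expect_equal(unname(heritability_targets("ADE", 0.4)), c(0.2, 0.1, 0.1))
  expect_equal(unname(heritability_targets("PE", 0.4)), c(0, 0, 0.4))
  expect_equal(unname(heritability_targets("AD", 0.8)), c(0.6, 0.2, 0))
  expect_equal(unname(heritability_targets("ADE", 0.8)), c(0.4, 0.2, 0.2))
  expect_equal(unname(heritability_targets("PE", 0.8)), c(0, 0, 0.8))
})

test_that("rescaling hits the realized variance targets for all scenarios", {
  fx <- tiny_population()
  for (sc in c("AD", "ADE", "PE")) for (H2 in c(0.4, 0.8)) {
    arch <- sample_qtl_architecture(fx$map, fx$geno, sc, 8, 3, seed = 21)
    arch <- draw_qtl_effects(arch, seed = 22)
    arch <- scale_to_target_variances(arch, fx$geno, H2)
    tg <- heritability_targets(sc, H2)
    expect_equal(unname(arch$realized_var),
                 unname(c(tg["h2_A"], tg["h2_D"], tg["h2_E"])),
                 tolerance = 1e-8)
    expect_equal(arch$sigma2_eps, 1 - H2)
    comp <- genoconnect:::genetic_components(fx$geno, arch)
    if (sc == "PE") {
      expect_equal(comp$additive, rep(0, 120))
      expect_equal(comp$dominance, rep(0, 120))
    }
    if (sc == "AD") expect_equal(comp$epistasis, rep(0, 120))
  }
})

test_that("rescaling is invariant to the initial effect scale", {
  fx <- tiny_population()
  arch <- draw_qtl_effects(
    sample_qtl_architecture(fx$map, fx$geno, "AD", 8, 3, seed = 23),
    seed = 24)
  s1 <- scale_to_target_variances(arch, fx$geno, 0.4)
  arch2 <- arch
  arch2$a <- 2 * arch$a
  arch2$d <- arch2$delta * abs(arch2$a)
  s2 <- scale_to_target_variances(arch2, fx$geno, 0.4)
  expect_equal(s1$a, s2$a, tolerance = 1e-10)
  expect_equal(s1$realized_var, s2$realized_var, tolerance = 1e-10)
})

test_that("phenotypes decompose exactly and have unit variance on average", {
  fx <- tiny_population()
  arch <- scale_to_target_variances(
    draw_qtl_effects(
      sample_qtl_architecture(fx$map, fx$geno, "AD", 8, 3, seed = 25),
      seed = 26),
    fx$geno, 0.4)
  # no residual: y coincides with the genetic value
  arch0 <- arch
  arch0$sigma2_eps <- 0
  phe0 <- simulate_phenotypes(fx$geno, arch0, seed = 27)
  expect_equal(phe0$y, phe0$g_true)
  # var(y) ~ 1 averaged over residual draws
  vy <- vapply(1:10, function(s)
    var(simulate_phenotypes(fx$geno, arch, seed = s)$y), 0)
  expect_equal(mean(vy), 1, tolerance = 0.1)
})

test_that("additive component regression recovers scaled effects on unlinked loci", {
  geno <- random_genotypes(150, 12, seed = 31)
  map1 <- geno$map
  map1$loci$type <- "qtl"
  geno$map <- map1
  arch <- draw_qtl_effects(
    sample_qtl_architecture(map1, geno, "AD", 12, 2, seed = 32), seed = 33)
  arch <- scale_to_target_variances(arch, geno, 0.4)
  comp <- genoconnect:::genetic_components(geno, arch)
  Wa <- genoconnect:::additive_codes(geno, arch$qtl_index)
  fitted <- coef(lm(comp$additive ~ Wa - 1))
  expect_equal(unname(fitted), arch$a, tolerance = 1e-8)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  map <- genome_map(2, 100, 30, 6, seed = 41)
  p1 <- simulate_historical_population(map, 80, 40, 10, seed = 42)
  p2 <- simulate_historical_population(map, 80, 40, 10, seed = 42)
  expect_identical(p1$haplotypes, p2$haplotypes)
  r1 <- simulate_recent_population(p1, 10, 3, 2, seed = 43)
  r2 <- simulate_recent_population(p2, 10, 3, 2, seed = 43)
  expect_identical(r1$genotypes$dosage, r2$genotypes$dosage)
  expect_identical(as.data.frame(r1$pedigree), as.data.frame(r2$pedigree))
})
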