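# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# small but realistic population: 3 chromosomes, bottleneck pool,
# 3 recent generations (120 non-founder individuals)
tiny_population <- function() {
  if (is.null(.fixtures$tiny)) {
    map <- genome_map(3, 100, 60, 12, seed = 11)
    pool <- simulate_historical_population(map, 300, 100, 30, seed = 12)
    pop <- simulate_recent_population(pool, n_dams = 20, n_sires = 5,
                                      n_generations = 3, seed = 13)
    ids <- pop$pedigree$id[pop$pedigree$generation >= 1]
    geno <- subset_genotypes(pop$genotypes, ids = ids)
    .fixtures$tiny <- list(map = map, pool = pool, pop = pop,
                           ids = ids, geno = geno,
                           markers = marker_matrix(geno))
  }
  .fixtures$tiny
}

# unlinked random genotype matrix (independent loci, HWE)
random_genotypes <- function(n, m, seed, p = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.1, 0.9)
  dos <- sapply(p, function(pk) rbinom(n, 2, pk))
  rownames(dos) <- sprintf("ID%05d", seq_len(n))
  map <- genome_map(1, m, m, 0)
  colnames(dos) <- map$loci$id
  genoconnect:::new_genotype_matrix(dos, map)
}

# random PSD kernel with unit-ish diagonal
random_kernel <- function(n, seed, kind = "G") {
  set.seed(seed)
  W <- matrix(rnorm(n * 2 * n), n)
  K <- tcrossprod(W) / (2 * n)
  dimnames(K) <- list(sprintf("ID%05d", 1:n), sprintf("ID%05d", 1:n))
  genoconnect:::new_kernel_matrix(K, kind)
}

# hand-built pedigree helper
make_pedigree <- function(id, sire, dam,
                          sex = rep("F", length(id)),
                          generation = rep(0L, length(id))) {
  genoconnect:::new_pedigree(data.frame(
    id = as.character(id), sire = as.character(sire),
    dam = as.character(dam), sex = sex, generation = generation))
}

# variance components object at fixed values (bypassing REML)
fixed_vc <- function(sigma2, sigma2_e) {
  structure(list(sigma2 = sigma2, sigma2_e = sigma2_e, loglik = NA_real_,
                 converged = TRUE, iterations = 0L, method = "fixed"),
            class = "variance_components")
}

# gene-dropping estimate of the numerator relationship matrix:
# founders carry two unique alleles; each transmission picks one
# parental allele at random; A_ij = 2 * P(IBD of random alleles).
gene_drop_A <- function(ped, n_rep, seed = 1) {
  set.seed(seed)
  ped <- as.data.frame(ped)
  n <- nrow(ped)
  ord <- genoconnect:::pedigree_order(ped)
  sire_i <- ifelse(ped$sire == 0, 0L, match(ped$sire, ped$id))
  dam_i <- ifelse(ped$dam == 0, 0L, match(ped$dam, ped$id))
  a1 <- matrix(0L, n_rep, n)
  a2 <- matrix(0L, n_rep, n)
  for (i in ord) {
    if (sire_i[i] == 0L) a1[, i] <- 2L * i - 1L
    else {
      pick <- runif(n_rep) < 0.5
      a1[, i] <- ifelse(pick, a1[, sire_i[i]], a2[, sire_i[i]])
    }
    if (dam_i[i] == 0L) a2[, i] <- 2L * i
    else {
      pick <- runif(n_rep) < 0.5
      a2[, i] <- ifelse(pick, a1[, dam_i[i]], a2[, dam_i[i]])
    }
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    ibd <- (a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
      (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])
    A[i, j] <- A[j, i] <- 2 * mean(ibd / 4)
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}
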