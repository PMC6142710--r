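# Kernel constructors against closed forms and brute-force oracles.

single_snp_geno <- function(dosages = c(0, 1, 2)) {
  dos <- matrix(as.integer(dosages), ncol = 1,
                dimnames = list(sprintf("ID%05d", seq_along(dosages)), "C01L00001"))
  genoconnect:::new_genotype_matrix(dos, genome_map(1, 1, 1, 0))
}

test_that("additive kernel matches the closed form at a single SNP", {
  G <- additive_kernel(single_snp_geno())
  expect_equal(unname(G$values),
               matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3))
  expect_equal(sum(G$values), 0)
})

test_that("dominance kernel codes and denominator follow the coding", {
  geno <- single_snp_geno(c(0, 1, 1, 2))   # p = 0.5 from data
  Wd <- genoconnect:::dominance_codes(geno, 1L)
  expect_equal(unname(drop(Wd)), c(-0.5, 0.5, 0.5, -0.5))
  expect_equal(mean(Wd), 0)                # exact HWE counts at p = 0.5
  D <- dominance_kernel(geno)
  expect_equal(unname(D$values), tcrossprod(c(-0.5, 0.5, 0.5, -0.5)) / 0.25)
})

test_that("G and D match brute-force double loops on a random panel", {
  geno <- random_genotypes(10, 50, seed = 51)
  p <- geno$p
  q <- 1 - p
  G <- additive_kernel(geno)$values
  D <- dominance_kernel(geno)$values
  Wa <- sweep(geno$dosage, 2, 2 * p)
  dom_code <- function(w, pk) c(-2 * pk^2, 2 * pk * (1 - pk),
                                -2 * (1 - pk)^2)[w + 1]
  Gbf <- matrix(0, 10, 10)
  Dbf <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    Gbf[i, j] <- sum(Wa[i, ] * Wa[j, ]) / (2 * sum(p * q))
    wi <- mapply(dom_code, geno$dosage[i, ], p)
    wj <- mapply(dom_code, geno$dosage[j, ], p)
    Dbf[i, j] <- sum(wi * wj) / sum((2 * p * q)^2)
  }
  expect_equal(unname(G), Gbf, tolerance = 1e-10)
  expect_equal(unname(D), Dbf, tolerance = 1e-10)
  expect_equal(sum(G), 0, tolerance = 1e-8)
})

test_that("marker kernels are invariant to SNP column order", {
  geno <- random_genotypes(8, 30, seed = 52)
  perm <- sample(30)
  geno_p <- subset_genotypes(geno, loci = perm)
  expect_equal(additive_kernel(geno)$values, additive_kernel(geno_p)$values,
               tolerance = 1e-12)
  expect_equal(dominance_kernel(geno)$values,
               dominance_kernel(geno_p)$values, tolerance = 1e-12)
})

test_that("Hadamard kernel is the entrywise product and preserves PSD", {
  G <- random_kernel(5, seed = 53, kind = "G")
  D <- random_kernel(5, seed = 54, kind = "D")
  H <- hadamard_kernel(G, D)
  expect_equal(H$values, G$values * D$values)
  expect_gte(kernel_min_eigenvalue(H), -1e-8)   # Schur product theorem
  ones <- genoconnect:::new_kernel_matrix(
    matrix(1, 5, 5, dimnames = dimnames(G$values)), "D")
  expect_equal(hadamard_kernel(G, ones)$values, G$values)
  D2 <- random_kernel(4, seed = 55)
  expect_error(hadamard_kernel(G, D2), "different individuals")
})

test_that("Gaussian kernel follows exp(-theta d^2) with unit diagonal", {
  dos <- matrix(c(0L, 2L, 1L, 1L), 2, 2, byrow = TRUE,
                dimnames = list(c("ID00001", "ID00002"), c("C01L00001", "C01L00002")))
  geno <- genoconnect:::new_genotype_matrix(dos, genome_map(1, 2, 2, 0))
  GK <- gaussian_kernel(geno, theta = 0.5, scaling = "raw")
  expect_equal(GK$values[1, 2], exp(-1))       # d^2 = 2, theta = 0.5
  expect_equal(diag(GK$values), c(ID00001 = 1, ID00002 = 1))
  expect_error(gaussian_kernel(geno, theta = 0), "positive")

  geno2 <- random_genotypes(12, 40, seed = 56)
  m_small <- genoconnect:::mean_offdiag(gaussian_kernel(geno2, 1e-6)$values)
  m_big <- genoconnect:::mean_offdiag(gaussian_kernel(geno2, 50)$values)
  expect_gt(m_small, 0.999)                    # global kernel limit
  expect_lt(m_big, 1e-6)                       # local kernel limit
  thetas <- c(0.1, 0.3, 0.6, 1, 2)
  means <- vapply(thetas, function(th)
    genoconnect:::mean_offdiag(gaussian_kernel(geno2, th)$values), 0)
  expect_true(all(diff(means) < 0))            # strictly decreasing in theta
})

test_that("bandwidth calibration reproduces the target and a grid search", {
  geno <- random_genotypes(15, 60, seed = 57)
  for (target in c(0.8, 0.6, 0.4, 0.2)) {
    th <- calibrate_theta(geno, target)
    got <- genoconnect:::mean_offdiag(gaussian_kernel(geno, th)$values)
    expect_equal(got, target, tolerance = 1e-4)
  }
  th <- calibrate_theta(geno, 0.4)
  grid <- seq(0.001, 5, by = 0.001)
  d2 <- genoconnect:::dosage_dist2(geno, "mean")
  off <- d2[lower.tri(d2)]
  gm <- vapply(grid, function(t) mean(exp(-t * off)), 0)
  expect_equal(th, grid[which.min(abs(gm - 0.4))], tolerance = 1e-3)
  expect_error(calibrate_theta(geno, 1.2), "target_mean_offdiag")
})

test_that("kernel averaging uses variance-share weights", {
  G <- random_kernel(6, seed = 58, kind = "G")
  D <- random_kernel(6, seed = 59, kind = "D")
  K <- average_kernels(list(G, D), c(0.3, 0.1))
  expect_equal(unname(K$params$weights), c(0.75, 0.25))
  expect_equal(sum(K$params$weights), 1)
  expect_equal(K$values, 0.75 * G$values + 0.25 * D$values)
  expect_identical(average_kernels(list(G), 0.3), G)
  E <- random_kernel(6, seed = 60)
  w <- c(1.2, 0.4, 2.1)
  K3 <- average_kernels(list(G, D, E), w)
  expect_equal(K3$values,
               (w[1] * G$values + w[2] * D$values + w[3] * E$values) / sum(w))
  expect_error(average_kernels(list(G, D), c(0, 0)), "zero")
})

test_that("numerator relationship reproduces textbook pedigree values", {
  # founders only
  ped <- make_pedigree(1:3, rep(0, 3), rep(0, 3))
  expect_equal(unname(numerator_relationship(ped)$values), diag(3))
  # parent-offspring, full sibs, and offspring of full sibs
  ped <- make_pedigree(c("s", "d", "o1", "o2", "x"),
                       c("0", "0", "s", "s", "o1"),
                       c("0", "0", "d", "d", "o2"),
                       sex = c("M", "F", "M", "F", "F"),
                       generation = c(0, 0, 1, 1, 2))
  A <- numerator_relationship(ped)$values
  expect_equal(A["s", "o1"], 0.5)
  expect_equal(A["o1", "o2"], 0.5)
  expect_equal(A["x", "x"], 1.25)        # inbred: parents are full sibs
  # out-of-order input is sorted internally, same values
  A2 <- numerator_relationship(ped[c(5, 3, 1, 4, 2), ])$values
  expect_equal(A2[rownames(A), colnames(A)], A)
  # cycles are detected
  bad <- make_pedigree(c("a", "b"), c("b", "a"), c("0", "0"))
  expect_error(numerator_relationship(bad), "cyclic")
})

test_that("numerator relationship agrees with gene dropping", {
  set.seed(61)
  # random 20-individual, 3-generation pedigree
  ped <- data.frame(id = as.character(1:20), sire = "0", dam = "0",
                    sex = rep(c("M", "F"), 10),
                    generation = rep(c(0L, 1L, 2L, 3L), each = 5))
  for (i in 6:20) {
    prev <- which(as.integer(ped$generation) < ped$generation[i])
    males <- prev[ped$sex[prev] == "M"]
    females <- prev[ped$sex[prev] == "F"]
    ped$sire[i] <- ped$id[sample(males, 1)]
    ped$dam[i] <- ped$id[sample(females, 1)]
  }
  ped <- make_pedigree(ped$id, ped$sire, ped$dam, ped$sex, ped$generation)
  A <- numerator_relationship(ped)$values
  Ahat <- gene_drop_A(ped, n_rep = 2e4, seed = 62)
  expect_lt(max(abs(A - Ahat)), 0.03)
})

test_that("kernels built from data are PSD within the tolerance floor", {
  fx <- tiny_population()
  for (K in list(additive_kernel(fx$markers), dominance_kernel(fx$markers),
                 gaussian_kernel(fx$markers, 0.9)))
    expect_gte(kernel_min_eigenvalue(K), -1e-8)
})
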