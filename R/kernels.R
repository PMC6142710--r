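# Relationship kernels: pedigree numerator matrix A, genomic additive G,
# dominance D, Hadamard G#D, Gaussian GK, and variance-weighted averages.

new_kernel_matrix <- function(values, kind, params = list()) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-8)
    stop("kernel matrix is not symmetric")
  structure(list(values = symmetrize(values), kind = kind, params = params),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("<kernel_matrix> kind=%s, %d x %d; mean diag %.3f, mean offdiag %.3f\n",
              x$kind, nrow(x$values), ncol(x$values),
              mean(diag(x$values)), mean_offdiag(x$values)))
  invisible(x)
}

kernel_ids <- function(K) rownames(K$values)

mean_offdiag <- function(M) {
  n <- nrow(M)
  (sum(M) - sum(diag(M))) / (n * (n - 1))
}

#' Smallest eigenvalue of a kernel
#'
#' Convenience check of positive semidefiniteness (up to a small
#' numerical floor).
#'
#' @param K a `kernel_matrix` or a symmetric matrix.
#' @return smallest eigenvalue.
#' @export
kernel_min_eigenvalue <- function(K) {
  M <- if (inherits(K, "kernel_matrix")) K$values else K
  min(eigen(symmetrize(M), symmetric = TRUE, only.values = TRUE)$values)
}

# topological order of a pedigree (parents before offspring); errors on
# cycles and on unknown parent ids
pedigree_order <- function(ped) {
  n <- nrow(ped)
  if (!all(ped$sire[ped$sire != 0] %in% ped$id) ||
      !all(ped$dam[ped$dam != 0] %in% ped$id))
    stop("pedigree contains unknown parent ids")
  sire_i <- ifelse(ped$sire == 0, 0L, match(ped$sire, ped$id))
  dam_i <- ifelse(ped$dam == 0, 0L, match(ped$dam, ped$id))
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- which(!placed &
                     (sire_i == 0L | placed[pmax(sire_i, 1L)]) &
                     (dam_i == 0L | placed[pmax(dam_i, 1L)]))
    if (!length(ready)) break
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  if (length(ord) < n)
    stop("pedigree is cyclic; offending ids: ",
         paste(ped$id[!placed], collapse = ", "))
  ord
}

#' Numerator relationship matrix from a pedigree
#'
#' Wright's A computed by the tabular method: `A[i,i] = 1 + 0.5 *
#' A[sire, dam]` and `A[i,j] = 0.5 * (A[j, sire] + A[j, dam])` for
#' individuals `j` preceding `i`, with unknown parents contributing
#' zero. Rows are returned in the input order.
#'
#' @param pedigree a `pedigree` (or data frame with columns `id`,
#'   `sire`, `dam`; 0 = unknown parent).
#' @return a `kernel_matrix` of kind `"A"`.
#' @export
numerator_relationship <- function(pedigree) {
  ped <- as.data.frame(pedigree)
  n <- nrow(ped)
  ord <- pedigree_order(ped)
  sire_i <- ifelse(ped$sire == 0, 0L, match(ped$sire, ped$id))
  dam_i <- ifelse(ped$dam == 0, 0L, match(ped$dam, ped$id))
  A <- matrix(0, n, n)
  done <- integer(0)
  for (i in ord) {
    s <- sire_i[i]
    d <- dam_i[i]
    if (length(done)) {
      as_ <- if (s > 0L) A[s, done] else 0
      ad_ <- if (d > 0L) A[d, done] else 0
      A[i, done] <- A[done, i] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
    done <- c(done, i)
  }
  dimnames(A) <- list(as.character(ped$id), as.character(ped$id))
  new_kernel_matrix(A, "A")
}

# shared guard for marker-based kernels; returns polymorphic column index
polymorphic_cols <- function(geno) {
  keep <- which(!geno$monomorphic)
  if (!length(keep)) stop("all SNPs are monomorphic")
  if (length(keep) < ncol(geno$dosage))
    message(sprintf("dropping %d monomorphic SNPs",
                    ncol(geno$dosage) - length(keep)))
  keep
}

#' Additive genomic relationship matrix (VanRaden G)
#'
#' `G = W_a W_a' / (2 sum p_k q_k)` with `W_a` the marker matrix centered
#' by twice the allele frequency. Monomorphic markers are dropped from
#' both the design and the denominator.
#'
#' @param genotypes a `genotype_matrix` (markers only; see
#'   [marker_matrix()]).
#' @return a `kernel_matrix` of kind `"G"`.
#' @export
additive_kernel <- function(genotypes) {
  keep <- polymorphic_cols(genotypes)
  p <- genotypes$p[keep]
  Wa <- additive_codes(genotypes, keep)
  G <- tcrossprod(Wa) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(rownames(genotypes$dosage), rownames(genotypes$dosage))
  new_kernel_matrix(G, "G", params = list(m = length(keep)))
}

#' Dominance genomic relationship matrix (Vitezica D)
#'
#' `D = W_d W_d' / sum (2 p_k q_k)^2` with dominance codes `-2p^2`,
#' `2pq`, `-2q^2` for dosages 0, 1, 2.
#'
#' @inheritParams additive_kernel
#' @return a `kernel_matrix` of kind `"D"`.
#' @export
dominance_kernel <- function(genotypes) {
  keep <- polymorphic_cols(genotypes)
  p <- genotypes$p[keep]
  Wd <- dominance_codes(genotypes, keep)
  D <- tcrossprod(Wd) / sum((2 * p * (1 - p))^2)
  dimnames(D) <- list(rownames(genotypes$dosage), rownames(genotypes$dosage))
  new_kernel_matrix(D, "D", params = list(m = length(keep)))
}

#' Hadamard (element-wise) product kernel G#D
#'
#' Models additive-by-dominance epistatic relationships. Both kernels
#' must index the same individuals in the same order; the Schur product
#' theorem guarantees the result is PSD when both inputs are.
#'
#' @param G,D `kernel_matrix` objects over identical ids.
#' @return a `kernel_matrix` of kind `"GxD"`.
#' @export
hadamard_kernel <- function(G, D) {
  stopifnot(inherits(G, "kernel_matrix"), inherits(D, "kernel_matrix"))
  if (!identical(kernel_ids(G), kernel_ids(D)))
    stop("kernels index different individuals")
  new_kernel_matrix(G$values * D$values, "GxD",
                    params = list(parents = c(G$kind, D$kind)))
}

# pairwise squared Euclidean distances between dosage rows, optionally
# divided by their off-diagonal mean so exp(-theta * d2) lives on a
# marker-count-free scale
dosage_dist2 <- function(genotypes, scaling = c("mean", "raw")) {
  scaling <- match.arg(scaling)
  W <- genotypes$dosage
  cp <- tcrossprod(W)
  sq <- diag(cp)
  d2 <- outer(sq, sq, `+`) - 2 * cp
  d2[d2 < 0] <- 0
  if (scaling == "mean") {
    mo <- mean_offdiag(d2)
    if (mo <= 0) stop("all individuals have identical genotypes")
    d2 <- d2 / mo
  }
  d2
}

#' Gaussian kernel over marker genotypes
#'
#' `GK(i, j) = exp(-theta * d2_ij)` with `d2` the squared Euclidean
#' distance between dosage vectors. By default the distances are divided
#' by their across-pair mean, which makes `theta` dimensionless: the
#' mean off-diagonal entry is then close to `exp(-theta)`, so theta =
#' 0.22, 0.5, 0.9, 1.6 give means near 0.8, 0.6, 0.4, 0.2 regardless of
#' panel size. Small theta yields a global kernel (entries near 1),
#' large theta a local one (entries near 0). `scaling = "raw"` uses the
#' raw distances.
#'
#' @param genotypes a `genotype_matrix`.
#' @param theta positive smoothing parameter.
#' @param scaling `"mean"` (default) or `"raw"`.
#' @return a `kernel_matrix` of kind `"GK"` with unit diagonal.
#' @export
gaussian_kernel <- function(genotypes, theta, scaling = c("mean", "raw")) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0)
    stop("theta must be a single positive value")
  d2 <- dosage_dist2(genotypes, scaling)
  GK <- exp(-theta * d2)
  diag(GK) <- 1
  dimnames(GK) <- list(rownames(genotypes$dosage), rownames(genotypes$dosage))
  new_kernel_matrix(GK, "GK", params = list(theta = theta,
                                            scaling = match.arg(scaling)))
}

#' Calibrate the Gaussian-kernel bandwidth to a target similarity
#'
#' Finds `theta` such that the mean off-diagonal entry of the Gaussian
#' kernel equals `target_mean_offdiag` (within 1e-4), by bisection; the
#' mean off-diagonal is strictly decreasing in theta.
#'
#' @param genotypes a `genotype_matrix` (at least two individuals).
#' @param target_mean_offdiag target mean off-diagonal, in (0, 1).
#' @param scaling distance scaling, as in [gaussian_kernel()].
#' @return the calibrated theta (scalar).
#' @export
calibrate_theta <- function(genotypes, target_mean_offdiag,
                            scaling = c("mean", "raw")) {
  stop_if_not_scalar_prob(target_mean_offdiag, "target_mean_offdiag",
                          open_lo = TRUE, open_hi = TRUE)
  if (nrow(genotypes$dosage) < 2) stop("need at least two individuals")
  d2 <- dosage_dist2(genotypes, scaling)
  off <- d2[lower.tri(d2)]
  f <- function(theta) mean(exp(-theta * off))
  lo <- 0
  hi <- 1
  while (f(hi) > target_mean_offdiag) hi <- hi * 2
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm - target_mean_offdiag) < 1e-4 / 10) break
    if (fm > target_mean_offdiag) lo <- mid else hi <- mid
  }
  mid
}

#' Variance-weighted average of kernels (kernel averaging)
#'
#' `K = sum_k (sigma2_k / sum sigma2) K_k`: each kernel is weighted by
#' its component's share of the marked genetic variance, collapsing a
#' multi-kernel model to a single random effect.
#'
#' @param kernels list of `kernel_matrix` objects over identical ids.
#' @param variances non-negative component variances, one per kernel.
#' @return a `kernel_matrix` of kind `"averaged"` (or the single input
#'   kernel unchanged) with the weights recorded in `params`.
#' @export
average_kernels <- function(kernels, variances) {
  stopifnot(is.list(kernels), length(kernels) == length(variances),
            all(variances >= 0))
  if (sum(variances) <= 0) stop("all component variances are zero")
  if (length(kernels) == 1L) return(kernels[[1L]])
  ids <- kernel_ids(kernels[[1L]])
  for (K in kernels[-1L])
    if (!identical(kernel_ids(K), ids))
      stop("kernels index different individuals")
  w <- variances / sum(variances)
  V <- Reduce(`+`, Map(function(K, wi) wi * K$values, kernels, w))
  new_kernel_matrix(V, "averaged",
                    params = list(weights = w,
                                  kinds = vapply(kernels, `[[`, "", "kind")))
}

#' Subset a kernel to a set of individuals
#'
#' @param K a `kernel_matrix`.
#' @param ids row/column names (or indices) to keep, in the requested
#'   order.
#' @return a `kernel_matrix` over the subset.
#' @export
subset_kernel <- function(K, ids) {
  stopifnot(inherits(K, "kernel_matrix"))
  new_kernel_matrix(K$values[ids, ids, drop = FALSE], K$kind, K$params)
}

#' Repair a kernel that is indefinite beyond tolerance
#'
#' If the smallest eigenvalue falls below `-1e-8`, a diagonal jitter is
#' added (with a message); otherwise the kernel is returned unchanged.
#'
#' @param K a `kernel_matrix`.
#' @param jitter diagonal constant to add when repair is needed.
#' @return a `kernel_matrix`.
#' @export
ensure_psd <- function(K, jitter = 1e-6) {
  ev <- kernel_min_eigenvalue(K)
  if (ev < -1e-8) {
    message(sprintf("kernel %s has min eigenvalue %.3g; adding jitter %g",
                    K$kind, ev, jitter))
    K$values <- K$values + diag(jitter, nrow(K$values))
    K$params$jitter <- jitter
  }
  K
}
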