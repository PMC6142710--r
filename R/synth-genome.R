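# Forward-in-time simulator: bottlenecked historical population that
# establishes linkage disequilibrium, followed by a structured recent
# pedigree, QTL architectures and phenotypes.

#' Build a genome map of SNPs and candidate QTL
#'
#' The map holds one row per locus with its chromosome, position in
#' centimorgans and role. Markers (`"snp"`) are equally spaced along each
#' chromosome; candidate QTL (`"qtl"`) are placed uniformly at random and
#' are kept disjoint from the marker panel, so that trait loci are never
#' handed to the kernel constructors.
#'
#' @param n_chromosomes number of autosomes.
#' @param chrom_length_cM map length of every chromosome, in cM.
#' @param n_snp_per_chrom markers per chromosome (equally spaced).
#' @param n_qtl_per_chrom candidate QTL per chromosome (uniform positions).
#' @param seed optional integer seed for the QTL placement.
#' @return An object of class `genome_map`: a list with `n_chromosomes`,
#'   `chrom_length_cM` and a `loci` data frame (`id`, `chrom`, `pos_cM`,
#'   `type`).
#' @export
genome_map <- function(n_chromosomes = 29, chrom_length_cM = 100,
                       n_snp_per_chrom = 1885, n_qtl_per_chrom = 65,
                       seed = NULL) {
  stopifnot(n_chromosomes >= 1, chrom_length_cM > 0, n_snp_per_chrom >= 1,
            n_qtl_per_chrom >= 0)
  loci <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_chromosomes), function(chr) {
      snp_pos <- chrom_length_cM * seq_len(n_snp_per_chrom) /
        (n_snp_per_chrom + 1)
      qtl_pos <- if (n_qtl_per_chrom > 0)
        sort(runif(n_qtl_per_chrom, 0, chrom_length_cM)) else numeric(0)
      df <- data.frame(
        chrom = chr,
        pos_cM = c(snp_pos, qtl_pos),
        type = c(rep("snp", n_snp_per_chrom), rep("qtl", n_qtl_per_chrom))
      )
      df <- df[order(df$pos_cM), , drop = FALSE]
      # nudge exact ties apart so positions are strictly increasing
      while (any(duplicated(df$pos_cM))) {
        i <- which(duplicated(df$pos_cM))
        df$pos_cM[i] <- df$pos_cM[i] + 1e-6
        df <- df[order(df$pos_cM), , drop = FALSE]
      }
      df
    }))
  })
  loci$id <- sprintf("C%02dL%05d", loci$chrom, ave(loci$chrom, loci$chrom,
                                                  FUN = seq_along))
  rownames(loci) <- NULL
  structure(list(n_chromosomes = n_chromosomes,
                 chrom_length_cM = chrom_length_cM,
                 loci = loci[, c("id", "chrom", "pos_cM", "type")]),
            class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("<genome_map> %d chromosomes x %.0f cM; %d snp, %d qtl loci\n",
              x$n_chromosomes, x$chrom_length_cM,
              sum(x$loci$type == "snp"), sum(x$loci$type == "qtl")))
  invisible(x)
}

# One meiosis per entry of `parents`: returns a gametes matrix
# (length(parents) x n_loci) drawn from the phased haplotypes in H
# (rows 2i-1, 2i belong to individual i). Crossovers follow the Haldane
# model: Poisson-many per chromosome (map length in Morgans), uniform
# positions, no interference. Vectorised over gametes.
recombine_gametes <- function(H, parents, map) {
  loci <- map$loci
  G <- length(parents)
  m <- nrow(loci)
  S <- matrix(0L, G, m)
  for (chr in seq_len(map$n_chromosomes)) {
    cols <- which(loci$chrom == chr)
    pos <- loci$pos_cM[cols]
    lambda <- map$chrom_length_cM / 100   # Morgans
    k <- rpois(G, lambda)
    Schr <- matrix(sample(0:1, G, replace = TRUE), G, length(cols))
    if (max(k) > 0L) {
      for (r in seq_len(max(k))) {
        has <- which(k >= r)
        cx <- runif(length(has), 0, map$chrom_length_cM)
        Schr[has, ] <- (Schr[has, , drop = FALSE] +
                          outer(cx, pos, `<=`)) %% 2
      }
    }
    S[, cols] <- Schr
  }
  ridx <- 2L * (parents - 1L) + 1L + S           # G x m row indices into H
  matrix(H[cbind(as.vector(ridx), rep(seq_len(m), each = G))], G, m)
}

#' Simulate the historical (LD-generating) population
#'
#' Wright-Fisher random mating with recombination, symmetric per-locus
#' mutation, and a population bottleneck: the census size shrinks
#' linearly from `n0` to `n_final` over `n_generations`. Drift through
#' the bottleneck spreads allele frequencies and builds linkage
#' disequilibrium, mimicking the burn-in phase of forward simulators
#' such as QMSim.
#'
#' @param map a [genome_map()].
#' @param n0 initial census size.
#' @param n_final census size of the last historical generation.
#' @param n_generations number of discrete generations simulated.
#' @param mutation_rate per-locus, per-gamete symmetric flip rate.
#' @param p0 initial reference-allele frequency for every locus.
#' @param seed integer seed.
#' @return An object of class `haplotype_pool`: phased haplotypes
#'   (`2 * n_final` rows), per-locus allele frequencies, the census-size
#'   trajectory and the map.
#' @export
simulate_historical_population <- function(map, n0 = 1000, n_final = 220,
                                           n_generations = 100,
                                           mutation_rate = 2.5e-5,
                                           p0 = 0.5, seed = NULL) {
  stopifnot(inherits(map, "genome_map"))
  if (!(n0 >= n_final && n_final >= 2))
    stop("need n0 >= n_final >= 2")
  stop_if_not_scalar_prob(p0, "p0", open_lo = TRUE, open_hi = TRUE)
  with_seed(seed, {
    m <- nrow(map$loci)
    sizes <- round(seq(n0, n_final, length.out = n_generations + 1))
    H <- matrix(rbinom(2L * n0 * m, 1L, p0), 2L * n0, m)
    for (t in seq_len(n_generations)) {
      nt <- sizes[t + 1L]
      n_par <- nrow(H) / 2L
      # two distinct parents per offspring
      p1 <- sample.int(n_par, nt, replace = TRUE)
      p2 <- sample.int(n_par, nt, replace = TRUE)
      clash <- which(p2 == p1)
      while (length(clash)) {
        p2[clash] <- sample.int(n_par, length(clash), replace = TRUE)
        clash <- clash[p2[clash] == p1[clash]]
      }
      g1 <- recombine_gametes(H, p1, map)
      g2 <- recombine_gametes(H, p2, map)
      Hn <- matrix(0L, 2L * nt, m)
      Hn[seq(1L, 2L * nt, by = 2L), ] <- g1
      Hn[seq(2L, 2L * nt, by = 2L), ] <- g2
      if (mutation_rate > 0) {
        n_mut <- rbinom(1L, length(Hn), mutation_rate)
        if (n_mut > 0) {
          idx <- sample.int(length(Hn), n_mut)
          Hn[idx] <- 1L - Hn[idx]
        }
      }
      H <- Hn
    }
    freq <- colMeans(H)
    if (all(freq %in% c(0, 1)))
      stop("all loci fixed after drift; increase mutation_rate or n_final")
    colnames(H) <- map$loci$id
    structure(list(haplotypes = H, allele_freqs = freq,
                   generation_sizes = sizes, map = map),
              class = "haplotype_pool")
  })
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf(
    "<haplotype_pool> %d individuals x %d loci; trajectory %d -> %d over %d generations; %.1f%% segregating\n",
    nrow(x$haplotypes) / 2, ncol(x$haplotypes),
    x$generation_sizes[1], x$generation_sizes[length(x$generation_sizes)],
    length(x$generation_sizes) - 1,
    100 * mean(x$allele_freqs > 0 & x$allele_freqs < 1)))
  invisible(x)
}

new_pedigree <- function(df) {
  stopifnot(all(c("id", "sire", "dam", "sex", "generation") %in% names(df)))
  structure(df, class = c("pedigree", "data.frame"))
}

new_genotype_matrix <- function(dosage, map, p = NULL) {
  stopifnot(is.matrix(dosage), all(dosage %in% 0:2))
  if (is.null(p)) p <- colMeans(dosage) / 2
  structure(list(dosage = dosage, map = map, p = p,
                 monomorphic = p <= 0 | p >= 1),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d loci (%d monomorphic)\n",
              nrow(x$dosage), ncol(x$dosage), sum(x$monomorphic)))
  invisible(x)
}

#' Expand the recent, pedigreed population from a haplotype pool
#'
#' Founders (`n_dams` females, `n_sires` males) are drawn from the last
#' historical generation. Each subsequent generation mates `n_dams` dams
#' (each to one sire drawn from the `n_sires` sires of the previous
#' generation) and every dam leaves `offspring_per_dam` offspring, so each
#' generation adds `n_dams * offspring_per_dam` individuals. Gametes are
#' transmitted with Haldane recombination; offspring sex is an equal
#' random split within each generation.
#'
#' @param pool a [simulate_historical_population()] result.
#' @param n_dams,n_sires breeding females/males per generation.
#' @param n_generations number of recent generations (founders are
#'   generation 0 and are not counted in the analysis total).
#' @param offspring_per_dam litter contribution per dam per generation;
#'   must be >= 2 so that enough replacement females exist.
#' @param expected_total optional assertion on the number of non-founder
#'   individuals produced (e.g. 2000 for 200 dams x 2 x 5 generations).
#' @param seed integer seed.
#' @return list with elements `genotypes` (a `genotype_matrix` covering
#'   founders and descendants) and `pedigree`.
#' @export
simulate_recent_population <- function(pool, n_dams = 200, n_sires = 10,
                                       n_generations = 5,
                                       offspring_per_dam = 2,
                                       expected_total = NULL, seed = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"))
  n_pool <- nrow(pool$haplotypes) / 2L
  if (n_dams + n_sires > n_pool)
    stop("haplotype pool has fewer individuals than n_dams + n_sires")
  n_off_gen <- n_dams * offspring_per_dam
  if (n_generations > 0 && offspring_per_dam < 2)
    stop("litter design inconsistent: offspring_per_dam < 2 cannot supply ",
         "n_dams replacement females per generation")
  if (!is.null(expected_total) &&
      n_generations * n_off_gen != expected_total)
    stop(sprintf("litter design produces %d non-founder individuals, not %d",
                 n_generations * n_off_gen, expected_total))
  with_seed(seed, {
    map <- pool$map
    m <- ncol(pool$haplotypes)
    founders <- sample.int(n_pool, n_dams + n_sires)
    # phased haplotypes for everyone, grown generation by generation
    H <- pool$haplotypes[as.vector(rbind(2L * founders - 1L, 2L * founders)), ,
                         drop = FALSE]
    n_total <- n_dams + n_sires + n_generations * n_off_gen
    Hall <- matrix(0L, 2L * n_total, m)
    Hall[seq_len(nrow(H)), ] <- H
    ped <- data.frame(
      id = seq_len(n_dams + n_sires), sire = 0L, dam = 0L,
      sex = c(rep("F", n_dams), rep("M", n_sires)), generation = 0L)
    cur_f <- seq_len(n_dams)
    cur_m <- n_dams + seq_len(n_sires)
    next_id <- n_dams + n_sires + 1L
    for (g in seq_len(n_generations)) {
      dams <- if (length(cur_f) == n_dams) cur_f else sample(cur_f, n_dams)
      sires <- if (length(cur_m) == n_sires) cur_m else sample(cur_m, n_sires)
      dam_of <- rep(dams, each = offspring_per_dam)
      sire_of <- rep(sample(sires, n_dams, replace = TRUE),
                     each = offspring_per_dam)
      g_d <- recombine_gametes(Hall, dam_of, map)
      g_s <- recombine_gametes(Hall, sire_of, map)
      ids <- next_id:(next_id + n_off_gen - 1L)
      Hall[2L * ids - 1L, ] <- g_d
      Hall[2L * ids, ] <- g_s
      sex <- sample(rep(c("F", "M"), length.out = n_off_gen))
      ped <- rbind(ped, data.frame(id = ids, sire = sire_of, dam = dam_of,
                                   sex = sex, generation = g))
      cur_f <- ids[sex == "F"]
      cur_m <- ids[sex == "M"]
      if (g < n_generations &&
          (length(cur_f) < n_dams || length(cur_m) < n_sires))
        stop("litter design inconsistent: not enough replacement parents")
      next_id <- next_id + n_off_gen
    }
    dosage <- Hall[seq(1L, 2L * n_total, by = 2L), , drop = FALSE] +
      Hall[seq(2L, 2L * n_total, by = 2L), , drop = FALSE]
    rownames(dosage) <- sprintf("ID%05d", ped$id)
    colnames(dosage) <- map$loci$id
    # pedigree ids share the genotype row-name convention ("0" = unknown)
    ped$id <- sprintf("ID%05d", ped$id)
    ped$sire <- ifelse(ped$sire == 0, "0", sprintf("ID%05d", ped$sire))
    ped$dam <- ifelse(ped$dam == 0, "0", sprintf("ID%05d", ped$dam))
    rownames(ped) <- NULL
    list(genotypes = new_genotype_matrix(dosage, map),
         pedigree = new_pedigree(ped))
  })
}

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param geno a `genotype_matrix`.
#' @param ids individual row names (or indices) to keep.
#' @param loci locus ids (or indices) to keep.
#' @param recompute_p recompute allele frequencies on the subset (default)
#'   or carry the originals over.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(geno, ids = NULL, loci = NULL,
                             recompute_p = TRUE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  dos <- geno$dosage
  if (!is.null(ids)) dos <- dos[ids, , drop = FALSE]
  keep <- if (is.null(loci)) seq_len(ncol(dos)) else loci
  dos <- dos[, keep, drop = FALSE]
  map <- geno$map
  map$loci <- map$loci[match(colnames(dos), map$loci$id), , drop = FALSE]
  new_genotype_matrix(dos, map,
                      p = if (recompute_p) NULL else unname(geno$p[keep]))
}

#' Extract the marker (SNP) panel of a genotype matrix
#'
#' Drops all QTL-role loci so downstream kernels only ever see markers.
#'
#' @param geno a `genotype_matrix`.
#' @return a `genotype_matrix` restricted to `type == "snp"` loci.
#' @export
marker_matrix <- function(geno) {
  subset_genotypes(geno, loci = which(geno$map$loci$type == "snp"))
}

# ---- trait architecture ----------------------------------------------------

#' Table of target variance partitions per gene-action scenario
#'
#' Returns the additive, dominance and epistatic heritability targets for
#' a scenario (`"AD"`, `"ADE"`, `"PE"`) at broad-sense heritability `H2`
#' (0.4 or 0.8 in the study design; any value in (0,1) is accepted and
#' split in the same proportions).
#'
#' @param scenario gene-action scenario label.
#' @param H2 broad-sense heritability.
#' @return named numeric vector `c(h2_A, h2_D, h2_E)` summing to `H2`.
#' @export
heritability_targets <- function(scenario = c("AD", "ADE", "PE"), H2 = 0.4) {
  scenario <- match.arg(scenario)
  stop_if_not_scalar_prob(H2, "H2", open_lo = TRUE, open_hi = TRUE)
  frac <- switch(scenario,
                 AD  = c(h2_A = 3 / 4, h2_D = 1 / 4, h2_E = 0),
                 ADE = c(h2_A = 2 / 4, h2_D = 1 / 4, h2_E = 1 / 4),
                 PE  = c(h2_A = 0, h2_D = 0, h2_E = 1))
  frac * H2
}

#' Sample a QTL architecture
#'
#' Samples `qtl_per_chrom` trait loci per chromosome (without
#' replacement, among segregating QTL-role loci), nests
#' `epi_qtl_per_chrom` epistatic QTL per chromosome inside that set, and
#' enumerates every unordered pair of epistatic QTL genome-wide.
#'
#' @param map a `genome_map`.
#' @param genotypes `genotype_matrix` used to check segregation.
#' @param scenario `"AD"`, `"ADE"` or `"PE"`.
#' @param qtl_per_chrom QTL per chromosome.
#' @param epi_qtl_per_chrom epistatic QTL per chromosome (subset of QTL).
#' @param seed integer seed.
#' @return object of class `trait_architecture` with QTL column indices,
#'   the epistatic subset, and the pair list (`k < k'` by column order).
#'   Effects are filled in by [draw_qtl_effects()].
#' @export
sample_qtl_architecture <- function(map, genotypes,
                                    scenario = c("AD", "ADE", "PE"),
                                    qtl_per_chrom = 65,
                                    epi_qtl_per_chrom = 5, seed = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (epi_qtl_per_chrom > qtl_per_chrom)
    stop("epi_qtl_per_chrom must not exceed qtl_per_chrom")
  if (!identical(map$loci$id, genotypes$map$loci$id))
    stop("map loci do not match the genotype columns")
  loci <- genotypes$map$loci
  with_seed(seed, {
    qtl_idx <- integer(0)
    epi_idx <- integer(0)
    for (chr in sort(unique(loci$chrom))) {
      cand <- which(loci$chrom == chr & loci$type == "qtl" &
                      !genotypes$monomorphic)
      if (length(cand) < qtl_per_chrom)
        stop(sprintf("chromosome %d has %d segregating QTL loci, need %d",
                     chr, length(cand), qtl_per_chrom))
      q <- sort(sample(cand, qtl_per_chrom))
      qtl_idx <- c(qtl_idx, q)
      if (epi_qtl_per_chrom > 0)
        epi_idx <- c(epi_idx, sort(sample(q, epi_qtl_per_chrom)))
    }
    pairs <- if (length(epi_idx) >= 2) t(utils::combn(sort(epi_idx), 2L))
    else matrix(integer(0), 0, 2)
    colnames(pairs) <- c("k", "k2")
    structure(list(scenario = scenario, qtl_index = qtl_idx,
                   epi_qtl_index = sort(epi_idx), pairs = pairs,
                   a = NULL, delta = NULL, d = NULL, ad_effects = NULL,
                   targets = NULL, sigma2_eps = NULL),
              class = "trait_architecture")
  })
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(sprintf(
    "<trait_architecture> %s: %d QTL, %d epistatic QTL, %d pairs%s\n",
    x$scenario, length(x$qtl_index), length(x$epi_qtl_index), nrow(x$pairs),
    if (is.null(x$targets)) " (effects not drawn)" else
      sprintf("; targets A=%.2f D=%.2f E=%.2f", x$targets["h2_A"],
              x$targets["h2_D"], x$targets["h2_E"])))
  invisible(x)
}

#' Draw QTL effects for an architecture
#'
#' Additive effect magnitudes follow a Gamma(shape, scale) distribution
#' with random sign; the dominance effect is the degree of dominance
#' (standard normal) times the absolute additive effect, `d = delta *
#' |a|`; each epistatic pair effect is normal with the given mean and
#' variance. Components not used by the scenario stay zero (PE: a = d =
#' 0; AD: no pair effects).
#'
#' @param arch a `trait_architecture` with QTL indices assigned.
#' @param shape,scale Gamma parameters of `|a|` (defaults 0.42, 8.282).
#' @param epi_mean,epi_var mean/variance of pair effects (0.02, 0.03).
#' @param seed integer seed.
#' @return the architecture with `a`, `delta`, `d`, `ad_effects` filled.
#' @export
draw_qtl_effects <- function(arch, shape = 0.42, scale = 8.282,
                             epi_mean = 0.02, epi_var = 0.03, seed = NULL) {
  stopifnot(inherits(arch, "trait_architecture"))
  with_seed(seed, {
    nq <- length(arch$qtl_index)
    if (arch$scenario %in% c("AD", "ADE")) {
      mag <- rgamma(nq, shape = shape, scale = scale)
      sgn <- sample(c(-1, 1), nq, replace = TRUE)
      arch$a <- sgn * mag
      arch$delta <- rnorm(nq)
      arch$d <- arch$delta * abs(arch$a)
    } else {
      arch$a <- numeric(nq)
      arch$delta <- numeric(nq)
      arch$d <- numeric(nq)
    }
    arch$ad_effects <- if (arch$scenario %in% c("ADE", "PE"))
      rnorm(nrow(arch$pairs), mean = epi_mean, sd = sqrt(epi_var))
    else numeric(nrow(arch$pairs)) * 0
    if (arch$scenario == "AD") arch$ad_effects <- numeric(nrow(arch$pairs))
    arch
  })
}

# centered additive codes (w - 2p) for the given columns
additive_codes <- function(genotypes, cols) {
  W <- genotypes$dosage[, cols, drop = FALSE]
  sweep(W, 2L, 2 * genotypes$p[cols])
}

# Vitezica dominance codes: dosage 0 -> -2p^2, 1 -> 2pq, 2 -> -2q^2
dominance_codes <- function(genotypes, cols) {
  W <- genotypes$dosage[, cols, drop = FALSE]
  p <- genotypes$p[cols]
  q <- 1 - p
  out <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
  out <- out + t(t(W == 0) * (-2 * p^2))
  out <- out + t(t(W == 1) * (2 * p * q))
  out <- out + t(t(W == 2) * (-2 * q^2))
  out
}

# Per-individual genetic component values implied by an architecture.
# The epistatic component codes pair (k, k') as additive code at k times
# dominance code at k' (A x D, k < k' by column order); chunked over
# pairs to bound memory. `coding = "AxA"` multiplies two additive codes.
genetic_components <- function(genotypes, arch, coding = c("AxD", "AxA"),
                               chunk = 2000L) {
  coding <- match.arg(coding)
  n <- nrow(genotypes$dosage)
  qtl <- arch$qtl_index
  addc <- if (any(arch$a != 0))
    drop(additive_codes(genotypes, qtl) %*% arch$a) else numeric(n)
  domc <- if (any(arch$d != 0))
    drop(dominance_codes(genotypes, qtl) %*% arch$d) else numeric(n)
  epic <- numeric(n)
  if (nrow(arch$pairs) > 0 && any(arch$ad_effects != 0)) {
    ucols <- sort(unique(as.vector(arch$pairs)))
    Wa <- additive_codes(genotypes, ucols)
    Wb <- if (coding == "AxD") dominance_codes(genotypes, ucols) else Wa
    i1 <- match(arch$pairs[, 1], ucols)
    i2 <- match(arch$pairs[, 2], ucols)
    for (s in seq(1L, nrow(arch$pairs), by = chunk)) {
      e <- min(s + chunk - 1L, nrow(arch$pairs))
      blk <- Wa[, i1[s:e], drop = FALSE] * Wb[, i2[s:e], drop = FALSE]
      epic <- epic + drop(blk %*% arch$ad_effects[s:e])
    }
  }
  list(additive = addc, dominance = domc, epistasis = epic)
}

#' Analytic variance-component formulas for an architecture
#'
#' Computes the textbook single-locus decompositions from effects and
#' allele frequencies: `sigma2_a = sum 2 p q alpha^2` with the allele
#' substitution effect `alpha = a + d (q - p)`, `sigma2_d = sum (2 p q
#' d)^2`, and the pairwise additive-by-dominance term `sigma2_ad = 2 sum
#' p_k^2 p_k' q_k' (alpha_k d_k')^2`. These assume Hardy-Weinberg and
#' linkage equilibrium and serve as diagnostics; the rescaling in
#' [scale_to_target_variances()] targets realized component variances
#' instead.
#'
#' @param arch `trait_architecture` with effects drawn.
#' @param genotypes `genotype_matrix` supplying allele frequencies.
#' @return named vector `c(sigma2_a, sigma2_d, sigma2_ad)`.
#' @export
expected_variance_components <- function(arch, genotypes) {
  qtl <- arch$qtl_index
  p <- genotypes$p[qtl]
  q <- 1 - p
  alpha <- arch$a + arch$d * (q - p)
  s_a <- sum(2 * p * q * alpha^2)
  s_d <- sum((2 * p * q * arch$d)^2)
  s_ad <- 0
  if (nrow(arch$pairs) > 0) {
    i1 <- match(arch$pairs[, 1], qtl)
    i2 <- match(arch$pairs[, 2], qtl)
    s_ad <- 2 * sum((p[i1]^2) * p[i2] * q[i2] *
                      (alpha[i1] * arch$d[i2])^2)
  }
  c(sigma2_a = s_a, sigma2_d = s_d, sigma2_ad = s_ad)
}

#' Rescale QTL effects to hit the target variance partition
#'
#' Each effect class is multiplied by one scalar so that the realized
#' variance of the corresponding genetic component, over the individuals
#' in `genotypes`, equals its target share of a unit phenotypic
#' variance. The additive component is linear in `a` (scaling `a` also
#' scales `d = delta |a|`), the dominance component is then linear in
#' `delta`, and the epistatic component is linear in the pair effects,
#' so one closed-form pass per class suffices. The residual variance is
#' set to `1 - H2`.
#'
#' @param arch `trait_architecture` with effects drawn.
#' @param genotypes `genotype_matrix` over the analysis individuals.
#' @param H2 broad-sense heritability target (splits per
#'   [heritability_targets()]).
#' @param coding epistatic pair coding, `"AxD"` (default) or `"AxA"`.
#' @return the architecture with scaled effects, `targets`,
#'   `sigma2_eps`, and the realized component variances in
#'   `realized_var`.
#' @export
scale_to_target_variances <- function(arch, genotypes, H2 = 0.4,
                                      coding = "AxD") {
  stopifnot(inherits(arch, "trait_architecture"))
  tg <- heritability_targets(arch$scenario, H2)
  comp <- genetic_components(genotypes, arch, coding = coding)
  if (tg["h2_A"] > 0) {
    v <- var(comp$additive)
    if (v <= 0) stop("additive target requested but additive effects are zero")
    c_a <- sqrt(tg[["h2_A"]] / v)
    arch$a <- arch$a * c_a
    arch$d <- arch$delta * abs(arch$a)
    comp$additive <- comp$additive * c_a
    comp$dominance <- comp$dominance * c_a   # d = delta * |a| scales with a
  }
  if (tg["h2_D"] > 0) {
    v <- var(comp$dominance)
    if (v <= 0) stop("dominance target requested but dominance effects are zero")
    c_d <- sqrt(tg[["h2_D"]] / v)
    arch$delta <- arch$delta * c_d
    arch$d <- arch$delta * abs(arch$a)
    comp$dominance <- comp$dominance * c_d
  }
  if (tg["h2_E"] > 0) {
    v <- var(comp$epistasis)
    if (v <= 0) stop("epistatic target requested but pair effects are zero")
    c_e <- sqrt(tg[["h2_E"]] / v)
    arch$ad_effects <- arch$ad_effects * c_e
    comp$epistasis <- comp$epistasis * c_e
  }
  arch$targets <- c(tg, H2 = H2)
  arch$sigma2_eps <- 1 - H2
  arch$coding <- coding
  arch$realized_var <- c(sigma2_a = var(comp$additive),
                         sigma2_d = var(comp$dominance),
                         sigma2_e = var(comp$epistasis))
  arch
}

#' Simulate phenotypes from a scaled architecture
#'
#' The phenotype is the sum of the additive, dominance and epistatic
#' genetic components plus a normal residual with variance
#' `arch$sigma2_eps`, giving unit phenotypic variance by construction.
#'
#' @param genotypes `genotype_matrix` covering all QTL columns.
#' @param arch scaled `trait_architecture` (see
#'   [scale_to_target_variances()]).
#' @param seed integer seed for the residual draw.
#' @return object of class `phenotype_set`: `y`, `g_true`, the three
#'   `components`, and `sigma2_eps`.
#' @export
simulate_phenotypes <- function(genotypes, arch, seed = NULL) {
  stopifnot(inherits(arch, "trait_architecture"))
  if (is.null(arch$sigma2_eps))
    stop("architecture not scaled; call scale_to_target_variances() first")
  comp <- genetic_components(genotypes, arch,
                             coding = arch$coding %||% "AxD")
  g <- comp$additive + comp$dominance + comp$epistasis
  eps <- with_seed(seed, rnorm(length(g), 0, sqrt(arch$sigma2_eps)))
  ids <- rownames(genotypes$dosage)
  y <- g + eps
  names(y) <- names(g) <- ids
  structure(list(y = y, g_true = g, components = comp,
                 sigma2_eps = arch$sigma2_eps),
            class = "phenotype_set")
}

#' @export
print.phenotype_set <- function(x, ...) {
  cat(sprintf(
    "<phenotype_set> n=%d; var(y)=%.3f, var(g)=%.3f, sigma2_eps=%.3f\n",
    length(x$y), var(x$y), var(x$g_true), x$sigma2_eps))
  invisible(x)
}
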