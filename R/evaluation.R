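# Experiment drivers: two-fold cross-validated prediction accuracy,
# the full scenario-grid experiment, and replicate summaries.

#' Two-fold cross-validated prediction accuracy
#'
#' Fold 1 trains on MU1 (REML variance components and BLUP on the
#' training phenotypes) and predicts MU2 through the kernel's
#' train-test block, `g_hat_test = sigma2_u K[test, train] P_train
#' y_train`; fold 2 reverses the roles. With several kernels the
#' training-fold variance estimates define the averaged kernel used for
#' prediction. Accuracy is `cor(g_true, g_hat)` on the test individuals
#' when a simulated truth is supplied, `cor(y, g_hat)` otherwise.
#'
#' @param spec a `model_spec` over all individuals (identity Z).
#' @param assignment a `unit_assignment` defining MU1/MU2.
#' @param truth optional `phenotype_set` with the true genetic values.
#' @param reml_opts list of arguments passed on to [reml_estimate()].
#' @return list with `pa` (mean over folds), `pa_fold` (per fold),
#'   `predictions` and `vc` (per-fold variance components).
#' @export
twofold_cv <- function(spec, assignment, truth = NULL, reml_opts = list()) {
  stopifnot(inherits(spec, "model_spec"), is.null(spec$Z),
            inherits(assignment, "unit_assignment"))
  ids <- spec$ids
  folds <- list(list(train = unit_ids(assignment, "MU1"),
                     test = unit_ids(assignment, "MU2")),
                list(train = unit_ids(assignment, "MU2"),
                     test = unit_ids(assignment, "MU1")))
  pa <- numeric(2)
  preds <- vector("list", 2)
  vcs <- vector("list", 2)
  y <- stats::setNames(spec$y, ids)
  for (f in 1:2) {
    tr <- match(folds[[f]]$train, ids)
    te <- match(folds[[f]]$test, ids)
    if (anyNA(tr) || anyNA(te)) stop("assignment ids not in model spec")
    ktrain <- lapply(spec$kernels, function(K) {
      new_kernel_matrix(K$values[tr, tr, drop = FALSE], K$kind, K$params)
    })
    spec_tr <- model_spec(y[tr], ktrain)
    vc <- do.call(reml_estimate, c(list(spec = spec_tr), reml_opts))
    fit <- fit_blup(spec_tr, vc)
    Kbar_full <- average_kernels(spec$kernels, pmax(vc$sigma2, 0))
    Py <- drop(fit$P %*% spec_tr$y)
    ghat <- fit$sigma2_u *
      drop(Kbar_full$values[te, tr, drop = FALSE] %*% Py)
    names(ghat) <- ids[te]
    target <- if (is.null(truth)) y[te] else truth$g_true[ids[te]]
    if (sd(ghat) < 1e-12) {
      warning("constant predictions in fold ", f, "; accuracy undefined")
      pa[f] <- NA_real_
    } else {
      pa[f] <- cor(target, ghat)
    }
    preds[[f]] <- ghat
    vcs[[f]] <- vc
  }
  list(pa = mean(pa), pa_fold = pa, predictions = preds, vc = vcs)
}

#' Default experiment configuration
#'
#' Bundles the simulation constants of the study design: historical
#' population 1000 -> 220 over 100 generations; recent population bred
#' from dams x sires for 5 generations; 65 QTL and 5 epistatic QTL per
#' chromosome; broad-sense heritabilities 0.4 and 0.8; exchange rates
#' 0-50%; Gaussian-kernel bandwidths 0.22, 0.5, 0.9, 1.6. The
#' `"reduced"` profile (default) keeps those population-genetic
#' conditions but shrinks the genome to 10 chromosomes x 200 SNPs and
#' the analysis set to 600 individuals (60 dams) so that a full grid
#' runs in minutes; `"full"` uses the complete 29 x 1885 panel and 2000
#' individuals.
#'
#' @param profile `"reduced"` or `"full"`.
#' @param ... named overrides of any config entry.
#' @return a named list (class `experiment_config`).
#' @export
experiment_config <- function(profile = c("reduced", "full"), ...) {
  profile <- match.arg(profile)
  base <- list(
    gene_action = c("AD", "ADE", "PE"),
    H2 = c(0.4, 0.8),
    rates = seq(0, 0.5, by = 0.1),
    replicates = if (profile == "reduced") 3L else 10L,
    n_chromosomes = if (profile == "reduced") 10L else 29L,
    chrom_length_cM = 100,
    n_snp_per_chrom = if (profile == "reduced") 200L else 1885L,
    qtl_per_chrom = 65L,
    epi_qtl_per_chrom = 5L,
    hist_n0 = 1000L, hist_n_final = 220L, hist_generations = 100L,
    mutation_rate = 2.5e-5,
    n_dams = if (profile == "reduced") 60L else 200L,
    n_sires = 10L,
    recent_generations = 5L,
    offspring_per_dam = 2L,
    gamma_shape = 0.42, gamma_scale = 8.282,
    epi_mean = 0.02, epi_var = 0.03,
    epi_coding = "AxD",
    theta_grid = c(0.22, 0.5, 0.9, 1.6),
    gk_scaling = "mean",
    cluster_nstart = 25L,
    cluster_kernel = "A",
    cd_unit_effect = TRUE,
    reml = list(method = "ai", max_iter = 200, tol = 1e-6),
    profile = profile)
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  structure(modifyList(base, over), class = c("experiment_config", "list"))
}

# Kernel model configurations benchmarked per gene-action scenario:
# always the additive baseline G; plus G+D (AD), G+D+G#D (ADE), or the
# Gaussian kernel at each bandwidth (PE).
build_kernel_sets <- function(markers, gene_action, config) {
  G <- additive_kernel(markers)
  sets <- list(G = list(G))
  if (gene_action == "AD") {
    D <- dominance_kernel(markers)
    sets[["G+D"]] <- list(G, D)
  } else if (gene_action == "ADE") {
    D <- dominance_kernel(markers)
    sets[["G+D"]] <- list(G, D)
    sets[["G+D+GxD"]] <- list(G, D, hadamard_kernel(G, D))
  } else if (gene_action == "PE") {
    for (th in config$theta_grid)
      sets[[sprintf("GK(%.2f)", th)]] <-
        list(gaussian_kernel(markers, th, scaling = config$gk_scaling))
  }
  sets
}

#' Run the full scenario-grid experiment
#'
#' For every gene-action scenario: simulate one historical pool, then
#' per replicate draw a fresh recent population (constant LD across
#' replicates), cluster the analysis individuals into two management
#' units on the pedigree numerator relationship, build the exchange
#' grid S1-S6, and for every heritability level and kernel
#' configuration estimate variance components on the full data (for CD)
#' and run two-fold cross-validation (for prediction accuracy).
#'
#' @param config an [experiment_config()].
#' @param seed master seed; everything else derives from it.
#' @param kernel_sets optional override: named list of kernel-config
#'   names to use (subset of those built for the scenario).
#' @param progress print per-replicate progress.
#' @return a tidy data frame with one row per (gene action, H2,
#'   scenario, kernel configuration, replicate): columns `pa`,
#'   `pa_fold1`, `pa_fold2`, `cd`, `pevd`, `sigma2_u`, `sigma2_e`,
#'   `error` (NA unless the cell failed, in which case the row carries
#'   the message and NA results).
#' @export
run_experiment <- function(config = experiment_config(), seed = 1,
                           kernel_sets = NULL, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list()
  sc_seeds <- derive_seeds(seed, length(config$gene_action))
  for (si in seq_along(config$gene_action)) {
    sc <- config$gene_action[si]
    child <- derive_seeds(sc_seeds[si], 3L + config$replicates)
    map <- genome_map(config$n_chromosomes, config$chrom_length_cM,
                      config$n_snp_per_chrom, config$qtl_per_chrom,
                      seed = child[1])
    pool <- simulate_historical_population(
      map, config$hist_n0, config$hist_n_final, config$hist_generations,
      config$mutation_rate, seed = child[2])
    for (rep in seq_len(config$replicates)) {
      if (progress)
        message(sprintf("[%s] replicate %d/%d", sc, rep, config$replicates))
      rs <- derive_seeds(child[3L + rep], 8L)
      pop <- simulate_recent_population(
        pool, config$n_dams, config$n_sires, config$recent_generations,
        config$offspring_per_dam, seed = rs[1])
      ids <- pop$pedigree$id[pop$pedigree$generation >= 1L]
      geno <- subset_genotypes(pop$genotypes, ids = ids)
      markers <- marker_matrix(geno)
      A <- numerator_relationship(pop$pedigree)
      Asub <- subset_kernel(A, ids)
      base <- cluster_units(Asub, nstart = config$cluster_nstart,
                            seed = rs[2])
      grid <- scenario_grid(base, config$rates, seed = rs[3])
      arch0 <- sample_qtl_architecture(map, geno, sc, config$qtl_per_chrom,
                                       config$epi_qtl_per_chrom,
                                       seed = rs[4])
      arch0 <- draw_qtl_effects(arch0, config$gamma_shape,
                                config$gamma_scale, config$epi_mean,
                                config$epi_var, seed = rs[5])
      ksets <- build_kernel_sets(markers, sc, config)
      if (!is.null(kernel_sets)) ksets <- ksets[intersect(names(ksets),
                                                          kernel_sets)]
      for (hi in seq_along(config$H2)) {
        H2 <- config$H2[hi]
        arch <- scale_to_target_variances(arch0, geno, H2,
                                          coding = config$epi_coding)
        phe <- simulate_phenotypes(geno, arch, seed = rs[5L + hi])
        for (kname in names(ksets)) {
          res <- tryCatch({
            spec_full <- model_spec(phe$y, ksets[[kname]])
            vc_full <- do.call(reml_estimate,
                               c(list(spec = spec_full), config$reml))
            lapply(names(grid), function(sname) {
              # CD model: full data at the full-data variance components,
              # with the management unit as contemporary-group fixed
              # effect (the design under which across-unit comparisons
              # are actually made); intercept-only via cd_unit_effect.
              Xcd <- if (isTRUE(config$cd_unit_effect))
                cbind(`(Intercept)` = 1,
                      MU2 = as.numeric(grid[[sname]]$unit[ids] == "MU2"))
              else NULL
              spec_cd <- model_spec(phe$y, ksets[[kname]], X = Xcd)
              fit <- fit_blup(spec_cd, vc_full)
              PEV <- prediction_error_variance(fit, spec_cd)
              x <- contrast_vector(grid[[sname]])
              cdr <- cd_of_contrast(x, fit$K, PEV, fit$sigma2_u)
              cv <- twofold_cv(spec_full, grid[[sname]], truth = phe,
                               reml_opts = config$reml)
              data.frame(gene_action = sc, H2 = H2, scenario = sname,
                         kernel_config = kname, replicate = rep,
                         pa = cv$pa, pa_fold1 = cv$pa_fold[1],
                         pa_fold2 = cv$pa_fold[2], cd = cdr$cd,
                         pevd = cdr$pevd, sigma2_u = fit$sigma2_u,
                         sigma2_e = fit$sigma2_e,
                         error = NA_character_)
            })
          }, error = function(e) {
            list(data.frame(gene_action = sc, H2 = H2, scenario = NA,
                            kernel_config = kname, replicate = rep,
                            pa = NA_real_, pa_fold1 = NA_real_,
                            pa_fold2 = NA_real_, cd = NA_real_,
                            pevd = NA_real_, sigma2_u = NA_real_,
                            sigma2_e = NA_real_,
                            error = conditionMessage(e)))
          })
          rows <- c(rows, res)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

#' Summarize replicates of a scenario-grid experiment
#'
#' Mean and standard error of prediction accuracy and CD per (gene
#' action, H2, scenario, kernel configuration) cell, with flags marking
#' the grid-wide extreme cells within each gene-action grid (both H2
#' levels pooled).
#'
#' @param table result of [run_experiment()].
#' @return data frame with `pa_mean`, `pa_se`, `cd_mean`, `cd_se`,
#'   `n_reps` and logical flags `pa_min`, `pa_max`, `cd_min`, `cd_max`.
#' @export
summarize_replicates <- function(table) {
  tab <- table[is.na(table$error), , drop = FALSE]
  if (!nrow(tab)) stop("no successful cells to summarize")
  key <- c("gene_action", "H2", "scenario", "kernel_config")
  se <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  agg <- function(col, fn, nm) {
    out <- aggregate(tab[[col]], tab[key], fn)
    names(out)[ncol(out)] <- nm
    out
  }
  s <- Reduce(function(a, b) merge(a, b, by = key), list(
    agg("pa", mean, "pa_mean"), agg("pa", se, "pa_se"),
    agg("cd", mean, "cd_mean"), agg("cd", se, "cd_se"),
    agg("pa", length, "n_reps")))
  s <- s[order(s$gene_action, s$H2, s$kernel_config, s$scenario), ]
  for (flag in c("pa_min", "pa_max", "cd_min", "cd_max")) s[[flag]] <- FALSE
  for (g in unique(s$gene_action)) {
    i <- which(s$gene_action == g)
    s$pa_min[i[which.min(s$pa_mean[i])]] <- TRUE
    s$pa_max[i[which.max(s$pa_mean[i])]] <- TRUE
    s$cd_min[i[which.min(s$cd_mean[i])]] <- TRUE
    s$cd_max[i[which.max(s$cd_mean[i])]] <- TRUE
  }
  rownames(s) <- NULL
  s
}
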