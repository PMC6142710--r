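# Management-unit construction: K-means split on a relationship matrix,
# the exchange-rate scenario grid, contrast vectors, forward validation.

new_unit_assignment <- function(unit, exchange_rate = 0,
                                provenance = list()) {
  stopifnot(all(unit %in% c("MU1", "MU2")), !is.null(names(unit)))
  if (!all(c("MU1", "MU2") %in% unit)) stop("both units must be non-empty")
  structure(list(unit = unit, exchange_rate = exchange_rate,
                 provenance = provenance),
            class = "unit_assignment")
}

#' @export
print.unit_assignment <- function(x, ...) {
  cat(sprintf("<unit_assignment> MU1: %d, MU2: %d; exchange rate %.0f%%\n",
              sum(x$unit == "MU1"), sum(x$unit == "MU2"),
              100 * x$exchange_rate))
  invisible(x)
}

#' Ids belonging to a unit
#' @param assignment a `unit_assignment`.
#' @param unit `"MU1"` or `"MU2"`.
#' @return character vector of ids.
#' @export
unit_ids <- function(assignment, unit) {
  names(assignment$unit)[assignment$unit == unit]
}

#' Split individuals into two management units by K-means
#'
#' Applies K-means (rows of the relationship matrix as feature vectors,
#' `nstart` restarts) so that individuals that are closely related end
#' up in the same unit and between-unit relatedness is minimized. Any
#' relationship kernel works: the pedigree numerator matrix (the default
#' design), G, or a combined G+D matrix. MU1 is the smaller cluster, so
#' that exchange rates up to 50% of MU1 are always feasible.
#'
#' @param relationship a `kernel_matrix`.
#' @param k number of units (2 for the designs supported downstream).
#' @param nstart K-means restarts; best within-inertia solution kept.
#' @param seed integer seed.
#' @return a `unit_assignment` with `exchange_rate = 0` (scenario S1).
#' @export
cluster_units <- function(relationship, k = 2, nstart = 25, seed = NULL) {
  stopifnot(inherits(relationship, "kernel_matrix"))
  M <- relationship$values
  if (nrow(M) < 2 * k) stop("need at least 2k individuals")
  if (max(apply(M, 2, function(col) diff(range(col)))) < 1e-12)
    stop("degenerate relationship matrix: all rows identical")
  km <- with_seed(seed, kmeans(M, centers = k, nstart = nstart))
  lab <- km$cluster
  # MU1 is the smaller cluster, so that exchanging up to 50% of MU1
  # can always be matched by MU2
  minor <- as.integer(names(sort(table(lab)))[1])
  unit <- ifelse(lab == minor, "MU1", "MU2")
  names(unit) <- rownames(M)
  new_unit_assignment(unit, 0,
                      provenance = list(kernel_kind = relationship$kind,
                                        seed = seed, nstart = nstart))
}

#' Exchange individuals between the two units
#'
#' Swaps `round(rate * |MU1|)` uniformly chosen individuals of MU1 with
#' equally many of MU2, preserving unit sizes (the scenario grid S2-S6
#' uses rates 0.1-0.5). `rate = 0` returns the assignment unchanged
#' (S1). `mode = "move"` moves MU1 individuals to MU2 without
#' replacement instead of swapping.
#'
#' @param assignment a `unit_assignment` (typically the S1 base).
#' @param rate exchange fraction in `[0, 0.5]`.
#' @param seed integer seed.
#' @param mode `"swap"` (default) or `"move"`.
#' @return a `unit_assignment` with `exchange_rate = rate`.
#' @export
apply_exchange <- function(assignment, rate, seed = NULL,
                           mode = c("swap", "move")) {
  mode <- match.arg(mode)
  stopifnot(inherits(assignment, "unit_assignment"))
  stop_if_not_scalar_prob(rate, "rate", 0, 0.5)
  if (rate == 0) return(assignment)
  unit <- assignment$unit
  mu1 <- names(unit)[unit == "MU1"]
  mu2 <- names(unit)[unit == "MU2"]
  n_swap <- round(rate * length(mu1))
  if (n_swap > length(mu2))
    stop("exchange rate requests more individuals than MU2 holds")
  with_seed(seed, {
    out1 <- sample(mu1, n_swap)
    if (mode == "swap") {
      out2 <- sample(mu2, n_swap)
      unit[out1] <- "MU2"
      unit[out2] <- "MU1"
    } else {
      unit[out1] <- "MU2"
    }
    new_unit_assignment(unit, rate, provenance = c(
      assignment$provenance, list(exchange_seed = seed, mode = mode)))
  })
}

#' Build the exchange-rate scenario grid S1-S6
#'
#' From one base clustering, applies exchange rates 0, 0.1, ..., 0.5;
#' the exchanged sets are drawn independently per scenario from the S1
#' base (not nested).
#'
#' @param base a `unit_assignment` with rate 0.
#' @param rates exchange rates, default `seq(0, 0.5, by = 0.1)`.
#' @param seed integer master seed (per-scenario seeds derived from it).
#' @return named list `S1`, `S2`, ... of `unit_assignment`s.
#' @export
scenario_grid <- function(base, rates = seq(0, 0.5, by = 0.1), seed = NULL) {
  seeds <- if (is.null(seed)) rep(list(NULL), length(rates))
  else as.list(derive_seeds(seed, length(rates)))
  out <- Map(function(r, s) apply_exchange(base, r, seed = s), rates, seeds)
  names(out) <- paste0("S", seq_along(rates))
  out
}

#' Contrast vector between the two management units
#'
#' Coefficients `1/n_MU1` for MU1 individuals, `-1/n_MU2` for MU2, zero
#' otherwise; the elements sum to zero, so the contrast annihilates the
#' overall mean.
#'
#' @param assignment a `unit_assignment`.
#' @return named numeric vector (class `contrast_vector`).
#' @export
contrast_vector <- function(assignment) {
  stopifnot(inherits(assignment, "unit_assignment"))
  unit <- assignment$unit
  n1 <- sum(unit == "MU1")
  n2 <- sum(unit == "MU2")
  if (n1 == 0 || n2 == 0) stop("both units must be non-empty")
  x <- ifelse(unit == "MU1", 1 / n1, -1 / n2)
  names(x) <- names(unit)
  structure(x, class = "contrast_vector")
}

#' Forward-validation split by generation
#'
#' Training unit MU1 = individuals whose generation is in
#' `train_generations`; MU2 = all remaining individuals (e.g.
#' generations 1-3 vs 4-5 in a five-generation design).
#'
#' @param pedigree a `pedigree` with generation labels.
#' @param train_generations generations assigned to MU1.
#' @return a `unit_assignment`.
#' @export
forward_split <- function(pedigree, train_generations) {
  ped <- as.data.frame(pedigree)
  in_train <- ped$generation %in% train_generations
  if (!any(in_train) || all(in_train))
    stop("forward split leaves one side empty")
  unit <- ifelse(in_train, "MU1", "MU2")
  names(unit) <- as.character(ped$id)
  new_unit_assignment(unit, NA_real_,
                      provenance = list(method = "forward",
                                        train_generations = train_generations))
}
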