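# Mixed linear model machinery: restricted maximum likelihood for one or
# more kernel-structured random effects, BLUP, and prediction error
# variances. Dense algebra throughout; the sample sizes this package
# targets (a few thousand) never require sparse factorizations.

#' Specify a kernel mixed model
#'
#' The model is `y = X b + Z u + e` with `var(u) = sum_k sigma2_k K_k`
#' and `var(e) = sigma2_e I`. `Z = NULL` means the identity (one record
#' per individual, in kernel order); a rectangular `Z` supports
#' individuals without records.
#'
#' @param y numeric phenotype vector (names matched against kernel ids
#'   when both are present).
#' @param kernels a `kernel_matrix` or list of them, all over the same
#'   ids.
#' @param X fixed-effect design matrix; default a column of ones.
#' @param Z random-effect incidence matrix or `NULL` for identity.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(y, kernels, X = NULL, Z = NULL) {
  if (inherits(kernels, "kernel_matrix")) kernels <- list(kernels)
  stopifnot(length(kernels) >= 1,
            all(vapply(kernels, inherits, TRUE, "kernel_matrix")))
  ids <- kernel_ids(kernels[[1L]])
  for (K in kernels[-1L])
    if (!identical(kernel_ids(K), ids))
      stop("kernels index different individuals")
  n_u <- nrow(kernels[[1L]]$values)
  if (is.null(Z)) {
    if (length(y) != n_u) stop("length(y) must match kernel dimension when Z is identity")
    if (!is.null(names(y)) && !is.null(ids) && !identical(names(y), ids))
      y <- y[ids]
  } else {
    stopifnot(is.matrix(Z), ncol(Z) == n_u, nrow(Z) == length(y))
  }
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  stopifnot(nrow(X) == n)
  if (qr(X)$rank < ncol(X)) stop("X is rank deficient")
  structure(list(y = as.numeric(y), X = X, Z = Z, kernels = kernels,
                 ids = ids), class = "model_spec")
}

# ZKZ' for each kernel (identity Z short-circuited)
spec_vcov_parts <- function(spec) {
  parts <- lapply(spec$kernels, function(K) {
    if (is.null(spec$Z)) K$values else spec$Z %*% K$values %*% t(spec$Z)
  })
  c(parts, list(diag(1, length(spec$y))))
}

# restricted log-likelihood pieces for given variances
reml_loglik_at <- function(spec, parts, theta) {
  n <- length(spec$y)
  V <- Reduce(`+`, Map(`*`, parts, theta))
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(NULL)
  Vinv <- chol2inv(cV)
  VinvX <- Vinv %*% spec$X
  XtVinvX <- crossprod(spec$X, VinvX)
  cX <- chol(symmetrize(XtVinvX))
  P <- Vinv - VinvX %*% chol2inv(cX) %*% t(VinvX)
  P <- symmetrize(P)
  Py <- drop(P %*% spec$y)
  ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cX))) +
                  sum(spec$y * Py))
  list(V = V, Vinv = Vinv, P = P, Py = Py, loglik = ll,
       XtVinvX = XtVinvX, VinvX = VinvX)
}

#' Restricted log-likelihood at fixed variance components
#'
#' Mostly useful for grid-search cross-checks of [reml_estimate()].
#'
#' @param spec a `model_spec`.
#' @param sigma2 kernel variances (one per kernel).
#' @param sigma2_e residual variance.
#' @return the restricted log-likelihood (or `-Inf` if V is singular).
#' @export
reml_loglik <- function(spec, sigma2, sigma2_e) {
  st <- reml_loglik_at(spec, spec_vcov_parts(spec), c(sigma2, sigma2_e))
  if (is.null(st)) -Inf else st$loglik
}

#' Estimate variance components by REML
#'
#' Average-information (AI) REML with EM fallback: when the AI update
#' proposes variances below the floor or the AI matrix is singular, an
#' EM step is taken instead (EM steps never leave the parameter space
#' and monotonically increase the restricted likelihood). `method =
#' "em"` forces pure EM throughout.
#'
#' @param spec a `model_spec`.
#' @param method `"ai"` (default) or `"em"`.
#' @param max_iter iteration cap (default 200).
#' @param tol relative-change convergence tolerance (default 1e-6).
#' @param init optional starting values `c(sigma2_1, ..., sigma2_e)`.
#' @return object of class `variance_components`: `sigma2` (one per
#'   kernel), `sigma2_e`, `loglik`, `converged`, `iterations`, and the
#'   per-iteration `history`.
#' @export
reml_estimate <- function(spec, method = c("ai", "em"), max_iter = 200,
                          tol = 1e-6, init = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "model_spec"))
  parts <- spec_vcov_parts(spec)
  r <- length(parts)                      # kernels + residual
  n <- length(spec$y)
  vy <- var(spec$y)
  floor_v <- 1e-8 * vy
  theta <- if (is.null(init)) rep(vy / r, r) else {
    stopifnot(length(init) == r)
    pmax(init, floor_v)
  }
  history <- matrix(NA_real_, 0, r + 1)
  converged <- FALSE
  st <- reml_loglik_at(spec, parts, theta)
  if (is.null(st)) stop("initial V is singular")
  for (it in seq_len(max_iter)) {
    Py <- st$Py
    u_list <- lapply(parts, function(Kp) drop(Kp %*% Py))
    q <- vapply(u_list, function(u) sum(Py * u), 0)       # y'P K P y
    trPK <- vapply(parts, function(Kp) sum(st$P * Kp), 0) # tr(P K)
    score <- -0.5 * (trPK - q)
    theta_new <- NULL
    if (method == "ai") {
      w_list <- lapply(u_list, function(u) drop(st$P %*% u))
      AI <- matrix(0, r, r)
      for (i in seq_len(r)) for (j in i:r)
        AI[i, j] <- AI[j, i] <- 0.5 * sum(u_list[[i]] * w_list[[j]])
      delta <- tryCatch(solve(AI, score), error = function(e) NULL)
      if (!is.null(delta) && all(is.finite(delta))) {
        cand <- theta + delta
        if (all(cand > floor_v)) {
          theta_new <- cand
        } else {
          # scale the AI step so boundary-bound components approach the
          # floor geometrically instead of overshooting into negatives
          neg <- cand <= floor_v
          s <- min(0.7 * (theta[neg] - floor_v) / (theta[neg] - cand[neg]))
          if (is.finite(s) && s > 1e-4)
            theta_new <- pmax(theta + s * delta, floor_v)
        }
      }
    }
    if (is.null(theta_new)) {
      # EM-REML update: sigma2 <- sigma2 + sigma2^2 (y'PKPy - tr(PK)) / n
      theta_new <- pmax(theta + theta^2 * (q - trPK) / n, floor_v)
    }
    st_new <- reml_loglik_at(spec, parts, theta_new)
    if (is.null(st_new)) {           # singular proposal: damped EM
      theta_new <- pmax(theta + 0.1 * theta^2 * (q - trPK) / n, floor_v)
      st_new <- reml_loglik_at(spec, parts, theta_new)
      if (is.null(st_new)) stop("V became singular during REML")
    }
    history <- rbind(history, c(theta_new, st_new$loglik))
    rel <- max(abs(theta_new - theta) / pmax(abs(theta), floor_v))
    dll <- abs(st_new$loglik - st$loglik)
    theta <- theta_new
    st <- st_new
    if (rel < tol || (method == "ai" && dll < 1e-8 * (1 + abs(st$loglik)))) {
      converged <- TRUE
      break
    }
  }
  kn <- vapply(spec$kernels, `[[`, "", "kind")
  colnames(history) <- c(kn, "residual", "loglik")
  structure(list(sigma2 = stats::setNames(theta[-r], kn),
                 sigma2_e = theta[r], loglik = st$loglik,
                 converged = converged, iterations = nrow(history),
                 history = history, method = method),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components>\n")
  comps <- c(x$sigma2, residual = x$sigma2_e)
  for (nm in names(comps)) cat(sprintf("  %-10s %.5f\n", nm, comps[[nm]]))
  cat(sprintf("  logLik %.4f after %d iterations (%s)%s\n", x$loglik,
              x$iterations, x$method,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Heritability implied by a variance-component fit
#' @param vc a `variance_components`.
#' @return total kernel variance over total variance.
#' @export
heritability <- function(vc) {
  sum(vc$sigma2) / (sum(vc$sigma2) + vc$sigma2_e)
}

#' Solve the BLUP equations at given variance components
#'
#' Computes GLS fixed effects `b = (X'V^-1 X)^- X'V^-1 y` and the BLUP
#' `u = sigma2_u K Z' P y`. With several kernels, the model is collapsed
#' to the variance-weighted average kernel (kernel averaging) with
#' `sigma2_u` the summed kernel variance; V is unchanged by this
#' collapse.
#'
#' @param spec a `model_spec`.
#' @param vc a `variance_components` for `spec` (or any object with
#'   `sigma2` and `sigma2_e`).
#' @return object of class `blup_fit`: `b_hat`, `u_hat`, the collapsed
#'   kernel `K`, `sigma2_u`, `sigma2_e`, and the projection pieces `P`,
#'   `Vinv` needed for prediction error variances.
#' @export
fit_blup <- function(spec, vc) {
  stopifnot(inherits(spec, "model_spec"))
  Kbar <- average_kernels(spec$kernels, pmax(vc$sigma2, 0))
  sigma2_u <- sum(vc$sigma2)
  parts <- spec_vcov_parts(spec)
  st <- reml_loglik_at(spec, parts, c(vc$sigma2, vc$sigma2_e))
  if (is.null(st)) stop("V is singular at the supplied variances")
  b_hat <- drop(chol2inv(chol(symmetrize(st$XtVinvX))) %*%
                  crossprod(spec$X, st$Vinv %*% spec$y))
  ZtPy <- if (is.null(spec$Z)) st$Py else drop(crossprod(spec$Z, st$Py))
  u_hat <- sigma2_u * drop(Kbar$values %*% ZtPy)
  names(u_hat) <- spec$ids
  structure(list(b_hat = b_hat, u_hat = u_hat, K = Kbar,
                 sigma2_u = sigma2_u, sigma2_e = vc$sigma2_e,
                 P = st$P, Vinv = st$Vinv, loglik = st$loglik),
            class = "blup_fit")
}

#' @export
print.blup_fit <- function(x, ...) {
  cat(sprintf("<blup_fit> %d genetic values; sigma2_u=%.4f sigma2_e=%.4f\n",
              length(x$u_hat), x$sigma2_u, x$sigma2_e))
  invisible(x)
}

#' Prediction error variance matrix of the genetic values
#'
#' `PEV = var(u_hat - u) = K sigma2_u - sigma2_u K Z' P Z K sigma2_u`,
#' the posterior variance of `u` given the data; equal to sigma2_e times
#' the random-effect block of the inverted mixed-model-equation
#' coefficient matrix.
#'
#' @param fit a `blup_fit`.
#' @param spec the `model_spec` the fit came from.
#' @return symmetric PEV matrix (individuals x individuals).
#' @export
prediction_error_variance <- function(fit, spec) {
  stopifnot(inherits(fit, "blup_fit"))
  K <- fit$K$values
  PZ <- if (is.null(spec$Z)) fit$P else crossprod(spec$Z, fit$P %*% spec$Z)
  PZK <- PZ %*% K
  PEV <- fit$sigma2_u * K - fit$sigma2_u^2 * crossprod(K, PZK)
  symmetrize(PEV)
}

#' Variance of the predictor, `var(u_hat) = K sigma2_u - PEV`
#' @inheritParams prediction_error_variance
#' @return symmetric matrix.
#' @export
predictor_variance <- function(fit, spec) {
  fit$sigma2_u * fit$K$values - prediction_error_variance(fit, spec)
}

# Henderson's mixed-model equations, used as an independent algebraic
# route in tests: coefficient matrix
#   [X'X      X'Z        ]
#   [Z'X  Z'Z + K^-1 lambda]
# with lambda = sigma2_e / sigma2_u; returns b, u and sigma2_e * C^-1.
solve_mme <- function(y, X, Z, K, sigma2_u, sigma2_e) {
  if (is.null(Z)) Z <- diag(1, nrow(K))
  lambda <- sigma2_e / sigma2_u
  Kinv <- chol2inv(chol(K + diag(1e-10, nrow(K))))
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * Kinv))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  Cinv <- solve(C)
  sol <- drop(Cinv %*% rhs)
  p <- ncol(X)
  list(b = sol[seq_len(p)], u = sol[-seq_len(p)],
       pev = sigma2_e * Cinv[-seq_len(p), -seq_len(p), drop = FALSE])
}
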