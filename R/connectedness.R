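# Connectedness statistics: the coefficient of determination (CD) of a
# management-unit contrast, and the prediction error variance of the
# difference (PEVD).

#' Prediction error variance of a contrast (PEVD)
#'
#' The quadratic form `x' PEV x`: the error variance of the predicted
#' difference in genetic values defined by the contrast.
#'
#' @param x a `contrast_vector` (or numeric vector).
#' @param PEV prediction error variance matrix (see
#'   [prediction_error_variance()]).
#' @return non-negative scalar.
#' @export
pevd_of_contrast <- function(x, PEV) {
  x <- align_contrast(x, PEV)
  drop(crossprod(x, PEV %*% x))
}

#' Coefficient of determination (CD) of a unit contrast
#'
#' `CD = 1 - (x' PEV x) / (x' K x * sigma2_u)`: one minus the error
#' variance of the predicted unit difference relative to its prior
#' genetic variance. CD is the squared correlation between the
#' predicted and the true difference in genetic values; values near 1
#' indicate strong connectedness (across-unit comparisons are
#' reliable), values near 0 indicate none. CD is invariant to flipping
#' the contrast's sign. Note the denominator also penalizes designs
#' whose units are so related that the contrast carries little genetic
#' variance.
#'
#' @param x a `contrast_vector`.
#' @param K the kernel defining `var(u) = K sigma2_u` (a
#'   `kernel_matrix` or matrix).
#' @param PEV prediction error variance matrix of `u`.
#' @param sigma2_u genetic variance attached to `K` (for averaged
#'   kernels, the summed component variance).
#' @return object of class `connectedness_result` with fields `cd`,
#'   `pevd`, `denominator`.
#' @export
cd_of_contrast <- function(x, K, PEV, sigma2_u) {
  Kv <- if (inherits(K, "kernel_matrix")) K$values else K
  x <- align_contrast(x, Kv)
  xKx <- drop(crossprod(x, Kv %*% x))
  if (xKx <= 0) stop("contrast has no genetic variance (x'Kx <= 0)")
  pevd <- drop(crossprod(x, PEV %*% x))
  denom <- xKx * sigma2_u
  structure(list(cd = 1 - pevd / denom, pevd = pevd, denominator = denom),
            class = "connectedness_result")
}

#' @export
print.connectedness_result <- function(x, ...) {
  cat(sprintf("<connectedness> CD = %.4f (PEVD = %.5g / x'Kx sigma2_u = %.5g)\n",
              x$cd, x$pevd, x$denominator))
  invisible(x)
}

# match contrast names against matrix dimnames when both are present
align_contrast <- function(x, M) {
  x <- unclass(x)
  if (!is.null(names(x)) && !is.null(rownames(M))) {
    if (!setequal(names(x), rownames(M)))
      stop("contrast and matrix index different individuals")
    x <- x[rownames(M)]
  } else if (length(x) != nrow(M)) {
    stop("contrast length does not match matrix dimension")
  }
  x
}
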