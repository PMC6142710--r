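# Internal helpers shared across modules.

# Derive reproducible child seeds from a master seed without disturbing
# the caller's RNG stream more than once. Child seeds stay below 2^31.
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  set.seed(as.integer(master_seed))
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Symmetric part; guards accumulated floating-point asymmetry.
symmetrize <- function(M) (M + t(M)) / 2

stop_if_not_scalar_prob <- function(x, name, lo = 0, hi = 1,
                                    open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lo) x > lo else x >= lo) &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok) stop(sprintf("`%s` must be a single value in %s%g, %g%s",
                        name, if (open_lo) "(" else "[", lo, hi,
                        if (open_hi) ")" else "]"), call. = FALSE)
  invisible(x)
}

# Tiny rolling polynomial hash of a character scalar; used only to
# fingerprint configurations in run manifests.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
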