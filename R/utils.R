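# Internal numeric helpers shared across modules.

#' Log-density of a multivariate normal
#'
#' @param x numeric matrix, one row per point.
#' @param mean numeric vector.
#' @param sigma symmetric positive-definite covariance matrix.
#' @return numeric vector of log-densities.
#' @noRd
dmvnorm_log <- function(x, mean, sigma) {
  x <- as.matrix(x)
  k <- length(mean)
  stopifnot(ncol(x) == k, all(dim(sigma) == k))
  ch <- chol(sigma)
  # solve against the Cholesky factor rather than inverting sigma
  centered <- sweep(x, 2L, mean)
  z <- backsolve(ch, t(centered), transpose = TRUE)
  quad <- colSums(z^2)
  logdet <- 2 * sum(log(diag(ch)))
  -0.5 * (k * log(2 * pi) + logdet + quad)
}

#' Check a matrix is symmetric positive-definite
#' @noRd
is_spd <- function(m, tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) return(FALSE)
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) return(FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol * max(abs(ev)))
}

#' Derive a child RNG seed from a base seed and a stream label
#'
#' Keeps independent stages of a pipeline reproducible under one user-facing
#' seed without sharing identical streams. Result is kept within 32-bit range.
#' @noRd
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

#' Run code with a temporary RNG seed, restoring global RNG state after
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
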