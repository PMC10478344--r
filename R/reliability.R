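## Minimum-residual single-factor loadings on a correlation matrix: minimize
## the squared off-diagonal residuals of R - ll'. Used when ML fails.
minres_loadings <- function(R) {
  p <- ncol(R)
  off <- upper.tri(R)
  obj <- function(l) sum((R[off] - tcrossprod(l)[off])^2)
  ev <- eigen(R, symmetric = TRUE)
  start <- ev$vectors[, 1L] * sqrt(max(ev$values[1L], 1e-6))
  start <- pmin(pmax(start, -0.99), 0.99)
  fit <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  fit$par
}

#' McDonald's omega-total for one scale
#'
#' Fits a single-factor model to the scale's item correlation matrix by
#' maximum likelihood ([stats::factanal()]), falling back to a
#' minimum-residual fit if ML does not converge, and computes
#' \deqn{\omega_t = (\sum \lambda)^2 / ((\sum \lambda)^2 + \sum \psi)}
#' from the standardized loadings \eqn{\lambda} and uniquenesses
#' \eqn{\psi = 1 - \lambda^2}. Working on the correlation matrix makes the
#' coefficient invariant to item rescaling and reordering.
#'
#' @param items Numeric matrix or data frame of item responses for a single
#'   scale (participants x items, at least 3 items). Correlations use
#'   pairwise-complete observations; at least 50 complete rows are required.
#' @param scale Scale label carried into the result.
#' @return A `reliability_result`: list with `scale`, `omega_t`, `loadings`,
#'   `uniquenesses`, `n_used`, `estimator` (`"ml"` or `"minres"`).
#' @examples
#' set.seed(1)
#' f <- rnorm(500)
#' items <- sapply(1:4, function(i) 0.7 * f + sqrt(1 - 0.49) * rnorm(500))
#' omega_total(items)$omega_t # about (4 * .7)^2 / ((4 * .7)^2 + 4 * .51) = .79
#' @export
omega_total <- function(items, scale = "scale") {
  m <- as.matrix(items)
  storage.mode(m) <- "double"
  if (ncol(m) < 3L) stop("omega_t needs at least 3 items", call. = FALSE)
  n_used <- sum(stats::complete.cases(m))
  if (n_used < 50L) stop("omega_t needs at least 50 complete rows", call. = FALSE)
  R <- stats::cor(m, use = "pairwise.complete.obs")
  if (anyNA(R)) stop("item correlation matrix has undefined entries", call. = FALSE)

  estimator <- "ml"
  lambda <- tryCatch({
    fa <- stats::factanal(covmat = R, factors = 1L, n.obs = n_used)
    as.numeric(fa$loadings[, 1L])
  }, error = function(e) {
    estimator <<- "minres"
    minres_loadings(R)
  })
  if (sum(lambda) < 0) lambda <- -lambda
  psi <- pmax(1 - lambda^2, 0)
  omega <- sum(lambda)^2 / (sum(lambda)^2 + sum(psi))
  names(lambda) <- names(psi) <- colnames(m)
  structure(list(scale = scale, omega_t = omega, loadings = lambda,
                 uniquenesses = psi, n_used = n_used, estimator = estimator),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("<reliability_result> %s: omega_t = %.3f (%s, n = %d)\n",
              x$scale, x$omega_t, x$estimator, x$n_used))
  invisible(x)
}
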