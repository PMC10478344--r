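#' Order predictions implied by circumplex structure
#'
#' For `k` equally spaced circumplex variables, correlations are predicted to
#' decrease as the circular distance between variables grows. Every unordered
#' pair of off-diagonal cells whose circular distance classes differ yields
#' one order prediction: the cell in the closer class should hold the larger
#' correlation. For `k = 8` the 28 cells fall into classes of 8, 8, 8 and 4
#' cells (distances 45, 90, 135, 180 degrees), giving 288 predictions.
#'
#' @param k Number of equally spaced variables (>= 3).
#' @return A data frame with one row per prediction: positional indices of
#'   the closer cell (`ci`, `cj`, distance class `c_class`) and the farther
#'   cell (`fi`, `fj`, `f_class`). Classes are in steps around the circle.
#' @examples
#' nrow(randall_predictions(8)) # 288
#' @export
randall_predictions <- function(k) {
  k <- as.integer(k)
  if (k < 3L) stop("k must be at least 3", call. = FALSE)
  pairs <- utils::combn(k, 2L)
  i <- pairs[1L, ]; j <- pairs[2L, ]
  dist_class <- pmin(j - i, k - (j - i))  # steps around the circle
  n_cells <- length(i)
  cp <- utils::combn(n_cells, 2L)
  a <- cp[1L, ]; b <- cp[2L, ]
  keep <- dist_class[a] != dist_class[b]
  a <- a[keep]; b <- b[keep]
  # orient so the first cell is the closer (smaller-distance) one
  swap <- dist_class[a] > dist_class[b]
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  data.frame(ci = i[a], cj = j[a], c_class = dist_class[a],
             fi = i[b], fj = j[b], f_class = dist_class[b])
}

## CI for one variable ordering `ord` (positions -> variable indices).
## preds holds cell index pairs; tol is the tie tolerance.
randall_ci_for_order <- function(R, preds, ord, tol) {
  closer <- R[cbind(ord[preds$ci], ord[preds$cj])]
  farther <- R[cbind(ord[preds$fi], ord[preds$fj])]
  d <- closer - farther
  met <- sum(d > tol)
  violated <- sum(d < -tol)
  c(met = met, violated = violated,
    ci = (met - violated) / nrow(preds))
}

## All orderings of 1..k distinct up to rotation and reflection:
## fix variable 1 in position 1 and require the second position to hold a
## smaller index than the last (kills reflections). k!/(2k) orders.
distinct_circular_orders <- function(k) {
  perms <- function(v) {
    if (length(v) <= 1L) return(matrix(v, nrow = max(1L, length(v))))
    out <- vector("list", length(v))
    for (i in seq_along(v)) out[[i]] <- cbind(v[i], perms(v[-i]))
    do.call(rbind, out)
  }
  p <- perms(seq(2L, k))
  p <- p[p[, 1L] < p[, k - 1L], , drop = FALSE]
  cbind(1L, p)
}

#' Randomization test of hypothesized circumplex order relations
#'
#' Counts how many of the order predictions from [randall_predictions()] a
#' correlation matrix meets, computes the correspondence index
#' \eqn{CI = (met - violated)/total} (ties count in the denominator only),
#' and obtains a p-value by relabeling the variable order: the proportion of
#' orderings (including the observed one) whose correspondence index is at
#' least the observed one. Exhaustive mode enumerates the \eqn{k!/(2k)}
#' orderings distinct up to rotation and reflection (2520 for `k = 8`), which
#' yields the same p-value as enumerating all \eqn{k!} permutations because
#' the index is invariant under rotation and reflection.
#'
#' @param R Symmetric correlation matrix with unit diagonal, variables in
#'   circumplex order (e.g. the geometry's octant order).
#' @param mode `"exhaustive"` (default for `k <= 8`) or `"sampled"`.
#' @param n_samples Number of random relabelings in sampled mode.
#' @param seed Optional RNG seed for sampled mode.
#' @param tie_tol Absolute tolerance under which two correlations tie.
#' @return A `randall_result`: list with `n_predictions`, `n_met`,
#'   `n_violated`, `n_tied`, `correspondence_index`, `p_value`,
#'   `n_relabelings`, `exhaustive`.
#' @examples
#' geom <- octant_geometry()
#' R <- circumplex_pattern_matrix(c(0.6, 0.4, 0.2, 0.1))
#' randall_test(R)$p_value # 1/2520, prints as .0004
#' @export
randall_test <- function(R, mode = c("exhaustive", "sampled"),
                         n_samples = 2000, seed = NULL, tie_tol = 1e-10) {
  mode <- match.arg(mode)
  R <- as.matrix(R)
  k <- nrow(R)
  if (ncol(R) != k || k < 3L) stop("R must be a square matrix, k >= 3", call. = FALSE)
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric", call. = FALSE)
  if (max(abs(diag(R) - 1)) > 1e-8) stop("R must have a unit diagonal", call. = FALSE)
  preds <- randall_predictions(k)
  obs <- randall_ci_for_order(R, preds, seq_len(k), tie_tol)
  n_pred <- nrow(preds)

  if (mode == "exhaustive") {
    orders <- distinct_circular_orders(k)
    cis <- apply(orders, 1L, function(o) randall_ci_for_order(R, preds, o, tie_tol)[["ci"]])
    p <- mean(cis >= obs[["ci"]] - 1e-12)
    n_rel <- nrow(orders)
  } else {
    if (!is.null(seed)) {
      old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
      set.seed(seed)
    }
    cis <- replicate(n_samples, {
      o <- sample.int(k)
      randall_ci_for_order(R, preds, o, tie_tol)[["ci"]]
    })
    # observed ordering is itself one relabeling
    p <- (1 + sum(cis >= obs[["ci"]] - 1e-12)) / (n_samples + 1)
    n_rel <- n_samples + 1L
  }

  structure(list(n_predictions = n_pred,
                 n_met = unname(obs[["met"]]),
                 n_violated = unname(obs[["violated"]]),
                 n_tied = n_pred - unname(obs[["met"]]) - unname(obs[["violated"]]),
                 correspondence_index = unname(obs[["ci"]]),
                 p_value = p,
                 n_relabelings = n_rel,
                 exhaustive = mode == "exhaustive"),
            class = "randall_result")
}

#' @export
print.randall_result <- function(x, ...) {
  cat("<randall_result> ", x$n_met, " of ", x$n_predictions, " predictions met; CI = ",
      sprintf("%.2f", x$correspondence_index), ", p = ", format(round(x$p_value, 4)),
      if (x$exhaustive) " (exhaustive)" else " (sampled)", "\n", sep = "")
  invisible(x)
}

#' Build a circulant circumplex correlation matrix by distance class
#'
#' Convenience constructor for test matrices: cell values depend only on the
#' circular distance class between variables.
#'
#' @param class_values Numeric vector of length `floor(k/2)`: the correlation
#'   for variables 1, 2, ... steps apart on the circle.
#' @param k Number of variables (default 8).
#' @return A `k x k` correlation matrix with unit diagonal.
#' @export
circumplex_pattern_matrix <- function(class_values, k = 8L) {
  k <- as.integer(k)
  if (length(class_values) != k %/% 2L) {
    stop("class_values must have floor(k/2) entries", call. = FALSE)
  }
  R <- diag(k)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      d <- min(j - i, k - (j - i))
      R[i, j] <- R[j, i] <- class_values[d]
    }
  }
  R
}
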