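#' Bootstrap configuration
#'
#' @param n_boot Number of case resamples (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional RNG seed; identical seed and config give identical
#'   intervals.
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(n_boot = 2000, level = 0.95, seed = NULL) {
  if (n_boot < 100) stop("n_boot must be at least 100", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  structure(list(n_boot = as.integer(n_boot), level = level, seed = seed),
            class = "bootstrap_config")
}

## One bootstrap pass: profiles for each column of `scales_mat` (n x m) against
## `octants` (n x 8) on the rows in `idx`. Returns m x 8 matrix or NULL if any
## correlation is degenerate/undefined in this resample.
resample_profiles <- function(scales_mat, octants, idx) {
  r <- suppressWarnings(stats::cor(scales_mat[idx, , drop = FALSE],
                                   octants[idx, , drop = FALSE],
                                   use = "pairwise.complete.obs"))
  if (anyNA(r)) NULL else r
}

#' Percentile bootstrap confidence intervals for SSM parameters
#'
#' Resamples participants (rows) with replacement, jointly for the scale and
#' the octant scores, refits the SSM per resample, and forms percentile
#' intervals for elevation, the vector components, amplitude, and angular
#' displacement. Angle intervals are computed on the circle: each bootstrap
#' angle is recentered on the point estimate into `(-180, 180]`, percentiles
#' are taken on the recentered deviations, and the point estimate is added
#' back, which avoids wrap-around artifacts near 0/360 degrees. Resamples in
#' which any correlation is undefined (a zero-variance column) are dropped
#' and counted.
#'
#' @param scale_scores Numeric vector of scale scores.
#' @param octant_scores Matrix/data frame of octant scores (columns in
#'   geometry order; reordered by name if needed).
#' @param geometry An [octant_geometry()].
#' @param config A [bootstrap_config()].
#' @param indices Optional integer matrix (`n_boot` rows, `n` columns) of
#'   prebuilt resample indices, for diagnostics and degenerate-resampler
#'   checks; overrides random resampling.
#' @param scale,surface Labels carried into the result.
#' @return An `ssm_boot`: list with `point` ([ssm_fit()] result), `ci`
#'   (tibble of parameter, lower, upper), `boot` (matrix of resampled
#'   parameters), `B`, `B_effective`, `level`.
#' @export
bootstrap_ssm <- function(scale_scores, octant_scores, geometry = octant_geometry(),
                          config = bootstrap_config(), indices = NULL,
                          scale = "scale", surface = "surface") {
  octants <- as.matrix(octant_scores)
  if (!is.null(colnames(octants)) && all(geometry$codes %in% colnames(octants))) {
    octants <- octants[, geometry$codes, drop = FALSE]
  }
  n <- length(scale_scores)
  if (n != nrow(octants)) stop("scale and octant tables must align", call. = FALSE)
  if (n < 20L) stop("refusing to bootstrap fewer than 20 participants", call. = FALSE)

  point <- ssm_fit(correlation_profile(scale_scores, octants, geometry,
                                       scale = scale, surface = surface), geometry)
  ang <- deg2rad(geometry$angles)
  cos_t <- cos(ang); sin_t <- sin(ang)
  s_mat <- matrix(scale_scores, ncol = 1L)

  B <- config$n_boot
  if (!is.null(indices)) {
    B <- nrow(indices)
  } else if (!is.null(config$seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
    set.seed(config$seed)
  }

  boot <- matrix(NA_real_, B, 6L,
                 dimnames = list(NULL, c("e", "x", "y", "a", "theta", "r2")))
  kept <- logical(B)
  for (b in seq_len(B)) {
    idx <- if (is.null(indices)) sample.int(n, n, replace = TRUE) else indices[b, ]
    r <- resample_profiles(s_mat, octants, idx)
    if (is.null(r)) next
    boot[b, ] <- ssm_fit_core(drop(r), cos_t, sin_t)
    kept[b] <- TRUE
  }
  boot <- boot[kept, , drop = FALSE]
  B_eff <- nrow(boot)
  if (B_eff < 0.9 * B) {
    warning(sprintf("only %d of %d bootstrap resamples usable", B_eff, B), call. = FALSE)
  }
  if (B_eff < 1L) stop("no usable bootstrap resamples", call. = FALSE)

  probs <- c((1 - config$level) / 2, 1 - (1 - config$level) / 2)
  qs <- apply(boot[, c("e", "x", "y", "a"), drop = FALSE], 2L, stats::quantile,
              probs = probs, names = FALSE)
  if (!is.na(point$theta)) {
    offs <- wrap_180(boot[, "theta"] - point$theta)
    tq <- stats::quantile(offs, probs = probs, names = FALSE, na.rm = TRUE)
    theta_ci <- wrap_360(point$theta + tq)
  } else {
    theta_ci <- c(NA_real_, NA_real_)
  }
  ci <- tibble::tibble(
    parameter = c("e", "x", "y", "a", "theta"),
    estimate = c(point$e, point$x, point$y, point$a, point$theta),
    boot_mean = unname(c(colMeans(boot[, c("e", "x", "y", "a"), drop = FALSE]),
                  if (is.na(point$theta)) NA_real_ else
                    wrap_360(point$theta + mean(wrap_180(boot[, "theta"] - point$theta))))),
    lower = unname(c(qs[1L, ], theta_ci[1L])),
    upper = unname(c(qs[2L, ], theta_ci[2L])))

  structure(list(point = point, ci = ci, boot = boot,
                 B = B, B_effective = B_eff, level = config$level,
                 scale = scale, surface = surface),
            class = "ssm_boot")
}

#' @export
print.ssm_boot <- function(x, ...) {
  cat("<ssm_boot> ", x$scale, " on ", x$surface, " (B = ", x$B_effective, "/", x$B,
      ", level = ", x$level, ")\n", sep = "")
  print(as.data.frame(lapply(x$ci, function(v) if (is.numeric(v)) round(v, 3) else v)))
  invisible(x)
}

#' Paired bootstrap contrast of two scales' SSM profiles
#'
#' Refits both scales' profiles on the same participant resamples and forms
#' percentile intervals for the parameter differences (scale A minus
#' scale B). Angular differences are taken on the circle and signed into
#' `(-180, 180]`; their interval is recentered on the point difference like
#' [bootstrap_ssm()] angle intervals. Interpretation gating is applied to the
#' point estimates first: if either scale fails the prototypicality or
#' amplitude cut-off, the angular contrast is computed but suppressed
#' (`angle_status = "excluded"`, `distinct_angle = NA`).
#'
#' A significant parameter difference is one whose interval excludes zero; a
#' distinct angle additionally requires at least `angle_distinct_min` degrees
#' of separation.
#'
#' @param scale_a_scores,scale_b_scores Score vectors on the same participants.
#' @param octant_scores Octant score table shared by both scales.
#' @param geometry An [octant_geometry()].
#' @param config A [bootstrap_config()].
#' @param cutoffs An [ssm_cutoffs()] used for gating.
#' @param indices Optional prebuilt resample index matrix (see
#'   [bootstrap_ssm()]).
#' @param labels Character vector of two scale labels.
#' @param surface Surface label.
#' @return An `ssm_contrast`: list with `delta` (tibble of parameter, point
#'   estimate, bootstrap mean, lower, upper, significant), `distinct_angle`,
#'   `angle_status`, gating of both scales, and the two point fits.
#' @export
contrast_profiles <- function(scale_a_scores, scale_b_scores, octant_scores,
                              geometry = octant_geometry(),
                              config = bootstrap_config(),
                              cutoffs = ssm_cutoffs(), indices = NULL,
                              labels = c("A", "B"), surface = "surface") {
  octants <- as.matrix(octant_scores)
  if (!is.null(colnames(octants)) && all(geometry$codes %in% colnames(octants))) {
    octants <- octants[, geometry$codes, drop = FALSE]
  }
  n <- nrow(octants)
  if (length(scale_a_scores) != n || length(scale_b_scores) != n) {
    stop("both scales must be measured on the same participants (paired design)",
         call. = FALSE)
  }
  if (n < 20L) stop("refusing to bootstrap fewer than 20 participants", call. = FALSE)

  fit_a <- ssm_fit(correlation_profile(scale_a_scores, octants, geometry,
                                       scale = labels[1], surface = surface), geometry)
  fit_b <- ssm_fit(correlation_profile(scale_b_scores, octants, geometry,
                                       scale = labels[2], surface = surface), geometry)
  gate_a <- apply_cutoffs(fit_a, cutoffs)
  gate_b <- apply_cutoffs(fit_b, cutoffs)
  angle_ok <- gate_a$angle_interpretable && gate_b$angle_interpretable

  ang <- deg2rad(geometry$angles)
  cos_t <- cos(ang); sin_t <- sin(ang)
  s_mat <- cbind(scale_a_scores, scale_b_scores)

  B <- config$n_boot
  if (!is.null(indices)) {
    B <- nrow(indices)
  } else if (!is.null(config$seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
    set.seed(config$seed)
  }

  d_boot <- matrix(NA_real_, B, 5L,
                   dimnames = list(NULL, c("e", "x", "y", "a", "theta")))
  kept <- logical(B)
  for (b in seq_len(B)) {
    idx <- if (is.null(indices)) sample.int(n, n, replace = TRUE) else indices[b, ]
    r <- resample_profiles(s_mat, octants, idx)
    if (is.null(r)) next
    pa <- ssm_fit_core(r[1L, ], cos_t, sin_t)
    pb <- ssm_fit_core(r[2L, ], cos_t, sin_t)
    d_boot[b, ] <- c(pa[["e"]] - pb[["e"]], pa[["x"]] - pb[["x"]],
                     pa[["y"]] - pb[["y"]], pa[["a"]] - pb[["a"]],
                     wrap_180(pa[["theta"]] - pb[["theta"]]))
    kept[b] <- TRUE
  }
  d_boot <- d_boot[kept, , drop = FALSE]
  B_eff <- nrow(d_boot)
  if (B_eff < 0.9 * B) {
    warning(sprintf("only %d of %d bootstrap resamples usable", B_eff, B), call. = FALSE)
  }
  if (B_eff < 1L) stop("no usable bootstrap resamples", call. = FALSE)

  d_point <- c(e = fit_a$e - fit_b$e, x = fit_a$x - fit_b$x,
               y = fit_a$y - fit_b$y, a = fit_a$a - fit_b$a,
               theta = if (is.na(fit_a$theta) || is.na(fit_b$theta)) NA_real_
                       else wrap_180(fit_a$theta - fit_b$theta))

  probs <- c((1 - config$level) / 2, 1 - (1 - config$level) / 2)
  qs <- apply(d_boot[, c("e", "x", "y", "a"), drop = FALSE], 2L, stats::quantile,
              probs = probs, names = FALSE)
  if (!is.na(d_point[["theta"]])) {
    offs <- wrap_180(d_boot[, "theta"] - d_point[["theta"]])
    tq <- stats::quantile(offs, probs = probs, names = FALSE, na.rm = TRUE)
    theta_ci <- d_point[["theta"]] + tq
    theta_mean <- d_point[["theta"]] + mean(offs, na.rm = TRUE)
  } else {
    theta_ci <- c(NA_real_, NA_real_); theta_mean <- NA_real_
  }

  delta <- tibble::tibble(
    parameter = c("e", "x", "y", "a", "theta"),
    estimate = unname(d_point),
    boot_mean = unname(c(colMeans(d_boot[, c("e", "x", "y", "a"), drop = FALSE]),
                         theta_mean)),
    lower = unname(c(qs[1L, ], theta_ci[1L])),
    upper = unname(c(qs[2L, ], theta_ci[2L])))
  delta$significant <- !is.na(delta$lower) & (delta$lower > 0 | delta$upper < 0)

  angle_sig <- delta$significant[delta$parameter == "theta"]
  distinct_angle <- if (!angle_ok) {
    NA
  } else {
    isTRUE(angle_sig) && abs(d_point[["theta"]]) >= cutoffs$angle_distinct_min
  }

  structure(list(scale_pair = labels, surface = surface, delta = delta,
                 angle_status = if (angle_ok) "ok" else "excluded",
                 distinct_angle = distinct_angle,
                 gating = list(a = gate_a, b = gate_b),
                 fits = list(a = fit_a, b = fit_b),
                 B = B, B_effective = B_eff, level = config$level),
            class = "ssm_contrast")
}

#' @export
print.ssm_contrast <- function(x, ...) {
  cat("<ssm_contrast> ", x$scale_pair[1], " vs. ", x$scale_pair[2], " on ", x$surface,
      " (angle ", x$angle_status, ")\n", sep = "")
  print(as.data.frame(lapply(x$delta, function(v) if (is.numeric(v)) round(v, 3) else v)))
  invisible(x)
}
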