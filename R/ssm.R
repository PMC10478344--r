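#' Correlation profile of an external scale against octant scores
#'
#' Correlates one external scale with each of the eight octant scores of an
#' IPC surface (Pearson, pairwise-complete). The resulting 8-vector is the
#' "interpersonal profile" that the structural summary method summarizes.
#'
#' @param scale_scores Numeric vector of per-participant scale scores.
#' @param octant_scores Numeric matrix or data frame, one column per octant,
#'   columns named and ordered as in `geometry$codes` (reordered if needed).
#' @param geometry An [octant_geometry()].
#' @param scale Label for the external scale (metadata only).
#' @param surface Label for the IPC surface (metadata only).
#'
#' @return A `correlation_profile`: list with `scale`, `surface`, `r` (named
#'   8-vector of correlations) and `n_pairs` (complete pairs per octant).
#' @export
correlation_profile <- function(scale_scores, octant_scores, geometry = octant_geometry(),
                                scale = "scale", surface = "surface") {
  octant_scores <- as.matrix(octant_scores)
  if (!all(geometry$codes %in% colnames(octant_scores))) {
    stop("octant_scores must have one column per octant code", call. = FALSE)
  }
  octant_scores <- octant_scores[, geometry$codes, drop = FALSE]
  if (length(scale_scores) != nrow(octant_scores)) {
    stop("scale_scores and octant_scores must cover the same participants", call. = FALSE)
  }
  if (stats::sd(scale_scores, na.rm = TRUE) == 0 || all(is.na(scale_scores))) {
    stop(sprintf("scale '%s' is constant; correlations are undefined", scale), call. = FALSE)
  }
  r <- numeric(8L); n_pairs <- integer(8L)
  for (k in seq_len(8L)) {
    ok <- stats::complete.cases(scale_scores, octant_scores[, k])
    n_pairs[k] <- sum(ok)
    if (n_pairs[k] < 3L) {
      stop(sprintf("octant %s has fewer than 3 complete pairs", geometry$codes[k]), call. = FALSE)
    }
    if (stats::sd(octant_scores[ok, k]) == 0) {
      stop(sprintf("octant %s is constant; correlation undefined", geometry$codes[k]), call. = FALSE)
    }
    r[k] <- stats::cor(scale_scores[ok], octant_scores[ok, k])
  }
  names(r) <- names(n_pairs) <- geometry$codes
  structure(list(scale = scale, surface = surface, r = r, n_pairs = n_pairs),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat("<correlation_profile> ", x$scale, " on ", x$surface, "\n", sep = "")
  print(round(x$r, 3))
  invisible(x)
}

## Fast internal fit on a bare 8-vector; cos_t/sin_t precomputed from angles.
## Returns c(e, x, y, a, theta, r2); r2 is NA for a flat profile.
ssm_fit_core <- function(r, cos_t, sin_t) {
  k <- length(r)
  e <- sum(r) / k
  x <- 2 * sum(r * cos_t) / k
  y <- 2 * sum(r * sin_t) / k
  a <- sqrt(x^2 + y^2)
  theta <- if (a > 1e-12) wrap_360(atan2(y, x) * 180 / pi) else NA_real_
  ss_tot <- sum((r - e)^2)
  if (ss_tot == 0) {
    r2 <- NA_real_
  } else {
    fitted <- e + x * cos_t + y * sin_t
    r2 <- 1 - sum((r - fitted)^2) / ss_tot
  }
  c(e = e, x = x, y = y, a = a, theta = theta, r2 = r2)
}

#' Closed-form structural summary (cosine-curve) fit
#'
#' Fits the model \eqn{r_k = e + a\,\cos(\theta_k - \Theta)} to the eight
#' profile correlations by the closed-form least-squares solution at equally
#' spaced angles: elevation \eqn{e} is the profile mean, the communion and
#' agency vector components are \eqn{x = (2/k)\sum r_k\cos\theta_k} and
#' \eqn{y = (2/k)\sum r_k\sin\theta_k}, amplitude \eqn{a=\sqrt{x^2+y^2}},
#' angular displacement \eqn{\Theta = \mathrm{atan2}(y,x)} in degrees, and
#' prototypicality \eqn{R^2 = 1 - SS_{res}/SS_{tot}} around the profile mean.
#'
#' A flat profile (all correlations equal) has amplitude 0; its angle and
#' \eqn{R^2} are undefined and returned as `NA` with a warning.
#'
#' @param profile A [correlation_profile()] or a numeric 8-vector of
#'   correlations ordered as `geometry$codes`.
#' @param geometry An [octant_geometry()].
#'
#' @return An `ssm_params` object: list with `e`, `x`, `y`, `a`, `theta`,
#'   `r2`, `fitted` (the fitted 8-vector), plus the profile labels.
#' @examples
#' geom <- octant_geometry()
#' r <- 0.3 + 0.2 * cos(pi / 180 * (geom$angles - 90))
#' ssm_fit(r, geom) # e = .3, a = .2, theta = 90, R2 = 1
#' @export
ssm_fit <- function(profile, geometry = octant_geometry()) {
  if (inherits(profile, "correlation_profile")) {
    r <- profile$r; scale <- profile$scale; surface <- profile$surface
  } else {
    r <- as.numeric(profile); scale <- "scale"; surface <- "surface"
  }
  if (length(r) != length(geometry$codes)) {
    stop("profile length must match the geometry", call. = FALSE)
  }
  if (anyNA(r)) stop("profile contains missing correlations", call. = FALSE)
  ang <- deg2rad(geometry$angles)
  fit <- ssm_fit_core(r, cos(ang), sin(ang))
  if (is.na(fit[["r2"]])) {
    warning("flat profile: angular displacement and R2 are undefined", call. = FALSE)
  }
  fitted <- fit[["e"]] + fit[["x"]] * cos(ang) + fit[["y"]] * sin(ang)
  names(fitted) <- geometry$codes
  structure(list(scale = scale, surface = surface,
                 e = fit[["e"]], x = fit[["x"]], y = fit[["y"]],
                 a = fit[["a"]], theta = fit[["theta"]], r2 = fit[["r2"]],
                 fitted = fitted),
            class = "ssm_params")
}

#' @export
print.ssm_params <- function(x, ...) {
  cat("<ssm_params> ", x$scale, " on ", x$surface, "\n", sep = "")
  cat(sprintf("  e = %.2f  a = %.2f  theta = %s  R2 = %s\n",
              x$e, x$a,
              if (is.na(x$theta)) "NA" else sprintf("%.1f deg", x$theta),
              if (is.na(x$r2)) "NA" else sprintf("%.3f", x$r2)))
  invisible(x)
}

#' Polar form of communion/agency vector components
#'
#' Converts the Cartesian vector components of an SSM fit (communion `x`,
#' agency `y`) to amplitude and angular displacement. Useful for checking
#' published vector components against published amplitude/angle cells.
#'
#' @param x,y Communion and agency components.
#' @return List with `a` (amplitude) and `theta` (degrees in `[0, 360)`,
#'   `NA` when `a == 0`).
#' @examples
#' polar_from_vectors(-0.28, -0.02)
#' @export
polar_from_vectors <- function(x, y) {
  a <- sqrt(x^2 + y^2)
  theta <- if (a > 0) wrap_360(atan2(y, x) * 180 / pi) else NA_real_
  list(a = a, theta = theta)
}

#' Interpretation cut-offs for SSM parameters
#'
#' Heuristic cut-offs used to gate interpretation: a profile is *elevated* if
#' `|e| >= elevation_min`, *prototypical* (has a unified interpersonal theme)
#' if `R2 >= r2_min`, and *differentiated* if `a >= amplitude_min`. Amplitude
#' and angle are only interpreted for prototypical profiles, and two angles
#' are treated as meaningfully distinct only when at least half an octant
#' (`angle_distinct_min` degrees) apart.
#'
#' @param elevation_min,amplitude_min Magnitude cut-offs (default 0.10).
#' @param r2_min Prototypicality cut-off (default 0.70; 0.80 is a good fit).
#' @param angle_distinct_min Angular distinctness heuristic in degrees
#'   (default 22.5, half an octant).
#' @return An `ssm_cutoffs` list.
#' @export
ssm_cutoffs <- function(elevation_min = 0.10, amplitude_min = 0.10,
                        r2_min = 0.70, angle_distinct_min = 22.5) {
  vals <- c(elevation_min, amplitude_min, r2_min, angle_distinct_min)
  if (any(vals <= 0)) stop("all cut-offs must be strictly positive", call. = FALSE)
  structure(list(elevation_min = elevation_min, amplitude_min = amplitude_min,
                 r2_min = r2_min, angle_distinct_min = angle_distinct_min),
            class = "ssm_cutoffs")
}

#' Gate SSM parameters for interpretation
#'
#' Applies [ssm_cutoffs()] to a fitted profile. A non-prototypical (complex)
#' profile has its amplitude and angle flagged non-interpretable regardless of
#' magnitude; `differentiated` is `NA` in that case because it is not
#' reported. The angle is interpretable only for profiles that are both
#' prototypical and differentiated.
#'
#' @param params An [ssm_fit()] result.
#' @param cutoffs An [ssm_cutoffs()].
#' @return A list of flags: `elevated`, `prototypical`, `differentiated`,
#'   `angle_interpretable`.
#' @export
apply_cutoffs <- function(params, cutoffs = ssm_cutoffs()) {
  prototypical <- !is.na(params$r2) && params$r2 >= cutoffs$r2_min
  differentiated <- if (prototypical) params$a >= cutoffs$amplitude_min else NA
  list(elevated = abs(params$e) >= cutoffs$elevation_min,
       prototypical = prototypical,
       differentiated = differentiated,
       angle_interpretable = prototypical && isTRUE(differentiated))
}
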