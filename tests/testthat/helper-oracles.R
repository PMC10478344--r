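# Independent oracles and shared generators for the test suite.

geom <- octant_geometry()

# Least-squares oracle for the cosine-curve fit: regress the profile on
# cos/sin of the octant angles and convert coefficients to polar form.
ls_ssm_oracle <- function(r, geometry = geom) {
  th <- geometry$angles * pi / 180
  fit <- lm(r ~ cos(th) + sin(th))
  cf <- unname(coef(fit))
  a <- sqrt(cf[2]^2 + cf[3]^2)
  theta <- (atan2(cf[3], cf[2]) * 180 / pi) %% 360
  r2 <- 1 - sum(residuals(fit)^2) / sum((r - mean(r))^2)
  list(e = cf[1], x = cf[2], y = cf[3], a = a, theta = theta, r2 = r2)
}

# Cosine profile at the octant angles.
cosine_profile <- function(e, a, theta, geometry = geom) {
  e + a * cos(pi / 180 * (geometry$angles - theta))
}

# Closed-form omega_t for k parallel items with common loading lambda.
parallel_omega <- function(k, lambda) {
  (k * lambda)^2 / ((k * lambda)^2 + k * (1 - lambda^2))
}

# Small bivariate sample with one scale and correlated octant scores drawn
# from a spec; returns list(scale, octants).
draw_scale_sample <- function(n, e, a, theta, seed, surface = "problems") {
  spec <- synthetic_spec(
    n = n,
    scales = data.frame(label = "S", surface = surface,
                        e = e, a = a, theta = theta),
    seed = seed)
  ds <- simulate_sample(spec)
  list(scale = ds$scales[, "S"], octants = ds$octants[[surface]])
}
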