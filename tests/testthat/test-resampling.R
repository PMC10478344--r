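test_that("identity resampling collapses the bootstrap CIs onto the point estimate", {
  d <- draw_scale_sample(200, e = 0.2, a = 0.3, theta = 180, seed = 41)
  idx <- matrix(rep(seq_len(200), 120), nrow = 120, byrow = TRUE)
  bt <- bootstrap_ssm(d$scale, d$octants, indices = idx)
  expect_equal(bt$B_effective, 120)
  expect_equal(bt$ci$lower, bt$ci$estimate, tolerance = 1e-10)
  expect_equal(bt$ci$upper, bt$ci$estimate, tolerance = 1e-10)
})

test_that("bootstrap intervals are reproducible, ordered, and respect domains", {
  d <- draw_scale_sample(300, e = 0.2, a = 0.3, theta = 180, seed = 42)
  cfg <- bootstrap_config(n_boot = 300, seed = 99)
  b1 <- bootstrap_ssm(d$scale, d$octants, config = cfg)
  b2 <- bootstrap_ssm(d$scale, d$octants, config = cfg)
  expect_identical(b1$ci, b2$ci)

  lin <- b1$ci[b1$ci$parameter != "theta", ]
  expect_true(all(lin$lower <= lin$estimate + 1e-12))
  expect_true(all(lin$upper >= lin$estimate - 1e-12))
  expect_gte(b1$ci$lower[b1$ci$parameter == "a"], 0)
  expect_true(all(b1$boot[, "a"] >= 0))

  # circular theta interval contains the point estimate, arc < 360
  tlo <- b1$ci$lower[b1$ci$parameter == "theta"]
  tup <- b1$ci$upper[b1$ci$parameter == "theta"]
  expect_true(angle_in_interval(b1$point$theta, tlo, tup))
  expect_lt((tup - tlo) %% 360, 360)

  expect_error(bootstrap_ssm(d$scale[1:10], d$octants[1:10, ]), "fewer than 20")
  expect_error(bootstrap_config(n_boot = 50), "at least 100")
  expect_error(bootstrap_config(level = 1.2), "in \\(0, 1\\)")
})

test_that("theta interval is recentered across the 0/360 wrap", {
  # true angle at 0 degrees: naive percentiles would span nearly 360
  d <- draw_scale_sample(856, e = 0.1, a = 0.2, theta = 0, seed = 43)
  bt <- bootstrap_ssm(d$scale, d$octants, config = bootstrap_config(500, seed = 7))
  tlo <- bt$ci$lower[bt$ci$parameter == "theta"]
  tup <- bt$ci$upper[bt$ci$parameter == "theta"]
  arc <- (tup - tlo) %% 360
  expect_lt(arc, 90)
  expect_true(angle_in_interval(bt$point$theta, tlo, tup))
})

test_that("contrasting a scale with itself gives exactly zero differences", {
  d <- draw_scale_sample(200, e = 0.2, a = 0.3, theta = 120, seed = 44)
  ct <- contrast_profiles(d$scale, d$scale, d$octants,
                          config = bootstrap_config(n_boot = 150, seed = 5))
  expect_true(all(abs(ct$delta$estimate) < 1e-12))
  expect_true(all(abs(ct$delta$lower) < 1e-12))
  expect_true(all(abs(ct$delta$upper) < 1e-12))
  expect_false(any(ct$delta$significant))
})

test_that("contrasts are antisymmetric under swapping the scales", {
  spec <- synthetic_spec(
    n = 400,
    scales = data.frame(label = c("A", "B"), surface = "problems",
                        e = c(0.2, 0.3), a = c(0.3, 0.25), theta = c(90, 180)),
    seed = 45)
  ds <- simulate_sample(spec)
  oct <- ds$octants$problems
  cfg <- bootstrap_config(n_boot = 200, seed = 17)
  ab <- contrast_profiles(ds$scales[, "A"], ds$scales[, "B"], oct, config = cfg,
                          labels = c("A", "B"))
  ba <- contrast_profiles(ds$scales[, "B"], ds$scales[, "A"], oct, config = cfg,
                          labels = c("B", "A"))
  expect_equal(ab$delta$estimate, -ba$delta$estimate, tolerance = 1e-10)
  expect_equal(ab$delta$lower, -ba$delta$upper, tolerance = 1e-10)
  expect_equal(ab$delta$upper, -ba$delta$lower, tolerance = 1e-10)
  expect_equal(ab$delta$significant, ba$delta$significant)
})

test_that("a true 90-degree angular separation is detected at study scale", {
  spec <- synthetic_spec(
    n = 856,
    scales = data.frame(label = c("A", "B"), surface = "problems",
                        e = c(0.2, 0.2), a = c(0.3, 0.3), theta = c(90, 180)),
    seed = 46)
  ds <- simulate_sample(spec)
  ct <- contrast_profiles(ds$scales[, "A"], ds$scales[, "B"], ds$octants$problems,
                          config = bootstrap_config(n_boot = 400, seed = 3),
                          labels = c("A", "B"))
  dth <- ct$delta[ct$delta$parameter == "theta", ]
  expect_equal(dth$estimate, -90, tolerance = 12)
  expect_true(dth$significant)
  expect_true(ct$distinct_angle)
  expect_equal(ct$angle_status, "ok")
})

test_that("gating suppresses the angular contrast for undifferentiated profiles", {
  spec <- synthetic_spec(
    n = 500,
    scales = data.frame(label = c("A", "B"), surface = "problems",
                        e = c(0.2, 0.3), a = c(0.3, 0.02), theta = c(90, 180)),
    seed = 47)
  ds <- simulate_sample(spec)
  ct <- contrast_profiles(ds$scales[, "A"], ds$scales[, "B"], ds$octants$problems,
                          config = bootstrap_config(n_boot = 150, seed = 9),
                          labels = c("A", "B"))
  expect_equal(ct$angle_status, "excluded")
  expect_true(is.na(ct$distinct_angle))

  expect_error(contrast_profiles(rnorm(30), rnorm(25), matrix(rnorm(30 * 8), 30, 8)),
               "paired")
})

test_that("significant but small angular differences are not called distinct", {
  # CI excludes 0 but |delta| below half an octant
  fake <- data.frame(surface = "problems", scale_a = "A", scale_b = "B",
                     delta_theta = -20.0, delta_theta_lower = -26.5,
                     delta_theta_upper = -13.3, angle_status = "ok")
  expect_equal(evaluate_convergence(fake)$call,
               "statistically distinct but overlapping")
})

test_that("order predictions enumerate distance-class contrasts", {
  expect_equal(nrow(randall_predictions(8)), 288)
  expect_equal(nrow(randall_predictions(4)), 8)
  expect_error(randall_predictions(3), NA)
  expect_equal(nrow(randall_predictions(3)), 0)
  expect_error(randall_predictions(2), "at least 3")
  p8 <- randall_predictions(8)
  expect_true(all(p8$c_class < p8$f_class))
})

test_that("randall_test resolves perfect and inverted circumplex matrices", {
  R <- circumplex_pattern_matrix(c(0.6, 0.4, 0.2, 0.1))
  res <- randall_test(R)
  expect_equal(res$n_met, 288)
  expect_equal(res$n_violated, 0)
  expect_equal(res$correspondence_index, 1)
  expect_equal(round(res$p_value, 4), 0.0004)
  expect_equal(res$n_relabelings, 2520)
  expect_gte(res$p_value, 1 / 2520)

  anti <- circumplex_pattern_matrix(c(0.1, 0.2, 0.4, 0.6))
  res2 <- randall_test(anti)
  expect_equal(res2$correspondence_index, -1)
  expect_equal(res2$n_violated, 288)

  expect_error(randall_test(matrix(rnorm(9), 3, 3)), "symmetric")
  sym <- diag(4) * 2
  expect_error(randall_test(sym), "unit diagonal")
})

test_that("correspondence index is invariant under rotation and reflection", {
  set.seed(48)
  z <- matrix(rnorm(200 * 8), 200, 8)
  # correlated noise with rough circumplex ordering plus jitter
  R <- cor(z %*% chol(circumplex_pattern_matrix(c(0.5, 0.3, 0.1, 0.0)) + diag(8) * 0.1))
  base <- randall_test(R, mode = "sampled", n_samples = 50, seed = 1)
  for (shift in c(1, 3)) {
    ord <- c((shift + 1):8, 1:shift)
    rot <- randall_test(R[ord, ord], mode = "sampled", n_samples = 50, seed = 1)
    expect_equal(rot$correspondence_index, base$correspondence_index)
  }
  refl <- c(1, 8:2)
  rr <- randall_test(R[refl, refl], mode = "sampled", n_samples = 50, seed = 1)
  expect_equal(rr$correspondence_index, base$correspondence_index)
  expect_true(abs(base$correspondence_index) <= 1)
})

test_that("sampled-mode p converges to the exhaustive p at k = 6", {
  R <- circumplex_pattern_matrix(c(0.5, 0.25, 0.05), k = 6)
  set.seed(49)
  noise <- matrix(rnorm(36, sd = 0.02), 6, 6)
  noise <- (noise + t(noise)) / 2; diag(noise) <- 0
  R <- R + noise
  ex <- randall_test(R, mode = "exhaustive")
  sam <- randall_test(R, mode = "sampled", n_samples = 4000, seed = 2)
  expect_equal(sam$p_value, ex$p_value, tolerance = 0.02)
  expect_equal(sam$correspondence_index, ex$correspondence_index)
})
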