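make_responses <- function(mat, prefix = "P") {
  rownames(mat) <- sprintf("%s%03d", prefix, seq_len(nrow(mat)))
  mat
}

test_that("sum and mean scoring with proration behave per contract", {
  key <- scoring_key("toy-sum", sprintf("T_%02d", 1:10),
                     list(S = sprintf("T_%02d", 1:10)), 0L, 4L, "sum")
  # all endorsed true/false style: score equals the count
  tf_key <- scoring_key("toy-tf", sprintf("B_%02d", 1:24),
                        list(S = sprintf("B_%02d", 1:24)), 0L, 1L, "sum")
  m <- make_responses(matrix(1, 3, 24, dimnames = list(NULL, tf_key$item_ids)))
  expect_equal(unname(score_scale(m, tf_key, "S")), rep(24, 3))

  # constant mean aggregation
  mean_key <- scoring_key("toy-mean", sprintf("M_%02d", 1:8),
                          list(S = sprintf("M_%02d", 1:8)), 1L, 5L, "mean")
  m3 <- make_responses(matrix(3, 4, 8, dimnames = list(NULL, mean_key$item_ids)))
  expect_equal(unname(score_scale(m3, mean_key, "S")), rep(3, 4))

  # proration: 10-item sum scale, 1 missing, answered mean 2 -> 20
  v <- make_responses(matrix(2, 1, 10, dimnames = list(NULL, key$item_ids)))
  v[1, 1] <- NA
  expect_equal(unname(score_scale(v, key, "S")), 20)

  # over the proration limit -> missing score
  w <- make_responses(matrix(2, 1, 10, dimnames = list(NULL, key$item_ids)))
  w[1, 1:3] <- NA  # 70% answered < 80%
  expect_true(is.na(score_scale(w, key, "S")))

  expect_error(score_scale(v, key, "nope"), "unknown scale")
  allna <- make_responses(matrix(NA_real_, 2, 10, dimnames = list(NULL, key$item_ids)))
  expect_error(score_scale(allna, key, "S"), "all items missing")
})

test_that("prorated sum equals the plain sum when nothing is missing", {
  key <- key_mss()
  set.seed(21)
  m <- make_responses(matrix(rbinom(50 * 77, 1, 0.3), 50, 77,
                             dimnames = list(NULL, key$item_ids)))
  for (sc in names(key$scale_map)) {
    expect_equal(unname(score_scale(m, key, sc)),
                 unname(rowSums(m[, key$scale_map[[sc]]])))
  }
})

test_that("octant scoring matches scale-by-scale scoring and geometry order", {
  key <- key_iip_sc()
  set.seed(22)
  m <- make_responses(matrix(sample(0:4, 60 * 32, TRUE), 60, 32,
                             dimnames = list(NULL, key$item_ids)))
  oct <- score_octants(m, key)
  expect_equal(colnames(oct), octant_geometry()$codes)
  for (code in colnames(oct)) {
    per_scale_key <- scoring_key(key$instrument, key$item_ids,
                                 key$octant_map, key$response_min,
                                 key$response_max, key$aggregation)
    expect_equal(oct[, code], score_scale(m, per_scale_key, code))
  }
  # constant extremes
  zeros <- make_responses(matrix(0, 5, 32, dimnames = list(NULL, key$item_ids)))
  expect_true(all(score_octants(zeros, key) == 0))
  isc <- key_isc()
  eights <- make_responses(matrix(8, 5, 64, dimnames = list(NULL, isc$item_ids)))
  expect_true(all(score_octants(eights, isc) == 8))
  expect_error(score_octants(m, key_mss()), "octant map")
})

test_that("item-scored octants track their generating latents", {
  spec <- synthetic_spec(n = 2000, items = TRUE,
                         surfaces = c("problems", "sensitivities"), seed = 31)
  ds <- simulate_sample(spec)
  oct_sens <- score_octants(ds$items$sensitivities, key_isc())
  oct_prob <- score_octants(ds$items$problems, key_iip_sc())
  for (code in octant_geometry()$codes) {
    # 8 items per octant: near-interchangeable with the latent
    expect_gt(cor(oct_sens[, code], ds$octants$sensitivities[, code]), 0.95)
    # 4 coarse Likert items: composite reliability caps the correlation lower
    expect_gt(cor(oct_prob[, code], ds$octants$problems[, code]), 0.90)
  }
})

test_that("protocol screening applies rules in order with strict thresholds", {
  key_items <- sprintf("I_%02d", 1:50)
  set.seed(23)
  m <- make_responses(matrix(sample(0:3, 40 * 50, TRUE), 40, 50,
                             dimnames = list(NULL, key_items)))
  ids <- rownames(m)
  # participant 1: exactly 2% missing (1 of 50) -> retained (strict >)
  m[1, 1] <- NA
  # participant 2: 3 of 50 = 6% -> excluded by missingness
  m[2, 1:3] <- NA
  validity <- setNames(rep(2, 40), ids)
  validity[3] <- 20   # above 4 + 2.5 * 2 = 9
  validity[2] <- 20   # also infrequent, but missingness attributes first
  rules <- screening_rules(infrequency_norm_mean = 4, infrequency_norm_sd = 2,
                           manual_exclusions = ids[4])
  res <- screen_protocols(m, validity, rules)
  expect_equal(unname(res$counts),
               c(1, 1, 1, 37))
  expect_setequal(res$ledger$participant_id, ids[2:4])
  expect_equal(res$ledger$rule[res$ledger$participant_id == ids[2]], "missingness")
  expect_true(ids[1] %in% rownames(res$retained))

  # boundary: infrequency exactly at the threshold is retained
  validity[5] <- 9
  res2 <- screen_protocols(m, validity, rules)
  expect_true(ids[5] %in% rownames(res2$retained))

  # idempotence: screening the retained set again excludes no one
  res3 <- screen_protocols(res$retained, validity[rownames(res$retained)],
                           screening_rules(infrequency_norm_mean = 4,
                                           infrequency_norm_sd = 2))
  expect_equal(unname(res3$counts[["retained"]]), nrow(res$retained))
  expect_equal(nrow(res3$ledger), 0L)

  # clean data: identity
  clean <- make_responses(matrix(1, 10, 50, dimnames = list(NULL, key_items)), "C")
  resc <- screen_protocols(clean, setNames(rep(2, 10), rownames(clean)),
                           screening_rules(infrequency_norm_mean = 4,
                                           infrequency_norm_sd = 2))
  expect_equal(unname(resc$counts[["retained"]]), 10)

  expect_error(screen_protocols(m[0, ], validity, rules), "empty")
  expect_error(screen_protocols(m, validity,
                                screening_rules(infrequency_norm_mean = 4,
                                                infrequency_norm_sd = 2,
                                                manual_exclusions = "ghost")),
               "unknown participants")
})

test_that("omega_t matches the parallel-items closed form and limiting cases", {
  set.seed(24)
  n <- 20000
  lam <- 0.7
  f <- rnorm(n)
  items <- sapply(1:4, function(i) lam * f + sqrt(1 - lam^2) * rnorm(n))
  rel <- omega_total(items)
  expect_equal(rel$omega_t, parallel_omega(4, lam), tolerance = 0.02)
  expect_true(all(rel$uniquenesses >= 0))
  expect_true(rel$omega_t >= 0 && rel$omega_t <= 1)

  # near-perfectly correlated items -> omega near 1
  tight <- sapply(1:4, function(i) f + 0.01 * rnorm(n))
  expect_gt(omega_total(tight)$omega_t, 0.98)

  # independent items -> omega near 0
  indep <- matrix(rnorm(5000 * 6), 5000, 6)
  expect_lt(omega_total(indep)$omega_t, 0.15)

  expect_error(omega_total(items[, 1:2]), "3 items")
  expect_error(omega_total(items[1:20, ]), "50 complete")
})

test_that("omega_t is invariant to item order and common rescaling", {
  set.seed(25)
  f <- rnorm(3000)
  items <- sapply(c(.6, .7, .8, .5), function(l) l * f + sqrt(1 - l^2) * rnorm(3000))
  w <- omega_total(items)$omega_t
  expect_equal(omega_total(items[, c(3, 1, 4, 2)])$omega_t, w, tolerance = 1e-10)
  expect_equal(omega_total(items * 7)$omega_t, w, tolerance = 1e-10)
})

test_that("scoring keys validate and round-trip through YAML", {
  expect_error(scoring_key("x", c("a", "b"), list(S = c("a", "z")), 0, 4, "sum"),
               "unknown items")
  expect_error(scoring_key("x", c("a", "b"), list(S = "a"), 0, 4, "sum"),
               "at least one scale")
  expect_error(scoring_key("x", c("a", "b"), list(S = c("a", "b")), 4, 0, "sum"),
               "response_min")

  key <- key_spq_bru()
  expect_length(key$scale_map[["Interpersonal (3-factor)"]], 13)
  path <- tempfile(fileext = ".yaml")
  write_scoring_key(key_iip_sc(), path)
  back <- read_scoring_key(path)
  expect_equal(back$octant_map, key_iip_sc()$octant_map)
  expect_equal(back$aggregation, "mean")

  # bundled key shapes
  expect_length(key_isc()$item_ids, 64)
  expect_length(key_mss()$item_ids, 77)
  expect_length(key_ffsi()$item_ids, 90)
  expect_length(key_pid5_stpd()$item_ids, 57)
  expect_length(key_pai_infrequency()$item_ids, 8)
  expect_true(all(lengths(key_iip_sc()$octant_map) == 4))
  expect_true(all(lengths(key_isc()$octant_map) == 8))
})
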