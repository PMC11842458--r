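test_that("z_variance is 1/(n-3) and rejects tiny samples", {
  expect_equal(z_variance(4L), 1)
  expect_equal(z_variance(103L), 0.01)
  expect_equal(z_variance(403L), 0.0025)
  expect_error(z_variance(3L), "n >= 4")
})

test_that("within-sample pooling is the inverse-variance fixed-effect mean", {
  one <- pool_within_sample(tibble::tibble(z = 0.3, v = 0.01))
  expect_equal(one$z, 0.3)
  expect_equal(one$v, 0.01)
  expect_identical(one$ne, 1L)
  eq <- pool_within_sample(tibble::tibble(z = c(0.2, 0.4), v = 0.01))
  expect_equal(eq$z, 0.3)
  expect_equal(eq$v, 0.005)
  iv <- pool_within_sample(tibble::tibble(z = c(0, 0.3), v = c(0.01, 0.02)))
  expect_equal(iv$z, 0.1)
  expect_equal(iv$v, 1 / 150)
  expect_error(pool_within_sample(tibble::tibble(z = numeric(), v = numeric())),
               "no records")
  grouped <- pool_within_sample(tibble::tibble(
    association = c("r_x1y1", "r_x1y1", "r_x1y2"),
    sample_id = "S1", z = c(0.2, 0.4, 0.1), v = 0.01
  ))
  expect_identical(nrow(grouped), 2L)
})

test_that("homogeneous inputs give a zero-heterogeneity pool equal to the FE mean", {
  d <- tibble::tibble(z = rep(0.3, 5), v = 0.01)
  p <- random_effects_pool(d)
  expect_equal(p$tau2, 0)
  expect_equal(p$Q, 0)
  expect_equal(p$I2, 0)
  expect_equal(p$z, 0.3)
  expect_equal(p$estimate, tanh(0.3))
  # with tau2 = 0 the RE weights are the FE weights exactly
  set.seed(7)
  d2 <- tibble::tibble(z = rnorm(8, 0.2, 0.001), v = runif(8, 0.01, 0.05))
  p2 <- random_effects_pool(d2)
  if (p2$tau2 == 0) {
    fe <- sum(d2$z / d2$v) / sum(1 / d2$v)
    expect_equal(p2$z, fe, tolerance = 1e-12)
  }
})

test_that("Cochran's Q matches its closed form and is order-invariant", {
  d <- tibble::tibble(z = c(0.1, 0.5), v = 0.01)
  p <- random_effects_pool(d)
  expect_equal(p$Q, 8)
  expect_identical(p$df, 1L)
  expect_equal(p$I2, (8 - 1) / 8 * 100)
  set.seed(11)
  d3 <- tibble::tibble(z = rnorm(12, 0.3, 0.1), v = runif(12, 0.005, 0.05))
  p_fwd <- random_effects_pool(d3)
  p_rev <- random_effects_pool(d3[12:1, ])
  expect_equal(p_fwd$Q, p_rev$Q, tolerance = 1e-12)
  expect_equal(p_fwd$z, p_rev$z, tolerance = 1e-12)
})

test_that("pooled estimate stays inside the input range and I2 inside [0, 100]", {
  set.seed(23)
  for (i in 1:50) {
    k <- sample(2:20, 1)
    d <- tibble::tibble(z = rnorm(k, 0.2, 0.2), v = runif(k, 0.002, 0.1))
    p <- random_effects_pool(d)
    expect_gte(p$z, min(d$z))
    expect_lte(p$z, max(d$z))
    expect_gte(p$I2, 0)
    expect_lte(p$I2, 100)
    expect_gte(p$tau2, 0)
    expect_lte(p$ci_low, p$estimate)
    expect_gte(p$ci_high, p$estimate)
  }
})

test_that("REML recovers a known between-sample variance", {
  set.seed(31)
  tau2_hat <- replicate(5, {
    z <- rnorm(40, 0.3, sqrt(0.0025 + 0.04))
    random_effects_pool(tibble::tibble(z = z, v = 0.0025))$tau2
  })
  expect_true(all(tau2_hat > 0.02 & tau2_hat < 0.07))
})

test_that("K < 2 is rejected with a pass-through hint", {
  expect_error(random_effects_pool(tibble::tibble(z = 0.3, v = 0.01)),
               "pass-through")
})

test_that("two-step pooling collapses to one-step when clustering is vacuous", {
  set.seed(41)
  d <- tibble::tibble(
    association = "r_x1y1",
    sample_id = sprintf("S%02d", 1:15),
    z = rnorm(15, 0.3, 0.1), v = runif(15, 0.005, 0.05)
  )
  two_step <- random_effects_pool(pool_within_sample(d))
  one_step <- random_effects_pool(d)
  expect_equal(two_step$z, one_step$z, tolerance = 1e-12)
  expect_equal(two_step$tau2, one_step$tau2, tolerance = 1e-12)
  expect_equal(two_step$Q, one_step$Q, tolerance = 1e-12)
})

test_that("meta_table bookkeeping: full sextets give identical counts everywhere", {
  cfg <- scenario_config(K = 8, sets = 1, missingness = 0, seed = 5)
  records <- generate_meta_dataset(cfg)
  expect_identical(nrow(records), 8L * 6L)
  mt <- meta_table(records)
  expect_identical(nrow(mt), 12L)
  expect_true(all(mt$K == 8L))
  expect_true(all(mt$NE == 8L))
  expect_identical(dplyr::n_distinct(mt$N), 1L)
  expect_identical(mt$association, association_labels()$association)
})

test_that("meta_table single-sample datasets pass through without heterogeneity", {
  cfg <- scenario_config(K = 1, sets = 1, missingness = 0, seed = 9)
  mt <- meta_table(generate_meta_dataset(cfg))
  expect_true(all(mt$K == 1L))
  expect_true(all(is.na(mt$Q)))
  expect_true(all(is.na(mt$I2)))
  expect_false(anyNA(mt$estimate))
  expect_true(all(mt$ci_low < mt$estimate & mt$estimate < mt$ci_high))
})

test_that("meta_table rejects invalid record tables", {
  expect_error(meta_table(tibble::tibble()), "missing column")
  rec <- generate_meta_dataset(scenario_config(K = 2, sets = 1, seed = 1))
  expect_error(meta_table(rec[0, ]), "empty")
  bad <- dplyr::mutate(rec, n = 3L)
  expect_error(meta_table(bad), "n < 4")
  expect_error(meta_table(dplyr::mutate(rec, association = "nope")),
               "unknown association")
})
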