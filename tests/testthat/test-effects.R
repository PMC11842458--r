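test_that("fisher_z matches the closed-form log expression and inverts", {
  closed_form <- function(r) 0.5 * log((1 + r) / (1 - r))
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), closed_form(0.5), tolerance = 1e-12)
  expect_equal(fisher_z(-0.339), closed_form(-0.339), tolerance = 1e-12)
  rs <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z_inv(fisher_z(rs)), rs, tolerance = 1e-12)
  expect_error(fisher_z(1), "\\|r\\| < 1")
  expect_error(fisher_z(-1.2), "-1.2")
})

test_that("closed-form betas reproduce the worked-example values", {
  # frozen by direct arithmetic on the published pooled correlations
  expect_equal(beta_lagged_adjusted(-0.266, -0.339, 0.587), -0.0757073662351,
               tolerance = 1e-10)
  expect_equal(beta_reverse_adjusted(-0.339, -0.266, 0.587), -0.1967814696678,
               tolerance = 1e-10)
  expect_equal(beta_on_change(-0.266, -0.339, 0.587), 0.0803216897848,
               tolerance = 1e-10)
  expect_equal(beta_lagged_adjusted(-0.273, -0.339, 0.572), -0.0893615146219,
               tolerance = 1e-10)
  expect_equal(beta_reverse_adjusted(-0.339, -0.273, 0.572), -0.1975685893993,
               tolerance = 1e-10)
  expect_equal(beta_on_change(-0.273, -0.339, 0.572), 0.0713357206926,
               tolerance = 1e-10)
})

test_that("betas vanish exactly on their null manifolds", {
  # numerator vanishes when the cross-lag equals concurrent * autocorrelation
  expect_identical(beta_lagged_adjusted(-0.3 * 0.6, -0.3, 0.6), 0)
  expect_identical(beta_reverse_adjusted(-0.25 * 0.5, -0.25, 0.5), 0)
  # change effect vanishes when cross-lagged equals concurrent
  expect_identical(beta_on_change(-0.31, -0.31, 0.55), 0)
})

test_that("degenerate denominators raise named errors", {
  expect_error(beta_lagged_adjusted(0.2, 1, 0.5), "collinear")
  expect_error(beta_reverse_adjusted(0.2, -1, 0.5), "collinear")
  expect_error(beta_on_change(0.2, 0.1, 1), "zero-variance")
  expect_error(beta_lagged_adjusted(1.4, 0.2, 0.1), "out of \\[-1, 1\\]")
})

test_that("adjusted betas equal the normal-equation solution on random sextets", {
  set.seed(421)
  for (i in 1:1000) {
    r <- random_valid_sextet()
    expect_equal(
      beta_lagged_adjusted(r["x1", "y2"], r["x1", "y1"], r["y1", "y2"]),
      oracle_beta_normal_eq(r, outcome = "y2", p1 = "x1", p2 = "y1"),
      tolerance = 1e-10
    )
    expect_equal(
      beta_reverse_adjusted(r["x1", "y1"], r["x1", "y2"], r["y1", "y2"]),
      oracle_beta_normal_eq(r, outcome = "y1", p1 = "x1", p2 = "y2"),
      tolerance = 1e-10
    )
  }
})

test_that("closed forms equal OLS on raw standardized scores", {
  set.seed(52)
  for (i in 1:25) {
    r <- random_valid_sextet()
    d <- MASS::mvrnorm(200, mu = rep(0, 4), Sigma = r)
    colnames(d) <- c("x1", "x2", "y1", "y2")
    d <- as.data.frame(scale(d))
    rc <- cor(d)
    dimnames(rc) <- dimnames(r)
    fit <- lm(y2 ~ x1 + y1, data = d)
    expect_equal(
      beta_lagged_adjusted(rc["x1", "y2"], rc["x1", "y1"], rc["y1", "y2"]),
      unname(coef(fit)["x1"]), tolerance = 1e-8
    )
    # the difference score scaled to unit sample sd (its variance is
    # 2 * (1 - r_y1y2) when both waves have unit variance)
    ch <- (d$y2 - d$y1) / sqrt(2 * (1 - rc["y1", "y2"]))
    fit_ch <- lm(ch ~ d$x1)
    expect_equal(
      beta_on_change(rc["x1", "y2"], rc["x1", "y1"], rc["y1", "y2"]),
      unname(coef(fit_ch)[2]), tolerance = 1e-8
    )
  }
})

test_that("effect_sextet applies all three forms in both directions", {
  pooled <- pooled_to_sextet(se_ed_pooled())
  eff <- effect_sextet(pooled)
  expect_equal(
    unname(unlist(eff[beta_cols()])),
    c(-0.0757073662351, -0.1967814696678, 0.0803216897848,
      -0.0893615146219, -0.1975685893993, 0.0713357206926),
    tolerance = 1e-10
  )
  zero <- correlation_sextet(0, 0, 0, 0, 0, 0, n = 100)
  expect_true(all(unlist(effect_sextet(zero)[beta_cols()]) == 0))
})

test_that("missing correlations propagate without aborting the other direction", {
  s <- correlation_sextet(r_x1y1 = -0.3, r_y1y2 = 0.6, r_x1y2 = -0.25, n = 100)
  eff <- effect_sextet(s)
  expect_false(anyNA(eff[c("b_x_lagged", "b_x_reverse", "b_x_change")]))
  expect_true(all(is.na(eff[c("b_y_lagged", "b_y_reverse", "b_y_change")])))
  # a degenerate denominator in one direction leaves the other intact
  s2 <- correlation_sextet(r_x1y1 = -0.3, r_y1y2 = 0.6, r_x1y2 = -0.25,
                           r_x1x2 = 1, r_x2y1 = -0.2, n = 100, validate = FALSE)
  eff2 <- suppressWarnings(effect_sextet(s2))
  expect_true(is.nan(eff2$b_y_change))
  expect_false(is.na(eff2$b_x_lagged))
})

test_that("predicted trajectories follow the three conditioning schemes", {
  pooled <- pooled_to_sextet(se_ed_pooled())
  none <- predicted_trajectories(pooled, "none", z_levels = c(-1, 0, 1))
  expect_equal(none$predicted[none$z == 0], c(0, 0))
  expect_equal(none$predicted[none$z == 1 & none$time == 1], -0.339)
  expect_equal(none$predicted[none$z == 1 & none$time == 2], -0.266)
  ini <- predicted_trajectories(pooled, "initial", z_levels = 1)
  expect_equal(ini$predicted[ini$time == 1], 0)
  expect_equal(ini$predicted[ini$time == 2], -0.0757073662351, tolerance = 1e-10)
  sub <- predicted_trajectories(pooled, "subsequent", z_levels = 1)
  expect_equal(sub$predicted[sub$time == 2], 0)
  expect_equal(sub$predicted[sub$time == 1], -0.1967814696678, tolerance = 1e-10)
})

test_that("sextet validation flags out-of-range and non-PSD input", {
  expect_error(correlation_sextet(r_x1y1 = 1.2), "out of \\[-1, 1\\]")
  expect_error(correlation_sextet(-0.9, -0.9, 0.9, 0.9, 0.9, 0.9),
               "positive semidefinite")
  expect_error(correlation_sextet(r_x1y1 = 0.5, n = 3), "minimum of 4")
  expect_silent(validate_sextets(pooled_to_sextet(se_ed_pooled())))
})
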