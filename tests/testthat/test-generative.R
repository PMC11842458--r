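test_that("implied correlations follow the path-tracing closed form", {
  s0 <- implied_sextet(generative_params(0.7, 0.7, 0.7))
  expect_equal(s0$r_x1x2, 0.49)
  expect_equal(s0$r_y1y2, 0.49)
  expect_equal(s0$r_x1y1, -0.2401)
  expect_equal(s0$r_x2y2, -0.2401)
  expect_equal(s0$r_x1y2, -0.2401)
  expect_equal(s0$r_x2y1, -0.2401)
  s3 <- implied_sextet(generative_params(0.7, 0.7, 0.7, s = 0.3))
  expect_equal(s3$r_x1y1, -0.3301)
  expect_equal(s3$r_x1y2, -0.2401)
  expect_equal(s3$r_x1x2, 0.49)
})

test_that("parameter constraints are enforced at the boundary", {
  expect_error(generative_params(0, 0.5, 0.5), "inside \\(0, 1\\)")
  expect_error(generative_params(0.5, 1, 0.5), "inside \\(0, 1\\)")
  expect_error(generative_params(0.5, 0.5, 0.9, s = 0.6), "exceeds 1")
  expect_error(generative_params(0.5, 0.5, 0.5, s = -0.1), ">= 0")
})

test_that("implied matrices are positive semidefinite across the parameter grid", {
  vals <- seq(0.1, 0.9, length.out = 10)
  worst <- Inf
  for (a in vals) for (b in vals) for (cc in vals) {
    for (s in base::c(0, 0.2, 0.4) [base::c(0, 0.2, 0.4)^2 + cc^2 <= 1]) {
      sx <- implied_sextet(generative_params(a, b, cc, s = s))
      m <- lagtriad:::sextet_matrix(unlist(sx[sextet_cols()]))
      worst <- min(worst, min(eigen(m, symmetric = TRUE, only.values = TRUE)$values))
    }
  }
  expect_gte(worst, -1e-12)
})

test_that("the sign pattern is the spurious signature on the whole grid", {
  vals <- seq(0.1, 0.9, length.out = 6)
  for (a in vals) for (b in vals) for (cc in vals) {
    signs0 <- predicted_signs(generative_params(a, b, cc, s = 0))
    expect_identical(unname(signs0),
                     base::c("negative", "negative", "zero",
                             "negative", "negative", "zero"))
    s <- 0.3
    if (cc^2 + s^2 <= 1 && a * b * (1 - cc^2) > s^2) {
      # inside the confounding-dominant regime: full spurious signature
      signs1 <- predicted_signs(generative_params(a, b, cc, s = s))
      expect_identical(unname(signs1),
                       base::c("negative", "negative", "positive",
                               "negative", "negative", "positive"))
    }
  }
  # outside that regime the adjusted lagged effect flips positive
  flipped <- predicted_signs(generative_params(0.1, 0.1, 0.9, s = 0.3))
  expect_identical(unname(flipped[base::c("b_x_lagged", "b_x_change")]),
                   base::c("positive", "positive"))
  expect_identical(unname(flipped["b_x_reverse"]), "negative")
  # model symmetry: equal a and b give equal effects in both directions
  eff <- effect_sextet(implied_sextet(generative_params(0.6, 0.6, 0.75, s = 0.2)))
  expect_equal(eff$b_x_lagged, eff$b_y_lagged)
  expect_equal(eff$b_x_change, eff$b_y_change)
})

test_that("the sampler is deterministic and leaves the session RNG alone", {
  p <- generative_params(0.7, 0.6, 0.75, s = 0.2, seed = 77)
  d1 <- simulate_sample(p, 50)
  d2 <- simulate_sample(p, 50)
  expect_identical(d1, d2)
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_sample(p, 50))
  expect_identical(.Random.seed, before)
  expect_error(simulate_sample(p, 3), ">= 4")
})

test_that("sample correlations converge to the implied ones", {
  p <- generative_params(0.7, 0.7, 0.7, seed = 2024)
  big <- simulate_sample(p, 1e6)
  got <- sample_sextet(big)
  want <- implied_sextet(p)
  for (col in sextet_cols()) {
    expect_equal(got[[col]], want[[col]], tolerance = 0.005,
                 label = paste0(col, " at n = 1e6"))
  }
  # columns are unit variance by construction
  expect_equal(unname(apply(big, 2, var)), rep(1, 4), tolerance = 0.01)
  # roughly 1/sqrt(n) error decay between n = 1e3 and n = 1e5 on average
  p2 <- generative_params(0.6, 0.7, 0.8, s = 0.2, seed = 31)
  err_at <- function(n, seed) {
    d <- simulate_sample(p2, n, seed = seed)
    mean(abs(unlist(sample_sextet(d)[sextet_cols()]) -
               unlist(implied_sextet(p2)[sextet_cols()])))
  }
  e_small <- mean(vapply(1:8, function(i) err_at(1e3, 100 + i), 0))
  e_big <- mean(vapply(1:8, function(i) err_at(1e5, 200 + i), 0))
  expect_lt(e_big, e_small / 4)
})

test_that("no direct path exists yet the lagged effect is strictly negative", {
  set.seed(6)
  for (i in 1:50) {
    a <- runif(1, 0.1, 0.9); b <- runif(1, 0.1, 0.9); cc <- runif(1, 0.1, 0.9)
    eff <- effect_sextet(implied_sextet(generative_params(a, b, cc)))
    expect_lt(eff$b_x_lagged, 0)
    expect_lt(eff$b_y_lagged, 0)
    expect_identical(eff$b_x_change, 0)
  }
})
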