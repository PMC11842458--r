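# Independent oracles used across the suite.

# Random positive-definite 4x4 correlation matrix via random Gram matrix,
# mapped to the sextet layout. Rejects near-singular draws so closed-form
# denominators stay well away from zero.
random_valid_sextet <- function() {
  repeat {
    w <- matrix(rnorm(4 * 6), nrow = 4)
    s <- w %*% t(w) + diag(4) * 0.05
    d <- diag(1 / sqrt(diag(s)))
    r <- d %*% s %*% d
    dimnames(r) <- list(c("x1", "x2", "y1", "y2"), c("x1", "x2", "y1", "y2"))
    ok <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) > 1e-4 &&
      max(abs(r[upper.tri(r)])) < 0.99
    if (ok) return(r)
  }
}

sextet_from_matrix <- function(r, n = NA_integer_) {
  correlation_sextet(
    r_x1y1 = r["x1", "y1"], r_x2y2 = r["x2", "y2"],
    r_x1x2 = r["x1", "x2"], r_y1y2 = r["y1", "y2"],
    r_x1y2 = r["x1", "y2"], r_x2y1 = r["x2", "y1"],
    n = n, validate = FALSE
  )
}

# Standardized partial coefficient of predictor p1 on outcome, adjusting for
# p2, by solving the two-predictor normal equations on the correlation
# matrix (independent of the package's closed form).
oracle_beta_normal_eq <- function(r, outcome, p1, p2) {
  rp <- r[c(p1, p2), c(p1, p2)]
  ry <- r[c(p1, p2), outcome]
  unname(solve(rp, ry)[1])
}

# Effect-size records for one sample with exactly reproduced correlations:
# mvrnorm(empirical = TRUE) makes the sample moments equal the target.
records_from_matrix <- function(r, sample_id, n) {
  d <- MASS::mvrnorm(n, mu = rep(0, 4), Sigma = r, empirical = TRUE)
  colnames(d) <- c("x1", "x2", "y1", "y2")
  sx <- sample_sextet(tibble::as_tibble(d))
  sx$sample_id <- sample_id
  sx$record_id <- paste0(sample_id, "_E1")
  sextets_to_records(sx)
}

# The published pooled effect rows (the worked-example targets).
published_effects <- function() {
  meta_effects(se_ed_pooled())
}
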