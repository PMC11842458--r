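#' Fisher z transformation
#'
#' Variance-stabilizing transform `z = atanh(r)` applied to correlations and
#' standardized regression effects before pooling; `fisher_z_inv()` maps back
#' via `tanh`. The approximate sampling variance of a transformed value is
#' `1 / (n - 3)` (see [z_variance()]).
#'
#' @param r Numeric vector of correlations (or standardized betas), |r| < 1.
#' @param z Numeric vector on the transformed scale.
#' @return Numeric vector of the same length.
#' @examples
#' fisher_z(0.5)
#' fisher_z_inv(fisher_z(-0.339))
#' @export
fisher_z <- function(r) {
  bad <- which(!is.na(r) & abs(r) >= 1)
  if (length(bad) > 0) {
    abort(sprintf("fisher_z requires |r| < 1; got r = %g", r[bad[1]]))
  }
  atanh(r)
}

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

# Shared guard for the closed-form denominators. Denominators this close to
# zero signal a collinear predictor pair or a zero-variance difference score.
.beta_tol <- 1e-10

#' Closed-form standardized regression effects from two-wave correlations
#'
#' The three effect families used for triangulating whether a prospective
#' association is genuine or spurious, each computed directly from zero-order
#' correlations:
#'
#' * `beta_lagged_adjusted()` — the adjusted cross-lagged effect: the
#'   standardized partial coefficient of X1 predicting Y2 with Y1 as
#'   covariate, `(r_x1y2 - r_x1y1 * r_y1y2) / (1 - r_x1y1^2)`.
#' * `beta_reverse_adjusted()` — the adjusted reverse effect: X1 predicting
#'   Y1 while adjusting for the *subsequent* outcome Y2,
#'   `(r_x1y1 - r_x1y2 * r_y1y2) / (1 - r_x1y2^2)`.
#' * `beta_on_change()` — the difference-score effect: the standardized
#'   regression of the change Y2 - Y1 on X1, with unit variances at both
#'   waves, `(r_x1y2 - r_x1y1) / sqrt(2 * (1 - r_y1y2))`.
#'
#' In the adjusted forms the two arguments after the numerator correlation
#' are the correlation between the two predictors and the correlation of the
#' covariate with the outcome; each function equals the solution of the
#' two-predictor normal equations on the implied correlation matrix.
#'
#' Under a pure common-cause data-generating process the cross-lagged and
#' concurrent correlations coincide, so `beta_on_change()` is exactly zero
#' while both adjusted forms are negative — the spurious signature.
#'
#' @param r_x1y2 Cross-lagged correlation (predictor at wave 1, outcome at
#'   wave 2).
#' @param r_x1y1 Concurrent wave-1 correlation.
#' @param r_y1y2 Auto-correlation of the outcome construct.
#' @param tol Degenerate-denominator tolerance.
#' @return Numeric vector of standardized betas (NA where any input is NA).
#' @examples
#' beta_lagged_adjusted(-0.266, -0.339, 0.587)
#' beta_reverse_adjusted(-0.339, -0.266, 0.587)
#' beta_on_change(-0.266, -0.339, 0.587)
#' @export
beta_lagged_adjusted <- function(r_x1y2, r_x1y1, r_y1y2, tol = .beta_tol) {
  check_r_range(r_x1y2, r_x1y1, r_y1y2)
  den <- 1 - r_x1y1^2
  check_denominator(den, tol, "collinear predictors: |r_x1y1| is (numerically) 1")
  (r_x1y2 - r_x1y1 * r_y1y2) / den
}

#' @rdname beta_lagged_adjusted
#' @export
beta_reverse_adjusted <- function(r_x1y1, r_x1y2, r_y1y2, tol = .beta_tol) {
  check_r_range(r_x1y1, r_x1y2, r_y1y2)
  den <- 1 - r_x1y2^2
  check_denominator(den, tol, "collinear predictors: |r_x1y2| is (numerically) 1")
  (r_x1y1 - r_x1y2 * r_y1y2) / den
}

#' @rdname beta_lagged_adjusted
#' @export
beta_on_change <- function(r_x1y2, r_x1y1, r_y1y2, tol = .beta_tol) {
  check_r_range(r_x1y2, r_x1y1, r_y1y2)
  den <- 2 * (1 - r_y1y2)
  check_denominator(den, tol, "zero-variance difference score: r_y1y2 is (numerically) 1")
  (r_x1y2 - r_x1y1) / sqrt(den)
}

check_r_range <- function(...) {
  vals <- c(...)
  bad <- which(!is.na(vals) & abs(vals) > 1)
  if (length(bad) > 0) {
    abort(sprintf("correlation out of [-1, 1]: %g", vals[bad[1]]))
  }
  invisible(NULL)
}

check_denominator <- function(den, tol, msg) {
  if (any(!is.na(den) & den <= tol)) {
    abort(paste0("degenerate input: ", msg))
  }
  invisible(NULL)
}

#' Derive the six regression effects from correlation sextets
#'
#' Applies the three closed forms of [beta_lagged_adjusted()] in both causal
#' directions to each row of a sextet table: the X -> Y direction uses
#' (`r_x1y2`, `r_x1y1`, `r_y1y2`), the Y -> X direction uses
#' (`r_x2y1`, `r_x1y1`, `r_x1x2`). Effects whose inputs are missing come back
#' `NA`; a degenerate denominator in one effect does not abort the others.
#'
#' @param data Data frame with the [sextet_cols()] columns (extra columns,
#'   e.g. `sample_id` or `n`, are carried through).
#' @param tol Degenerate-denominator tolerance.
#' @return `data` as a tibble with six new columns: `b_x_lagged`,
#'   `b_x_reverse`, `b_x_change` (X -> Y) and `b_y_lagged`, `b_y_reverse`,
#'   `b_y_change` (Y -> X). A degenerate denominator yields `NaN` for that
#'   effect with a warning naming the row.
#' @examples
#' pooled <- correlation_sextet(
#'   r_x1y1 = -0.339, r_x2y2 = -0.398, r_x1x2 = 0.572,
#'   r_y1y2 = 0.587, r_x1y2 = -0.266, r_x2y1 = -0.273, n = 19187
#' )
#' effect_sextet(pooled)
#' @export
effect_sextet <- function(data, tol = .beta_tol) {
  stopifnot(is.data.frame(data))
  validate_sextets(data)
  safe <- function(f, a, b, cc) {
    purrr::pmap_dbl(list(a, b, cc), function(u, v, w) {
      tryCatch(f(u, v, w, tol = tol), error = function(e) NaN)
    })
  }
  out <- dplyr::mutate(
    as_tibble(data),
    b_x_lagged  = safe(beta_lagged_adjusted, .data$r_x1y2, .data$r_x1y1, .data$r_y1y2),
    b_x_reverse = safe(beta_reverse_adjusted, .data$r_x1y1, .data$r_x1y2, .data$r_y1y2),
    b_x_change  = safe(beta_on_change, .data$r_x1y2, .data$r_x1y1, .data$r_y1y2),
    b_y_lagged  = safe(beta_lagged_adjusted, .data$r_x2y1, .data$r_x1y1, .data$r_x1x2),
    b_y_reverse = safe(beta_reverse_adjusted, .data$r_x1y1, .data$r_x2y1, .data$r_x1x2),
    b_y_change  = safe(beta_on_change, .data$r_x2y1, .data$r_x1y1, .data$r_x1x2)
  )
  n_degenerate <- sum(vapply(out[beta_cols()], function(x) sum(is.nan(x)), 0L))
  if (n_degenerate > 0) {
    warn(sprintf("%d effect(s) had degenerate denominators and are NaN", n_degenerate))
  }
  out
}

#' @rdname sextet_cols
#' @export
beta_cols <- function() {
  c("b_x_lagged", "b_x_reverse", "b_x_change",
    "b_y_lagged", "b_y_reverse", "b_y_change")
}

#' Predicted standardized outcome trajectories under three conditionings
#'
#' For a correlation sextet, predicts the standardized outcome (construct Y)
#' at waves 1 and 2 for individuals at given standard scores of the predictor
#' X1, under three conditioning schemes:
#'
#' * `"initial"` — condition on the mean initial outcome: wave-1 prediction
#'   is 0, wave-2 prediction is `beta_lagged_adjusted * z`;
#' * `"subsequent"` — condition on the mean subsequent outcome: wave-2
#'   prediction is 0, wave-1 prediction is `beta_reverse_adjusted * z`;
#' * `"none"` — no conditioning: predictions are `r_x1y1 * z` and
#'   `r_x1y2 * z`.
#'
#' The wave-to-wave slopes these trajectories display disagree across
#' conditionings when the underlying association is spurious: conditioning on
#' the initial outcome suggests a decreasing effect while the other two
#' suggest an increasing one.
#'
#' @param data One-row data frame with the needed sextet columns.
#' @param conditioning One of `"initial"`, `"subsequent"`, `"none"`.
#' @param z_levels Predictor standard scores (default low / mean / high).
#' @param direction `"x_on_y"` (default) predicts Y from X1; `"y_on_x"`
#'   swaps the construct roles.
#' @return Tibble with columns `conditioning`, `z`, `time` (1 or 2),
#'   `predicted`.
#' @examples
#' pooled <- correlation_sextet(
#'   r_x1y1 = -0.339, r_y1y2 = 0.587, r_x1y2 = -0.266
#' )
#' predicted_trajectories(pooled, "initial")
#' @export
predicted_trajectories <- function(data,
                                   conditioning = c("initial", "subsequent", "none"),
                                   z_levels = c(-1, 0, 1),
                                   direction = c("x_on_y", "y_on_x")) {
  conditioning <- match.arg(conditioning)
  direction <- match.arg(direction)
  stopifnot(is.data.frame(data), nrow(data) == 1)
  s <- as_tibble(data)
  if (direction == "y_on_x") {
    # swap construct roles: cross-lag Y1 -> X2, outcome autocorrelation of X
    s <- dplyr::mutate(s, r_x1y2 = .data$r_x2y1, r_y1y2 = .data$r_x1x2)
  }
  pred <- switch(conditioning,
    initial = {
      b <- beta_lagged_adjusted(s$r_x1y2, s$r_x1y1, s$r_y1y2)
      list(t1 = 0 * z_levels, t2 = b * z_levels)
    },
    subsequent = {
      b <- beta_reverse_adjusted(s$r_x1y1, s$r_x1y2, s$r_y1y2)
      list(t1 = b * z_levels, t2 = 0 * z_levels)
    },
    none = list(t1 = s$r_x1y1 * z_levels, t2 = s$r_x1y2 * z_levels)
  )
  tibble(
    conditioning = conditioning,
    z = rep(z_levels, 2L),
    time = rep(c(1L, 2L), each = length(z_levels)),
    predicted = c(pred$t1, pred$t2)
  )
}
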