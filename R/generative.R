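#' Parameters of the latent common-cause generative model
#'
#' The model that demonstrates how a fully spurious cross-lagged pattern
#' arises. A standard-normal common cause CC drives a general (trait-like)
#' level of each construct with opposite signs — `gX = a*CC + e`,
#' `gY = -b*CC + e` — and each general level loads with `c` on its two
#' measured occasions. Optionally, a wave-specific occasion-state factor
#' loads `+s` on the X measure and `-s` on the Y measure of the same wave,
#' inflating concurrent relative to cross-lagged correlations. All residuals
#' are independent normals scaled so every variable has unit variance, so
#' correlations and standardized coefficients coincide. There are no direct
#' paths between the constructs.
#'
#' @param a Loading of the common cause on the general X level, in (0, 1).
#' @param b Magnitude of the (negative) loading on the general Y level,
#'   in (0, 1).
#' @param c Loading of each general level on its two occasions, in (0, 1).
#' @param s Occasion-state strength, >= 0 (default 0 = off); `c^2 + s^2`
#'   must not exceed 1 so the indicator residual variance stays nonnegative.
#' @param seed Optional integer seed stored for [simulate_sample()].
#' @return A one-row tibble of class `lagtriad_params`.
#' @examples
#' generative_params(0.7, 0.7, 0.7, s = 0.3)
#' @export
generative_params <- function(a, b, c, s = 0, seed = NA_integer_) {
  for (nm in base::c("a", "b", "c")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1 || is.na(val) || val <= 0 || val >= 1) {
      abort(sprintf("parameter %s must lie strictly inside (0, 1); got %s", nm, format(val)))
    }
  }
  if (!is.numeric(s) || length(s) != 1 || is.na(s) || s < 0) {
    abort("occasion-state strength s must be >= 0")
  }
  if (c^2 + s^2 > 1) {
    abort(sprintf("c^2 + s^2 = %.3f exceeds 1: indicator residual variance would be negative", c^2 + s^2))
  }
  structure(
    tibble(a = a, b = b, c = c, s = s, seed = as.integer(seed)),
    class = c("lagtriad_params", class(tibble()))
  )
}

#' Population correlations implied by the common-cause model
#'
#' Closed-form path-traced correlations: both auto-correlations equal `c^2`;
#' both cross-lagged correlations equal `-a*b*c^2` (the common cause is the
#' only cross-construct route); both concurrent correlations equal
#' `-a*b*c^2 - s^2` (the occasion state adds only within wave). No sampling
#' is involved.
#'
#' @param params A [generative_params()] object.
#' @return A one-row correlation sextet tibble (see [correlation_sextet()]),
#'   with `n = NA`.
#' @examples
#' implied_sextet(generative_params(0.7, 0.7, 0.7))
#' @export
implied_sextet <- function(params) {
  stopifnot(inherits(params, "lagtriad_params"))
  cross <- -params$a * params$b * params$c^2
  concurrent <- cross - params$s^2
  auto <- params$c^2
  correlation_sextet(
    r_x1y1 = concurrent, r_x2y2 = concurrent,
    r_x1x2 = auto, r_y1y2 = auto,
    r_x1y2 = cross, r_x2y1 = cross
  )
}

#' Draw an individual-level sample from the common-cause model
#'
#' Simulates `n` individuals: common cause, general levels, optional
#' per-wave occasion states, and the four measured variables, each scaled to
#' unit population variance. Deterministic given `seed`; the calling R
#' session's RNG state is left untouched.
#'
#' @param params A [generative_params()] object.
#' @param n Sample size, integer >= 4.
#' @param seed Integer seed; defaults to the seed stored in `params`.
#' @return Tibble with `n` rows and columns `x1`, `x2`, `y1`, `y2`.
#' @examples
#' simulate_sample(generative_params(0.7, 0.7, 0.7, seed = 1), n = 100)
#' @export
simulate_sample <- function(params, n, seed = params$seed) {
  stopifnot(inherits(params, "lagtriad_params"))
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 4) {
    abort("sample size n must be an integer >= 4")
  }
  n <- as.integer(n)
  local_seed(seed)
  a <- params$a; b <- params$b; cc_load <- params$c; s <- params$s
  res_ind <- sqrt(1 - cc_load^2 - s^2)
  cc <- rnorm(n)
  g_x <- a * cc + sqrt(1 - a^2) * rnorm(n)
  g_y <- -b * cc + sqrt(1 - b^2) * rnorm(n)
  st1 <- rnorm(n)
  st2 <- rnorm(n)
  tibble(
    x1 = cc_load * g_x + s * st1 + res_ind * rnorm(n),
    x2 = cc_load * g_x + s * st2 + res_ind * rnorm(n),
    y1 = cc_load * g_y - s * st1 + res_ind * rnorm(n),
    y2 = cc_load * g_y - s * st2 + res_ind * rnorm(n)
  )
}

# Run code under a given seed without disturbing the caller's RNG stream.
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed) || is.na(seed)) return(invisible(NULL))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  if (has_seed) {
    withr::defer(assign(".Random.seed", old, envir = globalenv()), envir = env)
  } else {
    withr::defer(rm(".Random.seed", envir = globalenv()), envir = env)
  }
  invisible(NULL)
}

#' Sample correlation sextet of an individual-level dataset
#'
#' @param data Data frame with columns `x1`, `x2`, `y1`, `y2`.
#' @return A one-row correlation sextet tibble with `n = nrow(data)`.
#' @export
sample_sextet <- function(data) {
  stopifnot(all(c("x1", "x2", "y1", "y2") %in% names(data)))
  r <- cor(data[, c("x1", "x2", "y1", "y2")])
  correlation_sextet(
    r_x1y1 = r["x1", "y1"], r_x2y2 = r["x2", "y2"],
    r_x1x2 = r["x1", "x2"], r_y1y2 = r["y1", "y2"],
    r_x1y2 = r["x1", "y2"], r_x2y1 = r["x2", "y1"],
    n = nrow(data), validate = FALSE
  )
}

#' Sign pattern of the six effects implied by the common-cause model
#'
#' Evaluates [effect_sextet()] on the exact implied correlations and labels
#' each effect `"negative"`, `"zero"` (|effect| below `tol`), or
#' `"positive"`. Without an occasion state (`s = 0`) the pattern is
#' (negative, negative, zero, negative, negative, zero): the adjusted
#' cross-lagged and adjusted reverse effects are strictly negative even
#' though no direct path exists, while the difference-score effects vanish.
#' With `s > 0` the difference-score effects turn positive, giving the full
#' spurious signature (negative, negative, positive, twice) as long as the
#' confounding dominates the occasion state, i.e. `a*b*(1 - c^2) > s^2`
#' (the lagged numerator is `-a*b*c^2*(1 - c^2) + s^2*c^2`). A state factor
#' strong enough to break that inequality flips the adjusted lagged effects
#' positive; the reverse-adjusted effects stay negative for every valid
#' parameter value.
#'
#' @param params A [generative_params()] object.
#' @param tol Absolute threshold below which an effect counts as zero.
#' @return Named character vector over [beta_cols()].
#' @examples
#' predicted_signs(generative_params(0.5, 0.5, 0.5))
#' predicted_signs(generative_params(0.7, 0.7, 0.7, s = 0.3))
#' @export
predicted_signs <- function(params, tol = 1e-12) {
  eff <- effect_sextet(implied_sextet(params))
  vals <- unlist(eff[beta_cols()])
  out <- ifelse(abs(vals) < tol, "zero", ifelse(vals > 0, "positive", "negative"))
  setNames(out, beta_cols())
}
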