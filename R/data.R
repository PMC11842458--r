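#' Published pooled two-wave associations between self-esteem and eating pathology
#'
#' The twelve pooled estimates (six zero-order correlations, six derived
#' standardized regression effects) from a published multilevel
#' meta-analysis of two-wave panels of self-esteem (X) and eating pathology
#' (Y), with 95% CIs, heterogeneity statistics, and counts. Shipped as a
#' plain-text table; it is the canonical worked example for the closed-form
#' effect derivations — applying [effect_sextet()] to the six pooled
#' correlations reproduces the six pooled regression effects within 0.01.
#'
#' @return Tibble with columns `association`, `K`, `NE`, `N`, `estimate`,
#'   `ci_low`, `ci_high`, `Q`, `df`, `I2`, `I2_low`, `I2_high`.
#' @examples
#' pooled <- se_ed_pooled()
#' effect_sextet(pooled_to_sextet(pooled))
#' @export
se_ed_pooled <- function() {
  path <- system.file("extdata", "se_ed_pooled.csv", package = "lagtriad",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Collapse a pooled twelve-row table to a correlation sextet
#'
#' Takes the six correlation rows of a pooled table (such as
#' [se_ed_pooled()] or a [meta_table()] result) and arranges them as a
#' one-row sextet, with `n` set to the largest per-row participant total.
#'
#' @param pooled Data frame with columns `association` and `estimate`
#'   covering the six [sextet_cols()], and optionally `N`.
#' @return One-row correlation sextet tibble.
#' @export
pooled_to_sextet <- function(pooled) {
  stopifnot(all(c("association", "estimate") %in% names(pooled)))
  cors <- pooled[match(sextet_cols(), pooled$association), ]
  if (anyNA(cors$association)) abort("pooled table lacks some correlation rows")
  n <- if ("N" %in% names(pooled)) suppressWarnings(max(cors$N, na.rm = TRUE)) else NA_integer_
  correlation_sextet(
    r_x1y1 = cors$estimate[1], r_x2y2 = cors$estimate[2],
    r_x1x2 = cors$estimate[3], r_y1y2 = cors$estimate[4],
    r_x1y2 = cors$estimate[5], r_x2y1 = cors$estimate[6],
    n = n
  )
}
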