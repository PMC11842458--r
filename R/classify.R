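#' Predicted sign grid for the six triangulation effects
#'
#' The expected sign of each of the six regression effects under two
#' competing hypotheses about a negatively associated construct pair:
#' *genuine* reciprocal decreasing effects versus *spurious* effects arising
#' from correlated residuals and regression to the mean. For the default
#' negative cross-construct association the grid is:
#'
#' | effect       | genuine  | spurious         |
#' |--------------|----------|------------------|
#' | `b_x_lagged` | negative | negative         |
#' | `b_x_reverse`| positive | negative         |
#' | `b_x_change` | negative | zero_or_positive |
#' | `b_y_lagged` | negative | negative         |
#' | `b_y_reverse`| positive | negative         |
#' | `b_y_change` | negative | zero_or_positive |
#'
#' For a positively associated pair (`association_sign = 1`) every label is
#' mirrored (negative <-> positive, zero_or_positive <-> zero_or_negative).
#'
#' @param association_sign -1 (default) if the constructs correlate
#'   negatively, +1 if positively.
#' @return Tibble with columns `effect`, `genuine`, `spurious`, and an
#'   `association_sign` attribute.
#' @export
prediction_grid <- function(association_sign = -1) {
  stopifnot(association_sign %in% c(-1, 1))
  grid <- tibble(
    effect = beta_cols(),
    genuine = c("negative", "positive", "negative",
                "negative", "positive", "negative"),
    spurious = c("negative", "negative", "zero_or_positive",
                 "negative", "negative", "zero_or_positive")
  )
  if (association_sign == 1) {
    flip <- c(
      negative = "positive", positive = "negative",
      zero_or_positive = "zero_or_negative", zero_or_negative = "zero_or_positive"
    )
    grid$genuine <- unname(flip[grid$genuine])
    grid$spurious <- unname(flip[grid$spurious])
  }
  attr(grid, "association_sign") <- association_sign
  grid
}

sign_label_matches <- function(label, category) {
  dplyr::case_when(
    is.na(category) | category == "non_assessable" ~ NA,
    label == "negative" ~ category == "negative",
    label == "positive" ~ category == "positive",
    label == "zero_or_positive" ~ category %in% c("positive", "indistinguishable"),
    label == "zero_or_negative" ~ category %in% c("negative", "indistinguishable")
  )
}

#' Classify an observed effect pattern against the prediction grid
#'
#' Compares six estimated effects (point estimate plus 95% CI) with the
#' signs predicted under the genuine-decreasing and the spurious hypothesis.
#' An effect is *significantly negative* if its CI upper bound is below 0,
#' *significantly positive* if the lower bound is above 0, and otherwise
#' *indistinguishable from zero*. "Zero or positive" admits both the
#' positive and the indistinguishable category (mirrored for "zero or
#' negative").
#'
#' @param effects Data frame with columns `effect` (values among
#'   [beta_cols()]), `estimate`, `ci_low`, `ci_high`. Effects absent from
#'   the table, or with missing estimate or CI, are marked non-assessable
#'   and excluded from matching; the verdict is then flagged partial.
#' @param grid A [prediction_grid()].
#' @return A `lagtriad_verdict`: list with `$table` (per-effect categories
#'   and match flags), `$label` (one of `consistent_with_genuine`,
#'   `consistent_with_spurious`, `consistent_with_both`,
#'   `consistent_with_neither`), `$partial`, `$n_assessable`.
#' @examples
#' eff <- tibble::tibble(
#'   effect = beta_cols(),
#'   estimate = c(-0.079, -0.202, 0.083, -0.088, -0.202, 0.068),
#'   ci_low = c(-0.096, -0.236, 0.054, -0.102, -0.243, 0.043),
#'   ci_high = c(-0.062, -0.167, 0.112, -0.075, -0.161, 0.094)
#' )
#' classify_pattern(eff)
#' @export
classify_pattern <- function(effects, grid = prediction_grid()) {
  stopifnot(is.data.frame(effects),
            all(c("effect", "estimate", "ci_low", "ci_high") %in% names(effects)))
  unknown <- setdiff(effects$effect, beta_cols())
  if (length(unknown) > 0) {
    abort(paste0("unknown effect label(s): ", paste(unknown, collapse = ", ")))
  }
  tab <- dplyr::left_join(grid, as_tibble(effects), by = "effect")
  tab <- dplyr::mutate(
    tab,
    category = dplyr::case_when(
      is.na(.data$estimate) | is.na(.data$ci_low) | is.na(.data$ci_high) ~ "non_assessable",
      .data$ci_high < 0 ~ "negative",
      .data$ci_low > 0 ~ "positive",
      TRUE ~ "indistinguishable"
    ),
    matches_genuine = sign_label_matches(.data$genuine, .data$category),
    matches_spurious = sign_label_matches(.data$spurious, .data$category)
  )
  assessable <- tab$category != "non_assessable"
  g <- all(tab$matches_genuine[assessable])
  s <- all(tab$matches_spurious[assessable])
  label <- if (sum(assessable) == 0) {
    "consistent_with_neither"
  } else if (g && s) {
    "consistent_with_both"
  } else if (g) {
    "consistent_with_genuine"
  } else if (s) {
    "consistent_with_spurious"
  } else {
    "consistent_with_neither"
  }
  structure(
    list(
      table = dplyr::select(
        tab, "effect", "genuine", "spurious", "estimate", "ci_low",
        "ci_high", "category", "matches_genuine", "matches_spurious"
      ),
      label = label,
      partial = any(!assessable),
      n_assessable = sum(assessable)
    ),
    class = "lagtriad_verdict"
  )
}

#' @export
print.lagtriad_verdict <- function(x, ...) {
  cat("Triangulation verdict:", x$label,
      if (x$partial) "(partial: some effects non-assessable)" else "", "\n")
  print(as.data.frame(x$table), digits = 3)
  invisible(x)
}

#' @rdname classify_pattern
#' @param x A `lagtriad_verdict`.
#' @param ... Unused.
#' @method tidy lagtriad_verdict
#' @export
tidy.lagtriad_verdict <- function(x, ...) x$table

#' @rdname classify_pattern
#' @method glance lagtriad_verdict
#' @export
glance.lagtriad_verdict <- function(x, ...) {
  tibble(
    label = x$label,
    partial = x$partial,
    n_assessable = x$n_assessable,
    n_match_genuine = sum(x$table$matches_genuine, na.rm = TRUE),
    n_match_spurious = sum(x$table$matches_spurious, na.rm = TRUE)
  )
}
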