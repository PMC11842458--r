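#' The twelve pooled associations and their display labels
#'
#' Canonical ordering of the six zero-order correlations and six derived
#' regression effects reported by [meta_table()], with display labels in the
#' field's notation (X = self-esteem, Y = eating pathology in the motivating
#' application).
#'
#' @return Tibble with columns `association`, `label`, `type`
#'   (`"correlation"` or `"beta"`), `row`.
#' @export
association_labels <- function() {
  tibble(
    association = c(sextet_cols(), beta_cols()),
    label = c(
      "r(X1,Y1)", "r(X2,Y2)", "r(X1,X2)", "r(Y1,Y2)", "r(X1,Y2)", "r(X2,Y1)",
      "b(X1,Y2.Y1)", "b(X1,Y1.Y2)", "b(X1,Y2-Y1)",
      "b(Y1,X2.X1)", "b(Y1,X1.X2)", "b(Y1,X2-X1)"
    ),
    type = rep(c("correlation", "beta"), each = 6L),
    row = 1:12
  )
}

#' Sampling variance of a Fisher z transformed value
#'
#' The large-sample approximation `1 / (n - 3)` used to weight transformed
#' correlations (and, by the same approximation, transformed standardized
#' regression effects) in inverse-variance pooling.
#'
#' @param n Participant count, integer >= 4.
#' @return Numeric vector of variances on the z scale.
#' @examples
#' z_variance(103)
#' @export
z_variance <- function(n) {
  if (any(!is.na(n) & n < 4)) {
    abort(sprintf("z_variance requires n >= 4; got n = %d", n[which(!is.na(n) & n < 4)[1]]))
  }
  1 / (n - 3)
}

#' First pooling step: fixed-effect aggregation within sample
#'
#' Collapses the multiple effect sizes a sample contributes for the same
#' association into one estimate by the inverse-variance fixed-effect mean,
#' with pooled variance `1 / sum(1 / v)`. A sample with a single record
#' passes through unchanged. This is the first step of the two-step
#' multilevel analysis; it prevents samples contributing many effect sizes
#' from dominating the across-sample pool and counteracts artificially
#' reduced heterogeneity.
#'
#' @param data Data frame with numeric columns `z` (Fisher z values) and `v`
#'   (their variances).
#' @param by Character vector of grouping columns (default
#'   `c("association", "sample_id")`); columns absent from `data` are
#'   ignored, so ungrouped input pools to a single row.
#' @return Tibble with the grouping columns plus pooled `z`, `v`, and `ne`
#'   (records pooled).
#' @examples
#' pool_within_sample(tibble::tibble(z = c(0, 0.3), v = c(0.01, 0.02)))
#' @export
pool_within_sample <- function(data, by = c("association", "sample_id")) {
  stopifnot(is.data.frame(data), all(c("z", "v") %in% names(data)))
  if (nrow(data) == 0) abort("no records to pool")
  if (any(!is.finite(data$z)) || any(!is.finite(data$v)) || any(data$v <= 0)) {
    abort("z and v must be finite with v > 0")
  }
  by <- intersect(by, names(data))
  dplyr::summarise(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(by))),
    ne = dplyr::n(),
    z = sum(.data$z / .data$v) / sum(1 / .data$v),
    v = 1 / sum(1 / .data$v),
    .groups = "drop"
  )
}

#' Second pooling step: random-effects meta-analysis across samples
#'
#' Pools one z-scale estimate per independent sample under a random-effects
#' model. The between-sample variance tau^2 is estimated by REML (or
#' DerSimonian-Laird on request), the pooled estimate uses weights
#' `1 / (v + tau^2)`, and the 95% CI uses the normal quantile on the z
#' scale. Cochran's Q is the fixed-effect weighted sum of squared deviations
#' (reference chi-square with K - 1 df), the point estimate of I^2 is
#' `max(0, (Q - df) / Q) * 100`, and the I^2 interval is derived from the
#' Q-profile confidence interval for tau^2. Estimate and CI are
#' back-transformed through the inverse Fisher z for reporting.
#'
#' Model fitting is delegated to [metafor::rma()].
#'
#' @param data Data frame with columns `z` and `v`, one row per independent
#'   sample (use [pool_within_sample()] first when samples contribute
#'   several effect sizes).
#' @param method tau^2 estimator: `"REML"` (default) or `"DL"`.
#' @param n_total Optional total participant count, carried into the result.
#' @param ne_total Optional total number of effect sizes, carried into the
#'   result (defaults to the number of rows).
#' @return A `lagtriad_pool`: one-row tibble with `estimate`, `ci_low`,
#'   `ci_high` (back-transformed), `z`, `se_z`, `tau2`, `Q`, `df`,
#'   `Q_pvalue`, `I2`, `I2_low`, `I2_high`, `K`, `NE`, `N`.
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(z = rnorm(10, 0.3, 0.05), v = 0.01)
#' random_effects_pool(d)
#' @export
random_effects_pool <- function(data, method = c("REML", "DL"),
                                n_total = NA_integer_, ne_total = NULL) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data), all(c("z", "v") %in% names(data)))
  K <- nrow(data)
  if (K < 2) {
    abort("random_effects_pool needs K >= 2 samples; report a single sample by pass-through instead")
  }
  # damped step size makes Fisher scoring robust on ill-conditioned inputs
  fit <- metafor::rma(yi = data$z, vi = data$v, method = method, test = "z",
                      control = list(stepadj = 0.5, maxiter = 1000))
  w_fe <- 1 / data$v
  z_fe <- sum(w_fe * data$z) / sum(w_fe)
  Q <- sum(w_fe * (data$z - z_fe)^2)
  df <- K - 1
  I2 <- if (Q <= .Machine$double.eps) 0 else max(0, (Q - df) / Q) * 100
  i2_ci <- q_profile_i2_ci(fit)
  structure(
    tibble(
      estimate = fisher_z_inv(as.numeric(fit$beta)),
      ci_low = fisher_z_inv(fit$ci.lb),
      ci_high = fisher_z_inv(fit$ci.ub),
      z = as.numeric(fit$beta),
      se_z = fit$se,
      tau2 = fit$tau2,
      Q = Q,
      df = as.integer(df),
      Q_pvalue = pchisq(Q, df = df, lower.tail = FALSE),
      I2 = I2,
      I2_low = i2_ci[1],
      I2_high = i2_ci[2],
      K = K,
      NE = as.integer(ne_total %||% K),
      N = as.integer(n_total)
    ),
    class = c("lagtriad_pool", class(tibble())))
}

# I^2 interval from the Q-profile interval for tau^2 (metafor's confint).
q_profile_i2_ci <- function(fit) {
  ci <- tryCatch(metafor::confint.rma.uni(fit), error = function(e) NULL)
  if (is.null(ci)) return(c(NA_real_, NA_real_))
  rn <- rownames(ci$random)
  i2_row <- grep("^I\\^2", rn)
  if (length(i2_row) == 0) return(c(NA_real_, NA_real_))
  unname(ci$random[i2_row[1], c("ci.lb", "ci.ub")])
}

#' @rdname random_effects_pool
#' @param x A `lagtriad_pool`.
#' @param ... Unused.
#' @method glance lagtriad_pool
#' @export
glance.lagtriad_pool <- function(x, ...) as_tibble(x)

#' Full two-step meta-analytic table of the twelve associations
#'
#' Runs the whole pooling pipeline on a long table of study-level effect
#' sizes: derives the six regression effects from each record's correlation
#' sextet, Fisher z transforms every value, aggregates within sample by the
#' fixed-effect inverse-variance mean, pools across samples by REML
#' random-effects meta-analysis, and reports one row per association with
#' estimate, 95% CI, heterogeneity statistics, and the bookkeeping counts
#' K (samples), NE (effect sizes), N (participants).
#'
#' @param records Long-format data frame with columns `sample_id`,
#'   `record_id`, `association` (values among [sextet_cols()]), `value`,
#'   `n`. Regression-effect records are derived internally; correlation
#'   records are the input.
#' @param method tau^2 estimator passed to [random_effects_pool()].
#' @return A `lagtriad_meta` tibble with 12 rows in the order of
#'   [association_labels()]. Associations with a single contributing sample
#'   are reported by pass-through with heterogeneity columns `NA`;
#'   associations with no records have `NA` estimates and zero counts.
#' @examples
#' cfg <- scenario_config(K = 6, seed = 7)
#' meta_table(generate_meta_dataset(cfg))
#' @export
meta_table <- function(records, method = c("REML", "DL")) {
  method <- match.arg(method)
  check_records(records)
  beta_records <- derive_beta_records(records)
  all_records <- dplyr::bind_rows(
    dplyr::select(as_tibble(records), "sample_id", "record_id", "association", "value", "n"),
    beta_records
  )
  n_out <- sum(abs(all_records$value) >= 1, na.rm = TRUE)
  if (n_out > 0) {
    warn(sprintf("%d effect size(s) with |value| >= 1 cannot be z-transformed and were dropped", n_out))
  }
  all_records <- dplyr::filter(all_records, !is.na(.data$value), abs(.data$value) < 1)
  all_records <- dplyr::mutate(all_records, z = fisher_z(.data$value), v = z_variance(.data$n))

  per_sample <- pool_within_sample(all_records)
  sample_n <- dplyr::summarise(
    dplyr::group_by(all_records, .data$association, .data$sample_id),
    n_sample = max(.data$n), .groups = "drop"
  )
  per_sample <- dplyr::left_join(per_sample, sample_n, by = c("association", "sample_id"))

  pools <- lapply(split(per_sample, per_sample$association), function(d) {
    K <- nrow(d)
    ne <- sum(d$ne)
    n_tot <- sum(d$n_sample)
    if (K == 1) {
      tibble(
        estimate = fisher_z_inv(d$z), ci_low = fisher_z_inv(d$z - 1.96 * sqrt(d$v)),
        ci_high = fisher_z_inv(d$z + 1.96 * sqrt(d$v)),
        z = d$z, se_z = sqrt(d$v), tau2 = NA_real_, Q = NA_real_,
        df = 0L, Q_pvalue = NA_real_, I2 = NA_real_, I2_low = NA_real_,
        I2_high = NA_real_, K = 1L, NE = as.integer(ne), N = as.integer(n_tot)
      )
    } else {
      as_tibble(random_effects_pool(d, method = method, n_total = n_tot, ne_total = ne))
    }
  })
  out <- dplyr::bind_rows(pools, .id = "association")
  out <- dplyr::left_join(association_labels(), out, by = "association")
  out <- dplyr::mutate(
    out,
    K = dplyr::coalesce(.data$K, 0L),
    NE = dplyr::coalesce(.data$NE, 0L)
  )
  out <- dplyr::arrange(out, .data$row)
  attr(out, "samples") <- per_sample
  class(out) <- c("lagtriad_meta", class(tibble()))
  out
}

check_records <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("sample_id", "record_id", "association", "value", "n")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("records are missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(records) == 0) abort("empty record set")
  unknown <- setdiff(unique(records$association), sextet_cols())
  if (length(unknown) > 0) {
    abort(paste0("unknown association label(s): ", paste(unknown, collapse = ", ")))
  }
  if (any(!is.na(records$n) & records$n < 4)) {
    abort("records with n < 4 are not admissible (Fisher variance 1/(n-3) must be positive)")
  }
  invisible(records)
}

# One beta record per computable effect of each (sample_id, record_id) sextet.
derive_beta_records <- function(records) {
  wide <- records_to_sextets(records)
  eff <- suppressWarnings(effect_sextet(wide))
  long <- tidyr::pivot_longer(
    dplyr::select(eff, "sample_id", "record_id", "n", dplyr::all_of(beta_cols())),
    cols = dplyr::all_of(beta_cols()),
    names_to = "association", values_to = "value"
  )
  dplyr::select(
    dplyr::filter(long, is.finite(.data$value)),
    "sample_id", "record_id", "association", "value", "n"
  )
}

#' Reshape between long effect-size records and wide correlation sextets
#'
#' `records_to_sextets()` pivots long records (one row per correlation) to
#' one row per (sample_id, record_id) with the [sextet_cols()] columns;
#' `sextets_to_records()` is the inverse, dropping missing correlations.
#'
#' @param records Long-format records (`sample_id`, `record_id`,
#'   `association`, `value`, `n`).
#' @param sextets Wide table with `sample_id`, `record_id`, `n` and the
#'   [sextet_cols()] columns.
#' @return A tibble in the other layout.
#' @export
records_to_sextets <- function(records) {
  wide <- tidyr::pivot_wider(
    as_tibble(records),
    id_cols = c("sample_id", "record_id", "n"),
    names_from = "association", values_from = "value"
  )
  for (col in setdiff(sextet_cols(), names(wide))) wide[[col]] <- NA_real_
  dplyr::select(wide, "sample_id", "record_id", "n", dplyr::all_of(sextet_cols()))
}

#' @rdname records_to_sextets
#' @export
sextets_to_records <- function(sextets) {
  stopifnot(all(c("sample_id", "record_id", "n") %in% names(sextets)))
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(sextets), "sample_id", "record_id", "n",
                  dplyr::all_of(sextet_cols())),
    cols = dplyr::all_of(sextet_cols()),
    names_to = "association", values_to = "value"
  )
  dplyr::select(
    dplyr::filter(long, !is.na(.data$value)),
    "sample_id", "record_id", "association", "value", "n"
  )
}

#' Extract the six regression-effect rows of a meta table for classification
#'
#' Convenience bridge between [meta_table()] and [classify_pattern()].
#'
#' @param meta A `lagtriad_meta` table.
#' @return Tibble with columns `effect`, `estimate`, `ci_low`, `ci_high`.
#' @export
meta_effects <- function(meta) {
  stopifnot(is.data.frame(meta))
  out <- dplyr::filter(as_tibble(meta), .data$association %in% beta_cols())
  tibble(
    effect = out$association,
    estimate = out$estimate,
    ci_low = out$ci_low,
    ci_high = out$ci_high
  )
}
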