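#' Read a study table of two-wave effect sizes from CSV
#'
#' Two dialects are supported. *Wide*: one row per effect-size set with
#' columns `sample_id`, optional `record_id` (generated when absent), `n`,
#' and the six correlation columns of [sextet_cols()] (empty cells are
#' missing correlations); extra columns such as study labels are ignored.
#' *Long*: one row per correlation with columns `sample_id`, `record_id`,
#' `association`, `value`, `n`. Column names can be remapped through
#' `col_map` for files using other headers.
#'
#' Rows failing validation (correlations outside \[-1, 1\], n < 4) abort
#' with the offending row number unless `permissive = TRUE`, in which case
#' they are reported and skipped.
#'
#' @param path CSV file path (RFC 4180, UTF-8).
#' @param schema `"wide"` or `"long"`.
#' @param col_map Optional named character vector mapping file headers to
#'   the canonical names, e.g. `c(study = "sample_id")`.
#' @param permissive Skip invalid rows (with a warning) instead of failing.
#' @return Long-format record tibble (`sample_id`, `record_id`,
#'   `association`, `value`, `n`).
#' @export
read_study_table <- function(path, schema = c("wide", "long"),
                             col_map = NULL, permissive = FALSE) {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    idx <- match(names(col_map), names(raw))
    if (anyNA(idx)) abort(paste0("col_map names absent from file: ",
                                 paste(names(col_map)[is.na(idx)], collapse = ", ")))
    names(raw)[idx] <- unname(col_map)
  }
  if (schema == "wide") {
    needed <- c("sample_id", "n")
    if (!all(needed %in% names(raw))) {
      abort(paste0("wide study table needs columns: ", paste(needed, collapse = ", ")))
    }
    present_cors <- intersect(sextet_cols(), names(raw))
    if (length(present_cors) == 0) abort("no correlation columns found in wide study table")
    if (!"record_id" %in% names(raw)) {
      raw <- dplyr::mutate(
        dplyr::group_by(raw, .data$sample_id),
        record_id = paste0(.data$sample_id, "_E", dplyr::row_number())
      )
      raw <- dplyr::ungroup(raw)
    }
    for (col in setdiff(sextet_cols(), names(raw))) raw[[col]] <- NA_real_
    wide <- dplyr::select(raw, "sample_id", "record_id", "n", dplyr::all_of(sextet_cols()))
    wide <- check_study_rows(wide, permissive)
    records <- sextets_to_records(wide)
  } else {
    needed <- c("sample_id", "record_id", "association", "value", "n")
    if (!all(needed %in% names(raw))) {
      abort(paste0("long study table needs columns: ", paste(needed, collapse = ", ")))
    }
    unknown <- setdiff(unique(raw$association), sextet_cols())
    if (length(unknown) > 0) {
      abort(paste0("unknown association label(s): ", paste(unknown, collapse = ", ")))
    }
    wide <- records_to_sextets(raw)
    wide <- check_study_rows(wide, permissive)
    records <- sextets_to_records(wide)
  }
  records
}

check_study_rows <- function(wide, permissive) {
  rr <- as.matrix(wide[sextet_cols()])
  bad_r <- rowSums(!is.na(rr) & abs(rr) > 1) > 0
  bad_n <- is.na(wide$n) | wide$n < 4
  bad <- bad_r | bad_n
  if (any(bad)) {
    first <- which(bad)[1]
    what <- if (bad_n[first]) {
      sprintf("row %d: n = %s is below the minimum of 4", first, format(wide$n[first]))
    } else {
      col <- sextet_cols()[which(!is.na(rr[first, ]) & abs(rr[first, ]) > 1)[1]]
      sprintf("row %d: %s = %g is outside [-1, 1]", first, col, rr[first, col])
    }
    if (!permissive) abort(paste0("invalid study table: ", what))
    warn(sprintf("skipping %d invalid row(s); first: %s", sum(bad), what))
    wide <- wide[!bad, , drop = FALSE]
  }
  wide
}

#' Write effect-size records to CSV
#'
#' Inverse of [read_study_table()]; both dialects round-trip.
#'
#' @param records Long-format record tibble.
#' @param path Output CSV path.
#' @param schema `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(records, path, schema = c("wide", "long")) {
  schema <- match.arg(schema)
  check_records(records)
  out <- if (schema == "wide") records_to_sextets(records) else as_tibble(records)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Run the full triangulation analysis on a record table
#'
#' Chains the two pooling steps and the sign-pattern classification:
#' derives per-record regression effects, builds the twelve-row
#' meta-analytic table, classifies the six pooled regression effects
#' against the prediction grid, and assembles per-association forest data
#' (sample-level back-transformed estimates with 95% CIs plus the pooled
#' diamond).
#'
#' @param records Long-format record tibble (see [meta_table()]).
#' @param grid A [prediction_grid()].
#' @param method tau^2 estimator, `"REML"` or `"DL"`.
#' @param quiet Suppress the one-line progress messages.
#' @return A `lagtriad_report` list: `$meta` (the twelve-row table),
#'   `$verdict` (see [classify_pattern()]), `$forest`, `$config`.
#' @examples
#' report <- run_analysis(generate_meta_dataset(scenario_config(K = 6, seed = 3)))
#' report$verdict$label
#' @export
run_analysis <- function(records, grid = prediction_grid(),
                         method = c("REML", "DL"), quiet = FALSE) {
  method <- match.arg(method)
  say <- function(...) if (!quiet) inform(sprintf(...))
  check_records(records)
  say("records: %d effect sizes in %d samples", nrow(records),
      dplyr::n_distinct(records$sample_id))
  meta <- meta_table(records, method = method)
  say("meta-analysis: pooled %d of 12 associations (tau2 estimator: %s)",
      sum(!is.na(meta$estimate)), method)
  verdict <- classify_pattern(meta_effects(meta), grid)
  say("verdict: %s", verdict$label)
  samples <- attr(meta, "samples")
  forest <- dplyr::mutate(
    samples,
    estimate = fisher_z_inv(.data$z),
    ci_low = fisher_z_inv(.data$z - 1.96 * sqrt(.data$v)),
    ci_high = fisher_z_inv(.data$z + 1.96 * sqrt(.data$v))
  )
  structure(
    list(
      meta = meta,
      verdict = verdict,
      forest = dplyr::select(forest, "association", "sample_id", "ne",
                             "estimate", "ci_low", "ci_high"),
      config = list(method = method,
                    association_sign = attr(grid, "association_sign") %||% -1,
                    within_sample = "fixed-effect inverse-variance",
                    n_records = nrow(records))
    ),
    class = "lagtriad_report"
  )
}

#' @export
print.lagtriad_report <- function(x, ...) {
  cat(format_meta_lines(x$meta), sep = "\n")
  cat("\n")
  print(x$verdict)
  invisible(x)
}

#' Run the default spurious scenario end-to-end
#'
#' Generates a synthetic meta-analytic dataset from the common-cause model
#' with an occasion state (the configuration under which the prospective
#' effects are spurious by construction) and runs [run_analysis()] on it.
#'
#' @param seed Master seed.
#' @param K Number of samples.
#' @param quiet Passed to [run_analysis()].
#' @return A `lagtriad_report`.
#' @export
run_demo <- function(seed = 1L, K = 40L, quiet = FALSE) {
  cfg <- scenario_config(K = K, seed = seed)
  run_analysis(generate_meta_dataset(cfg), quiet = quiet)
}

# Fixed-format display lines for the twelve-row table (3 decimals for
# estimates, 1 for Q and I2), so regenerated reports are byte-identical.
format_meta_lines <- function(meta) {
  f3 <- function(x) ifelse(is.na(x), "", sprintf("%.3f", x))
  f1 <- function(x) ifelse(is.na(x), "", sprintf("%.1f", x))
  rows <- sprintf(
    "%2d. %-12s K=%3d NE=%3d N=%6s  %7s (%7s; %7s)  Q=%6s (df=%d)  I2=%5s (%s; %s)",
    meta$row, meta$label, meta$K, meta$NE,
    ifelse(is.na(meta$N), "", format(meta$N)),
    f3(meta$estimate), f3(meta$ci_low), f3(meta$ci_high),
    f1(meta$Q), meta$df, f1(meta$I2), f1(meta$I2_low), f1(meta$I2_high)
  )
  c("Meta-analytic correlations and regression effects (two-step pooling)", rows)
}

#' Write a report bundle to disk
#'
#' Emits, under `dir`: `report.txt` (fixed-format human-readable table and
#' verdict), `report.json` (every displayed number at full precision),
#' `meta_table.csv`, and `forest.csv`. Regeneration from the same report
#' object is byte-identical.
#'
#' @param report A `lagtriad_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  stopifnot(inherits(report, "lagtriad_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  verdict_lines <- c(
    paste0("Verdict: ", report$verdict$label,
           if (report$verdict$partial) " (partial)" else ""),
    utils::capture.output(print(as.data.frame(report$verdict$table), digits = 3))
  )
  writeLines(c(format_meta_lines(report$meta), "", verdict_lines),
             file.path(dir, "report.txt"))
  jsonlite::write_json(
    list(
      meta = as.data.frame(dplyr::select(report$meta, -dplyr::any_of("row"))),
      verdict = list(label = report$verdict$label,
                     partial = report$verdict$partial,
                     table = as.data.frame(report$verdict$table)),
      config = report$config
    ),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  readr::write_csv(as_tibble(report$meta), file.path(dir, "meta_table.csv"),
                   na = "", progress = FALSE)
  readr::write_csv(report$forest, file.path(dir, "forest.csv"),
                   na = "", progress = FALSE)
  invisible(dir)
}
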