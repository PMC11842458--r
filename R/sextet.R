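#' The six two-wave correlations handled by the package
#'
#' Canonical column names for a two-wave correlation sextet between a
#' construct X (self-esteem in the motivating application) and a construct Y
#' (eating pathology), each measured at waves 1 and 2:
#' `r_x1y1`, `r_x2y2` (concurrent), `r_x1x2`, `r_y1y2` (auto-correlations),
#' `r_x1y2`, `r_x2y1` (cross-lagged).
#'
#' @return Character vector of the six column names, in canonical order.
#' @export
sextet_cols <- function() {
  c("r_x1y1", "r_x2y2", "r_x1x2", "r_y1y2", "r_x1y2", "r_x2y1")
}

#' Build a one-row correlation sextet
#'
#' A correlation sextet holds the six zero-order correlations among the four
#' measured variables (X1, X2, Y1, Y2) of a two-wave panel, plus the sample
#' size. Any correlation may be `NA` (not every study administers every
#' instrument at every wave); effects requiring a missing input are simply
#' not computable for that sextet.
#'
#' @param r_x1y1,r_x2y2 Concurrent cross-construct correlations at waves 1, 2.
#' @param r_x1x2,r_y1y2 Auto-correlations of X and of Y across waves.
#' @param r_x1y2,r_x2y1 Cross-lagged correlations (X1 with Y2, X2 with Y1).
#' @param n Participant count (integer >= 4), or `NA`.
#' @param validate Check ranges and, when all six are present, positive
#'   semidefiniteness of the implied 4x4 correlation matrix.
#'
#' @return A one-row tibble with columns [sextet_cols()] and `n`.
#' @examples
#' correlation_sextet(r_x1y1 = -0.339, r_y1y2 = 0.587, r_x1y2 = -0.266, n = 19046)
#' @export
correlation_sextet <- function(r_x1y1 = NA_real_, r_x2y2 = NA_real_,
                               r_x1x2 = NA_real_, r_y1y2 = NA_real_,
                               r_x1y2 = NA_real_, r_x2y1 = NA_real_,
                               n = NA_integer_, validate = TRUE) {
  out <- tibble(
    r_x1y1 = as.numeric(r_x1y1), r_x2y2 = as.numeric(r_x2y2),
    r_x1x2 = as.numeric(r_x1x2), r_y1y2 = as.numeric(r_y1y2),
    r_x1y2 = as.numeric(r_x1y2), r_x2y1 = as.numeric(r_x2y1),
    n = as.integer(n)
  )
  if (validate) validate_sextets(out)
  out
}

#' Validate a table of correlation sextets
#'
#' Checks that every present correlation lies in \[-1, 1\], that `n` (when
#' present) is at least 4, and that every fully observed sextet implies a
#' positive semidefinite 4x4 correlation matrix (smallest eigenvalue
#' >= -1e-8). A correlation matrix that fails the eigenvalue check cannot
#' have arisen from any real dataset.
#'
#' @param data Data frame with columns [sextet_cols()] and optionally `n`.
#' @param tol Eigenvalue tolerance for the semidefiniteness check.
#' @return `data`, invisibly, if all checks pass; otherwise an error.
#' @export
validate_sextets <- function(data, tol = 1e-8) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(sextet_cols(), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing sextet column(s): ", paste(missing_cols, collapse = ", ")))
  }
  rr <- as.matrix(data[sextet_cols()])
  bad <- which(!is.na(rr) & abs(rr) > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "correlation out of [-1, 1]: %s = %.4f (row %d)",
      colnames(rr)[bad[1, 2]], rr[bad[1, , drop = FALSE]], bad[1, 1]
    ))
  }
  if ("n" %in% names(data)) {
    n <- data$n
    if (any(!is.na(n) & n < 4)) {
      abort(sprintf("sample size n = %d below the minimum of 4 (row %d)",
                    n[which(!is.na(n) & n < 4)[1]], which(!is.na(n) & n < 4)[1]))
    }
  }
  complete <- which(rowSums(is.na(rr)) == 0)
  for (i in complete) {
    ev <- min(eigen(sextet_matrix(rr[i, ]), symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -tol) {
      abort(sprintf(
        "row %d: implied correlation matrix is not positive semidefinite (min eigenvalue %.3g)",
        i, ev
      ))
    }
  }
  invisible(data)
}

# 4x4 implied correlation matrix over (X1, X2, Y1, Y2) from a named sextet.
sextet_matrix <- function(r) {
  m <- diag(4)
  dimnames(m) <- list(c("x1", "x2", "y1", "y2"), c("x1", "x2", "y1", "y2"))
  m["x1", "x2"] <- m["x2", "x1"] <- r[["r_x1x2"]]
  m["y1", "y2"] <- m["y2", "y1"] <- r[["r_y1y2"]]
  m["x1", "y1"] <- m["y1", "x1"] <- r[["r_x1y1"]]
  m["x2", "y2"] <- m["y2", "x2"] <- r[["r_x2y2"]]
  m["x1", "y2"] <- m["y2", "x1"] <- r[["r_x1y2"]]
  m["x2", "y1"] <- m["y1", "x2"] <- r[["r_x2y1"]]
  m
}
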