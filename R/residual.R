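#' Global-cognition composite from subtest scores
#'
#' Z-scores each subtest within the sample and combines the z-scores into
#' a single composite — by default their mean, so the composite is on an
#' SD-like scale (a subject one sample-SD above the mean on every subtest
#' scores +1); `combine = "sum"` is available.
#'
#' @param data Cohort tibble containing the subtest columns.
#' @param subtest_cols Names of the subtest columns ([cr_subtests()] by
#'   default).
#' @param combine `"mean"` (default) or `"sum"` of the z-scores.
#' @return `data` with a `global_cognition` column appended.
#' @export
composite_cognition <- function(data, subtest_cols = cr_subtests(),
                                combine = c("mean", "sum")) {
  combine <- match.arg(combine)
  stopifnot(nrow(data) >= 2)
  missing <- setdiff(subtest_cols, names(data))
  if (length(missing)) {
    stop("missing subtest column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  z <- vapply(subtest_cols, function(nm) {
    x <- data[[nm]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("subtest '", nm, "' has zero variance", call. = FALSE)
    }
    (x - mean(x)) / s
  }, numeric(nrow(data)))
  comp <- rowMeans(z)
  if (combine == "sum") comp <- comp * length(subtest_cols)
  dplyr::mutate(data, global_cognition = comp)
}

#' Cognitive-reserve residual from a brain-structure regression
#'
#' Fits the reserve-residual model: ordinary least squares of global
#' cognition on age, sex, grey-matter volume, hippocampal volume and mean
#' cortical thickness. The per-subject residual is the cognitive-reserve
#' (CR) measure — positive residuals mean cognition better than predicted
#' from demographics and brain structure. Rows with missing values in any
#' model variable are dropped (complete-case) and counted.
#'
#' @param data Cohort tibble with a `global_cognition` column (see
#'   [composite_cognition()]) and the predictor columns.
#' @param cognition Name of the cognition column.
#' @param predictors Names of the predictor columns.
#' @return A `cr_residual_model`: list with `fit` (the `lm`), `data` (the
#'   complete-case rows with a `cr_residual` column), `coefficients`,
#'   `fit_r2`, `n`, `n_dropped`. Supports [generics::tidy()],
#'   [generics::glance()] and `autoplot()`.
#' @export
fit_cr_residual <- function(data, cognition = "global_cognition",
                            predictors = c("age", "sex", "gm_volume",
                                           "hippocampal_volume",
                                           "cortical_thickness")) {
  vars <- c(cognition, predictors)
  missing <- setdiff(vars, names(data))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cc <- stats::complete.cases(data[vars])
  n_dropped <- sum(!cc)
  d <- data[cc, , drop = FALSE]
  if (nrow(d) <= length(predictors) + 1) {
    stop("need more subjects than predictors + 1 after dropping ",
         n_dropped, " incomplete rows", call. = FALSE)
  }
  x <- stats::model.matrix(
    stats::reformulate(predictors), data = d
  )
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(stats::reformulate(predictors, response = cognition),
                   data = d)
  structure(
    list(
      fit = fit,
      data = dplyr::mutate(d, cr_residual = unname(stats::residuals(fit))),
      coefficients = stats::coef(fit),
      fit_r2 = summary(fit)$r.squared,
      n = nrow(d),
      n_dropped = n_dropped,
      cognition = cognition,
      predictors = predictors
    ),
    class = "cr_residual_model"
  )
}

#' @export
print.cr_residual_model <- function(x, ...) {
  cat("CR residual model: ", x$cognition, " ~ ",
      paste(x$predictors, collapse = " + "), "\n",
      "n = ", x$n, " (", x$n_dropped, " dropped), R² = ",
      signif(x$fit_r2, 3), ", residual SD = ",
      signif(stats::sd(x$data$cr_residual), 3), "\n", sep = "")
  invisible(x)
}

#' Min-max normalise a numeric vector
#'
#' Maps values linearly onto `[0, 1]`: the minimum to 0, the maximum
#' to 1. Used to put proxy scores from different test versions on a
#' common scale before comparison.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return `(x - min) / (max - min)`.
#' @examples
#' minmax_normalize(c(10, 20, 30))
#' @export
minmax_normalize <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    stop("cannot min-max normalise a constant vector", call. = FALSE)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Serialise a CR residual model
#'
#' Coefficients and fit summary as JSON, per-subject residuals as CSV.
#'
#' @param model A `cr_residual_model`.
#' @param prefix Path prefix; writes `<prefix>.json` and
#'   `<prefix>_residuals.csv`.
#' @export
write_cr_residual <- function(model, prefix) {
  stopifnot(inherits(model, "cr_residual_model"))
  jsonlite::write_json(
    list(coefficients = as.list(model$coefficients),
         fit_r2 = model$fit_r2, n = model$n, n_dropped = model$n_dropped,
         predictors = model$predictors),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  readr::write_csv(
    dplyr::select(model$data, dplyr::any_of("subject_id"), "cr_residual"),
    paste0(prefix, "_residuals.csv")
  )
  invisible(prefix)
}
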