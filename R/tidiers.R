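#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a CR residual model
#'
#' @param x A `cr_residual_model`.
#' @param ... Unused.
#' @return One row per model term: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.cr_residual_model <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(co), estimate = co[, 1], std.error = co[, 2],
    statistic = co[, 3], p.value = co[, 4]
  )
}

#' @rdname tidy.cr_residual_model
#' @export
glance.cr_residual_model <- function(x, ...) {
  tibble::tibble(r.squared = x$fit_r2, n = x$n, n_dropped = x$n_dropped,
                 residual_sd = stats::sd(x$data$cr_residual))
}

#' @rdname tidy.cr_residual_model
#' @export
augment.cr_residual_model <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = unname(stats::fitted(x$fit)))
}

#' Tidy CPM cross-validation results
#'
#' @param x A `cpm_cv` or `cpm_repeated_cv`.
#' @param ... Unused.
#' @return `tidy()`: accuracy metrics per tail (per repeat for repeated
#'   k-fold). `glance()`: a one-row summary keyed on the combined tail.
#' @export
tidy.cpm_cv <- function(x, ...) x$metrics

#' @rdname tidy.cpm_cv
#' @export
glance.cpm_cv <- function(x, ...) {
  comb <- dplyr::filter(x$metrics, .data$tail == "combined")
  tibble::tibble(
    scheme = x$scheme, threshold = x$threshold,
    n = nrow(x$predictions), r = comb$r, r2 = comb$r2, mae = comb$mae,
    n_fallback = x$n_fallback
  )
}

#' @rdname tidy.cpm_cv
#' @export
augment.cpm_cv <- function(x, ...) x$predictions

#' @rdname tidy.cpm_cv
#' @export
tidy.cpm_repeated_cv <- function(x, ...) x$metrics

#' @rdname tidy.cpm_cv
#' @export
glance.cpm_repeated_cv <- function(x, ...) {
  comb <- dplyr::filter(x$summary, .data$tail == "combined")
  tibble::tibble(
    scheme = "kfold", k = x$k, repeats = x$n_repeats,
    threshold = x$threshold,
    r = comb$r_mean, r_sd = comb$r_sd,
    r2 = comb$r2_mean, mae = comb$mae_mean
  )
}

#' Tidy an aggregated CPM model
#'
#' @param x A `cpm_aggregate`.
#' @param ... Unused.
#' @return `tidy()`: the aggregated edges with node pairs, sign and
#'   selection frequency. `glance()`: rule, threshold and mask sizes.
#' @export
tidy.cpm_aggregate <- function(x, ...) {
  ei <- edge_index(x$provenance$n_nodes, x$provenance$node_ids)
  kept <- dplyr::bind_rows(
    tibble::tibble(edge = x$positive, sign = "positive"),
    tibble::tibble(edge = x$negative, sign = "negative")
  )
  dplyr::inner_join(kept, x$frequency, by = c("edge", "sign")) |>
    dplyr::inner_join(ei, by = "edge") |>
    dplyr::select("node_i", "node_j", "sign", "frequency")
}

#' @rdname tidy.cpm_aggregate
#' @export
glance.cpm_aggregate <- function(x, ...) {
  tibble::tibble(
    rule = x$provenance$rule, threshold = x$provenance$threshold,
    n_folds = x$provenance$n_folds,
    n_positive = length(x$positive), n_negative = length(x$negative)
  )
}

#' Tidy a hierarchical regression
#'
#' @param x A `hier_reg`.
#' @param ... Unused.
#' @return `tidy()`: the step table (R², increments, F tests).
#'   `glance()`: one row with the independence and moderation
#'   increments.
#' @export
tidy.hier_reg <- function(x, ...) x$steps

#' @rdname tidy.hier_reg
#' @export
glance.hier_reg <- function(x, ...) {
  tibble::tibble(
    independence_delta_r2 = x$steps$delta_r2[2],
    independence_p = x$steps$p[2],
    moderation_delta_r2 = x$steps$delta_r2[3],
    moderation_p = x$steps$p[3]
  )
}
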