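#' Fisher z-transform a correlation coefficient
#'
#' `z = artanh(r)`, the variance-stabilising transform applied to every
#' edge of a connectivity matrix. Correlations are first clipped to
#' `|r| <= 1 - clip_eps` so that degenerate node pairs (e.g. duplicated
#' time series, `r = 1`) yield a large finite z rather than infinity —
#' downstream network-strength sums must stay finite.
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @param clip_eps Clipping margin; `|r|` is capped at `1 - clip_eps`
#'   before the transform.
#' @return Fisher z value(s), an odd strictly increasing function of `r`.
#' @examples
#' fisher_z(0.5) # 0.5493061
#' fisher_z(-0.5) == -fisher_z(0.5)
#' @export
fisher_z <- function(r, clip_eps = 1e-7) {
  if (any(abs(r) > 1, na.rm = TRUE)) {
    stop("correlation outside [-1, 1]: ", max(abs(r), na.rm = TRUE),
         call. = FALSE)
  }
  atanh(pmin(pmax(r, -1 + clip_eps), 1 - clip_eps))
}

#' Build a Fisher-z connectivity matrix from node time series
#'
#' Correlates every pair of node time courses (Pearson) and Fisher
#' z-transforms the coefficients, giving the symmetric zero-diagonal
#' matrix that is the unit of CPM input.
#'
#' @param ts Numeric matrix, nodes x time points (>= 3), with node labels
#'   as row names (defaults to `1:n`).
#' @param clip_eps Passed to [fisher_z()].
#' @return A nodes x nodes symmetric matrix of Fisher z values with zero
#'   diagonal and the node labels as dimnames.
#' @examples
#' ts <- rbind(a = c(1, 2, 3), b = c(1, 3, 2))
#' build_connectivity(ts)["a", "b"] # atanh(0.5)
#' @export
build_connectivity <- function(ts, clip_eps = 1e-7) {
  stopifnot(is.matrix(ts), is.numeric(ts))
  if (ncol(ts) < 3) stop("need at least 3 time points", call. = FALSE)
  if (anyNA(ts)) stop("time series contain missing values", call. = FALSE)
  ids <- connectivity_node_ids(ts)
  if (anyDuplicated(ids)) stop("node labels are not unique", call. = FALSE)
  v <- apply(ts, 1, stats::var)
  if (any(v == 0)) {
    stop("zero-variance node(s): ", paste(ids[v == 0], collapse = ", "),
         call. = FALSE)
  }
  z <- fisher_z(stats::cor(t(ts)), clip_eps = clip_eps)
  diag(z) <- 0
  z <- (z + t(z)) / 2 # enforce exact symmetry against FP asymmetries
  dimnames(z) <- list(ids, ids)
  z
}

#' Drop nodes from a connectivity matrix
#'
#' Removes the given nodes (e.g. the 63 cerebellum/brainstem nodes of a
#' 268-node parcellation, leaving 205) and returns the submatrix over the
#' retained nodes in their original order.
#'
#' @param m Connectivity matrix with node labels as dimnames.
#' @param drop_ids Labels of the nodes to remove (may be empty).
#' @return The retained submatrix; for k retained nodes it has
#'   `k * (k - 1) / 2` unique edges.
#' @export
remove_nodes <- function(m, drop_ids) {
  ids <- connectivity_node_ids(m)
  drop_ids <- as.character(drop_ids)
  unknown <- setdiff(drop_ids, ids)
  if (length(unknown)) {
    stop("unknown node label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- !(ids %in% drop_ids)
  out <- m[keep, keep, drop = FALSE]
  dimnames(out) <- list(ids[keep], ids[keep])
  out
}

#' Framewise displacement from rigid-body realignment parameters
#'
#' Computes per-frame framewise displacement (FWD, mm) from 6-parameter
#' rigid-body motion estimates: the sum of absolute frame-to-frame
#' differences of the three translations (mm) and the three rotations
#' (radians), the latter converted to arc length on a sphere of
#' `head_radius_mm` (the Power convention, 50 mm by default). The first
#' frame has FWD 0 by definition.
#'
#' @param params Numeric matrix or data frame, frames x 6: three
#'   translations (mm) then three rotations (radians).
#' @param head_radius_mm Sphere radius for the rotation-to-arc-length
#'   conversion.
#' @return A `motion_record`: list with `fwd` (per-frame series),
#'   `mean_fwd` and `max_frame_to_frame` (both mm).
#' @export
compute_fwd <- function(params, head_radius_mm = 50) {
  params <- as.matrix(params)
  if (ncol(params) != 6) {
    stop("expected 6 motion parameter columns, got ", ncol(params),
         call. = FALSE)
  }
  if (nrow(params) < 2) stop("need at least 2 frames", call. = FALSE)
  d <- abs(diff(params))
  d[, 4:6] <- d[, 4:6] * head_radius_mm
  motion_record(c(0, rowSums(d)))
}

#' @rdname compute_fwd
#' @param fwd A non-negative per-frame FWD series (mm).
#' @export
motion_record <- function(fwd) {
  fwd <- as.numeric(fwd)
  stopifnot(length(fwd) >= 1, all(fwd >= 0))
  structure(
    list(fwd = fwd, mean_fwd = mean(fwd), max_frame_to_frame = max(fwd)),
    class = "motion_record"
  )
}

#' Flag subjects for motion-based exclusion
#'
#' A subject is excluded if mean FWD exceeds `mean_fwd_limit` (0.4 mm by
#' default) or if any of their frame-to-frame movements exceeds the
#' `ftf_quantile` quantile (97.5th percentile by default) of frame-to-frame
#' movements pooled across the whole sample.
#'
#' @param records Named list of `motion_record`s (or bare numeric FWD
#'   series), one per subject; >= 2 subjects.
#' @param mean_fwd_limit Mean-FWD exclusion threshold (mm).
#' @param ftf_quantile Pooled-sample quantile defining the frame-to-frame
#'   spike threshold.
#' @return A tibble, one row per subject: `subject_id`, `mean_fwd`,
#'   `max_frame_to_frame`, `excluded_mean_fwd`, `excluded_spike`,
#'   `excluded`.
#' @export
flag_high_motion <- function(records, mean_fwd_limit = 0.4,
                             ftf_quantile = 0.975) {
  if (length(records) < 2) {
    stop("motion exclusion needs at least 2 subjects (the spike rule is ",
         "a sample percentile)", call. = FALSE)
  }
  records <- lapply(records, function(r) {
    if (inherits(r, "motion_record")) r else motion_record(r)
  })
  ids <- names(records)
  if (is.null(ids)) ids <- as.character(seq_along(records))
  pooled <- unlist(lapply(records, `[[`, "fwd"), use.names = FALSE)
  spike_cut <- stats::quantile(pooled, ftf_quantile, names = FALSE)
  tibble::tibble(
    subject_id = ids,
    mean_fwd = vapply(records, `[[`, numeric(1), "mean_fwd"),
    max_frame_to_frame = vapply(records, `[[`, numeric(1),
                                "max_frame_to_frame")
  ) |>
    dplyr::mutate(
      excluded_mean_fwd = .data$mean_fwd > mean_fwd_limit,
      excluded_spike = .data$max_frame_to_frame > spike_cut,
      excluded = .data$excluded_mean_fwd | .data$excluded_spike
    )
}

#' Validate a connectivity matrix
#'
#' Checks the invariants every connectivity matrix must satisfy: square,
#' finite, exactly symmetric, zero diagonal.
#'
#' @param m Matrix to check.
#' @return `m`, invisibly; errors describe the violated invariant.
#' @export
validate_connectivity <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (nrow(m) != ncol(m)) stop("matrix is not square", call. = FALSE)
  if (!all(is.finite(m))) stop("matrix has non-finite entries", call. = FALSE)
  if (!identical(m, t(m))) stop("matrix is not symmetric", call. = FALSE)
  if (any(diag(m) != 0)) stop("diagonal is not zero", call. = FALSE)
  invisible(m)
}
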