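#' Mass-univariate edge selection
#'
#' Correlates every unique connectome edge with the target across
#' subjects (Pearson; partial correlation when covariates are supplied,
#' by residualising both edge and target on the covariates) and splits
#' the edges passing the p-value threshold by sign: the positive tail
#' (`r > 0, p < threshold`) and the negative tail (`r < 0,
#' p < threshold`). Two-sided p-values come from the t distribution with
#' `n - 2 - c` degrees of freedom (`c` covariates).
#'
#' @param edge_values Subjects x unique-edges matrix (see
#'   [edges_from_matrices()]).
#' @param target Per-subject numeric target (e.g. the CR residual).
#' @param p_threshold Selection threshold on the two-sided p-value.
#' @param covariates Optional per-subject covariate table (data frame or
#'   matrix), e.g. age, sex and mean FWD.
#' @return An `edge_mask_pair`: list with `stats` (tibble: `edge`, `r`,
#'   `p`), `positive` / `negative` (integer edge indices), `threshold`,
#'   `n`, `df`, `covariate_names`, `n_nodes`, `node_ids`.
#' @export
select_edges <- function(edge_values, target, p_threshold,
                         covariates = NULL) {
  stopifnot(is.matrix(edge_values), nrow(edge_values) == length(target))
  n <- length(target)
  ncov <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n < 4 + ncov) {
    stop("edge selection needs at least ", 4 + ncov, " subjects",
         call. = FALSE)
  }
  if (stats::sd(target) == 0) {
    stop("target is constant; edge correlations are undefined",
         call. = FALSE)
  }
  ec <- edge_correlations(edge_values, target, covariates)
  sel <- ec$p < p_threshold
  structure(
    list(
      stats = tibble::tibble(edge = seq_along(ec$r), r = ec$r, p = ec$p),
      positive = which(sel & ec$r > 0),
      negative = which(sel & ec$r < 0),
      threshold = p_threshold,
      n = n,
      df = ec$df,
      covariate_names = ec$covariate_names,
      n_nodes = attr(edge_values, "n_nodes"),
      node_ids = attr(edge_values, "node_ids")
    ),
    class = "edge_mask_pair"
  )
}

# Vectorised (partial) Pearson correlation of every column of x with y.
# Residualises on [1 | covariates] via QR, then correlates through a
# centred cross-product (BLAS) — equivalent to looping stats::cor but
# fast enough for 20k+ edges inside cross-validation.
edge_correlations <- function(x, y, covariates = NULL) {
  n <- length(y)
  if (is.null(covariates)) {
    xr <- sweep(x, 2, colMeans(x))
    yr <- y - mean(y)
    df <- n - 2L
    cov_names <- character(0)
  } else {
    cv <- as.matrix(covariates)
    stopifnot(nrow(cv) == n)
    q <- qr.Q(qr(cbind(1, cv)))
    xr <- x - q %*% crossprod(q, x)
    yr <- as.vector(y - q %*% crossprod(q, y))
    df <- n - 2L - ncol(cv)
    cov_names <- colnames(covariates)
    if (is.null(cov_names)) cov_names <- paste0("cov", seq_len(ncol(cv)))
  }
  ys <- sqrt(sum(yr^2))
  if (ys < 1e-12) {
    stop("target is collinear with the covariates", call. = FALSE)
  }
  xs <- sqrt(colSums(xr^2))
  r <- as.vector(crossprod(xr, yr)) / (xs * ys)
  r[xs < 1e-12] <- 0 # constant edges carry no signal
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt(df / pmax(1 - r^2, 1e-15))
  list(r = r, p = 2 * stats::pt(-abs(t), df), df = df,
       covariate_names = cov_names)
}

#' @export
print.edge_mask_pair <- function(x, ...) {
  cat("Edge selection at p <", format(x$threshold), "(n =", x$n,
      if (length(x$covariate_names))
        paste0("; covariates: ", paste(x$covariate_names, collapse = ", "))
      else "", "):",
      length(x$positive), "positive,", length(x$negative),
      "negative edges\n")
  invisible(x)
}

#' Binary mask matrix for one tail of an edge selection
#'
#' @param emp An `edge_mask_pair`.
#' @param sign `"positive"` or `"negative"`.
#' @return A symmetric 0/1 matrix with zero diagonal.
#' @export
mask_matrix <- function(emp, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  stopifnot(inherits(emp, "edge_mask_pair"), !is.null(emp$n_nodes))
  v <- numeric(n_unique_edges(emp$n_nodes))
  v[emp[[sign]]] <- 1
  matrix_from_edges(v, emp$node_ids)
}

#' Network strength of a connectivity matrix under a mask
#'
#' Sums the masked entries of the full symmetric matrix and halves the
#' sum to account for the symmetry — equal to the sum over the unique
#' (upper-triangle) masked edges.
#'
#' @param m Connectivity matrix.
#' @param mask Binary symmetric matrix of the same dimensions.
#' @return The network-strength scalar.
#' @export
network_strength <- function(m, mask) {
  if (!identical(dim(m), dim(mask))) {
    stop("matrix and mask dimensions differ", call. = FALSE)
  }
  sum(m * mask) / 2
}

#' Combined network strength
#'
#' @param pos,neg Positive- and negative-tail network strengths.
#' @return `pos - neg`.
#' @export
combined_strength <- function(pos, neg) pos - neg

#' Least-squares line from network strength to target
#'
#' The per-tail CPM model: `target = intercept + slope * strength`,
#' ordinary least squares.
#'
#' @param strength,target Per-subject numeric vectors (length >= 3).
#' @return Named vector `c(intercept, slope)`.
#' @export
fit_strength_model <- function(strength, target) {
  stopifnot(length(strength) == length(target), length(strength) >= 3)
  v <- stats::var(strength)
  if (v == 0) stop("strengths are constant; slope undefined", call. = FALSE)
  slope <- stats::cov(strength, target) / v
  c(intercept = mean(target) - slope * mean(strength), slope = slope)
}

# --- cross-validation core -------------------------------------------

# Row sums of selected edge columns; 0 when the selection is empty.
edge_strength <- function(x, idx) {
  if (length(idx) == 0) return(numeric(nrow(x)))
  rowSums(x[, idx, drop = FALSE])
}

cpm_tails <- c("positive", "negative", "combined")

# One cross-validation pass over a fixed fold assignment. Returns
# out-of-fold predictions per tail plus the per-fold models. Folds whose
# mask is empty (or whose strengths are constant) fall back to predicting
# the fold-training-target mean, with the event counted.
cv_core <- function(x, target, fold, p_threshold, covariates = NULL) {
  n <- length(target)
  cv <- if (is.null(covariates)) NULL else as.matrix(covariates)
  pred <- matrix(NA_real_, n, 3, dimnames = list(NULL, cpm_tails))
  folds <- vector("list", length(unique(fold)))
  fold_levels <- sort(unique(fold))
  n_fallback <- 0L
  for (fi in seq_along(fold_levels)) {
    test <- fold == fold_levels[fi]
    train <- !test
    emp <- tryCatch(
      select_edges(x[train, , drop = FALSE], target[train], p_threshold,
                   covariates = if (is.null(cv)) NULL
                                else cv[train, , drop = FALSE]),
      error = function(e) {
        stop("fold ", fold_levels[fi], ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    s_train <- cbind(
      positive = edge_strength(x[train, , drop = FALSE], emp$positive),
      negative = edge_strength(x[train, , drop = FALSE], emp$negative)
    )
    s_train <- cbind(s_train,
                     combined = s_train[, 1] - s_train[, 2])
    s_test <- cbind(
      positive = edge_strength(x[test, , drop = FALSE], emp$positive),
      negative = edge_strength(x[test, , drop = FALSE], emp$negative)
    )
    s_test <- cbind(s_test, combined = s_test[, 1] - s_test[, 2])
    coefs <- matrix(NA_real_, 3, 2,
                    dimnames = list(cpm_tails, c("intercept", "slope")))
    for (tail in cpm_tails) {
      if (stats::var(s_train[, tail]) > 0) {
        coefs[tail, ] <- fit_strength_model(s_train[, tail], target[train])
        pred[test, tail] <- coefs[tail, "intercept"] +
          coefs[tail, "slope"] * s_test[, tail]
      } else {
        # empty mask (or degenerate strengths): fold mean fallback
        pred[test, tail] <- mean(target[train])
        n_fallback <- n_fallback + 1L
      }
    }
    folds[[fi]] <- list(fold = fold_levels[fi], positive = emp$positive,
                        negative = emp$negative, coefficients = coefs)
  }
  if (n_fallback > 0) {
    warning(n_fallback,
            " fold-tail(s) had an empty mask or constant strengths; ",
            "fold-mean predictions used", call. = FALSE)
  }
  list(predictions = pred, folds = folds, n_fallback = n_fallback)
}

resolve_edge_matrix <- function(matrices) {
  if (is.matrix(matrices) && !is.null(attr(matrices, "n_nodes"))) {
    matrices
  } else {
    edges_from_matrices(matrices)
  }
}

cpm_cv_result <- function(core, x, target, p_threshold, covariates,
                          scheme, extra = list()) {
  preds <- tibble::tibble(
    subject = if (is.null(rownames(x))) as.character(seq_along(target))
              else rownames(x),
    observed = target,
    predicted_positive = core$predictions[, "positive"],
    predicted_negative = core$predictions[, "negative"],
    predicted_combined = core$predictions[, "combined"]
  )
  metrics <- dplyr::bind_rows(lapply(cpm_tails, function(tail) {
    dplyr::mutate(
      evaluate_predictions(core$predictions[, tail], target),
      tail = tail, .before = 1
    )
  }))
  structure(
    c(list(
      predictions = preds,
      metrics = metrics,
      folds = core$folds,
      n_fallback = core$n_fallback,
      threshold = p_threshold,
      covariate_names = if (is.null(covariates)) character(0)
                        else colnames(as.matrix(covariates)),
      scheme = scheme,
      n_nodes = attr(x, "n_nodes"),
      node_ids = attr(x, "node_ids")
    ), extra),
    class = "cpm_cv"
  )
}

#' CPM with leave-one-out cross-validation
#'
#' The full CPM loop: for each subject, edges are selected and the three
#' network-strength models (positive, negative, combined = positive
#' minus negative) are fitted on the remaining subjects only; the
#' held-out subject's strengths under the fold's masks then yield three
#' out-of-fold predictions. The held-out target never enters selection
#' or fitting.
#'
#' @param matrices Named list of connectivity matrices or a precomputed
#'   subject x edge matrix from [edges_from_matrices()].
#' @param target Per-subject target (the CR residual).
#' @param p_threshold Edge-selection p-value threshold.
#' @param covariates Optional covariate table for partial-correlation
#'   selection (e.g. age, sex, mean FWD).
#' @return A `cpm_cv`: `predictions` (tibble with observed and the three
#'   predicted values per subject), `metrics` (r / R² / MAE per tail),
#'   `folds` (per-fold masks and line coefficients), `threshold`,
#'   `scheme`, node roster. Supports `tidy()`, `glance()`, `autoplot()`.
#' @export
run_loocv <- function(matrices, target, p_threshold = 0.01,
                      covariates = NULL) {
  x <- resolve_edge_matrix(matrices)
  n <- length(target)
  stopifnot(nrow(x) == n)
  if (n < 10) stop("LOOCV needs at least 10 subjects", call. = FALSE)
  core <- cv_core(x, target, seq_len(n), p_threshold, covariates)
  cpm_cv_result(core, x, target, p_threshold, covariates, "loocv")
}

#' CPM with repeated k-fold cross-validation
#'
#' Repeats the CPM loop over seeded random k-fold partitions (fold sizes
#' differ by at most one). Each repeat yields out-of-fold predictions
#' and metrics; the summary reports the mean and SD of each metric
#' across repeats. With `k = n` every partition reduces to singleton
#' folds, reproducing [run_loocv()] exactly.
#'
#' @inheritParams run_loocv
#' @param k Number of folds (2..n).
#' @param repeats Number of repeated partitions.
#' @param seed Root seed; repeat `i` uses a sub-seed derived from it.
#' @return A `cpm_repeated_cv`: `summary` (tail x metric mean/sd),
#'   `metrics` (per repeat and tail), `repeats` (list of per-repeat
#'   `cpm_cv` results), `k`, `n_repeats`.
#' @export
run_repeated_kfold <- function(matrices, target, k = 10, repeats = 100,
                               p_threshold = 0.01, covariates = NULL,
                               seed = 1L) {
  x <- resolve_edge_matrix(matrices)
  n <- length(target)
  stopifnot(nrow(x) == n)
  if (k > n) stop("k = ", k, " exceeds the number of subjects (", n, ")",
                  call. = FALSE)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  runs <- vector("list", repeats)
  for (rep_i in seq_len(repeats)) {
    set.seed(derive_seed(seed, rep_i))
    fold <- sample(rep_len(seq_len(k), n))
    core <- cv_core(x, target, fold, p_threshold, covariates)
    runs[[rep_i]] <- cpm_cv_result(core, x, target, p_threshold,
                                   covariates, "kfold",
                                   extra = list(fold = fold, k = k))
  }
  per_repeat <- dplyr::bind_rows(lapply(seq_len(repeats), function(i) {
    dplyr::mutate(runs[[i]]$metrics, repeat_i = i, .before = 1)
  }))
  summary <- per_repeat |>
    dplyr::group_by(.data$tail) |>
    dplyr::summarise(dplyr::across(c("r", "r2", "mae"),
                                   list(mean = ~mean(.x, na.rm = TRUE),
                                        sd = ~stats::sd(.x))),
                     .groups = "drop")
  structure(
    list(summary = summary, metrics = per_repeat, repeats = runs,
         k = k, n_repeats = repeats, threshold = p_threshold, seed = seed),
    class = "cpm_repeated_cv"
  )
}

#' Default edge-selection p-value threshold grid
#'
#' @return The default grid used by [optimize_threshold()].
#' @export
default_threshold_grid <- function() {
  c(0.0001, 0.0005, 0.0009, 0.001, 0.005, 0.01, 0.05)
}

#' Data-driven edge-selection threshold optimisation
#'
#' Runs the requested cross-validation scheme at every threshold in the
#' grid and picks the threshold maximising the out-of-fold Pearson r of
#' the combined tail (ties go to the smaller, i.e. stricter, threshold).
#' When even the best r is not significantly positive the result is
#' flagged non-significant.
#'
#' @inheritParams run_repeated_kfold
#' @param grid P-value thresholds in (0, 1].
#' @param scheme `"loocv"` or `"kfold"`.
#' @return A `cpm_threshold_trace`: `trace` (tibble: threshold and the
#'   combined-tail r / R² / MAE), `best_threshold`, `best` (the `cpm_cv`
#'   or `cpm_repeated_cv` at the optimum), `significant`, `p_best`.
#' @export
optimize_threshold <- function(matrices, target,
                               grid = default_threshold_grid(),
                               scheme = c("loocv", "kfold"),
                               k = 10, repeats = 1, covariates = NULL,
                               seed = 1L) {
  scheme <- match.arg(scheme)
  if (length(grid) == 0) stop("threshold grid is empty", call. = FALSE)
  if (any(grid <= 0 | grid > 1)) {
    stop("threshold grid values must lie in (0, 1]; offending: ",
         paste(grid[grid <= 0 | grid > 1], collapse = ", "),
         call. = FALSE)
  }
  x <- resolve_edge_matrix(matrices)
  grid <- sort(grid)
  runs <- lapply(grid, function(th) {
    if (scheme == "loocv") {
      run_loocv(x, target, p_threshold = th, covariates = covariates)
    } else {
      run_repeated_kfold(x, target, k = k, repeats = repeats,
                         p_threshold = th, covariates = covariates,
                         seed = seed)
    }
  })
  combined <- function(run) {
    if (inherits(run, "cpm_cv")) {
      dplyr::filter(run$metrics, .data$tail == "combined")
    } else {
      run$summary |>
        dplyr::filter(.data$tail == "combined") |>
        dplyr::transmute(r = .data$r_mean, r2 = .data$r2_mean,
                         mae = .data$mae_mean)
    }
  }
  trace <- dplyr::bind_rows(lapply(runs, combined)) |>
    dplyr::mutate(threshold = grid, .before = 1) |>
    dplyr::select(dplyr::any_of(c("threshold", "r", "r2", "mae")))
  # ties -> smaller threshold: grid is sorted, which.max takes the first
  best_i <- which.max(ifelse(is.na(trace$r), -Inf, trace$r))
  n <- length(target)
  r_best <- trace$r[best_i]
  t_best <- r_best * sqrt((n - 2) / max(1 - r_best^2, 1e-15))
  p_best <- 2 * stats::pt(-abs(t_best), n - 2)
  structure(
    list(trace = trace, best_threshold = grid[best_i],
         best = runs[[best_i]], scheme = scheme,
         p_best = p_best,
         significant = is.finite(r_best) && r_best > 0 && p_best < 0.05),
    class = "cpm_threshold_trace"
  )
}

#' @export
print.cpm_threshold_trace <- function(x, ...) {
  cat("Edge-selection threshold optimisation (", x$scheme, "):\n", sep = "")
  print(x$trace)
  cat("Best threshold:", format(x$best_threshold),
      if (!x$significant) "(combined-tail r not significantly positive)",
      "\n")
  invisible(x)
}

#' Aggregate per-fold CPM models for external application
#'
#' Combines the per-fold edge masks by a recorded rule — `"intersection"`
#' (edges selected in every fold; the consensus-edge default), `"union"`,
#' or `"frequency"` (selection frequency at least `min_frequency`) — and
#' averages the per-tail regression parameters across folds, yielding a
#' single model applicable to an external cohort.
#'
#' @param cv A `cpm_cv` from [run_loocv()] (or one repeat of
#'   [run_repeated_kfold()]).
#' @param rule Mask-aggregation rule.
#' @param min_frequency Selection-frequency cutoff for
#'   `rule = "frequency"`.
#' @return A `cpm_aggregate`: `positive` / `negative` (edge indices),
#'   `frequency` (tibble: edge, sign, selection frequency),
#'   `coefficients` (tail x intercept/slope, averaged over folds) and
#'   `provenance` (rule, threshold, covariates, fold count, edge order,
#'   node roster).
#' @export
aggregate_model <- function(cv, rule = c("intersection", "union",
                                         "frequency"),
                            min_frequency = 0.5) {
  rule <- match.arg(rule)
  stopifnot(inherits(cv, "cpm_cv"), length(cv$folds) >= 1)
  n_folds <- length(cv$folds)
  n_edges <- n_unique_edges(cv$n_nodes)
  freq <- function(sign) {
    counts <- tabulate(
      unlist(lapply(cv$folds, `[[`, sign), use.names = FALSE), n_edges
    )
    counts / n_folds
  }
  pos_freq <- freq("positive")
  neg_freq <- freq("negative")
  cut <- switch(rule, intersection = 1, union = 1 / n_folds,
                frequency = min_frequency)
  positive <- which(pos_freq >= cut)
  negative <- which(neg_freq >= cut)
  if (length(positive) == 0 || length(negative) == 0) {
    warning("aggregated ", paste(c("positive", "negative")[
      c(length(positive) == 0, length(negative) == 0)], collapse = " and "),
      " mask is empty; strengths for that tail will be 0", call. = FALSE)
  }
  coef_arr <- vapply(cv$folds, `[[`, matrix(0, 3, 2), "coefficients")
  coefficients <- apply(coef_arr, c(1, 2), mean, na.rm = TRUE)
  dimnames(coefficients) <- list(cpm_tails, c("intercept", "slope"))
  if (any(is.na(vapply(cv$folds, function(f) f$coefficients[, "slope"],
                       numeric(3))))) {
    warning("some folds had undefined slopes (empty masks); ",
            "averages taken over the remaining folds", call. = FALSE)
  }
  frequency <- dplyr::bind_rows(
    tibble::tibble(edge = which(pos_freq > 0), sign = "positive",
                   frequency = pos_freq[pos_freq > 0]),
    tibble::tibble(edge = which(neg_freq > 0), sign = "negative",
                   frequency = neg_freq[neg_freq > 0])
  )
  structure(
    list(
      positive = positive, negative = negative,
      frequency = frequency, coefficients = coefficients,
      provenance = list(
        rule = rule, min_frequency = min_frequency,
        threshold = cv$threshold, covariates = cv$covariate_names,
        n_folds = n_folds, scheme = cv$scheme,
        edge_order = "upper-triangle-row-major",
        n_nodes = cv$n_nodes, node_ids = cv$node_ids
      )
    ),
    class = "cpm_aggregate"
  )
}

#' Apply an aggregated CPM model to an external cohort
#'
#' Computes network strengths from the aggregated masks and predictions
#' from the averaged regression lines on new connectivity data sharing
#' the training node roster. When observed targets are supplied the
#' three accuracy metrics are computed, and any tail whose out-of-sample
#' correlation is negative is flagged as not meaningful as prediction
#' (the predictions point the wrong way).
#'
#' @param model A `cpm_aggregate`.
#' @param matrices External connectivity matrices (or subject x edge
#'   matrix) with the same node roster as the model.
#' @param target Optional observed per-subject target.
#' @return A `cpm_external`: `predictions` tibble (strengths and
#'   predicted values per tail, plus `observed` if given) and, with a
#'   target, `metrics` with a `meaningful` flag per tail.
#' @export
apply_external <- function(model, matrices, target = NULL) {
  stopifnot(inherits(model, "cpm_aggregate"))
  x <- resolve_edge_matrix(matrices)
  if (!identical(attr(x, "node_ids"), model$provenance$node_ids)) {
    stop("external node roster does not match the model's", call. = FALSE)
  }
  s <- cbind(positive = edge_strength(x, model$positive),
             negative = edge_strength(x, model$negative))
  s <- cbind(s, combined = s[, "positive"] - s[, "negative"])
  co <- model$coefficients
  pred <- vapply(cpm_tails, function(tail) {
    co[tail, "intercept"] + co[tail, "slope"] * s[, tail]
  }, numeric(nrow(x)))
  preds <- tibble::tibble(
    subject = if (is.null(rownames(x))) as.character(seq_len(nrow(x)))
              else rownames(x),
    strength_positive = s[, "positive"],
    strength_negative = s[, "negative"],
    strength_combined = s[, "combined"],
    predicted_positive = pred[, "positive"],
    predicted_negative = pred[, "negative"],
    predicted_combined = pred[, "combined"]
  )
  out <- list(predictions = preds, model = model)
  if (!is.null(target)) {
    stopifnot(length(target) == nrow(x))
    out$predictions$observed <- target
    out$metrics <- dplyr::bind_rows(lapply(cpm_tails, function(tail) {
      dplyr::mutate(evaluate_predictions(pred[, tail], target),
                    tail = tail, .before = 1)
    })) |>
      dplyr::mutate(meaningful = !is.na(.data$r) & .data$r >= 0)
    if (any(!out$metrics$meaningful)) {
      message("negative external correlation for tail(s): ",
              paste(out$metrics$tail[!out$metrics$meaningful],
                    collapse = ", "),
              " - not meaningful as prediction")
    }
  }
  structure(out, class = "cpm_external")
}

#' Prediction accuracy metrics
#'
#' The three CPM evaluation metrics: Pearson correlation between
#' predicted and observed, the coefficient of determination R² from the
#' regression of observed on predicted (for a single predictor with an
#' intercept this equals the squared correlation), and the mean absolute
#' error in target units.
#'
#' @param pred,obs Equal-length numeric vectors (>= 3).
#' @return One-row tibble: `r`, `r2`, `mae`, `n`, `note` (reason when r
#'   is undefined; MAE is always returned).
#' @export
evaluate_predictions <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(pred) >= 3)
  mae <- mean(abs(pred - obs))
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    return(tibble::tibble(
      r = NA_real_, r2 = NA_real_, mae = mae, n = length(pred),
      note = "constant input: correlation undefined"
    ))
  }
  r <- stats::cor(pred, obs)
  tibble::tibble(r = r, r2 = r^2, mae = mae, n = length(pred),
                 note = NA_character_)
}

#' @export
print.cpm_cv <- function(x, ...) {
  cat("CPM ", x$scheme, " (p < ", format(x$threshold), ", n = ",
      nrow(x$predictions),
      if (length(x$covariate_names))
        paste0(", covariates: ", paste(x$covariate_names, collapse = ", ")),
      "):\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @export
print.cpm_repeated_cv <- function(x, ...) {
  cat("CPM repeated ", x$k, "-fold x ", x$n_repeats, " (p < ",
      format(x$threshold), "):\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Serialise an aggregated CPM model
#'
#' Writes `<prefix>.json` (coefficients, rule, threshold, edge order,
#' node roster) and `<prefix>_edges.csv` (node_i, node_j, sign, selection
#' frequency).
#'
#' @param model A `cpm_aggregate`.
#' @param prefix Path prefix.
#' @export
write_cpm_model <- function(model, prefix) {
  stopifnot(inherits(model, "cpm_aggregate"))
  jsonlite::write_json(
    list(coefficients = apply(model$coefficients, 1, as.list,
                              simplify = FALSE),
         positive = model$positive, negative = model$negative,
         provenance = model$provenance),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  ei <- edge_index(model$provenance$n_nodes, model$provenance$node_ids)
  readr::write_csv(
    dplyr::inner_join(model$frequency, ei, by = "edge") |>
      dplyr::select("node_i", "node_j", "sign", "frequency"),
    paste0(prefix, "_edges.csv")
  )
  invisible(prefix)
}
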