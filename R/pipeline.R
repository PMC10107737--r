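#' Study configuration for the end-to-end pipeline
#'
#' Collects every setting of the full study replica — cohort sources,
#' motion-exclusion thresholds, edge-selection threshold (or an
#' optimisation grid), cross-validation scheme, covariates for adjusted
#' CPM, mask-aggregation rule, output directory and the root seed — into
#' one validated object consumed by [run_study()].
#'
#' @param training Generator settings for the training cohort (a list of
#'   [generator_config()] arguments) or `list(files = <dir>)` pointing at
#'   a serialised cohort.
#' @param external Settings for the external cohort, or `NULL` to skip
#'   the external stage. A generated external cohort shares the training
#'   cohort's planted edges (so transfer is possible by construction).
#' @param flip_external_sign Flip the sign of the external cohort's
#'   edge-reserve couplings — an in-silico replica of the
#'   task-to-rest generalisation failure mode.
#' @param mean_fwd_limit,ftf_quantile Motion-exclusion thresholds (see
#'   [flag_high_motion()]).
#' @param threshold Edge-selection p-value threshold; ignored when
#'   `optimize_grid` is given.
#' @param optimize_grid Optional threshold grid for data-driven
#'   optimisation.
#' @param scheme Cross-validation scheme: `"loocv"` or `"kfold"`.
#' @param k,repeats K-fold settings (used when `scheme = "kfold"`).
#' @param covariates Cohort columns to partial out at edge selection
#'   (e.g. `c("age", "sex", "mean_fwd")`); empty for plain CPM.
#' @param aggregation_rule,min_frequency Mask aggregation for external
#'   application (see [aggregate_model()]).
#' @param assignment Path to a node-network assignment CSV, or `NULL`
#'   for a seeded random assignment.
#' @param out_dir Output directory for serialised intermediates and the
#'   report; `NULL` keeps everything in memory.
#' @param seed Root seed; every stage derives a named sub-seed from it.
#' @return A `study_config` list (unvalidated; [validate_config()] is
#'   called by [run_study()]).
#' @export
study_config <- function(training = list(),
                         external = NULL,
                         flip_external_sign = FALSE,
                         mean_fwd_limit = 0.4,
                         ftf_quantile = 0.975,
                         threshold = 0.01,
                         optimize_grid = NULL,
                         scheme = "loocv",
                         k = 10,
                         repeats = 10,
                         covariates = character(0),
                         aggregation_rule = "intersection",
                         min_frequency = 0.5,
                         assignment = NULL,
                         out_dir = NULL,
                         seed = 1L) {
  structure(as.list(environment()), class = "study_config")
}

#' Validate and normalise a study configuration
#'
#' Fills defaults for missing fields, checks every constraint and
#' reports all violations at once.
#'
#' @param config A `study_config` or bare list of settings.
#' @return The normalised `study_config`; errors aggregate every
#'   violation found.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "study_config")) {
    config <- do.call(study_config, as.list(config))
  }
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  if (!config$scheme %in% c("loocv", "kfold")) {
    note(paste0("scheme must be 'loocv' or 'kfold', got '",
                config$scheme, "'"))
  }
  if (config$scheme == "kfold" && config$k < 2) {
    note("k must be at least 2")
  }
  if (!is.null(config$threshold) &&
      (config$threshold <= 0 || config$threshold > 1)) {
    note("threshold must lie in (0, 1]")
  }
  if (!is.null(config$optimize_grid) &&
      any(config$optimize_grid <= 0 | config$optimize_grid > 1)) {
    note(paste0("optimize_grid values outside (0, 1]: ",
                paste(config$optimize_grid[
                  config$optimize_grid <= 0 | config$optimize_grid > 1],
                  collapse = ", ")))
  }
  if (!config$aggregation_rule %in% c("intersection", "union",
                                      "frequency")) {
    note("aggregation_rule must be intersection, union or frequency")
  }
  if (config$mean_fwd_limit <= 0) note("mean_fwd_limit must be positive")
  if (config$ftf_quantile <= 0 || config$ftf_quantile >= 1) {
    note("ftf_quantile must lie in (0, 1)")
  }
  for (side in c("training", "external")) {
    src <- config[[side]]
    if (is.null(src)) next
    if (!is.null(src$files) && length(src) > 1) {
      note(paste0(side, ": give either files or generator settings, ",
                  "not both"))
    }
  }
  if (length(problems)) {
    stop("invalid study configuration:\n- ",
         paste(problems, collapse = "\n- "), call. = FALSE)
  }
  config
}

#' Read a study configuration from YAML or JSON
#'
#' @param path Path to a YAML (`.yml`/`.yaml`, requires the yaml
#'   package) or JSON configuration mirroring [study_config()].
#' @return A validated `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_config(raw)
}

# Load or compute one pipeline stage. When the study has an output
# directory, results are cached as RDS keyed by a hash of the stage's
# inputs, so re-running after deleting downstream outputs reuses
# upstream stages unchanged.
stage_cache <- function(out_dir, name, key, compute) {
  if (is.null(out_dir)) return(compute())
  dir.create(file.path(out_dir, "cache"), showWarnings = FALSE,
             recursive = TRUE)
  path <- file.path(out_dir, "cache",
                    paste0(name, "_", rlang::hash(key), ".rds"))
  if (file.exists(path)) return(readRDS(path))
  value <- compute()
  saveRDS(value, path)
  value
}

load_or_generate <- function(src, seed, planted = NULL, flip = FALSE) {
  if (!is.null(src$files)) {
    list(
      cohort = read_cohort(file.path(src$files, "cohort.csv")),
      matrices = read_matrix_set(file.path(src$files, "matrices",
                                           "manifest.csv")),
      truth = NULL
    )
  } else {
    args <- src
    args$seed <- seed
    cfg <- do.call(generator_config, args)
    if (flip) cfg$gamma <- -cfg$gamma
    generate_cohort(cfg, planted = planted)
  }
}

#' Run the full study replica
#'
#' Executes every stage in order from one [study_config()]: cohort
#' generation (or ingestion), motion-based exclusion, global-cognition
#' composite and CR residual, CPM with the configured scheme (optionally
#' with threshold optimisation), theoretical-validity testing of the
#' predicted reserve values, consensus-edge anatomy, and — when an
#' external cohort is configured — aggregation of the fold models and
#' external application. Re-running with the same config and seed
#' reproduces every number exactly.
#'
#' @param config A [study_config()] (validated on entry).
#' @return A `study_report`: list with per-stage results
#'   (`exclusions`, `residual_model`, `cpm`, `threshold_trace`,
#'   `validity`, `anatomy`, `external`) and a numeric `report` suitable
#'   for JSON serialisation, including provenance (config hash, seed,
#'   package version).
#' @export
run_study <- function(config) {
  cfg <- validate_config(config)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  cfg_key <- unclass(cfg)
  cfg_key$out_dir <- NULL # identical studies hash alike wherever written

  # --- stage 1: training cohort --------------------------------------
  train <- stage_cache(out_dir, "training_cohort",
                       list(cfg_key$training, cfg$seed), function() {
    load_or_generate(cfg$training, derive_seed(cfg$seed, 10L))
  })

  # --- stage 2: motion exclusion -------------------------------------
  keep <- stage_cache(out_dir, "exclusion",
                      list(cfg_key$training, cfg$seed,
                           cfg$mean_fwd_limit, cfg$ftf_quantile),
                      function() {
    if (!is.null(train$motion)) {
      flags <- flag_high_motion(train$motion,
                                mean_fwd_limit = cfg$mean_fwd_limit,
                                ftf_quantile = cfg$ftf_quantile)
    } else {
      flags <- tibble::tibble(
        subject_id = train$cohort$subject_id,
        excluded = train$cohort$mean_fwd > cfg$mean_fwd_limit
      )
    }
    flags
  })
  included <- keep$subject_id[!keep$excluded]
  cohort <- dplyr::filter(train$cohort, .data$subject_id %in% included)

  # --- stage 3: composite and CR residual ----------------------------
  res <- stage_cache(out_dir, "residual", list(cfg_key, included),
                     function() {
    fit_cr_residual(composite_cognition(cohort))
  })
  rd <- res$data
  x <- resolve_edge_matrix(train$matrices)[
    match(rd$subject_id, train$cohort$subject_id), , drop = FALSE]
  attr(x, "node_ids") <- attr(resolve_edge_matrix(train$matrices),
                              "node_ids")
  attr(x, "n_nodes") <- length(attr(x, "node_ids"))
  rownames(x) <- rd$subject_id
  target <- rd$cr_residual
  covariates <- if (length(cfg$covariates)) {
    as.matrix(rd[cfg$covariates])
  } else NULL

  # --- stage 4: CPM ---------------------------------------------------
  cpm <- stage_cache(out_dir, "cpm", list(cfg_key, included), function() {
    if (!is.null(cfg$optimize_grid)) {
      opt <- optimize_threshold(x, target, grid = cfg$optimize_grid,
                                scheme = cfg$scheme, k = cfg$k,
                                repeats = cfg$repeats,
                                covariates = covariates,
                                seed = derive_seed(cfg$seed, 30L))
      list(trace = opt, cv = opt$best, threshold = opt$best_threshold)
    } else if (cfg$scheme == "loocv") {
      list(trace = NULL,
           cv = run_loocv(x, target, p_threshold = cfg$threshold,
                          covariates = covariates),
           threshold = cfg$threshold)
    } else {
      list(trace = NULL,
           cv = run_repeated_kfold(x, target, k = cfg$k,
                                   repeats = cfg$repeats,
                                   p_threshold = cfg$threshold,
                                   covariates = covariates,
                                   seed = derive_seed(cfg$seed, 31L)),
           threshold = cfg$threshold)
    }
  })
  # validity and anatomy read from a single cpm_cv: the LOOCV result or
  # the first k-fold repeat
  cv1 <- if (inherits(cpm$cv, "cpm_cv")) cpm$cv else cpm$cv$repeats[[1]]

  # --- stage 5: validity ----------------------------------------------
  predicted <- cv1$predictions$predicted_combined
  validity <- list(
    face = face_validity(predicted, rd$proxy_score),
    hier = hierarchical_regression(rd, predicted)
  )

  # --- stage 6: anatomy -----------------------------------------------
  assignment <- if (is.null(cfg$assignment)) {
    random_assignment(cv1$node_ids, seed = derive_seed(cfg$seed, 40L))
  } else {
    read_network_assignment(cfg$assignment)
  }
  ce <- consensus_edges(cv1)
  anatomy <- anatomy_summary(ce, assignment)

  # --- stage 7: external application ----------------------------------
  external <- NULL
  if (!is.null(cfg$external)) {
    ext <- stage_cache(out_dir, "external_cohort",
                       list(cfg_key$external, cfg$seed,
                            cfg$flip_external_sign), function() {
      load_or_generate(cfg$external, derive_seed(cfg$seed, 20L),
                       planted = list(pos = train$truth$pos_edges,
                                      neg = train$truth$neg_edges),
                       flip = cfg$flip_external_sign)
    })
    ext_res <- fit_cr_residual(composite_cognition(ext$cohort))
    ext_x <- resolve_edge_matrix(ext$matrices)[
      match(ext_res$data$subject_id, ext$cohort$subject_id), ,
      drop = FALSE]
    attr(ext_x, "node_ids") <- attr(resolve_edge_matrix(ext$matrices),
                                    "node_ids")
    attr(ext_x, "n_nodes") <- length(attr(ext_x, "node_ids"))
    agg <- aggregate_model(cv1, rule = cfg$aggregation_rule,
                           min_frequency = cfg$min_frequency)
    applied <- apply_external(agg, ext_x,
                              target = ext_res$data$cr_residual)
    external <- list(model = agg, applied = applied,
                     residual_model = ext_res)
  }

  report <- list(
    n_generated = nrow(train$cohort),
    n_excluded_motion = sum(keep$excluded),
    n_analysed = res$n,
    residual_fit_r2 = res$fit_r2,
    threshold = cpm$threshold,
    training_metrics = as.data.frame(
      if (inherits(cpm$cv, "cpm_cv")) cpm$cv$metrics else cpm$cv$summary),
    face_validity = as.data.frame(validity$face),
    hierarchical = as.data.frame(validity$hier$steps),
    consensus_positive = nrow(ce$positive),
    consensus_negative = nrow(ce$negative),
    external_metrics = if (!is.null(external)) {
      as.data.frame(external$applied$metrics)
    },
    provenance = list(
      seed = cfg$seed,
      config_hash = rlang::hash(cfg_key),
      package_version = as.character(utils::packageVersion("cpmreserve"))
    )
  )
  out <- structure(
    list(config = cfg, exclusions = keep, residual_model = res,
         cpm = cpm$cv, threshold_trace = cpm$trace, validity = validity,
         consensus = ce, anatomy = anatomy, external = external,
         report = report),
    class = "study_report"
  )
  if (!is.null(out_dir)) write_study_report(out, out_dir)
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report (seed ", x$config$seed, "): n = ",
      x$report$n_analysed, " analysed (",
      x$report$n_excluded_motion, " excluded for motion)\n", sep = "")
  cat("Edge-selection threshold:", format(x$report$threshold), "\n")
  print(x$cpm)
  if (!is.null(x$external)) {
    cat("External application:\n")
    print(x$external$applied$metrics)
  }
  invisible(x)
}

#' Serialise a study report
#'
#' Writes the numeric report as JSON plus the main intermediates
#' (residuals, predictions, consensus edges) as CSV under `dir`.
#'
#' @param report A `study_report`.
#' @param dir Output directory.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_cr_residual(report$residual_model,
                    file.path(dir, "cr_residual"))
  cv <- report$cpm
  if (inherits(cv, "cpm_cv")) {
    readr::write_csv(cv$predictions, file.path(dir, "predictions.csv"))
  } else {
    readr::write_csv(cv$metrics, file.path(dir, "kfold_metrics.csv"))
  }
  readr::write_csv(report$consensus$frequency,
                   file.path(dir, "consensus_edges.csv"))
  if (!is.null(report$external)) {
    write_cpm_model(report$external$model,
                    file.path(dir, "aggregate_model"))
    readr::write_csv(report$external$applied$predictions,
                     file.path(dir, "external_predictions.csv"))
  }
  invisible(dir)
}
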