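#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a cohort with
#' demographics, brain structure, five cognitive subtests, a
#' verbal-intelligence proxy and one Fisher-z connectivity matrix per
#' subject, where cognition depends linearly on demographics/structure
#' plus a latent reserve variable, and a small set of planted edges
#' carries a signed reserve signal of known strength.
#'
#' Defaults mirror an ageing-cohort neuroimaging study: 200 subjects, a
#' 205-node connectome (a 268-node parcellation minus 63 cerebellum and
#' brainstem nodes), 10 planted edges per sign with an edge-reserve
#' coupling of Pearson r = 0.4, a latent-reserve SD of 0.6 (the scale of
#' observed reserve residuals), and mean framewise displacement around
#' 0.2 mm.
#'
#' @param n_subjects Number of subjects.
#' @param n_nodes Number of connectome nodes.
#' @param n_pos_edges,n_neg_edges Number of planted positively / negatively
#'   coupled edges (disjoint sets).
#' @param gamma Target Pearson correlation between each planted edge and
#'   the latent reserve, in (-1, 1); negative-tail edges use `-gamma`.
#' @param sigma_reserve SD of the latent reserve (composite-cognition
#'   units).
#' @param sigma_cog_noise SD of the cognition noise shared across subtests.
#' @param sigma_subtest_noise SD of per-subtest independent noise (on the
#'   common signal scale, before each subtest is rescaled).
#' @param structural_coefficients Named vector of effects of `age`, `sex`,
#'   `gm_volume`, `hippocampal_volume` and `cortical_thickness` on the
#'   cognition signal.
#' @param edge_mean,edge_sd Mean and SD of the i.i.d. baseline edge
#'   distribution on the Fisher-z scale.
#' @param motion_location,motion_scale Log-scale location and scale of the
#'   subject mean-FWD distribution (lognormal).
#' @param high_motion_fraction Probability that a subject is drawn as
#'   high-motion (mean FWD above 0.4 mm).
#' @param spike_fraction Probability that a subject's series contains a
#'   few isolated large frame-to-frame spikes (the events the pooled
#'   97.5th-percentile exclusion rule targets).
#' @param age_range Uniform age range (years).
#' @param seed Integer root seed; all draws flow from it.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_subjects = 200,
                             n_nodes = 205,
                             n_pos_edges = 10,
                             n_neg_edges = 10,
                             gamma = 0.4,
                             sigma_reserve = 0.6,
                             sigma_cog_noise = 0.3,
                             sigma_subtest_noise = 0.4,
                             structural_coefficients = c(
                               age = -0.015, sex = 0.1, gm_volume = 6,
                               hippocampal_volume = 200,
                               cortical_thickness = 0.4
                             ),
                             edge_mean = 0.3,
                             edge_sd = 0.25,
                             motion_location = log(0.18),
                             motion_scale = 0.3,
                             high_motion_fraction = 0,
                             spike_fraction = 0.05,
                             age_range = c(25, 80),
                             seed = 1L) {
  cfg <- structure(as.list(environment()), class = "generator_config")
  validate_generator_config(cfg)
}

#' @rdname generator_config
#' @param config A `generator_config` to validate.
#' @export
validate_generator_config <- function(config) {
  with(config, {
    if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
    if (n_nodes < 3) stop("n_nodes must be >= 3", call. = FALSE)
    if (n_pos_edges < 0 || n_neg_edges < 0) {
      stop("planted edge counts must be non-negative", call. = FALSE)
    }
    if (n_pos_edges + n_neg_edges > n_unique_edges(n_nodes)) {
      stop("n_pos_edges + n_neg_edges exceeds the number of unique edges (",
           n_unique_edges(n_nodes), ")", call. = FALSE)
    }
    if (abs(gamma) >= 1) stop("gamma must lie in (-1, 1)", call. = FALSE)
    for (nm in c("sigma_reserve", "sigma_cog_noise", "sigma_subtest_noise",
                 "edge_sd", "motion_scale")) {
      if (get(nm) <= 0) stop(nm, " must be > 0", call. = FALSE)
    }
    if (high_motion_fraction < 0 || high_motion_fraction > 1) {
      stop("high_motion_fraction must lie in [0, 1]", call. = FALSE)
    }
    if (spike_fraction < 0 || spike_fraction > 1) {
      stop("spike_fraction must lie in [0, 1]", call. = FALSE)
    }
    req <- c("age", "sex", "gm_volume", "hippocampal_volume",
             "cortical_thickness")
    if (!all(req %in% names(structural_coefficients))) {
      stop("structural_coefficients must name: ",
           paste(req, collapse = ", "), call. = FALSE)
    }
  })
  invisible(config)
}

# Coupling coefficient giving cor(edge, reserve) = gamma when the edge is
# baseline noise (sd = edge_sd) plus c * reserve (sd = sigma_reserve).
reserve_coupling <- function(gamma, edge_sd, sigma_reserve) {
  gamma / sqrt(1 - gamma^2) * edge_sd / sigma_reserve
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a full synthetic dataset from a [generator_config()]: a cohort
#' table, one connectivity matrix per subject, and the ground truth
#' (latent reserve and planted edge locations) that downstream
#' parameter-recovery tests compare against.
#'
#' The generative model: latent reserve `R ~ N(0, sigma_reserve)`; a
#' cognition signal that is linear in demographics/structure plus `R`
#' plus `N(0, sigma_cog_noise)`; five subtests, each the signal plus
#' independent noise, rescaled to test-specific units; edges i.i.d.
#' `N(edge_mean, edge_sd)` on the Fisher-z scale except the planted
#' edges, which add (positive tail) or subtract (negative tail) a
#' reserve term scaled so that the edge-reserve correlation is `gamma`;
#' a proxy score (verbal intelligence) loading on reserve and education.
#'
#' @param config A [generator_config()].
#' @param planted Optional list with tibbles `pos` and `neg` (columns
#'   `i`, `j`) fixing the planted edge locations — used to generate an
#'   external cohort sharing the truth of a training cohort.
#' @return A `synthetic_cohort`: list with `cohort` (tibble in the
#'   [cohort_columns()] schema), `matrices` (named list of Fisher-z
#'   matrices), `edge_values` (subjects x unique-edges matrix, canonical
#'   order), `truth` (list: `reserve`, `pos_edges`, `neg_edges`,
#'   `cognition_signal`) and `config`.
#' @export
generate_cohort <- function(config, planted = NULL) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  k <- config$n_nodes
  ei <- edge_index(k)
  n_edges <- nrow(ei)

  # --- demographics and structure ------------------------------------
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- stats::rbinom(n, 1, 0.5)
  education <- round(stats::runif(n, 10, 22))
  gm_volume <- 0.47 - 8e-4 * age + stats::rnorm(n, 0, 0.01)
  hippocampal_volume <- 0.006 - 1e-5 * age + stats::rnorm(n, 0, 5e-4)
  cortical_thickness <- 2.9 - 5e-3 * age + stats::rnorm(n, 0, 0.08)

  # --- latent reserve and cognition ----------------------------------
  reserve <- stats::rnorm(n, 0, config$sigma_reserve)
  b <- config$structural_coefficients
  signal <- b[["age"]] * age + b[["sex"]] * sex +
    b[["gm_volume"]] * gm_volume +
    b[["hippocampal_volume"]] * hippocampal_volume +
    b[["cortical_thickness"]] * cortical_thickness +
    reserve + stats::rnorm(n, 0, config$sigma_cog_noise)
  subtest_scale <- c(verbal_fluency = 12, processing_speed = 15,
                     executive_function = 10, immediate_memory = 8,
                     delayed_memory = 8)
  subtest_center <- c(verbal_fluency = 40, processing_speed = 55,
                      executive_function = 30, immediate_memory = 25,
                      delayed_memory = 20)
  subtests <- lapply(cr_subtests(), function(nm) {
    raw <- signal + stats::rnorm(n, 0, config$sigma_subtest_noise)
    subtest_center[[nm]] + subtest_scale[[nm]] * raw
  })
  names(subtests) <- cr_subtests()

  # proxy: verbal intelligence loads on reserve and education
  proxy_score <- 33 + 7 * reserve + 0.4 * (education - 16) +
    stats::rnorm(n, 0, 6)

  # --- planted edges --------------------------------------------------
  if (is.null(planted)) {
    pick <- sample.int(n_edges, config$n_pos_edges + config$n_neg_edges)
    pos_idx <- pick[seq_len(config$n_pos_edges)]
    neg_idx <- pick[config$n_pos_edges + seq_len(config$n_neg_edges)]
  } else {
    pos_idx <- match_planted(planted$pos, ei)
    neg_idx <- match_planted(planted$neg, ei)
    if (length(intersect(pos_idx, neg_idx))) {
      stop("planted edge sets must be disjoint", call. = FALSE)
    }
  }

  # --- edge values -----------------------------------------------------
  edge_values <- matrix(
    stats::rnorm(n * n_edges, config$edge_mean, config$edge_sd),
    nrow = n, ncol = n_edges
  )
  cpl <- reserve_coupling(config$gamma, config$edge_sd,
                          config$sigma_reserve)
  if (length(pos_idx)) {
    edge_values[, pos_idx] <- edge_values[, pos_idx] + cpl * reserve
  }
  if (length(neg_idx)) {
    edge_values[, neg_idx] <- edge_values[, neg_idx] - cpl * reserve
  }

  subject_id <- sprintf("S%03d", seq_len(n))
  rownames(edge_values) <- subject_id
  node_ids <- as.character(seq_len(k))
  attr(edge_values, "node_ids") <- node_ids
  attr(edge_values, "n_nodes") <- k
  matrices <- lapply(seq_len(n), function(s) {
    matrix_from_edges(edge_values[s, ], node_ids)
  })
  names(matrices) <- subject_id

  # --- motion ----------------------------------------------------------
  motion <- generate_motion(config, seed = derive_seed(config$seed, 1L))
  mean_fwd <- vapply(motion, `[[`, numeric(1), "mean_fwd")

  cohort <- tibble::tibble(
    subject_id = subject_id, age = age, sex = sex, education = education,
    proxy_score = proxy_score, !!!subtests, gm_volume = gm_volume,
    hippocampal_volume = hippocampal_volume,
    cortical_thickness = cortical_thickness, mean_fwd = mean_fwd
  )

  structure(
    list(
      cohort = cohort,
      matrices = matrices,
      edge_values = edge_values,
      truth = list(
        reserve = stats::setNames(reserve, subject_id),
        pos_edges = ei[pos_idx, ],
        neg_edges = ei[neg_idx, ],
        cognition_signal = stats::setNames(signal, subject_id)
      ),
      motion = motion,
      config = config
    ),
    class = "synthetic_cohort"
  )
}

match_planted <- function(tbl, ei) {
  if (is.null(tbl) || nrow(tbl) == 0) return(integer(0))
  idx <- match(paste(tbl$i, tbl$j), paste(ei$i, ei$j))
  if (anyNA(idx)) stop("planted edge outside the node roster", call. = FALSE)
  idx
}

# Sub-seed derivation: keeps derived seeds within 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1000003 + stream) %% .Machine$integer.max)
}

#' Generate per-subject framewise-displacement series
#'
#' Draws each subject's target mean FWD from a lognormal with the
#' config's location/scale (high-motion subjects instead get a mean
#' above 0.4 mm), then a tight gamma-distributed per-frame baseline
#' rescaled so its arithmetic mean equals the target; a `spike_fraction`
#' of subjects additionally receive a couple of isolated large spikes
#' (several times their baseline), which nudges their mean slightly
#' above target but never across the 0.4 mm line for low-motion
#' subjects. The first frame is 0 by definition.
#'
#' @param config A [generator_config()]; `motion_scale` must be positive.
#' @param n_frames Frames per subject.
#' @param seed Seed for this draw (defaults to the config's root seed).
#' @return Named list of `motion_record`s, one per subject.
#' @export
generate_motion <- function(config, n_frames = 200,
                            seed = config$seed) {
  validate_generator_config(config)
  set.seed(seed)
  n <- config$n_subjects
  high <- stats::runif(n) < config$high_motion_fraction
  spiky <- stats::runif(n) < config$spike_fraction
  target <- exp(stats::rnorm(n, config$motion_location, config$motion_scale))
  target[!high] <- pmin(target[!high], 0.37) # low-motion by construction
  target[high] <- 0.41 + stats::rexp(sum(high), rate = 10)
  out <- lapply(seq_len(n), function(s) {
    frames <- stats::rgamma(n_frames - 1, shape = 300, rate = 300)
    frames <- frames * ((n_frames * target[s]) / sum(frames))
    if (spiky[s]) {
      at <- sample.int(length(frames), 2)
      frames[at] <- frames[at] + stats::runif(2, 3, 6) * target[s]
    }
    motion_record(c(0, frames))
  })
  names(out) <- sprintf("S%03d", seq_len(n))
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$cohort), "subjects,",
      x$config$n_nodes, "nodes,",
      nrow(x$truth$pos_edges), "positive /", nrow(x$truth$neg_edges),
      "negative planted edges (gamma =", x$config$gamma, ")\n")
  invisible(x)
}

#' Serialise a synthetic cohort to plain-text files
#'
#' Writes the cohort CSV, per-subject matrix files plus manifest, the
#' ground-truth CSVs and the generator config as JSON into `dir`.
#'
#' @param sc A `synthetic_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_cohort <- function(sc, dir) {
  stopifnot(inherits(sc, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(sc$cohort, file.path(dir, "cohort.csv"))
  write_matrix_set(sc$matrices, file.path(dir, "matrices"))
  readr::write_csv(
    tibble::tibble(subject_id = names(sc$truth$reserve),
                   reserve = unname(sc$truth$reserve)),
    file.path(dir, "truth_reserve.csv")
  )
  readr::write_csv(dplyr::bind_rows(
    dplyr::mutate(sc$truth$pos_edges, sign = "positive"),
    dplyr::mutate(sc$truth$neg_edges, sign = "negative")
  ), file.path(dir, "truth_edges.csv"))
  cfg <- sc$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "generator_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
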