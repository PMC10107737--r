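# Shared small-scale fixtures, generated in code. The cache keeps the
# default small cohort from being regenerated in every test file.
.fixture_env <- new.env(parent = emptyenv())

small_config <- function(n_subjects = 60, n_nodes = 40, n_pos_edges = 4,
                         n_neg_edges = 4, gamma = 0.5, seed = 7, ...) {
  generator_config(n_subjects = n_subjects, n_nodes = n_nodes,
                   n_pos_edges = n_pos_edges, n_neg_edges = n_neg_edges,
                   gamma = gamma, seed = seed, ...)
}

small_cohort <- function() {
  if (is.null(.fixture_env$sc)) {
    .fixture_env$sc <- generate_cohort(small_config())
  }
  .fixture_env$sc
}

small_residual <- function() {
  if (is.null(.fixture_env$res)) {
    .fixture_env$res <- fit_cr_residual(
      composite_cognition(small_cohort()$cohort)
    )
  }
  .fixture_env$res
}

small_loocv <- function() {
  if (is.null(.fixture_env$cv)) {
    .fixture_env$cv <- run_loocv(small_cohort()$edge_values,
                                 small_residual()$data$cr_residual,
                                 p_threshold = 0.01)
  }
  .fixture_env$cv
}

# A tiny cohort table with hand-checkable numbers.
toy_cohort <- function() {
  tibble::tibble(
    subject_id = c("a", "b", "c", "d"),
    age = c(30, 40, 50, 60),
    sex = c(0, 1, 0, 1),
    education = c(12, 14, 16, 18),
    proxy_score = c(25, 30, 35, 40),
    verbal_fluency = c(30, 40, 50, 60),
    processing_speed = c(40, 50, 60, 70),
    executive_function = c(20, 25, 30, 35),
    immediate_memory = c(15, 20, 25, 30),
    delayed_memory = c(10, 15, 20, 25),
    gm_volume = c(0.44, 0.43, 0.42, 0.41),
    hippocampal_volume = c(0.0055, 0.0052, 0.0050, 0.0048),
    cortical_thickness = c(2.75, 2.68, 2.62, 2.55),
    mean_fwd = c(0.15, 0.2, 0.25, 0.3)
  )
}
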