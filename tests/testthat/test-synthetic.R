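test_that("generator config rejects invalid settings by name", {
  expect_error(generator_config(gamma = 1), "gamma")
  expect_error(generator_config(sigma_reserve = 0), "sigma_reserve")
  expect_error(generator_config(n_nodes = 5, n_pos_edges = 6,
                                n_neg_edges = 6), "unique edges")
  expect_error(generator_config(high_motion_fraction = 2),
               "high_motion_fraction")
  expect_error(
    generator_config(structural_coefficients = c(age = 1)),
    "structural_coefficients"
  )
})

test_that("the generator is bit-reproducible from its seed", {
  cfg <- small_config(n_subjects = 20, n_nodes = 12, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$edge_values, b$edge_values)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(small_config(n_subjects = 20, n_nodes = 12,
                                    seed = 100))
  expect_false(identical(a$edge_values, c$edge_values))
})

test_that("matrices are symmetric, zero-diagonal, and match the truth", {
  sc <- small_cohort()
  m <- sc$matrices[[3]]
  expect_no_error(validate_connectivity(m))
  expect_equal(nrow(sc$truth$pos_edges), sc$config$n_pos_edges)
  expect_equal(nrow(sc$truth$neg_edges), sc$config$n_neg_edges)
  expect_length(intersect(sc$truth$pos_edges$edge,
                          sc$truth$neg_edges$edge), 0)
  # edge_values really is the vectorised matrices
  expect_equal(edges_from_matrices(sc$matrices)[3, ],
               unname(sc$edge_values[3, ]))
})

test_that("planted edges carry the configured reserve coupling", {
  cfg <- generator_config(n_subjects = 300, n_nodes = 30,
                          n_pos_edges = 8, n_neg_edges = 8,
                          gamma = 0.4, seed = 1)
  sc <- generate_cohort(cfg)
  r_pos <- vapply(sc$truth$pos_edges$edge, function(e) {
    cor(sc$edge_values[, e], sc$truth$reserve)
  }, numeric(1))
  r_neg <- vapply(sc$truth$neg_edges$edge, function(e) {
    cor(sc$edge_values[, e], sc$truth$reserve)
  }, numeric(1))
  expect_equal(mean(r_pos), 0.4, tolerance = 0.05 / 0.4)
  expect_equal(mean(r_neg), -0.4, tolerance = 0.05 / 0.4)
})

test_that("gamma = 0 leaves planted edges at the null", {
  cfg <- generator_config(n_subjects = 400, n_nodes = 20,
                          n_pos_edges = 10, n_neg_edges = 10,
                          gamma = 0, seed = 2)
  sc <- generate_cohort(cfg)
  r <- vapply(c(sc$truth$pos_edges$edge, sc$truth$neg_edges$edge),
              function(e) cor(sc$edge_values[, e], sc$truth$reserve),
              numeric(1))
  expect_lt(max(abs(r)), 4 / sqrt(400)) # ~4 null SDs
})

test_that("non-planted edge correlations behave as a null at level alpha", {
  cfg <- generator_config(n_subjects = 150, n_nodes = 40,
                          n_pos_edges = 3, n_neg_edges = 3, seed = 5)
  sc <- generate_cohort(cfg)
  planted <- c(sc$truth$pos_edges$edge, sc$truth$neg_edges$edge)
  emp <- select_edges(sc$edge_values, sc$truth$reserve, p_threshold = 1)
  p_null <- emp$stats$p[-planted]
  for (alpha in c(0.01, 0.05)) {
    frac <- mean(p_null < alpha)
    mc_se <- sqrt(alpha * (1 - alpha) / length(p_null))
    expect_lt(abs(frac - alpha), 4 * mc_se + 1e-3)
  }
})

test_that("OLS on generated cognition recovers the structural coefficients", {
  cfg <- generator_config(n_subjects = 500, n_nodes = 10,
                          n_pos_edges = 0, n_neg_edges = 0, seed = 11)
  sc <- generate_cohort(cfg)
  d <- composite_cognition(sc$cohort)
  # the composite averages z-scored subtests, so refit on the raw signal
  # scale: regress the stored signal-plus-noise construction directly
  fit <- lm(sc$truth$cognition_signal ~ age + sex + gm_volume +
              hippocampal_volume + cortical_thickness, data = sc$cohort)
  est <- coef(fit)[-1]
  se <- summary(fit)$coefficients[-1, 2]
  truth <- cfg$structural_coefficients[names(est)]
  expect_true(all(abs(est - truth) < 3 * se))
  # and the composite is a monotone image: correlates strongly with signal
  expect_gt(cor(d$global_cognition, sc$truth$cognition_signal), 0.95)
})

test_that("residuals converge on the latent reserve as noise vanishes", {
  runs <- lapply(c(1, 0.3, 0.01), function(noise) {
    cfg <- generator_config(n_subjects = 200, n_nodes = 10,
                            n_pos_edges = 0, n_neg_edges = 0,
                            sigma_cog_noise = noise,
                            sigma_subtest_noise = noise, seed = 21)
    sc <- generate_cohort(cfg)
    m <- fit_cr_residual(composite_cognition(sc$cohort))
    list(m = m, sc = sc)
  })
  cors <- vapply(runs, function(run) {
    cor(run$m$data$cr_residual, run$sc$truth$reserve)
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
  expect_gt(cors[3], 0.95)
  # the exact zero-noise limit is the reserve *residualised on the
  # predictors* (the finite-sample ceiling); against that oracle the
  # correlation reaches 1
  low <- runs[[3]]
  oracle <- resid(lm(low$sc$truth$reserve ~ age + sex + gm_volume +
                       hippocampal_volume + cortical_thickness,
                     data = low$sc$cohort))
  expect_gt(cor(low$m$data$cr_residual, oracle), 0.999)
})

test_that("generated motion respects the high-motion fraction", {
  cfg0 <- small_config(n_subjects = 50, high_motion_fraction = 0,
                       seed = 31)
  mot0 <- generate_motion(cfg0)
  means <- vapply(mot0, `[[`, numeric(1), "mean_fwd")
  expect_true(all(means <= 0.4))
  expect_true(all(unlist(lapply(mot0, `[[`, "fwd")) >= 0))

  expect_identical(generate_motion(cfg0), mot0) # seeded determinism

  cfg2 <- small_config(n_subjects = 100, high_motion_fraction = 0.2,
                       seed = 32)
  mot2 <- generate_motion(cfg2)
  n_high <- sum(vapply(mot2, `[[`, numeric(1), "mean_fwd") > 0.4)
  ci <- qbinom(c(0.005, 0.995), 100, 0.2)
  expect_gte(n_high, ci[1])
  expect_lte(n_high, ci[2])
})

test_that("a synthetic cohort round-trips through its text serialisation", {
  sc <- generate_cohort(small_config(n_subjects = 6, n_nodes = 8,
                                     n_pos_edges = 2, n_neg_edges = 2,
                                     seed = 41))
  d <- withr::local_tempdir()
  write_synthetic_cohort(sc, d)
  cohort <- read_cohort(file.path(d, "cohort.csv"))
  expect_equal(as.data.frame(cohort), as.data.frame(sc$cohort),
               tolerance = 1e-12)
  mats <- read_matrix_set(file.path(d, "matrices", "manifest.csv"))
  expect_equal(mats, sc$matrices, tolerance = 1e-12)
  truth <- readr::read_csv(file.path(d, "truth_edges.csv"),
                           show_col_types = FALSE)
  expect_equal(nrow(truth), 4)
})
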