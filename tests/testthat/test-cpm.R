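test_that("edge correlations agree with stats::cor and cor.test", {
  set.seed(3)
  x <- matrix(rnorm(40 * 30), 40, 30)
  y <- rnorm(40)
  emp <- select_edges(x, y, p_threshold = 1)
  ref_r <- apply(x, 2, cor, y)
  ref_p <- apply(x, 2, function(col) cor.test(col, y)$p.value)
  expect_equal(emp$stats$r, ref_r, tolerance = 1e-12)
  expect_equal(emp$stats$p, ref_p, tolerance = 1e-10)
})

test_that("partial correlation equals residualise-then-correlate", {
  set.seed(4)
  n <- 50
  cv <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  x <- matrix(rnorm(n * 10) + 0.5 * cv[, "age"], n, 10)
  y <- rnorm(n) + 0.3 * cv[, "age"]
  emp <- select_edges(x, y, p_threshold = 1, covariates = cv)
  ref <- apply(x, 2, function(col) {
    cor(resid(lm(col ~ cv)), resid(lm(y ~ cv)))
  })
  expect_equal(emp$stats$r, unname(ref), tolerance = 1e-10)
  expect_equal(emp$df, n - 4L)
})

test_that("a strongly coupled edge is selected with high probability", {
  # power of the correlation test at n = 200, population r = 0.6,
  # alpha = 9e-4 exceeds 0.99 (Fisher-z approximation); check one seeded
  # draw lands in the positive mask
  set.seed(5)
  n <- 200
  latent <- rnorm(n)
  x <- matrix(rnorm(n * 50), n, 50)
  x[, 7] <- 0.6 / sqrt(1 - 0.36) * latent + rnorm(n)
  emp <- select_edges(x, latent, p_threshold = 9e-4)
  expect_true(7 %in% emp$positive)
  # analytic power check of the stated claim
  crit <- qnorm(1 - 9e-4 / 2) / sqrt(n - 3)
  power <- pnorm((atanh(0.6) - crit) * sqrt(n - 3))
  expect_gt(power, 0.99)
})

test_that("select_edges edge cases: empty threshold, constant target", {
  set.seed(6)
  x <- matrix(rnorm(20 * 10), 20, 10)
  emp <- select_edges(x, rnorm(20), p_threshold = 0)
  expect_length(emp$positive, 0)
  expect_length(emp$negative, 0)
  expect_error(select_edges(x, rep(1, 20), 0.05), "constant")
  expect_error(select_edges(x, rnorm(20), 0.05,
                            covariates = cbind(x[, 1], x[, 1] * 2)),
               NA) # collinear covariates alone are fine via QR
  y <- rnorm(20)
  expect_error(select_edges(x, y, 0.05, covariates = cbind(y)),
               "collinear")
})

test_that("network strength halves the full-matrix masked sum", {
  # 3-node toy: unique edges 0.2, -0.1, 0.4 -> all-edge strength 0.5
  m <- matrix_from_edges(c(0.2, -0.1, 0.4), node_ids = 1:3)
  mask <- matrix_from_edges(c(1, 1, 1), node_ids = 1:3)
  expect_equal(network_strength(m, mask), 0.5)
  expect_equal(network_strength(matrix(0, 3, 3), mask), 0)
  expect_equal(network_strength(m, matrix(0, 3, 3)), 0)
  expect_error(network_strength(m, matrix(0, 4, 4)), "dimensions")
})

test_that("network strength equals a brute-force pair loop", {
  set.seed(7)
  for (trial in 1:20) {
    k <- sample(3:20, 1)
    ne <- n_unique_edges(k)
    m <- matrix_from_edges(rnorm(ne), node_ids = 1:k)
    mask <- matrix_from_edges(rbinom(ne, 1, 0.3), node_ids = 1:k)
    brute <- 0
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        if (mask[i, j] == 1) brute <- brute + m[i, j]
      }
    }
    expect_equal(network_strength(m, mask), brute, tolerance = 1e-12)
  }
})

test_that("combined strength is the signed-mask identity", {
  expect_equal(combined_strength(0, 0), 0)
  expect_equal(combined_strength(1.5, 0.5), 1)
  set.seed(8)
  ne <- n_unique_edges(6)
  vals <- rnorm(ne)
  m <- matrix_from_edges(vals, 1:6)
  pos <- rbinom(ne, 1, 0.3)
  neg <- rbinom(ne, 1, 0.3) * (1 - pos) # disjoint
  signed <- matrix_from_edges(pos - neg, 1:6)
  expect_equal(
    combined_strength(network_strength(m, matrix_from_edges(pos, 1:6)),
                      network_strength(m, matrix_from_edges(neg, 1:6))),
    sum(m * signed) / 2,
    tolerance = 1e-12
  )
})

test_that("the strength model matches closed-form least squares", {
  s <- c(1, 2, 3, 4)
  expect_equal(fit_strength_model(s, 2 * s + 1),
               c(intercept = 1, slope = 2))
  sc <- s - mean(s)
  y <- c(-1, 0.5, 0, 0.5)
  co <- fit_strength_model(sc, y - mean(y))
  expect_equal(unname(co["intercept"]), 0)
  # normal equations by hand
  expect_equal(unname(co["slope"]),
               sum(sc * (y - mean(y))) / sum(sc^2))
  expect_error(fit_strength_model(rep(2, 5), rnorm(5)), "constant")
})

test_that("evaluation metrics match hand arithmetic", {
  obs <- c(1, 2, 3, 4, 5)
  expect_equal(evaluate_predictions(obs, obs)$r, 1)
  expect_equal(evaluate_predictions(obs, obs)$mae, 0)
  m <- evaluate_predictions(-obs + 6, obs) # reversed
  expect_equal(m$r, -1)

  pred <- c(1.5, 2.5, 2, 4.5, 4)
  m <- evaluate_predictions(pred, obs)
  expect_equal(m$r, cor(pred, obs))
  expect_equal(m$r2, summary(lm(obs ~ pred))$r.squared, tolerance = 1e-12)
  expect_equal(m$mae, mean(abs(pred - obs)))

  const <- evaluate_predictions(rep(1, 5), obs)
  expect_true(is.na(const$r))
  expect_match(const$note, "constant")
  expect_equal(const$mae, mean(abs(1 - obs)))
})

test_that("LOOCV predicts every subject out of fold without leakage", {
  cv <- small_loocv()
  n <- nrow(small_cohort()$cohort)
  expect_equal(nrow(cv$predictions), n)
  expect_false(anyNA(cv$predictions$predicted_combined))
  expect_length(cv$folds, n)

  # leakage audit: stored fold masks equal a from-scratch selection on
  # the n-1 training subjects, and differ from the full-sample masks
  x <- small_cohort()$edge_values
  target <- small_residual()$data$cr_residual
  full <- select_edges(x, target, cv$threshold)
  audited <- c(1, 17, 42)
  any_differs <- FALSE
  for (i in audited) {
    ref <- select_edges(x[-i, , drop = FALSE], target[-i], cv$threshold)
    expect_identical(cv$folds[[i]]$positive, ref$positive)
    expect_identical(cv$folds[[i]]$negative, ref$negative)
    if (!identical(ref$stats$p, full$stats$p)) any_differs <- TRUE
  }
  expect_true(any_differs)
})

test_that("planted-signal LOOCV recovers signal; permuted target does not", {
  cv <- small_loocv()
  comb <- dplyr::filter(cv$metrics, tail == "combined")
  expect_gt(comb$r, 0.3)

  set.seed(123)
  perm <- sample(small_residual()$data$cr_residual)
  cvp <- suppressWarnings(
    run_loocv(small_cohort()$edge_values, perm, p_threshold = 0.01)
  )
  rp <- dplyr::filter(cvp$metrics, tail == "combined")$r
  expect_lt(abs(rp), 0.25)
})

test_that("repeated k-fold is seeded, summarised, and equals LOOCV at k = n", {
  x <- small_cohort()$edge_values
  target <- small_residual()$data$cr_residual
  n <- length(target)

  rk <- run_repeated_kfold(x, target, k = n, repeats = 1,
                           p_threshold = 0.01, seed = 5)
  cv <- small_loocv()
  expect_identical(rk$repeats[[1]]$predictions$predicted_positive,
                   cv$predictions$predicted_positive)
  expect_identical(rk$repeats[[1]]$predictions$predicted_combined,
                   cv$predictions$predicted_combined)

  r5a <- run_repeated_kfold(x, target, k = 5, repeats = 3,
                            p_threshold = 0.01, seed = 9)
  r5b <- run_repeated_kfold(x, target, k = 5, repeats = 3,
                            p_threshold = 0.01, seed = 9)
  expect_identical(r5a$metrics, r5b$metrics)
  expect_identical(r5a$repeats[[2]]$fold, r5b$repeats[[2]]$fold)
  # folds balanced within 1
  sizes <- table(r5a$repeats[[1]]$fold)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(nrow(r5a$summary), 3)

  expect_error(run_repeated_kfold(x, target, k = n + 1), "exceeds")
  expect_error(run_repeated_kfold(x, target, k = 1), "at least 2")
})

test_that("k-fold accuracy tracks LOOCV accuracy on planted signal", {
  x <- small_cohort()$edge_values
  target <- small_residual()$data$cr_residual
  rk <- run_repeated_kfold(x, target, k = 10, repeats = 10,
                           p_threshold = 0.01, seed = 2)
  r_kfold <- dplyr::filter(rk$summary, tail == "combined")$r_mean
  r_loocv <- dplyr::filter(small_loocv()$metrics, tail == "combined")$r
  expect_lt(abs(r_kfold - r_loocv), 0.15)
})

test_that("threshold optimisation picks the best grid point", {
  x <- small_cohort()$edge_values
  target <- small_residual()$data$cr_residual

  single <- optimize_threshold(x, target, grid = 0.01)
  expect_equal(single$best_threshold, 0.01)

  opt <- optimize_threshold(x, target, grid = c(0.001, 0.01, 0.05))
  expect_equal(nrow(opt$trace), 3)
  expect_equal(opt$best_threshold,
               opt$trace$threshold[which.max(opt$trace$r)])
  expect_true(opt$significant)

  expect_error(optimize_threshold(x, target, grid = c(0.01, 1.5)),
               "\\(0, 1\\]")
  expect_error(optimize_threshold(x, target, grid = numeric(0)), "empty")
})

test_that("pure-noise cohorts yield a non-significant optimisation trace", {
  cfg <- small_config(n_subjects = 40, n_nodes = 20, n_pos_edges = 0,
                      n_neg_edges = 0, seed = 77)
  sc <- generate_cohort(cfg)
  set.seed(1)
  noise_target <- rnorm(40)
  opt <- suppressWarnings(
    optimize_threshold(sc$edge_values, noise_target,
                       grid = c(0.005, 0.05))
  )
  expect_false(opt$significant)
  # no spurious positive accuracy; strongly negative r can occur at
  # strict thresholds because fold-mean fallback predictions are
  # anticorrelated with held-out targets by construction
  expect_lt(max(opt$trace$r, na.rm = TRUE), 0.4)
})

test_that("aggregation rules match hand enumeration on a toy fold set", {
  cv <- small_loocv()
  toy <- cv
  toy$folds <- list(
    list(fold = 1, positive = c(1L, 2L, 3L), negative = c(9L),
         coefficients = matrix(1, 3, 2,
                               dimnames = list(cpmreserve:::cpm_tails,
                                               c("intercept", "slope")))),
    list(fold = 2, positive = c(2L, 3L), negative = c(9L, 10L),
         coefficients = matrix(2, 3, 2,
                               dimnames = list(cpmreserve:::cpm_tails,
                                               c("intercept", "slope")))),
    list(fold = 3, positive = c(3L), negative = c(9L),
         coefficients = matrix(3, 3, 2,
                               dimnames = list(cpmreserve:::cpm_tails,
                                               c("intercept", "slope"))))
  )
  inter <- aggregate_model(toy, rule = "intersection")
  expect_identical(inter$positive, 3L)
  expect_identical(inter$negative, 9L)
  expect_equal(unname(inter$coefficients["combined", "slope"]), 2)

  un <- aggregate_model(toy, rule = "union")
  expect_identical(un$positive, 1:3)
  expect_identical(un$negative, c(9L, 10L))

  fr <- aggregate_model(toy, rule = "frequency", min_frequency = 2 / 3)
  expect_identical(fr$positive, 2:3)
  expect_identical(fr$negative, 9L)

  single <- cv
  single$folds <- cv$folds[1]
  ag1 <- aggregate_model(single, rule = "union")
  expect_identical(ag1$positive, cv$folds[[1]]$positive)
  expect_equal(ag1$coefficients, cv$folds[[1]]$coefficients)
})

test_that("external application is consistent, transfers, and flags flips", {
  # a cohort large enough for stable fold masks
  sc <- generate_cohort(small_config(n_subjects = 100, seed = 7))
  res <- fit_cr_residual(composite_cognition(sc$cohort))
  cv <- run_loocv(sc$edge_values, res$data$cr_residual,
                  p_threshold = 0.01)
  agg <- aggregate_model(cv, rule = "frequency", min_frequency = 0.9)

  # applied back to training: tracks the LOOCV predictions
  back <- apply_external(agg, sc$edge_values,
                         target = res$data$cr_residual)
  expect_gt(cor(back$predictions$predicted_combined,
                cv$predictions$predicted_combined), 0.9)

  # shared-truth external cohort: positive out-of-sample r
  ext_cfg <- small_config(n_subjects = 50, seed = 101)
  ext <- generate_cohort(ext_cfg,
                         planted = list(pos = sc$truth$pos_edges,
                                        neg = sc$truth$neg_edges))
  ext_res <- fit_cr_residual(composite_cognition(ext$cohort))
  fwd <- apply_external(agg, ext$edge_values,
                        target = ext_res$data$cr_residual)
  comb <- dplyr::filter(fwd$metrics, tail == "combined")
  expect_gt(comb$r, 0)
  expect_true(comb$meaningful)

  # sign-flipped couplings: negative r, flagged not meaningful
  flip_cfg <- ext_cfg
  flip_cfg$gamma <- -flip_cfg$gamma
  flipped <- generate_cohort(flip_cfg,
                             planted = list(pos = sc$truth$pos_edges,
                                            neg = sc$truth$neg_edges))
  flip_res <- fit_cr_residual(composite_cognition(flipped$cohort))
  expect_message(
    rev <- apply_external(agg, flipped$edge_values,
                          target = flip_res$data$cr_residual),
    "not meaningful"
  )
  comb_rev <- dplyr::filter(rev$metrics, tail == "combined")
  expect_lt(comb_rev$r, 0)
  expect_false(comb_rev$meaningful)

  # node roster mismatch
  bad <- ext$edge_values[, 1:n_unique_edges(10)]
  attr(bad, "node_ids") <- as.character(1:10)
  attr(bad, "n_nodes") <- 10L
  expect_error(apply_external(agg, bad), "roster")
})

test_that("combined metrics ignore constant shifts of unselected edges", {
  sc <- small_cohort()
  target <- small_residual()$data$cr_residual
  cv <- small_loocv()
  selected <- sort(unique(unlist(lapply(cv$folds, function(f) {
    c(f$positive, f$negative)
  }))))
  shifted <- sc$edge_values
  unsel <- setdiff(seq_len(ncol(shifted)), selected)
  shifted[, unsel] <- shifted[, unsel] + 100
  cv2 <- run_loocv(shifted, target, p_threshold = cv$threshold)
  expect_equal(dplyr::filter(cv2$metrics, tail == "combined")$r,
               dplyr::filter(cv$metrics, tail == "combined")$r,
               tolerance = 1e-8)
})

test_that("aggregated models serialise to JSON + edge CSV and read back", {
  cv <- small_loocv()
  agg <- aggregate_model(cv, rule = "frequency", min_frequency = 0.9)
  prefix <- file.path(withr::local_tempdir(), "model")
  write_cpm_model(agg, prefix)
  js <- jsonlite::read_json(paste0(prefix, ".json"),
                            simplifyVector = TRUE)
  expect_equal(js$positive, agg$positive)
  expect_equal(js$provenance$rule, "frequency")
  edges <- readr::read_csv(paste0(prefix, "_edges.csv"),
                           show_col_types = FALSE)
  expect_named(edges, c("node_i", "node_j", "sign", "frequency"))
})
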