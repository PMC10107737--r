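#' Face validity of a candidate reserve measure
#'
#' A reserve measure has face validity if it correlates positively with
#' an established socio-behavioural proxy (here, verbal intelligence).
#'
#' @param measure,proxy Per-subject numeric vectors (equal length >= 4).
#' @param alpha Significance level for the verdict.
#' @return A one-row tibble: `r`, `p` (two-sided), `n`, `valid`
#'   (`r > 0 & p < alpha`).
#' @export
face_validity <- function(measure, proxy, alpha = 0.05) {
  stopifnot(length(measure) == length(proxy), length(measure) >= 4)
  if (stats::sd(measure) == 0 || stats::sd(proxy) == 0) {
    stop("face validity needs nonconstant measure and proxy", call. = FALSE)
  }
  ct <- stats::cor.test(measure, proxy)
  tibble::tibble(
    r = unname(ct$estimate), p = ct$p.value, n = length(measure),
    valid = unname(ct$estimate) > 0 && ct$p.value < alpha
  )
}

#' Hierarchical regression for independence and moderation effects
#'
#' Tests the protective effect of a candidate reserve measure with three
#' nested OLS models: Step 1 regresses global cognition on age, sex and
#' mean cortical thickness; Step 2 adds the measure (its R² increment is
#' the *independence* effect — variance in cognition explained beyond
#' brain structure); Step 3 adds the cortical-thickness x measure
#' interaction (the *moderation* effect). Each increment gets a
#' nested-model F test. The interaction is built from mean-centred
#' components by default so the Step-3 increment does not depend on the
#' location of either variable; `center = FALSE` uses the raw product.
#'
#' @param data Cohort tibble with the cognition and Step-1 columns.
#' @param measure Per-subject candidate reserve measure (same order as
#'   `data`), or the name of a column of `data`.
#' @param cognition Name of the cognition column.
#' @param step1 Step-1 predictor columns.
#' @param moderator The structural variable forming the interaction.
#' @param center Mean-centre the interaction components?
#' @return A `hier_reg`: list of the three `lm` fits plus a `steps`
#'   tibble (`step`, `r2`, `delta_r2`, `f`, `df1`, `df2`, `p`).
#' @export
hierarchical_regression <- function(data, measure,
                                    cognition = "global_cognition",
                                    step1 = c("age", "sex",
                                              "cortical_thickness"),
                                    moderator = "cortical_thickness",
                                    center = TRUE) {
  if (is.character(measure) && length(measure) == 1) {
    measure <- data[[measure]]
  }
  stopifnot(length(measure) == nrow(data), moderator %in% step1)
  d <- dplyr::select(data, dplyr::all_of(c(cognition, step1)))
  d$..measure <- measure
  ctr <- function(x) if (center) x - mean(x) else x
  d$..interaction <- ctr(d[[moderator]]) * ctr(measure)

  fits <- list(
    stats::lm(stats::reformulate(step1, response = cognition), data = d),
    stats::lm(stats::reformulate(c(step1, "..measure"),
                                 response = cognition), data = d),
    stats::lm(stats::reformulate(c(step1, "..measure", "..interaction"),
                                 response = cognition), data = d)
  )
  for (s in 1:3) {
    if (any(is.na(stats::coef(fits[[s]])))) {
      stop("rank-deficient design at step ", s, call. = FALSE)
    }
  }
  r2 <- vapply(fits, function(f) summary(f)$r.squared, numeric(1))
  inc <- function(a, b) {
    an <- stats::anova(fits[[a]], fits[[b]])
    c(f = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2], p = an$`Pr(>F)`[2])
  }
  i12 <- inc(1, 2); i23 <- inc(2, 3)
  steps <- tibble::tibble(
    step = 1:3,
    r2 = r2,
    delta_r2 = c(NA, r2[2] - r2[1], r2[3] - r2[2]),
    f = c(NA, i12["f"], i23["f"]),
    df1 = c(NA, i12["df1"], i23["df1"]),
    df2 = c(NA, i12["df2"], i23["df2"]),
    p = c(NA, i12["p"], i23["p"])
  )
  structure(list(fits = fits, steps = steps, center = center,
                 moderator = moderator),
            class = "hier_reg")
}

#' @export
print.hier_reg <- function(x, ...) {
  cat("Hierarchical regression (independence / moderation):\n")
  print(x$steps)
  invisible(x)
}

#' Pooled two-sample t-test from group summaries
#'
#' Independent-samples t-test computed from per-group (n, mean, sd)
#' triples with a pooled variance estimate and `n1 + n2 - 2` degrees of
#' freedom — the form that reproduces published group comparisons from
#' their printed descriptive statistics. A Welch variant is available.
#'
#' @param n1,mean1,sd1 Summary of group 1.
#' @param n2,mean2,sd2 Summary of group 2.
#' @param welch Use the Welch (unequal-variance) statistic instead.
#' @return A one-row tibble: `t`, `df`, `p` (two-sided).
#' @examples
#' pooled_t(220, 51.905, 17.043, 294, 68.301, 7.177) # t ~ -14.84
#' @export
pooled_t <- function(n1, mean1, sd1, n2, mean2, sd2, welch = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 != mean2) {
      stop("both groups have zero variance but unequal means: ",
           "t is undefined", call. = FALSE)
    }
    return(tibble::tibble(t = 0, df = n1 + n2 - 2, p = 1))
  }
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / (sd1^4 / (n1^2 * (n1 - 1)) + sd2^4 / (n2^2 * (n2 - 1)))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tibble::tibble(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Group summary triples from raw data
#'
#' @param data Tibble.
#' @param var Name of the numeric variable.
#' @param group Name of the grouping column.
#' @return Tibble with one row per group: `group`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(data, var, group) {
  data |>
    dplyr::group_by(.group = .data[[group]]) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data[[var]]),
                     sd = stats::sd(.data[[var]]), .groups = "drop") |>
    dplyr::rename(group = ".group")
}

#' Chi-square test for a 2x2 frequency table
#'
#' Pearson chi-square without continuity correction (df = 1) — the form
#' matching published sex-by-dataset comparisons computed from printed
#' counts.
#'
#' @param counts 2x2 matrix (or object coercible to one) of frequencies.
#' @return A one-row tibble: `chi2`, `df`, `p`.
#' @examples
#' chi2_2x2(matrix(c(115, 105, 152, 142), 2, byrow = TRUE)) # ~0.016
#' @export
chi2_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(2L, 2L)), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal: expected counts are undefined", call. = FALSE)
  }
  ht <- stats::chisq.test(counts, correct = FALSE)
  tibble::tibble(chi2 = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value)
}
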