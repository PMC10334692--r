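# sex coding used throughout: 0 = male, 1 = female
.sex_indicator <- function(sex) {
  s <- match(sex, c("male", "female")) - 1L
  if (anyNA(s)) {
    stop(errorCondition("sex must be 'male' or 'female'",
                        class = c("migstates_argument_error", "error", "condition")))
  }
  s
}

#' Resample lifetime-prevalence tables from their confidence limits
#'
#' For each lifetime point, draws `n_samples` values from a normal
#' distribution centred at the reported prevalence with standard deviation
#' `(upper - lower) / (2 * 1.96)`. Draws outside (0, 1) are recorded as
#' missing (the logit is undefined there); they are counted, never dropped.
#'
#' @param points A [lifetime_table] (or data frame with `sex`, `age_mid`,
#'   `q0`, `lower`, `upper`).
#' @param n_samples Number of resampled tables (>= 1).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return Tibble with one row per (sample, point): columns `sample`, `sex`,
#'   `age_mid`, `q0` (`NA` where the draw fell outside (0, 1)).
#' @export
sample_lifetime_sets <- function(points, n_samples, seed = 1) {
  stopifnot(n_samples >= 1)
  d <- tibble::as_tibble(points)
  if (any(d$upper <= d$lower)) {
    stop(errorCondition("every point needs upper > lower confidence limits",
                        class = c("migstates_argument_error", "error", "condition")))
  }
  sd_pt <- (d$upper - d$lower) / (2 * 1.96)
  n_pt <- nrow(d)
  draws <- withr::with_seed(seed, {
    stats::rnorm(n_pt * n_samples,
                 mean = rep(d$q0, times = n_samples),
                 sd = rep(sd_pt, times = n_samples))
  })
  draws[draws <= 0 | draws >= 1] <- NA_real_
  tibble::tibble(
    sample = rep(seq_len(n_samples), each = n_pt),
    sex = rep(d$sex, times = n_samples),
    age_mid = rep(d$age_mid, times = n_samples),
    q0 = draws)
}

#' Logit-linear regression of lifetime prevalence on age and sex
#'
#' Ordinary least squares of `logit(q0)` on age, a female indicator, and
#' their interaction: coefficients `b0` (intercept), `b1` (age slope, per
#' year), `b2` (female main effect), `b3` (age-by-female interaction). With
#' two ages per sex the fit is saturated and interpolates exactly.
#'
#' @param sampled_table Data frame with columns `sex`, `age_mid`, `q0`
#'   (`NA` rows are treated as missing).
#' @return Named numeric vector `c(b0, b1, b2, b3)`, or `NULL` when the
#'   design is rank-deficient (for example one sex entirely missing) or has
#'   fewer than 4 usable points or fewer than 2 distinct ages in either sex.
#' @export
fit_logit_model <- function(sampled_table) {
  d <- sampled_table[!is.na(sampled_table$q0), , drop = FALSE]
  if (nrow(d) < 4) return(NULL)
  s <- .sex_indicator(d$sex)
  if (length(unique(d$age_mid[s == 0])) < 2 ||
      length(unique(d$age_mid[s == 1])) < 2) return(NULL)
  X <- cbind(1, d$age_mid, s, d$age_mid * s)
  fit <- stats::lm.fit(X, stats::qlogis(d$q0))
  if (fit$rank < 4) return(NULL)
  stats::setNames(fit$coefficients, c("b0", "b1", "b2", "b3"))
}

#' Admissibility of a lifetime-regression coefficient set
#'
#' A set is admissible when the implied lifetime prevalence is increasing in
#' age for both sexes: `b1 > 0` (males) and `b1 + b3 > 0` (females).
#'
#' @param coefs Named vector `c(b0, b1, b2, b3)`.
#' @return Logical scalar.
#' @export
coef_admissible <- function(coefs) {
  is.finite(coefs[["b1"]]) && is.finite(coefs[["b3"]]) &&
    coefs[["b1"]] > 0 && coefs[["b1"]] + coefs[["b3"]] > 0
}

#' Baseline never-migraine functions from a pooled coefficient set
#'
#' Builds the three closures derived from the logit-linear lifetime model:
#' lifetime prevalence `q0(age, sex)`, never-migraine prevalence
#' `p0 = 1 - q0`, and the first-incidence hazard among the never-migraine
#' pool, `i0 = q0'/(1 - q0) = (b1 + b3 s) q0` — the susceptible-pool
#' incidence implied by a closed cohort in which the ever-had-migraine pool
#' can only be entered, never left.
#'
#' @param coefs Named vector `c(b0, b1, b2, b3)`.
#' @param n_valid,n_total Bookkeeping counts from pooling (optional).
#' @return Object of class `baseline_functions`: list with `coefs`, vectorized
#'   functions `q0(age, sex)`, `p0(age, sex)`, `i0(age, sex)`, and the counts.
#' @export
baseline_from_coefs <- function(coefs, n_valid = NA_integer_, n_total = NA_integer_) {
  stopifnot(all(c("b0", "b1", "b2", "b3") %in% names(coefs)))
  b <- coefs
  q0 <- function(age, sex) {
    s <- .sex_indicator(sex)
    stats::plogis(b[["b0"]] + b[["b1"]] * age + b[["b2"]] * s + b[["b3"]] * age * s)
  }
  structure(list(
    coefs = b[c("b0", "b1", "b2", "b3")],
    q0 = q0,
    p0 = function(age, sex) 1 - q0(age, sex),
    i0 = function(age, sex) {
      s <- .sex_indicator(sex)
      (b[["b1"]] + b[["b3"]] * s) * q0(age, sex)
    },
    n_valid = n_valid, n_total = n_total),
    class = "baseline_functions")
}

#' Filter inadmissible coefficient sets and pool by medians
#'
#' Drops sets with a decreasing age-dependency in either sex (see
#' [coef_admissible]) and pools the remainder by coordinate-wise median.
#'
#' @param sets Data frame (or tibble) with columns `b0`, `b1`, `b2`, `b3`,
#'   one row per fitted set.
#' @return A [baseline_from_coefs] object with `n_valid` and `n_total` set.
#' @export
filter_and_pool <- function(sets) {
  d <- tibble::as_tibble(sets)
  ok <- d$b1 > 0 & d$b1 + d$b3 > 0 &
    is.finite(d$b0) & is.finite(d$b1) & is.finite(d$b2) & is.finite(d$b3)
  if (!any(ok)) {
    stop(errorCondition("no admissible coefficient sets after filtering",
                        class = c("migstates_estimation_error", "error", "condition")))
  }
  pooled <- vapply(c("b0", "b1", "b2", "b3"),
                   function(nm) stats::median(d[[nm]][ok]), numeric(1))
  baseline_from_coefs(pooled, n_valid = sum(ok), n_total = nrow(d))
}

#' @export
print.baseline_functions <- function(x, ...) {
  cat(sprintf("<baseline_functions> b0=%.4f b1=%.5f b2=%.4f b3=%.5f | %s valid of %s sets\n",
              x$coefs[["b0"]], x$coefs[["b1"]], x$coefs[["b2"]], x$coefs[["b3"]],
              format(x$n_valid), format(x$n_total)))
  invisible(x)
}

#' First-incidence hazard among the never-migraine pool
#'
#' @param baseline A [baseline_from_coefs] object.
#' @param age Age(s) in years.
#' @param sex `"male"` or `"female"`.
#' @param support Age range over which the lifetime model is considered
#'   supported; evaluation outside it warns (the value is still returned).
#' @return First-incidence rate(s) per person-year.
#' @export
i0_eval <- function(baseline, age, sex, support = c(15, 80)) {
  stopifnot(inherits(baseline, "baseline_functions"))
  if (any(age < support[1] | age > support[2])) {
    warning(sprintf("age outside supported range [%g, %g]; extrapolating the lifetime model",
                    support[1], support[2]))
  }
  baseline$i0(age, sex)
}

#' Fit the lifetime stage: resample, regress, filter, pool
#'
#' Runs the full lifetime-prevalence stage: [sample_lifetime_sets], one
#' [fit_logit_model] per sampled table, the admissibility filter, and median
#' pooling via [filter_and_pool].
#'
#' @param points A [lifetime_table].
#' @param n_samples Number of resampled tables (default 5000).
#' @param seed Integer seed.
#' @return A `baseline_functions` object; the number of rank-deficient
#'   (skipped) fits is attached as attribute `n_fit_failed`.
#' @export
fit_lifetime <- function(points, n_samples = 5000, seed = 1) {
  samples <- sample_lifetime_sets(points, n_samples, seed)
  n_pt <- nrow(tibble::as_tibble(points))
  coefs <- matrix(NA_real_, n_samples, 4)
  for (k in seq_len(n_samples)) {
    rows <- ((k - 1) * n_pt + 1):(k * n_pt)
    b <- fit_logit_model(samples[rows, , drop = FALSE])
    if (!is.null(b)) coefs[k, ] <- b
  }
  fitted <- stats::complete.cases(coefs)
  out <- filter_and_pool(tibble::tibble(
    b0 = coefs[fitted, 1], b1 = coefs[fitted, 2],
    b2 = coefs[fitted, 3], b3 = coefs[fitted, 4]))
  attr(out, "n_fit_failed") <- sum(!fitted)
  attr(out, "seed") <- seed
  out
}
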