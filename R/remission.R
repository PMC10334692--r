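#' Remission rate from the illness-death balance equation
#'
#' In the two-state illness-death model without differential mortality, the
#' prevalence p of the active state satisfies
#' \deqn{\partial p/\partial a + \partial p/\partial t = i (1 - p) - r p,}
#' so the remission hazard can be recovered as
#' \deqn{r = (i (1 - p) - \partial p/\partial a - \partial p/\partial t) / p.}
#'
#' @param p Prevalence of the active state, strictly inside (0, 1).
#' @param i Incidence rate (per person-year) applied to the non-active pool.
#' @param dp_da Partial derivative of prevalence in age (per year).
#' @param dp_dt Partial derivative of prevalence in calendar time (per year);
#'   defaults to 0 (stationary prevalence).
#' @return Remission rate per person-year (may be negative if the inputs are
#'   inconsistent with a nonnegative hazard; callers decide how to flag or
#'   clamp).
#' @export
remission_from_pde <- function(p, i, dp_da, dp_dt = 0) {
  if (any(p <= 0) || any(p >= 1)) {
    stop(errorCondition("prevalence must lie strictly inside (0, 1)",
                        class = c("migstates_rate_error", "error", "condition")))
  }
  if (any(i < 0)) {
    stop(errorCondition("incidence must be nonnegative",
                        class = c("migstates_rate_error", "error", "condition")))
  }
  (i * (1 - p) - dp_da - dp_dt) / p
}

#' Remission curve from fitted prevalence and incidence surfaces
#'
#' Applies [remission_from_pde] pointwise along an age grid, using surface
#' predictions and their analytic partial derivatives at a fixed calendar
#' year. Rates are per person-year; use [remission_report] for the per-100
#' person-years reporting convention.
#'
#' @param prev_surface,inc_surface [fit_surface] results for prevalence and
#'   incidence of the same sex and location.
#' @param ages Age grid (years).
#' @param year Calendar year at which to evaluate.
#' @param include_dt Include the calendar-time partial of prevalence
#'   (default); set `FALSE` to invert with the age derivative only.
#' @return Tibble of class `remission_curve` with columns `sex`, `location`,
#'   `year`, `age`, `rate` (per person-year) and `flag_negative` (`TRUE`
#'   where the inverted rate was negative; rates are retained unclamped).
#' @export
estimate_remission <- function(prev_surface, inc_surface, ages, year,
                               include_dt = TRUE) {
  stopifnot(inherits(prev_surface, "rate_surface"),
            inherits(inc_surface, "rate_surface"))
  if (prev_surface$sex != inc_surface$sex ||
      prev_surface$location != inc_surface$location) {
    stop(errorCondition("surfaces disagree on sex or location",
                        class = c("migstates_argument_error", "error", "condition")))
  }
  if (prev_surface$kind != "prevalence" || inc_surface$kind != "incidence") {
    stop(errorCondition("expected one prevalence and one incidence surface",
                        class = c("migstates_argument_error", "error", "condition")))
  }
  p <- prev_surface$predict(ages, year)
  i <- inc_surface$predict(ages, year)
  dp_da <- prev_surface$d_age(ages, year)
  dp_dt <- if (include_dt) prev_surface$d_year(ages, year) else 0
  r <- remission_from_pde(p, i, dp_da, dp_dt)
  structure(
    tibble::tibble(sex = prev_surface$sex, location = prev_surface$location,
                   year = year, age = ages, rate = r, flag_negative = r < 0),
    class = c("remission_curve", class(tibble::tibble())))
}

#' Resampling-based remission estimate with 95% confidence bands
#'
#' Propagates the uncertainty intervals of the input records to the remission
#' curve by a parametric resampling scheme: each record's value is perturbed
#' by a normal draw centred at the value with standard deviation
#' `(upper - lower) / (2 * 1.96)` (prevalence draws truncated to \[0, 1\],
#' incidence draws to nonnegative), both surfaces are refitted, and the curve
#' recomputed. The point estimate is the age-wise median across resamples;
#' the bands are the 2.5th and 97.5th percentiles. A plug-in curve from the
#' unperturbed fit is also returned for comparison.
#'
#' @param table A [gbd_table] holding prevalence and incidence records for
#'   one sex and location.
#' @param spec A [surface_spec] used for every refit.
#' @param ages Age grid (years).
#' @param year Calendar year at which to evaluate.
#' @param n_resamples Number of resamples (>= 2).
#' @param seed Integer seed; the estimate is deterministic given the seed.
#' @param include_dt Passed to [estimate_remission].
#' @return An object of class `remission_estimate`: a list with
#'   `point`, `lower`, `upper` (each a `remission_curve`), `plugin`
#'   (unperturbed-fit curve), the resample matrix `draws`
#'   (n_resamples x length(ages)), and counts `n_resamples`, `n_failed`,
#'   plus the `seed`.
#' @export
resample_remission <- function(table, spec = surface_spec(), ages, year,
                               n_resamples = 1000, seed = 1,
                               include_dt = TRUE) {
  stopifnot(n_resamples >= 2)
  d <- tibble::as_tibble(table)
  sexes <- unique(d$sex); locs <- unique(d$location)
  if (length(sexes) != 1 || length(locs) != 1) {
    stop(errorCondition("table must hold one sex and one location",
                        class = c("migstates_argument_error", "error", "condition")))
  }
  is_prev <- d$measure == "prevalence"
  sd_rec <- (d$upper - d$lower) / (2 * 1.96)
  curve_from <- function(dd) {
    ps <- fit_surface(dd[dd$measure == "prevalence", , drop = FALSE], spec)
    is_ <- fit_surface(dd[dd$measure == "incidence", , drop = FALSE], spec)
    estimate_remission(ps, is_, ages, year, include_dt = include_dt)$rate
  }
  plugin_rate <- curve_from(d)
  draws <- matrix(NA_real_, n_resamples, length(ages))
  failures <- character(0)
  withr::with_seed(seed, {
    for (b in seq_len(n_resamples)) {
      db <- d
      db$value <- stats::rnorm(nrow(db), mean = db$value, sd = sd_rec)
      db$value[is_prev] <- pmin(pmax(db$value[is_prev], 0), 1)
      db$value[!is_prev] <- pmax(db$value[!is_prev], 0)
      res <- tryCatch(curve_from(db), error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures, sprintf("resample %d: %s", b, conditionMessage(res)))
      } else {
        draws[b, ] <- res
      }
    }
  })
  ok <- stats::complete.cases(draws)
  if (!any(ok)) {
    stop(errorCondition(
      paste0("all resamples failed to fit:\n",
             paste(utils::head(failures, 10), collapse = "\n")),
      class = c("migstates_estimation_error", "error", "condition")))
  }
  qs <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.5, 0.975), names = FALSE)
  as_curve <- function(rate) {
    structure(
      tibble::tibble(sex = sexes, location = locs, year = year, age = ages,
                     rate = rate, flag_negative = rate < 0),
      class = c("remission_curve", class(tibble::tibble())))
  }
  structure(list(point = as_curve(qs[2, ]), lower = as_curve(qs[1, ]),
                 upper = as_curve(qs[3, ]), plugin = as_curve(plugin_rate),
                 draws = draws, n_resamples = n_resamples,
                 n_failed = sum(!ok), failures = failures, seed = seed),
            class = "remission_estimate")
}

#' @export
print.remission_estimate <- function(x, ...) {
  cat(sprintf("<remission_estimate> %s, %s | year %s | %d ages | %d resamples (%d failed) | seed %d\n",
              x$point$sex[1], x$point$location[1], x$point$year[1],
              nrow(x$point), x$n_resamples, x$n_failed, x$seed))
  invisible(x)
}

#' Reporting table for a remission estimate, per 100 person-years
#'
#' The per-100 person-years scaling is applied only at this output boundary;
#' all internal rates are per person-year.
#'
#' @param estimate A [resample_remission] result.
#' @return Tibble with columns `sex`, `location`, `year`, `age`,
#'   `rate_per_100py`, `lower`, `upper`, `flag_negative`.
#' @export
remission_report <- function(estimate) {
  stopifnot(inherits(estimate, "remission_estimate"))
  tibble::tibble(
    sex = estimate$point$sex, location = estimate$point$location,
    year = estimate$point$year, age = estimate$point$age,
    rate_per_100py = 100 * estimate$point$rate,
    lower = 100 * estimate$lower$rate,
    upper = 100 * estimate$upper$rate,
    flag_negative = estimate$point$flag_negative)
}
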