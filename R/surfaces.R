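#' Configuration for age-by-year rate surfaces
#'
#' The surface model is a linear fit on a transformed scale: logit for
#' prevalence, log for incidence. The linear predictor is a polynomial in
#' (centred, rescaled) age plus an optional linear calendar-year term and an
#' age-by-year interaction. Derivatives in age and year are obtained
#' analytically from the fitted form, never by differencing data.
#'
#' The default age degree (12) is deliberately high: the remission stage
#' inverts a differential equation, so bias in the fitted age profile is
#' amplified through its derivative. With the 17+ age-group midpoints of a
#' GBD extract, a degree-12 polynomial keeps that bias well below the
#' resampling noise while remaining an ordinary least-squares fit.
#'
#' @param degree_age Polynomial degree in age (capped at the number of
#'   distinct age midpoints minus one at fit time).
#' @param year_effect Include a linear calendar-year term.
#' @param interaction Include an age-by-year interaction term.
#' @param weighted Use inverse-variance weights derived from the uncertainty
#'   intervals, `((upper - lower)/(2 * 1.96))^2`, propagated to the
#'   transformed scale by the delta method.
#' @param age_scale Age is centred and divided by this before taking powers
#'   (conditioning only; does not change the fitted function).
#' @param eps Clamp width keeping transformed responses finite.
#' @return A list of class `surface_spec`.
#' @export
surface_spec <- function(degree_age = 12, year_effect = TRUE, interaction = TRUE,
                         weighted = FALSE, age_scale = 10, eps = 1e-10) {
  stopifnot(degree_age >= 1, age_scale > 0, eps > 0, eps < 0.5)
  structure(list(degree_age = degree_age, year_effect = year_effect,
                 interaction = interaction, weighted = weighted,
                 age_scale = age_scale, eps = eps),
            class = "surface_spec")
}

# design matrix for the linear predictor; x = scaled centred age, y = centred year
.surface_design <- function(x, y, degree, year_effect, interaction) {
  X <- cbind(1, outer(x, seq_len(degree), `^`))
  if (year_effect) X <- cbind(X, y)
  if (interaction) X <- cbind(X, x * y)
  X
}

#' Fit a smooth prevalence or incidence surface over age and year
#'
#' Fits the transformed-scale linear model described in [surface_spec] to one
#' (measure, sex, location) slice of a [gbd_table]. Prevalence is fitted on
#' the logit scale, incidence on the log scale; predictions are mapped back
#' through the inverse link (prevalence clamped to (0, 1), incidence
#' nonnegative by construction).
#'
#' @param slice A [gbd_table] (or plain data frame) holding exactly one
#'   measure, sex and location, with columns `age_mid`, `year`, `value` and
#'   (if weighting) `lower`, `upper`.
#' @param spec A [surface_spec].
#' @return An object of class `rate_surface` with fields `kind`, `sex`,
#'   `location`, `domain` (age and year ranges of the training data),
#'   `coef`, and functions `predict(age, year)`, `d_age(age, year)`,
#'   `d_year(age, year)` (analytic partial derivatives of the fitted form).
#' @export
fit_surface <- function(slice, spec = surface_spec()) {
  d <- tibble::as_tibble(slice)
  for (col in c("measure", "sex", "location")) {
    if (length(unique(d[[col]])) != 1) {
      stop(errorCondition(
        sprintf("slice must hold exactly one %s", col),
        class = c("migstates_fit_error", "error", "condition")))
    }
  }
  kind <- d$measure[1]
  stopifnot(kind %in% c("prevalence", "incidence"))
  n_ages <- length(unique(d$age_mid))
  n_years <- length(unique(d$year))
  if (n_ages < 4 || n_years < 2) {
    stop(errorCondition(
      sprintf("too few support points: %d distinct ages, %d distinct years (need >= 4 and >= 2)",
              n_ages, n_years),
      class = c("migstates_fit_error", "error", "condition")))
  }
  degree <- min(spec$degree_age, n_ages - 1)
  age_center <- mean(unique(d$age_mid))
  year_center <- mean(unique(d$year))
  x <- (d$age_mid - age_center) / spec$age_scale
  y <- d$year - year_center
  X <- .surface_design(x, y, degree, spec$year_effect, spec$interaction)
  value <- pmin(pmax(d$value, spec$eps), if (kind == "prevalence") 1 - spec$eps else Inf)
  z <- if (kind == "prevalence") stats::qlogis(value) else log(value)
  if (spec$weighted) {
    if (!all(c("lower", "upper") %in% names(d))) {
      stop(errorCondition("weighted fit requires lower/upper columns",
                          class = c("migstates_fit_error", "error", "condition")))
    }
    sd_nat <- pmax((d$upper - d$lower) / (2 * 1.96), 1e-12)
    # delta method: sd on transformed scale = |g'(value)| * sd
    gprime <- if (kind == "prevalence") 1 / (value * (1 - value)) else 1 / value
    w <- 1 / (gprime * sd_nat)^2
    fit <- stats::lm.wfit(X, z, w)
  } else {
    fit <- stats::lm.fit(X, z)
  }
  beta <- unname(fit$coefficients)
  beta[is.na(beta)] <- 0
  if (!all(is.finite(beta))) {
    stop(errorCondition("non-finite surface fit coefficients",
                        class = c("migstates_fit_error", "error", "condition")))
  }
  k_age <- seq_len(degree) + 1L
  k_year <- if (spec$year_effect) degree + 2L else NA_integer_
  k_int <- if (spec$interaction) degree + 2L + spec$year_effect else NA_integer_

  eta_parts <- function(age, year) {
    xx <- (age - age_center) / spec$age_scale
    yy <- year - year_center
    pow <- outer(xx, seq_len(degree), `^`)
    eta <- beta[1] + drop(pow %*% beta[k_age])
    deta_dx <- drop(outer(xx, seq_len(degree) - 1, `^`) %*% (beta[k_age] * seq_len(degree)))
    deta_dy <- rep(0, length(xx))
    if (spec$year_effect) eta <- eta + beta[k_year] * yy
    if (spec$year_effect) deta_dy <- deta_dy + beta[k_year]
    if (spec$interaction) {
      eta <- eta + beta[k_int] * xx * yy
      deta_dx <- deta_dx + beta[k_int] * yy
      deta_dy <- deta_dy + beta[k_int] * xx
    }
    list(eta = eta, deta_da = deta_dx / spec$age_scale, deta_dt = deta_dy)
  }
  linkinv <- if (kind == "prevalence") stats::plogis else exp
  mu_prime <- if (kind == "prevalence") {
    function(eta) { m <- stats::plogis(eta); m * (1 - m) }
  } else {
    exp
  }
  surface <- list(
    kind = kind, sex = d$sex[1], location = d$location[1],
    coef = beta, degree = degree, spec = spec,
    centers = c(age = age_center, year = year_center),
    domain = list(age = range(d$age_mid), year = range(d$year)),
    residual_max = max(abs(fit$residuals)),
    predict = function(age, year) {
      eta <- eta_parts(age, year)$eta
      mu <- linkinv(eta)
      if (kind == "prevalence") mu <- pmin(pmax(mu, 0), 1)
      mu
    },
    d_age = function(age, year) {
      pp <- eta_parts(age, year)
      mu_prime(pp$eta) * pp$deta_da
    },
    d_year = function(age, year) {
      pp <- eta_parts(age, year)
      mu_prime(pp$eta) * pp$deta_dt
    })
  class(surface) <- "rate_surface"
  surface
}

#' @export
print.rate_surface <- function(x, ...) {
  cat(sprintf("<rate_surface> %s | %s, %s | age degree %d | ages %.1f-%.1f | years %d-%d\n",
              x$kind, x$sex, x$location, x$degree,
              x$domain$age[1], x$domain$age[2], x$domain$year[1], x$domain$year[2]))
  cat(sprintf("  max |residual| on transformed scale: %.3g\n", x$residual_max))
  invisible(x)
}

#' Evaluate a surface on a rectangular (age, year) grid
#'
#' @param surface A [fit_surface] result.
#' @param ages,years Numeric vectors of evaluation points.
#' @return Tibble with columns `age`, `year`, `value`, `d_age`, `d_year`,
#'   `extrapolated` (`TRUE` for cells outside the training domain; such
#'   cells are still evaluated, with a warning).
#' @export
surface_grid <- function(surface, ages, years) {
  stopifnot(inherits(surface, "rate_surface"))
  if (length(ages) == 0 || length(years) == 0) {
    stop(errorCondition("empty evaluation grid",
                        class = c("migstates_argument_error", "error", "condition")))
  }
  g <- expand.grid(age = ages, year = years, KEEP.OUT.ATTRS = FALSE)
  extra <- g$age < surface$domain$age[1] | g$age > surface$domain$age[2] |
    g$year < surface$domain$year[1] | g$year > surface$domain$year[2]
  if (any(extra)) warning("some grid cells lie outside the training domain; extrapolating")
  tibble::tibble(
    age = g$age, year = g$year,
    value = surface$predict(g$age, g$year),
    d_age = surface$d_age(g$age, g$year),
    d_year = surface$d_year(g$age, g$year),
    extrapolated = extra)
}
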