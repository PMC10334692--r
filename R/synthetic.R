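#' Default ground-truth hazards for the synthetic world
#'
#' Shapes chosen to echo the magnitudes seen in migraine epidemiology:
#' first-incidence among the never pool rising from roughly 0.33%/yr at 25
#' to 0.54%/yr at 65 in women (0.08% to 0.13% in men), remission rising
#' with age from about 1.5 to 6.5 per 100 person-years, and a small constant
#' reactivation hazard of 1 per 100 person-years. All hazards are
#' time-invariant (no secular trend).
#'
#' @name truth-defaults
#' @param age Age(s) in years.
#' @param sex `"male"` or `"female"`.
#' @return Hazard(s) per person-year.
NULL

#' @rdname truth-defaults
#' @export
default_i0_true <- function(age, sex) {
  if (sex[1] == "female") pmax(0.0033 + 5.25e-5 * (age - 25), 1e-4)
  else pmax(0.0008 + 1.25e-5 * (age - 25), 5e-5)
}

#' @rdname truth-defaults
#' @export
default_r_true <- function(age, sex) 0.015 + 0.001 * (age - 15)

#' @rdname truth-defaults
#' @export
default_f_true <- function(age, sex) rep(0.01, length(age))

#' Define a ground-truth three-state world
#'
#' @param i0,r,f Hazard functions of `(age, sex)` returning per-person-year
#'   rates; defaults are the [truth-defaults].
#' @param sexes Sexes to simulate.
#' @param age_span Simulated age range; the cohort starts disease-free at
#'   its lower end.
#' @param years Calendar years the emitted extract will cover (the truth
#'   itself is time-invariant).
#' @param noise Default relative 95% uncertainty-interval half-width used by
#'   [emit_gbd_tables].
#' @param seed Default seed for the emitters.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(i0 = default_i0_true, r = default_r_true,
                         f = default_f_true,
                         sexes = c("male", "female"),
                         age_span = c(10, 97.5), years = 1990:2019,
                         noise = 0.05, seed = 1) {
  stopifnot(noise >= 0, age_span[2] > age_span[1])
  check_ages <- seq(age_span[1], age_span[2], by = 0.5)
  for (sx in sexes) {
    for (fn in list(i0, r, f)) {
      v <- fn(check_ages, sx)
      if (any(!is.finite(v)) || any(v < 0) || any(v > 0.5)) {
        stop(errorCondition(
          "ground-truth hazards must be finite, nonnegative and at most 0.5/year",
          class = c("migstates_argument_error", "error", "condition")))
      }
    }
  }
  structure(list(i0 = i0, r = r, f = f, sexes = sexes, age_span = age_span,
                 years = years, noise = noise, seed = seed),
            class = "ground_truth")
}

#' Integrate the ground-truth dynamics to exact state occupancies
#'
#' Solves the three-state system from the lower end of the age span with
#' everyone in the never state, using a fixed-step fourth-order Runge-Kutta
#' integrator. The pooled GBD-style incidence is derived as
#' `i_gbd = (i0 S0 + f Ci) / (S0 + Ci)` and the lifetime prevalence as
#' `q0 = 1 - p0`.
#'
#' @param truth A [ground_truth].
#' @param h_fine Integration step in years (at most 0.005).
#' @param out_by Spacing of the returned age grid (a multiple of `h_fine`).
#' @return Tibble with columns `age`, `sex`, `p0`, `p_a`, `p_i`, `i_gbd`,
#'   `q0`, at ages `seq(age_span[1], age_span[2], by = out_by)` per sex.
#' @export
solve_truth <- function(truth, h_fine = 0.0025, out_by = 0.25) {
  stopifnot(inherits(truth, "ground_truth"), h_fine <= 0.005)
  ages_out <- seq(truth$age_span[1], truth$age_span[2], by = out_by)
  res <- lapply(truth$sexes, function(sx) {
    derivs <- function(a, y, parms) {
      i0 <- truth$i0(a, sx); r <- truth$r(a, sx); f <- truth$f(a, sx)
      dS0 <- -i0 * y[1]
      dCa <- i0 * y[1] + f * y[3] - r * y[2]
      dCi <- r * y[2] - f * y[3]
      list(c(dS0, dCa, dCi))
    }
    times <- seq(truth$age_span[1], truth$age_span[2], by = h_fine)
    sol <- deSolve::ode(y = c(S0 = 1, Ca = 0, Ci = 0), times = times,
                        func = derivs, parms = NULL, method = "rk4")
    idx <- match(round(ages_out / h_fine), round(sol[, "time"] / h_fine))
    S0 <- sol[idx, "S0"]; Ca <- sol[idx, "Ca"]; Ci <- sol[idx, "Ci"]
    tibble::tibble(
      age = ages_out, sex = sx, p0 = S0, p_a = Ca, p_i = Ci,
      i_gbd = (truth$i0(ages_out, sx) * S0 + truth$f(ages_out, sx) * Ci) / (S0 + Ci),
      q0 = 1 - S0)
  })
  do.call(rbind, res)
}

# truth-solution lookup at exact grid ages
.truth_at <- function(solution, ages, sex, col) {
  sol <- solution[solution$sex == sex, , drop = FALSE]
  idx <- vapply(ages, function(a) which.min(abs(sol$age - a)), integer(1))
  if (any(abs(sol$age[idx] - ages) > 1e-6)) {
    stop(errorCondition("requested ages are not on the solved age grid",
                        class = c("migstates_argument_error", "error", "condition")))
  }
  sol[[col]][idx]
}

#' Emit a GBD-style extract from a solved ground truth
#'
#' Aggregates the solution to five-year age groups at their midpoints, one
#' record per (measure, sex, year, age group). Values are perturbed
#' multiplicatively by `Normal(1, noise / 1.96)` draws and the uncertainty
#' limits are written as `value * (1 -/+ noise)`; perturbed prevalences are
#' truncated to \[0, 1\] and incidences to nonnegative (truncations are
#' reported in the table's reject-free validation because bounds are built
#' around the truncated value).
#'
#' @param solution A [solve_truth] table.
#' @param noise Relative 95% UI half-width (0 emits the truth exactly).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param years Calendar years to emit (truth is time-invariant, so records
#'   repeat across years up to noise).
#' @param location Location label for the records.
#' @param age_groups GBD age-group labels to emit; defaults to all groups
#'   whose midpoint lies inside the solved age span.
#' @return A validated [gbd_table].
#' @export
emit_gbd_tables <- function(solution, noise = 0, seed = 1, years = 1990:2019,
                            location = "Germany", age_groups = NULL) {
  stopifnot(noise >= 0, noise <= 0.5)
  if (is.null(age_groups)) {
    labels <- gbd_age_labels()
    mids <- age_midpoint(labels)
    keep <- mids >= min(solution$age) & mids <= max(solution$age)
    age_groups <- labels[keep]
  }
  mids <- age_midpoint(age_groups)
  sexes <- unique(solution$sex)
  grid <- expand.grid(measure = c("prevalence", "incidence"), sex = sexes,
                      year = years, age_label = age_groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$age_mid <- age_midpoint(grid$age_label)
  truthval <- numeric(nrow(grid))
  for (sx in sexes) {
    for (ms in c("prevalence", "incidence")) {
      sel <- grid$sex == sx & grid$measure == ms
      col <- if (ms == "prevalence") "p_a" else "i_gbd"
      truthval[sel] <- .truth_at(solution, grid$age_mid[sel], sx, col)
    }
  }
  value <- withr::with_seed(seed, {
    truthval * stats::rnorm(length(truthval), mean = 1, sd = noise / 1.96)
  })
  is_prev <- grid$measure == "prevalence"
  value[is_prev] <- pmin(pmax(value[is_prev], 0), 1)
  value <- pmax(value, 0)
  gbd_table(tibble::tibble(
    measure = grid$measure, location = location, sex = grid$sex,
    year = grid$year, age_label = grid$age_label, age_mid = grid$age_mid,
    value = value, lower = value * (1 - noise),
    upper = pmin(value * (1 + noise), ifelse(is_prev, 1, Inf))),
    meta = list(source = "synthetic ground truth", noise = noise, seed = seed))
}

#' Emit a lifetime-prevalence table from a solved ground truth
#'
#' Evaluates the lifetime prevalence `q0` at the survey age-group midpoints
#' (29.5, 39.5, 49.5, 59.5) per sex and attaches symmetric 95% confidence
#' limits of half-width `ci_halfwidth` (floored at 0 and capped at 1).
#'
#' @param solution A [solve_truth] table.
#' @param ci_halfwidth Half-width of the attached confidence interval
#'   (strictly between 0 and 0.5).
#' @return A validated [lifetime_table].
#' @export
emit_lifetime_table <- function(solution, ci_halfwidth = 0.05) {
  stopifnot(ci_halfwidth > 0, ci_halfwidth < 0.5)
  groups <- c("25-34", "35-44", "45-54", "55-64")
  mids <- c(29.5, 39.5, 49.5, 59.5)
  sexes <- unique(solution$sex)
  rows <- expand.grid(sex = sexes, age_group = groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$age_mid <- mids[match(rows$age_group, groups)]
  q0 <- numeric(nrow(rows))
  for (sx in sexes) {
    sel <- rows$sex == sx
    q0[sel] <- .truth_at(solution, rows$age_mid[sel], sx, "q0")
  }
  lifetime_table(tibble::tibble(
    sex = rows$sex, age_group = rows$age_group, q0 = q0,
    lower = pmax(q0 - ci_halfwidth, 0),
    upper = pmin(q0 + ci_halfwidth, 1)))
}

#' Lifetime points generated directly from a logit-linear coefficient set
#'
#' Bypasses the cohort dynamics: evaluates
#' `q0 = plogis(b0 + b1 age + b2 s + b3 age s)` at the survey midpoints for
#' both sexes and attaches symmetric confidence limits. Used for
#' parameter-recovery checks of the lifetime stage against a known truth.
#'
#' @param coefs Named vector `c(b0, b1, b2, b3)`.
#' @param ci_halfwidth Half-width of the attached 95% interval.
#' @return A validated [lifetime_table].
#' @export
lifetime_points_from_coefs <- function(coefs, ci_halfwidth = 0.02) {
  groups <- c("25-34", "35-44", "45-54", "55-64")
  mids <- c(29.5, 39.5, 49.5, 59.5)
  rows <- expand.grid(sex = c("male", "female"), age_group = groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$age_mid <- mids[match(rows$age_group, groups)]
  s <- .sex_indicator(rows$sex)
  q0 <- stats::plogis(coefs[["b0"]] + coefs[["b1"]] * rows$age_mid +
                        coefs[["b2"]] * s + coefs[["b3"]] * rows$age_mid * s)
  lifetime_table(tibble::tibble(
    sex = rows$sex, age_group = rows$age_group, q0 = q0,
    lower = pmax(q0 - ci_halfwidth, 0),
    upper = pmin(q0 + ci_halfwidth, 1)))
}

#' Write a complete synthetic fixture set to a directory
#'
#' Writes `gbd.csv` (GBD-layout extract) and `lifetime.csv` (survey-layout
#' lifetime table). Output is byte-identical for a fixed seed.
#'
#' @param dir Output directory (created if needed).
#' @param truth A [ground_truth].
#' @param noise Relative UI half-width for the GBD extract.
#' @param ci_halfwidth Confidence half-width for the lifetime table.
#' @param seed Integer seed.
#' @param h_fine Integration step passed to [solve_truth].
#' @return Named character vector of the paths written, invisibly; the
#'   solved truth is attached as attribute `solution`.
#' @export
write_fixtures <- function(dir, truth = ground_truth(), noise = truth$noise,
                           ci_halfwidth = 0.05, seed = truth$seed,
                           h_fine = 0.0025) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  solution <- solve_truth(truth, h_fine = h_fine)
  gbd <- emit_gbd_tables(solution, noise = noise, seed = seed, years = truth$years)
  lt <- emit_lifetime_table(solution, ci_halfwidth = ci_halfwidth)
  paths <- c(gbd = file.path(dir, "gbd.csv"), lifetime = file.path(dir, "lifetime.csv"))
  write_gbd_csv(gbd, paths[["gbd"]])
  write_lifetime_table(lt, paths[["lifetime"]])
  attr(paths, "solution") <- solution
  invisible(paths)
}
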