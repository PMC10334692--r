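# normalize a user-supplied rate into function(age, year, S0, Ci) -> scalar
.as_rate_fun <- function(rate, name) {
  if (is.numeric(rate) && length(rate) == 1) {
    val <- rate
    return(function(age, year, S0, Ci) val)
  }
  if (!is.function(rate)) {
    stop(errorCondition(
      sprintf("rate '%s' must be a single number or a function", name),
      class = c("migstates_argument_error", "error", "condition")))
  }
  n_args <- length(formals(rate))
  switch(as.character(min(n_args, 4)),
         "1" = function(age, year, S0, Ci) rate(age),
         "2" = function(age, year, S0, Ci) rate(age, year),
         "3" = stop(errorCondition(
           sprintf("rate '%s' must take 1, 2 or 4 arguments (age[, year[, S0, Ci]])", name),
           class = c("migstates_argument_error", "error", "condition"))),
         "4" = function(age, year, S0, Ci) rate(age, year, S0, Ci))
}

#' Bundle the three transition hazards of the extended model
#'
#' @param i0 First-incidence hazard (never -> active), per person-year: a
#'   constant or a function of `age` or `(age, year)`.
#' @param r Remission hazard (active -> inactive), same forms.
#' @param f Reactivation hazard (inactive -> active); may additionally be a
#'   function of `(age, year, S0, Ci)` for occupancy-dependent hazards such
#'   as the GBD balance identity ([reactivation_from_gbd]).
#' @return Object of class `transition_rates`.
#' @export
transition_rates <- function(i0, r, f) {
  structure(list(i0 = .as_rate_fun(i0, "i0"),
                 r = .as_rate_fun(r, "r"),
                 f = .as_rate_fun(f, "f")),
            class = "transition_rates")
}

#' Cohort occupancy at one age
#'
#' @param age Age in years.
#' @param S0,Ca,Ci Nonnegative counts in the never, active and inactive
#'   states.
#' @return Object of class `cohort_state` (a named list).
#' @export
cohort_state <- function(age, S0, Ca, Ci) {
  if (any(c(S0, Ca, Ci) < 0)) {
    stop(errorCondition("state counts must be nonnegative",
                        class = c("migstates_argument_error", "error", "condition")))
  }
  structure(list(age = age, S0 = S0, Ca = Ca, Ci = Ci), class = "cohort_state")
}

#' Reactivation hazard implied by the GBD incidence
#'
#' The GBD incidence i_gbd applies to the whole no-active-migraine pool
#' (S0 + Ci). Requiring the extended model's inflow into the active state,
#' i0 S0 + f Ci, to equal i_gbd (S0 + Ci) identifies the reactivation
#' hazard:
#' \deqn{f = (i_{gbd} (S_0 + C_i) - i_0 S_0) / C_i.}
#' When the inactive pool is numerically empty
#' (`Ci < eps * (S0 + Ci)`) the identity is ill-conditioned and the limit
#' value `f = i_gbd` is returned with a flag; negative solutions are clamped
#' to 0 with a flag. Because the identity divides by the inactive-pool
#' occupancy, small pools can also produce implausibly large hazards; values
#' above `f_max` are truncated with a flag.
#'
#' @param i_gbd Incidence of active migraine in the pooled no-active group,
#'   per person-year.
#' @param i0 First-incidence hazard among the never group, per person-year.
#' @param S0,Ci Occupancy counts of the never and inactive states.
#' @param eps Relative pool-size threshold for the empty-pool fallback.
#' @param f_max Upper truncation bound for the hazard, per person-year.
#' @return Reactivation hazard per person-year, with logical attributes
#'   `fallback`, `clamped` and `capped`.
#' @export
reactivation_from_gbd <- function(i_gbd, i0, S0, Ci, eps = 1e-6, f_max = 0.5) {
  if (S0 + Ci <= 0) {
    stop(errorCondition("no-active pool is empty (S0 + Ci = 0)",
                        class = c("migstates_rate_error", "error", "condition")))
  }
  if (Ci < 0) {
    stop(errorCondition("Ci must be nonnegative",
                        class = c("migstates_rate_error", "error", "condition")))
  }
  pool <- S0 + Ci
  fallback <- Ci < eps * pool
  f <- if (fallback) i_gbd else (i_gbd * pool - i0 * S0) / Ci
  clamped <- f < 0
  if (clamped) f <- 0
  capped <- f > f_max
  if (capped) f <- f_max
  structure(f, fallback = fallback, clamped = clamped, capped = capped)
}

#' One Euler step of the three-state cohort recursion
#'
#' Updates the occupancy counts by the explicit recursion
#' `S0' = S0 - h i0 S0`,
#' `Ca' = Ca + h i0 S0 + h f Ci - h r Ca`,
#' `Ci' = Ci + h r Ca - h f Ci`,
#' which conserves the total count exactly (closed cohort, no differential
#' mortality).
#'
#' @param state A [cohort_state].
#' @param rates A [transition_rates] bundle.
#' @param h Step length in years; every `h * hazard` must stay below 1.
#' @param year Calendar year at which to evaluate the rates (optional; `NA`
#'   for year-free rates).
#' @return The updated `cohort_state` at `age + h`.
#' @export
markov_step <- function(state, rates, h, year = NA_real_) {
  stopifnot(inherits(state, "cohort_state"), inherits(rates, "transition_rates"), h > 0)
  i0 <- rates$i0(state$age, year, state$S0, state$Ci)
  r <- rates$r(state$age, year, state$S0, state$Ci)
  f <- rates$f(state$age, year, state$S0, state$Ci)
  if (any(!is.finite(c(i0, r, f))) || any(c(i0, r, f) < 0)) {
    stop(errorCondition(
      sprintf("hazards must be finite and nonnegative at age %.3f", state$age),
      class = c("migstates_rate_error", "error", "condition")))
  }
  if (h * max(i0, r, f) >= 1) {
    stop(errorCondition(
      sprintf("step size too large: h * hazard = %.3f >= 1 at age %.3f",
              h * max(i0, r, f), state$age),
      class = c("migstates_step_error", "error", "condition")))
  }
  flow_i <- h * i0 * state$S0
  flow_r <- h * r * state$Ca
  flow_f <- h * f * state$Ci
  cohort_state(age = state$age + h,
               S0 = state$S0 - flow_i,
               Ca = state$Ca + flow_i + flow_f - flow_r,
               Ci = state$Ci + flow_r - flow_f)
}

#' Run the three-state cohort over a follow-up period
#'
#' Repeated [markov_step] with rates evaluated at the current age and the
#' calendar year advancing in lockstep from `start_year`.
#'
#' @param init Initial [cohort_state].
#' @param rates A [transition_rates] bundle.
#' @param follow_up Follow-up length in years; must be a whole number of
#'   steps.
#' @param h Step length in years.
#' @param start_year Calendar year at the initial age.
#' @return Tibble of class `trajectory` with columns `age`, `year`, `S0`,
#'   `Ca`, `Ci` (one row per step, `follow_up / h + 1` rows); attributes
#'   `step` and `meta`.
#' @export
run_cohort <- function(init, rates, follow_up, h, start_year = 1990) {
  stopifnot(inherits(init, "cohort_state"))
  n_steps <- follow_up / h
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop(errorCondition("follow_up must be a whole number of steps",
                        class = c("migstates_argument_error", "error", "condition")))
  }
  n_steps <- as.integer(round(n_steps))
  out <- matrix(NA_real_, n_steps + 1L, 4L)
  state <- init
  for (k in seq_len(n_steps + 1L)) {
    out[k, ] <- c(state$age, state$S0, state$Ca, state$Ci)
    if (k <= n_steps) {
      year <- start_year + (state$age - init$age)
      state <- tryCatch(markov_step(state, rates, h, year), error = function(e) {
        stop(errorCondition(
          sprintf("cohort aborted at age %.3f: %s", state$age, conditionMessage(e)),
          class = class(e)))
      })
    }
  }
  structure(
    tibble::tibble(age = out[, 1],
                   year = start_year + (out[, 1] - init$age),
                   S0 = out[, 2], Ca = out[, 3], Ci = out[, 4]),
    step = h, meta = list(start_year = start_year, follow_up = follow_up),
    class = c("trajectory", class(tibble::tibble())))
}

#' State-occupancy proportions along a trajectory
#'
#' @param traj A [run_cohort] trajectory.
#' @return Tibble with columns `age`, `p0`, `p_a`, `p_i`; each row sums to 1.
#' @export
prevalence_curves <- function(traj) {
  stopifnot(inherits(traj, "trajectory"), nrow(traj) > 0)
  N <- traj$S0 + traj$Ca + traj$Ci
  tibble::tibble(age = traj$age, p0 = traj$S0 / N,
                 p_a = traj$Ca / N, p_i = traj$Ci / N)
}

#' Initialize the cohort from the baseline and prevalence surface
#'
#' Active-state occupancy comes from the prevalence surface at
#' (start_age, start_year); the never state from the baseline never-migraine
#' prevalence p0(start_age); the inactive state takes the remainder. If the
#' two sources together exceed the cohort (implied Ci < 0), Ci is floored at
#' 0, S0 is rescaled to the remainder and the result is flagged.
#'
#' @param baseline A [baseline_from_coefs] object.
#' @param prev_surface A prevalence [fit_surface] result.
#' @param start_age,start_year Cohort entry age and calendar year.
#' @param N Cohort size.
#' @param sex `"male"` or `"female"`.
#' @return A [cohort_state] with attribute `flag_renormalized`.
#' @export
initialize_cohort <- function(baseline, prev_surface, start_age = 30,
                              start_year = 1990, N = 1e5, sex) {
  stopifnot(inherits(baseline, "baseline_functions"),
            inherits(prev_surface, "rate_surface"))
  Ca <- N * prev_surface$predict(start_age, start_year)
  S0 <- N * baseline$p0(start_age, sex)
  Ci <- N - S0 - Ca
  flagged <- FALSE
  if (Ci < 0) {
    warning("implied inactive-state count negative at start age; flooring Ci at 0 and rescaling S0")
    Ci <- 0
    S0 <- N - Ca
    flagged <- TRUE
  }
  out <- cohort_state(age = start_age, S0 = S0, Ca = Ca, Ci = Ci)
  attr(out, "flag_renormalized") <- flagged
  out
}

#' Simulate the extended model wired to fitted inputs
#'
#' Convenience driver for the full estimation chain: first-incidence from
#' the lifetime baseline, remission from the illness-death inversion of the
#' fitted surfaces (clamped at 0 where the raw inversion is negative), and
#' reactivation from the GBD balance identity evaluated at the current
#' state occupancy.
#'
#' @param baseline A [baseline_from_coefs] object.
#' @param prev_surface,inc_surface Fitted surfaces for the sex/location.
#' @param sex `"male"` or `"female"`.
#' @param N Cohort size.
#' @param start_age,start_year,follow_up,h Cohort settings.
#' @param include_dt Include the calendar-time partial in the remission
#'   inversion.
#' @return List with `init` (the initial state), `trajectory`, and
#'   `prevalence` (the [prevalence_curves] table).
#' @export
simulate_extended <- function(baseline, prev_surface, inc_surface, sex,
                              N = 1e5, start_age = 30, start_year = 1990,
                              follow_up = 30, h = 0.01, include_dt = TRUE) {
  init <- initialize_cohort(baseline, prev_surface, start_age, start_year, N, sex)
  rates <- transition_rates(
    i0 = function(age, year) baseline$i0(age, sex),
    r = function(age, year) {
      p <- prev_surface$predict(age, year)
      i <- inc_surface$predict(age, year)
      dp_da <- prev_surface$d_age(age, year)
      dp_dt <- if (include_dt) prev_surface$d_year(age, year) else 0
      max(remission_from_pde(p, i, dp_da, dp_dt), 0)
    },
    f = function(age, year, S0, Ci) {
      as.numeric(reactivation_from_gbd(
        i_gbd = inc_surface$predict(age, year),
        i0 = baseline$i0(age, sex), S0 = S0, Ci = Ci))
    })
  traj <- run_cohort(init, rates, follow_up, h, start_year)
  list(init = init, trajectory = traj, prevalence = prevalence_curves(traj))
}
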