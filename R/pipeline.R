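#' Cohort simulation settings
#'
#' Defaults: 100,000 individuals entering at age 30 in 1990, followed for
#' 30 years with an Euler step of 0.01 years.
#'
#' @param N Cohort size.
#' @param start_age Entry age in years.
#' @param start_year Calendar year at entry.
#' @param follow_up Follow-up length in years.
#' @param h Step length in years.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(N = 1e5, start_age = 30, start_year = 1990,
                          follow_up = 30, h = 0.01) {
  structure(list(N = N, start_age = start_age, start_year = start_year,
                 follow_up = follow_up, h = h),
            class = "cohort_config")
}

#' Run the full estimation pipeline
#'
#' Orchestrates the stages per sex for one location: surface fitting of
#' prevalence and incidence, resampling-based remission estimation, the
#' lifetime stage (never-migraine prevalence and first-incidence), and the
#' three-state cohort simulation. Optionally writes the remission curves,
#' baseline functions, trajectories and a metadata JSON to `out_dir`.
#'
#' @param gbd A [gbd_table] or path to a GBD-layout CSV.
#' @param lifetime A [lifetime_table] or path to a lifetime-prevalence CSV.
#' @param location Location to process.
#' @param sexes Sexes to process.
#' @param report_year Calendar year for the remission report.
#' @param report_ages Age grid for the remission report.
#' @param spec A [surface_spec].
#' @param n_resamples Remission resamples (>= 2).
#' @param n_lifetime_samples Lifetime resamples (default 5000).
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param cohort A [cohort_config].
#' @param baseline_ages Age grid for the baseline CSV output.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return Named list (per sex) with elements `surfaces`, `remission`,
#'   `baseline`, `simulation`; the run configuration is attached as
#'   attribute `config`.
#' @export
run_pipeline <- function(gbd, lifetime, location = "Germany",
                         sexes = c("male", "female"), report_year = 2019,
                         report_ages = seq(17.5, 72.5, by = 2.5),
                         spec = surface_spec(), n_resamples = 1000,
                         n_lifetime_samples = 5000, seed = 1,
                         cohort = cohort_config(),
                         baseline_ages = seq(15, 80, by = 1),
                         out_dir = NULL) {
  if (is.character(gbd)) gbd <- read_gbd_csv(gbd)
  if (is.character(lifetime)) lifetime <- read_lifetime_table(lifetime)
  stopifnot(inherits(gbd, "gbd_table"), inherits(lifetime, "lifetime_table"))

  baseline <- fit_lifetime(lifetime, n_samples = n_lifetime_samples, seed = seed)
  results <- list()
  for (k in seq_along(sexes)) {
    sx <- sexes[k]
    prev_s <- fit_surface(gbd_slice(gbd, "prevalence", sx, location), spec)
    inc_s <- fit_surface(gbd_slice(gbd, "incidence", sx, location), spec)
    sex_tab <- gbd[gbd$sex == sx & gbd$location == location, , drop = FALSE]
    rem <- resample_remission(sex_tab, spec, ages = report_ages,
                              year = report_year, n_resamples = n_resamples,
                              seed = seed + k)
    sim <- simulate_extended(baseline, prev_s, inc_s, sex = sx,
                             N = cohort$N, start_age = cohort$start_age,
                             start_year = cohort$start_year,
                             follow_up = cohort$follow_up, h = cohort$h)
    results[[sx]] <- list(surfaces = list(prevalence = prev_s, incidence = inc_s),
                          remission = rem, baseline = baseline, simulation = sim)
  }

  config <- list(location = location, sexes = sexes, report_year = report_year,
                 report_ages = report_ages, surface_spec = unclass(spec),
                 n_resamples = n_resamples,
                 n_lifetime_samples = n_lifetime_samples, seed = seed,
                 cohort = unclass(cohort),
                 baseline_coefs = as.list(baseline$coefs),
                 n_valid = baseline$n_valid, n_total = baseline$n_total)
  attr(results, "config") <- config

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    rem_tab <- do.call(rbind, lapply(results, function(x) remission_report(x$remission)))
    utils::write.csv(rem_tab, file.path(out_dir, "remission.csv"), row.names = FALSE)
    base_tab <- do.call(rbind, lapply(sexes, function(sx) {
      tibble::tibble(sex = sx, age = baseline_ages,
                     q0 = baseline$q0(baseline_ages, sx),
                     p0 = baseline$p0(baseline_ages, sx),
                     i0 = baseline$i0(baseline_ages, sx))
    }))
    utils::write.csv(base_tab, file.path(out_dir, "baseline.csv"), row.names = FALSE)
    traj_tab <- do.call(rbind, lapply(sexes, function(sx) {
      sim <- results[[sx]]$simulation
      prev <- prevalence_curves(sim$trajectory)
      tibble::tibble(sex = sx, location = location,
                     age = sim$trajectory$age, year = sim$trajectory$year,
                     S0 = sim$trajectory$S0, Ca = sim$trajectory$Ca,
                     Ci = sim$trajectory$Ci,
                     p0 = prev$p0, p_a = prev$p_a, p_i = prev$p_i)
    }))
    utils::write.csv(traj_tab, file.path(out_dir, "trajectory.csv"), row.names = FALSE)
    jsonlite::write_json(config, file.path(out_dir, "metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  results
}
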