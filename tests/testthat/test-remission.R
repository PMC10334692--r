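test_that("steady-state balance gives the closed-form remission rate", {
  expect_equal(remission_from_pde(0.5, 0, 0, 0), 0)
  expect_equal(remission_from_pde(0.2, 0.01, 0, 0), 0.04)
  # property: with both partials zero, r = i (1 - p) / p exactly
  set.seed(11)
  for (k in 1:20) {
    p <- runif(1, 0.01, 0.99); i <- runif(1, 0, 0.2)
    expect_identical(remission_from_pde(p, i, 0, 0), i * (1 - p) / p)
  }
  expect_error(remission_from_pde(0, 0.01, 0), class = "migstates_rate_error")
  expect_error(remission_from_pde(1, 0.01, 0), class = "migstates_rate_error")
  expect_error(remission_from_pde(0.5, -0.01, 0), class = "migstates_rate_error")
})

test_that("inversion of the closed-form two-state world is exact", {
  # forward solution of p' = i(1-p) - r p from p(10) = 0, evaluated analytically
  i <- 0.02; r <- 0.05; a <- 40
  p <- constant_world_p(a, i, r)
  dp_da <- i * (1 - p) - r * p
  expect_equal(remission_from_pde(p, i, dp_da, 0), r, tolerance = 1e-6)
})

test_that("surface-fitted inversion recovers a constant remission rate", {
  tab <- constant_world_table(i = 0.02, r = 0.05)
  prev_s <- fit_surface(tab[tab$measure == "prevalence", ])
  inc_s <- fit_surface(tab[tab$measure == "incidence", ])
  curve <- estimate_remission(prev_s, inc_s, ages = seq(30, 60, by = 2.5), year = 2019)
  expect_true(all(abs(curve$rate - 0.05) / 0.05 <= 0.10))
})

test_that("oracle equivalence holds across constant (i, r) pairs at interior ages", {
  for (pars in list(c(0.01, 0.02), c(0.05, 0.2), c(0.2, 0.1))) {
    tab <- constant_world_table(i = pars[1], r = pars[2])
    prev_s <- fit_surface(tab[tab$measure == "prevalence", ])
    inc_s <- fit_surface(tab[tab$measure == "incidence", ])
    curve <- estimate_remission(prev_s, inc_s, ages = seq(30, 60, by = 5), year = 2019)
    expect_true(all(abs(curve$rate - pars[2]) / pars[2] <= 0.10))
  }
})

test_that("declining prevalence with no incidence implies positive remission", {
  prev <- make_slice(function(a, t) plogis(-1 - 0.01 * a))
  inc <- make_slice(function(a, t) rep(0, length(a)), measure = "incidence")
  prev_s <- fit_surface(prev); inc_s <- fit_surface(inc)
  curve <- estimate_remission(prev_s, inc_s, ages = seq(20, 80, by = 10), year = 2005)
  expect_true(all(curve$rate > 0))
  expect_false(any(curve$flag_negative))
})

test_that("constant prevalence and incidence give the steady-state rate at all ages", {
  prev <- make_slice(function(a, t) rep(0.2, length(a)))
  inc <- make_slice(function(a, t) rep(0.01, length(a)), measure = "incidence")
  curve <- estimate_remission(fit_surface(prev), fit_surface(inc),
                              ages = seq(20, 80, by = 10), year = 2005)
  expect_equal(curve$rate, rep(0.01 * 0.8 / 0.2, nrow(curve)), tolerance = 1e-6)
})

test_that("mismatched surfaces are refused", {
  tab <- constant_world_table()
  prev_s <- fit_surface(tab[tab$measure == "prevalence", ])
  tab_m <- constant_world_table(sex = "male")
  inc_m <- fit_surface(tab_m[tab_m$measure == "incidence", ])
  expect_error(estimate_remission(prev_s, inc_m, 30, 2019),
               class = "migstates_argument_error")
  expect_error(estimate_remission(prev_s, prev_s, 30, 2019),
               class = "migstates_argument_error")
})

test_that("zero-variance resampling collapses the band onto the point estimate", {
  tab <- constant_world_table(ui_halfwidth = 0)
  est <- resample_remission(tab, ages = seq(30, 60, by = 10), year = 2019,
                            n_resamples = 10, seed = 3)
  expect_equal(est$lower$rate, est$point$rate)
  expect_equal(est$upper$rate, est$point$rate)
  expect_equal(est$point$rate, est$plugin$rate)
})

test_that("resampled estimates are deterministic under a fixed seed", {
  tab <- constant_world_table(ui_halfwidth = 0.05)
  a <- resample_remission(tab, ages = seq(30, 60, by = 10), year = 2019,
                          n_resamples = 25, seed = 42)
  b <- resample_remission(tab, ages = seq(30, 60, by = 10), year = 2019,
                          n_resamples = 25, seed = 42)
  expect_identical(a$draws, b$draws)
  expect_identical(a$point$rate, b$point$rate)
})

test_that("confidence bands widen pointwise with the input uncertainty", {
  ages <- seq(30, 60, by = 5)
  narrow <- resample_remission(constant_world_table(ui_halfwidth = 0.01),
                               ages = ages, year = 2019, n_resamples = 50, seed = 5)
  wide <- resample_remission(constant_world_table(ui_halfwidth = 0.2),
                             ages = ages, year = 2019, n_resamples = 50, seed = 5)
  w_narrow <- narrow$upper$rate - narrow$lower$rate
  w_wide <- wide$upper$rate - wide$lower$rate
  expect_true(all(w_wide >= w_narrow))
})

test_that("the per-100-person-years convention is applied only at reporting", {
  tab <- constant_world_table(ui_halfwidth = 0.05)
  est <- resample_remission(tab, ages = seq(30, 60, by = 10), year = 2019,
                            n_resamples = 10, seed = 2)
  rep_tab <- remission_report(est)
  expect_equal(rep_tab$rate_per_100py, 100 * est$point$rate)
})
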