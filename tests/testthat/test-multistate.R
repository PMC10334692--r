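test_that("the balance identity gives the reactivation hazard", {
  expect_equal(as.numeric(reactivation_from_gbd(0.01, 0.01, 80, 20)), 0.01)
  expect_equal(as.numeric(reactivation_from_gbd(0.02, 0.01, 70, 30)),
               (0.02 * 100 - 0.01 * 70) / 30)
  # empty inactive pool falls back to the pooled incidence, flagged
  f <- reactivation_from_gbd(0.01, 0.01, 100, 0)
  expect_equal(as.numeric(f), 0.01)
  expect_true(attr(f, "fallback"))
  # negative solutions clamp to zero, flagged
  f2 <- reactivation_from_gbd(0.001, 0.01, 90, 10)
  expect_equal(as.numeric(f2), 0)
  expect_true(attr(f2, "clamped"))
  expect_error(reactivation_from_gbd(0.01, 0.01, 0, 0),
               class = "migstates_rate_error")
})

test_that("one Euler step matches the hand-computed recursion and conserves N", {
  st <- cohort_state(30, S0 = 900, Ca = 80, Ci = 20)
  rates <- transition_rates(i0 = 0.01, r = 0.05, f = 0.02)
  nxt <- markov_step(st, rates, h = 0.01)
  expect_equal(nxt$S0, 899.91)
  expect_equal(nxt$Ca, 80.054)
  expect_equal(nxt$Ci, 20.036)
  expect_lt(abs(nxt$S0 + nxt$Ca + nxt$Ci - 1000), 1e-9)
  expect_equal(nxt$age, 30.01)

  same <- markov_step(st, transition_rates(0, 0, 0), h = 0.5)
  expect_equal(c(same$S0, same$Ca, same$Ci), c(900, 80, 20))
  expect_error(markov_step(st, transition_rates(0, 150, 0), h = 0.01),
               class = "migstates_step_error")
})

test_that("an all-zero-rate cohort is absorbing", {
  traj <- run_cohort(cohort_state(30, 1e5, 0, 0), transition_rates(0, 0, 0),
                     follow_up = 30, h = 0.01)
  expect_equal(nrow(traj), 3001L)
  expect_equal(traj$S0[nrow(traj)], 1e5)
  prev <- prevalence_curves(traj)
  expect_true(all(prev$p0 == 1))
})

test_that("pure remission decay matches its exponential solution", {
  traj <- run_cohort(cohort_state(30, 0, 1e5, 0), transition_rates(0, 0.05, 0),
                     follow_up = 30, h = 0.01)
  prev <- prevalence_curves(traj)
  end <- nrow(prev)
  expect_equal(prev$p_a[end], exp(-1.5), tolerance = 0.005)
  expect_equal(prev$p_i[end], 1 - exp(-1.5), tolerance = 0.005)
  expect_equal(prev$p0[end], 0)
})

test_that("totals are conserved and the never state never grows", {
  rates <- transition_rates(i0 = function(a) 0.005 + 1e-4 * a,
                            r = function(a) 0.02 + 5e-4 * a,
                            f = 0.01)
  traj <- run_cohort(cohort_state(30, 9e4, 8e3, 2e3), rates,
                     follow_up = 30, h = 0.01)
  totals <- traj$S0 + traj$Ca + traj$Ci
  expect_true(all(abs(totals - 1e5) < 1e-6))
  expect_true(all(diff(traj$S0) <= 0))
  prev <- prevalence_curves(traj)
  expect_true(all(abs(prev$p0 + prev$p_a + prev$p_i - 1) < 1e-12))
})

test_that("halving the step changes end-of-follow-up prevalences by < 0.1%", {
  rates <- transition_rates(i0 = 0.005, r = 0.04, f = 0.01)
  end_prev <- function(h) {
    traj <- run_cohort(cohort_state(30, 9e4, 8e3, 2e3), rates, 30, h)
    unlist(prevalence_curves(traj)[nrow(traj), c("p0", "p_a", "p_i")])
  }
  coarse <- end_prev(0.01); fine <- end_prev(0.005)
  expect_true(all(abs(coarse - fine) / fine < 0.001))
})

test_that("non-integral step counts are refused", {
  expect_error(run_cohort(cohort_state(30, 1e5, 0, 0), transition_rates(0, 0, 0),
                          follow_up = 30, h = 0.007),
               class = "migstates_argument_error")
})

test_that("cohort initialization splits the complement and flags degenerate inputs", {
  prev_s <- fit_surface(make_slice(function(a, t) rep(0.2, length(a))))
  base <- baseline_from_coefs(c(b0 = qlogis(0.22), b1 = 0, b2 = 0, b3 = 0))
  init <- initialize_cohort(base, prev_s, start_age = 30, start_year = 1990,
                            N = 1e5, sex = "female")
  expect_equal(init$S0, 78000, tolerance = 1e-6)
  expect_equal(init$Ca, 20000, tolerance = 1e-6)
  expect_equal(init$Ci, 2000, tolerance = 1e-3)
  expect_false(attr(init, "flag_renormalized"))

  base_hi <- baseline_from_coefs(c(b0 = qlogis(0.15), b1 = 0, b2 = 0, b3 = 0))
  expect_warning(
    init2 <- initialize_cohort(base_hi, prev_s, 30, 1990, 1e5, "female"),
    "flooring")
  expect_equal(init2$Ci, 0)
  expect_equal(init2$S0, 80000, tolerance = 1e-6)
  expect_true(attr(init2, "flag_renormalized"))
})
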