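test_that("resampling uses the normal rule implied by the confidence limits", {
  pt <- data.frame(sex = "female", age_mid = 29.5, q0 = 0.20,
                   lower = 0.10, upper = 0.30)
  draws <- sample_lifetime_sets(pt, n_samples = 20000, seed = 1)
  # sd = (0.30 - 0.10) / (2 * 1.96)
  expect_equal(sd(draws$q0, na.rm = TRUE), 0.20 / 3.92, tolerance = 0.03)
  expect_equal(mean(draws$q0, na.rm = TRUE), 0.20, tolerance = 0.01)

  degenerate <- pt; degenerate$lower <- 0.2; degenerate$upper <- 0.2
  expect_error(sample_lifetime_sets(degenerate, 10, seed = 1),
               class = "migstates_argument_error")
})

test_that("draws outside (0, 1) become missing and tables keep their size", {
  pt <- data.frame(sex = c("male", "female"), age_mid = c(29.5, 29.5),
                   q0 = c(0.02, 0.98), lower = c(0.001, 0.9), upper = c(0.15, 0.999))
  draws <- sample_lifetime_sets(pt, n_samples = 2000, seed = 9)
  expect_equal(nrow(draws), 2 * 2000)
  expect_true(anyNA(draws$q0))
  expect_true(all(draws$q0 > 0 & draws$q0 < 1, na.rm = TRUE))
})

test_that("the logit-linear regression interpolates a saturated design exactly", {
  truth <- c(b0 = -2.8, b1 = 0.014, b2 = 1.4, b3 = 0.003)
  pts <- lifetime_points_from_coefs(truth, ci_halfwidth = 0.02)
  b <- fit_logit_model(pts)
  expect_equal(unname(b), unname(truth), tolerance = 1e-10)
})

test_that("rank-deficient designs return a fit-failure marker", {
  women_only <- data.frame(sex = "female", age_mid = c(29.5, 39.5, 49.5, 59.5),
                           q0 = c(0.2, 0.25, 0.3, 0.33))
  expect_null(fit_logit_model(women_only))
  too_few <- data.frame(sex = c("male", "female"), age_mid = c(29.5, 29.5),
                        q0 = c(0.1, 0.2))
  expect_null(fit_logit_model(too_few))
})

test_that("two-point anchors give the analytic logit slope", {
  anchors <- data.frame(
    sex = c("female", "female", "male", "male"),
    age_mid = c(25, 65, 25, 65),
    q0 = c(0.198, 0.325, 0.056, 0.094))
  b <- fit_logit_model(anchors)
  female_slope <- (qlogis(0.325) - qlogis(0.198)) / 40
  male_slope <- (qlogis(0.094) - qlogis(0.056)) / 40
  expect_equal(b[["b1"]] + b[["b3"]], female_slope, tolerance = 1e-10)
  expect_equal(b[["b1"]], male_slope, tolerance = 1e-10)
})

test_that("admissibility excludes decreasing age-dependency and pooling is the median", {
  sets <- tibble::tibble(
    b0 = c(-3, -3, -3), b1 = c(0.01, 0.02, 0.03),
    b2 = c(0.5, 0.5, 0.5), b3 = c(0.005, 0.005, 0.005))
  pooled <- filter_and_pool(sets)
  expect_equal(pooled$coefs[["b1"]], 0.02)
  expect_equal(pooled$n_valid, 3L)

  mixed <- sets; mixed$b1[2] <- -0.01  # male slope negative -> inadmissible
  pooled2 <- filter_and_pool(mixed)
  expect_equal(pooled2$n_valid, 2L)
  expect_equal(pooled2$coefs[["b1"]], 0.02)

  neg_female <- sets; neg_female$b3 <- -0.05  # b1 + b3 < 0
  expect_error(filter_and_pool(neg_female), class = "migstates_estimation_error")
  expect_false(coef_admissible(c(b0 = 0, b1 = -0.01, b2 = 0, b3 = 0.005)))
  expect_true(coef_admissible(c(b0 = 0, b1 = 0.01, b2 = 0, b3 = -0.005)))
})

test_that("the susceptible-pool identity i0 = q0'/(1 - q0) holds analytically", {
  base <- baseline_from_coefs(recovery_coefs)
  h <- 1e-5
  for (sx in c("male", "female")) {
    ages <- c(25, 45, 65)
    dq0 <- (base$q0(ages + h, sx) - base$q0(ages - h, sx)) / (2 * h)
    expect_equal(base$i0(ages, sx) * (1 - base$q0(ages, sx)), dq0, tolerance = 1e-8)
    expect_identical(base$p0(ages, sx) + base$q0(ages, sx), rep(1, 3))
    expect_true(all(diff(base$q0(seq(15, 80, by = 5), sx)) > 0))
  }
})

test_that("a flat lifetime curve implies zero first-incidence", {
  flat <- baseline_from_coefs(c(b0 = -1, b1 = 0, b2 = 0.5, b3 = 0))
  expect_equal(flat$i0(c(25, 65), "male"), c(0, 0))
  expect_equal(flat$i0(c(25, 65), "female"), c(0, 0))
})

test_that("evaluation outside the supported age range warns but returns", {
  base <- baseline_from_coefs(recovery_coefs)
  expect_warning(v <- i0_eval(base, 95, "female"), "outside")
  expect_true(is.finite(v))
  expect_silent(i0_eval(base, 40, "female"))
})

test_that("the lifetime stage is reproducible under a fixed seed", {
  pts <- lifetime_points_from_coefs(recovery_coefs, ci_halfwidth = 0.05)
  a <- fit_lifetime(pts, n_samples = 300, seed = 21)
  b <- fit_lifetime(pts, n_samples = 300, seed = 21)
  expect_identical(a$coefs, b$coefs)
  expect_identical(a$n_valid, b$n_valid)
})

test_that("pooled coefficients converge to truth as the interval width shrinks", {
  pts_wide <- lifetime_points_from_coefs(recovery_coefs, ci_halfwidth = 0.05)
  pts_narrow <- lifetime_points_from_coefs(recovery_coefs, ci_halfwidth = 0.005)
  err <- function(pts) {
    fit <- fit_lifetime(pts, n_samples = 400, seed = 8)
    max(abs(fit$coefs - recovery_coefs) / abs(recovery_coefs))
  }
  e_wide <- err(pts_wide); e_narrow <- err(pts_narrow)
  expect_lt(e_narrow, e_wide)
  expect_lt(e_narrow, 0.02)
})
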