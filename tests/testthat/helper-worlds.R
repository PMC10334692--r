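# shared synthetic worlds, computed once per session
.worlds <- new.env(parent = emptyenv())

default_truth <- function() {
  if (is.null(.worlds$truth)) .worlds$truth <- ground_truth()
  .worlds$truth
}

default_solution <- function() {
  if (is.null(.worlds$solution)) {
    .worlds$solution <- solve_truth(default_truth(), h_fine = 0.005)
  }
  .worlds$solution
}

# closed-form two-state world (the independent oracle for the PDE stage):
# constant incidence i and remission r, disease-free at age 10, so
# p(a) = i/(i+r) * (1 - exp(-(i+r)(a-10))) and p' = i(1-p) - r p.
constant_world_p <- function(age, i = 0.02, r = 0.05) {
  i / (i + r) * (1 - exp(-(i + r) * (age - 10)))
}

# build a one-measure (sex, location) slice from a value function of (age, year)
make_slice <- function(value_fun, measure = "prevalence", sex = "female",
                       location = "Germany", ages = seq(12.5, 92.5, by = 5),
                       years = 1990:2019, ui_halfwidth = 0) {
  labels <- gbd_age_labels()
  mids <- age_midpoint(labels)
  g <- expand.grid(age_mid = ages, year = years, KEEP.OUT.ATTRS = FALSE)
  v <- value_fun(g$age_mid, g$year)
  tibble::tibble(
    measure = measure, location = location, sex = sex, year = g$year,
    age_label = labels[match(g$age_mid, mids)], age_mid = g$age_mid,
    value = v, lower = v * (1 - ui_halfwidth), upper = v * (1 + ui_halfwidth))
}

# full two-measure gbd_table for the constant-rate two-state world
constant_world_table <- function(i = 0.02, r = 0.05, sex = "female",
                                 ui_halfwidth = 0, years = 1990:2019) {
  prev <- make_slice(function(a, t) constant_world_p(a, i, r),
                     measure = "prevalence", sex = sex, years = years,
                     ui_halfwidth = ui_halfwidth)
  inc <- make_slice(function(a, t) rep(i, length(a)),
                    measure = "incidence", sex = sex, years = years,
                    ui_halfwidth = ui_halfwidth)
  gbd_table(rbind(prev, inc))
}

# hand-picked logit-linear lifetime truth used in recovery checks
recovery_coefs <- c(b0 = -3.2, b1 = 0.022, b2 = 0.7, b3 = 0.012)

# plain column data, ignoring container bookkeeping (meta/reject attributes)
strip_attrs <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "class", "row.names")]
  x
}
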