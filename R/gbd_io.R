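#' Ordered GBD age-group labels
#'
#' The age grouping used by the GBD Results Tool: `"<1 year"`, `"1 to 4"`,
#' then five-year groups `"5 to 9"` through `"90 to 94"`, and `"95 plus"`.
#'
#' @return Character vector of labels in increasing age order.
#' @export
gbd_age_labels <- function() {
  c("<1 year", "1 to 4",
    paste(seq(5, 90, by = 5), "to", seq(9, 94, by = 5)),
    "95 plus")
}

#' Midpoint age of a GBD age-group label
#'
#' Age spans are treated as half-open year intervals, so `"10 to 14"` covers
#' ages 10 up to (but excluding) 15 and has midpoint 12.5. The open-ended
#' `"95 plus"` group is assigned 97.5 and `"<1 year"` is assigned 0.5.
#'
#' @param age_label Character vector of GBD age-group labels.
#' @return Numeric vector of midpoint ages in years.
#' @examples
#' age_midpoint(c("5 to 9", "95 plus", "1 to 4"))
#' @export
age_midpoint <- function(age_label) {
  labels <- gbd_age_labels()
  lows <- c(0, 1, seq(5, 90, by = 5), 95)
  highs <- c(1, 5, seq(10, 95, by = 5), 100)
  mids <- (lows + highs) / 2
  idx <- match(age_label, labels)
  if (anyNA(idx)) {
    bad <- unique(age_label[is.na(idx)])
    stop(errorCondition(
      sprintf("unrecognized age-group label(s): %s", paste(bad, collapse = ", ")),
      class = c("migstates_parse_error", "error", "condition")))
  }
  mids[idx]
}

# default mapping from GBD Results Tool export headers to internal names
.default_gbd_schema <- function() {
  c(measure = "measure", location = "location", sex = "sex", year = "year",
    age_label = "age", value = "val", lower = "lower", upper = "upper")
}

# row-level invariant checks; returns a character reason or NA if valid
.gbd_row_problems <- function(d) {
  reason <- rep(NA_character_, nrow(d))
  bad_order <- !(d$lower <= d$value & d$value <= d$upper)
  reason[bad_order] <- "value outside [lower, upper]"
  neg <- d$lower < 0
  reason[neg & is.na(reason)] <- "negative lower bound"
  prev_oob <- d$measure == "prevalence" & (d$value < 0 | d$value > 1 | d$upper > 1)
  reason[prev_oob & is.na(reason)] <- "prevalence outside [0, 1]"
  inc_neg <- d$measure == "incidence" & d$value < 0
  reason[inc_neg & is.na(reason)] <- "negative incidence"
  nonfin <- !is.finite(d$value) | !is.finite(d$lower) | !is.finite(d$upper)
  reason[nonfin] <- "non-finite value"
  reason
}

#' Construct and validate a GBD-style table
#'
#' Normalizes a data frame of prevalence/incidence records into the tidy
#' container used throughout the package. Rows violating record invariants
#' are never dropped silently: they are removed from the table and attached,
#' with a reason each, as the `"rejects"` attribute.
#'
#' @param records Data frame with columns `measure` (`"prevalence"` or
#'   `"incidence"`), `location`, `sex` (`"male"`/`"female"`), `year`,
#'   `age_label`, `value`, `lower`, `upper`. An `age_mid` column is derived
#'   from `age_label` if absent.
#' @param meta Optional list describing provenance (echoed on the object).
#' @return A tibble of class `gbd_table`, ordered by
#'   (measure, location, sex, year, age_mid), with attributes `meta` and
#'   `rejects`.
#' @export
gbd_table <- function(records, meta = list()) {
  d <- tibble::as_tibble(records)
  required <- c("measure", "location", "sex", "year", "age_label",
                "value", "lower", "upper")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0) {
    stop(errorCondition(
      sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
      class = c("migstates_schema_error", "error", "condition")))
  }
  d$measure <- as.character(d$measure)
  d$sex <- as.character(d$sex)
  d$year <- as.integer(d$year)
  if (!"age_mid" %in% names(d)) d$age_mid <- age_midpoint(d$age_label)

  reason <- .gbd_row_problems(d)
  rejects <- d[!is.na(reason), , drop = FALSE]
  rejects$reason <- reason[!is.na(reason)]
  d <- d[is.na(reason), , drop = FALSE]

  key <- paste(d$measure, d$location, d$sex, d$year, d$age_mid, sep = "|")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop(errorCondition(
      sprintf("duplicate (measure, location, sex, year, age) key(s): %s",
              paste(utils::head(dup, 5), collapse = "; ")),
      class = c("migstates_validation_error", "error", "condition")))
  }
  d <- d[order(d$measure, d$location, d$sex, d$year, d$age_mid),
         c(required[1:5], "age_mid", "value", "lower", "upper")]
  structure(d, meta = meta, rejects = rejects,
            class = c("gbd_table", class(tibble::tibble())))
}

#' Read a GBD Results Tool style CSV extract
#'
#' @param path Path to a comma-separated UTF-8 file with a header row.
#' @param schema Named character vector mapping internal names
#'   (`measure`, `location`, `sex`, `year`, `age_label`, `value`, `lower`,
#'   `upper`) to the column names used in the file. Defaults accept the GBD
#'   export headers (`age`, `val`, ...); entries already matching internal
#'   names are also accepted.
#' @param values_are_percent If `TRUE`, `value`, `lower`, `upper` are divided
#'   by 100 on read. Never guessed from the data.
#' @return A validated [gbd_table]; rejected rows (with reasons) are in
#'   `attr(, "rejects")`.
#' @export
read_gbd_csv <- function(path, schema = NULL, values_are_percent = FALSE) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("file not found: %s", path),
                        class = c("migstates_io_error", "error", "condition")))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  sch <- .default_gbd_schema()
  if (!is.null(schema)) sch[names(schema)] <- schema
  out <- list()
  for (nm in names(sch)) {
    col <- if (sch[[nm]] %in% names(raw)) sch[[nm]] else nm
    if (!col %in% names(raw)) {
      stop(errorCondition(
        sprintf("missing column: expected '%s' (for field '%s')", sch[[nm]], nm),
        class = c("migstates_schema_error", "error", "condition")))
    }
    out[[nm]] <- raw[[col]]
  }
  d <- tibble::as_tibble(out)
  if (values_are_percent) {
    d$value <- d$value / 100; d$lower <- d$lower / 100; d$upper <- d$upper / 100
  }
  gbd_table(d, meta = list(source = path, values_are_percent = values_are_percent))
}

#' Write a GBD table to CSV
#'
#' Writes the normalized column order (measure, location, sex, year,
#' age_label, age_mid, value, lower, upper) so that [read_gbd_csv] with
#' `schema = c(value = "value", age_label = "age_label")` round-trips the
#' table field-for-field.
#'
#' @param table A [gbd_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gbd_csv <- function(table, path) {
  stopifnot(inherits(table, "gbd_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

# midpoints for the lifetime-prevalence age groups (Danish survey layout)
.lifetime_age_mid <- function(age_group) {
  map <- c("25-34" = 29.5, "35-44" = 39.5, "45-54" = 49.5, "55-64" = 59.5)
  idx <- match(gsub("\\s", "", age_group), names(map))
  if (anyNA(idx)) {
    bad <- unique(age_group[is.na(idx)])
    stop(errorCondition(
      sprintf("unknown lifetime age group(s): %s", paste(bad, collapse = ", ")),
      class = c("migstates_parse_error", "error", "condition")))
  }
  unname(map[idx])
}

#' Construct and validate a lifetime-prevalence table
#'
#' One row per (sex, age group): the lifetime prevalence `q0` of ever having
#' had migraine, with its 95% confidence limits. Age-group midpoints
#' (25-34 -> 29.5, ..., 55-64 -> 59.5) are attached.
#'
#' @param points Data frame with columns `sex`, `age_group`, `q0`, `lower`,
#'   `upper` (all proportions).
#' @return A tibble of class `lifetime_table` with an `age_mid` column.
#' @export
lifetime_table <- function(points) {
  d <- tibble::as_tibble(points)
  required <- c("sex", "age_group", "q0", "lower", "upper")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0) {
    stop(errorCondition(
      sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
      class = c("migstates_schema_error", "error", "condition")))
  }
  d$age_mid <- .lifetime_age_mid(d$age_group)
  ok <- d$lower <= d$q0 & d$q0 <= d$upper & d$lower >= 0 & d$upper <= 1
  if (!all(ok)) {
    stop(errorCondition(
      sprintf("lifetime prevalence outside its confidence limits in row(s): %s",
              paste(which(!ok), collapse = ", ")),
      class = c("migstates_validation_error", "error", "condition")))
  }
  d <- d[order(d$sex, d$age_mid), c("sex", "age_group", "age_mid", "q0", "lower", "upper")]
  structure(d, class = c("lifetime_table", class(tibble::tibble())))
}

#' Read a lifetime-prevalence CSV
#'
#' @param path CSV with columns `sex`, `age_group`, `q0`, `lower`, `upper`.
#' @return A validated [lifetime_table].
#' @export
read_lifetime_table <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("file not found: %s", path),
                        class = c("migstates_io_error", "error", "condition")))
  }
  lifetime_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a lifetime-prevalence table to CSV
#'
#' @param points A [lifetime_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lifetime_table <- function(points, path) {
  stopifnot(inherits(points, "lifetime_table"))
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}

#' Extract one (measure, sex, location) slice of a GBD table
#'
#' @param table A [gbd_table].
#' @param measure,sex,location Slice selectors.
#' @return The matching rows, still a `gbd_table`.
#' @export
gbd_slice <- function(table, measure, sex, location) {
  stopifnot(inherits(table, "gbd_table"))
  keep <- table$measure == measure & table$sex == sex & table$location == location
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    stop(errorCondition(
      sprintf("no records for (%s, %s, %s)", measure, sex, location),
      class = c("migstates_validation_error", "error", "condition")))
  }
  out
}
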