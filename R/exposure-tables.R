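#' Read a food concentration/intake summary table
#'
#' Reads a delimited text table with one row per food category and one
#' header row naming the summary statistics. Comma and tab delimiters are
#' accepted. Each row carries the cadmium concentration statistics of the
#' food (mg/kg) and the daily-intake statistics of the surveyed population
#' (g/day). Empty cells become `NA` ("statistic not reported"), never zero:
#' an unreported 90th-percentile concentration must not silently deflate
#' extreme-exposure totals.
#'
#' Recognised columns are `food`, `conc_mean`, `conc_std`, `conc_median`,
#' `conc_p90`, `conc_ref2000` (an older reference survey mean, carried but
#' unused computationally), `intake_mean`, `intake_std`, `intake_median`,
#' `intake_p90`, and `extreme_override` (a per-food extreme-P90 exposure in
#' ug/day used when `conc_p90` is unreported; see
#' [food_exposure_extreme()]). `food`, `conc_mean` and `intake_mean` are
#' required.
#'
#' @param path Path to a CSV or TSV file.
#' @return A `food_table`: a data frame with one row per food, all
#'   statistic columns numeric, `NA` for absent cells.
#' @seealso [shanghai_food_table()] for the shipped survey fixture,
#'   [write_food_table()] for the inverse.
#' @export
#' @examples
#' tab <- shanghai_food_table()
#' tab[tab$food == "Rice", c("conc_mean", "intake_mean")]
read_food_table <- function(path) {
  if (!file.exists(path)) {
    stop_domain("food table file does not exist: ", path)
  }
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header)) {
    stop_domain("food table is empty: ", path)
  }
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = TRUE,
                           na.strings = c("", "NA"))
  as_food_table(raw)
}

food_stat_columns <- c("conc_mean", "conc_std", "conc_median", "conc_p90",
                       "conc_ref2000", "intake_mean", "intake_std",
                       "intake_median", "intake_p90", "extreme_override")

#' Validate and classify a data frame as a food table
#'
#' Checks the header, coerces statistic columns to numeric, and enforces
#' the row-level invariants: all present statistics are non-negative,
#' medians do not exceed 90th percentiles, and food names are unique.
#' Violations raise an error naming the offending row and column.
#'
#' @param x A data frame with at least `food`, `conc_mean`, `intake_mean`.
#' @return A validated `food_table`.
#' @export
as_food_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("food", "conc_mean", "intake_mean")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop_domain("malformed food table header: missing column(s) ",
                paste(missing_cols, collapse = ", "))
  }
  if (nrow(x) == 0L) {
    stop_domain("food table has no rows")
  }
  x$food <- as.character(x$food)
  dup <- x$food[duplicated(x$food)]
  if (length(dup) > 0L) {
    stop_domain("duplicate food name(s): ", paste(unique(dup), collapse = ", "))
  }
  for (col in intersect(food_stat_columns, names(x))) {
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }
  for (col in setdiff(food_stat_columns, names(x))) {
    x[[col]] <- NA_real_
  }
  for (col in food_stat_columns) {
    bad <- which(!is.na(x[[col]]) & x[[col]] < 0)
    if (length(bad) > 0L) {
      stop_domain("negative value in food table: row '", x$food[bad[1L]],
                  "', column '", col, "'")
    }
  }
  check_order <- function(lo, hi) {
    bad <- which(!is.na(x[[lo]]) & !is.na(x[[hi]]) & x[[lo]] > x[[hi]])
    if (length(bad) > 0L) {
      stop_domain("food table row '", x$food[bad[1L]], "': ", lo,
                  " exceeds ", hi)
    }
  }
  check_order("conc_median", "conc_p90")
  check_order("intake_median", "intake_p90")
  x <- x[c("food", food_stat_columns)]
  class(x) <- c("food_table", "data.frame")
  x
}

#' Write a food table back to delimited text
#'
#' Numeric cells are written at full precision so that
#' `read_food_table(write_food_table(x))` round-trips bit-exactly; `NA`
#' cells are written as empty strings.
#'
#' @param x A `food_table`.
#' @param path Output file path.
#' @param sep Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_food_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "food_table"))
  utils::write.table(x, path, sep = sep, na = "", row.names = FALSE,
                     quote = TRUE)
  invisible(path)
}

#' Shipped survey tables and reference files
#'
#' Accessors for the plain-text tables installed with the package:
#'
#' * `shanghai_food_table()`: the 14-category food cadmium concentration
#'   (mg/kg) and daily intake (g/day) summary table from the 2008 Shanghai
#'   survey of adults over 40.
#' * `reported_exposure_breakdown()`: the survey's published per-source
#'   exposure breakdown (ug/day and contribution rates in percent) at the
#'   four summary levels, used as a reference for validating
#'   [exposure_breakdown()].
#' * `reported_exposure_distributions()`: the published Monte Carlo output
#'   summaries (lognormal family; mean, median, std, 5th-95th percentile
#'   and range in ug/day) for the total population and the sex/smoking
#'   strata, used to reconstruct the reported output distributions via
#'   [lognormal_from_mean_median()].
#' * `cadmium_max_levels()`: a static reference table of regulatory
#'   cadmium maximum levels in foodstuffs (no computation is performed on
#'   it).
#'
#' @return A data frame (a `food_table` for `shanghai_food_table()`).
#' @export
shanghai_food_table <- function() {
  read_food_table(system.file("extdata", "shanghai_food_cadmium.csv",
                              package = "cadexpo", mustWork = TRUE))
}

#' @rdname shanghai_food_table
#' @export
reported_exposure_breakdown <- function() {
  utils::read.csv(system.file("extdata", "reported_exposure_breakdown.csv",
                              package = "cadexpo", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' @rdname shanghai_food_table
#' @export
reported_exposure_distributions <- function() {
  utils::read.csv(system.file("extdata", "reported_exposure_distributions.csv",
                              package = "cadexpo", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' @rdname shanghai_food_table
#' @export
cadmium_max_levels <- function() {
  utils::read.csv(system.file("extdata", "cadmium_max_levels_reference.csv",
                              package = "cadexpo", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Convert a tolerable monthly intake to a daily intake
#'
#' The health-based limit for cadmium is expressed as a provisional
#' tolerable monthly intake (PTMI) in ug per kg body weight per month;
#' risk characterisation here works on a daily scale. The conversion is
#' `ptmi * body_weight / days_per_month`. At the study values (PTMI 25,
#' body weight 60 kg) a month length of 30.3 days recovers the study's
#' PTDI of 49.5 ug/day; the calendar mean of 30.44 days gives 49.28.
#'
#' @param ptmi Tolerable monthly intake, ug/kg-bw/month.
#' @param body_weight Body weight, kg.
#' @param days_per_month Days per month used for the conversion.
#' @return Tolerable daily intake, ug/day.
#' @export
#' @examples
#' derive_ptdi(25, 60, 30.3) # 49.5
derive_ptdi <- function(ptmi, body_weight, days_per_month = 30.3) {
  if (any(c(ptmi, body_weight, days_per_month) <= 0)) {
    stop_domain("derive_ptdi: all arguments must be positive")
  }
  ptmi * body_weight / days_per_month
}

#' Exposure-assessment configuration
#'
#' Bundles the scalar constants of the assessment. Defaults are the study
#' values: PTMI 25 ug/kg-bw/month converted at 60 kg to a PTDI of 49.5
#' ug/day; tobacco cadmium 1.5 ug per g of tobacco with 1 g of tobacco per
#' cigarette; water cadmium fixed at half the 0.05 ug/L detection limit
#' (0.025 ug/L) with 1.2 L drunk per day; 100,000 Monte Carlo iterations.
#' The PTDI is carried as a configurable constant rather than always
#' re-derived because the month length implied by the study's conversion
#' (30.3 days) is nonstandard; when `ptdi = NULL` it is derived from
#' `ptmi` and `body_weight` via [derive_ptdi()].
#'
#' @param ptmi Tolerable monthly intake, ug/kg-bw/month.
#' @param body_weight Mean body weight, kg.
#' @param ptdi Tolerable daily intake, ug/day, or `NULL` to derive it.
#' @param tobacco_conc Cadmium per gram of tobacco, ug/g (= mg/kg).
#' @param cigarette_mass Tobacco per cigarette, g.
#' @param water_conc Drinking-water cadmium, ug/L.
#' @param water_volume Daily water consumption, L/day.
#' @param lod Analytical limit of detection, ug/L.
#' @param n_iterations Monte Carlo iteration count.
#' @param seed Default RNG seed recorded in outputs.
#' @param smoking_prevalence Named list/vector with elements `male`,
#'   `female`, `total`: smoking prevalence per stratum, in `[0, 1]`.
#' @return An `exposure_config` list.
#' @export
exposure_config <- function(ptmi = 25, body_weight = 60, ptdi = 49.5,
                            tobacco_conc = 1.5, cigarette_mass = 1.0,
                            water_conc = 0.025, water_volume = 1.2,
                            lod = 0.05, n_iterations = 100000,
                            seed = 20130618,
                            smoking_prevalence = list(male = 0.662,
                                                      female = 0.033,
                                                      total = 0.295)) {
  if (is.null(ptdi)) {
    ptdi <- derive_ptdi(ptmi, body_weight)
  }
  scalars <- c(ptmi = ptmi, body_weight = body_weight, ptdi = ptdi,
               tobacco_conc = tobacco_conc, cigarette_mass = cigarette_mass,
               water_conc = water_conc, water_volume = water_volume,
               lod = lod, n_iterations = n_iterations)
  bad <- names(scalars)[!is.finite(scalars) | scalars <= 0]
  if (length(bad) > 0L) {
    stop_domain("exposure_config: non-positive value for ",
                paste(bad, collapse = ", "))
  }
  prev <- as.list(smoking_prevalence)
  for (nm in c("male", "female", "total")) {
    p <- prev[[nm]]
    if (is.null(p) || !is.finite(p) || p < 0 || p > 1) {
      stop_domain("exposure_config: smoking_prevalence$", nm,
                  " must lie in [0, 1]")
    }
  }
  structure(list(ptmi = ptmi, body_weight = body_weight, ptdi = ptdi,
                 tobacco_conc = tobacco_conc, cigarette_mass = cigarette_mass,
                 water_conc = water_conc, water_volume = water_volume,
                 lod = lod, n_iterations = as.integer(n_iterations),
                 seed = seed, smoking_prevalence = prev),
            class = "exposure_config")
}

#' Read an exposure configuration from YAML or JSON
#'
#' Field names mirror the arguments of [exposure_config()]; absent fields
#' take the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `exposure_config`.
#' @export
read_exposure_config <- function(path) {
  if (!file.exists(path)) {
    stop_domain("config file does not exist: ", path)
  }
  fields <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(exposure_config))
  unknown <- setdiff(names(fields), known)
  if (length(unknown) > 0L) {
    stop_domain("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(exposure_config, fields)
}

#' @export
print.exposure_config <- function(x, ...) {
  cat("Exposure configuration\n")
  cat(sprintf("  PTMI %g ug/kg-bw/month, body weight %g kg, PTDI %g ug/day\n",
              x$ptmi, x$body_weight, x$ptdi))
  cat(sprintf("  tobacco %g ug Cd/g x %g g/cigarette; water %g ug/L x %g L/day\n",
              x$tobacco_conc, x$cigarette_mass, x$water_conc, x$water_volume))
  cat(sprintf("  LOD %g ug/L; %d iterations; seed %s\n", x$lod,
              x$n_iterations, format(x$seed)))
  cat(sprintf("  smoking prevalence: male %.3f, female %.3f, total %.3f\n",
              x$smoking_prevalence$male, x$smoking_prevalence$female,
              x$smoking_prevalence$total))
  invisible(x)
}

#' Read and validate an individual-level cohort table
#'
#' A cohort table has one row per participant with columns `id`, `age`
#' (years), `sex` (`"male"`/`"female"`), `smoker` (logical),
#' `cigarettes_per_day`, one `intake_<food>` column per food category
#' (g/day), and the internal-dose measurements `ucd` and `bcd` (ug/L).
#' Validation enforces positive ages, zero cigarettes for non-smokers and
#' non-negative intakes.
#'
#' @param path Path to a CSV file.
#' @return A validated `cohort_table` data frame.
#' @seealso [generate_cohort()] to create synthetic cohorts.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) {
    stop_domain("cohort file does not exist: ", path)
  }
  as_cohort_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_cohort_table
#' @param x A data frame shaped as described above.
#' @export
as_cohort_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("id", "age", "sex", "smoker", "cigarettes_per_day")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop_domain("cohort table: missing column(s) ",
                paste(missing_cols, collapse = ", "))
  }
  x$smoker <- as.logical(x$smoker)
  if (any(!is.finite(x$age)) || any(x$age <= 0)) {
    stop_domain("cohort table: ages must be positive")
  }
  if (!all(x$sex %in% c("male", "female"))) {
    stop_domain("cohort table: sex must be 'male' or 'female'")
  }
  if (any(!x$smoker & x$cigarettes_per_day != 0)) {
    stop_domain("cohort table: non-smokers must have cigarettes_per_day = 0")
  }
  intake_cols <- grep("^intake_", names(x), value = TRUE)
  for (col in intake_cols) {
    if (any(x[[col]] < 0, na.rm = TRUE)) {
      stop_domain("cohort table: negative intake in column ", col)
    }
  }
  class(x) <- c("cohort_table", "data.frame")
  x
}

#' @rdname read_cohort_table
#' @param cohort A `cohort_table`.
#' @export
write_cohort_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
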