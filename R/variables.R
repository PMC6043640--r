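# Variable registries for the two running models, athlete-table ingestion and
# validation, quartile summaries, and the world-record ratio utilities.

# Full per-variable table: identity (name/label/unit/category) plus the
# published cohort quartiles used as synthetic-marginal targets. `free` and
# `tethered` share 18 variables (with condition-specific quartiles); tethered
# adds 5 biomechanics outputs measured by the load-cell instrument.
variable_table <- function(condition = c("free", "tethered")) {
  condition <- match.arg(condition)
  common <- tibble::tribble(
    ~name,              ~label,                    ~unit,     ~category,
    "mean_velocity",    "Mean velocity",           "km/h",    "time_limit",
    "peak_lactate",     "Peak lactate",            "mmol/L",  "time_limit",
    "peak_vo2",         "Peak VO2",                "mL/min",  "time_limit",
    "mean_vo2",         "Mean VO2",                "mL/min",  "time_limit",
    "heart_rate",       "Heart rate",              "bpm",     "time_limit",
    "mean_r",           "Mean R",                  "dimensionless", "time_limit",
    "peak_r",           "Peak R",                  "dimensionless", "time_limit",
    "mean_vco2",        "Mean VCO2",               "mL/min",  "time_limit",
    "peak_vco2",        "Peak VCO2",               "mL/min",  "time_limit",
    "time_limit",       "Time limit",              "min",     "time_limit",
    "lean_mass_pct",    "% Lean mass",             "%",       "anthropometric",
    "bmi",              "BMI",                     "kg/m^2",  "anthropometric",
    "peak_p_vvo2",      "Peak P vVO2",             "km/h",    "aerobic_power",
    "peak_p_vo2",       "Peak P VO2",              "mL/min",  "aerobic_power",
    "aerobic_capacity", "Aerobic capacity",        "km/h",    "aerobic_capacity",
    "c_vo2",            "C VO2",                   "mL/min",  "aerobic_capacity",
    "peak_vo2_pct",     "% Peak VO2",              "%",       "aerobic_capacity",
    "maod",             "MAOD",                    "mL",      "anaerobic_capacity"
  )
  quart <- if (condition == "free") {
    tibble::tribble(
      ~q1,    ~median, ~q3,
      19.2,   19.6,    20.8,
      9.7,    10.7,    11.9,
      3372.5, 3499.5,  3550.9,
      2889.1, 3018.6,  3239.4,
      188,    191,     193,
      1.1,    1.1,     1.2,
      1.4,    1.4,     1.5,
      3528.2, 3714.6,  3818.0,
      4826.0, 4939.6,  5192.9,
      2.3,    2.7,     2.9,
      94.1,   95.0,    96.0,
      20.8,   22.7,    23.5,
      16.0,   16.3,    17.3,
      3284.1, 3337.9,  3818.8,
      12.4,   12.6,    12.7,
      2624.0, 2715.6,  2955.1,
      74.5,   78.9,    81.5,
      2699.3, 3482.5,  4866.7
    )
  } else {
    tibble::tribble(
      ~q1,    ~median, ~q3,
      15.6,   15.8,    16.0,
      9.1,    9.6,     10.8,
      3350.2, 3610.5,  3685.6,
      2989.7, 3124.1,  3272.1,
      173,    182,     186,
      1.2,    1.2,     1.2,
      1.4,    1.4,     1.5,
      3777.6, 3930.2,  4059.5,
      5003.5, 5305.1,  5494.2,
      3.0,    3.4,     3.8,
      94.1,   95.0,    96.0,
      20.8,   22.7,    23.5,
      14.1,   14.3,    14.5,
      3379.0, 3560.7,  3738.0,
      10.9,   11.0,    11.6,
      2656.4, 2849.6,  3099.5,
      80.4,   82.6,    82.9,
      3148.7, 3425.3,  4052.5
    )
  }
  out <- dplyr::bind_cols(common, quart)
  if (condition == "tethered") {
    biomech <- tibble::tribble(
      ~name,            ~label,           ~unit,  ~category,      ~q1,     ~median, ~q3,
      "power",          "Power",          "W",    "biomechanics", 96.8,    101.0,   111.2,
      "force",          "Force",          "N",    "biomechanics", 21.6,    23.0,    24.9,
      "work",           "Work",           "J",    "biomechanics", 19756.2, 22137.6, 24766.3,
      "step_frequency", "Step frequency", "s^-1", "biomechanics", 2.8,     2.9,     2.9,
      "step_length",    "Step length",    "m",    "biomechanics", 1.5,     1.6,     1.6
    )
    out <- dplyr::bind_rows(out, biomech)
  }
  out
}

#' Variable registry for a running model
#'
#' Returns the ordered registry of measured variables used as network nodes:
#' 18 variables for free running (ten Time Limit test outputs including the
#' time limit itself, two anthropometric measures, two aerobic-power and three
#' aerobic-capacity outputs from incremental testing, and the anaerobic
#' capacity MAOD), or those 18 plus five biomechanics outputs (power, force,
#' work, step frequency, step length) for tethered running.
#'
#' @param condition `"free"` or `"tethered"`.
#' @return A tibble with columns `name`, `label`, `unit`, `category`; one row
#'   per variable, in fixed registry order.
#' @examples
#' nrow(sprint_variables("free"))     # 18
#' nrow(sprint_variables("tethered")) # 23
#' @export
sprint_variables <- function(condition = c("free", "tethered")) {
  dplyr::select(variable_table(condition), "name", "label", "unit", "category")
}

valid_categories <- c(
  "time_limit", "anthropometric", "aerobic_power",
  "aerobic_capacity", "anaerobic_capacity", "biomechanics"
)

validate_registry <- function(registry) {
  if (!is.data.frame(registry) ||
      !all(c("name", "label", "unit", "category") %in% names(registry))) {
    abort("`registry` must have columns name, label, unit, category.",
          class = "sprintnet_error_bad_input")
  }
  if (anyDuplicated(registry$name) > 0) {
    abort("registry variable names must be unique.",
          class = "sprintnet_error_bad_input")
  }
  if (any(!nzchar(registry$unit))) {
    abort("registry units must be non-empty.",
          class = "sprintnet_error_bad_input")
  }
  bad <- setdiff(unique(registry$category), valid_categories)
  if (length(bad) > 0) {
    abort(paste0("unknown variable category: ", paste(bad, collapse = ", ")),
          class = "sprintnet_error_bad_input")
  }
  as_tibble(registry)
}

#' Construct a validated athlete table
#'
#' An athlete table is a tibble with one row per subject: a `subject`
#' identifier column followed by one numeric column per registry variable, in
#' registry order, with the registry attached as an attribute. Validation
#' rejects missing columns, non-numeric cells, missing values, and fewer than
#' three subjects (pairwise correlation is undefined below that).
#'
#' @param data A data frame containing one column per registry variable
#'   (extra columns are dropped); an optional `subject` column supplies
#'   subject identifiers.
#' @param registry A variable registry, e.g. [sprint_variables()].
#' @return An `athlete_table` tibble.
#' @export
as_athlete_table <- function(data, registry) {
  registry <- validate_registry(registry)
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.", class = "sprintnet_error_bad_input")
  }
  missing_cols <- setdiff(registry$name, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing variable column(s): ", paste(missing_cols, collapse = ", ")),
      class = "sprintnet_error_missing_column"
    )
  }
  if (nrow(data) < 3) {
    abort("at least 3 subjects are required.",
          class = "sprintnet_error_too_few_subjects")
  }
  subjects <- if ("subject" %in% names(data)) {
    as.character(data[["subject"]])
  } else {
    paste0("S", seq_len(nrow(data)))
  }
  vals <- data[registry$name]
  non_num <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(non_num) > 0) {
    abort(
      paste0("non-numeric value(s) in column(s): ", paste(non_num, collapse = ", ")),
      class = "sprintnet_error_non_numeric"
    )
  }
  has_na <- names(vals)[vapply(vals, anyNA, logical(1))]
  if (length(has_na) > 0) {
    abort(
      paste0("missing value(s) in column(s): ", paste(has_na, collapse = ", ")),
      class = "sprintnet_error_missing_value"
    )
  }
  out <- dplyr::bind_cols(tibble(subject = subjects), as_tibble(vals))
  attr(out, "registry") <- registry
  class(out) <- c("athlete_table", class(out))
  out
}

#' Read an athlete table from CSV
#'
#' Reads a subjects-by-variables CSV (UTF-8, comma separator, dot decimal,
#' header row mandatory) and validates it against a variable registry. Column
#' order in the result follows the registry, not the file. Cells that cannot
#' be parsed as numbers are reported as non-numeric; empty cells as missing
#' values.
#'
#' @inheritParams as_athlete_table
#' @param path Path to the CSV file.
#' @return An `athlete_table` tibble.
#' @export
read_athlete_table <- function(path, registry) {
  registry <- validate_registry(registry)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(registry$name, names(raw))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing variable column(s): ", paste(missing_cols, collapse = ", ")),
      class = "sprintnet_error_missing_column"
    )
  }
  for (nm in registry$name) {
    col <- raw[[nm]]
    parsed <- suppressWarnings(as.numeric(col))
    bad <- !is.na(col) & nzchar(trimws(col)) & is.na(parsed)
    if (any(bad)) {
      abort(paste0("non-numeric value(s) in column(s): ", nm),
            class = "sprintnet_error_non_numeric")
    }
    raw[[nm]] <- parsed
  }
  as_athlete_table(raw, registry)
}

#' @export
print.athlete_table <- function(x, ...) {
  reg <- attr(x, "registry")
  cat(sprintf("<athlete_table: %d subjects x %d variables>\n", nrow(x), nrow(reg)))
  NextMethod()
}

# Numeric subjects-by-variables matrix underlying an athlete table.
#' @rdname as_athlete_table
#' @param x An `athlete_table`.
#' @export
athlete_matrix <- function(x) {
  reg <- attr(x, "registry")
  m <- as.matrix(as.data.frame(x)[reg$name])
  rownames(m) <- x$subject
  m
}

#' Per-variable quartile summary
#'
#' First quartile, median and third quartile of every variable in an athlete
#' table, using linear interpolation between order statistics (the
#' spreadsheet/statistics default, R quantile type 7). This is the summary
#' convention used throughout the package, including the synthetic-marginal
#' calibration checks.
#'
#' @param table An `athlete_table`.
#' @return A tibble with columns `variable`, `unit`, `q1`, `median`, `q3`.
#' @export
summarize_quartiles <- function(table) {
  reg <- attr(table, "registry")
  if (is.null(reg)) {
    abort("`table` must be an athlete_table.", class = "sprintnet_error_bad_input")
  }
  m <- athlete_matrix(table)
  qs <- apply(m, 2, quantile, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble(
    variable = reg$name,
    unit = reg$unit,
    q1 = qs[1, ],
    median = qs[2, ],
    q3 = qs[3, ]
  )
}

#' @rdname summarize_quartiles
#' @param summary A quartile summary tibble.
#' @param path Output TSV path.
#' @export
write_quartile_summary <- function(summary, path) {
  readr::write_tsv(summary, path)
  invisible(path)
}

#' Persist and reload a variable registry
#'
#' The registry is stored as a YAML list of name/label/unit/category records,
#' so a model configuration can travel with exported results.
#'
#' @param registry A variable registry tibble.
#' @param path File path.
#' @return `read_registry()` returns the registry tibble; `write_registry()`
#'   returns `path` invisibly.
#' @export
write_registry <- function(registry, path) {
  registry <- validate_registry(registry)
  yaml::write_yaml(purrr::transpose(as.list(registry)), path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  recs <- yaml::read_yaml(path)
  validate_registry(purrr::map_dfr(recs, as_tibble))
}

#' Cohort eliteness: percent of world record
#'
#' For each sprint record entry, the ratio of the current world-record time to
#' the athlete's personal-record time, expressed as a percentage and rounded
#' half-up to two decimals. A value of 100 means the athlete holds the world
#' record; elite cohorts sit above 90.
#'
#' @param records A data frame with numeric columns `personal_record` and
#'   `world_record` (times in seconds; the world record is the faster, so
#'   `personal_record >= world_record > 0`).
#' @return `percent_world_record()` returns the input tibble with a `pct_wr`
#'   column appended; `mean_percent_wr()` returns the arithmetic mean of the
#'   per-entry percentages, rounded half-up to two decimals.
#' @examples
#' rec <- sprint_records()
#' percent_world_record(rec)$pct_wr[1] # 89.55
#' mean_percent_wr(rec)                # 90.92
#' @export
percent_world_record <- function(records) {
  check_record_times(records)
  dplyr::mutate(
    as_tibble(records),
    pct_wr = round_half_up(100 * .data$world_record / .data$personal_record, 2)
  )
}

#' @rdname percent_world_record
#' @export
mean_percent_wr <- function(records) {
  if (nrow(records) == 0) {
    abort("no record entries supplied.", class = "sprintnet_error_bad_input")
  }
  round_half_up(mean(percent_world_record(records)$pct_wr), 2)
}

check_record_times <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("personal_record", "world_record") %in% names(records))) {
    abort("`records` needs personal_record and world_record columns.",
          class = "sprintnet_error_bad_input")
  }
  pr <- records$personal_record
  wr <- records$world_record
  if (any(!is.finite(pr)) || any(!is.finite(wr)) || any(wr <= 0) || any(pr <= 0)) {
    abort("record times must be positive.", class = "sprintnet_error_bad_input")
  }
  if (any(pr < wr)) {
    abort("personal records cannot be faster than the world record.",
          class = "sprintnet_error_bad_input")
  }
  invisible(records)
}

#' Published sprint cohort records
#'
#' The eight-athlete cohort record list: discipline, personal record and the
#' corresponding world record (seconds) at the time of the study. Used for the
#' cohort-eliteness (%WR) computation.
#'
#' @return A tibble with columns `athlete`, `discipline`, `personal_record`,
#'   `world_record`.
#' @export
sprint_records <- function() {
  tibble::tribble(
    ~athlete, ~discipline,          ~personal_record, ~world_record,
    1L,       "Men's 400 m",         48.05,            43.03,
    2L,       "Men's 400 m",         46.22,            43.03,
    3L,       "Men's 400 m",         46.64,            43.03,
    4L,       "Men's 100 m",         10.50,            9.58,
    5L,       "Men's 100 m",         10.40,            9.58,
    6L,       "Men's 100 m",         10.84,            9.58,
    7L,       "Men's 400 m hurdles", 51.75,            46.78,
    8L,       "Men's 110 m hurdles", 14.17,            12.80
  )
}
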