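# Model inputs: the base-case parameter record and the age-indexed life table.

# Field registry: base-case value and admissible range for every model input.
# Probabilities and utilities live in [0,1]; the salvage disutility is a one-off
# QALY decrement in [-1,0]; costs are 2020 USD and nonnegative.
.PARAM_FIELDS <- list(
  periop_mort_if      = list(default = 0.041,  lower = 0,  upper = 1,   integer = FALSE),
  periop_mort_ha      = list(default = 0.053,  lower = 0,  upper = 1,   integer = FALSE),
  periop_mort_tha     = list(default = 0.039,  lower = 0,  upper = 1,   integer = FALSE),
  fail_if             = list(default = 0.033,  lower = 0,  upper = 1,   integer = FALSE),
  fail_ha             = list(default = 0.015,  lower = 0,  upper = 1,   integer = FALSE),
  conv_split_if_to_ha = list(default = 0.5,    lower = 0,  upper = 1,   integer = FALSE),
  u_if                = list(default = 0.63,   lower = 0,  upper = 1,   integer = FALSE),
  u_ha                = list(default = 0.68,   lower = 0,  upper = 1,   integer = FALSE),
  u_tha               = list(default = 0.70,   lower = 0,  upper = 1,   integer = FALSE),
  disutil_salvage     = list(default = -0.15,  lower = -1, upper = 0,   integer = FALSE),
  c_if                = list(default = 8632,   lower = 0,  upper = Inf, integer = FALSE),
  c_ha                = list(default = 12449,  lower = 0,  upper = Inf, integer = FALSE),
  c_if_to_ha          = list(default = 26670,  lower = 0,  upper = Inf, integer = FALSE),
  c_if_to_tha         = list(default = 25508,  lower = 0,  upper = Inf, integer = FALSE),
  c_ha_to_tha         = list(default = 22662,  lower = 0,  upper = Inf, integer = FALSE),
  wtp                 = list(default = 11083,  lower = 0,  upper = Inf, integer = FALSE),
  discount_rate       = list(default = 0.03,   lower = 0,  upper = Inf, integer = FALSE),
  horizon_cycles      = list(default = 5,      lower = 1,  upper = Inf, integer = TRUE),
  start_age           = list(default = 80,     lower = 0,  upper = Inf, integer = TRUE)
)

#' Names of all model parameters
#'
#' @return Character vector of the field names of a [`cea_params`] record.
#' @export
param_names <- function() names(.PARAM_FIELDS)

#' Base-case model parameters
#'
#' Returns the base-case input set of the decision model: perioperative
#' mortality for internal fixation (IF, 4.1%), hemiarthroplasty (HA, 5.3%) and
#' total hip arthroplasty (THA, 3.9%); annual failure probabilities for IF
#' (3.3%) and HA (1.5%); the 50/50 split of failed IF between salvage HA and
#' salvage THA; health-state utilities (IF 0.63, HA 0.68, THA 0.70) and the
#' one-off salvage disutility (-0.15); procedure and conversion costs in 2020
#' USD; the willingness-to-pay threshold ($11,083/QALY); a 3% annual discount
#' rate; a 5-cycle (annual) horizon starting at age 80.
#'
#' @return A validated `cea_params` object (named list).
#' @export
#' @examples
#' p <- default_params()
#' p$c_ha
default_params <- function() {
  validate_params(lapply(.PARAM_FIELDS, `[[`, "default"))
}

#' Validate a parameter record
#'
#' Checks that every field of a model-parameter record is present, numeric,
#' scalar, finite, and within its admissible range. Errors name the offending
#' field and the violated bound; values are never silently clamped.
#'
#' @param x Named list with one entry per field of [default_params()].
#' @return `x` with class `cea_params`, invisibly usable downstream.
#' @export
validate_params <- function(x) {
  if (!is.list(x)) stop("parameters must be a named list", call. = FALSE)
  missing <- setdiff(param_names(), names(x))
  if (length(missing) > 0) {
    stop("missing required parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in param_names()) {
    spec <- .PARAM_FIELDS[[nm]]
    v <- x[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite numeric value", call. = FALSE)
    }
    if (v < spec$lower || v > spec$upper) {
      stop("parameter '", nm, "' = ", v, " is outside its admissible range [",
           spec$lower, ", ", spec$upper, "]", call. = FALSE)
    }
    if (spec$integer && v != round(v)) {
      stop("parameter '", nm, "' must be an integer (got ", v, ")", call. = FALSE)
    }
    x[[nm]] <- as.numeric(v)
  }
  out <- x[param_names()]
  class(out) <- c("cea_params", "list")
  out
}

#' Load model parameters from a config file, list, or overrides
#'
#' Reads a flat YAML or JSON document whose keys match the fields of
#' [default_params()]. Missing fields are filled with the base-case values;
#' unknown keys raise a warning (not an error); out-of-range values raise a
#' validation error naming the field. A named list may be passed instead of a
#' path, and individual overrides may be given through `...`.
#'
#' @param source Path to a YAML (`.yaml`/`.yml`) or JSON (`.json`) file, a
#'   named list of overrides, or `NULL` for the base case.
#' @param ... Additional `name = value` overrides applied after `source`.
#' @return A validated `cea_params` object.
#' @export
#' @examples
#' load_params()                     # base case
#' load_params(list(discount_rate = 0))
load_params <- function(source = NULL, ...) {
  overrides <- list()
  if (is.character(source)) {
    if (length(source) != 1L || !file.exists(source)) {
      stop("configuration file not found: ", source, call. = FALSE)
    }
    ext <- tolower(tools::file_ext(source))
    overrides <- switch(ext,
      yaml = ,
      yml  = yaml::read_yaml(source),
      json = jsonlite::read_json(source, simplifyVector = TRUE),
      stop("unsupported configuration format '.", ext, "' (use YAML or JSON)",
           call. = FALSE)
    )
    if (is.null(overrides)) overrides <- list()
  } else if (is.list(source)) {
    overrides <- source
  } else if (!is.null(source)) {
    stop("'source' must be a file path, a named list, or NULL", call. = FALSE)
  }
  dots <- list(...)
  if (length(dots) > 0) overrides[names(dots)] <- dots

  if (length(overrides) > 0 && (is.null(names(overrides)) || any(names(overrides) == ""))) {
    stop("all configuration entries must be named", call. = FALSE)
  }
  unknown <- setdiff(names(overrides), param_names())
  if (length(unknown) > 0) {
    warning("ignoring unknown configuration key(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
    overrides <- overrides[setdiff(names(overrides), unknown)]
  }
  x <- lapply(.PARAM_FIELDS, `[[`, "default")
  x[names(overrides)] <- overrides
  validate_params(x)
}

#' Write model parameters to YAML or JSON
#'
#' Serializes a parameter record so that [load_params()] on the written file
#' reproduces it field for field.
#'
#' @param params A `cea_params` object.
#' @param path Output path; format chosen from the extension
#'   (`.yaml`/`.yml`/`.json`).
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  params <- validate_params(unclass(params))
  ext <- tolower(tools::file_ext(path))
  x <- lapply(unclass(params), as.numeric)
  switch(ext,
    yaml = ,
    yml  = yaml::write_yaml(x, path, precision = 15),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported configuration format '.", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' @export
print.cea_params <- function(x, ...) {
  cat("Model parameters (", length(x), " fields)\n", sep = "")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}

# ---- life table -------------------------------------------------------------

#' Construct a life table
#'
#' An age-indexed table of annual probabilities of death from causes other than
#' the modelled surgical events.
#'
#' @param age Integer vector of ages (years), strictly increasing.
#' @param qx Annual death probabilities in `[0, 1]`, one per age.
#' @return A `life_table` (a `data.frame` with columns `age` and `qx`).
#' @export
#' @examples
#' life_table(80:82, c(0.035, 0.039, 0.044))
life_table <- function(age, qx) {
  if (length(age) == 0L) stop("life table must have at least one row", call. = FALSE)
  if (length(age) != length(qx)) stop("'age' and 'qx' must have equal length", call. = FALSE)
  if (any(!is.finite(age)) || any(age != round(age))) {
    stop("life-table ages must be finite integers", call. = FALSE)
  }
  if (any(diff(age) <= 0)) stop("life-table ages must be strictly increasing", call. = FALSE)
  if (any(!is.finite(qx)) || any(qx < 0) || any(qx > 1)) {
    stop("life-table death probabilities 'qx' must lie in [0, 1]", call. = FALSE)
  }
  out <- data.frame(age = as.integer(age), qx = as.numeric(qx))
  class(out) <- c("life_table", "data.frame")
  out
}

#' Read a life table from CSV
#'
#' Expects a two-column CSV with header `age,qx`, one row per integer age.
#'
#' @param path Path to the CSV file.
#' @return A validated [life_table()].
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life-table file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(d))) {
    stop("life-table CSV must have columns 'age' and 'qx'", call. = FALSE)
  }
  life_table(d$age, d$qx)
}

#' Write a life table to CSV
#'
#' @param table A [life_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("age", "qx")], path, row.names = FALSE)
  invisible(path)
}

#' Bundled life-table fixture (ages 80-85, synthetic)
#'
#' A small annual life table covering ages 80-85 shipped with the package.
#' The values are a constructed stand-in, not a transcription of an official
#' table: they follow a Gompertz law anchored at q(80) = 0.035 with slope
#' 0.11/year, placed at the level of unadjusted Chinese old-age mortality
#' around 2020. The original analysis this package re-implements cited a
#' national census life table without printing its values, so any base-case
#' run is conditional on the mortality assumption; all model functions take
#' the life table as an explicit argument so users can substitute their own
#' (see the package vignette).
#'
#' @return A [life_table()] covering ages 80-85.
#' @export
#' @examples
#' example_lifetable()
example_lifetable <- function() {
  path <- system.file("extdata", "china2020_qx_ages80to85_synthetic.csv",
                      package = "hipcea", mustWork = TRUE)
  read_life_table(path)
}

#' Look up the annual death probability at an age
#'
#' Exact table lookup; no extrapolation or interpolation is performed.
#'
#' @param table A [life_table()].
#' @param age Integer age in years.
#' @return The tabulated annual death probability.
#' @export
#' @examples
#' mortality_at_age(example_lifetable(), 80)
mortality_at_age <- function(table, age) {
  stopifnot(length(age) == 1L)
  i <- match(as.integer(age), table$age)
  if (is.na(i)) {
    stop("age ", age, " is outside life-table coverage [",
         min(table$age), ", ", max(table$age), "]", call. = FALSE)
  }
  table$qx[i]
}

# Internal: assert the table covers every age the horizon will visit.
check_lifetable_coverage <- function(table, params) {
  need <- params$start_age + seq_len(params$horizon_cycles) - 1L
  missing <- setdiff(need, table$age)
  if (length(missing) > 0) {
    stop("life table does not cover required age(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
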