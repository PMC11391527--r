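# Deterministic sensitivity analysis: one-way (tornado), two-way grids,
# and threshold searches for cost-effectiveness and dominance of HA vs IF.

# Inputs varied in deterministic sensitivity analysis: every probability,
# utility, disutility and cost. WTP, discount rate, horizon, start age and the
# conversion split are held fixed (includable by passing them explicitly).
.ONE_WAY_PARAMS <- c(
  "periop_mort_if", "periop_mort_ha", "periop_mort_tha",
  "fail_if", "fail_ha",
  "u_if", "u_ha", "u_tha", "disutil_salvage",
  "c_if", "c_ha", "c_if_to_ha", "c_if_to_tha", "c_ha_to_tha"
)

#' Parameters eligible for one-way sensitivity analysis
#'
#' @return Character vector of parameter names varied by [tornado()].
#' @export
eligible_one_way_params <- function() .ONE_WAY_PARAMS

# Internal: set one parameter, clamping scaled values back into the field's
# admissible range with a warning (keeps the symmetric relative range valid).
set_param_clamped <- function(params, name, value) {
  spec <- .PARAM_FIELDS[[name]]
  if (is.null(spec)) {
    stop("unknown parameter '", name, "'; eligible parameters: ",
         paste(eligible_one_way_params(), collapse = ", "), call. = FALSE)
  }
  clamped <- min(max(value, spec$lower), spec$upper)
  if (clamped != value) {
    warning("value ", value, " for '", name, "' clamped to ", clamped,
            " (admissible range [", spec$lower, ", ", spec$upper, "])",
            call. = FALSE)
  }
  x <- unclass(params)
  x[[name]] <- clamped
  validate_params(x)
}

# Internal: ICER of HA vs IF for a parameter record.
icer_ha_vs_if <- function(params, table, wtp = params$wtp, ...) {
  compute_icer(run_cohort("IF", params, table, ...),
               run_cohort("HA", params, table, ...), wtp)
}

#' One-way sensitivity analysis for a single parameter
#'
#' Recomputes the HA-vs-IF ICER with the named parameter set to
#' `base * (1 - rel_range)` and `base * (1 + rel_range)`, all other inputs
#' fixed at their current values. Probabilities and utilities pushed outside
#' their admissible range by the scaling are clamped with a warning.
#'
#' @param param_name One of [eligible_one_way_params()].
#' @param params A [`cea_params`][default_params] object.
#' @param table A [life_table()].
#' @param rel_range Relative variation (default 0.2, i.e. +/-20%).
#' @param wtp Willingness-to-pay threshold used in classification.
#' @param ... Passed to [run_cohort()] (accrual conventions).
#' @return One-row `data.frame`: `parameter`, `base`, `low`, `high`,
#'   `icer_low`, `icer_high`, `bar_width` (`|icer_high - icer_low|`).
#' @export
one_way <- function(param_name, params, table, rel_range = 0.2,
                    wtp = params$wtp, ...) {
  if (!param_name %in% eligible_one_way_params()) {
    stop("unknown or ineligible parameter '", param_name,
         "'; eligible parameters: ",
         paste(eligible_one_way_params(), collapse = ", "), call. = FALSE)
  }
  stopifnot(is.numeric(rel_range), length(rel_range) == 1L, rel_range >= 0)
  base <- params[[param_name]]
  p_lo <- set_param_clamped(params, param_name, base * (1 - rel_range))
  p_hi <- set_param_clamped(params, param_name, base * (1 + rel_range))
  icer_lo <- icer_ha_vs_if(p_lo, table, wtp, ...)$icer
  icer_hi <- icer_ha_vs_if(p_hi, table, wtp, ...)$icer
  data.frame(
    parameter = param_name,
    base = base,
    low = p_lo[[param_name]],
    high = p_hi[[param_name]],
    icer_low = icer_lo,
    icer_high = icer_hi,
    bar_width = abs(icer_hi - icer_lo),
    stringsAsFactors = FALSE
  )
}

#' Tornado analysis over all eligible parameters
#'
#' Runs [one_way()] for every eligible input and sorts the entries by
#' descending bar width (ICER swing).
#'
#' @inheritParams one_way
#' @return A `data.frame` with one row per parameter, ordered by `bar_width`.
#' @export
#' @examples
#' tornado(default_params(), example_lifetable())
tornado <- function(params, table, rel_range = 0.2, wtp = params$wtp, ...) {
  rows <- lapply(eligible_one_way_params(), one_way,
                 params = params, table = table,
                 rel_range = rel_range, wtp = wtp, ...)
  out <- do.call(rbind, rows)
  out <- out[order(-out$bar_width), ]
  rownames(out) <- NULL
  out
}

#' Two-way sensitivity analysis over a parameter grid
#'
#' Classifies HA vs IF at every combination of two parameter values.
#'
#' @param param_x,param_y Parameter names.
#' @param x_values,y_values Strictly increasing numeric grids.
#' @inheritParams one_way
#' @return A `data.frame` with columns `x`, `y`, `classification`, and
#'   `cost_effective` (`TRUE` when the classification is `cost_effective` or
#'   `dominant`).
#' @export
two_way_region <- function(param_x, x_values, param_y, y_values,
                           params, table, wtp = params$wtp, ...) {
  for (nm in c(param_x, param_y)) {
    if (!nm %in% param_names()) stop("unknown parameter '", nm, "'", call. = FALSE)
  }
  if (!is.numeric(x_values) || !is.numeric(y_values)) {
    stop("grid values must be numeric", call. = FALSE)
  }
  if (length(x_values) > 1 && any(diff(x_values) <= 0) ||
      length(y_values) > 1 && any(diff(y_values) <= 0)) {
    stop("grid values must be strictly increasing", call. = FALSE)
  }
  grid <- expand.grid(x = x_values, y = y_values, KEEP.OUT.ATTRS = FALSE)
  cls <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- set_param_clamped(set_param_clamped(params, param_x, grid$x[i]),
                           param_y, grid$y[i])
    cls[i] <- icer_ha_vs_if(p, table, wtp, ...)$classification
  }
  grid$classification <- cls
  grid$cost_effective <- cls %in% c("cost_effective", "dominant")
  grid
}

#' Threshold search for cost-effectiveness or dominance of HA
#'
#' Finds the value of a single parameter at which HA vs IF crosses a decision
#' boundary, holding everything else fixed:
#'
#' * `criterion = "cost_effective"`: root of
#'   `delta_cost - wtp * delta_qaly = 0` (the net-monetary-benefit boundary,
#'   equivalent to `ICER = wtp` when `delta_qaly > 0`);
#' * `criterion = "dominant"`: root of `delta_cost = 0` with
#'   `delta_qaly > 0` required at the root.
#'
#' The search scans the admissible domain (`[0, 1]` for probabilities and
#' utilities, `[0, 4 * base]` for costs by default) on a grid, then bisects the
#' bracketing interval with [stats::uniroot()]. When the boundary function has
#' no sign change over the domain — e.g. utilities cannot change costs, so no
#' utility value can make HA dominant — the result is `NA` with a reason, not
#' an error.
#'
#' @param param_name A numeric model parameter.
#' @param criterion `"cost_effective"` or `"dominant"`.
#' @inheritParams one_way
#' @param domain Optional `c(lower, upper)` search interval.
#' @param tol Relative bisection tolerance (default `1e-6`).
#' @param grid_n Number of scan points used to bracket the root.
#' @return A `data.frame` row: `parameter`, `criterion`, `threshold` (`NA` when
#'   unattainable), `direction` (`"below"`/`"above"`: the side of the threshold
#'   on which the criterion holds), `reason` (`NA` or why no threshold exists).
#' @export
#' @examples
#' threshold_search("c_ha", "cost_effective", default_params(), example_lifetable())
threshold_search <- function(param_name, criterion = c("cost_effective", "dominant"),
                             params, table, wtp = params$wtp,
                             domain = NULL, tol = 1e-6, grid_n = 129L, ...) {
  criterion <- match.arg(criterion)
  if (!param_name %in% param_names()) {
    stop("unknown parameter '", param_name, "'", call. = FALSE)
  }
  spec <- .PARAM_FIELDS[[param_name]]
  if (is.null(domain)) {
    domain <- if (is.finite(spec$upper)) {
      c(spec$lower, spec$upper)
    } else {
      c(0, 4 * max(params[[param_name]], 1))
    }
  }
  stopifnot(length(domain) == 2L, domain[1] < domain[2])

  delta <- function(v) {
    x <- unclass(params); x[[param_name]] <- v
    p <- validate_params(x)
    res <- compute_icer(run_cohort("IF", p, table, ...),
                        run_cohort("HA", p, table, ...), wtp)
    c(dc = res$delta_cost, de = res$delta_qaly)
  }
  f <- function(v) {
    d <- delta(v)
    if (criterion == "cost_effective") d[["dc"]] - wtp * d[["de"]] else d[["dc"]]
  }

  na_result <- function(reason) {
    data.frame(parameter = param_name, criterion = criterion,
               threshold = NA_real_, direction = NA_character_,
               reason = reason, stringsAsFactors = FALSE)
  }

  grid <- seq(domain[1], domain[2], length.out = grid_n)
  fv <- vapply(grid, f, numeric(1))
  sign_change <- which(fv[-1] * fv[-length(fv)] <= 0 &
                         !(fv[-1] == 0 & fv[-length(fv)] == 0))
  if (length(sign_change) == 0) {
    return(na_result("criterion boundary not crossed over the admissible domain"))
  }
  i <- sign_change[1]
  root <- stats::uniroot(f, lower = grid[i], upper = grid[i + 1],
                         tol = tol * max(1, abs(grid[i + 1])))$root

  if (criterion == "dominant" && delta(root)[["de"]] <= 0) {
    return(na_result("QALY gain not positive at the cost-parity boundary"))
  }
  if (criterion == "cost_effective" && delta(root)[["de"]] <= 0) {
    return(na_result("QALY gain not positive at the boundary"))
  }

  met <- function(v) {
    d <- delta(v)
    if (criterion == "dominant") d[["dc"]] < 0 && d[["de"]] > 0
    else wtp * d[["de"]] - d[["dc"]] > 0
  }
  eps <- (domain[2] - domain[1]) / (grid_n - 1) / 4
  below_ok <- root - eps >= domain[1] && met(root - eps)
  direction <- if (below_ok) "below" else "above"

  data.frame(parameter = param_name, criterion = criterion,
             threshold = root, direction = direction,
             reason = NA_character_, stringsAsFactors = FALSE)
}

#' Threshold table for the six headline parameters
#'
#' Runs [threshold_search()] for both criteria over the two procedure costs,
#' the two failure probabilities, and the two primary-procedure utilities.
#'
#' @inheritParams one_way
#' @return A `data.frame` with one row per parameter: `parameter`,
#'   `cost_effective`, `dominant` (threshold values, `NA` where unattainable),
#'   and the corresponding `direction_*` columns.
#' @export
threshold_table <- function(params, table, wtp = params$wtp, ...) {
  pars <- c("c_ha", "c_if", "fail_if", "fail_ha", "u_if", "u_ha")
  rows <- lapply(pars, function(nm) {
    ce <- threshold_search(nm, "cost_effective", params, table, wtp, ...)
    dom <- threshold_search(nm, "dominant", params, table, wtp, ...)
    data.frame(parameter = nm,
               cost_effective = ce$threshold, direction_ce = ce$direction,
               dominant = dom$threshold, direction_dom = dom$direction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
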