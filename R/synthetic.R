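# Synthetic inputs and an independent patient-level oracle.
#
# The microsimulation shares no transition algebra with the cohort engine: it
# samples each patient's events (uniform draws against the same published
# probabilities) and averages realized discounted rewards, so agreement with
# run_cohort() is evidence of correctness rather than a tautology.

#' Gompertz mortality law
#'
#' Annual death probability `q(age) = min(1, a * exp(b * age))`, the classical
#' exponential rise of adult mortality with age; used to generate plausible
#' life tables for ages the bundled fixture does not cover.
#'
#' @param a Baseline hazard scale, positive.
#' @param b Age slope per year, nonnegative.
#' @return A `gompertz_law` object.
#' @export
#' @examples
#' gompertz_law(a = 0.05 * exp(-0.1 * 80), b = 0.1)
gompertz_law <- function(a, b) {
  stopifnot(is.numeric(a), length(a) == 1L, a > 0,
            is.numeric(b), length(b) == 1L, b >= 0)
  structure(list(a = a, b = b), class = c("gompertz_law", "list"))
}

#' Gompertz law anchored at a reference age
#'
#' Convenience constructor choosing `a` so that `q(age0) = q0`.
#'
#' @param q0 Annual death probability at the anchor age, in `(0, 1]`.
#' @param age0 Anchor age in years.
#' @param b Age slope per year.
#' @return A [gompertz_law()].
#' @export
gompertz_anchored <- function(q0, age0, b) {
  stopifnot(q0 > 0, q0 <= 1)
  gompertz_law(a = q0 * exp(-b * age0), b = b)
}

#' Generate a life table from a Gompertz law
#'
#' @param law A [gompertz_law()].
#' @param ages Integer vector of ages (strictly increasing).
#' @return A [life_table()] with `qx = min(1, a * exp(b * age))`.
#' @export
#' @examples
#' generate_lifetable(gompertz_anchored(0.05, 80, 0.1), 80:90)
generate_lifetable <- function(law, ages) {
  stopifnot(inherits(law, "gompertz_law"), length(ages) >= 1)
  qx <- pmin(1, law$a * exp(law$b * ages))
  life_table(ages, qx)
}

# Default uniform sampling bounds for random but valid parameter records.
# Horizon and start age are pinned to the base case so the bundled life-table
# fixture always covers the run.
default_param_bounds <- function() {
  list(
    periop_mort_if      = c(0.005, 0.12),
    periop_mort_ha      = c(0.005, 0.12),
    periop_mort_tha     = c(0.005, 0.12),
    fail_if             = c(0.005, 0.10),
    fail_ha             = c(0.005, 0.10),
    conv_split_if_to_ha = c(0.2, 0.8),
    u_if                = c(0.40, 0.90),
    u_ha                = c(0.40, 0.90),
    u_tha               = c(0.40, 0.90),
    disutil_salvage     = c(-0.30, -0.05),
    c_if                = c(3000, 20000),
    c_ha                = c(5000, 25000),
    c_if_to_ha          = c(8000, 40000),
    c_if_to_tha         = c(8000, 40000),
    c_ha_to_tha         = c(8000, 40000),
    wtp                 = c(5000, 30000),
    discount_rate       = c(0, 0.05),
    horizon_cycles      = c(5, 5),
    start_age           = c(80, 80)
  )
}

#' Draw a random, valid parameter record
#'
#' Samples every model input uniformly within a bounds profile; used for
#' property-style tests of the engine. Degenerate bounds (`lo == hi`)
#' reproduce that value exactly.
#'
#' @param seed Integer seed.
#' @param bounds Named list of `c(lo, hi)` per parameter; defaults keep all
#'   probabilities and utilities inside `(0, 1)` and costs positive, and pin
#'   the horizon and start age to the base case.
#' @return A validated [`cea_params`][default_params] object.
#' @export
#' @examples
#' generate_random_params(seed = 7)
generate_random_params <- function(seed, bounds = default_param_bounds()) {
  missing <- setdiff(param_names(), names(bounds))
  if (length(missing) > 0) {
    stop("bounds profile is missing parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (nm in param_names()) {
    b <- bounds[[nm]]
    spec <- .PARAM_FIELDS[[nm]]
    if (length(b) != 2L || b[1] > b[2] || b[1] < spec$lower || b[2] > spec$upper) {
      stop("infeasible bounds for '", nm, "': [", b[1], ", ", b[2],
           "] not within [", spec$lower, ", ", spec$upper, "]", call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  x <- lapply(stats::setNames(param_names(), param_names()), function(nm) {
    b <- bounds[[nm]]
    v <- stats::runif(1, b[1], b[2])
    if (.PARAM_FIELDS[[nm]]$integer) round(v) else v
  })
  validate_params(x)
}

#' Patient-level microsimulation of one strategy arm
#'
#' Simulates `n` independent patients through the same event sequence as the
#' cohort model — perioperative death at entry; each year, other-cause death,
#' implant failure, conversion with perioperative risk — by sampling each
#' event per patient, and accumulates realized discounted costs and QALYs with
#' the same reward-timing conventions as [run_cohort()]. Serves as an
#' independent oracle: its means converge to the cohort engine's outputs with
#' Monte Carlo standard error proportional to `1/sqrt(n)`.
#'
#' @param arm `"IF"` or `"HA"`.
#' @param params A [`cea_params`][default_params] object.
#' @param table A [life_table()].
#' @param n Number of simulated patients (>= 1).
#' @param seed Integer seed.
#' @param accrual Reward timing, `"end"` (default) or `"begin"`, matching
#'   [run_cohort()].
#' @return A `cea_microsim` object: `n`, `seed`, `mean_cost`, `se_cost`,
#'   `mean_qaly`, `se_qaly` (standard errors are `NA` when `n = 1`).
#' @export
#' @examples
#' microsimulate("HA", default_params(), example_lifetable(), n = 5000, seed = 1)
microsimulate <- function(arm, params, table, n, seed,
                          accrual = c("end", "begin")) {
  arm <- match.arg(arm, c("IF", "HA"))
  accrual <- match.arg(accrual)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  params <- validate_params(unclass(params))
  check_lifetable_coverage(table, params)

  H <- params$horizon_cycles
  r <- params$discount_rate
  # state codes: 1 primary IF, 2 primary HA, 3 salvage HA, 4 salvage THA, 5 dead
  u_state <- c(params$u_if, params$u_ha, params$u_ha, params$u_tha, 0)

  set.seed(as.integer(seed))
  pm0 <- if (arm == "IF") params$periop_mort_if else params$periop_mort_ha
  c0 <- if (arm == "IF") params$c_if else params$c_ha

  state <- rep.int(if (arm == "IF") 1L else 2L, n)
  cost <- rep.int(c0, n)
  qaly <- numeric(n)

  state[stats::runif(n) < pm0] <- 5L

  for (t in seq_len(H)) {
    q <- mortality_at_age(table, params$start_age + t - 1L)
    disc <- (1 + r)^(-(t - (accrual == "begin")))

    if (accrual == "begin") qaly <- qaly + u_state[state] * disc

    # other-cause death
    dies <- state != 5L & stats::runif(n) < q
    state[dies] <- 5L

    # implant failure and conversion
    u_fail <- stats::runif(n)
    u_route <- stats::runif(n)
    u_periop <- stats::runif(n)

    fail_if <- state == 1L & u_fail < params$fail_if
    fail_ha <- (state == 2L | state == 3L) & u_fail < params$fail_ha

    to_ha <- fail_if & u_route < params$conv_split_if_to_ha
    to_tha_from_if <- fail_if & !to_ha

    cost[to_ha] <- cost[to_ha] + params$c_if_to_ha * disc
    cost[to_tha_from_if] <- cost[to_tha_from_if] + params$c_if_to_tha * disc
    cost[fail_ha] <- cost[fail_ha] + params$c_ha_to_tha * disc

    die_conv <- (to_ha & u_periop < params$periop_mort_ha) |
      ((to_tha_from_if | fail_ha) & u_periop < params$periop_mort_tha)

    state[to_ha] <- 3L
    state[to_tha_from_if | fail_ha] <- 4L
    state[die_conv] <- 5L

    converted_alive <- (to_ha | to_tha_from_if | fail_ha) & state != 5L
    if (accrual == "end") qaly <- qaly + u_state[state] * disc
    qaly[converted_alive] <- qaly[converted_alive] + params$disutil_salvage * disc
  }

  out <- list(
    arm = arm, n = n, seed = as.integer(seed), accrual = accrual,
    mean_cost = mean(cost),
    se_cost = if (n > 1) stats::sd(cost) / sqrt(n) else NA_real_,
    mean_qaly = mean(qaly),
    se_qaly = if (n > 1) stats::sd(qaly) / sqrt(n) else NA_real_
  )
  class(out) <- c("cea_microsim", "list")
  out
}

#' @export
print.cea_microsim <- function(x, ...) {
  cat(sprintf("Microsimulation, arm %s, n = %d (seed %d)\n", x$arm, x$n, x$seed))
  cat(sprintf("  cost: $%.2f (SE %.2f)\n  QALY: %.4f (SE %.5f)\n",
              x$mean_cost, x$se_cost, x$mean_qaly, x$se_qaly))
  invisible(x)
}
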