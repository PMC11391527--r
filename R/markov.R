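# Markov cohort engine: state space, per-cycle transitions, discounted rewards.
#
# Five states rather than the four of the published diagram: salvage HA after a
# failed IF is kept separate from salvage THA, so that a salvage HA can itself
# fail (at the same annual probability as a primary HA) into a THA. Salvage THA
# is assumed never to fail within the horizon. DEAD is absorbing.

.STATES <- c("PRIMARY_IF", "PRIMARY_HA", "CONVERTED_HA", "CONVERTED_THA", "DEAD")

#' Model state names
#'
#' @return Character vector of the five ordered health states:
#'   `PRIMARY_IF`, `PRIMARY_HA`, `CONVERTED_HA` (salvage hemiarthroplasty after
#'   failed internal fixation), `CONVERTED_THA` (salvage total hip
#'   arthroplasty), `DEAD`.
#' @export
cea_states <- function() .STATES

# Internal: per-state annual utilities. Both HA states share u_ha.
state_utilities <- function(params) {
  c(PRIMARY_IF = params$u_if, PRIMARY_HA = params$u_ha,
    CONVERTED_HA = params$u_ha, CONVERTED_THA = params$u_tha, DEAD = 0)
}

#' Advance the cohort one annual cycle
#'
#' Applies, in order: (1) other-cause death at the life-table probability for
#' age `start_age + cycle_index - 1`; (2) among survivors still holding a
#' primary internal fixation, failure with probability `fail_if`, split
#' `conv_split_if_to_ha` to salvage HA (with perioperative mortality
#' `periop_mort_ha`) and the remainder to salvage THA (`periop_mort_tha`);
#' (3) among survivors in either HA state, failure with probability `fail_ha`
#' to salvage THA (`periop_mort_tha`). Salvage THA never fails. Conversions
#' occurring in the same cycle are not exposed to a second failure.
#'
#' @param occupancy Probability vector over [cea_states()], summing to 1.
#' @param arm `"IF"` or `"HA"`; used to assert the opposite primary state is
#'   unoccupied.
#' @param cycle_index Cycle number, 1-based.
#' @param params A [`cea_params`][default_params] object.
#' @param table A [life_table()].
#' @return A list with `occupancy` (next state vector, sums to 1) and `events`,
#'   a record of the cycle's conversion flows: attempted conversions by route
#'   (`conv_if_to_ha`, `conv_if_to_tha`, `conv_ha_to_tha`), perioperative
#'   conversion deaths (`conv_deaths`), surviving converters
#'   (`conv_survivors`), and other-cause deaths (`other_deaths`).
#' @export
cycle_transition <- function(occupancy, arm, cycle_index, params, table) {
  occ <- as.numeric(occupancy)
  if (length(occ) != length(.STATES)) {
    stop("occupancy must have one entry per state (", length(.STATES), ")", call. = FALSE)
  }
  if (any(occ < -1e-12)) stop("occupancy has negative entries", call. = FALSE)
  if (abs(sum(occ) - 1) > 1e-8) {
    stop("occupancy must sum to 1 (got ", format(sum(occ), digits = 12), ")", call. = FALSE)
  }
  arm <- match.arg(arm, c("IF", "HA"))
  other_primary <- if (arm == "IF") "PRIMARY_HA" else "PRIMARY_IF"
  if (occ[match(other_primary, .STATES)] > 1e-12) {
    stop("state ", other_primary, " must be unoccupied in the ", arm, " arm", call. = FALSE)
  }
  if (cycle_index < 1 || cycle_index > params$horizon_cycles) {
    stop("cycle_index must lie in [1, ", params$horizon_cycles, "]", call. = FALSE)
  }
  names(occ) <- .STATES

  q <- mortality_at_age(table, params$start_age + cycle_index - 1L)

  # (1) other-cause death
  alive <- occ[1:4]
  other_deaths <- sum(alive) * q
  surv <- alive * (1 - q)

  nxt <- c(surv, DEAD = occ[["DEAD"]] + other_deaths)

  # (2) failure of primary IF, split between salvage HA and salvage THA
  fail_if_mass <- surv[["PRIMARY_IF"]] * params$fail_if
  conv_if_to_ha <- fail_if_mass * params$conv_split_if_to_ha
  conv_if_to_tha <- fail_if_mass - conv_if_to_ha

  # (3) failure of any in-place hemiarthroplasty (primary or salvage)
  conv_ha_to_tha <- (surv[["PRIMARY_HA"]] + surv[["CONVERTED_HA"]]) * params$fail_ha

  d_ha <- conv_if_to_ha * params$periop_mort_ha
  d_tha <- (conv_if_to_tha + conv_ha_to_tha) * params$periop_mort_tha

  nxt[["PRIMARY_IF"]] <- nxt[["PRIMARY_IF"]] - fail_if_mass
  nxt[["PRIMARY_HA"]] <- nxt[["PRIMARY_HA"]] * (1 - params$fail_ha)
  nxt[["CONVERTED_HA"]] <- nxt[["CONVERTED_HA"]] * (1 - params$fail_ha) +
    (conv_if_to_ha - d_ha)
  nxt[["CONVERTED_THA"]] <- nxt[["CONVERTED_THA"]] + (conv_if_to_tha + conv_ha_to_tha) -
    d_tha
  nxt[["DEAD"]] <- nxt[["DEAD"]] + d_ha + d_tha

  list(
    occupancy = nxt,
    events = list(
      conv_if_to_ha = conv_if_to_ha,
      conv_if_to_tha = conv_if_to_tha,
      conv_ha_to_tha = conv_ha_to_tha,
      conv_deaths = d_ha + d_tha,
      conv_survivors = conv_if_to_ha + conv_if_to_tha + conv_ha_to_tha - d_ha - d_tha,
      other_deaths = other_deaths
    )
  )
}

#' Run the cohort model for one strategy arm
#'
#' Cycle 0 applies the initial procedure: its full cost (undiscounted) accrues
#' to the whole cohort, perioperative mortality removes `periop_mort_if` (IF
#' arm) or `periop_mort_ha` (HA arm), and no utility accrues. Each subsequent
#' cycle `t = 1..horizon` advances the cohort with [cycle_transition()] and
#' accrues rewards:
#'
#' * `accrual = "end"` (default): occupants alive at the end of cycle `t`
#'   accrue their end-of-cycle state's utility; that cycle's surviving
#'   converters additionally accrue `disutil_salvage`; conversion costs accrue
#'   to all who undergo conversion (including perioperative deaths); everything
#'   is discounted by `(1 + discount_rate)^-t`. Occupants dying during the
#'   cycle (other-cause or perioperative) accrue no utility that cycle.
#' * `accrual = "begin"`: occupants alive at the start of cycle `t` accrue
#'   their start-of-cycle state's utility, discounted by
#'   `(1 + discount_rate)^-(t-1)`; the salvage disutility and conversion costs
#'   keep the same incidence rules at the same exponent.
#' * `half_cycle_correction = TRUE`: the utility reward uses the mean of the
#'   start- and end-of-cycle state-utility totals, discounted at exponent
#'   `t - 1/2`; costs keep the timing of the chosen `accrual`.
#'
#' @param arm `"IF"` or `"HA"`.
#' @param params A [`cea_params`][default_params] object.
#' @param table A [life_table()] covering ages `start_age` to
#'   `start_age + horizon_cycles - 1`.
#' @param accrual Reward timing convention, `"end"` or `"begin"`.
#' @param half_cycle_correction Logical; see above.
#' @param well_state_basis Denominator for `well_state_share`: fraction of
#'   `"survivors"` at horizon end still holding the arm's primary implant
#'   (default), or of the `"initial"` cohort.
#' @return A `cea_arm` object: `strategy`, `discounted_cost` (USD),
#'   `discounted_qaly`, `trace` (matrix, rows = cycles 0..horizon, columns =
#'   states), `cost_by_cycle` / `qaly_by_cycle` (discounted increments),
#'   `well_state_share`, `alive_at_end`, and the conventions used.
#' @export
#' @examples
#' run_cohort("HA", default_params(), example_lifetable())
run_cohort <- function(arm, params, table,
                       accrual = c("end", "begin"),
                       half_cycle_correction = FALSE,
                       well_state_basis = c("survivors", "initial")) {
  arm <- match.arg(arm, c("IF", "HA"))
  accrual <- match.arg(accrual)
  well_state_basis <- match.arg(well_state_basis)
  params <- validate_params(unclass(params))
  check_lifetable_coverage(table, params)

  H <- params$horizon_cycles
  r <- params$discount_rate
  u <- state_utilities(params)

  primary <- if (arm == "IF") "PRIMARY_IF" else "PRIMARY_HA"
  pm0 <- if (arm == "IF") params$periop_mort_if else params$periop_mort_ha
  c0 <- if (arm == "IF") params$c_if else params$c_ha

  trace <- matrix(0, nrow = H + 1L, ncol = length(.STATES),
                  dimnames = list(cycle = 0:H, state = .STATES))
  occ <- stats::setNames(numeric(length(.STATES)), .STATES)
  occ[primary] <- 1 - pm0
  occ["DEAD"] <- pm0
  trace[1L, ] <- occ

  cost_by_cycle <- numeric(H + 1L)
  qaly_by_cycle <- numeric(H + 1L)
  cost_by_cycle[1L] <- c0 # whole cohort undergoes the initial procedure

  for (t in seq_len(H)) {
    step <- cycle_transition(occ, arm, t, params, table)
    occ_end <- step$occupancy
    ev <- step$events

    exp_t <- if (accrual == "end") t else t - 1L
    disc <- (1 + r)^(-exp_t)

    if (half_cycle_correction) {
      u_reward <- 0.5 * (sum(occ * u) + sum(occ_end * u)) * (1 + r)^(-(t - 0.5))
      disutil <- params$disutil_salvage * ev$conv_survivors * (1 + r)^(-(t - 0.5))
    } else if (accrual == "end") {
      u_reward <- sum(occ_end * u) * disc
      disutil <- params$disutil_salvage * ev$conv_survivors * disc
    } else {
      u_reward <- sum(occ * u) * disc
      disutil <- params$disutil_salvage * ev$conv_survivors * disc
    }
    qaly_by_cycle[t + 1L] <- u_reward + disutil

    cost_by_cycle[t + 1L] <- disc * (
      ev$conv_if_to_ha * params$c_if_to_ha +
      ev$conv_if_to_tha * params$c_if_to_tha +
      ev$conv_ha_to_tha * params$c_ha_to_tha
    )

    occ <- occ_end
    trace[t + 1L, ] <- occ
  }

  alive_at_end <- 1 - occ[["DEAD"]]
  well <- occ[[primary]]
  well_share <- if (well_state_basis == "survivors") {
    if (alive_at_end > 0) well / alive_at_end else NA_real_
  } else {
    well
  }

  out <- list(
    strategy = arm,
    discounted_cost = sum(cost_by_cycle),
    discounted_qaly = sum(qaly_by_cycle),
    trace = trace,
    cost_by_cycle = cost_by_cycle,
    qaly_by_cycle = qaly_by_cycle,
    well_state_share = well_share,
    alive_at_end = alive_at_end,
    accrual = accrual,
    half_cycle_correction = half_cycle_correction,
    start_age = params$start_age
  )
  class(out) <- c("cea_arm", "list")
  out
}

#' @export
print.cea_arm <- function(x, ...) {
  cat(sprintf("Strategy %s: discounted cost $%.2f, %.4f QALYs (accrual: %s%s)\n",
              x$strategy, x$discounted_cost, x$discounted_qaly, x$accrual,
              if (x$half_cycle_correction) ", half-cycle corrected" else ""))
  cat(sprintf("  alive at horizon end: %.1f%%; in primary state (of survivors): %.1f%%\n",
              100 * x$alive_at_end, 100 * x$well_state_share))
  invisible(x)
}

#' Incremental cost-effectiveness ratio and dominance classification
#'
#' Computes `delta = comparator - reference` for discounted cost and QALYs,
#' the ICER `delta_cost / delta_qaly` (undefined when `delta_qaly` is zero),
#' and a classification: `dominant` (cheaper and more effective),
#' `dominated` (costlier and less effective), `cost_effective` when the net
#' monetary benefit `wtp * delta_qaly - delta_cost` is positive,
#' `not_cost_effective` otherwise, and `indeterminate` when `delta_qaly = 0`.
#'
#' @param reference,comparator `cea_arm` objects (or any list carrying
#'   `discounted_cost` and `discounted_qaly`).
#' @param wtp Willingness-to-pay threshold, USD per QALY.
#' @return A `cea_icer` object with `delta_cost`, `delta_qaly`, `icer`
#'   (`NA` when undefined), `classification`, and `wtp`.
#' @export
#' @examples
#' lt <- example_lifetable(); p <- default_params()
#' compute_icer(run_cohort("IF", p, lt), run_cohort("HA", p, lt), p$wtp)
compute_icer <- function(reference, comparator, wtp) {
  stopifnot(is.numeric(wtp), length(wtp) == 1L, wtp >= 0)
  dc <- comparator$discounted_cost - reference$discounted_cost
  de <- comparator$discounted_qaly - reference$discounted_qaly
  icer <- if (de != 0) dc / de else NA_real_
  classification <- if (de == 0) {
    "indeterminate"
  } else if (dc < 0 && de > 0) {
    "dominant"
  } else if (dc > 0 && de < 0) {
    "dominated"
  } else if (wtp * de - dc > 0) {
    "cost_effective"
  } else {
    "not_cost_effective"
  }
  out <- list(delta_cost = dc, delta_qaly = de, icer = icer,
              classification = classification, wtp = wtp)
  class(out) <- c("cea_icer", "list")
  out
}

#' @export
print.cea_icer <- function(x, ...) {
  cat(sprintf("Incremental cost $%.2f, incremental QALYs %.4f\n",
              x$delta_cost, x$delta_qaly))
  if (is.na(x$icer)) {
    cat("ICER: undefined (no QALY difference)\n")
  } else {
    cat(sprintf("ICER: $%.2f/QALY (WTP $%.0f/QALY)\n", x$icer, x$wtp))
  }
  cat("Classification:", x$classification, "\n")
  invisible(x)
}
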