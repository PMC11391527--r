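# Cohort engine: transition composition, conservation, rewards, ICER logic.

test_that("dead cohort is absorbing and transitions conserve mass", {
  p <- default_params()
  lt <- fixture_lifetable()
  all_dead <- c(0, 0, 0, 0, 1)
  out <- cycle_transition(all_dead, "IF", 1, p, lt)
  expect_equal(unname(out$occupancy), all_dead)
  expect_equal(out$events$conv_survivors, 0)

  set.seed(401)
  for (i in 1:25) {
    arm <- sample(c("IF", "HA"), 1)
    occ <- random_occupancy(arm)
    prm <- generate_random_params(seed = i)
    nxt <- cycle_transition(occ, arm, sample(5, 1), prm, lt)$occupancy
    expect_equal(sum(nxt), 1, tolerance = 1e-12)
    expect_true(all(nxt >= 0))
    expect_gte(nxt[["DEAD"]], occ[5])
  }
})

test_that("conversion inflow matches the event-probability product", {
  # all mass in PRIMARY_IF, no other-cause mortality: mass entering salvage HA
  # is fail_if * split * (1 - periop_mort_ha)
  p <- default_params()
  lt <- flat_lifetable(0)
  out <- cycle_transition(c(1, 0, 0, 0, 0), "IF", 1, p, lt)
  expect_equal(out$occupancy[["CONVERTED_HA"]], 0.033 * 0.5 * (1 - 0.053),
               tolerance = 1e-15)
  expect_equal(out$occupancy[["CONVERTED_THA"]], 0.033 * 0.5 * (1 - 0.039),
               tolerance = 1e-15)
  expect_equal(out$events$conv_if_to_ha, 0.0165)
})

test_that("invalid occupancies and misplaced primary mass are rejected", {
  p <- default_params()
  lt <- fixture_lifetable()
  expect_error(cycle_transition(c(0.5, 0, 0, 0, 0.4), "IF", 1, p, lt), "sum to 1")
  expect_error(cycle_transition(c(0, 0.5, 0, 0, 0.5), "IF", 1, p, lt), "PRIMARY_HA")
  expect_error(cycle_transition(c(0.5, 0, 0, 0, 0.5), "IF", 6, p, lt), "cycle_index")
})

test_that("degenerate cohorts match the closed-form annuity", {
  lt <- flat_lifetable(0)
  p0 <- zero_event_params(discount_rate = 0)
  a <- run_cohort("IF", p0, lt)
  expect_equal(a$discounted_qaly, 5 * 0.63, tolerance = 1e-12)
  expect_equal(a$discounted_cost, 8632, tolerance = 1e-12)

  p3 <- zero_event_params(discount_rate = 0.03)
  b <- run_cohort("IF", p3, lt)
  expect_equal(b$discounted_qaly, 0.63 * annuity(0.03, 5), tolerance = 1e-12)
  h <- run_cohort("HA", p3, lt)
  expect_equal(h$discounted_qaly, 0.68 * annuity(0.03, 5), tolerance = 1e-12)
  expect_equal(h$discounted_cost, 12449, tolerance = 1e-12)
  # begin accrual shifts the annuity one year earlier
  b2 <- run_cohort("IF", p3, lt, accrual = "begin")
  expect_equal(b2$discounted_qaly, 0.63 * annuity(0.03, 5) * 1.03, tolerance = 1e-12)
})

test_that("trace rows sum to one and death occupancy is monotone", {
  lt <- fixture_lifetable()
  for (i in 1:10) {
    prm <- generate_random_params(seed = 100 + i)
    for (arm in c("IF", "HA")) {
      tr <- run_cohort(arm, prm, lt)$trace
      expect_equal(unname(rowSums(tr)), rep(1, nrow(tr)), tolerance = 1e-12)
      expect_true(all(diff(tr[, "DEAD"]) >= -1e-15))
      expect_true(all(tr >= 0))
    }
  }
})

test_that("discounted QALYs strictly decrease with the discount rate", {
  lt <- fixture_lifetable()
  p <- default_params()
  rates <- c(0, 0.01, 0.03, 0.06, 0.10)
  for (arm in c("IF", "HA")) {
    q <- vapply(rates, function(r) {
      run_cohort(arm, base_params(discount_rate = r), lt)$discounted_qaly
    }, numeric(1))
    expect_true(all(diff(q) < 0))
  }
})

test_that("costs only accrue: arm cost is at least the initial procedure cost", {
  lt <- fixture_lifetable()
  for (i in 1:10) {
    prm <- generate_random_params(seed = 300 + i)
    expect_gte(run_cohort("IF", prm, lt)$discounted_cost, prm$c_if)
    expect_gte(run_cohort("HA", prm, lt)$discounted_cost, prm$c_ha)
    q <- run_cohort("HA", prm, lt)$discounted_qaly
    expect_lte(q, prm$horizon_cycles * max(prm$u_if, prm$u_ha, prm$u_tha))
    expect_gte(q, 0)
  }
})

test_that("ICER arithmetic, dominance, and the identity case", {
  # arithmetic on the published rounded arm totals
  ref <- list(discounted_cost = 12167, discounted_qaly = 2.75)
  cmp <- list(discounted_cost = 13324, discounted_qaly = 2.94)
  res <- compute_icer(ref, cmp, 11083)
  expect_equal(res$icer, 1157 / 0.19, tolerance = 1e-12)
  expect_equal(res$classification, "cost_effective")

  dom <- compute_icer(list(discounted_cost = 100, discounted_qaly = 1),
                      list(discounted_cost = 90, discounted_qaly = 1.1), 11083)
  expect_equal(dom$classification, "dominant")
  expect_lt(dom$icer, 0)

  same <- compute_icer(ref, ref, 11083)
  expect_true(is.na(same$icer))
  expect_equal(same$classification, "indeterminate")

  worse <- compute_icer(ref, list(discounted_cost = 13324, discounted_qaly = 2.70),
                        11083)
  expect_equal(worse$classification, "dominated")
  # cheaper but less effective: judged by net monetary benefit, not dominance
  sw <- compute_icer(cmp, ref, 11083)
  expect_equal(sw$classification, "not_cost_effective")
  expect_gt(sw$icer, 0)
})

test_that("ICER scales linearly with a global cost multiplier", {
  lt <- fixture_lifetable()
  p <- default_params()
  icer_at_scale <- function(k) {
    scaled <- base_params(c_if = p$c_if * k, c_ha = p$c_ha * k,
                          c_if_to_ha = p$c_if_to_ha * k,
                          c_if_to_tha = p$c_if_to_tha * k,
                          c_ha_to_tha = p$c_ha_to_tha * k)
    compute_icer(run_cohort("IF", scaled, lt), run_cohort("HA", scaled, lt), p$wtp)$icer
  }
  base <- icer_at_scale(1)
  for (k in c(0.5, 2, 3.7)) {
    expect_equal(icer_at_scale(k), k * base, tolerance = 1e-10)
  }
})

test_that("well-state share supports both denominators", {
  lt <- fixture_lifetable()
  p <- default_params()
  surv <- run_cohort("HA", p, lt, well_state_basis = "survivors")
  init <- run_cohort("HA", p, lt, well_state_basis = "initial")
  expect_equal(init$well_state_share, surv$well_state_share * surv$alive_at_end,
               tolerance = 1e-12)
  expect_lt(init$well_state_share, surv$well_state_share)
})
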