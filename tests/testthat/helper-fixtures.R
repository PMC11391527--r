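# Shared fixtures: built in code at test time.

base_params <- function(...) load_params(list(...))

fixture_lifetable <- function() example_lifetable()

# Flat life table with constant annual mortality q over the given ages.
flat_lifetable <- function(q, ages = 80:85) life_table(ages, rep(q, length(ages)))

# Degenerate parameter set: no deaths, no failures; discount configurable.
zero_event_params <- function(discount_rate = 0) {
  base_params(
    periop_mort_if = 0, periop_mort_ha = 0, periop_mort_tha = 0,
    fail_if = 0, fail_ha = 0,
    discount_rate = discount_rate
  )
}

# Present value of an n-year annuity-immediate at rate r (end-of-year payments).
annuity <- function(r, n) if (r == 0) n else (1 - (1 + r)^(-n)) / r

# An occupancy vector for the given arm (opposite primary state empty).
random_occupancy <- function(arm) {
  w <- stats::runif(4)
  if (arm == "IF") {
    v <- c(w[1], 0, w[2], w[3], w[4])
  } else {
    v <- c(0, w[1], w[2], w[3], w[4])
  }
  v / sum(v)
}
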