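# Probabilistic sensitivity analysis: method-of-moments Beta/Gamma
# distributions, seeded Monte Carlo over the cohort model, cost-effectiveness
# plane summaries and acceptability curves.

#' Beta distribution from a mean and standard deviation
#'
#' Method of moments: `nu = mean * (1 - mean) / sd^2 - 1`,
#' `alpha = mean * nu`, `beta = (1 - mean) * nu`. The construction round-trips:
#' the analytic mean and SD of `Beta(alpha, beta)` equal the inputs.
#'
#' @param mean Target mean, strictly inside `(0, 1)`.
#' @param sd Target standard deviation; must satisfy `sd^2 < mean * (1 - mean)`.
#' @return A `beta_spec` list: `alpha`, `beta`, `mean`, `sd`.
#' @export
#' @examples
#' beta_from_moments(0.033, 0.0033) # alpha 96.67, beta 2832.64
beta_from_moments <- function(mean, sd) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.numeric(sd), length(sd) == 1L)
  if (!(mean > 0 && mean < 1)) {
    stop("Beta mean must lie strictly inside (0, 1), got ", mean, call. = FALSE)
  }
  if (sd <= 0) stop("Beta sd must be positive, got ", sd, call. = FALSE)
  if (sd^2 >= mean * (1 - mean)) {
    stop("sd too large for a Beta distribution: need sd^2 < mean*(1-mean) = ",
         mean * (1 - mean), call. = FALSE)
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  out <- list(alpha = mean * nu, beta = (1 - mean) * nu, mean = mean, sd = sd)
  class(out) <- c("beta_spec", "list")
  out
}

#' Gamma distribution from a mean and standard deviation
#'
#' Method of moments on the shape/rate parameterization:
#' `shape = (mean / sd)^2`, `rate = shape / mean`. The coefficient of variation
#' is `1 / sqrt(shape)`, so a 10%-of-mean SD always gives shape 100.
#'
#' @param mean Target mean, positive.
#' @param sd Target standard deviation, positive.
#' @return A `gamma_spec` list: `shape`, `rate`, `mean`, `sd`.
#' @export
#' @examples
#' gamma_from_moments(12449, 1244.9) # shape 100, rate 0.008033
gamma_from_moments <- function(mean, sd) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.numeric(sd), length(sd) == 1L)
  if (mean <= 0) stop("Gamma mean must be positive, got ", mean, call. = FALSE)
  if (sd <= 0) stop("Gamma sd must be positive, got ", sd, call. = FALSE)
  shape <- (mean / sd)^2
  out <- list(shape = shape, rate = shape / mean, mean = mean, sd = sd)
  class(out) <- c("gamma_spec", "list")
  out
}

# Ten uncertain inputs sampled in the PSA, in the fixed draw order. Failure
# probabilities and utilities are Beta; costs are Gamma. Perioperative
# mortalities, the 50/50 conversion split, the discount rate, horizon and the
# life table are held at their base-case values.
.PSA_PARAMS <- c("fail_if", "fail_ha", "u_if", "u_ha", "u_tha",
                 "c_if", "c_ha", "c_if_to_ha", "c_if_to_tha", "c_ha_to_tha")
.PSA_BETA <- c("fail_if", "fail_ha", "u_if", "u_ha", "u_tha")

#' Moment-matched sampling distributions for the PSA
#'
#' Builds the Beta (probabilities, utilities) and Gamma (costs) sampling
#' distributions for the ten uncertain inputs, with the standard deviation set
#' to `cv` times the mean (the published analysis used 10% of the mean where
#' no SD was available).
#'
#' @param params A [`cea_params`][default_params] object supplying the means.
#' @param cv Coefficient of variation applied to every input (default 0.10).
#' @return Named list of `beta_spec` / `gamma_spec` objects, in draw order.
#' @export
#' @examples
#' psa_distributions(default_params())$fail_if
psa_distributions <- function(params, cv = 0.10) {
  stopifnot(is.numeric(cv), length(cv) == 1L, cv > 0)
  out <- lapply(stats::setNames(.PSA_PARAMS, .PSA_PARAMS), function(nm) {
    m <- params[[nm]]
    if (nm %in% .PSA_BETA) beta_from_moments(m, cv * m) else gamma_from_moments(m, cv * m)
  })
  out
}

# Internal: n draws from a beta_spec / gamma_spec.
draw_spec <- function(spec, n) {
  if (inherits(spec, "beta_spec")) {
    stats::rbeta(n, spec$alpha, spec$beta)
  } else {
    stats::rgamma(n, shape = spec$shape, rate = spec$rate)
  }
}

#' Assemble a PSA result from per-iteration vectors
#'
#' Container used by [sample_psa()] and handy for constructing small results
#' directly in examples and tests.
#'
#' @param cost_if,qaly_if,cost_ha,qaly_ha Equal-length numeric vectors of
#'   per-iteration discounted costs and QALYs for each arm.
#' @param seed Seed recorded for reproducibility (may be `NA`).
#' @return A `cea_psa` object with the four arm vectors, `delta_cost`
#'   (`cost_ha - cost_if`), `delta_qaly`, `n_iter` and `seed`.
#' @export
psa_result <- function(cost_if, qaly_if, cost_ha, qaly_ha, seed = NA_integer_) {
  n <- length(cost_if)
  stopifnot(n >= 1L, length(qaly_if) == n, length(cost_ha) == n, length(qaly_ha) == n)
  out <- list(
    n_iter = n,
    cost_if = as.numeric(cost_if), qaly_if = as.numeric(qaly_if),
    cost_ha = as.numeric(cost_ha), qaly_ha = as.numeric(qaly_ha),
    delta_cost = as.numeric(cost_ha) - as.numeric(cost_if),
    delta_qaly = as.numeric(qaly_ha) - as.numeric(qaly_if),
    seed = seed
  )
  class(out) <- c("cea_psa", "list")
  out
}

#' Monte Carlo probabilistic sensitivity analysis
#'
#' For each iteration, independently draws the ten uncertain inputs from their
#' moment-matched distributions (see [psa_distributions()]), holds every other
#' input at its base-case value, runs the cohort model for both arms with the
#' same draw, and records discounted costs and QALYs. All randomness flows
#' from one seeded generator; the draw order (one vector per parameter, in the
#' order of `psa_distributions()`) is fixed, so results are fully reproducible
#' given the seed.
#'
#' @param params A [`cea_params`][default_params] object.
#' @param table A [life_table()].
#' @param n_iter Number of Monte Carlo iterations (>= 1).
#' @param seed Integer seed.
#' @param cv Coefficient of variation for all sampled inputs (default 0.10).
#' @param ... Passed to [run_cohort()] (accrual conventions).
#' @return A [psa_result()] object.
#' @export
#' @examples
#' sample_psa(default_params(), example_lifetable(), n_iter = 50, seed = 1)
sample_psa <- function(params, table, n_iter, seed, cv = 0.10, ...) {
  stopifnot(is.numeric(n_iter), length(n_iter) == 1L, n_iter >= 1)
  n_iter <- as.integer(n_iter)
  params <- validate_params(unclass(params))
  specs <- psa_distributions(params, cv = cv)

  set.seed(as.integer(seed))
  draws <- vapply(specs, draw_spec, numeric(n_iter), n = n_iter)
  draws <- matrix(draws, nrow = n_iter,
                  dimnames = list(NULL, names(specs)))

  cost_if <- qaly_if <- cost_ha <- qaly_ha <- numeric(n_iter)
  base <- unclass(params)
  for (i in seq_len(n_iter)) {
    x <- base
    x[colnames(draws)] <- draws[i, ]
    p <- tryCatch(validate_params(x), error = function(e) {
      stop("invalid parameter draw at iteration ", i, ": ", conditionMessage(e),
           call. = FALSE)
    })
    arm_if <- tryCatch(run_cohort("IF", p, table, ...), error = function(e) {
      stop("model failure at iteration ", i, ": ", conditionMessage(e), call. = FALSE)
    })
    arm_ha <- run_cohort("HA", p, table, ...)
    cost_if[i] <- arm_if$discounted_cost
    qaly_if[i] <- arm_if$discounted_qaly
    cost_ha[i] <- arm_ha$discounted_cost
    qaly_ha[i] <- arm_ha$discounted_qaly
  }
  psa_result(cost_if, qaly_if, cost_ha, qaly_ha, seed = as.integer(seed))
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("PSA with %d iterations (seed %s)\n", x$n_iter, format(x$seed)))
  cat(sprintf("  HA: $%.0f +/- %.0f, %.3f +/- %.3f QALYs\n",
              mean(x$cost_ha), stats::sd(x$cost_ha),
              mean(x$qaly_ha), stats::sd(x$qaly_ha)))
  cat(sprintf("  IF: $%.0f +/- %.0f, %.3f +/- %.3f QALYs\n",
              mean(x$cost_if), stats::sd(x$cost_if),
              mean(x$qaly_if), stats::sd(x$qaly_if)))
  invisible(x)
}

#' Cost-effectiveness plane summaries of a PSA
#'
#' Computes, over the iterations of a PSA: the share with positive incremental
#' cost (`delta_cost > 0`), positive incremental effect (`delta_qaly > 0`),
#' and acceptable at the willingness-to-pay threshold (positive net monetary
#' benefit, `wtp * delta_qaly - delta_cost > 0`); the ICER of the means
#' (`mean(delta_cost) / mean(delta_qaly)`); and the 95% covariance ellipse of
#' the `(delta_qaly, delta_cost)` cloud at the chi-squared (2 df) contour.
#'
#' @param psa A [psa_result()] object.
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @return A list: `share_more_costly`, `share_more_effective`,
#'   `share_acceptable_at_wtp`, `icer_of_means`, and `ellipse_95` (a list with
#'   `center` = (effect, cost), `radii` (semi-axes), `angle` (radians, major
#'   axis from the effect axis), and the 2x2 `cov` matrix).
#' @export
ce_summaries <- function(psa, wtp) {
  stopifnot(inherits(psa, "cea_psa"))
  if (psa$n_iter < 1) stop("PSA has no iterations", call. = FALSE)
  stopifnot(is.numeric(wtp), length(wtp) == 1L)
  de <- psa$delta_qaly
  dc <- psa$delta_cost
  mde <- mean(de)
  mdc <- mean(dc)

  ellipse <- NULL
  if (psa$n_iter >= 3) {
    S <- stats::cov(cbind(effect = de, cost = dc))
    eig <- eigen(S, symmetric = TRUE)
    k <- stats::qchisq(0.95, df = 2)
    ellipse <- list(
      center = c(effect = mde, cost = mdc),
      radii = sqrt(pmax(eig$values, 0) * k),
      angle = atan2(eig$vectors[2, 1], eig$vectors[1, 1]),
      cov = S
    )
  }

  list(
    share_more_costly = mean(dc > 0),
    share_more_effective = mean(de > 0),
    share_acceptable_at_wtp = mean(wtp * de - dc > 0),
    icer_of_means = if (mde != 0) mdc / mde else NA_real_,
    ellipse_95 = ellipse
  )
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA iterations with positive net monetary benefit at each
#' willingness-to-pay value. At `wtp = 0` this equals the share of iterations
#' in which HA is cheaper; as `wtp` grows it approaches the share in which HA
#' is more effective.
#'
#' @param psa A [psa_result()] object.
#' @param wtp_grid Increasing vector of willingness-to-pay values.
#' @return A `data.frame` with columns `wtp` and `fraction`.
#' @export
#' @examples
#' psa <- sample_psa(default_params(), example_lifetable(), 100, seed = 1)
#' acceptability_curve(psa, c(0, 11083, 22166))
acceptability_curve <- function(psa, wtp_grid) {
  stopifnot(inherits(psa, "cea_psa"))
  if (length(wtp_grid) == 0) stop("wtp_grid must be nonempty", call. = FALSE)
  frac <- vapply(wtp_grid, function(w) mean(w * psa$delta_qaly - psa$delta_cost > 0),
                 numeric(1))
  data.frame(wtp = as.numeric(wtp_grid), fraction = frac)
}
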