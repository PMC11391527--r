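# Moment matching, Monte Carlo PSA, plane summaries, acceptability curves.

test_that("Beta moment matching reproduces the published parameterizations", {
  b <- beta_from_moments(0.033, 0.0033)
  expect_equal(b$alpha, 96.67, tolerance = 0.005 / 96.67)
  expect_equal(b$beta, 2832.64, tolerance = 0.005 / 2832.64)
  u <- beta_from_moments(0.63, 0.063)
  expect_equal(u$alpha, 36.37, tolerance = 0.005 / 36.37)
  expect_equal(u$beta, 21.36, tolerance = 0.005 / 21.36)
  # symmetry at mean one-half
  s <- beta_from_moments(0.5, 0.1)
  expect_equal(s$alpha, s$beta)
})

test_that("Gamma moment matching gives shape 100 for a 10% CV", {
  g <- gamma_from_moments(8632, 863.2)
  expect_equal(g$shape, 100, tolerance = 1e-12)
  expect_equal(g$rate, 100 / 8632, tolerance = 1e-12)
  g2 <- gamma_from_moments(12449, 1244.9)
  expect_equal(g2$shape, 100, tolerance = 1e-12)
  expect_equal(g2$rate, 0.008033, tolerance = 1e-4)
  # CV = 1 is the exponential
  expect_equal(gamma_from_moments(5, 5)$shape, 1)
})

test_that("infeasible moments are rejected as domain errors", {
  expect_error(beta_from_moments(0.5, 0.6), "sd too large")
  expect_error(beta_from_moments(0, 0.1), "inside \\(0, 1\\)")
  expect_error(beta_from_moments(0.5, 0), "positive")
  expect_error(gamma_from_moments(-1, 1), "positive")
  expect_error(gamma_from_moments(10, 0), "positive")
})

test_that("moment construction round-trips analytically to 1e-10", {
  set.seed(77)
  for (i in 1:1000) {
    m <- stats::runif(1, 0.01, 0.99)
    s <- stats::runif(1, 1e-4, 0.9) * sqrt(m * (1 - m))
    b <- beta_from_moments(m, s)
    ab <- b$alpha + b$beta
    expect_equal(b$alpha / ab, m, tolerance = 1e-10)
    expect_equal(sqrt(b$alpha * b$beta / (ab^2 * (ab + 1))), s, tolerance = 1e-10)

    mg <- stats::runif(1, 1, 1e5)
    sg <- stats::runif(1, 0.01, 2) * mg
    g <- gamma_from_moments(mg, sg)
    expect_equal(g$shape / g$rate, mg, tolerance = 1e-10)
    expect_equal(sqrt(g$shape) / g$rate, sg, tolerance = 1e-10)
  }
})

test_that("draws from the fitted distributions follow the intended law", {
  # Kolmogorov-Smirnov against the analytic CDF each sampler was built from:
  # any alpha/beta or shape/rate mix-up collapses the p-value to zero.
  specs <- psa_distributions(default_params())
  expect_named(specs, c("fail_if", "fail_ha", "u_if", "u_ha", "u_tha",
                        "c_if", "c_ha", "c_if_to_ha", "c_if_to_tha", "c_ha_to_tha"))
  set.seed(501)
  n <- 1e5
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    x <- hipcea:::draw_spec(sp, n) # the sampler the PSA actually uses
    pv <- suppressWarnings(if (inherits(sp, "beta_spec")) {
      stats::ks.test(x, stats::pbeta, sp$alpha, sp$beta)$p.value
    } else {
      stats::ks.test(x, stats::pgamma, sp$shape, sp$rate)$p.value
    })
    expect_gt(pv, 1e-3, label = paste("KS p-value for", nm))
    if (inherits(sp, "beta_spec")) expect_true(all(x > 0 & x < 1))
    else expect_true(all(x > 0))
  }
})

test_that("the PSA is reproducible given its seed", {
  p <- default_params()
  lt <- fixture_lifetable()
  a <- sample_psa(p, lt, n_iter = 40, seed = 9)
  b <- sample_psa(p, lt, n_iter = 40, seed = 9)
  expect_identical(a, b)
  c <- sample_psa(p, lt, n_iter = 40, seed = 10)
  expect_false(identical(a$cost_ha, c$cost_ha))
  expect_equal(a$delta_cost, a$cost_ha - a$cost_if)
  expect_equal(length(a$delta_qaly), a$n_iter)
})

test_that("vanishing dispersion collapses the PSA onto the base case", {
  p <- default_params()
  lt <- fixture_lifetable()
  psa <- sample_psa(p, lt, n_iter = 20, seed = 3, cv = 1e-6)
  base_if <- run_cohort("IF", p, lt)
  base_ha <- run_cohort("HA", p, lt)
  expect_equal(mean(psa$cost_if), base_if$discounted_cost, tolerance = 1e-4)
  expect_equal(mean(psa$qaly_if), base_if$discounted_qaly, tolerance = 1e-4)
  expect_equal(mean(psa$cost_ha), base_ha$discounted_cost, tolerance = 1e-4)
  expect_equal(mean(psa$qaly_ha), base_ha$discounted_qaly, tolerance = 1e-4)
})

test_that("plane shares follow from the iteration cloud", {
  # two-point toy cloud: (dE, dC) = (1, 1) and (-1, -1)
  toy <- psa_result(cost_if = c(0, 0), qaly_if = c(0, 0),
                    cost_ha = c(1, -1), qaly_ha = c(1, -1))
  s <- ce_summaries(toy, wtp = 11083)
  expect_equal(s$share_more_effective, 0.5)
  expect_equal(s$share_more_costly, 0.5)
  expect_equal(s$icer_of_means, NA_real_)

  # wtp = 0: acceptability reduces to the share with cost savings
  p <- default_params()
  lt <- fixture_lifetable()
  psa <- sample_psa(p, lt, n_iter = 100, seed = 21)
  s0 <- ce_summaries(psa, wtp = 0)
  expect_equal(s0$share_acceptable_at_wtp, mean(psa$delta_cost < 0))
})

test_that("acceptability equals positive net monetary benefit, iteration-wise", {
  p <- default_params()
  lt <- fixture_lifetable()
  psa <- sample_psa(p, lt, n_iter = 60, seed = 31)
  for (w in c(0, 5000, 11083, 22166)) {
    by_rule <- psa$delta_cost < w * psa$delta_qaly
    by_nmb <- logical(psa$n_iter)
    for (i in seq_len(psa$n_iter)) {
      by_nmb[i] <- w * psa$delta_qaly[i] - psa$delta_cost[i] > 0
    }
    expect_identical(by_rule, by_nmb)
    expect_equal(acceptability_curve(psa, w)$fraction, mean(by_nmb))
  }
})

test_that("acceptability-curve endpoints hit their finite-sample identities", {
  p <- default_params()
  lt <- fixture_lifetable()
  psa <- sample_psa(p, lt, n_iter = 200, seed = 13)
  curve <- acceptability_curve(psa, c(0, 11083, 1e9))
  expect_equal(curve$fraction[1], mean(psa$delta_cost < 0))
  expect_equal(curve$fraction[3], mean(psa$delta_qaly > 0))
  expect_true(all(curve$fraction >= 0 & curve$fraction <= 1))

  single <- psa_result(100, 1, 200, 1.5)
  step <- acceptability_curve(single, c(0, 1e9))
  expect_true(all(step$fraction %in% c(0, 1)))
})

test_that("the 95% ellipse reflects the cloud's covariance", {
  p <- default_params()
  lt <- fixture_lifetable()
  psa <- sample_psa(p, lt, n_iter = 400, seed = 17)
  ell <- ce_summaries(psa, p$wtp)$ellipse_95
  expect_equal(unname(ell$center),
               c(mean(psa$delta_qaly), mean(psa$delta_cost)))
  expect_equal(ell$cov, stats::cov(cbind(effect = psa$delta_qaly,
                                         cost = psa$delta_cost)))
  expect_true(all(ell$radii > 0))
  # ~95% of points fall inside the chi-squared contour of the fitted ellipse
  S_inv <- solve(ell$cov)
  d <- cbind(psa$delta_qaly - mean(psa$delta_qaly),
             psa$delta_cost - mean(psa$delta_cost))
  m2 <- rowSums((d %*% S_inv) * d)
  expect_equal(mean(m2 <= stats::qchisq(0.95, 2)), 0.95, tolerance = 0.05)
})
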