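test_that("follow-up inversion reproduces the published annual probabilities", {
  # 44 subjects, 20 years, proportion 0.550 -> pa 0.039
  e <- pa_from_followup(44, 20.0, 24, pfu_override = 0.550)
  expect_equal(round(e$pa, 3), 0.039)
  # 2024 subjects, 7 years, 494 cases -> pa 0.039, sd 0.004
  e2 <- pa_from_followup(2024, 7.0, 494)
  expect_equal(round(e2$pa, 3), 0.039)
  expect_equal(round(e2$sd, 3), 0.004)
  # one year of follow-up: pa equals the proportion exactly
  e3 <- pa_from_followup(100, 1, 10)
  expect_equal(e3$pa, 0.1, tolerance = 1e-12)
  # inverting pa reproduces Pfu to numerical precision
  expect_equal(1 - (1 - e2$pa)^e2$n_years, e2$pfu, tolerance = 1e-12)
  expect_error(pa_from_followup(10, 5, 10), "undefined")
  e0 <- pa_from_followup(10, 5, 0)
  expect_identical(e0$pa, 0)
  expect_true(e0$degenerate)
})

test_that("every reproducible study row matches its printed pa within 0.001", {
  est <- transition_estimates(natural_history_records())
  est <- est[est$reproducible & !is.na(est$pa_printed), ]
  expect_gt(nrow(est), 15)
  expect_true(all(abs(round(est$pa, 3) - est$pa_printed) <= 0.001 + 1e-12))
  expect_true(all(abs(round(est$sd, 3) - est$sd_printed) <= 0.002 + 1e-12))
})

test_that("inverse-variance pooling behaves and matches the printed summaries", {
  expect_equal(pool_estimates(0.3, 0.1), 0.3)
  expect_equal(pool_estimates(c(0.2, 0.4), c(0.05, 0.05)), 0.3)
  # invariant to rescaling all sds by a constant; bounded by the inputs
  pa <- c(0.1, 0.25, 0.4); sd <- c(0.02, 0.07, 0.01)
  expect_equal(pool_estimates(pa, sd), pool_estimates(pa, 3 * sd))
  expect_gt(pool_estimates(pa, sd), min(pa))
  expect_lt(pool_estimates(pa, sd), max(pa))
  expect_error(pool_estimates(numeric(0), numeric(0)), "no estimates")

  pool <- pooled_transitions()
  pooled <- setNames(pool$pooled_pa, pool$transition)
  # progression from subclinical hypothyroidism: ~0.022, printed as 0.02
  expect_equal(pooled[["t42"]], 0.0218, tolerance = 0.002)
  expect_equal(round(pooled[["t42"]], 2), 0.02)
  expect_equal(round(pooled[["t47"]], 2), 0.08)
  expect_equal(round(pooled[["t53"]], 2), 0.03)
  expect_equal(round(pooled[["t57"]], 2), 0.06)
  expect_equal(round(pooled[["t26"]], 2), 0.21)
})

test_that("pooling agrees with an independent fixed-effect meta-analysis", {
  skip_if_not_installed("metafor")
  est <- transition_estimates(natural_history_records())
  g <- est[est$transition == "t42", ]
  fit <- metafor::rma(yi = g$pa, sei = g$sd, method = "FE")
  expect_equal(pool_estimates(g$pa, g$sd), as.numeric(fit$beta),
               tolerance = 1e-10)
})

test_that("3x published-incidence onset priors reproduce the printed table", {
  onset <- flynn_onset_priors()
  tab <- onset_prior_table()
  for (i in seq_len(nrow(tab))) {
    got <- 100 * onset[[tab$parameter[i]]][tab$sex[i], tab$age_group[i]]
    expect_equal(got, tab$prior_pct[i], tolerance = 1e-9)
  }
  # spot values: female 50-59 hypothyroidism, male 40-49 hyperthyroidism
  expect_equal(100 * onset$t14["female", "50-59"], 2.334)
  expect_equal(100 * onset$t15["male", "40-49"], 0.063)
  expect_error(flynn_onset_priors(flynn_incidence()[-1, ]), "missing")
})

test_that("maximum-variance prior construction pins the smallest parameter", {
  b <- make_prior(0.5, "beta")
  expect_equal(unname(b$concentration), c(1.05, 1.05))
  b2 <- make_prior(0.02, "beta")
  expect_equal(unname(b2$concentration), c(1.05, 51.45))
  expect_equal(b2$concentration[["alpha"]] / sum(b2$concentration), 0.02,
               tolerance = 1e-12)
  # above 0.5 the beta side is pinned instead
  b3 <- make_prior(0.8, "beta")
  expect_equal(b3$concentration[["beta"]], 1.05)
  expect_equal(b3$concentration[["alpha"]] / sum(b3$concentration), 0.8,
               tolerance = 1e-12)

  d <- make_prior(c(a = 0.2, b = 0.3, c = 0.5), "dirichlet")
  expect_equal(unname(d$concentration), c(1.05, 1.575, 2.625))
  expect_equal(min(d$concentration), 1.05)
  expect_equal(unname(d$concentration / sum(d$concentration)),
               c(0.2, 0.3, 0.5), tolerance = 1e-9)
  expect_error(make_prior(0, "beta"), "\\(0, 1\\)")
  expect_error(make_prior(c(0.3, 0.3), "dirichlet"), "sum to 1")
})

test_that("the assembled prior set has the pooled means on both scales", {
  pri <- fixture_priors()
  expect_equal(min(vapply(pri, function(s) min(s$concentration), numeric(1))),
               1.05)
  mp <- fixture_prior_means()
  ann <- attr(pri, "annual_means")
  expect_equal(quarterly_to_annual(mp$t42), ann[["t42"]], tolerance = 1e-9)
  expect_equal(quarterly_to_annual(mp$t46), 0.02, tolerance = 1e-9)
  expect_equal(quarterly_to_annual(mp$t56), 0.02, tolerance = 1e-9)
  expect_equal(quarterly_to_annual(mp$t14["female", "50-59"]), 0.02334,
               tolerance = 1e-9)
})

test_that("prior draws are valid and have finite joint density", {
  set.seed(11)
  pri <- fixture_priors()
  for (i in 1:5) {
    p <- sample_prior_params(pri)
    expect_s3_class(p, "thyro_params")
    expect_true(is.finite(log_prior_density(p, pri)))
  }
})
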