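test_that("count generation is seeded and matches the analytic law", {
  truth <- fixture_prior_means()
  d <- synthetic_design(truth, n_total = 12000)
  expect_identical(generate_counts(d, seed = 5)$diagnosed,
                   generate_counts(d, seed = 5)$diagnosed)

  # huge denominators: empirical proportions within 0.2% of analytic
  big <- synthetic_design(truth, n_total = 12e6)
  tg <- generate_counts(big, seed = 6)
  pp <- predicted_prevalence(truth)
  for (i in seq_len(nrow(tg$diagnosed))) {
    r <- tg$diagnosed[i, ]
    p6 <- pp$proportion[pp$sex == r$sex & pp$age_group == r$age_group &
                          pp$category == "treated"]
    expect_lt(abs(r$cases / r$denominator - p6), 0.002)
  }
  u <- tg$undiagnosed
  for (cc in c("normal", "subclin_hypo")) {
    for (i in seq_len(nrow(u))) {
      pc <- pp$proportion[pp$sex == u$sex[i] & pp$age_group == u$age_group[i] &
                            pp$category == cc]
      expect_lt(abs(u[[cc]][i] / u$denominator[i] - pc), 0.002)
    }
  }
})

test_that("a null parameter set yields only normal, untreated records", {
  zero <- thyro_params(time_scale = "quarterly")
  d <- synthetic_design(zero, n_total = 1200, nonfunctional_rate = 0)
  tg <- generate_counts(d, seed = 7)
  expect_true(all(tg$diagnosed$cases == 0))
  expect_equal(sum(tg$undiagnosed$normal), sum(tg$undiagnosed$denominator))
  rec <- generate_records(d, seed = 8)
  expect_true(all(rec$latent_state %in% c(1L)))
  expect_true(all(!rec$diagnosed_flag))
})

test_that("noise-free hormone boxes recover the latent state exactly", {
  truth <- fixture_prior_means()
  d <- synthetic_design(truth, n_total = 6000)
  rec <- generate_records(d, seed = 9)
  m <- !is.na(rec$tsh)
  cat_of_state <- c("normal", "overt_hypo", "overt_hyper", "subclin_hypo",
                    "subclin_hyper", "treated", "normal")
  got <- classify_thyroid_state(rec$tsh[m], rec$ft4[m])
  expect_identical(got, cat_of_state[rec$latent_state[m]])
})

test_that("nonfunctional diagnoses add ~5% to the raw diagnosed counts", {
  truth <- fixture_prior_means()
  d <- synthetic_design(truth, n_total = 60000, nonfunctional_rate = 0.05)
  rec <- generate_records(d, seed = 10)
  raw <- sum(rec$diagnosed_flag)
  functional <- sum(rec$diagnosed_flag & rec$latent_state == 6L)
  frac_nonfunctional <- (raw - functional) / raw
  expect_lt(abs(frac_nonfunctional - 0.05), 0.015)
  # the 0.95 adjustment approximately recovers the functional count
  tt <- build_target_tables(rec, functional_fraction = 0.95)
  expect_lt(abs(sum(tt$diagnosed$cases_functional) - functional) /
              functional, 0.05)
})

test_that("record and count routes agree in distribution", {
  truth <- fixture_prior_means()
  d <- synthetic_design(truth, n_total = 6000, nonfunctional_rate = 0,
                        functional_fraction = 1)
  pp <- predicted_prevalence(truth)
  pvals_diag <- pvals_und <- numeric(0)
  for (seed in 1:20) {
    tt <- build_target_tables(generate_records(d, seed = seed),
                              functional_fraction = 1)
    # pooled diagnosed counts vs the analytic binomial expectation
    exp_cases <- obs_cases <- tot <- 0
    for (i in seq_len(nrow(tt$diagnosed))) {
      r <- tt$diagnosed[i, ]
      p6 <- pp$proportion[pp$sex == r$sex & pp$age_group == r$age_group &
                            pp$category == "treated"]
      exp_cases <- exp_cases + r$denominator * p6
      obs_cases <- obs_cases + r$cases
      tot <- tot + r$denominator
    }
    pvals_diag <- c(pvals_diag,
                    stats::binom.test(obs_cases, tot,
                                      exp_cases / tot)$p.value)
    # pooled undiagnosed categories vs the analytic conditional law
    cats <- c("normal", "subclin_hypo", "overt_hypo", "subclin_hyper",
              "overt_hyper")
    obs <- colSums(tt$undiagnosed[cats])
    probs <- rep(0, 5)
    for (i in seq_len(nrow(tt$undiagnosed))) {
      r <- tt$undiagnosed[i, ]
      pr <- pp$proportion[pp$sex == r$sex & pp$age_group == r$age_group]
      names(pr) <- pp$category[pp$sex == r$sex & pp$age_group == r$age_group]
      probs <- probs + r$denominator * pr[cats]
    }
    probs <- probs / sum(probs)
    keep <- obs + probs * sum(obs) > 5  # chi-square validity
    pvals_und <- c(pvals_und,
                   suppressWarnings(stats::chisq.test(
                     obs[keep], p = probs[keep] / sum(probs[keep]))$p.value))
  }
  # goodness of fit not rejected at alpha = 0.01 (allow one chance failure)
  expect_lte(sum(pvals_diag < 0.01), 1)
  expect_lte(sum(pvals_und < 0.01), 1)
})

test_that("latent-state prevalence in records matches the analytic engine", {
  truth <- fixture_prior_means()
  d <- synthetic_design(truth, n_total = 24000)
  rec <- generate_records(d, seed = 11)
  pp <- predicted_prevalence(truth)
  for (s in c("male", "female")) {
    sub <- rec[rec$sex == s & rec$age >= 50 & rec$age < 60, ]
    p6 <- pp$proportion[pp$sex == s & pp$age_group == "50-59" &
                          pp$category == "treated"]
    phat <- mean(sub$latent_state == 6L)
    se <- sqrt(p6 * (1 - p6) / nrow(sub))
    expect_lt(abs(phat - p6), 3 * se + 1 / nrow(sub))
  }
})
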