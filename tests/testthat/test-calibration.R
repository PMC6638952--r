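toy_targets <- function(cases = c(30, 80), denom = c(500, 600),
                        counts = rbind(c(150, 20, 2, 5, 1),
                                       c(160, 30, 3, 6, 2))) {
  cats <- c("normal", "subclin_hypo", "overt_hypo", "subclin_hyper",
            "overt_hyper")
  grid <- expand.grid(sex = c("male", "female"),
                      age_group = paste(seq(20, 70, 10), seq(29, 79, 10),
                                        sep = "-"),
                      stringsAsFactors = FALSE)
  diagnosed <- data.frame(grid, cases = 0L, cases_functional = 0L,
                          denominator = 0L)
  und <- cbind(grid, as.data.frame(matrix(0L, nrow(grid), 5,
                                          dimnames = list(NULL, cats))),
               denominator = 0L)
  pick <- c(which(grid$sex == "male" & grid$age_group == "40-49"),
            which(grid$sex == "female" & grid$age_group == "60-69"))
  diagnosed$cases[pick] <- diagnosed$cases_functional[pick] <- cases
  diagnosed$denominator[pick] <- denom
  und[pick, cats] <- counts
  und$denominator[pick] <- rowSums(counts)
  thyro_targets(diagnosed, und, functional_fraction = 1)
}

test_that("log-likelihood equals the hand-computed binomial+multinomial sum", {
  p <- fixture_prior_means()
  tg <- toy_targets()
  # independent oracle: assemble the same quantity cell by cell from
  # predicted_prevalence() and stats densities
  expected <- 0
  cells <- list(list("male", "40-49", 1), list("female", "60-69", 2))
  for (cl in cells) {
    pp <- predicted_prevalence(p, sexes_use = cl[[1]], decades = cl[[2]])
    prop <- setNames(pp$proportion, pp$category)
    i <- cl[[3]]
    expected <- expected +
      dbinom(tg$diagnosed$cases_functional[tg$diagnosed$sex == cl[[1]] &
               tg$diagnosed$age_group == cl[[2]]],
             tg$diagnosed$denominator[tg$diagnosed$sex == cl[[1]] &
               tg$diagnosed$age_group == cl[[2]]],
             prop[["treated"]], log = TRUE) +
      dmultinom(c(150, 20, 2, 5, 1, 160, 30, 3, 6, 2)[(i - 1) * 5 + 1:5],
                prob = prop[c("normal", "subclin_hypo", "overt_hypo",
                              "subclin_hyper", "overt_hyper")], log = TRUE)
  }
  expect_equal(log_likelihood(p, tg), expected, tolerance = 1e-10)
})

test_that("likelihood is additive over cells and zero for empty tables", {
  p <- fixture_prior_means()
  empty <- toy_targets(cases = c(0, 0), denom = c(0, 0),
                       counts = matrix(0L, 2, 5))
  empty$diagnosed$denominator[] <- 0L
  empty$undiagnosed$denominator[] <- 0L
  empty$undiagnosed[c("normal", "subclin_hypo", "overt_hypo",
                      "subclin_hyper", "overt_hyper")] <- 0L
  expect_identical(log_likelihood(p, empty), 0)

  # permuting rows leaves the sum unchanged
  tg <- toy_targets()
  tg2 <- tg
  tg2$diagnosed <- tg$diagnosed[rev(seq_len(nrow(tg$diagnosed))), ]
  tg2$undiagnosed <- tg$undiagnosed[sample(nrow(tg$undiagnosed)), ]
  expect_equal(log_likelihood(p, tg2), log_likelihood(p, tg))
})

test_that("impossible observations give -Inf, not an error", {
  zero <- thyro_params(time_scale = "quarterly")
  tg <- toy_targets()  # nonzero treated counts but predicted p6 = 0
  expect_identical(log_likelihood(zero, tg), -Inf)
})

test_that("observed counts at the predicted mode maximise the likelihood", {
  p <- fixture_prior_means()
  pp <- predicted_prevalence(p, sexes_use = "male", decades = "40-49")
  prop <- setNames(pp$proportion, pp$category)
  n <- 500
  mode_cases <- floor((n + 1) * prop[["treated"]])
  base <- toy_targets(cases = c(mode_cases, 0), denom = c(n, 0),
                      counts = matrix(0L, 2, 5))
  ll0 <- log_likelihood(p, base)
  for (shift in c(-2L, 2L)) {
    alt <- toy_targets(cases = c(mode_cases + shift, 0), denom = c(n, 0),
                       counts = matrix(0L, 2, 5))
    expect_lt(log_likelihood(p, alt), ll0)
  }
})

test_that("parameter vector round trip preserves every entry", {
  p <- random_params()
  v <- params_to_vector(p)
  expect_length(v, 36)
  q <- vector_to_params(v)
  expect_equal(params_to_vector(q), v)
  expect_equal(q$t14, p$t14)
  expect_equal(q$t36, p$t36)
})

test_that("with a flat likelihood the sampler reproduces the prior", {
  pri <- fixture_priors()
  empty <- toy_targets(cases = c(0, 0), denom = c(0, 0),
                       counts = matrix(0L, 2, 5))
  empty$diagnosed$denominator[] <- 0L
  empty$undiagnosed$denominator[] <- 0L
  fit <- sample_posterior(pri, empty, n_chains = 3, n_iter = 700,
                          n_warmup = 300, seed = 5)
  expect_identical(unique(fit$log_likelihood), 0)
  prior_mean <- params_to_vector(prior_mean_params(pri))
  post <- fit$diagnostics
  # each posterior mean within 4 batch-based Monte-Carlo SEs of the
  # analytic prior mean
  mcse <- post$sd / sqrt(pmax(post$ess, 10))
  off <- abs(post$mean - prior_mean) / pmax(mcse, 1e-12)
  expect_gte(mean(off < 4), 0.9)
  expect_true(all(off < 8))
})

test_that("the sampler is deterministic given the seed", {
  pri <- fixture_priors()
  tg <- toy_targets()
  f1 <- sample_posterior(pri, tg, n_chains = 1, n_iter = 120, n_warmup = 60,
                         seed = 7)
  f2 <- sample_posterior(pri, tg, n_chains = 1, n_iter = 120, n_warmup = 60,
                         seed = 7)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$log_likelihood, f2$log_likelihood)
})

test_that("MAP bookkeeping and posterior summaries are consistent", {
  pri <- fixture_priors()
  tg <- toy_targets()
  fit <- sample_posterior(pri, tg, n_chains = 2, n_iter = 260, n_warmup = 120,
                          seed = 9)
  expect_equal(max(fit$log_likelihood),
               log_likelihood(fit$map_params, tg), tolerance = 1e-9)
  smry <- summarize_posterior(fit)
  expect_equal(nrow(smry), 36)
  # annual MAP round-trips to the stored quarterly MAP
  expect_equal(annual_to_quarterly(smry$map_annual),
               unname(params_to_vector(fit$map_params)), tolerance = 1e-12)
})

test_that("doubling the target denominators concentrates the posterior", {
  pri <- fixture_priors()
  truth <- prior_mean_params(pri)
  design1 <- synthetic_design(truth, n_total = 2000)
  design2 <- synthetic_design(truth, n_total = 32000)
  tg1 <- generate_counts(design1, seed = 21)
  tg2 <- generate_counts(design2, seed = 21)
  f1 <- sample_posterior(pri, tg1, n_chains = 2, n_iter = 600, n_warmup = 300,
                         seed = 31)
  f2 <- sample_posterior(pri, tg2, n_chains = 2, n_iter = 600, n_warmup = 300,
                         seed = 31)
  # the data-informed scalar parameters must tighten on average (geometric
  # mean across the eight, robust to per-parameter sampling noise)
  informed <- scalar_names <- c("t42", "t46", "t47", "t53", "t56", "t57",
                                "t26", "t36")
  sd1 <- f1$diagnostics$sd[match(informed, f1$diagnostics$parameter)]
  sd2 <- f2$diagnostics$sd[match(informed, f2$diagnostics$parameter)]
  expect_lt(exp(mean(log(sd2 / sd1))), 0.85)
})
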