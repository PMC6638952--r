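# Shared fixtures, built once per test run.

fixture_priors <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_priors()
    cache
  }
})

fixture_prior_means <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- prior_mean_params(fixture_priors())
    cache
  }
})

# A small, fully hand-specified quarterly parameter set.
toy_params <- function(t14 = 0.002, t15 = 0.001, t42 = 0.01, t46 = 0.01,
                       t47 = 0.02, t53 = 0.01, t56 = 0.01, t57 = 0.02,
                       t26 = 0.08, t36 = 0.1) {
  thyro_params(t14 = t14, t15 = t15, t42 = t42, t46 = t46, t47 = t47,
               t53 = t53, t56 = t56, t57 = t57, t26 = t26, t36 = t36,
               time_scale = "quarterly")
}

# Random valid quarterly parameter set (draw from the priors).
random_params <- function() sample_prior_params(fixture_priors())
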