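# Meta-analytic priors: natural-history study counts -> annual transition
# probabilities -> inverse-variance pools -> beta/Dirichlet prior specs.

#' Bundled natural-history study summaries
#'
#' One row per study result used to inform a transition probability:
#' subjects at baseline, years of follow-up, cases developing the outcome,
#' the transition it informs, and bookkeeping flags. `pfu_override` carries
#' the published follow-up proportion where it differs from `n_cases /
#' n_subjects` (studies reporting proportions among subjects actually
#' followed); `exclude_pool` marks rows kept out of the pooled summary
#' (the outlier reversion estimate contaminated by iatrogenic cases);
#' `reproducible = FALSE` marks rows whose published annual probability
#' cannot be recovered from the printed counts under the follow-up
#' inversion (both from the same secondary source, follow-up 11.1 y).
#'
#' @param path optional path to an alternative CSV with the same columns.
#' @return A data.frame of study records.
#' @export
natural_history_records <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "natural_history.csv", package = "thyrolife",
                        mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(df$n_cases >= 0), all(df$n_cases <= df$n_subjects),
            all(df$years_followup > 0))
  df
}

#' Bundled published incidence rates of treated thyroid disease
#'
#' Sex- and decade-specific incidence rates (per 1000 person-years, with
#' 95% CI) of treated hypo- and hyperthyroidism from the Tayside
#' population study of Flynn et al. (2004), used both to seed the onset
#' priors and as the published benchmark in the fold-ratio evaluation.
#'
#' @return A data.frame with columns sex, age_group, disease, rate, ci_lo, ci_hi.
#' @export
flynn_incidence <- function() {
  utils::read.csv(system.file("extdata", "flynn_incidence.csv",
                              package = "thyrolife", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Reference model-predicted incidence rates
#'
#' Incidence rates of treated thyroid disease predicted by the originally
#' published calibration of this model class (80,000 individuals per sex),
#' bundled so the fold-ratio evaluation can be exercised against the
#' published benchmark without refitting.
#'
#' @return A data.frame shaped like [flynn_incidence()].
#' @export
reference_predicted_incidence <- function() {
  utils::read.csv(system.file("extdata", "reference_predicted_incidence.csv",
                              package = "thyrolife", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Published a-priori onset probability table
#'
#' The published annual prior means (%) for `t14`/`t15` by sex and decade,
#' bundled as a cross-check for [flynn_onset_priors()].
#'
#' @return A data.frame with columns parameter, sex, age_group, prior_pct.
#' @export
onset_prior_table <- function() {
  utils::read.csv(system.file("extdata", "onset_prior_means.csv",
                              package = "thyrolife", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Observed (and reference predicted) prevalence target tables
#'
#' Sex- and decade-specific observed prevalences (%) of diagnosed thyroid
#' disease and of the four undiagnosed hormone-defined categories, from
#' NHANES 2007-2012, together with the originally published model
#' predictions for side-by-side comparison.
#'
#' @return A data.frame with columns table, sex, age_group, category,
#'   observed_pct, reference_predicted_pct.
#' @export
observed_prevalence <- function() {
  utils::read.csv(system.file("extdata", "observed_prevalence.csv",
                              package = "thyrolife", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Annual transition probability from a follow-up proportion
#'
#' Given a cohort of `N` subjects followed `years` years of whom `cases`
#' developed the outcome, the constant annual transition probability `pa`
#' solving `Pfu = 1 - (1 - pa)^n` (the geometric-series accumulation of a
#' constant annual hazard over `n = round(years)` years) is returned, with
#' `sd = sqrt(pa (1 - pa) / N)`.
#'
#' @param n_subjects subjects at baseline (N).
#' @param years_followup follow-up in years; rounded to the nearest integer.
#' @param n_cases subjects developing the outcome.
#' @param pfu_override optional published follow-up proportion to use in
#'   place of `n_cases / n_subjects`.
#' @return list with `pfu`, `n_years`, `pa`, `sd`, `weight` (= 1/sd^2),
#'   and `degenerate` (TRUE when Pfu = 0).
#' @export
pa_from_followup <- function(n_subjects, years_followup, n_cases,
                             pfu_override = NULL) {
  stopifnot(n_subjects >= 1, n_cases >= 0, n_cases <= n_subjects,
            years_followup > 0)
  n <- max(1L, as.integer(round(years_followup)))
  pfu <- if (!is.null(pfu_override) && !is.na(pfu_override)) pfu_override
         else n_cases / n_subjects
  if (pfu >= 1) stop("follow-up proportion of 1 leaves pa undefined")
  pa <- 1 - (1 - pfu)^(1 / n)
  sd <- sqrt(pa * (1 - pa) / n_subjects)
  list(pfu = pfu, n_years = n, pa = pa, sd = sd,
       weight = if (sd > 0) 1 / sd^2 else Inf, degenerate = pfu == 0)
}

#' Annual transition estimates for a table of study records
#'
#' Applies [pa_from_followup()] row-wise.
#'
#' @param records data.frame shaped like [natural_history_records()].
#' @return `records` with columns `pfu`, `pa`, `sd`, `weight` appended.
#' @export
transition_estimates <- function(records) {
  est <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    ov <- if ("pfu_override" %in% names(r)) r$pfu_override else NULL
    pa_from_followup(r$n_subjects, r$years_followup, r$n_cases, ov)
  })
  records$pfu <- vapply(est, `[[`, numeric(1), "pfu")
  records$pa <- vapply(est, `[[`, numeric(1), "pa")
  records$sd <- vapply(est, `[[`, numeric(1), "sd")
  records$weight <- vapply(est, `[[`, numeric(1), "weight")
  records
}

#' Fixed-effect inverse-variance pooled annual probability
#'
#' @param pa vector of annual probabilities.
#' @param sd vector of their standard deviations (> 0).
#' @return The weighted mean with weights 1/sd^2.
#' @export
pool_estimates <- function(pa, sd) {
  if (length(pa) == 0L) stop("no estimates to pool")
  stopifnot(length(pa) == length(sd), all(sd > 0))
  w <- 1 / sd^2
  sum(w * pa) / sum(w)
}

#' Pooled annual transition probabilities per transition
#'
#' Computes study-level estimates, drops `exclude_pool` rows, and pools
#' within each transition by inverse-variance weighting.
#'
#' @param records data.frame shaped like [natural_history_records()].
#' @return data.frame with columns transition, n_studies, pooled_pa.
#' @export
pooled_transitions <- function(records = natural_history_records()) {
  est <- transition_estimates(records)
  est <- est[!est$exclude_pool, ]
  out <- do.call(rbind, lapply(split(est, est$transition), function(g) {
    data.frame(transition = g$transition[1], n_studies = nrow(g),
               pooled_pa = pool_estimates(g$pa, g$sd))
  }))
  rownames(out) <- NULL
  out
}

#' Onset prior means from published treated-disease incidence
#'
#' A-priori annual means for the onset probabilities `t14`/`t15` are three
#' times the published incidence rates of treated hypo-/hyperthyroidism
#' (per 1000 person-years): `prior mean (%) = 3 * rate / 10`.
#'
#' @param flynn data.frame shaped like [flynn_incidence()].
#' @param multiplier scaling of the treated-disease rate (default 3).
#' @return list of two 2 x 7 matrices `t14`, `t15` of annual probabilities
#'   (fractions, not %), rows male/female, columns [onset_decades()].
#' @export
flynn_onset_priors <- function(flynn = flynn_incidence(), multiplier = 3) {
  disease_of <- c(t14 = "hypothyroidism", t15 = "hyperthyroidism")
  out <- list()
  for (nm in names(disease_of)) {
    m <- matrix(NA_real_, 2, 7, dimnames = list(sexes(), onset_decades()))
    sub <- flynn[flynn$disease == disease_of[[nm]], ]
    m[cbind(sub$sex, sub$age_group)] <- multiplier * sub$rate / 1000
    if (anyNA(m)) stop("missing sex/decade cell in the incidence table")
    out[[nm]] <- m
  }
  out
}

#' Maximum-variance beta/Dirichlet prior with given means
#'
#' Parameterises a beta or Dirichlet distribution whose mean(s) equal the
#' target(s) exactly while the smallest concentration parameter is pinned
#' at `min_conc` (default 1.05). Driving the smallest parameter towards 1
#' maximises the variance; holding it slightly above 1 keeps the density
#' mode strictly inside (0, 1).
#'
#' @param means for `"beta"` a single mean in (0, 1); for `"dirichlet"` a
#'   named vector of component means (including the "stay" complement)
#'   summing to 1.
#' @param family `"beta"` or `"dirichlet"`.
#' @param min_conc smallest concentration parameter (default 1.05).
#' @return list of class `thyro_prior` with `family`, `concentration`
#'   (named; `c(alpha, beta)` for the beta family) and `mean`.
#' @export
make_prior <- function(means, family = c("beta", "dirichlet"),
                       min_conc = 1.05) {
  family <- match.arg(family)
  if (any(means <= 0) || any(means >= 1)) stop("means must lie in (0, 1)")
  if (family == "beta") {
    stopifnot(length(means) == 1L)
    m <- unname(means)
    conc <- if (m <= 0.5) c(alpha = min_conc, beta = min_conc * (1 - m) / m)
            else c(alpha = min_conc * m / (1 - m), beta = min_conc)
  } else {
    if (abs(sum(means) - 1) > 1e-9) stop("dirichlet means must sum to 1")
    conc <- min_conc * means / min(means)
  }
  structure(list(family = family, concentration = conc, mean = means),
            class = "thyro_prior")
}

dirichlet_mean <- function(spec) spec$concentration / sum(spec$concentration)

#' Build the full prior set for the chain
#'
#' Assembles the a-priori distributions for every free transition
#' probability: Dirichlet rows for states 1 (per sex x decade), 4 and 5,
#' and beta distributions for `t26` and `t36`. Annual prior means come
#' from the 3x published-incidence rule (`t14`, `t15`), the
#' inverse-variance pools (`t42`, `t47`, `t53`, `t57`, `t26`, `t36`) and
#' assigned constants (`t46`, `t56`, default 0.02/year); they are
#' converted to the quarterly scale before parameterisation, since the
#' chain steps quarterly.
#'
#' @param records natural-history study table ([natural_history_records()]).
#' @param flynn published incidence table ([flynn_incidence()]).
#' @param t46,t56 assigned annual prior means for subclinical -> treated.
#' @param min_conc smallest concentration parameter (default 1.05).
#' @param override_means optional named list of annual means replacing the
#'   pooled values (e.g. `list(t42 = 0.05, t47 = 0.06)` for the
#'   restricted-studies sensitivity scenario).
#' @return An object of class `thyro_priors`: named list of `thyro_prior`
#'   specs (`state1.<sex>.<decade>`, `state4`, `state5`, `t26`, `t36`)
#'   with the annual mean table attached as attribute `annual_means`.
#' @export
build_priors <- function(records = natural_history_records(),
                         flynn = flynn_incidence(),
                         t46 = 0.02, t56 = 0.02, min_conc = 1.05,
                         override_means = NULL) {
  onset <- flynn_onset_priors(flynn)
  pool <- pooled_transitions(records)
  ann <- stats::setNames(pool$pooled_pa, pool$transition)
  ann["t46"] <- t46
  ann["t56"] <- t56
  for (nm in names(override_means)) ann[nm] <- override_means[[nm]]
  q <- function(x) annual_to_quarterly(x)
  specs <- list()
  for (s in sexes()) for (d in onset_decades()) {
    m14 <- q(onset$t14[s, d]); m15 <- q(onset$t15[s, d])
    specs[[paste("state1", s, d, sep = ".")]] <- make_prior(
      c(t14 = m14, t15 = m15, stay = 1 - m14 - m15),
      family = "dirichlet", min_conc = min_conc)
  }
  m4 <- c(t42 = q(ann[["t42"]]), t46 = q(ann[["t46"]]), t47 = q(ann[["t47"]]))
  specs$state4 <- make_prior(c(m4, stay = 1 - sum(m4)), "dirichlet", min_conc)
  m5 <- c(t53 = q(ann[["t53"]]), t56 = q(ann[["t56"]]), t57 = q(ann[["t57"]]))
  specs$state5 <- make_prior(c(m5, stay = 1 - sum(m5)), "dirichlet", min_conc)
  specs$t26 <- make_prior(q(ann[["t26"]]), "beta", min_conc)
  specs$t36 <- make_prior(q(ann[["t36"]]), "beta", min_conc)
  structure(specs, class = "thyro_priors",
            annual_means = ann, onset_annual = onset, min_conc = min_conc)
}

#' Parameter set at the prior means
#'
#' @param priors A `thyro_priors` object.
#' @return A quarterly-scale `thyro_params` whose entries are the prior means.
#' @export
prior_mean_params <- function(priors) {
  stopifnot(inherits(priors, "thyro_priors"))
  t14 <- t15 <- matrix(0, 2, 7, dimnames = list(sexes(), onset_decades()))
  for (s in sexes()) for (d in onset_decades()) {
    m <- priors[[paste("state1", s, d, sep = ".")]]$mean
    t14[s, d] <- m[["t14"]]; t15[s, d] <- m[["t15"]]
  }
  m4 <- priors$state4$mean; m5 <- priors$state5$mean
  thyro_params(t14 = t14, t15 = t15,
               t42 = m4[["t42"]], t46 = m4[["t46"]], t47 = m4[["t47"]],
               t53 = m5[["t53"]], t56 = m5[["t56"]], t57 = m5[["t57"]],
               t26 = priors$t26$mean, t36 = priors$t36$mean,
               time_scale = "quarterly")
}

# Dirichlet sampling/density built from gamma draws; base R has no Dirichlet.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

ddirichlet_log <- function(x, alpha) {
  if (any(x <= 0) || abs(sum(x) - 1) > 1e-8) return(-Inf)
  lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * log(x))
}

#' Draw one parameter set from the priors
#'
#' @param priors A `thyro_priors` object.
#' @return A quarterly-scale `thyro_params` object.
#' @export
sample_prior_params <- function(priors) {
  stopifnot(inherits(priors, "thyro_priors"))
  t14 <- t15 <- matrix(0, 2, 7, dimnames = list(sexes(), onset_decades()))
  for (s in sexes()) for (d in onset_decades()) {
    draw <- rdirichlet1(priors[[paste("state1", s, d, sep = ".")]]$concentration)
    t14[s, d] <- draw[1]; t15[s, d] <- draw[2]
  }
  d4 <- rdirichlet1(priors$state4$concentration)
  d5 <- rdirichlet1(priors$state5$concentration)
  rb <- function(spec) stats::rbeta(1, spec$concentration[["alpha"]],
                                    spec$concentration[["beta"]])
  thyro_params(t14 = t14, t15 = t15,
               t42 = d4[1], t46 = d4[2], t47 = d4[3],
               t53 = d5[1], t56 = d5[2], t57 = d5[3],
               t26 = rb(priors$t26), t36 = rb(priors$t36),
               time_scale = "quarterly")
}

#' Joint prior log-density of a parameter set
#'
#' @param params quarterly-scale `thyro_params`.
#' @param priors A `thyro_priors` object.
#' @return log prior density (-Inf outside the support).
#' @export
log_prior_density <- function(params, priors) {
  stopifnot(inherits(params, "thyro_params"), params$time_scale == "quarterly")
  lp <- 0
  for (s in sexes()) for (d in onset_decades()) {
    x <- c(params$t14[s, d], params$t15[s, d])
    lp <- lp + ddirichlet_log(c(x, 1 - sum(x)),
      priors[[paste("state1", s, d, sep = ".")]]$concentration)
  }
  x4 <- c(params$t42, params$t46, params$t47)
  lp <- lp + ddirichlet_log(c(x4, 1 - sum(x4)), priors$state4$concentration)
  x5 <- c(params$t53, params$t56, params$t57)
  lp <- lp + ddirichlet_log(c(x5, 1 - sum(x5)), priors$state5$concentration)
  lp <- lp + stats::dbeta(params$t26, priors$t26$concentration[["alpha"]],
                          priors$t26$concentration[["beta"]], log = TRUE)
  lp + stats::dbeta(params$t36, priors$t36$concentration[["alpha"]],
                    priors$t36$concentration[["beta"]], log = TRUE)
}

#' Write prior means and concentrations to CSV
#'
#' One row per prior component: `(prior, component, mean_quarterly,
#' mean_annual, concentration)`.
#'
#' @param priors A `thyro_priors` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_priors_csv <- function(priors, path) {
  rows <- lapply(names(priors), function(nm) {
    spec <- priors[[nm]]
    mq <- if (spec$family == "beta") spec$mean else spec$mean
    comp <- if (spec$family == "beta") "p" else names(spec$concentration)
    data.frame(prior = nm, component = comp,
               mean_quarterly = unname(mq),
               mean_annual = unname(quarterly_to_annual(mq)),
               concentration = if (spec$family == "beta")
                 sum(spec$concentration) else unname(spec$concentration))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
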