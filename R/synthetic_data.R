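# Synthetic survey-like data generated from a known parameter set, so
# every downstream stage (target tables, calibration, recovery) is
# testable without external data.

default_hormone_boxes <- function() {
  list(normal        = c(tsh_lo = 0.50, tsh_hi = 3.50, ft4_lo = 0.60, ft4_hi = 1.20),
       subclin_hypo  = c(tsh_lo = 4.50, tsh_hi = 10.0, ft4_lo = 0.60, ft4_hi = 1.20),
       overt_hypo    = c(tsh_lo = 4.50, tsh_hi = 10.0, ft4_lo = 0.20, ft4_hi = 0.45),
       subclin_hyper = c(tsh_lo = 0.02, tsh_hi = 0.15, ft4_lo = 0.60, ft4_hi = 1.20),
       overt_hyper   = c(tsh_lo = 0.02, tsh_hi = 0.15, ft4_lo = 1.35, ft4_hi = 2.50))
}

#' Design for a synthetic survey
#'
#' Describes the synthetic population: the true parameter set, how many
#' records per sex x decade cell (default: a survey-scale total of 16,453
#' split uniformly over the 12 cells covering ages 20-79), the fraction
#' of eligible undiagnosed records with hormone measurements (default one
#' third), the share of diagnosed disease that is nonfunctional (extra
#' diagnosed cases drawn from biochemically normal subjects; default
#' 0.05, matching a 95% functional fraction), and per-category rectangular
#' (TSH, fT4) sampling regions nested strictly inside the classification
#' thresholds (so zero-noise classification recovers the latent state).
#'
#' @param true_params quarterly-scale `thyro_params` generating the data.
#' @param n_total total records across cells (default 16453).
#' @param cell_sizes optional 2 x 6 matrix (sex x decade 20-29..70-79) of
#'   per-cell record counts, overriding the uniform split.
#' @param hormone_frac fraction of eligible records with hormones (1/3).
#' @param nonfunctional_rate proportion of diagnosed cases that are
#'   nonfunctional (default 0.05).
#' @param functional_fraction adjustment used downstream when tables are
#'   built from the records (default 0.95).
#' @param hormone_boxes named list of sampling rectangles per category.
#' @return list of class `thyro_synth_design`.
#' @export
synthetic_design <- function(true_params, n_total = 16453, cell_sizes = NULL,
                             hormone_frac = 1 / 3, nonfunctional_rate = 0.05,
                             functional_fraction = 0.95,
                             hormone_boxes = default_hormone_boxes()) {
  stopifnot(inherits(true_params, "thyro_params"),
            true_params$time_scale == "quarterly",
            hormone_frac > 0, hormone_frac <= 1,
            nonfunctional_rate >= 0, nonfunctional_rate < 1)
  if (is.null(cell_sizes)) {
    cell_sizes <- matrix(round(n_total / 12), 2, 6,
                         dimnames = list(sexes(), target_decades()))
  }
  structure(list(true_params = true_params, cell_sizes = cell_sizes,
                 hormone_frac = hormone_frac,
                 nonfunctional_rate = nonfunctional_rate,
                 functional_fraction = functional_fraction,
                 hormone_boxes = hormone_boxes),
            class = "thyro_synth_design")
}

# Predicted cell quantities under the design's true parameters.
design_cell_probs <- function(design) {
  out <- list()
  for (s in sexes()) {
    davg <- decade_occupancy(design$true_params, s)
    for (d in target_decades())
      out[[paste(s, d)]] <- occupancy_to_categories(davg[d, ])
  }
  out
}

#' Draw a target table directly from the design's sampling model
#'
#' Per sex x decade cell: treated cases are binomial with the analytic
#' state-6 prevalence; the hormone subsample denominator is the
#' `hormone_frac` share of the remaining records; undiagnosed category
#' counts are multinomial with the analytic conditional probabilities.
#'
#' @param design A `thyro_synth_design`.
#' @param seed integer seed.
#' @return A `thyro_targets` object (counts are functional by
#'   construction, so `functional_fraction = 1`).
#' @export
generate_counts <- function(design, seed = 1) {
  stopifnot(inherits(design, "thyro_synth_design"))
  set.seed(seed)
  probs <- design_cell_probs(design)
  cats <- prevalence_categories()
  diag_rows <- und_rows <- list()
  for (s in sexes()) for (d in target_decades()) {
    p <- probs[[paste(s, d)]]
    n <- design$cell_sizes[s, d]
    cases <- stats::rbinom(1, n, p[["treated"]])
    n_und <- round((n - cases) * design$hormone_frac)
    counts <- drop(stats::rmultinom(1, n_und, p[cats]))
    diag_rows[[length(diag_rows) + 1L]] <- data.frame(
      sex = s, age_group = d, cases = cases, cases_functional = cases,
      denominator = n)
    und_rows[[length(und_rows) + 1L]] <- cbind(
      data.frame(sex = s, age_group = d),
      as.data.frame(as.list(stats::setNames(counts, cats))),
      denominator = n_und)
  }
  thyro_targets(do.call(rbind, diag_rows), do.call(rbind, und_rows),
                functional_fraction = 1)
}

#' Generate unit-level synthetic survey records
#'
#' Each record draws a quarter-age uniformly within its cell's decade and
#' a latent thyroid state from the analytic occupancy at that age. Latent
#' treated subjects are flagged diagnosed; additional nonfunctional
#' diagnoses are sprinkled over biochemically normal subjects at a rate
#' calibrated so they form `nonfunctional_rate` of all diagnosed cases in
#' expectation. Undiagnosed subjects receive (TSH, fT4) values uniform in
#' their latent state's rectangle with probability `hormone_frac`
#' (hormones are missing otherwise). Running [build_target_tables()] on
#' the output reproduces the distribution of [generate_counts()].
#'
#' @param design A `thyro_synth_design`.
#' @param seed integer seed.
#' @return data.frame of survey records (sex, age, latent_state,
#'   diagnosed_flag, tsh, ft4 and all-FALSE exclusion flags).
#' @export
generate_records <- function(design, seed = 1) {
  stopifnot(inherits(design, "thyro_synth_design"))
  set.seed(seed)
  f <- design$nonfunctional_rate
  cat_of_state <- c("normal", "overt_hypo", "overt_hyper", "subclin_hypo",
                    "subclin_hyper", "treated", "normal")
  out <- list()
  for (s in sexes()) {
    occ <- propagate(design$true_params, s)
    cumocc <- t(apply(occ, 1, cumsum))
    davg <- decade_occupancy(design$true_params, s, occ = occ)
    for (d in target_decades()) {
      n <- design$cell_sizes[s, d]
      a0 <- as.integer(sub("-.*", "", d))
      q <- sample.int(40, n, replace = TRUE) + a0 * 4
      latent <- rowSums(stats::runif(n) > cumocc[q, 1:6, drop = FALSE]) + 1L
      diagnosed <- latent == 6L
      p6 <- occupancy_to_categories(davg[d, ])[["treated"]]
      # extras from normal-range states so nonfunctional disease is ~f of
      # all diagnoses: q_extra * P(normal) = p6 * f / (1 - f)
      normalish <- latent %in% c(1L, 7L)
      p_norm <- sum(davg[d, c("normal", "reverted_normal")])
      if (f > 0 && p_norm > 0) {
        q_extra <- min(1, p6 * f / (1 - f) / p_norm)
        diagnosed[normalish] <- diagnosed[normalish] |
          stats::runif(sum(normalish)) < q_extra
      }
      measured <- !diagnosed & stats::runif(n) < design$hormone_frac
      tsh <- ft4 <- rep(NA_real_, n)
      for (st in 1:7) {
        idx <- which(measured & latent == st)
        if (!length(idx) || st == 6L) next
        box <- design$hormone_boxes[[cat_of_state[st]]]
        tsh[idx] <- stats::runif(length(idx), box[["tsh_lo"]], box[["tsh_hi"]])
        ft4[idx] <- stats::runif(length(idx), box[["ft4_lo"]], box[["ft4_hi"]])
      }
      out[[length(out) + 1L]] <- data.frame(
        sex = s, age = (q - 1) / 4, latent_state = latent,
        diagnosed_flag = diagnosed, tsh = tsh, ft4 = ft4,
        thyroid_cancer = FALSE, pregnant_or_breastfeeding = FALSE,
        poor_health = FALSE, chemo_or_dialysis = FALSE,
        interfering_drugs = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
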