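# Analytic propagation of the state-occupancy distribution and its
# aggregation into sex x decade predicted prevalence tables.

#' Propagate the occupancy distribution over quarterly steps
#'
#' Starting from all mass in the normal state at age 0, the 7-state
#' occupancy vector is right-multiplied each quarter by the age- and
#' sex-appropriate transition matrix. Row `k` of the result is the
#' distribution at age `(k - 1) / 4` years, for the 320 quarters covering
#' ages \[0, 80).
#'
#' @param params quarterly-scale `thyro_params`.
#' @param sex `"male"` or `"female"`.
#' @return A 320 x 7 matrix; rows sum to 1.
#' @export
propagate <- function(params, sex) {
  mats <- decade_matrices(params, sex)
  occ <- matrix(0, 320, 7, dimnames = list(NULL, state_labels()))
  v <- c(1, rep(0, 6))
  for (k in 1:320) {
    occ[k, ] <- v
    v <- drop(v %*% mats[[(k - 1) %/% 40 + 1]])
  }
  occ
}

# Decade-averaged occupancy: 8 x 7 matrix (decades 0-9 .. 70-79), the mean
# of the 40 quarterly occupancy vectors within each decade.
decade_occupancy <- function(params, sex, occ = NULL) {
  if (is.null(occ)) occ <- propagate(params, sex)
  dec <- rep(1:8, each = 40)
  out <- rowsum(occ, dec) / 40
  rownames(out) <- paste(seq(0, 70, 10), seq(9, 79, 10), sep = "-")
  out
}

prevalence_categories <- function() {
  c("normal", "subclin_hypo", "overt_hypo", "subclin_hyper", "overt_hyper")
}

# Map decade-averaged occupancy to the observable categories:
# treated = state 6; the rest conditional on not being treated, with
# "normal" combining the biochemically normal states 1 and 7.
occupancy_to_categories <- function(occ_row) {
  p6 <- occ_row[["treated"]]
  if (1 - p6 <= 0) {
    cond <- rep(NA_real_, 5)
  } else {
    cond <- c(occ_row[["normal"]] + occ_row[["reverted_normal"]],
              occ_row[["subclinical_hypothyroid"]],
              occ_row[["overt_hypothyroid"]],
              occ_row[["subclinical_hyperthyroid"]],
              occ_row[["overt_hyperthyroid"]]) / (1 - p6)
  }
  c(treated = p6, stats::setNames(cond, prevalence_categories()))
}

#' Predicted prevalence table from the analytic occupancy
#'
#' For each sex and decade the 40 quarterly occupancy vectors are
#' averaged; the treated prevalence is the mean state-6 mass, and the
#' five undiagnosed-category proportions are conditional on not being
#' treated (mirroring a survey design in which hormone classification
#' applies only to those without diagnosed disease).
#'
#' @param params quarterly-scale `thyro_params`.
#' @param sexes_use sexes to include (default both).
#' @param decades decade labels to report (default `"20-29"` ... `"70-79"`,
#'   the range with observable survey data).
#' @return data.frame with columns sex, age_group, category, proportion;
#'   categories are `treated` plus the five conditional categories.
#' @export
predicted_prevalence <- function(params, sexes_use = sexes(),
                                 decades = paste(seq(20, 70, 10),
                                                 seq(29, 79, 10), sep = "-")) {
  rows <- list()
  for (s in sexes_use) {
    davg <- decade_occupancy(params, s)
    for (d in decades) {
      p <- occupancy_to_categories(davg[d, ])
      rows[[length(rows) + 1L]] <- data.frame(
        sex = s, age_group = d, category = names(p), proportion = unname(p))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a prevalence table to CSV
#' @param prev data.frame from [predicted_prevalence()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_prevalence_csv <- function(prev, path) {
  utils::write.csv(prev, path, row.names = FALSE)
  invisible(path)
}
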