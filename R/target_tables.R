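# Target tables from survey-like unit records: TSH/fT4 classification,
# exclusion rules, and the functional-fraction adjustment of treated counts.

# Half-up rounding to an integer count (round() rounds half to even,
# which is not wanted for count adjustment).
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Classify thyroid state from TSH and free T4
#'
#' Diagnostic thresholds (strict inequalities; boundary values classify as
#' the normal range): overt hypothyroidism TSH > 4 uIU/mL and fT4 <
#' 0.5 ng/dL; subclinical hypothyroidism TSH > 4 with fT4 in the normal
#' range \[0.5, 1.28\]; overt hyperthyroidism TSH < 0.2 and fT4 > 1.28;
#' subclinical hyperthyroidism TSH < 0.2 with normal fT4; TSH in
#' \[0.2, 4\] is normal regardless of fT4. Concordant-threshold violations
#' (TSH > 4 with fT4 > 1.28, or TSH < 0.2 with fT4 < 0.5) fit no modelled
#' state and return `"discordant"`.
#'
#' @param tsh thyroid stimulating hormone, uIU/mL (vectorised).
#' @param ft4 free thyroxine, ng/dL (vectorised).
#' @return character vector of categories.
#' @export
classify_thyroid_state <- function(tsh, ft4) {
  if (any(is.na(tsh)) || any(is.na(ft4)))
    stop("classify_thyroid_state() requires both hormone values")
  out <- rep("normal", length(tsh))
  hi <- tsh > 4; lo <- tsh < 0.2
  out[hi & ft4 < 0.5] <- "overt_hypo"
  out[hi & ft4 >= 0.5 & ft4 <= 1.28] <- "subclin_hypo"
  out[hi & ft4 > 1.28] <- "discordant"
  out[lo & ft4 > 1.28] <- "overt_hyper"
  out[lo & ft4 >= 0.5 & ft4 <= 1.28] <- "subclin_hyper"
  out[lo & ft4 < 0.5] <- "discordant"
  out
}

target_decades <- function() paste(seq(20, 70, 10), seq(29, 79, 10), sep = "-")

decade_of_age <- function(age) {
  paste(floor(age / 10) * 10, floor(age / 10) * 10 + 9, sep = "-")
}

#' Build the calibration target tables from survey records
#'
#' `records` needs columns `sex`, `age`, `diagnosed_flag`, `tsh`, `ft4`
#' (hormones may be NA) and logical exclusion flags `thyroid_cancer`,
#' `pregnant_or_breastfeeding`, `poor_health`, `chemo_or_dialysis`,
#' `interfering_drugs`. The diagnosed table counts everyone aged 20-79
#' without a thyroid-cancer history; diagnosed cases are multiplied by
#' `functional_fraction` (rounded half-up) to form the likelihood target,
#' since a share of reported disease is nonfunctional. The undiagnosed
#' table additionally drops diagnosed subjects, the remaining exclusion
#' flags, and records with missing or discordant hormones, then counts
#' the five hormone-defined categories.
#'
#' @param records data.frame of survey records.
#' @param functional_fraction proportion of diagnosed cases assumed
#'   functional (default 0.95; 0.85 in sensitivity analyses).
#' @return Object of class `thyro_targets`: list with data.frames
#'   `diagnosed` (sex, age_group, cases, cases_functional, denominator)
#'   and `undiagnosed` (sex, age_group, five category counts,
#'   denominator), plus `functional_fraction`. The number of discordant
#'   records dropped is attached as attribute `n_discordant`.
#' @export
build_target_tables <- function(records, functional_fraction = 0.95) {
  stopifnot(functional_fraction >= 0, functional_fraction <= 1)
  flags <- c("thyroid_cancer", "pregnant_or_breastfeeding", "poor_health",
             "chemo_or_dialysis", "interfering_drugs")
  for (f in c(flags, "diagnosed_flag"))
    if (is.null(records[[f]])) records[[f]] <- FALSE
  eligible <- records$age >= 20 & records$age < 80 & !records$thyroid_cancer
  diag_pool <- records[eligible, ]
  grid <- expand.grid(sex = sexes(), age_group = target_decades(),
                      stringsAsFactors = FALSE)
  diag_pool$age_group <- decade_of_age(diag_pool$age)
  diagnosed <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- diag_pool[diag_pool$sex == grid$sex[i] &
                   diag_pool$age_group == grid$age_group[i], ]
    cases <- sum(g$diagnosed_flag)
    data.frame(sex = grid$sex[i], age_group = grid$age_group[i],
               cases = cases,
               cases_functional = round_half_up(cases * functional_fraction),
               denominator = nrow(g))
  }))

  und_pool <- diag_pool[!diag_pool$diagnosed_flag &
                        !diag_pool$pregnant_or_breastfeeding &
                        !diag_pool$poor_health &
                        !diag_pool$chemo_or_dialysis &
                        !diag_pool$interfering_drugs, ]
  has_horm <- !is.na(und_pool$tsh) & !is.na(und_pool$ft4)
  und_pool <- und_pool[has_horm, ]
  und_pool$category <- classify_thyroid_state(und_pool$tsh, und_pool$ft4)
  n_discordant <- sum(und_pool$category == "discordant")
  und_pool <- und_pool[und_pool$category != "discordant", ]
  cats <- prevalence_categories()
  undiagnosed <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- und_pool[und_pool$sex == grid$sex[i] &
                  und_pool$age_group == grid$age_group[i], ]
    counts <- vapply(cats, function(cc) sum(g$category == cc), integer(1))
    cbind(data.frame(sex = grid$sex[i], age_group = grid$age_group[i]),
          as.data.frame(as.list(counts)), denominator = nrow(g))
  }))
  structure(list(diagnosed = diagnosed, undiagnosed = undiagnosed,
                 functional_fraction = functional_fraction),
            class = "thyro_targets", n_discordant = n_discordant)
}

#' Construct a target-table object from pre-aggregated counts
#'
#' @param diagnosed data.frame (sex, age_group, cases, cases_functional,
#'   denominator); `cases_functional` defaults to `cases`.
#' @param undiagnosed data.frame (sex, age_group, normal, subclin_hypo,
#'   overt_hypo, subclin_hyper, overt_hyper, denominator).
#' @param functional_fraction the adjustment already applied to
#'   `cases_functional`.
#' @return A `thyro_targets` object.
#' @export
thyro_targets <- function(diagnosed, undiagnosed, functional_fraction = 1) {
  if (is.null(diagnosed$cases_functional))
    diagnosed$cases_functional <- round_half_up(diagnosed$cases *
                                                functional_fraction)
  stopifnot(all(diagnosed$cases <= diagnosed$denominator),
            all(rowSums(undiagnosed[prevalence_categories()]) ==
                undiagnosed$denominator))
  structure(list(diagnosed = diagnosed, undiagnosed = undiagnosed,
                 functional_fraction = functional_fraction),
            class = "thyro_targets")
}

#' Write a target-table object to a long CSV
#'
#' Columns `(table, sex, age_group, category, count, denominator)`.
#'
#' @param targets A `thyro_targets` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_targets_csv <- function(targets, path) {
  d <- targets$diagnosed
  rows <- data.frame(table = "diagnosed", sex = d$sex, age_group = d$age_group,
                     category = "treated_functional",
                     count = d$cases_functional, denominator = d$denominator)
  rows <- rbind(rows, data.frame(table = "diagnosed", sex = d$sex,
                                 age_group = d$age_group, category = "treated_raw",
                                 count = d$cases, denominator = d$denominator))
  u <- targets$undiagnosed
  for (cc in prevalence_categories()) {
    rows <- rbind(rows, data.frame(table = "undiagnosed", sex = u$sex,
                                   age_group = u$age_group, category = cc,
                                   count = u[[cc]], denominator = u$denominator))
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a target-table object from the CSV written by [write_targets_csv()]
#' @param path file path.
#' @param functional_fraction recorded adjustment fraction.
#' @return A `thyro_targets` object.
#' @export
read_targets_csv <- function(path, functional_fraction = 0.95) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  d_raw <- df[df$category == "treated_raw", ]
  d_fun <- df[df$category == "treated_functional", ]
  key <- function(x) paste(x$sex, x$age_group)
  d_raw <- d_raw[order(key(d_raw)), ]
  d_fun <- d_fun[order(key(d_fun)), ]
  diagnosed <- data.frame(sex = d_raw$sex, age_group = d_raw$age_group,
                          cases = d_raw$count, cases_functional = d_fun$count,
                          denominator = d_raw$denominator)
  u <- df[df$table == "undiagnosed", ]
  und <- stats::reshape(u[c("sex", "age_group", "category", "count")],
                        idvar = c("sex", "age_group"), timevar = "category",
                        direction = "wide")
  names(und) <- sub("^count\\.", "", names(und))
  und$denominator <- rowSums(und[prevalence_categories()])
  thyro_targets(diagnosed, und, functional_fraction)
}
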