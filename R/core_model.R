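# Core domain objects: the 7-state chain, transition parameter sets,
# annual<->quarterly conversion and transition-matrix assembly.

#' State codes and labels of the thyroid disease chain
#'
#' The model tracks seven mutually exclusive functional thyroid states.
#' Numeric codes follow the transition-symbol convention (`t42` is the
#' probability of moving from state 4 to state 2, etc.):
#' 1 = normal, 2 = overt hypothyroid, 3 = overt hyperthyroid,
#' 4 = subclinical hypothyroid, 5 = subclinical hyperthyroid,
#' 6 = treated (ever; absorbing), 7 = reverted to normal (absorbing).
#'
#' @return A data.frame with columns `code` and `label`.
#' @export
disease_states <- function() {
  data.frame(
    code = 1:7,
    label = c("normal", "overt_hypothyroid", "overt_hyperthyroid",
              "subclinical_hypothyroid", "subclinical_hyperthyroid",
              "treated", "reverted_normal"),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
state_labels <- function() disease_states()$label

#' Decade labels used for the age-specific onset probabilities
#' @return Character vector `"10-19"` ... `"70-79"`.
#' @export
onset_decades <- function() {
  paste(seq(10, 70, by = 10), seq(19, 79, by = 10), sep = "-")
}

sexes <- function() c("male", "female")

scalar_param_names <- function() c("t42", "t46", "t47", "t53", "t56", "t57", "t26", "t36")

#' Construct a transition parameter set
#'
#' Bundles the free transition probabilities of the chain: onset probabilities
#' `t14` (normal -> subclinical hypothyroidism) and `t15` (normal ->
#' subclinical hyperthyroidism), each sex- and decade-specific
#' (2 x 7 matrices, rows `male`/`female`, columns [onset_decades()]),
#' plus eight scalar probabilities for progression (`t42`, `t53`),
#' treatment (`t46`, `t56`, `t26`, `t36`) and reversion (`t47`, `t57`).
#' Probabilities are per year or per quarter according to `time_scale`.
#'
#' @param t14,t15 2 x 7 numeric matrices (or a single number, recycled).
#' @param t42,t46,t47,t53,t56,t57,t26,t36 scalar probabilities.
#' @param time_scale `"annual"` or `"quarterly"`.
#' @return An object of class `thyro_params`.
#' @export
thyro_params <- function(t14 = 0, t15 = 0, t42 = 0, t46 = 0, t47 = 0,
                         t53 = 0, t56 = 0, t57 = 0, t26 = 0, t36 = 0,
                         time_scale = c("annual", "quarterly")) {
  time_scale <- match.arg(time_scale)
  expand <- function(x) {
    if (length(x) == 1L) x <- matrix(x, 2, 7)
    x <- as.matrix(x)
    stopifnot(identical(dim(x), c(2L, 7L)))
    dimnames(x) <- list(sexes(), onset_decades())
    x
  }
  p <- structure(
    list(t14 = expand(t14), t15 = expand(t15),
         t42 = t42, t46 = t46, t47 = t47,
         t53 = t53, t56 = t56, t57 = t57,
         t26 = t26, t36 = t36,
         time_scale = time_scale),
    class = "thyro_params"
  )
  validate_params(p)
  p
}

#' Validate a transition parameter set
#'
#' Checks that every probability lies in \[0, 1\] and that the outgoing
#' probabilities of each multi-destination row (states 1, 4 and 5) sum to
#' at most 1, so the diagonal "stay" complement is a valid probability.
#'
#' @param p A `thyro_params` object.
#' @return `p`, invisibly; errors otherwise.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "thyro_params"))
  vals <- c(p$t14, p$t15, p$t42, p$t46, p$t47, p$t53, p$t56, p$t57, p$t26, p$t36)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("all transition probabilities must lie in [0, 1]")
  if (any(p$t14 + p$t15 > 1 + 1e-12))
    stop("state-1 row: t14 + t15 exceeds 1 for some sex/decade")
  if (p$t42 + p$t46 + p$t47 > 1 + 1e-12)
    stop("state-4 row: t42 + t46 + t47 exceeds 1")
  if (p$t53 + p$t56 + p$t57 > 1 + 1e-12)
    stop("state-5 row: t53 + t56 + t57 exceeds 1")
  invisible(p)
}

#' Convert an annual probability to the equivalent quarterly probability
#'
#' Solves `1 - (1 - pq)^4 = pa`, i.e. four independent quarterly chances
#' compound to the annual probability.
#'
#' @param pa probability per year, in \[0, 1\] (vectorised).
#' @return probability per quarter.
#' @export
annual_to_quarterly <- function(pa) {
  stopifnot(all(pa >= 0 & pa <= 1))
  1 - (1 - pa)^(1 / 4)
}

#' Convert a quarterly probability back to the annual scale
#'
#' Inverse of [annual_to_quarterly()]: `pa = 1 - (1 - pq)^4`.
#'
#' @param pq probability per quarter, in \[0, 1\] (vectorised).
#' @return probability per year.
#' @export
quarterly_to_annual <- function(pq) {
  stopifnot(all(pq >= 0 & pq <= 1))
  1 - (1 - pq)^4
}

#' Re-express a whole parameter set on the other time scale
#'
#' Applies the compounding conversion to every free probability
#' independently. Each outgoing arrow is converted on its own; the
#' diagonal is always rebuilt as the row complement at matrix-assembly
#' time, so row-stochasticity is preserved exactly on either scale.
#'
#' @param p A `thyro_params` object.
#' @param to `"quarterly"` or `"annual"`.
#' @return A `thyro_params` object on the requested scale.
#' @export
convert_params <- function(p, to = c("quarterly", "annual")) {
  to <- match.arg(to)
  stopifnot(inherits(p, "thyro_params"))
  if (p$time_scale == to) return(p)
  f <- if (to == "quarterly") annual_to_quarterly else quarterly_to_annual
  q <- p
  for (nm in c("t14", "t15", scalar_param_names())) q[[nm]] <- f(p[[nm]])
  q$time_scale <- to
  validate_params(q)
  q
}

#' Assemble the 7 x 7 quarterly transition matrix for a sex and age
#'
#' Below age 10 everyone remains normal (identity matrix). From age 10,
#' the onset probabilities are looked up by sex and decade
#' (`floor(age / 10)`); the quarter within the year does not change the
#' decade. Diagonal entries are the complements of the row sums, and
#' entries are zero exactly where the state diagram has no arrow
#' (1 -> \{4, 5\}, 4 -> \{2, 6, 7\}, 5 -> \{3, 6, 7\}, 2 -> 6, 3 -> 6;
#' states 6 and 7 are absorbing).
#'
#' @param params A quarterly-scale `thyro_params` object.
#' @param sex `"male"` or `"female"`.
#' @param age age in years, in \[0, 80); fractional (quarter) ages allowed.
#' @return A 7 x 7 row-stochastic matrix with state labels as dimnames.
#' @export
build_matrix <- function(params, sex, age) {
  stopifnot(inherits(params, "thyro_params"))
  if (params$time_scale != "quarterly")
    stop("build_matrix() requires quarterly-scale parameters; see convert_params()")
  sex <- match.arg(sex, sexes())
  if (!is.finite(age) || age < 0 || age >= 80)
    stop("age must lie in [0, 80)")
  M <- diag(7)
  dimnames(M) <- list(state_labels(), state_labels())
  if (age < 10) return(M)
  dec <- floor(age / 10)  # 1..7 indexes the 10-19 .. 70-79 columns
  t14 <- params$t14[sex, dec]
  t15 <- params$t15[sex, dec]
  M[1, 4] <- t14; M[1, 5] <- t15; M[1, 1] <- 1 - t14 - t15
  M[4, 2] <- params$t42; M[4, 6] <- params$t46; M[4, 7] <- params$t47
  M[4, 4] <- 1 - params$t42 - params$t46 - params$t47
  M[5, 3] <- params$t53; M[5, 6] <- params$t56; M[5, 7] <- params$t57
  M[5, 5] <- 1 - params$t53 - params$t56 - params$t57
  M[2, 6] <- params$t26; M[2, 2] <- 1 - params$t26
  M[3, 6] <- params$t36; M[3, 3] <- 1 - params$t36
  if (any(diag(M) < -1e-12))
    stop("row probabilities exceed 1; refusing to renormalise")
  M
}

# One matrix per decade block (index 1 = ages 0-9 identity, 2..8 = decades
# 10-19 .. 70-79). Internal work-horse for propagation and simulation.
decade_matrices <- function(params, sex) {
  lapply(0:7, function(d) build_matrix(params, sex, age = max(d * 10, 0) + 0.125))
}

#' Write a parameter set to a flat CSV
#'
#' Columns are `(parameter, sex, age_group, value, time_scale)`; `sex` and
#' `age_group` are blank for the scalar parameters.
#'
#' @param params A `thyro_params` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_params_csv <- function(params, path) {
  stopifnot(inherits(params, "thyro_params"))
  rows <- list()
  for (nm in c("t14", "t15")) {
    for (s in sexes()) for (d in onset_decades()) {
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = nm, sex = s, age_group = d,
        value = params[[nm]][s, d], time_scale = params$time_scale)
    }
  }
  for (nm in scalar_param_names()) {
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = nm, sex = "", age_group = "",
      value = params[[nm]], time_scale = params$time_scale)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a parameter set from the flat CSV written by [write_params_csv()]
#'
#' @param path file path.
#' @return A `thyro_params` object.
#' @export
read_params_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$sex[is.na(df$sex)] <- ""
  df$age_group[is.na(df$age_group)] <- ""
  scale <- unique(df$time_scale)
  stopifnot(length(scale) == 1L)
  grab <- function(nm) {
    m <- matrix(NA_real_, 2, 7, dimnames = list(sexes(), onset_decades()))
    sub <- df[df$parameter == nm, ]
    m[cbind(sub$sex, sub$age_group)] <- sub$value
    stopifnot(!anyNA(m))
    m
  }
  args <- c(list(t14 = grab("t14"), t15 = grab("t15")),
            stats::setNames(lapply(scalar_param_names(),
                                   function(nm) df$value[df$parameter == nm]),
                            scalar_param_names()),
            list(time_scale = scale))
  do.call(thyro_params, args)
}

#' @export
print.thyro_params <- function(x, ...) {
  cat("Thyroid-chain transition parameters (", x$time_scale, " scale)\n", sep = "")
  cat("t14 (normal -> subclinical hypo), % per ", x$time_scale, ":\n", sep = "")
  print(round(100 * x$t14, 4))
  cat("t15 (normal -> subclinical hyper), % per ", x$time_scale, ":\n", sep = "")
  print(round(100 * x$t15, 4))
  sc <- vapply(scalar_param_names(), function(nm) x[[nm]], numeric(1))
  cat("scalars (%):\n")
  print(round(100 * sc, 4))
  invisible(x)
}
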