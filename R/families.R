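#' Read sibship lifespan records from a CSV file
#'
#' One row per individual; rows sharing a `family_id` form a sibship. Sex
#' codes are normalized at read time (`f/m`, `F/M`, `1/2`, `female/male` all
#' accepted; `1` is male, following the common demographic coding).
#'
#' @param path Path to a CSV file with a header row.
#' @param cols Named list mapping the roles `family_id`, `individual_id`,
#'   `sex`, `birth_year`, `age_at_death`, `alive` to column names.
#' @return A tibble with columns `family_id`, `individual_id`, `sex`,
#'   `birth_year`, `age_at_death` (NA when unknown) and `alive` (logical).
#' @export
read_families <- function(path,
                          cols = list(family_id = "family_id",
                                      individual_id = "individual_id",
                                      sex = "sex",
                                      birth_year = "birth_year",
                                      age_at_death = "age_at_death",
                                      alive = "alive")) {
  data <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(sprintf("Cannot read family CSV '%s': %s",
                                      path, conditionMessage(e)))
  )
  if (nrow(data) == 0) {
    return(tibble::tibble(family_id = character(), individual_id = character(),
                          sex = character(), birth_year = integer(),
                          age_at_death = numeric(), alive = logical()))
  }
  missing_cols <- setdiff(unlist(cols), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Family file is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::tibble(
    family_id = as.character(data[[cols$family_id]]),
    individual_id = as.character(data[[cols$individual_id]]),
    sex = normalize_sex(data[[cols$sex]]),
    birth_year = as.integer(data[[cols$birth_year]]),
    age_at_death = suppressWarnings(as.numeric(data[[cols$age_at_death]])),
    alive = parse_logical01(data[[cols$alive]])
  )
  bad <- which(is.na(out$family_id) | is.na(out$individual_id) |
                 is.na(out$birth_year) | is.na(out$alive))
  if (length(bad) > 0) {
    abort(sprintf("Unparseable family row(s) at line(s): %s.",
                  paste(utils::head(bad + 1L, 5L), collapse = ", ")))
  }
  dup <- duplicated(out[, c("family_id", "individual_id")])
  if (any(dup)) {
    abort(sprintf("Duplicated individual_id within family: %s.",
                  paste(unique(out$individual_id[dup]), collapse = ", ")))
  }
  validate_individuals(out)
  out
}

parse_logical01 <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  dplyr::case_match(x, c("1", "true", "t", "yes") ~ TRUE,
                    c("0", "false", "f", "no") ~ FALSE,
                    .default = NA)
}

validate_individuals <- function(x, require_cols = character()) {
  needed <- c("family_id", "individual_id", "sex", "birth_year",
              "age_at_death", "alive", require_cols)
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("Individuals table is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  # dead members may have missing ages (they are filtered, not invalid),
  # but alive members must not carry an age at death
  if (any(x$alive & !is.na(x$age_at_death))) {
    abort("Alive individuals must not have an age at death.")
  }
  invisible(x)
}

#' Apply the standard exclusion filters to sibship data
#'
#' Excludes, in order: (1) individuals with missing age at death (including
#' alive individuals — censored lifespans are out of scope); (2) individuals
#' from non-extinct birth cohorts, i.e. cohorts young enough that members
#' could still be alive at the reference date (`birth_year + max_age >
#' reference_year`); (3) sibships reduced to fewer than two members. An
#' exclusion report is attached as an attribute and retrievable with
#' [exclusion_report()].
#'
#' @param individuals Tibble of individuals (see [read_families()]).
#' @param reference_year Date at which vital status was last updated.
#' @param max_age Maximum attainable age used to define extinct cohorts.
#' @return The filtered tibble, with attribute `exclusions`.
#' @export
apply_filters <- function(individuals, reference_year = 2017, max_age = 110) {
  validate_individuals(individuals)
  report <- tibble::tibble(reason = character(), n_individuals = integer(),
                           n_families = integer())
  note <- function(rep, reason, dropped) {
    dplyr::bind_rows(rep, tibble::tibble(
      reason = reason,
      n_individuals = nrow(dropped),
      n_families = dplyr::n_distinct(dropped$family_id)))
  }

  drop1 <- individuals[individuals$alive | is.na(individuals$age_at_death), ]
  keep <- individuals[!individuals$alive & !is.na(individuals$age_at_death), ]
  if (nrow(drop1) > 0) report <- note(report, "missing_age_at_death", drop1)

  non_extinct <- keep$birth_year + max_age > reference_year
  if (any(non_extinct)) {
    report <- note(report, "non_extinct_cohort", keep[non_extinct, ])
  }
  keep <- keep[!non_extinct, ]

  sizes <- table(keep$family_id)
  singleton <- keep$family_id %in% names(sizes)[sizes < 2]
  if (any(singleton)) {
    report <- note(report, "singleton_sibship", keep[singleton, ])
  }
  keep <- keep[!singleton, ]

  attr(keep, "exclusions") <- report
  keep
}

#' @rdname apply_filters
#' @param x A tibble returned by [apply_filters()].
#' @export
exclusion_report <- function(x) {
  attr(x, "exclusions") %||%
    tibble::tibble(reason = character(), n_individuals = integer(),
                   n_families = integer())
}

#' Annotate individuals with survival percentiles and longevity indicators
#'
#' Adds, per individual, the survival probability at death, the survival
#' percentile \eqn{P = 1 - S(t)}, and the binary longevity indicator
#' \eqn{Y = I(P \ge c)} (the threshold is inclusive). Raising the threshold
#' can only turn indicators off, never on.
#'
#' @param individuals Tibble of individuals with complete ages at death.
#' @param lt A [lifetable] covering every (sex, cohort) stratum present.
#' @param threshold Longevity threshold `c` on the percentile scale.
#' @param conditioning_age If non-`NULL`, percentiles are computed from
#'   survival conditional on reaching this age.
#' @return The input tibble with columns `survival`, `percentile`,
#'   `longevous` appended.
#' @export
annotate_longevity <- function(individuals, lt, threshold = 0.9,
                               conditioning_age = NULL) {
  validate_individuals(individuals)
  stopifnot_scalar_prob(threshold, "threshold")
  if (any(individuals$alive) || anyNA(individuals$age_at_death)) {
    abort("All individuals must have an observed age at death; run apply_filters() first.")
  }
  missing_sex <- setdiff(unique(individuals$sex), unique(lt$sex))
  if (length(missing_sex) > 0) {
    offenders <- individuals$individual_id[individuals$sex %in% missing_sex]
    abort(sprintf(
      "Lifetable lacks strata for sex '%s' (individuals: %s%s).",
      paste(missing_sex, collapse = "', '"),
      paste(utils::head(offenders, 5L), collapse = ", "),
      if (length(offenders) > 5) ", ..." else ""))
  }
  surv <- if (is.null(conditioning_age)) {
    lt_survival(lt, individuals$sex, individuals$birth_year,
                individuals$age_at_death)
  } else {
    lt_conditional_survival(lt, individuals$sex, individuals$birth_year,
                            individuals$age_at_death, conditioning_age)
  }
  individuals |>
    dplyr::mutate(survival = surv,
                  percentile = 1 - surv,
                  longevous = as.integer(.data$percentile >= threshold))
}

#' Split sibships into one holdout member and a scoring set
#'
#' Draws exactly one member at random from every sibship into a validation
#' set; the remaining siblings form the scoring set on which family scores
#' are computed. The validation individuals never contribute to scores, so
#' score-based selections can be tested against their survival without
#' circularity. Scoring sibships may drop to size 1; they remain scorable.
#'
#' @param individuals Tibble of individuals; every family must have at least
#'   2 members.
#' @param seed Integer seed making the split reproducible (optional).
#' @return A list with tibbles `validation` (one row per family) and
#'   `scoring` (the rest).
#' @export
holdout_split <- function(individuals, seed = NULL) {
  validate_individuals(individuals)
  sizes <- table(individuals$family_id)
  if (any(sizes < 2)) {
    abort(sprintf("Sibship(s) with fewer than 2 members: %s.",
                  paste(utils::head(names(sizes)[sizes < 2], 5L),
                        collapse = ", ")))
  }
  picked <- with_seed_if(seed, {
    individuals |>
      dplyr::mutate(.row = dplyr::row_number()) |>
      dplyr::slice_sample(n = 1, by = "family_id") |>
      dplyr::pull(.data$.row)
  })
  list(validation = individuals[picked, , drop = FALSE],
       scoring = individuals[-picked, , drop = FALSE])
}

#' Per-family sufficient statistics for the longevity indicators
#'
#' The random-intercept logistic model depends on a family's indicator
#' vector only through the number of long-lived members `k` and the family
#' size `n`.
#'
#' @param individuals Tibble with a `longevous` column (see
#'   [annotate_longevity()]).
#' @return Tibble with columns `family_id`, `k`, `n`.
#' @export
family_stats <- function(individuals) {
  if (!"longevous" %in% names(individuals)) {
    abort("`individuals` must carry a `longevous` column; run annotate_longevity().")
  }
  individuals |>
    dplyr::summarise(k = sum(.data$longevous), n = dplyr::n(),
                     .by = "family_id") |>
    dplyr::arrange(.data$family_id)
}
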