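#' Build a reference lifetable from a data frame
#'
#' A lifetable gives, for each stratum defined by sex and birth cohort, the
#' probability of surviving to each tabulated age in a reference population.
#' It is the source of the survival percentiles \eqn{P = 1 - S(t \mid
#' \mathrm{cohort}, \mathrm{sex})} on which all longevity scores are based.
#'
#' Birth cohorts may be given as single years (`1890`) or as band labels
#' (`"1890-1899"`); bands are matched by their midpoint. Queries for a birth
#' year that is not tabulated are matched to the nearest tabulated cohort,
#' with ties resolved toward the earlier cohort.
#'
#' @param data A data frame with one row per (sex, birth cohort, age) giving
#'   the survival probability at that age. Column names are given by `cols`.
#' @param cols Named list mapping the roles `sex`, `birth_year`, `age`,
#'   `survival` to column names in `data`.
#' @param min_survival Smallest representable survival probability; tabulated
#'   values below it are clamped (a survival of exactly 0 would make the
#'   cumulative hazard infinite and is rejected).
#' @return A `lifetable` object (a tibble with columns `sex`, `cohort`,
#'   `cohort_center`, `age`, `survival`).
#' @examples
#' toy <- data.frame(sex = "female", birth_year = 1900,
#'                   age = c(0, 50, 99), survival = c(1, 0.6, 0.01))
#' lt <- lifetable(toy)
#' lt_survival(lt, "female", 1900, 50)
#' @export
lifetable <- function(data,
                      cols = list(sex = "sex", birth_year = "birth_year",
                                  age = "age", survival = "survival"),
                      min_survival = 1e-6) {
  missing_cols <- setdiff(unlist(cols), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Lifetable is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) == 0) abort("Lifetable has no rows.")
  lt <- tibble::tibble(
    sex = normalize_sex(data[[cols$sex]]),
    cohort = as.character(data[[cols$birth_year]]),
    age = as.numeric(data[[cols$age]]),
    survival = as.numeric(data[[cols$survival]])
  )
  lt$cohort_center <- parse_cohort(lt$cohort)
  if (anyNA(lt$age) || anyNA(lt$survival)) {
    abort("Lifetable has missing ages or survival probabilities.")
  }
  if (any(lt$survival <= 0)) {
    abort("Lifetable survival probabilities must be strictly positive.")
  }
  if (any(lt$survival > 1)) {
    abort("Lifetable survival probabilities must not exceed 1.")
  }
  lt$survival <- pmax(lt$survival, min_survival)
  lt <- dplyr::arrange(lt, .data$sex, .data$cohort_center, .data$age)
  # survival must be non-increasing in age within every stratum
  bad <- lt |>
    dplyr::summarise(ok = !is.unsorted(rev(.data$survival)),
                     .by = c("sex", "cohort"))
  bad <- bad[!bad$ok, , drop = FALSE]
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Survival is not non-increasing in age in stratum (%s).",
      paste(sprintf("%s, %s", bad$sex, bad$cohort), collapse = "; ")))
  }
  lt <- lt[, c("sex", "cohort", "cohort_center", "age", "survival")]
  structure(lt, class = c("lifetable", class(tibble::tibble())),
            min_survival = min_survival)
}

#' Read a lifetable from a CSV file
#'
#' @param path Path to a CSV file with a header row.
#' @inheritParams lifetable
#' @return A [lifetable] object.
#' @export
read_lifetable <- function(path,
                           cols = list(sex = "sex", birth_year = "birth_year",
                                       age = "age", survival = "survival"),
                           min_survival = 1e-6) {
  data <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(sprintf("Cannot read lifetable CSV '%s': %s",
                                      path, conditionMessage(e)))
  )
  if (nrow(data) == 0) abort(sprintf("Lifetable file '%s' is empty.", path))
  lifetable(data, cols = cols, min_survival = min_survival)
}

# "1890" -> 1890; "1890-1899" (or en-dash) -> 1894.5
parse_cohort <- function(x) {
  x <- trimws(x)
  out <- suppressWarnings(as.numeric(x))
  band <- is.na(out) & grepl("^[0-9]{3,4}\\s*[-–]\\s*[0-9]{3,4}$", x)
  if (any(band)) {
    parts <- strsplit(x[band], "[-–]")
    out[band] <- vapply(parts, function(p) mean(as.numeric(trimws(p))), 0)
  }
  if (anyNA(out)) {
    abort(sprintf("Cannot parse birth cohort label(s): %s.",
                  paste(unique(x[is.na(out)]), collapse = ", ")))
  }
  out
}

#' @export
print.lifetable <- function(x, ...) {
  strata <- dplyr::distinct(tibble::as_tibble(x), .data$sex, .data$cohort)
  cat(sprintf("<lifetable> %d strata (%s), ages %g-%g\n",
              nrow(strata),
              paste(sort(unique(strata$sex)), collapse = "/"),
              min(x$age), max(x$age)))
  NextMethod()
}

# nearest-cohort matching; ties go to the earlier cohort
match_cohort <- function(centers, birth_year) {
  # ties: earlier (smaller) center wins because max.col(ties.method="first")
  # scans in column order and centers are sorted ascending
  centers_sorted <- sort(unique(centers))
  d <- abs(outer(birth_year, centers_sorted, "-"))
  centers_sorted[max.col(-d, ties.method = "first")]
}

#' Survival probability at a given age
#'
#' Looks up \eqn{S(t \mid \mathrm{cohort}, \mathrm{sex})} with linear
#' interpolation on the survival scale between tabulated ages. Ages above a
#' stratum's maximum tabulated age return the terminal survival value; ages
#' below the minimum are interpolated against survival 1 at age 0. All
#' arguments are vectorized and recycled to a common length.
#'
#' @param lt A [lifetable].
#' @param sex Sex codes (`"female"`/`"male"`, or `f/m/1/2`).
#' @param birth_year Birth years; matched to the nearest tabulated cohort.
#' @param age Ages in years, `>= 0`.
#' @return Numeric vector of survival probabilities in `(0, 1]`.
#' @export
lt_survival <- function(lt, sex, birth_year, age) {
  if (!inherits(lt, "lifetable")) abort("`lt` must be a lifetable object.")
  n <- max(length(sex), length(birth_year), length(age))
  sex <- rep_len(normalize_sex(sex), n)
  birth_year <- rep_len(as.numeric(birth_year), n)
  age <- rep_len(as.numeric(age), n)
  if (any(is.na(age)) || any(age < 0)) abort("`age` must be >= 0.")

  out <- rep(NA_real_, n)
  capped <- FALSE
  for (s in unique(sex)) {
    block <- lt[lt$sex == s, , drop = FALSE]
    if (nrow(block) == 0) {
      abort(sprintf("Lifetable has no stratum for sex '%s'.", s))
    }
    i_s <- which(sex == s)
    matched <- match_cohort(unique(block$cohort_center), birth_year[i_s])
    for (cc in unique(matched)) {
      i <- i_s[matched == cc]
      grid <- block[block$cohort_center == cc, , drop = FALSE]
      ages <- grid$age
      surv <- grid$survival
      if (min(ages) > 0) {
        ages <- c(0, ages)
        surv <- c(1, surv)
      }
      above <- age[i] > max(ages)
      if (any(above)) capped <- TRUE
      out[i] <- approx(ages, surv, xout = pmin(age[i], max(ages)),
                       method = "linear", rule = 2)$y
    }
  }
  if (capped) {
    inform("Some ages exceed the lifetable maximum; terminal survival used.",
           .frequency = "once", .frequency_id = "famscore_lt_cap")
  }
  pmax(out, attr(lt, "min_survival") %||% 1e-6)
}

#' Cumulative hazard at a given age
#'
#' \eqn{\Lambda(t) = -\log S(t)} under the matched stratum.
#'
#' @inheritParams lt_survival
#' @return Numeric vector of cumulative hazards, `>= 0`.
#' @export
lt_cumulative_hazard <- function(lt, sex, birth_year, age) {
  -log(lt_survival(lt, sex, birth_year, age))
}

#' Survival percentile at a given age
#'
#' \eqn{P = 1 - S(t)}: the fraction of the reference cohort already dead at
#' age `t`. A value of 0.9 or more marks an individual among the top 10%
#' survivors of their sex-specific birth cohort.
#'
#' @inheritParams lt_survival
#' @return Numeric vector of percentiles in `[0, 1)`.
#' @export
lt_percentile <- function(lt, sex, birth_year, age) {
  1 - lt_survival(lt, sex, birth_year, age)
}

#' Survival probability conditional on being alive at an age
#'
#' \eqn{S(t)/S(t_0)} for a conditioning age \eqn{t_0 \le t}. Conditioning on
#' survival to, say, age 40 shifts the reference point of the
#' survival-exceptionality score toward older ages.
#'
#' @inheritParams lt_survival
#' @param conditioning_age Age(s) the individual is known to have reached.
#' @return Numeric vector of conditional survival probabilities in `(0, 1]`.
#' @export
lt_conditional_survival <- function(lt, sex, birth_year, age, conditioning_age) {
  n <- max(length(sex), length(birth_year), length(age),
           length(conditioning_age))
  age <- rep_len(as.numeric(age), n)
  conditioning_age <- rep_len(as.numeric(conditioning_age), n)
  if (any(conditioning_age < 0)) abort("`conditioning_age` must be >= 0.")
  if (any(age < conditioning_age)) {
    abort("`age` must be at least `conditioning_age`.")
  }
  lt_survival(lt, sex, birth_year, age) /
    lt_survival(lt, sex, birth_year, conditioning_age)
}

#' Synthetic Gompertz reference lifetable
#'
#' Builds a lifetable from a Gompertz proportional-hazards model,
#' \eqn{S(t) = \exp\{-\frac{a}{b}(e^{bt}-1)\, e^{\eta}\}} with
#' \eqn{\eta = \log(\mathrm{HR}_{male})\,[\mathrm{sex=male}] +
#' \gamma\,(\mathrm{cohort}-\mathrm{ref})}. It is the reference population
#' used by [generate_hsn_like()], which draws lifespans from the same model,
#' so annotation of the synthetic data against this table is coherent.
#'
#' @param cohorts Integer vector of tabulated birth cohorts.
#' @param ages Integer vector of tabulated ages.
#' @param gompertz_a,gompertz_b Baseline Gompertz rate and shape (female,
#'   reference cohort).
#' @param hr_male Hazard ratio for males.
#' @param year_trend Additive log-hazard change per birth year (secular
#'   mortality decline when negative).
#' @param ref_year Reference birth year for the trend.
#' @param min_survival Passed to [lifetable()].
#' @return A [lifetable] object with `2 * length(cohorts)` strata.
#' @export
synthetic_lifetable <- function(cohorts = seq(1860, 1910, by = 5),
                                ages = 0:110,
                                gompertz_a = 1e-4, gompertz_b = 0.08,
                                hr_male = 1.4, year_trend = -0.005,
                                ref_year = 1880, min_survival = 1e-6) {
  grid <- expand.grid(sex = c("female", "male"), birth_year = cohorts,
                      age = ages, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  eta <- log(hr_male) * (grid$sex == "male") +
    year_trend * (grid$birth_year - ref_year)
  H0 <- gompertz_a / gompertz_b * (exp(gompertz_b * grid$age) - 1)
  grid$survival <- pmax(exp(-H0 * exp(eta)), min_survival)
  lifetable(grid, min_survival = min_survival)
}

# invert the same Gompertz PH model: lifespan for unit-exponential draw e
gompertz_lifespan <- function(e, eta, gompertz_a = 1e-4, gompertz_b = 0.08,
                              max_age = 110) {
  t <- log(1 + gompertz_b * e / (gompertz_a * exp(eta))) / gompertz_b
  pmin(t, max_age)
}
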