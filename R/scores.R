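#' Per-member survival exceptionality
#'
#' \eqn{SE = -\log S - 1 = \Lambda - 1}: the cumulative hazard at death
#' minus one. It is \eqn{-1} when \eqn{S = 1}, zero when \eqn{S = e^{-1}
#' \approx 0.37} (so members dying beyond the top 37% survivors contribute
#' positively), and grows without bound as \eqn{S \to 0}.
#'
#' @param survival_prob Survival probabilities in `(0, 1]`.
#' @return Numeric vector of exceptionality contributions in `[-1, Inf)`.
#' @export
se_contribution <- function(survival_prob) {
  if (!is.numeric(survival_prob) || anyNA(survival_prob) ||
      any(survival_prob <= 0) || any(survival_prob > 1)) {
    abort("`survival_prob` must lie in (0, 1].")
  }
  -log(survival_prob) - 1
}

new_score_set <- function(family_id, size, value, score, threshold = NA_real_) {
  tibble::tibble(family_id = as.character(family_id),
                 size = as.integer(size),
                 score = score,
                 value = as.numeric(value),
                 threshold = threshold)
}

#' Family survival-exceptionality sum (SE_f)
#'
#' Sums [se_contribution()] over the members of each sibship. The sum makes
#' the score additive in members: appending a member with survival above
#' \eqn{e^{-1}} always increases it, so large families with no long-lived
#' members can outscore small families of long-lived ones. The score is
#' provided for comparison with the proportion-based scores; the
#' living-member bonus of its descendants is a documented extension point,
#' not implemented here.
#'
#' @param individuals Tibble of individuals with observed ages at death.
#' @param lt A [lifetable].
#' @param conditioning_age If non-`NULL`, use survival conditional on
#'   reaching this age.
#' @return A score tibble with columns `family_id`, `size`, `score`
#'   (`"SE_f"`), `value`, `threshold` (`NA`).
#' @export
score_sef <- function(individuals, lt, conditioning_age = NULL) {
  validate_individuals(individuals)
  if (any(individuals$alive) || anyNA(individuals$age_at_death)) {
    abort("SE_f requires observed ages at death for all members (censoring is out of scope).")
  }
  surv <- if (is.null(conditioning_age)) {
    lt_survival(lt, individuals$sex, individuals$birth_year,
                individuals$age_at_death)
  } else {
    lt_conditional_survival(lt, individuals$sex, individuals$birth_year,
                            individuals$age_at_death, conditioning_age)
  }
  agg <- individuals |>
    dplyr::mutate(.se = se_contribution(surv)) |>
    dplyr::summarise(value = sum(.data$.se), size = dplyr::n(),
                     .by = "family_id") |>
    dplyr::arrange(.data$family_id)
  new_score_set(agg$family_id, agg$size, agg$value, "SE_f")
}

#' Longevity Relatives Count (LRC)
#'
#' The proportion of a sibship's members whose survival percentile reaches
#' the longevity threshold:
#' \deqn{LRC_i = \frac{1}{N_i}\sum_{j=1}^{N_i} I(P_{ij} \ge c).}
#' Bounded in `[0, 1]` and invariant to how far percentiles sit above or
#' below `c`. Because it is an empirical proportion, small families reach
#' extreme values more easily than large ones.
#'
#' @param individuals Tibble of individuals carrying either a `longevous`
#'   indicator or a `percentile` column (see [annotate_longevity()]).
#' @param threshold Longevity threshold `c` (used when only percentiles are
#'   present; inclusive).
#' @return A score tibble with columns `family_id`, `size`, `score`
#'   (`"LRC"`), `value`, `threshold`.
#' @export
score_lrc <- function(individuals, threshold = 0.9) {
  stopifnot_scalar_prob(threshold, "threshold")
  if (nrow(individuals) == 0) abort("No individuals to score.")
  y <- if ("longevous" %in% names(individuals)) {
    individuals$longevous
  } else if ("percentile" %in% names(individuals)) {
    as.integer(individuals$percentile >= threshold)
  } else {
    abort("`individuals` must carry a `longevous` or `percentile` column.")
  }
  agg <- individuals |>
    dplyr::mutate(.y = y) |>
    dplyr::summarise(value = mean(.data$.y), size = dplyr::n(),
                     .by = "family_id") |>
    dplyr::arrange(.data$family_id)
  new_score_set(agg$family_id, agg$size, agg$value, "LRC", threshold)
}

#' Write a score tibble to CSV
#'
#' @param scores A score tibble (from [score_sef()], [score_lrc()] or
#'   [score_mlrc()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  readr::write_csv(scores, path)
  invisible(path)
}
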