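#' Survival evaluation of a family selection on holdout individuals
#'
#' Fits a Cox proportional-hazards model to the validation individuals'
#' lifespans with the selection indicator ("member of a selected family")
#' as the explanatory variable, adjusted for sex and birth cohort. A
#' negative coefficient means members of selected families live longer.
#' All lifespans must be complete (extinct cohorts), so no censoring term
#' enters the model.
#'
#' @param validation Tibble of holdout individuals with complete
#'   `age_at_death`.
#' @param selection A [family_selection][select_top] (or a character vector
#'   of selected family ids).
#' @param adjust Covariates to adjust for (subset of `"sex"`,
#'   `"birth_year"`).
#' @param cohort_as `"linear"` enters birth year as a continuous term,
#'   `"decade"` as a factor of decades.
#' @return A one-row tibble: `score`, `rule`, `estimate` (log hazard
#'   ratio), `std_error`, `n_validation`.
#' @export
evaluate_selection <- function(validation, selection,
                               adjust = c("sex", "birth_year"),
                               cohort_as = c("linear", "decade")) {
  cohort_as <- match.arg(cohort_as)
  if (anyNA(validation$age_at_death)) {
    abort("Validation individuals must have complete ages at death.")
  }
  sel_ids <- if (inherits(selection, "family_selection")) selection$selected
             else as.character(selection)
  df <- validation |>
    dplyr::mutate(selected = .data$family_id %in% sel_ids,
                  decade = factor(10 * (.data$birth_year %/% 10)))
  if (all(df$selected) || !any(df$selected)) {
    abort("Selection is constant across the validation set; the hazard ratio is not identifiable.")
  }
  terms <- "selected"
  if ("sex" %in% adjust) terms <- c(terms, "sex")
  if ("birth_year" %in% adjust) {
    terms <- c(terms, if (cohort_as == "linear") "birth_year" else "decade")
  }
  fml <- as.formula(paste("survival::Surv(age_at_death) ~",
                          paste(terms, collapse = " + ")))
  fit <- tryCatch(survival::coxph(fml, data = df),
                  error = function(e) {
                    abort(sprintf("Cox model failed: %s", conditionMessage(e)))
                  })
  co <- summary(fit)$coefficients
  rule <- if (inherits(selection, "family_selection")) {
    if (selection$rule$type == "threshold") {
      sprintf(">= %g", selection$rule$threshold)
    } else {
      sprintf("top %g%%", 100 * selection$rule$fraction)
    }
  } else "custom"
  score <- if (inherits(selection, "family_selection")) selection$score_name
           else NA_character_
  tibble::tibble(score = score, rule = rule,
                 estimate = co["selectedTRUE", "coef"],
                 std_error = co["selectedTRUE", "se(coef)"],
                 n_validation = nrow(df))
}

#' Holdout validation pipeline for LRC and mLRC selections
#'
#' The full workflow used to compare the two proportion-based scores on
#' sibship data: set one random member of every sibship aside as a
#' validation individual, annotate the remaining siblings against the
#' lifetable, compute LRC and mLRC, select long-lived families by each
#' score (fixed thresholds or a common top fraction), and test each
#' selection against the validation individuals' survival with a
#' sex- and birth-cohort-adjusted Cox model. Validation individuals never
#' contribute to the scores.
#'
#' @param individuals Tibble of filtered sibship individuals (every family
#'   of size `>= 2`, all ages at death observed).
#' @param lt Reference [lifetable].
#' @param mode `"threshold"` (default: LRC `>= 0.3`, mLRC `>= 0.15`) or
#'   `"top_fraction"` (a common top fraction for both scores).
#' @param thresholds Named vector `c(LRC = , mLRC = )` for threshold mode.
#' @param top_fraction Fraction for top-fraction mode.
#' @param longevity_threshold Percentile threshold defining a long-lived
#'   member.
#' @param cohort_as Birth-cohort adjustment: `"linear"` or `"decade"`.
#' @param quadrature_order Gauss-Hermite order for the mLRC fit.
#' @param seed Seed controlling the holdout split and tie-breaks.
#' @return A two-row tibble (LRC, mLRC) as from [evaluate_selection()],
#'   with the mLRC fit and the implied selection thresholds in attributes
#'   `fit` and `implied_thresholds`.
#' @export
run_hsn_pipeline <- function(individuals, lt,
                             mode = c("threshold", "top_fraction"),
                             thresholds = c(LRC = 0.3, mLRC = 0.15),
                             top_fraction = 0.15,
                             longevity_threshold = 0.9,
                             cohort_as = c("linear", "decade"),
                             quadrature_order = 30, seed = NULL) {
  mode <- match.arg(mode)
  cohort_as <- match.arg(cohort_as)
  split <- holdout_split(individuals, seed = seed)
  stopifnot(length(intersect(split$validation$individual_id,
                             split$scoring$individual_id)) == 0)
  scoring <- annotate_longevity(split$scoring, lt,
                                threshold = longevity_threshold)
  lrc <- score_lrc(scoring, threshold = longevity_threshold)
  mlrc <- score_mlrc(scoring, threshold = longevity_threshold,
                     quadrature_order = quadrature_order)
  selections <- if (mode == "threshold") {
    list(LRC = select_threshold(lrc, thresholds[["LRC"]]),
         mLRC = select_threshold(mlrc, thresholds[["mLRC"]]))
  } else {
    list(LRC = select_top(lrc, top_fraction, ties = "random",
                          seed = if (is.null(seed)) NULL else seed + 1L),
         mLRC = select_top(mlrc, top_fraction, ties = "random",
                           seed = if (is.null(seed)) NULL else seed + 2L))
  }
  out <- dplyr::bind_rows(
    evaluate_selection(split$validation, selections$LRC,
                       cohort_as = cohort_as),
    evaluate_selection(split$validation, selections$mLRC,
                       cohort_as = cohort_as))
  attr(out, "fit") <- attr(mlrc, "fit")
  attr(out, "implied_thresholds") <-
    c(LRC = selections$LRC$implied_threshold,
      mLRC = selections$mLRC$implied_threshold)
  out
}
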