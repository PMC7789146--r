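#' Configuration for the family-longevity simulation design
#'
#' The benchmark design generates sibships whose members' survival
#' percentiles are driven by a latent family effect: per family,
#' \eqn{u_i \sim N(0, \mathrm{re\_sd}^2)}; given \eqn{u_i}, each member's
#' survival probability is an independent draw from
#' \eqn{\mathrm{Beta}(a,\; a\,e^{-(1+u_i)})}. Low `u` pushes the draws
#' toward 0 (exceptional survival), so the families with the lowest `u` are
#' the most enriched for longevity. A member is long-lived when its
#' percentile \eqn{P = 1 - S} reaches `threshold`.
#'
#' `u_direction = "flipped"` instead treats the Beta draw as the percentile
#' itself with the sign of `u` reversed (so low `u` remains the long-lived
#' direction); it is provided because the two conventions are easy to
#' confuse and give different marginal indicator rates.
#'
#' @param family_sizes Named integer vector: `counts` of families per
#'   `size` (names). Default: 200 families each of sizes 2, 3, 8, 10, 14.
#' @param re_sd Standard deviation of the family random effect.
#' @param a First Beta shape parameter.
#' @param threshold Longevity threshold on the percentile scale.
#' @param u_direction `"low_enriched"` (default) or `"flipped"`, see above.
#' @return A `sim_config` list.
#' @export
sim_config <- function(family_sizes = c(`2` = 200, `3` = 200, `8` = 200,
                                        `10` = 200, `14` = 200),
                       re_sd = 2, a = exp(0.1), threshold = 0.9,
                       u_direction = c("low_enriched", "flipped")) {
  sizes <- as.integer(names(family_sizes))
  counts <- as.integer(family_sizes)
  if (anyNA(sizes) || any(sizes < 1)) {
    abort("`family_sizes` must be a named vector: names are sizes.")
  }
  if (any(counts < 1)) abort("Family counts must be positive.")
  if (re_sd < 0) abort("`re_sd` must be >= 0.")
  if (a <= 0) abort("`a` must be > 0.")
  stopifnot_scalar_prob(threshold, "threshold", open0 = TRUE, open1 = TRUE)
  structure(list(sizes = sizes, counts = counts, re_sd = re_sd, a = a,
                 threshold = threshold,
                 u_direction = match.arg(u_direction)),
            class = "sim_config")
}

#' Generate a synthetic population of sibships
#'
#' Draws one population under a [sim_config()]: a latent effect per family
#' and conditionally independent member percentiles (see [sim_config()] for
#' the model). The returned individuals carry `percentile` and `longevous`
#' columns and can be scored directly with [score_lrc()] and
#' [score_mlrc()].
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (optional); the population is fully reproducible
#'   from it.
#' @return A `sim_population`: list with `individuals` (tibble:
#'   `family_id`, `individual_id`, `size`, `survival`, `percentile`,
#'   `longevous`), `effects` (tibble: `family_id`, `u`) and the `config`.
#' @export
generate_population <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_fam <- sum(config$counts)
  sizes <- rep(config$sizes, config$counts)
  fam_id <- sprintf("F%0*d", nchar(n_fam), seq_len(n_fam))
  with_seed_if(seed, {
    u <- rnorm(n_fam, 0, config$re_sd)
    ue <- rep(u, sizes)
    a <- config$a
    if (config$u_direction == "low_enriched") {
      surv <- rbeta(length(ue), a, a * exp(-(1 + ue)))
      perc <- 1 - surv
    } else {
      perc <- rbeta(length(ue), a, a * exp(-(1 - ue)))
      surv <- 1 - perc
    }
    individuals <- tibble::tibble(
      family_id = rep(fam_id, sizes),
      individual_id = paste0(rep(fam_id, sizes), "-",
                             unlist(lapply(sizes, seq_len))),
      size = rep(sizes, sizes),
      survival = surv,
      percentile = perc,
      longevous = as.integer(perc >= config$threshold))
    structure(list(individuals = individuals,
                   effects = tibble::tibble(family_id = fam_id, u = u),
                   config = config, seed = seed),
              class = "sim_population")
  })
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf(
    "<sim_population> %d families, %d individuals, indicator rate %.3f\n",
    nrow(x$effects), nrow(x$individuals), mean(x$individuals$longevous)))
  invisible(x)
}

#' Families defined as truly long-lived
#'
#' The fraction of families with the lowest latent effect `u` — the ground
#' truth a score-based selection is judged against. Ties in `u` are broken
#' by `family_id` (lexicographically smaller first).
#'
#' @param pop A `sim_population` (or a tibble with `family_id` and `u`).
#' @param fraction Fraction of families to label, in `(0, 1)`.
#' @param count_rule How to turn `fraction * N` into a count.
#' @return Character vector of family ids.
#' @export
truly_long_lived <- function(pop, fraction,
                             count_rule = c("round", "floor", "ceiling")) {
  stopifnot_scalar_prob(fraction, "fraction", open0 = TRUE, open1 = TRUE)
  count_rule <- match.arg(count_rule)
  eff <- if (inherits(pop, "sim_population")) pop$effects else pop
  m <- switch(count_rule, round = round(fraction * nrow(eff)),
              floor = floor(fraction * nrow(eff)),
              ceiling = ceiling(fraction * nrow(eff)))
  if (m < 1) abort("`fraction` selects no family.")
  eff$family_id[order(eff$u, eff$family_id)][seq_len(m)]
}

#' Generate a synthetic historical sibship dataset
#'
#' A stand-in for a non-public historical population register: sibships
#' with sexes, birth years and complete lifespans, in which a fixed
#' fraction of families carries a longevity advantage. The advantage is a
#' proportional-hazards effect (`log_hr`, negative = protective) shared by
#' all members of a long-lived family, so it simultaneously raises members'
#' survival percentiles (relative to the reference [synthetic_lifetable()])
#' and lowers the hazard of any held-out member — the structure the holdout
#' validation pipeline is designed to detect.
#'
#' Sibship sizes are drawn as 1 + Poisson, zero-truncated to a minimum of
#' 2, with the Poisson rate solved so that the expected size equals
#' `mean_size`.
#'
#' @param n_families Number of sibships.
#' @param mean_size Expected sibship size.
#' @param prop_long_lived Fraction of families with the longevity
#'   advantage.
#' @param log_hr Log hazard ratio of members of long-lived families.
#' @param frailty_sd Standard deviation of an additional continuous
#'   family-level log-frailty, independent of the long-lived flag. It
#'   emulates the continuous familial clustering of lifespan seen in real
#'   registers: siblings of a low-frailty family are jointly long-lived,
#'   which is the signal the scores rank and the holdout member inherits.
#'   Set to 0 for the purely binary design.
#' @param birth_range Range of family founding birth years.
#' @param lt Reference lifetable; defaults to [synthetic_lifetable()], the
#'   population the lifespans are drawn from.
#' @param seed Integer seed (optional).
#' @return An `hsn_population`: list with `individuals` (family CSV
#'   dialect columns), `truth` (tibble: `family_id`, `long_lived`) and the
#'   reference `lifetable`.
#' @export
generate_hsn_like <- function(n_families = 1105, mean_size = 4.85,
                              prop_long_lived = 0.15, log_hr = -0.3,
                              frailty_sd = 0.5,
                              birth_range = c(1860, 1905),
                              lt = synthetic_lifetable(), seed = NULL) {
  if (mean_size <= 2) abort("`mean_size` must exceed 2.")
  stopifnot_scalar_prob(prop_long_lived, "prop_long_lived",
                        open0 = TRUE, open1 = TRUE)
  # rate of the shifted Poisson so that E[size | size >= 2] = mean_size
  lam <- stats::uniroot(function(l) l / (1 - exp(-l)) - (mean_size - 1),
                        c(1e-6, 4 * mean_size))$root
  with_seed_if(seed, {
    sizes <- 1L + stats::rpois(n_families, lam)
    while (any(sizes < 2)) {
      sizes[sizes < 2] <- 1L + stats::rpois(sum(sizes < 2), lam)
    }
    fam_id <- sprintf("H%0*d", nchar(n_families), seq_len(n_families))
    n_long <- max(1L, round(prop_long_lived * n_families))
    long_ids <- sample(fam_id, n_long)
    long <- fam_id %in% long_ids

    base_year <- sample(seq(birth_range[1], birth_range[2]), n_families,
                        replace = TRUE)
    total <- sum(sizes)
    fam_of <- rep(seq_len(n_families), sizes)
    birth_year <- pmin(rep(base_year, sizes) +
                         unlist(lapply(sizes, function(s) {
                           cumsum(c(0L, sample(1:3, s - 1L, replace = TRUE)))
                         })),
                       birth_range[2] + 10)
    sex <- sample(c("female", "male"), total, replace = TRUE)
    frailty <- rnorm(n_families, 0, frailty_sd)
    eta <- log(1.4) * (sex == "male") - 0.005 * (birth_year - 1880) +
      rep(log_hr * long + frailty, sizes)
    age <- gompertz_lifespan(rexp(total), eta)
    individuals <- tibble::tibble(
      family_id = rep(fam_id, sizes),
      individual_id = paste0(rep(fam_id, sizes), "-",
                             unlist(lapply(sizes, seq_len))),
      sex = sex,
      birth_year = as.integer(birth_year),
      age_at_death = age,
      alive = FALSE)
    structure(list(individuals = individuals,
                   truth = tibble::tibble(family_id = fam_id,
                                          long_lived = long,
                                          frailty = frailty),
                   lifetable = lt, seed = seed),
              class = "hsn_population")
  })
}

#' Write a simulated population to CSV files
#'
#' The individuals go to `path` (percentile dialect for a
#' `sim_population`, family dialect for an `hsn_population`); the latent
#' truth goes to `effects_path` when given.
#'
#' @param pop A `sim_population` or `hsn_population`.
#' @param path Output CSV for individuals.
#' @param effects_path Optional output CSV for the per-family truth.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path, effects_path = NULL) {
  readr::write_csv(pop$individuals, path)
  if (!is.null(effects_path)) {
    truth <- if (inherits(pop, "sim_population")) pop$effects else pop$truth
    readr::write_csv(truth, effects_path)
  }
  invisible(path)
}
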