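# In-code fixtures shared across test files.

# one female stratum (cohort 1900) anchored at round survival values
toy_lifetable <- function() {
  lifetable(data.frame(
    sex = "female", birth_year = 1900,
    age = c(0, 50, 99),
    survival = c(1, 0.6, 0.01)))
}

# exact-grid stratum hitting the survival anchors used by the score tests
anchor_lifetable <- function() {
  lifetable(data.frame(
    sex = "female", birth_year = 1900,
    age = c(0, 40, 70, 95, 99),
    survival = c(1, exp(-1), 0.30, 0.05, 0.01)))
}

make_individuals <- function(family_sizes, ages, sex = "female",
                             birth_year = 1900L) {
  fam <- rep(sprintf("fam%02d", seq_along(family_sizes)), family_sizes)
  tibble::tibble(
    family_id = fam,
    individual_id = paste0(fam, "-", unlist(lapply(family_sizes, seq_len))),
    sex = sex,
    birth_year = as.integer(birth_year),
    age_at_death = ages,
    alive = FALSE)
}

write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path)
  path
}
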