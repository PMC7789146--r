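test_that("family CSVs are read, grouped and sex codes normalized", {
  df <- data.frame(
    family_id = c("A", "A", "A", "B", "B"),
    individual_id = c("a1", "a2", "a3", "b1", "b2"),
    sex = c("f", "M", "2", "1", "female"),
    birth_year = 1900,
    age_at_death = c(70, 80, 90, 60, 65),
    alive = 0)
  fam <- read_families(write_temp_csv(df))
  expect_equal(nrow(fam), 5)
  expect_equal(as.vector(table(fam$family_id)), c(3, 2))
  expect_equal(fam$sex, c("female", "male", "female", "male", "female"))

  df_dup <- df
  df_dup$individual_id[2] <- "a1"
  expect_error(read_families(write_temp_csv(df_dup)), "Duplicated")

  empty <- read_families(write_temp_csv(df[0, ]))
  expect_equal(nrow(empty), 0)
})

test_that("exclusion filters drop missing ages, non-extinct cohorts, singletons", {
  ind <- make_individuals(c(2, 2), ages = c(70, NA, 80, 85))
  ind$alive[2] <- TRUE
  out <- apply_filters(ind, reference_year = 2017, max_age = 110)
  # the missing-age member makes its sibship a singleton: both rows gone
  expect_equal(sort(unique(out$family_id)), "fam02")
  rep <- exclusion_report(out)
  expect_equal(rep$n_individuals[rep$reason == "missing_age_at_death"], 1L)
  expect_equal(rep$n_individuals[rep$reason == "singleton_sibship"], 1L)

  # born 1950, max age 110: cohort not extinct at 2017
  ind2 <- make_individuals(c(2, 2), ages = c(70, 75, 80, 85),
                           birth_year = c(1950L, 1900L, 1900L, 1900L))
  out2 <- apply_filters(ind2, reference_year = 2017, max_age = 110)
  rep2 <- exclusion_report(out2)
  expect_equal(rep2$n_individuals[rep2$reason == "non_extinct_cohort"], 1L)
  expect_false("fam01" %in% out2$family_id)

  # clean data passes through identically with an empty report
  ind3 <- make_individuals(c(2, 3), ages = c(70, 75, 80, 85, 90))
  out3 <- apply_filters(ind3)
  expect_equal(nrow(out3), 5)
  expect_equal(nrow(exclusion_report(out3)), 0)
})

test_that("annotation assigns percentiles and inclusive-threshold indicators", {
  lt <- anchor_lifetable()
  ind <- make_individuals(3, ages = c(95, 70, 40))  # S = 0.05, 0.30, e^-1
  ann <- annotate_longevity(ind, lt, threshold = 0.9)
  expect_equal(ann$percentile, c(0.95, 0.70, 1 - exp(-1)))
  expect_equal(ann$longevous, c(1L, 0L, 0L))
  # boundary is inclusive: P = 0.95 with c = 0.95 counts as long-lived
  ann95 <- annotate_longevity(ind, lt, threshold = 0.95)
  expect_equal(ann95$longevous[1], 1L)
  # raising the threshold never turns an indicator on
  for (c2 in c(0.5, 0.7, 0.9, 0.99)) {
    a_lo <- annotate_longevity(ind, lt, threshold = c2)
    a_hi <- annotate_longevity(ind, lt, threshold = min(c2 + 0.05, 1))
    expect_true(all(a_hi$longevous <= a_lo$longevous))
  }
  # alive members cannot be annotated
  ind_alive <- ind
  ind_alive$alive[1] <- TRUE
  ind_alive$age_at_death[1] <- NA
  expect_error(annotate_longevity(ind_alive, lt), "age at death")
  # missing sex stratum names the offenders
  ind_m <- make_individuals(2, ages = c(70, 80), sex = "male")
  expect_error(annotate_longevity(ind_m, lt), "fam01-1")
})

test_that("holdout split moves exactly one member per family, reproducibly", {
  ind <- make_individuals(rep(c(2, 3, 5), times = 10),
                          ages = rep(70, 100))
  sp <- holdout_split(ind, seed = 11)
  expect_equal(nrow(sp$validation), 30)
  expect_equal(nrow(sp$scoring), 70)
  expect_equal(sort(unique(sp$validation$family_id)),
               sort(unique(ind$family_id)))
  # conservation, disjointness, determinism
  expect_setequal(c(sp$validation$individual_id, sp$scoring$individual_id),
                  ind$individual_id)
  expect_length(intersect(sp$validation$individual_id,
                          sp$scoring$individual_id), 0)
  sp2 <- holdout_split(ind, seed = 11)
  expect_identical(sp$validation$individual_id,
                   sp2$validation$individual_id)
  sp3 <- holdout_split(ind, seed = 12)
  expect_false(identical(sp$validation$individual_id,
                         sp3$validation$individual_id))
  # three families of size 2 -> scoring drops to singletons but remains
  small <- make_individuals(c(2, 2, 2), ages = rep(70, 6))
  spsm <- holdout_split(small, seed = 1)
  expect_equal(nrow(spsm$validation), 3)
  expect_equal(nrow(spsm$scoring), 3)
  expect_error(holdout_split(make_individuals(c(1, 2), ages = rep(70, 3))),
               "fewer than 2")
})

test_that("family_stats reduces indicators to (k, n)", {
  ind <- make_individuals(c(3, 2), ages = rep(70, 5))
  ind$longevous <- c(1L, 1L, 0L, 0L, 0L)
  st <- family_stats(ind)
  expect_equal(st$k, c(2L, 0L))
  expect_equal(st$n, c(3L, 2L))
  expect_error(family_stats(make_individuals(2, ages = c(70, 80))),
               "longevous")
})
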