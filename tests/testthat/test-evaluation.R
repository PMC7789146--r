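score_fixture <- function(values, sizes = rep(2L, length(values)),
                          name = "LRC") {
  tibble::tibble(family_id = sprintf("F%03d", seq_along(values)),
                 size = sizes, score = name, value = values,
                 threshold = 0.9)
}

test_that("top-fraction selection counts and tie rules behave", {
  sc <- score_fixture(seq(0, 1, length.out = 1000))
  sel <- select_top(sc, 0.10, seed = 1)
  expect_length(sel$selected, 100)
  # distinct scores: tie-break irrelevant, top values selected
  expect_setequal(sel$selected,
                  sc$family_id[order(-sc$value)][1:100])
  expect_identical(select_top(sc, 0.10, ties = "deterministic")$selected,
                   sel$selected)
  # all tied: deterministic rule prefers larger families then smaller ids
  tied <- score_fixture(rep(0.5, 6), sizes = c(2L, 14L, 8L, 14L, 2L, 8L))
  d <- select_top(tied, 0.5, ties = "deterministic")
  expect_equal(d$selected, c("F002", "F004", "F003"))
  # random mode is reproducible under a seed
  r1 <- select_top(tied, 0.5, seed = 4)
  r2 <- select_top(tied, 0.5, seed = 4)
  expect_identical(r1$selected, r2$selected)
  expect_error(select_top(score_fixture(c(0.2, 0.4)), 0.1), "no family")
})

test_that("threshold selection is inclusive at the boundary", {
  sc <- score_fixture(c(0.5, 0.3, 0.2))
  expect_setequal(select_threshold(sc, 0.3)$selected, c("F001", "F002"))
  expect_length(select_threshold(sc, 0.9)$selected, 0)
  expect_length(select_threshold(sc, 0)$selected, 3)
})

test_that("PPV is the truth fraction of the selection", {
  sc <- score_fixture(1:10 / 10)
  sel <- select_top(sc, 0.3, seed = 1)
  expect_equal(ppv(sel, sel$selected), 1)
  expect_equal(ppv(sel, c("none", "such")), 0)
  expect_error(ppv(select_threshold(sc, 2), sc$family_id), "Empty")
  # uninformative scores: PPV concentrates on the truth fraction
  set.seed(31)
  ppvs <- replicate(60, {
    random_sc <- score_fixture(runif(300))
    truth <- sample(random_sc$family_id, 30)
    ppv(select_top(random_sc, 0.10), truth)
  })
  expect_lt(abs(mean(ppvs) - 0.10), 0.02)
})

test_that("score bins report median family size, zeros excluded by default", {
  sc <- score_fixture(c(0.5, 0.1, 0.1), sizes = c(2L, 10L, 10L))
  b <- score_size_bins(sc)
  expect_equal(b$median_size[b$bin == "(0,0.1]"], 10)
  expect_equal(b$median_size[b$bin == "(0.4,0.5]"], 2)
  # zero scores are excluded unless include_zero = TRUE
  sc0 <- score_fixture(c(0, 0.05, 0.6), sizes = c(3L, 9L, 2L))
  expect_equal(sum(score_size_bins(sc0)$n_families), 2)
  b0 <- score_size_bins(sc0, include_zero = TRUE)
  expect_equal(sum(b0$n_families), 3)
  expect_equal(b0$median_size[b0$bin == "[0,0.1]"], 6)
  # single-bin degenerate case
  one <- score_size_bins(score_fixture(c(0.15, 0.12), sizes = c(4L, 8L)))
  expect_equal(nrow(one), 1)
  expect_equal(one$median_size, 6)
})

test_that("small replicated studies run, aggregate and reproduce", {
  cfg <- sim_config(family_sizes = c(`2` = 20, `3` = 10, `8` = 10,
                                     `10` = 5, `14` = 5))
  st <- suppressWarnings(
    run_simulation_study(cfg, n_reps = 2, fractions = c(0.2), seed = 5))
  expect_s3_class(st, "study_summary")
  expect_equal(nrow(st$ppv), 2 * 2 * 1)  # 2 reps x 2 scores x 1 fraction
  expect_equal(sort(unique(st$ppv$score)), c("LRC", "mLRC"))
  # aggregates recompute from the per-replicate values
  agg <- st$ppv |>
    dplyr::summarise(m = mean(ppv), .by = c(score, fraction))
  expect_equal(sort(agg$m), sort(st$ppv_summary$mean_ppv))
  st2 <- suppressWarnings(
    run_simulation_study(cfg, n_reps = 2, fractions = c(0.2), seed = 5))
  expect_identical(st$ppv, st2$ppv)
  expect_error(run_simulation_study(cfg, n_reps = 1), "n_reps")
  expect_output(print(st), "PPV")
})

test_that("study plots and score-comparison plots build", {
  cfg <- sim_config(family_sizes = c(`2` = 30, `8` = 30))
  st <- suppressWarnings(
    run_simulation_study(cfg, n_reps = 2, fractions = 0.2, seed = 3))
  expect_s3_class(autoplot(st), "ggplot")
  pop <- generate_population(cfg, seed = 2)
  p <- plot_score_comparison(score_lrc(pop$individuals),
                             suppressWarnings(score_mlrc(pop$individuals)))
  expect_s3_class(p, "ggplot")
})
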