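test_that("mean BSI is the mean gap between consecutive distinct days", {
  s <- compute_bsi(mk_table("A", day0 + c(0, 10, 30)))
  expect_equal(s$mean_bsi, 15)
  expect_equal(compute_bsi(mk_table("A", day0 + 5:8))$mean_bsi, 1)
  # a single sighting leaves the BSI undefined, not zero
  expect_true(is.na(compute_bsi(mk_table("A", day0))$mean_bsi))
  # same-day repeats collapse to one date
  rep2 <- mk_table("A", day0 + c(0, 0, 10), group = c("g1", "g2", "g3"))
  expect_equal(compute_bsi(rep2)$mean_bsi, 10)
  expect_equal(compute_bsi(rep2)$n_days, 2L)
  expect_error(compute_bsi(mk_table(c("A", "B"), day0 + 0:1)), "mix")
})

test_that("mean BSI equals (last-first)/(n-1) on random day sequences", {
  set.seed(1)
  for (i in 1:200) {
    d <- day0 + sort(sample(0:2000, sample(2:40, 1)))
    s <- compute_bsi(mk_table("A", d, study_start = day0))
    expect_equal(s$mean_bsi, mean(as.numeric(diff(d))))
    expect_equal(s$mean_bsi,
                 as.numeric(d[length(d)] - d[1]) / (length(d) - 1))
  }
})

test_that("yearly means use within-year gaps; the overall mean keeps cross-year gaps", {
  s <- compute_bsi(mk_table("A", day0 + c(300, 360, 380, 400), study_start = day0))
  expect_equal(s$mean_bsi, 100 / 3)
  expect_equal(unname(s$yearly_mean_bsi), c(60, 20))  # 300-360 | 380-400
  expect_equal(s$years_seen, c(1L, 2L))
  one_per_year <- compute_bsi(mk_table("A", day0 + c(100, 500),
                                       study_start = day0))
  expect_equal(one_per_year$mean_bsi, 400)
  expect_true(all(is.na(one_per_year$yearly_mean_bsi)))
})

test_that("strategy classification matches its definition and ignores order", {
  expect_equal(classify_strategy(mk_table("M1", day0 + 0:1)), "foraging_only")
  expect_equal(classify_strategy(mk_table("M1", day0, state = "musth")),
               "musth_only")
  both <- mk_table("M1", day0 + 0:1, state = c("foraging", "musth"))
  expect_equal(classify_strategy(both), "foraging_and_musth")
  expect_equal(classify_strategy(both[2:1, ]), "foraging_and_musth")
  expect_error(classify_strategy(both[0, ]), "zero sightings")
})

test_that("male-week scoring follows the 0/1/2 rule", {
  # musth Monday + foraging Friday in the same 7-day bin scores 2
  tab <- mk_table("M1", day0 + c(0, 4), state = c("musth", "foraging"))
  mw <- male_week_scores(tab)
  expect_equal(unname(mw$scores[1, 1]), 2L)
  # seen foraging in 3 distinct bins: 3 male-weeks, 0 musth-weeks
  tab3 <- mk_table("M1", day0 + c(0, 8, 20), study_end = day0 + 27)
  mw3 <- male_week_scores(tab3)
  expect_equal(sum(mw3$scores >= 1), 3L)
  expect_equal(sum(mw3$scores == 2), 0L)
  # unseen males score all zeros
  mw0 <- male_week_scores(mk_table("M1", day0, study_end = day0 + 27),
                          males = c("M1", "M2"))
  expect_equal(sum(mw0$scores["M2", ]), 0L)
  expect_error(male_week_scores(tab, week_origin = day0 + 1), "week_origin")
})

test_that("male-weeks seen partition into musth and foraging-only weeks", {
  set.seed(8)
  ids <- sprintf("M%02d", 1:10)
  tab <- mk_table(sample(ids, 120, replace = TRUE),
                  day0 + sample(0:364, 120, TRUE),
                  state = sample(c("foraging", "musth"), 120, TRUE,
                                 prob = c(0.8, 0.2)))
  tab <- sighting_table(tab[!duplicated(tab[c("group_id", "individual_id")]), ])
  mw <- male_week_scores(tab)
  expect_equal(sum(mw$scores >= 1),
               sum(mw$scores == 2) + sum(mw$scores == 1))
  expect_equal(sum(mw$totals$male_weeks_seen),
               sum(mw$totals$musth_weeks) + sum(mw$totals$foraging_weeks))
})

test_that("musth bouts are maximal uninterrupted runs", {
  tab <- mk_table("M1", day0 + c(90, 100, 110, 120, 130),
                  state = c("foraging", "musth", "musth", "musth", "foraging"))
  b <- musth_bouts(tab)
  expect_equal(nrow(b), 1L)
  expect_equal(b$duration, 20)
  expect_true(b$complete)
  # an intervening non-musth sighting splits the run
  tab2 <- mk_table("M1", day0 + c(100, 105, 110),
                   state = c("musth", "foraging", "musth"))
  expect_equal(nrow(musth_bouts(tab2)), 2L)
  expect_false(any(musth_bouts(tab2)$complete))
  # single bracketed musth sighting: duration 0, complete
  tab3 <- mk_table("M1", day0 + c(0, 5, 10),
                   state = c("foraging", "musth", "foraging"))
  b3 <- musth_bouts(tab3)
  expect_equal(b3$duration, 0)
  expect_true(b3$complete)
  expect_equal(nrow(musth_bouts(mk_table("M1", day0))), 0L)
})

test_that("residency requires BSI under the cutoff and multiple years", {
  mk_sum <- function(bsi, years) {
    structure(list(mean_bsi = bsi, years_seen = years), class = "bsi_summary")
  }
  expect_true(residency_flag(mk_sum(30, 1:3)))
  expect_false(residency_flag(mk_sum(30, 1L)))
  expect_false(residency_flag(mk_sum(90, 1:2)))   # strict inequality
  expect_false(residency_flag(mk_sum(NA_real_, 1:2)))
})

test_that("strategy-by-years tabulation gives within-strategy percentages", {
  # 99 foraging-only males, of which 38 seen in one year and 11 in all six
  years <- c(rep(1L, 38), rep(2L, 18), rep(3L, 14), rep(4L, 9), rep(5L, 9),
             rep(6L, 11))
  ids <- sprintf("m%02d", seq_along(years))
  labels <- stats::setNames(rep("foraging_only", 99), ids)
  tab <- tabulate_strategy_by_years(labels, stats::setNames(years, ids))
  expect_equal(tab$pct["6", "foraging_only"], 100 * 11 / 99)
  expect_equal(round_pct(tab$pct["6", "foraging_only"]), 11.1)
  expect_equal(round_pct(tab$pct["1", "foraging_only"]), 38.4)
  # column percentages sum to 100 within each non-empty strategy
  expect_equal(unname(colSums(tab$pct)[tab$n > 0]), 100)
  single <- tabulate_strategy_by_years(c(x = "musth_only"), c(x = 1L))
  expect_equal(sum(single$counts), 1L)
  expect_equal(single$counts["1", "musth_only"], 1L)
  expect_error(tabulate_strategy_by_years(labels, c(bad = 1L)), "same males")
})
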