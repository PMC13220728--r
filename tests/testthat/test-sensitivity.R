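test_that("a single-stratum grouping reproduces the unstratified ratio", {
  ds <- make_dataset(tibble::tibble(
    competition_id = "A", event_id = "444", round_number = 1:2,
    bin = c(52L, 36L), attempts = c(2000L, 6000L), records = c(1L, 9L)
  ))
  tab <- tally_bins(ds, "444", scale = 50000, min_attempts = 1)
  wr <- window_rates(tab, window_spec())
  overall <- window_ratio(wr$inside_rate, wr$outside_rate)

  by_cont <- dip_ratio_by(ds, "444", "continent")
  expect_equal(nrow(by_cont), 1L)
  expect_equal(by_cont$dip_ratio, overall)
  expect_equal(by_cont$n_records, 10L)
})

test_that("continent strata separate differing inside suppression", {
  # continent A: inside rate 1/4 of outside; continent B: equal rates
  comps <- dplyr::bind_rows(
    make_competitions("A1", continent = "Asia", timezone = "Asia/Tokyo"),
    make_competitions("B1", continent = "Europe", timezone = "Europe/Berlin")
  )
  ds <- make_dataset(tibble::tibble(
    competition_id = c("A1", "A1", "B1", "B1"), event_id = "444",
    round_number = c(1L, 2L, 1L, 2L),
    bin = c(52L, 36L, 52L, 36L),
    attempts = c(4000L, 4000L, 4000L, 4000L),
    records = c(1L, 4L, 3L, 3L)
  ), competitions = comps)
  out <- dip_ratio_by(ds, "444", "continent")
  ra <- out$dip_ratio[out$label == "Asia"]
  rb <- out$dip_ratio[out$label == "Europe"]
  expect_equal(ra, 4)
  expect_equal(rb, 1)
  expect_gt(ra, rb)
  # complete grouping partitions the event's records
  expect_equal(sum(out$n_records),
               sum(ds$rounds$records_total[ds$rounds$event_id == "444"]))
})

test_that("era strata split on the competition year boundary", {
  comps <- dplyr::bind_rows(
    make_competitions("Old", year = 2019L),
    make_competitions("New", year = 2024L)
  )
  ds <- make_dataset(tibble::tibble(
    competition_id = c("Old", "Old", "New", "New"), event_id = "444",
    round_number = c(1L, 2L, 1L, 2L),
    bin = c(52L, 36L, 52L, 36L),
    attempts = 4000L, records = c(1L, 2L, 2L, 2L)
  ), competitions = comps)
  out <- dip_ratio_by(ds, "444", "era")
  expect_setequal(out$label, c("pre-2023", "2023+"))
  expect_equal(out$dip_ratio[out$label == "pre-2023"], 2)
  expect_equal(out$dip_ratio[out$label == "2023+"], 1)
})

test_that("round-stage strata keep early, final and other apart", {
  ds <- make_dataset(tibble::tibble(
    competition_id = "A", event_id = "444", round_number = 1:4,
    bin = c(52L, 36L, 40L, 70L),
    attempts = c(4000L, 4000L, 2000L, 1000L),
    records = c(1L, 2L, 1L, 1L)
  ))
  out <- dip_ratio_by(ds, "444", "round_stage")
  expect_setequal(out$label, c("early", "final", "other"))
  # early rounds span inside and outside; final and other rounds carry no
  # inside-window exposure and must be flagged untestable, not dropped
  expect_true(out$testable[out$label == "early"])
  expect_false(out$testable[out$label == "final"])
  expect_false(out$testable[out$label == "other"])
  expect_true(is.na(out$dip_ratio[out$label == "final"]))
  expect_error(dip_ratio_by(ds, "444", "venue"), "arg")
})

test_that("evening peak composition attributes records to finals", {
  # peak bin 72 (18:00): 4 final records vs 1 early record
  ds <- make_dataset(tibble::tibble(
    competition_id = c("A", "A", "B"), event_id = "333",
    round_number = c(1L, 2L, 1L),
    bin = c(72L, 72L, 70L),
    attempts = c(4000L, 1000L, 1000L),
    records = c(1L, 4L, 2L)
  ))
  comp <- final_round_share(ds, "333")
  expect_equal(comp$peak_bin, 72L)
  expect_equal(comp$peak_clock_label, "18:00")
  expect_equal(comp$final_share, 0.8)

  # ties resolve toward the earlier bin
  tie <- make_dataset(tibble::tibble(
    competition_id = c("A", "B"), event_id = "333", round_number = 1L,
    bin = c(74L, 70L), attempts = 1000L, records = c(3L, 3L)
  ))
  expect_equal(final_round_share(tie, "333")$peak_bin, 70L)

  # a single-round event's records are all from finals
  solo <- make_dataset(tibble::tibble(
    competition_id = "A", event_id = "666", round_number = 1L,
    bin = 74L, attempts = 500L, records = 2L
  ))
  expect_equal(final_round_share(solo, "666")$final_share, 1)

  # empty window errors
  none <- make_dataset(tibble::tibble(
    competition_id = "A", event_id = "333", round_number = 1L,
    bin = 36L, attempts = 500L, records = 2L
  ))
  expect_error(final_round_share(none, "333"), "no records")
})
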