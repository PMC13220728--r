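test_that("per-solve rows aggregate to round tallies with pooled tiers", {
  df <- tibble::tibble(
    competition_id = "C1", event_id = "333", round_number = 1L,
    record_single = c("NR", NA, NA),
    record_average = c(NA, NA, "CR")
  )
  out <- results_tallies(df)
  expect_equal(nrow(out), 1L)
  expect_equal(out$attempts, 3L)
  expect_equal(out$wr, 0L)
  expect_equal(out$cr, 1L)
  expect_equal(out$nr, 1L)
  expect_equal(out$records_total, 2L)

  # a solve flagged in both categories contributes two pooled records by
  # default, one when categories are collapsed
  both <- tibble::tibble(
    competition_id = "C1", event_id = "333", round_number = 1L,
    record_single = c("NR", NA, NA), record_average = c("NR", NA, NA)
  )
  expect_equal(results_tallies(both)$records_total, 2L)
  expect_equal(results_tallies(both, count_both_categories = FALSE)$records_total, 1L)

  # empty input stays empty
  expect_equal(nrow(results_tallies(df[0, ])), 0L)
})

test_that("aggregated dialect validates counts and invariants", {
  ok <- tibble::tibble(competition_id = "C1", event_id = "444",
                       round_number = 1L, attempts = 10L,
                       wr = 0L, cr = 1L, nr = 2L)
  expect_equal(results_tallies(ok)$records_total, 3L)

  bad <- ok; bad$attempts <- 2L
  expect_error(results_tallies(bad), "exceeds attempts")
  neg <- ok; neg$nr <- -1L
  expect_error(results_tallies(neg), "negative")
  expect_error(results_tallies(ok[, -1]), "competition_id")
  expect_error(
    results_tallies(tibble::tibble(competition_id = "C", event_id = "333",
                                   round_number = 1L, something = 1)),
    "aggregated columns|per-solve columns"
  )
  # zero-attempt rows are retained as exposure-zero
  zero <- ok; zero$attempts <- 0L; zero[, c("wr", "cr", "nr")] <- 0L
  expect_equal(results_tallies(zero)$attempts, 0L)
})

test_that("results reader round-trips CSV and gzip", {
  df <- tibble::tibble(competition_id = c("A", "A"), event_id = "444",
                       round_number = 1:2, attempts = c(40L, 20L),
                       wr = 0L, cr = c(1L, 0L), nr = c(2L, 1L))
  p <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, p)
  expect_equal(read_results_table(p)$records_total, c(3L, 1L))
  pgz <- withr::local_tempfile(fileext = ".csv.gz")
  readr::write_csv(df, pgz)
  expect_equal(read_results_table(pgz)$attempts, c(40L, 20L))
})

test_that("schedule parser extracts rounds, earliest starts and exclusions", {
  doc <- make_wcif("Tokyo2024", timezone = "Asia/Tokyo", activities = list(
    make_activity("333-r1", "2024-06-01T00:30:00Z"),
    make_activity("other-lunch", "2024-06-01T03:00:00Z")
  ))
  out <- parse_schedule(doc)
  expect_equal(nrow(out$entries), 1L)
  expect_equal(out$entries$event_id, "333")
  expect_equal(out$entries$round_number, 1L)
  expect_equal(out$entries$timezone, "Asia/Tokyo")
  expect_equal(format(out$entries$utc_start, tz = "UTC", "%H:%M"), "00:30")
  expect_equal(nrow(out$excluded), 0L)

  # same round in two rooms: earliest start wins
  two_rooms <- list(id = "C2", schedule = list(venues = list(list(
    timezone = "UTC",
    rooms = list(
      list(activities = list(make_activity("444-r1", "2024-06-01T01:00:00Z"))),
      list(activities = list(make_activity("444-r1", "2024-06-01T00:30:00Z")))
    )
  ))))
  e <- parse_schedule(two_rooms)$entries
  expect_equal(nrow(e), 1L)
  expect_equal(format(e$utc_start, tz = "UTC", "%H:%M"), "00:30")

  # empty venues: excluded, not an error
  out <- parse_schedule(make_wcif("Old2009", n_venues = 0L))
  expect_equal(nrow(out$entries), 0L)
  expect_equal(out$excluded$reason, "no schedule")

  # venue present but only non-round activities
  out <- parse_schedule(make_wcif("Lunch", activities = list(
    make_activity("other-lunch", "2024-06-01T03:00:00Z"))))
  expect_equal(out$excluded$reason, "no schedule")

  # malformed timestamp: parse failure
  out <- parse_schedule(make_wcif("Bad", activities = list(
    make_activity("333-r1", "not-a-time"))))
  expect_equal(out$excluded$reason, "parse failure")
})

test_that("read_schedules accumulates the three-way exclusion ledger", {
  dir <- withr::local_tempdir()
  write_wcif(file.path(dir, "Good.json"), id = "Good", timezone = "UTC",
             activities = list(make_activity("333-r1", "2024-06-01T09:00:00Z")))
  write_wcif(file.path(dir, "Empty.json"), id = "Empty", n_venues = 0L)
  write_wcif(file.path(dir, "Bad.json"), id = "Bad",
             activities = list(make_activity("333-r1", "nope")))
  paths <- c(file.path(dir, c("Good.json", "Empty.json", "Bad.json")),
             file.path(dir, "Missing.json"))
  ss <- read_schedules(paths)
  expect_s3_class(ss, "schedule_set")
  expect_equal(nrow(ss$entries), 1L)
  expect_setequal(ss$excluded$reason, c("no schedule", "parse failure", "no file"))
  cov <- coverage_summary(ss)
  expect_equal(cov$retained, 1L)
  expect_equal(cov$queried, 4L)
  expect_equal(cov$coverage_pct, 25)
})

test_that("round stages follow contest order with final precedence", {
  one <- map_round_stage(1L)
  expect_true(one$is_final)
  expect_equal(one$stage, "final")

  three <- map_round_stage(1:3)
  expect_equal(three$is_final, c(FALSE, FALSE, TRUE))
  expect_equal(three$stage, c("early", "early", "final"))

  four <- map_round_stage(1:4)
  expect_equal(four$stage, c("early", "early", "other", "final"))

  expect_error(map_round_stage(c(1L, 1L)), "duplicate")
  expect_error(map_round_stage(c(1L, 3L)), "contiguous")
})

test_that("join drops unscheduled rounds and accounts coverage", {
  comps <- make_competitions(paste0("C", 1:4))
  results <- tibble::tibble(
    competition_id = rep(paste0("C", 1:4), each = 1),
    event_id = "333", round_number = 1L, attempts = 30L,
    wr = 0L, cr = 0L, nr = 1L
  )
  results <- results_tallies(results)
  entries <- tibble::tibble(
    competition_id = paste0("C", 1:3), event_id = "333", round_number = 1L,
    utc_start = as.POSIXct("2022-06-01 09:00:00", tz = "UTC"),
    timezone = "UTC"
  )
  ds <- join_dataset(results, schedule_set(entries), comps)
  expect_equal(nrow(ds$rounds), 3L)
  expect_equal(ds$excluded$competition_id, "C4")
  expect_equal(ds$excluded$reason, "no schedule")
  cov <- coverage_summary(ds)
  expect_equal(cov$coverage_pct, 75)
  expect_equal(ds$rounds$bin, rep(36L, 3))

  # disjoint keys: empty dataset, everything excluded
  ds2 <- join_dataset(results, schedule_set(
    entries[0, ]), comps)
  expect_equal(nrow(ds2$rounds), 0L)
  expect_equal(sort(ds2$excluded$competition_id), paste0("C", 1:4))
})

test_that("fixture round-trip preserves the dataset and its totals", {
  cfg <- synthetic_config(n_competitions = 25, seed = 11)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_fixtures(ds, dir, config = cfg)
  back <- read_fixtures(dir)

  expect_equal(as.data.frame(back$rounds), as.data.frame(ds$rounds))
  expect_equal(as.data.frame(back$competitions), as.data.frame(ds$competitions))

  # conservation: attempts and pooled records survive the join untouched
  raw <- read_results_table(file.path(dir, "results.csv"))
  expect_equal(sum(back$rounds$attempts), sum(raw$attempts))
  expect_equal(sum(back$rounds$records_total), sum(raw$records_total))

  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$total_records, sum(ds$rounds$records_total))
  expect_equal(man$n_rounds, nrow(ds$rounds))
})

test_that("tier pooling conserves per-solve record flags end to end", {
  set.seed(5)
  n <- 400L
  solves <- tibble::tibble(
    competition_id = sample(c("A", "B"), n, TRUE),
    event_id = "333",
    round_number = 1L,
    record_single = sample(c(NA, "WR", "CR", "NR"), n, TRUE,
                           prob = c(0.9, 0.01, 0.03, 0.06)),
    record_average = sample(c(NA, "CR", "NR"), n, TRUE,
                            prob = c(0.92, 0.03, 0.05))
  )
  tal <- results_tallies(solves)
  n_flags <- sum(!is.na(solves$record_single)) + sum(!is.na(solves$record_average))
  expect_equal(sum(tal$records_total), n_flags)
  expect_equal(sum(tal$attempts), n)
})
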