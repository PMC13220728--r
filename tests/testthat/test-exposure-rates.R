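test_that("bin tallies scale rates and pool rounds additively", {
  ds <- make_dataset(tibble::tibble(
    competition_id = c("A", "A", "B"), event_id = "444",
    round_number = c(1L, 2L, 1L),
    bin = c(36L, 40L, 36L),
    attempts = c(4000L, 500L, 2000L),
    records = c(1L, 0L, 2L)
  ))
  tab <- tally_bins(ds, "444", scale = 50000, min_attempts = 1000)
  expect_equal(tab$attempts[tab$bin == 36], 6000)
  expect_equal(tab$records[tab$bin == 36], 3)
  expect_equal(tab$rate[tab$bin == 36], 25) # 50000 * 3 / 6000
  expect_true(tab$valid[tab$bin == 36])
  expect_false(tab$valid[tab$bin == 40]) # 500 < min_attempts
  # zero-attempt bins: undefined rate, invalid
  expect_true(is.na(tab$rate[tab$bin == 0]))
  expect_false(tab$valid[tab$bin == 0])
  expect_error(tally_bins(ds, "777"), "no rounds")

  # conservation across the whole curve
  expect_equal(sum(tab$attempts), sum(ds$rounds$attempts[ds$rounds$event_id == "444"]))
  expect_equal(sum(tab$records), sum(ds$rounds$records_total[ds$rounds$event_id == "444"]))
})

test_that("overall rate supports unweighted and exposure-weighted means", {
  ds <- make_dataset(tibble::tibble(
    competition_id = "A", event_id = "444", round_number = 1:2,
    bin = c(36L, 60L), attempts = c(1000L, 3000L), records = c(2L, 3L)
  ))
  unw <- tally_bins(ds, "444", scale = 1000, min_attempts = 1)
  # rates: 2 and 1 per 1000 -> unweighted mean 1.5
  expect_equal(overall_rate(unw), 1.5)
  wt <- tally_bins(ds, "444", scale = 1000, min_attempts = 1,
                   rate_mean = "weighted")
  # pooled: 5 records / 4000 attempts
  expect_equal(overall_rate(wt), 1000 * 5 / 4000)
})

test_that("exposure-weighted mean rate equals the pooled rate identity", {
  ds <- generate_dataset(synthetic_config(n_competitions = 30, seed = 3))
  for (ev in c("333", "555")) {
    tab <- tally_bins(ds, ev, min_attempts = 1)
    has <- tab$attempts > 0
    lhs <- sum(tab$rate[has] * tab$attempts[has]) / sum(tab$attempts[has])
    rhs <- attr(tab, "scale") * sum(tab$records) / sum(tab$attempts)
    expect_equal(lhs, rhs)
  }
})

test_that("raising the minimum-attempts filter never adds valid bins", {
  ds <- generate_dataset(synthetic_config(n_competitions = 30, seed = 4))
  thresholds <- c(1, 50, 200, 1000, 10000)
  nvalid <- vapply(thresholds, function(m) {
    sum(tally_bins(ds, "333", min_attempts = m)$valid)
  }, numeric(1))
  expect_true(all(diff(nvalid) <= 0))
})

test_that("exact Poisson intervals match an independent CDF-inversion oracle", {
  cases <- expand.grid(records = c(0L, 1L, 4L, 25L),
                       attempts = c(500L, 10000L))
  for (i in seq_len(nrow(cases))) {
    r <- cases$records[i]; a <- cases$attempts[i]
    got <- poisson_ci(r, a, scale = 50000)
    want <- oracle_poisson_ci(r, a, scale = 50000)
    expect_equal(got, want, tolerance = 1e-6,
                 info = sprintf("records=%d attempts=%d", r, a))
  }
  expect_equal(poisson_ci(0, 10000, scale = 50000)[1], 0)
  expect_error(poisson_ci(4, 0), "attempts > 0")

  # the interval brackets the point rate and narrows as exposure grows
  widths <- vapply(c(1000, 4000, 16000, 64000), function(a) {
    ci <- poisson_ci(round(a * 6e-4), a, scale = 50000)
    ci[2] - ci[1]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  ci <- poisson_ci(4, 10000, scale = 50000)
  expect_true(ci[1] <= 50000 * 4 / 10000 && 50000 * 4 / 10000 <= ci[2])
})

test_that("window rates pool inside bins and attempt-bearing outside bins", {
  ds <- make_dataset(tibble::tibble(
    competition_id = "A", event_id = "444", round_number = 1:2,
    bin = c(52L, 36L), # one round inside 12:30-15:00, one outside
    attempts = c(2000L, 6000L), records = c(1L, 9L)
  ))
  tab <- tally_bins(ds, "444", scale = 50000, min_attempts = 1)
  wr <- window_rates(tab, window_spec())
  expect_equal(wr$inside_rate, 25)  # 50000 * 1 / 2000
  expect_equal(wr$outside_rate, 75) # 50000 * 9 / 6000
  expect_equal(wr$inside_records + wr$outside_records, 10)

  # symmetric rates inside and outside give equal pooled rates
  ds2 <- make_dataset(tibble::tibble(
    competition_id = "A", event_id = "444", round_number = 1:2,
    bin = c(52L, 36L), attempts = c(4000L, 4000L), records = c(2L, 2L)
  ))
  wr2 <- window_rates(tally_bins(ds2, "444", scale = 50000, min_attempts = 1),
                      window_spec())
  expect_equal(wr2$inside_rate, wr2$outside_rate)

  # no exposure inside the window is untestable, not silently zero
  ds3 <- make_dataset(tibble::tibble(
    competition_id = "A", event_id = "444", round_number = 1L,
    bin = 36L, attempts = 1000L, records = 1L
  ))
  expect_error(window_rates(tally_bins(ds3, "444", scale = 50000,
                                       min_attempts = 1), window_spec()),
               "untestable")
})
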