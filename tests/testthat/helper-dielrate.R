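# Shared fixture builders. Everything is constructed in code; nothing is
# stored on disk between runs.

make_competitions <- function(ids, continent = "Europe", year = 2022L,
                              timezone = "UTC") {
  tibble::tibble(
    competition_id = ids,
    country = rep_len("X", length(ids)),
    continent = rep_len(continent, length(ids)),
    year = rep_len(as.integer(year), length(ids)),
    timezone = rep_len(timezone, length(ids))
  )
}

# Hand-built dataset: rounds placed at known bins with known counts.
# `rows` is a data frame with competition_id, event_id, round_number, bin,
# attempts, records (all NR tier), plus optional continent/year columns on
# the competitions side.
make_dataset <- function(rows, competitions = NULL, bin_minutes = 15L) {
  rows <- tibble::as_tibble(rows)
  if (is.null(competitions)) {
    competitions <- make_competitions(unique(rows$competition_id))
  }
  stage <- dplyr::mutate(
    dplyr::group_by(rows, competition_id, event_id),
    is_final = round_number == max(round_number),
    stage = ifelse(is_final, "final", ifelse(round_number <= 2L, "early", "other"))
  )
  rows <- dplyr::ungroup(stage)
  mins <- rows$bin * bin_minutes
  rows$local_start <- sprintf("%02d:%02d", mins %/% 60, mins %% 60)
  rows$utc_start <- as.POSIXct("2022-06-01", tz = "UTC") + mins * 60
  rows$nr <- rows$records
  rows$cr <- 0L
  rows$wr <- 0L
  rows$records_total <- rows$records
  dielrate::diel_dataset(
    competitions,
    rows[, c("competition_id", "event_id", "round_number", "is_final", "stage",
             "utc_start", "local_start", "bin", "attempts", "wr", "cr", "nr",
             "records_total")],
    bin_minutes = bin_minutes
  )
}

# Minimal WCIF-style document as a nested list.
make_wcif <- function(id, timezone = "UTC", activities = list(),
                      n_venues = 1L) {
  venue <- list(timezone = timezone,
                rooms = list(list(name = "Main", activities = activities)))
  list(id = id,
       schedule = list(venues = if (n_venues == 0L) list() else list(venue)))
}

make_activity <- function(code, start) list(activityCode = code, startTime = start)

write_wcif <- function(path, ...) {
  jsonlite::write_json(make_wcif(...), path, auto_unbox = TRUE)
  path
}

# Independent exact Poisson interval oracle: inverts the cumulative Poisson
# distribution by root-finding, no chi-square quantiles involved.
oracle_poisson_ci <- function(records, attempts, scale = 1, level = 0.95) {
  alpha <- 1 - level
  lo <- if (records == 0) 0 else {
    stats::uniroot(function(m) stats::ppois(records - 1, m, lower.tail = FALSE) - alpha / 2,
                   c(1e-12, 10 * records + 100), tol = 1e-10)$root
  }
  hi <- stats::uniroot(function(m) stats::ppois(records, m) - alpha / 2,
                       c(1e-12, 10 * records + 100), tol = 1e-10)$root
  c(lo, hi) / attempts * scale
}

# Small flat-rate (dip-free) synthetic configuration used by permutation
# calibration checks: one event, morning/evening-skewed scheduling, record
# volume large enough that the inside-window record count is essentially
# never zero.
flat_calibration_config <- function(seed, n_competitions = 400L,
                                    dip_multiplier = 1) {
  dielrate::synthetic_config(
    n_competitions = n_competitions,
    events = list("444" = list(rounds_dist = c(0.45, 0.35, 0.20, 0),
                               attempts_meanlog = log(400),
                               attempts_sdlog = 0.4,
                               baseline_p = 6e-4)),
    dip_multiplier = dip_multiplier,
    seed = seed
  )
}
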