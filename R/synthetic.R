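#' Default diel scheduling-density curve
#'
#' Bin weights for round start times over the civil day, emulating how
#' competitions concentrate rounds non-uniformly: a heavy morning block
#' (08:00-11:00), a lighter midday-to-afternoon plateau (11:00-17:00) and an
#' evening block (17:00-19:00) where finals cluster. Weights need not sum
#' to 1; they are normalised at sampling time.
#'
#' @param bin_minutes Bin width in minutes.
#' @return Numeric weight vector of length `1440 / bin_minutes`.
#' @export
default_schedule_density <- function(bin_minutes = 15L) {
  nb <- n_bins(bin_minutes)
  w <- numeric(nb)
  mins <- (seq_len(nb) - 1L) * bin_minutes
  w[mins >= 8 * 60 & mins < 11 * 60] <- 3
  w[mins >= 11 * 60 & mins < 17 * 60] <- 1
  w[mins >= 17 * 60 & mins < 19 * 60] <- 1.5
  w
}

DEFAULT_TZ_POOL <- list(
  Europe = c("Europe/Berlin", "Europe/London", "Europe/Paris", "Europe/Warsaw"),
  Asia = c("Asia/Tokyo", "Asia/Shanghai", "Asia/Seoul", "Asia/Kolkata"),
  Americas = c("America/New_York", "America/Chicago", "America/Los_Angeles",
               "America/Sao_Paulo"),
  Oceania = c("Australia/Sydney", "Pacific/Auckland"),
  Africa = c("Africa/Johannesburg", "Africa/Cairo")
)

#' @noRd
default_event_params <- function() {
  # baseline_p chosen so pooled rates land near the per-event display
  # conventions (e.g. ~30 records per 50,000 attempts for 444)
  list(
    "333" = list(rounds_dist = c(0.30, 0.30, 0.30, 0.10),
                 attempts_meanlog = log(300), attempts_sdlog = 0.4,
                 baseline_p = 1.8e-4),
    "444" = list(rounds_dist = c(0.45, 0.35, 0.20, 0.00),
                 attempts_meanlog = log(130), attempts_sdlog = 0.4,
                 baseline_p = 6e-4),
    "555" = list(rounds_dist = c(0.55, 0.30, 0.15, 0.00),
                 attempts_meanlog = log(70), attempts_sdlog = 0.4,
                 baseline_p = 1.15e-3),
    "666" = list(rounds_dist = c(0.75, 0.20, 0.05, 0.00),
                 attempts_meanlog = log(35), attempts_sdlog = 0.4,
                 baseline_p = 3.6e-3)
  )
}

#' Configuration for the synthetic competition-data generator
#'
#' Defines every knob of the generative model: how many competitions, their
#' continent/timezone/year mix, the per-event round-count and attempt-count
#' distributions and baseline per-attempt record probability, the
#' scheduling-density curve over local-time bins, the probability that a
#' final is pulled into the evening block, and an optional multiplicative
#' dip in record probability inside a local-time window.
#'
#' @param n_competitions Number of competitions.
#' @param continent_mix Named probability vector over the five continents
#'   (normalised internally).
#' @param year_range Integer `c(min, max)` calendar years.
#' @param timezone_pool Named list, continent -> character vector of IANA
#'   zone ids to sample venues from.
#' @param events Named list of per-event parameter lists with elements
#'   `rounds_dist` (probabilities over 1-4 rounds), `attempts_meanlog`,
#'   `attempts_sdlog` (log-normal first-round attempt counts),
#'   `baseline_p` (per-attempt record probability). Defaults emulate the
#'   four analysis events.
#' @param schedule_density Bin-weight vector for round start times (length
#'   `1440 / bin_minutes`); default [default_schedule_density()].
#' @param evening_bins Bin indices of the evening block finals are biased
#'   toward; default 17:00-19:00.
#' @param finals_evening_bias Probability a final's start bin is drawn from
#'   the evening block instead of the full density.
#' @param dip_window A [window_spec()]; inside it the record probability is
#'   multiplied by `dip_multiplier`.
#' @param dip_multiplier Multiplier in (0, 1]; 1 means no dip (null model).
#' @param tier_probs Probabilities that a record is NR/CR/NR-tier, named
#'   `c(nr=, cr=, wr=)`; cosmetic, since tiers are pooled downstream.
#' @param round_decay Geometric shrink factor for attempts in successive
#'   rounds.
#' @param min_round_attempts Floor on per-round attempts.
#' @param bin_minutes Bin width.
#' @param seed Integer seed; the whole generated dataset is a deterministic
#'   function of the configuration including the seed.
#' @return A `synthetic_config` object (validated list).
#' @export
synthetic_config <- function(n_competitions = 200L,
                             continent_mix = c(Europe = 0.40, Asia = 0.25,
                                               Americas = 0.25, Oceania = 0.06,
                                               Africa = 0.04),
                             year_range = c(2012L, 2025L),
                             timezone_pool = DEFAULT_TZ_POOL,
                             events = default_event_params(),
                             schedule_density = default_schedule_density(bin_minutes),
                             evening_bins = NULL,
                             finals_evening_bias = 0.7,
                             dip_window = window_spec(),
                             dip_multiplier = 1.0,
                             tier_probs = c(nr = 0.94, cr = 0.05, wr = 0.01),
                             round_decay = 0.5,
                             min_round_attempts = 8L,
                             bin_minutes = 15L,
                             seed = 42L) {
  check_bin_minutes(bin_minutes)
  nb <- n_bins(bin_minutes)
  stopifnot(n_competitions >= 1, length(year_range) == 2,
            year_range[1] <= year_range[2])
  if (!setequal(names(continent_mix), CONTINENTS)) {
    stop("continent_mix must be named over the five continents", call. = FALSE)
  }
  if (any(continent_mix < 0) || sum(continent_mix) <= 0) {
    stop("continent_mix weights must be non-negative and not all zero",
         call. = FALSE)
  }
  continent_mix <- continent_mix / sum(continent_mix)
  if (is.character(events)) events <- default_event_params()[events]
  if (any(vapply(events, is.null, logical(1L)))) {
    stop("unknown event id(s) in 'events'", call. = FALSE)
  }
  if (length(schedule_density) != nb || any(schedule_density < 0) ||
      sum(schedule_density) <= 0) {
    stop("schedule_density must be ", nb,
         " non-negative weights with positive sum", call. = FALSE)
  }
  if (is.null(evening_bins)) {
    mins <- (seq_len(nb) - 1L) * bin_minutes
    evening_bins <- which(mins >= 17 * 60 & mins < 19 * 60) - 1L
  }
  for (ev in names(events)) {
    p <- events[[ev]]
    stopifnot(length(p$rounds_dist) >= 1, all(p$rounds_dist >= 0),
              sum(p$rounds_dist) > 0,
              p$baseline_p >= 0, p$baseline_p <= 1)
    events[[ev]]$rounds_dist <- p$rounds_dist / sum(p$rounds_dist)
  }
  stopifnot(dip_multiplier > 0, dip_multiplier <= 1,
            finals_evening_bias >= 0, finals_evening_bias <= 1,
            inherits(dip_window, "window_spec"))
  for (cont in unique(names(timezone_pool))) check_timezone(timezone_pool[[cont]])
  tier_probs <- tier_probs / sum(tier_probs)

  structure(
    list(n_competitions = as.integer(n_competitions),
         continent_mix = continent_mix, year_range = as.integer(year_range),
         timezone_pool = timezone_pool, events = events,
         schedule_density = schedule_density,
         evening_bins = as.integer(evening_bins),
         finals_evening_bias = finals_evening_bias,
         dip_window = dip_window, dip_multiplier = dip_multiplier,
         tier_probs = tier_probs, round_decay = round_decay,
         min_round_attempts = as.integer(min_round_attempts),
         bin_minutes = as.integer(bin_minutes), seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate a synthetic analysis dataset
#'
#' Simulates competitions with continent-consistent IANA timezones, per-event
#' round sequences whose local start bins follow the scheduling-density
#' curve (finals redirected to the evening block with probability
#' `finals_evening_bias`), per-round attempt counts, and record counts drawn
#' as `Binomial(attempts, p_eff)` with
#' `p_eff = baseline_p * dip_multiplier` inside the dip window and
#' `baseline_p` elsewhere. Records carry NR/CR/WR tier labels in fixed
#' proportions. Each record flag is an independent Bernoulli event: the
#' elite-gated lineage of real records (every record must beat all previous
#' ones) is deliberately not simulated, because the analysis consumes
#' pre-flagged records and is agnostic to their provenance.
#'
#' UTC start times are derived by anchoring each round at its local bin
#' start (plus a small within-bin offset) on a random date in the
#' competition's year and converting local to UTC through the venue's
#' timezone; the stored `bin` is then recomputed from the UTC time exactly
#' as ingestion would, so generated datasets and fixture round-trips agree
#' even across daylight-saving transitions.
#'
#' @param config A [synthetic_config()].
#' @return A [diel_dataset()]; deterministic given the configuration.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nb <- n_bins(config$bin_minutes)

  n <- config$n_competitions
  continent <- sample(names(config$continent_mix), n, replace = TRUE,
                      prob = config$continent_mix)
  timezone <- vapply(continent, function(ct) {
    pool <- config$timezone_pool[[ct]]
    if (is.null(pool)) stop("no timezone pool for continent ", ct, call. = FALSE)
    pool[sample.int(length(pool), 1L)]
  }, character(1L))
  year <- sample(seq(config$year_range[1], config$year_range[2]), n,
                 replace = TRUE)
  competitions <- tibble(
    competition_id = sprintf("SynthComp%04d", seq_len(n)),
    country = unname(vapply(strsplit(timezone, "/"), `[`, character(1L), 2L)),
    continent = continent, year = year, timezone = unname(timezone)
  )

  density <- config$schedule_density / sum(config$schedule_density)
  ev_density <- numeric(nb)
  ev_density[config$evening_bins + 1L] <- config$schedule_density[config$evening_bins + 1L]
  if (sum(ev_density) <= 0) ev_density <- config$schedule_density
  ev_density <- ev_density / sum(ev_density)
  dip_bins <- config$dip_window$bins

  rows <- vector("list", length(config$events))
  for (e in seq_along(config$events)) {
    ev <- names(config$events)[e]
    p <- config$events[[ev]]
    k <- sample.int(length(p$rounds_dist), n, replace = TRUE,
                    prob = p$rounds_dist)
    comp <- rep.int(seq_len(n), k)
    round_number <- sequence(k)
    last <- rep.int(k, k)
    is_final <- round_number == last
    stage <- ifelse(is_final, "final",
                    ifelse(round_number <= 2L, "early", "other"))
    use_evening <- is_final & (stats::runif(length(comp)) <
                                 config$finals_evening_bias)
    bins <- integer(length(comp))
    if (any(!use_evening)) {
      bins[!use_evening] <- sample.int(nb, sum(!use_evening), replace = TRUE,
                                       prob = density) - 1L
    }
    if (any(use_evening)) {
      bins[use_evening] <- sample.int(nb, sum(use_evening), replace = TRUE,
                                      prob = ev_density) - 1L
    }
    # earlier rounds in ascending clock order; the final keeps its own slot
    nf <- !is_final
    bins[nf] <- unlist(lapply(split(bins[nf], comp[nf]), sort),
                       use.names = FALSE)

    a1 <- pmax(config$min_round_attempts,
               round(stats::rlnorm(n, p$attempts_meanlog, p$attempts_sdlog)))
    attempts <- pmax(config$min_round_attempts,
                     round(a1[comp] * config$round_decay^(round_number - 1L)))
    p_eff <- ifelse(bins %in% dip_bins,
                    p$baseline_p * config$dip_multiplier, p$baseline_p)
    records <- stats::rbinom(length(comp), attempts, p_eff)
    nr <- cr <- wr <- integer(length(comp))
    hit <- which(records > 0)
    for (j in hit) {
      t3 <- stats::rmultinom(1, records[j], config$tier_probs)[, 1L]
      nr[j] <- t3[1L]; cr[j] <- t3[2L]; wr[j] <- t3[3L]
    }
    rows[[e]] <- tibble(
      competition_id = competitions$competition_id[comp],
      event_id = ev, round_number = round_number,
      is_final = is_final, stage = stage,
      bin_intended = bins, attempts = as.integer(attempts),
      nr = nr, cr = cr, wr = wr,
      year = competitions$year[comp], timezone = competitions$timezone[comp]
    )
  }
  rounds <- dplyr::bind_rows(rows)
  rounds$records_total <- rounds$wr + rounds$cr + rounds$nr

  # anchor each competition on a random date of its year, rounds at local
  # bin starts with a small within-bin minute offset
  date_map <- stats::setNames(
    as.Date(sprintf("%d-01-01", competitions$year)) +
      sample.int(365, n, replace = TRUE) - 1L,
    competitions$competition_id
  )
  offset_min <- sample.int(config$bin_minutes, nrow(rounds), replace = TRUE) - 1L
  local_minutes <- rounds$bin_intended * config$bin_minutes + offset_min
  local_str <- sprintf("%s %02d:%02d:00",
                       format(date_map[rounds$competition_id]),
                       local_minutes %/% 60, local_minutes %% 60)
  utc <- as.POSIXct(rep(NA_real_, nrow(rounds)), origin = "1970-01-01",
                    tz = "UTC")
  for (tz in unique(rounds$timezone)) {
    idx <- which(rounds$timezone == tz)
    loc <- as.POSIXct(local_str[idx], tz = tz)
    gap <- is.na(loc) # nonexistent local times at a DST spring-forward gap
    if (any(gap)) {
      shifted <- format(as.POSIXct(local_str[idx][gap], tz = "UTC") + 3600,
                        tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
      loc[gap] <- as.POSIXct(shifted, tz = tz)
    }
    utc[idx] <- as.POSIXct(format(loc, tz = "UTC",
                                  format = "%Y-%m-%d %H:%M:%S"), tz = "UTC")
  }
  rounds$utc_start <- utc
  # recompute local clock and bin from UTC, exactly as ingestion does
  rounds$local_start <- to_local(rounds$utc_start, rounds$timezone)
  rounds$bin <- assign_bin(rounds$local_start, config$bin_minutes)

  diel_dataset(
    competitions,
    rounds[, c("competition_id", "event_id", "round_number", "is_final",
               "stage", "utc_start", "local_start", "bin", "attempts",
               "wr", "cr", "nr", "records_total")],
    bin_minutes = config$bin_minutes
  )
}

#' Write a dataset to on-disk fixtures in the ingest dialects
#'
#' Emits `competitions.csv`, an aggregated-dialect `results.csv`, one
#' schedule JSON per competition under `schedules/`, and `manifest.json`
#' recording exact counts (and the generating configuration when supplied),
#' such that reading the directory back through the ingestion path
#' reproduces the dataset.
#'
#' @param dataset A [diel_dataset()].
#' @param dir Output directory (created if needed).
#' @param config Optional [synthetic_config()] echoed into the manifest.
#' @param drop_schedule_for Competition ids whose schedule file is written
#'   with no venues (exercising the `"no schedule"` exclusion path on
#'   read-back).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(dataset, dir, config = NULL,
                           drop_schedule_for = character()) {
  stopifnot(inherits(dataset, "diel_dataset"))
  dir.create(file.path(dir, "schedules"), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dataset$competitions, file.path(dir, "competitions.csv"))
  res <- dataset$rounds[, c("competition_id", "event_id", "round_number",
                            "attempts", "wr", "cr", "nr")]
  readr::write_csv(res, file.path(dir, "results.csv"))

  tzmap <- stats::setNames(dataset$competitions$timezone,
                           dataset$competitions$competition_id)
  for (id in unique(dataset$rounds$competition_id)) {
    sub <- dataset$rounds[dataset$rounds$competition_id == id, , drop = FALSE]
    if (id %in% drop_schedule_for) {
      doc <- list(id = id, schedule = list(venues = list()))
    } else {
      acts <- lapply(seq_len(nrow(sub)), function(j) {
        list(activityCode = sprintf("%s-r%d", sub$event_id[j],
                                    sub$round_number[j]),
             startTime = format(sub$utc_start[j], tz = "UTC",
                                format = "%Y-%m-%dT%H:%M:%SZ"))
      })
      doc <- list(id = id, schedule = list(venues = list(list(
        timezone = unname(tzmap[id]),
        rooms = list(list(name = "Main", activities = acts))
      ))))
    }
    jsonlite::write_json(doc, file.path(dir, "schedules", paste0(id, ".json")),
                         auto_unbox = TRUE)
  }

  per_event <- dplyr::summarise(
    dplyr::group_by(dataset$rounds, .data$event_id),
    rounds = dplyr::n(), attempts = sum(.data$attempts),
    records = sum(.data$records_total), .groups = "drop"
  )
  manifest <- list(
    n_competitions = nrow(dataset$competitions),
    n_rounds = nrow(dataset$rounds),
    total_attempts = sum(dataset$rounds$attempts),
    total_records = sum(dataset$rounds$records_total),
    per_event = per_event,
    bin_minutes = dataset$bin_minutes,
    config = if (!is.null(config)) unclass_config(config) else NULL
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @noRd
unclass_config <- function(config) {
  x <- unclass(config)
  x$dip_window <- list(start = x$dip_window$start, end = x$dip_window$end)
  x
}

#' Read a fixture directory back into a dataset
#'
#' Convenience wrapper: reads `competitions.csv`, `results.csv` and
#' `schedules/*.json` from `dir` and joins them via [join_dataset()].
#'
#' @param dir Fixture directory as written by [write_fixtures()].
#' @param events Events to retain.
#' @param bin_minutes Bin width.
#' @return A [diel_dataset()].
#' @export
read_fixtures <- function(dir, events = DEFAULT_EVENTS, bin_minutes = 15L) {
  join_dataset(
    read_results_table(file.path(dir, "results.csv")),
    read_schedules(file.path(dir, "schedules")),
    read_competitions(file.path(dir, "competitions.csv")),
    events = events, bin_minutes = bin_minutes
  )
}
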