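#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

CONTINENTS <- c("Africa", "Americas", "Asia", "Europe", "Oceania")
DEFAULT_EVENTS <- c("333", "444", "555", "666")

# Display scales: records per N attempts, chosen per event so rates are O(10).
DEFAULT_SCALES <- c("333" = 100000L, "444" = 50000L, "555" = 20000L, "666" = 5000L)

# Minimum per-bin attempt totals for a bin to count as "valid" exposure.
DEFAULT_MIN_ATTEMPTS <- c("333" = 10000L, "444" = 7825L, "555" = 3954L, "666" = 977L)

#' Default per-event display scales and minimum-attempts filters
#'
#' `event_scale()` returns the denominator used to display rates (records per
#' `scale` attempts); `event_min_attempts()` returns the per-bin attempt
#' threshold below which a bin is flagged invalid for rate display and the
#' non-uniformity statistic.
#'
#' @param event_id Event identifier(s), e.g. `"444"`.
#' @return Named integer vector.
#' @export
event_scale <- function(event_id = DEFAULT_EVENTS) {
  lookup_per_event(DEFAULT_SCALES, event_id, "scale")
}

#' @rdname event_scale
#' @export
event_min_attempts <- function(event_id = DEFAULT_EVENTS) {
  lookup_per_event(DEFAULT_MIN_ATTEMPTS, event_id, "min_attempts")
}

#' @noRd
lookup_per_event <- function(table, event_id, what) {
  missing <- setdiff(event_id, names(table))
  if (length(missing) > 0L) {
    stop("no default ", what, " for event(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  table[event_id]
}

#' Validate a competitions table
#'
#' A competitions table has one row per competition with columns
#' `competition_id`, `country`, `continent`, `year` and `timezone`.
#' Competition ids must be unique, continents must be one of the five
#' analysis continents, and every timezone must resolve in the IANA database
#' (no geographic imputation fallback exists).
#'
#' @param competitions Data frame.
#' @return The validated table as a tibble (invisibly usable downstream).
#' @export
validate_competitions <- function(competitions) {
  competitions <- as_tibble(competitions)
  need <- c("competition_id", "country", "continent", "year", "timezone")
  check_columns(competitions, need, "competitions table")
  if (anyDuplicated(competitions$competition_id)) {
    stop("duplicate competition_id in competitions table", call. = FALSE)
  }
  bad <- setdiff(unique(competitions$continent), CONTINENTS)
  if (length(bad) > 0L) {
    stop("unknown continent(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  check_timezone(competitions$timezone)
  competitions$year <- as.integer(competitions$year)
  competitions
}

#' @noRd
check_columns <- function(df, need, what) {
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct an analysis dataset
#'
#' Bundles validated competitions, analysis-ready round observations and the
#' schedule-exclusion ledger into a `diel_dataset`. Most users will obtain
#' one from [join_dataset()] or [generate_dataset()] rather than calling this
#' directly.
#'
#' @param competitions Competitions tibble (see [validate_competitions()]).
#' @param rounds Round observations: one row per scheduled round with
#'   `competition_id`, `event_id`, `round_number`, `is_final`, `stage`,
#'   `utc_start`, `local_start`, `bin`, `attempts`, `wr`, `cr`, `nr`,
#'   `records_total`.
#' @param excluded Tibble with `competition_id` and `reason` (one of
#'   `"no schedule"`, `"no file"`, `"parse failure"`) for competitions whose
#'   schedules could not be used.
#' @param bin_minutes Bin width used for `bin`.
#' @return A `diel_dataset` object.
#' @export
diel_dataset <- function(competitions, rounds,
                         excluded = tibble(competition_id = character(),
                                           reason = character()),
                         bin_minutes = 15L) {
  competitions <- validate_competitions(competitions)
  rounds <- as_tibble(rounds)
  need <- c("competition_id", "event_id", "round_number", "is_final", "stage",
            "utc_start", "local_start", "bin", "attempts", "wr", "cr", "nr",
            "records_total")
  check_columns(rounds, need, "rounds table")
  excluded <- as_tibble(excluded)
  check_columns(excluded, c("competition_id", "reason"), "exclusion ledger")

  if (nrow(rounds) > 0L) {
    orphan <- setdiff(rounds$competition_id, competitions$competition_id)
    if (length(orphan) > 0L) {
      stop("rounds reference unknown competition(s): ",
           paste(utils::head(orphan, 3L), collapse = ", "), call. = FALSE)
    }
    if (any(rounds$competition_id %in% excluded$competition_id)) {
      stop("excluded competitions must contribute no rounds", call. = FALSE)
    }
    with_tot <- rounds$wr + rounds$cr + rounds$nr
    if (any(with_tot != rounds$records_total)) {
      stop("records_total must equal wr + cr + nr", call. = FALSE)
    }
    if (any(rounds$records_total > rounds$attempts)) {
      stop("records_total exceeds attempts in some round(s)", call. = FALSE)
    }
    if (any(rounds$attempts < 0)) stop("negative attempts", call. = FALSE)
    if (any(rounds$bin < 0L | rounds$bin >= n_bins(bin_minutes))) {
      stop("bin index out of range for bin_minutes = ", bin_minutes, call. = FALSE)
    }
    rounds <- dplyr::arrange(rounds, .data$competition_id, .data$event_id,
                             .data$round_number)
  }

  structure(
    list(competitions = competitions, rounds = rounds, excluded = excluded,
         bin_minutes = as.integer(bin_minutes)),
    class = "diel_dataset"
  )
}

#' @export
print.diel_dataset <- function(x, ...) {
  cat(sprintf("<diel_dataset> %d competitions, %d rounds, %d excluded\n",
              nrow(x$competitions), nrow(x$rounds), nrow(x$excluded)))
  if (nrow(x$rounds) > 0L) {
    ev <- dplyr::count(x$rounds, .data$event_id,
                       wt = .data$records_total, name = "records")
    at <- dplyr::count(x$rounds, .data$event_id,
                       wt = .data$attempts, name = "attempts")
    tab <- dplyr::left_join(at, ev, by = "event_id")
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  %s: %d attempts, %d records\n", tab$event_id[i],
                  tab$attempts[i], tab$records[i]))
    }
  }
  cov <- coverage_summary(x)
  cat(sprintf("  schedule coverage: %d/%d competitions (%.1f%%)\n",
              cov$retained, cov$queried, cov$coverage_pct))
  invisible(x)
}

#' Schedule coverage accounting
#'
#' Summarises how many of the competitions submitted to schedule ingestion
#' were retained (had machine-readable round start times) versus excluded,
#' with the per-reason exclusion breakdown. "Queried" is retained plus
#' excluded: competitions never submitted to ingestion are out of scope.
#'
#' @param x A `diel_dataset` or a `schedule_set` (from [read_schedules()]).
#' @return List with `retained`, `excluded`, `queried`, `coverage_pct` (on a
#'   0-100 scale) and a `reasons` table.
#' @export
coverage_summary <- function(x) {
  if (inherits(x, "diel_dataset")) {
    retained_ids <- unique(x$rounds$competition_id)
    excluded <- x$excluded
  } else if (inherits(x, "schedule_set")) {
    retained_ids <- unique(x$entries$competition_id)
    excluded <- x$excluded
  } else {
    stop("coverage_summary() expects a diel_dataset or schedule_set", call. = FALSE)
  }
  retained <- length(retained_ids)
  nexc <- nrow(excluded)
  queried <- retained + nexc
  list(
    retained = retained,
    excluded = nexc,
    queried = queried,
    coverage_pct = if (queried > 0L) 100 * retained / queried else NA_real_,
    reasons = if (nexc > 0L) dplyr::count(excluded, .data$reason) else
      tibble(reason = character(), n = integer())
  )
}
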