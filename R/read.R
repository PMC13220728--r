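#' Read a competition results table
#'
#' Reads per-round result tallies from a CSV/TSV file in either of two
#' documented dialects and normalises both to one row per
#' (competition, event, round) with pooled record-tier counts:
#'
#' * **Aggregated dialect** — one row per round with columns
#'   `competition_id`, `event_id`, `round_number`, `attempts`, `wr`, `cr`,
#'   `nr` (tier counts already pooled across single and average categories).
#' * **Per-solve dialect** — one row per started solve with columns
#'   `competition_id`, `event_id`, `round_number`, `record_single`,
#'   `record_average`, where the record-flag columns hold `""`/`NA` or one of
#'   `WR`, `CR`, `NR`. The reader counts rows as attempts (every started
#'   solve is one attempt, DNFs included) and sums flags over both columns,
#'   so a solve that sets both a single and an average record contributes two
#'   pooled records.
#'
#' The dialect is detected from the header. Gzip-compressed files are
#' accepted. Rows with zero attempts are retained: they carry zero exposure
#' and simply cannot host records.
#'
#' @param path Path to a CSV/TSV file, optionally `.gz`-compressed.
#' @param count_both_categories If `FALSE`, a per-solve row flagged in both
#'   the single and the average column contributes only its highest-priority
#'   flag (single wins). Default `TRUE`: flags are counted independently.
#' @return Tibble with columns `competition_id`, `event_id`, `round_number`,
#'   `attempts`, `wr`, `cr`, `nr`, `records_total`.
#' @export
read_results_table <- function(path, count_both_categories = TRUE) {
  delim <- if (grepl("\\.tsv(\\.gz)?$", path)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  results_tallies(df, count_both_categories = count_both_categories)
}

#' Normalise an in-memory results table to per-round tallies
#'
#' The data-frame counterpart of [read_results_table()]; accepts either
#' dialect described there.
#'
#' @param df Data frame in the aggregated or per-solve dialect.
#' @inheritParams read_results_table
#' @return Tibble of per-round tallies.
#' @export
results_tallies <- function(df, count_both_categories = TRUE) {
  df <- as_tibble(df)
  key <- c("competition_id", "event_id", "round_number")
  check_columns(df, key, "results table")
  df$event_id <- as.character(df$event_id)
  df$round_number <- as.integer(df$round_number)

  if (all(c("attempts", "wr", "cr", "nr") %in% names(df))) {
    out <- df[, c(key, "attempts", "wr", "cr", "nr")]
    for (col in c("attempts", "wr", "cr", "nr")) {
      if (any(is.na(out[[col]])) || any(out[[col]] < 0)) {
        stop("negative or missing counts in column '", col, "'", call. = FALSE)
      }
      out[[col]] <- as.integer(out[[col]])
    }
    out <- dplyr::summarise(
      dplyr::group_by(out, .data$competition_id, .data$event_id, .data$round_number),
      dplyr::across(c("attempts", "wr", "cr", "nr"), sum),
      .groups = "drop"
    )
  } else if (all(c("record_single", "record_average") %in% names(df))) {
    tally_flag <- function(single, average, tier) {
      s <- !is.na(single) & single == tier
      a <- !is.na(average) & average == tier
      if (count_both_categories) as.integer(s) + as.integer(a)
      else as.integer(s | a)
    }
    flags <- c("WR", "CR", "NR")
    known <- function(x) all(is.na(x) | x %in% c(flags, ""))
    if (!known(df$record_single) || !known(df$record_average)) {
      stop("record flags must be one of WR, CR, NR or empty", call. = FALSE)
    }
    df$record_single[!is.na(df$record_single) & df$record_single == ""] <- NA
    df$record_average[!is.na(df$record_average) & df$record_average == ""] <- NA
    df$.wr <- tally_flag(df$record_single, df$record_average, "WR")
    df$.cr <- tally_flag(df$record_single, df$record_average, "CR")
    df$.nr <- tally_flag(df$record_single, df$record_average, "NR")
    out <- dplyr::summarise(
      dplyr::group_by(df, .data$competition_id, .data$event_id, .data$round_number),
      attempts = dplyr::n(),
      wr = sum(.data$.wr), cr = sum(.data$.cr), nr = sum(.data$.nr),
      .groups = "drop"
    )
  } else {
    stop("results table must have either aggregated columns ",
         "(attempts, wr, cr, nr) or per-solve columns ",
         "(record_single, record_average)", call. = FALSE)
  }

  out$records_total <- out$wr + out$cr + out$nr
  if (any(out$records_total > out$attempts)) {
    stop("records_total exceeds attempts for some round(s)", call. = FALSE)
  }
  dplyr::arrange(out, .data$competition_id, .data$event_id, .data$round_number)
}

#' Read a competitions metadata table
#'
#' CSV with columns `competition_id`, `country`, `continent`, `year`,
#' `timezone`; validated via [validate_competitions()]. Gzip accepted.
#'
#' @param path Path to CSV (optionally `.gz`).
#' @return Validated competitions tibble.
#' @export
read_competitions <- function(path) {
  validate_competitions(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  )
}

#' Parse one schedule document (WCIF-style subset)
#'
#' The supported subset of the competition schedule interchange format is:
#' top-level `id`; `schedule$venues[]`, each venue with an IANA `timezone`
#' and `rooms[]`; each room with `activities[]`; each activity with an
#' `activityCode` of the form `"<event>-r<round>"` and a UTC `startTime`.
#' Activities whose code does not match that form (lunch breaks, awards) are
#' ignored. When the same (event, round) appears in several rooms or venues,
#' the earliest start wins, and the timezone of the venue hosting that
#' earliest activity is used.
#'
#' A document with no venues, rooms or round activities is not an error: the
#' competition is marked excluded with reason `"no schedule"` (electronic
#' scheduling simply was not in use). A malformed start timestamp excludes
#' the competition with reason `"parse failure"`.
#'
#' @param x A parsed JSON document (nested list, as from
#'   [jsonlite::read_json()]).
#' @param competition_id Fallback id when the document lacks a top-level `id`.
#' @return List with `entries` (tibble: `competition_id`, `event_id`,
#'   `round_number`, `utc_start`, `timezone`) and `excluded` (zero- or
#'   one-row tibble with `competition_id`, `reason`).
#' @export
parse_schedule <- function(x, competition_id = NULL) {
  id <- x[["id"]] %||% competition_id
  if (is.null(id)) stop("schedule document has no competition id", call. = FALSE)
  id <- as.character(id)

  no_entries <- function(reason) {
    list(entries = empty_schedule_entries(),
         excluded = tibble(competition_id = id, reason = reason))
  }

  venues <- x[["schedule"]][["venues"]]
  if (is.null(venues) || length(venues) == 0L) return(no_entries("no schedule"))

  rows <- list()
  for (venue in venues) {
    tz <- venue[["timezone"]]
    for (room in venue[["rooms"]] %||% list()) {
      for (act in room[["activities"]] %||% list()) {
        code <- act[["activityCode"]]
        if (is.null(code) || !grepl("^[A-Za-z0-9]+-r\\d+$", code)) next
        rows[[length(rows) + 1L]] <- list(
          event_id = sub("-r\\d+$", "", code),
          round_number = as.integer(sub("^.*-r", "", code)),
          start_raw = as.character(act[["startTime"]] %||% NA_character_),
          timezone = as.character(tz %||% NA_character_)
        )
      }
    }
  }
  if (length(rows) == 0L) return(no_entries("no schedule"))

  ent <- dplyr::bind_rows(lapply(rows, as_tibble))
  ent$utc_start <- parse_utc(ent$start_raw)
  if (anyNA(ent$utc_start)) return(no_entries("parse failure"))

  ent$competition_id <- id
  ent <- dplyr::slice_min(
    dplyr::group_by(ent, .data$competition_id, .data$event_id, .data$round_number),
    order_by = .data$utc_start, n = 1L, with_ties = FALSE
  )
  ent <- dplyr::ungroup(ent)
  list(
    entries = dplyr::arrange(
      ent[, c("competition_id", "event_id", "round_number", "utc_start", "timezone")],
      .data$competition_id, .data$event_id, .data$round_number
    ),
    excluded = tibble(competition_id = character(), reason = character())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
empty_schedule_entries <- function() {
  tibble(competition_id = character(), event_id = character(),
         round_number = integer(),
         utc_start = as.POSIXct(character(), tz = "UTC"),
         timezone = character())
}

#' Read one schedule JSON file
#'
#' @param path Path to a JSON file (optionally `.gz`). A missing file is a
#'   hard error here; [read_schedules()] turns missing files into `"no
#'   file"` exclusions.
#' @param competition_id Fallback id (defaults to the filename stem).
#' @return As [parse_schedule()].
#' @export
read_schedule_json <- function(path, competition_id = NULL) {
  if (is.null(competition_id)) {
    competition_id <- sub("\\.json(\\.gz)?$", "", basename(path))
  }
  if (!file.exists(path)) stop("no such schedule file: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con), add = TRUE)
  doc <- tryCatch(jsonlite::parse_json(paste(readLines(con, warn = FALSE),
                                             collapse = "\n")),
                  error = function(e) NULL)
  if (is.null(doc)) {
    return(list(entries = empty_schedule_entries(),
                excluded = tibble(competition_id = competition_id,
                                  reason = "parse failure")))
  }
  parse_schedule(doc, competition_id = competition_id)
}

#' Read a set of schedule files
#'
#' Reads every schedule JSON for a set of competitions and accumulates the
#' three-way exclusion ledger: `"no file"` (path missing), `"no schedule"`
#' (document carries no venue/activity records) and `"parse failure"`
#' (unreadable JSON or malformed timestamp).
#'
#' @param paths Character vector of JSON paths. Names, if present, are taken
#'   as competition ids; otherwise the filename stem is used. Alternatively a
#'   single directory, in which case all `*.json`/`*.json.gz` files in it are
#'   read.
#' @return A `schedule_set`: list with `entries` and `excluded` tibbles.
#' @export
read_schedules <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.json(\\.gz)?$", full.names = TRUE)
  }
  ids <- names(paths) %||% sub("\\.json(\\.gz)?$", "", basename(paths))
  ids[ids == ""] <- sub("\\.json(\\.gz)?$", "", basename(paths[ids == ""]))

  entries <- vector("list", length(paths))
  excluded <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    if (!file.exists(paths[i])) {
      excluded[[i]] <- tibble(competition_id = ids[i], reason = "no file")
      next
    }
    parsed <- read_schedule_json(paths[i], competition_id = ids[i])
    entries[[i]] <- parsed$entries
    excluded[[i]] <- parsed$excluded
  }
  schedule_set(dplyr::bind_rows(entries), dplyr::bind_rows(excluded))
}

#' Construct a schedule set from entries and an exclusion ledger
#'
#' @param entries Tibble of schedule entries (`competition_id`, `event_id`,
#'   `round_number`, `utc_start`, `timezone`).
#' @param excluded Tibble with `competition_id`, `reason`.
#' @return A `schedule_set` object.
#' @export
schedule_set <- function(entries = empty_schedule_entries(),
                         excluded = tibble(competition_id = character(),
                                           reason = character())) {
  entries <- as_tibble(entries)
  if (nrow(entries) == 0L) entries <- empty_schedule_entries()
  check_columns(entries, c("competition_id", "event_id", "round_number",
                           "utc_start", "timezone"), "schedule entries")
  excluded <- as_tibble(excluded)
  check_columns(excluded, c("competition_id", "reason"), "exclusion ledger")
  overlap <- intersect(unique(entries$competition_id),
                       unique(excluded$competition_id))
  if (length(overlap) > 0L) {
    stop("competition(s) both retained and excluded: ",
         paste(utils::head(overlap, 3L), collapse = ", "), call. = FALSE)
  }
  structure(list(entries = entries, excluded = excluded),
            class = "schedule_set")
}

#' @export
print.schedule_set <- function(x, ...) {
  cov <- coverage_summary(x)
  cat(sprintf("<schedule_set> %d entries, %d/%d competitions retained (%.1f%%)\n",
              nrow(x$entries), cov$retained, cov$queried, cov$coverage_pct))
  invisible(x)
}

#' Derive round stages within one competition-event group
#'
#' Round numbers within a (competition, event) group must form a contiguous
#' sequence starting at 1 (the contest order). The highest round number is
#' the final. Stage labels partition the rounds with final status taking
#' precedence: `"final"` for the last round, `"early"` for rounds 1-2 that
#' are not the final, `"other"` for any later non-final round.
#'
#' @param round_number Integer vector of round numbers for one group.
#' @return Tibble with `round_number`, `is_final`, `stage` in input order.
#' @examples
#' map_round_stage(1:3) # rounds 1,2 early; round 3 final
#' map_round_stage(1)   # a single-round event's only round is the final
#' @export
map_round_stage <- function(round_number) {
  round_number <- as.integer(round_number)
  if (anyDuplicated(round_number)) {
    stop("duplicate round_number within a competition-event group", call. = FALSE)
  }
  if (!setequal(round_number, seq_len(length(round_number)))) {
    stop("round numbers must be contiguous from 1; got ",
         paste(sort(round_number), collapse = ","), call. = FALSE)
  }
  is_final <- round_number == max(round_number)
  stage <- ifelse(is_final, "final",
                  ifelse(round_number <= 2L, "early", "other"))
  tibble(round_number = round_number, is_final = is_final, stage = stage)
}

#' Join results, schedules and competition metadata into a dataset
#'
#' Inner-joins per-round result tallies with schedule entries on
#' (competition, event, round), converts each retained round's UTC start to
#' local civil time using the venue timezone (falling back to the
#' competitions table when the schedule carries none), assigns time-of-day
#' bins, and derives round stages. Rounds lacking a schedule entry are
#' dropped; a competition whose rounds all lack entries joins the exclusion
#' ledger with reason `"no schedule"`. A coverage summary is reported via
#' [coverage_summary()] and `print()`.
#'
#' @param results Per-round tallies from [read_results_table()] /
#'   [results_tallies()].
#' @param schedules A `schedule_set` from [read_schedules()] (or a plain
#'   entries tibble, taken as having an empty exclusion ledger).
#' @param competitions Competitions tibble.
#' @param events Events to retain (default the four analysis events).
#' @param bin_minutes Bin width for time-of-day discretisation.
#' @return A [diel_dataset()].
#' @export
join_dataset <- function(results, schedules, competitions,
                         events = DEFAULT_EVENTS, bin_minutes = 15L) {
  if (!inherits(schedules, "schedule_set")) schedules <- schedule_set(schedules)
  competitions <- validate_competitions(competitions)
  results <- as_tibble(results)
  check_columns(results, c("competition_id", "event_id", "round_number",
                           "attempts", "wr", "cr", "nr", "records_total"),
                "results tallies")
  results <- results[results$event_id %in% events, , drop = FALSE]

  # Stage structure comes from the full contested round sequence, before any
  # schedule-driven drop can break its contiguity.
  if (nrow(results) > 0L) {
    chk <- dplyr::summarise(
      dplyr::group_by(results, .data$competition_id, .data$event_id),
      ok = !anyDuplicated(.data$round_number) &&
        setequal(.data$round_number, seq_along(.data$round_number)),
      .groups = "drop"
    )
    if (!all(chk$ok)) {
      bad <- chk[!chk$ok, ]
      stop("round numbers must be a contiguous sequence from 1 within each ",
           "competition-event group; offending group(s): ",
           paste(utils::head(paste(bad$competition_id, bad$event_id, sep = "/"), 3L),
                 collapse = ", "), call. = FALSE)
    }
    results <- dplyr::mutate(
      dplyr::group_by(results, .data$competition_id, .data$event_id),
      is_final = .data$round_number == max(.data$round_number),
      stage = ifelse(.data$is_final, "final",
                     ifelse(.data$round_number <= 2L, "early", "other"))
    )
    results <- dplyr::ungroup(results)
  } else {
    results$is_final <- logical()
    results$stage <- character()
  }

  joined <- dplyr::inner_join(
    results, schedules$entries,
    by = c("competition_id", "event_id", "round_number")
  )

  # competitions with results for analysed events but no joined round at all
  resultful <- unique(results$competition_id)
  joined_ids <- unique(joined$competition_id)
  already <- unique(schedules$excluded$competition_id)
  unscheduled <- setdiff(setdiff(resultful, joined_ids), already)
  excluded <- dplyr::bind_rows(
    schedules$excluded,
    tibble(competition_id = unscheduled,
           reason = rep("no schedule", length(unscheduled)))
  )

  joined <- joined[joined$competition_id %in% competitions$competition_id, ,
                   drop = FALSE]

  if (nrow(joined) > 0L) {
    tzmap <- stats::setNames(competitions$timezone, competitions$competition_id)
    tz <- joined$timezone
    tz[is.na(tz)] <- tzmap[joined$competition_id[is.na(tz)]]
    joined$local_start <- to_local(joined$utc_start, tz)
    joined$bin <- assign_bin(joined$local_start, bin_minutes)
  } else {
    joined$local_start <- character()
    joined$bin <- integer()
  }

  rounds <- joined[, c("competition_id", "event_id", "round_number", "is_final",
                       "stage", "utc_start", "local_start", "bin", "attempts",
                       "wr", "cr", "nr", "records_total")]
  keep <- competitions[competitions$competition_id %in%
                         unique(rounds$competition_id), , drop = FALSE]
  diel_dataset(keep, rounds, excluded = excluded, bin_minutes = bin_minutes)
}
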