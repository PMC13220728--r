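#' Stratified window dip ratios
#'
#' Computes the outside-to-inside window rate ratio separately within strata
#' of one grouping, using the same rate metric and window definition as the
#' unstratified analysis:
#'
#' * `"continent"` — the competition's continent;
#' * `"era"` — competitive era by competition calendar year, `"pre-2023"`
#'   (years through 2022) versus `"2023+"` (2023 onwards; boundary
#'   configurable via `era_split`);
#' * `"round_stage"` — `"early"` (rounds 1-2 that are not the final),
#'   `"final"`, and `"other"` (later non-final rounds, reported explicitly
#'   rather than merged into either printed stratum).
#'
#' Each stratum's rates are obtained by restricting the dataset to that
#' stratum and re-running the window contrast, so a grouping with a single
#' stratum reproduces the unstratified ratio exactly. Strata with records
#' but no inside-window (or no outside-window) exposure are reported with
#' `testable = FALSE` and `NA` rates rather than dropped silently.
#'
#' @param dataset A [diel_dataset()].
#' @param event_id Event to analyse.
#' @param grouping One of `"continent"`, `"era"`, `"round_stage"`.
#' @param window A [window_spec()].
#' @param scale Display scale (default per-event convention).
#' @param era_split First year of the later era (default 2023).
#' @return Tibble with `grouping`, `label`, `n_records`, `inside_rate`,
#'   `outside_rate`, `dip_ratio`, `testable`.
#' @export
dip_ratio_by <- function(dataset, event_id,
                         grouping = c("continent", "era", "round_stage"),
                         window = window_spec(), scale = NULL,
                         era_split = 2023L) {
  stopifnot(inherits(dataset, "diel_dataset"))
  grouping <- match.arg(grouping)
  if (is.null(scale)) scale <- unname(event_scale(event_id))
  rounds <- dataset$rounds[dataset$rounds$event_id == event_id, , drop = FALSE]
  if (nrow(rounds) == 0L) {
    stop("no rounds for event '", event_id, "'", call. = FALSE)
  }

  label <- switch(
    grouping,
    continent = {
      cmap <- stats::setNames(dataset$competitions$continent,
                              dataset$competitions$competition_id)
      unname(cmap[rounds$competition_id])
    },
    era = {
      ymap <- stats::setNames(dataset$competitions$year,
                              dataset$competitions$competition_id)
      yr <- unname(ymap[rounds$competition_id])
      ifelse(yr >= era_split, paste0(era_split, "+"), paste0("pre-", era_split))
    },
    round_stage = rounds$stage
  )

  out <- lapply(sort(unique(label)), function(lab) {
    sub <- rounds[label == lab, , drop = FALSE]
    tab <- stratum_bin_table(sub, event_id, scale, dataset$bin_minutes)
    wr <- tryCatch(window_rates(tab, window), error = function(e) NULL)
    if (is.null(wr)) {
      tibble(grouping = grouping, label = lab,
             n_records = sum(sub$records_total),
             inside_rate = NA_real_, outside_rate = NA_real_,
             dip_ratio = NA_real_, testable = FALSE)
    } else {
      # inside exposure with zero records leaves the ratio undefined (the
      # suppression estimate is unbounded); rates are still reported
      ratio <- if (wr$inside_rate > 0)
        window_ratio(wr$inside_rate, wr$outside_rate) else NA_real_
      tibble(grouping = grouping, label = lab,
             n_records = wr$inside_records + wr$outside_records,
             inside_rate = wr$inside_rate, outside_rate = wr$outside_rate,
             dip_ratio = ratio, testable = TRUE)
    }
  })
  dplyr::bind_rows(out)
}

# bin table for a subset of rounds without re-filtering by event
#' @noRd
stratum_bin_table <- function(rounds, event_id, scale, bin_minutes) {
  nb <- n_bins(bin_minutes)
  attempts <- numeric(nb)
  records <- numeric(nb)
  if (nrow(rounds) > 0L) {
    at <- rowsum(rounds$attempts, rounds$bin)
    re <- rowsum(rounds$records_total, rounds$bin)
    idx <- as.integer(rownames(at)) + 1L
    attempts[idx] <- at[, 1L]
    records[idx] <- re[, 1L]
  }
  bin_table(bins = seq_len(nb) - 1L, attempts = attempts, records = records,
            event_id = event_id, scale = scale, min_attempts = 1L,
            bin_minutes = bin_minutes)
}

#' Final-round composition at the evening peak
#'
#' Locates the bin with the most records inside an evening search window
#' (ties broken toward the earlier bin) and reports the share of that bin's
#' records contributed by final rounds. A share near 1 indicates the raw
#' evening elevation is driven by finals scheduling and competitor
#' selection rather than a diel performance effect.
#'
#' @param dataset A [diel_dataset()].
#' @param event_id Event to analyse.
#' @param search_window A [window_spec()] delimiting the evening search
#'   range; default 17:00-19:00 local, which brackets typical finals slots.
#' @return List with `event_id`, `peak_bin`, `peak_clock_label`,
#'   `peak_records`, `final_records`, `final_share`.
#' @export
final_round_share <- function(dataset, event_id,
                              search_window = window_spec("17:00", "19:00")) {
  stopifnot(inherits(dataset, "diel_dataset"),
            inherits(search_window, "window_spec"))
  rounds <- dataset$rounds[dataset$rounds$event_id == event_id, , drop = FALSE]
  rounds <- rounds[rounds$bin %in% search_window$bins, , drop = FALSE]
  if (nrow(rounds) == 0L || sum(rounds$records_total) == 0) {
    stop("no records in the evening search window for event '", event_id, "'",
         call. = FALSE)
  }
  per_bin <- dplyr::summarise(
    dplyr::group_by(rounds, .data$bin),
    records = sum(.data$records_total),
    final_records = sum(.data$records_total[.data$is_final]),
    .groups = "drop"
  )
  per_bin <- per_bin[per_bin$records > 0, , drop = FALSE]
  peak <- per_bin[order(-per_bin$records, per_bin$bin), ][1L, ]
  list(
    event_id = event_id,
    peak_bin = peak$bin,
    peak_clock_label = bin_clock_label(peak$bin, dataset$bin_minutes),
    peak_records = peak$records,
    final_records = peak$final_records,
    final_share = peak$final_records / peak$records
  )
}

#' Write a stratified sensitivity table to CSV
#' @param x Tibble from [dip_ratio_by()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
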