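#' Tally exposure and records into time-of-day bins
#'
#' Aggregates one event's round observations into per-bin attempt and record
#' totals and derives the exposure-adjusted rate for each bin:
#' `rate = scale * records / attempts`, i.e. records per `scale` attempts.
#' A bin is *valid* when its attempt total reaches `min_attempts`; rates in
#' bins with zero attempts are undefined (`NA`). Exact Poisson confidence
#' limits for the per-bin record count are attached on the scaled-rate axis.
#' The overall rate `r_bar` is the unweighted mean of the per-bin rates over
#' valid bins (set `rate_mean = "weighted"` for the attempt-weighted
#' alternative, which equals the event's pooled rate over valid bins).
#'
#' @param dataset A [diel_dataset()].
#' @param event_id Single event identifier present in the dataset.
#' @param scale Display denominator (records per `scale` attempts); default
#'   the per-event convention from [event_scale()].
#' @param min_attempts Validity threshold on per-bin attempts; default from
#'   [event_min_attempts()].
#' @param level Confidence level for the Poisson intervals.
#' @param rate_mean `"unweighted"` (default) or `"weighted"`; how the overall
#'   rate across valid bins is averaged.
#' @return A `bin_table`: tibble with one row per bin (`bin`, `clock_label`,
#'   `attempts`, `records`, `rate`, `ci_low`, `ci_high`, `valid`) and
#'   attributes `event_id`, `scale`, `min_attempts`, `overall_rate`,
#'   `bin_minutes`, `rate_mean`.
#' @export
tally_bins <- function(dataset, event_id,
                       scale = NULL, min_attempts = NULL, level = 0.95,
                       rate_mean = c("unweighted", "weighted")) {
  stopifnot(inherits(dataset, "diel_dataset"))
  rate_mean <- match.arg(rate_mean)
  rounds <- dataset$rounds[dataset$rounds$event_id == event_id, , drop = FALSE]
  if (nrow(rounds) == 0L) {
    stop("no rounds for event '", event_id, "' in dataset", call. = FALSE)
  }
  if (is.null(scale)) scale <- unname(event_scale(event_id))
  if (is.null(min_attempts)) min_attempts <- unname(event_min_attempts(event_id))

  nb <- n_bins(dataset$bin_minutes)
  attempts <- integer(nb)
  records <- integer(nb)
  at <- rowsum(rounds$attempts, rounds$bin)
  re <- rowsum(rounds$records_total, rounds$bin)
  idx <- as.integer(rownames(at)) + 1L
  attempts[idx] <- at[, 1L]
  records[idx] <- re[, 1L]

  bin_table(bins = seq_len(nb) - 1L, attempts = attempts, records = records,
            event_id = event_id, scale = scale, min_attempts = min_attempts,
            level = level, bin_minutes = dataset$bin_minutes,
            rate_mean = rate_mean)
}

#' @noRd
bin_table <- function(bins, attempts, records, event_id, scale, min_attempts,
                      level = 0.95, bin_minutes = 15L,
                      rate_mean = "unweighted") {
  rate <- ifelse(attempts > 0, scale * records / attempts, NA_real_)
  ci <- matrix(NA_real_, length(bins), 2L)
  pos <- attempts > 0
  if (any(pos)) {
    ci[pos, ] <- t(vapply(which(pos), function(i) {
      poisson_ci(records[i], attempts[i], scale = scale, level = level)
    }, numeric(2L)))
  }
  valid <- attempts >= min_attempts
  overall <- if (any(valid)) {
    if (rate_mean == "unweighted") mean(rate[valid])
    else scale * sum(records[valid]) / sum(attempts[valid])
  } else NA_real_

  out <- tibble(
    bin = as.integer(bins),
    clock_label = bin_clock_label(bins, bin_minutes),
    attempts = as.numeric(attempts),
    records = as.numeric(records),
    rate = rate,
    ci_low = ci[, 1L],
    ci_high = ci[, 2L],
    valid = valid
  )
  structure(out, class = c("bin_table", class(out)),
            event_id = event_id, scale = scale, min_attempts = min_attempts,
            level = level, overall_rate = overall, bin_minutes = bin_minutes,
            rate_mean = rate_mean)
}

#' Overall (mean) rate of a bin table
#' @param bintable A `bin_table` from [tally_bins()].
#' @return The mean rate across valid bins, on the scaled-rate axis.
#' @export
overall_rate <- function(bintable) {
  stopifnot(inherits(bintable, "bin_table"))
  attr(bintable, "overall_rate")
}

#' Exact Poisson confidence interval for a scaled event rate
#'
#' Garwood-style exact interval for the mean of the Poisson count `records`,
#' obtained by inverting the cumulative Poisson distribution (equivalently
#' via chi-square quantiles), then expressed as records per `scale` attempts.
#' The lower limit is exactly 0 when no records were observed. The exact
#' interval is preferred over a normal approximation because per-bin record
#' counts are small.
#'
#' @param records Non-negative record count.
#' @param attempts Positive attempt count (the exposure).
#' @param scale Display denominator.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)` on the scaled-rate axis.
#' @examples
#' poisson_ci(0, 10000, scale = 50000) # lower limit exactly 0
#' @export
poisson_ci <- function(records, attempts, scale = 1, level = 0.95) {
  stopifnot(length(records) == 1L, length(attempts) == 1L)
  if (is.na(attempts) || attempts <= 0) {
    stop("poisson_ci() requires attempts > 0", call. = FALSE)
  }
  if (records < 0) stop("negative record count", call. = FALSE)
  alpha <- 1 - level
  low <- if (records == 0) 0 else stats::qchisq(alpha / 2, 2 * records) / 2
  high <- stats::qchisq(1 - alpha / 2, 2 * (records + 1)) / 2
  c(low, high) / attempts * scale
}

#' Inside- and outside-window pooled rates
#'
#' Pools attempts and records over the window's bins (inside) and over its
#' complement restricted to bins with at least one attempt (outside), and
#' returns both pooled rates on the scaled axis. Note the outside bin set
#' (>= 1 attempt) is deliberately different from the display validity filter
#' (`min_attempts`): the window contrast uses every bin that carries
#' exposure.
#'
#' @param bintable A `bin_table` from [tally_bins()].
#' @param window A [window_spec()].
#' @return List with `inside_rate`, `outside_rate`, `inside_records`,
#'   `outside_records`, `inside_attempts`, `outside_attempts`.
#' @export
window_rates <- function(bintable, window = window_spec()) {
  stopifnot(inherits(bintable, "bin_table"), inherits(window, "window_spec"))
  if (window$bin_minutes != attr(bintable, "bin_minutes")) {
    stop("window and bin table use different bin widths", call. = FALSE)
  }
  scale <- attr(bintable, "scale")
  inside <- bintable$bin %in% window$bins
  outside <- !inside & bintable$attempts >= 1

  in_att <- sum(bintable$attempts[inside])
  out_att <- sum(bintable$attempts[outside])
  if (in_att == 0 || out_att == 0) {
    stop("window contrast untestable: zero attempts ",
         if (in_att == 0) "inside" else "outside", " the window", call. = FALSE)
  }
  in_rec <- sum(bintable$records[inside])
  out_rec <- sum(bintable$records[outside])
  list(
    inside_rate = scale * in_rec / in_att,
    outside_rate = scale * out_rec / out_att,
    inside_records = in_rec, outside_records = out_rec,
    inside_attempts = in_att, outside_attempts = out_att
  )
}

#' Write a per-bin rate table to CSV
#'
#' @param bintable A `bin_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(bintable, path) {
  stopifnot(inherits(bintable, "bin_table"))
  readr::write_csv(as_tibble(bintable), path)
  invisible(path)
}
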