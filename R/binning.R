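#' Convert UTC timestamps to local civil clock time
#'
#' Converts round start times from UTC to the local civil time of the venue
#' using the IANA timezone database bundled with R. Daylight-saving
#' transitions are applied automatically by the zone's own rules. Only the
#' clock time survives the conversion: the civil date is dropped, because the
#' analysis pools rounds across dates and treats local clock time as a proxy
#' for diel phase.
#'
#' @param utc_start A `POSIXct` vector in UTC (or an ISO-8601 character
#'   vector such as `"2024-06-01T00:30:00Z"`, which is parsed as UTC).
#' @param timezone Character vector of IANA zone identifiers (recycled if
#'   length 1). Unknown zones are a hard error: venue timezones are expected
#'   to be curated upstream and no geographic imputation is attempted.
#' @return Character vector of local clock times, `"HH:MM"`.
#' @examples
#' to_local("2024-07-01T14:00:00Z", "America/Chicago") # "09:00"
#' to_local("2024-06-01T00:30:00Z", "Asia/Tokyo")      # "09:30"
#' @export
to_local <- function(utc_start, timezone) {
  if (is.character(utc_start)) {
    utc_start <- parse_utc(utc_start)
    if (anyNA(utc_start)) {
      stop("malformed UTC timestamp(s); expected ISO-8601 like 2024-06-01T00:30:00Z",
           call. = FALSE)
    }
  }
  stopifnot(inherits(utc_start, "POSIXct"))
  if (length(timezone) == 1L) timezone <- rep(timezone, length(utc_start))
  stopifnot(length(timezone) == length(utc_start))
  check_timezone(timezone)

  out <- character(length(utc_start))
  for (tz in unique(timezone)) {
    idx <- which(timezone == tz)
    out[idx] <- format(utc_start[idx], tz = tz, format = "%H:%M")
  }
  out
}

#' @noRd
check_timezone <- function(timezone) {
  bad <- setdiff(unique(timezone), OlsonNames())
  if (length(bad) > 0L) {
    stop("unknown IANA timezone(s): ", paste(bad, collapse = ", "),
         " (no geographic imputation is performed)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Parse ISO-8601 UTC timestamps strictly
#'
#' Accepts `YYYY-MM-DDTHH:MM:SS` with a trailing `Z` or numeric offset.
#' Returns `NA` for malformed entries rather than guessing.
#'
#' @param x Character vector.
#' @return `POSIXct` vector in UTC, `NA` where unparseable.
#' @keywords internal
#' @export
parse_utc <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  ok_z <- grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}(\\.\\d+)?Z$", x)
  out[ok_z] <- as.POSIXct(x[ok_z], format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  ok_off <- grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}(\\.\\d+)?[+-]\\d{2}:?\\d{2}$", x)
  if (any(ok_off)) {
    y <- sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", x[ok_off])
    out[ok_off] <- as.POSIXct(y, format = "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC")
  }
  out
}

#' Assign a local clock time to a time-of-day bin
#'
#' Bins tile the civil day in `bin_minutes`-wide half-open intervals
#' `[start, start + bin_minutes)`. With the default 15-minute width there are
#' 96 bins indexed 0-95 and `bin = 4 * hour + minute %/% 15`; a round starting
#' exactly on a boundary belongs to the later bin.
#'
#' @param local Character vector of `"HH:MM"` clock times (as returned by
#'   [to_local()]).
#' @param bin_minutes Bin width in minutes; must divide 60. Default 15.
#' @return Integer vector of bin indices in `0:(1440 / bin_minutes - 1)`.
#' @examples
#' assign_bin(c("00:00", "12:30", "14:45", "15:00", "23:59"))
#' # 0 50 59 60 95
#' @export
assign_bin <- function(local, bin_minutes = 15L) {
  check_bin_minutes(bin_minutes)
  ok <- grepl("^\\d{1,2}:\\d{2}$", local)
  if (!all(ok)) {
    stop("local clock times must be 'HH:MM'; got e.g. ",
         local[which(!ok)[1L]], call. = FALSE)
  }
  hh <- as.integer(sub(":.*$", "", local))
  mm <- as.integer(sub("^.*:", "", local))
  if (any(hh > 23L | mm > 59L)) stop("clock time out of range", call. = FALSE)
  as.integer((hh * 60L + mm) %/% bin_minutes)
}

#' @noRd
check_bin_minutes <- function(bin_minutes) {
  if (length(bin_minutes) != 1L || is.na(bin_minutes) ||
      bin_minutes <= 0 || 60 %% bin_minutes != 0) {
    stop("bin_minutes must be a positive divisor of 60", call. = FALSE)
  }
  invisible(TRUE)
}

#' @noRd
n_bins <- function(bin_minutes = 15L) as.integer(1440L %/% bin_minutes)

#' Label a bin by the clock time it starts at
#' @param bin Integer bin indices.
#' @param bin_minutes Bin width in minutes.
#' @return Character `"HH:MM"` labels.
#' @export
bin_clock_label <- function(bin, bin_minutes = 15L) {
  check_bin_minutes(bin_minutes)
  m <- bin * bin_minutes
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}

#' Define a local-time window as a set of bins
#'
#' A window is the half-open local-time interval `[start, end)`, materialised
#' as the set of bins whose start times fall inside it. The default,
#' 12:30-15:00, is the post-prandial window: the early-afternoon interval in
#' which a transient alertness reduction tied to the 12-hour harmonic of the
#' circadian system is expected. With 15-minute bins it comprises bins 50-59;
#' a round starting exactly at the end boundary is outside.
#'
#' @param start,end `"HH:MM"` clock times on bin boundaries; `start < end`.
#' @param bin_minutes Bin width in minutes; must divide 60.
#' @return An object of class `window_spec`: a list with `start`, `end`,
#'   `bin_minutes` and the integer bin set `bins`.
#' @examples
#' window_spec() # post-prandial default, bins 50..59
#' window_spec("09:00", "09:15") # single bin 36
#' @export
window_spec <- function(start = "12:30", end = "15:00", bin_minutes = 15L) {
  check_bin_minutes(bin_minutes)
  parse_clock <- function(x, what) {
    if (!grepl("^\\d{1,2}:\\d{2}$", x)) {
      stop(what, " must be 'HH:MM'", call. = FALSE)
    }
    hh <- as.integer(sub(":.*$", "", x))
    mm <- as.integer(sub("^.*:", "", x))
    if (hh > 24L || mm > 59L) stop(what, " out of range", call. = FALSE)
    hh * 60L + mm
  }
  s <- parse_clock(start, "start")
  e <- parse_clock(end, "end")
  if (s %% bin_minutes != 0L || e %% bin_minutes != 0L) {
    stop("window boundaries must lie on ", bin_minutes,
         "-minute bin boundaries", call. = FALSE)
  }
  if (s >= e) stop("window must be non-empty: start < end", call. = FALSE)
  structure(
    list(start = start, end = end, bin_minutes = as.integer(bin_minutes),
         bins = as.integer(seq.int(s %/% bin_minutes, e %/% bin_minutes - 1L))),
    class = "window_spec"
  )
}

#' Bin indices covered by a window
#' @param spec A [window_spec()].
#' @return Integer vector of bin indices (end-exclusive).
#' @export
window_bins <- function(spec) {
  stopifnot(inherits(spec, "window_spec"))
  spec$bins
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %s-%s (%d-min bins: %s)\n",
              x$start, x$end, x$bin_minutes,
              paste(range(x$bins), collapse = "..")))
  invisible(x)
}
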