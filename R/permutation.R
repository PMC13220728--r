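#' Multinomially reallocate a stratum's records across its rounds
#'
#' The permutation null preserves each stratum's schedule and exposure
#' exactly: the stratum's total record count is redistributed over its
#' rounds by a multinomial draw with probabilities proportional to the
#' observed per-round attempt counts. Attempts themselves are never moved.
#'
#' @param attempts Non-negative per-round attempt counts for one stratum.
#' @param total_records The stratum's total record count to reallocate.
#' @param draws Number of independent reallocations.
#' @return An integer matrix, `length(attempts)` rows by `draws` columns;
#'   each column sums to `total_records`. Uses R's global RNG stream.
#' @examples
#' set.seed(1)
#' permute_stratum(c(100, 0), 5) # all 5 records forced into round 1
#' @export
permute_stratum <- function(attempts, total_records, draws = 1L) {
  stopifnot(all(attempts >= 0), total_records >= 0)
  if (total_records > 0 && sum(attempts) == 0) {
    stop("cannot reallocate records over a stratum with zero exposure",
         call. = FALSE)
  }
  if (total_records == 0 || sum(attempts) == 0) {
    return(matrix(0L, nrow = length(attempts), ncol = draws))
  }
  stats::rmultinom(draws, size = total_records, prob = attempts)
}

#' Normalised maximum absolute deviation of a rate curve
#'
#' The non-uniformity statistic `T = max_b |r_b - r_bar| / r_bar`, taken
#' over valid bins, where `r_bar` is the bin table's overall rate. `T` is
#' invariant to rescaling of the rate axis; `T = 0` iff the valid-bin rates
#' are exactly uniform.
#'
#' @param bintable A `bin_table` from [tally_bins()].
#' @return The statistic as a single number.
#' @export
max_deviation_stat <- function(bintable) {
  stopifnot(inherits(bintable, "bin_table"))
  rates <- bintable$rate[bintable$valid]
  if (length(rates) < 2L) {
    stop("need at least 2 valid bins for the non-uniformity statistic",
         call. = FALSE)
  }
  r_bar <- attr(bintable, "overall_rate")
  if (is.na(r_bar) || r_bar <= 0) {
    stop("degenerate rate curve: no records in valid bins", call. = FALSE)
  }
  max(abs(rates - r_bar)) / r_bar
}

#' Outside-to-inside window rate ratio
#'
#' The post-prandial contrast statistic: values above 1 indicate suppressed
#' record probability inside the window relative to the rest of the day.
#'
#' @param inside_rate,outside_rate Pooled rates on a common scale.
#' @return `outside_rate / inside_rate`.
#' @examples
#' window_ratio(26.51, 30.20) # 1.14 after rounding
#' @export
window_ratio <- function(inside_rate, outside_rate) {
  if (any(inside_rate <= 0)) {
    stop("window ratio undefined: inside rate must be positive", call. = FALSE)
  }
  outside_rate / inside_rate
}

#' Within-competition permutation test for a time-of-day statistic
#'
#' Builds the schedule-preserving null for one event: in each iteration,
#' every stratum's total record count is reallocated across the stratum's
#' rounds proportional to attempts ([permute_stratum()]), the per-bin record
#' curve is rebuilt, and the chosen statistic recomputed on exactly the same
#' bin sets as the observed statistic (valid bins for the non-uniformity
#' statistic; all bins with at least one attempt for the outside-window
#' rate). Attempts are never permuted, so exposure structure is identical
#' across observed and null. The one-tailed p-value uses the add-one
#' permutation estimator `(1 + #(null >= observed)) / (1 + iterations)`,
#' upper tail for both statistics (large values mean non-uniformity or
#' inside-window suppression); it can therefore never be exactly zero.
#'
#' By default strata are (competition, event) groups: reallocating records
#' across a competition's rounds of the event moves them between time bins
#' while respecting where that competition actually scheduled exposure.
#' `stratum = "competition_event_round"` restricts reallocation within a
#' single round; since all of a round's attempts share one start bin this
#' null is degenerate (the bin curve never changes) and is provided only to
#' demonstrate that degeneracy.
#'
#' @param dataset A [diel_dataset()].
#' @param event_id Event to test.
#' @param statistic `"window_ratio"` or `"max_deviation"`.
#' @param window A [window_spec()] (used by the window statistic).
#' @param iterations Number of permutation iterations (default 10,000).
#' @param seed Integer seed for the run's RNG (default 42); identical
#'   inputs and seed reproduce identical null draws.
#' @param scale,min_attempts,rate_mean Passed to [tally_bins()].
#' @param stratum Stratum definition, see Details.
#' @return A `perm_test` object: list with `statistic`, `observed`,
#'   `null_draws`, `p_value`, `iterations`, `seed`, `event_id`, `window`,
#'   and the bin sets used.
#' @export
run_permutation_test <- function(dataset, event_id,
                                 statistic = c("window_ratio", "max_deviation"),
                                 window = window_spec(),
                                 iterations = 10000L, seed = 42L,
                                 scale = NULL, min_attempts = NULL,
                                 rate_mean = c("unweighted", "weighted"),
                                 stratum = c("competition_event",
                                             "competition_event_round")) {
  stopifnot(inherits(dataset, "diel_dataset"))
  statistic <- match.arg(statistic)
  rate_mean <- match.arg(rate_mean)
  stratum <- match.arg(stratum)
  iterations <- as.integer(iterations)
  stopifnot(iterations >= 1L)

  obs_tab <- tally_bins(dataset, event_id, scale = scale,
                        min_attempts = min_attempts, rate_mean = rate_mean)
  scale_v <- attr(obs_tab, "scale")
  rounds <- dataset$rounds[dataset$rounds$event_id == event_id, , drop = FALSE]
  if (sum(rounds$records_total) == 0) {
    stop("no records for event '", event_id, "': nothing to permute",
         call. = FALSE)
  }

  # observed statistic first: its preconditions must hold before any draw
  if (statistic == "window_ratio") {
    wr <- window_rates(obs_tab, window)
    window_ratio(wr$inside_rate, wr$outside_rate) # assert preconditions
    # same arithmetic as the null path so exact ties are exact
    observed <- (wr$outside_records / wr$outside_attempts) /
      (wr$inside_records / wr$inside_attempts)
    in_bins <- window$bins
    out_bins <- setdiff(obs_tab$bin[obs_tab$attempts >= 1], in_bins)
    in_att <- wr$inside_attempts
    out_att <- wr$outside_attempts
  } else {
    observed <- max_deviation_stat(obs_tab)
    valid_bins <- obs_tab$bin[obs_tab$valid]
    valid_att <- obs_tab$attempts[obs_tab$valid]
  }

  # stratum bookkeeping; sorted key order makes RNG consumption reproducible
  key <- if (stratum == "competition_event") rounds$competition_id
         else paste(rounds$competition_id, rounds$round_number, sep = "\r")
  ord <- order(key, rounds$round_number)
  rounds <- rounds[ord, , drop = FALSE]
  key <- key[ord]
  totals <- rowsum(rounds$records_total, key)
  att_tot <- rowsum(rounds$attempts, key)
  if (any(totals[, 1L] > 0 & att_tot[, 1L] == 0)) {
    stop("stratum with records but zero attempts: impossible exposure",
         call. = FALSE)
  }
  active_keys <- rownames(totals)[totals[, 1L] > 0] # zero-record strata are no-ops
  active <- key %in% active_keys
  a_key <- factor(key[active], levels = active_keys)
  a_att <- rounds$attempts[active]
  a_bin <- rounds$bin[active]
  a_R <- totals[active_keys, 1L]
  rows_by_stratum <- split(seq_along(a_key), a_key)

  nb <- n_bins(dataset$bin_minutes)
  set.seed(seed)
  null_draws <- numeric(iterations)
  chunk_size <- 2000L
  done <- 0L
  while (done < iterations) {
    k <- min(chunk_size, iterations - done)
    counts <- matrix(0L, nrow = sum(active), ncol = k)
    for (s in seq_along(active_keys)) {
      rows <- rows_by_stratum[[s]]
      counts[rows, ] <- permute_stratum(a_att[rows], a_R[s], draws = k)
    }
    by_bin <- rowsum(counts, a_bin)
    full <- matrix(0, nrow = nb, ncol = k)
    full[as.integer(rownames(by_bin)) + 1L, ] <- by_bin

    if (statistic == "window_ratio") {
      r_in <- colSums(full[in_bins + 1L, , drop = FALSE])
      r_out <- colSums(full[out_bins + 1L, , drop = FALSE])
      null_draws[done + seq_len(k)] <-
        (r_out / out_att) / (r_in / in_att) # Inf when r_in = 0: extreme tail
    } else {
      vrec <- full[valid_bins + 1L, , drop = FALSE]
      vrate <- scale_v * vrec / valid_att
      r_bar <- if (rate_mean == "unweighted") colMeans(vrate)
               else scale_v * colSums(vrec) / sum(valid_att)
      dev <- abs(vrate - rep(r_bar, each = nrow(vrate)))
      null_draws[done + seq_len(k)] <- apply(dev, 2L, max) / r_bar
    }
    done <- done + k
  }

  p_value <- (1 + sum(null_draws >= observed)) / (1 + iterations)
  structure(
    list(statistic = statistic, observed = observed, null_draws = null_draws,
         p_value = p_value, iterations = iterations, seed = as.integer(seed),
         event_id = event_id,
         window = if (statistic == "window_ratio") window else NULL,
         bin_sets = if (statistic == "window_ratio")
           list(inside = in_bins, outside = out_bins)
         else list(valid = valid_bins),
         stratum = stratum, scale = scale_v,
         n_strata = length(active_keys)),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> %s, event %s\n  observed = %.4f, one-tailed p = %.4g (%d iterations, seed %d)\n",
    x$statistic, x$event_id, x$observed, x$p_value, x$iterations, x$seed))
  invisible(x)
}

#' Write a permutation test result to JSON
#'
#' Serialises the statistic name, observed value, p-value, iteration count,
#' seed, window definition and the bin sets used, plus summary quantiles of
#' the null distribution (the raw draws are omitted by default).
#'
#' @param x A `perm_test`.
#' @param path Output JSON path.
#' @param include_null_draws Include the full vector of null draws.
#' @return `path`, invisibly.
#' @export
write_perm_test <- function(x, path, include_null_draws = FALSE) {
  stopifnot(inherits(x, "perm_test"))
  fin <- x$null_draws[is.finite(x$null_draws)]
  out <- list(
    statistic = x$statistic, event_id = x$event_id, observed = x$observed,
    p_value = x$p_value, iterations = x$iterations, seed = x$seed,
    stratum = x$stratum, scale = x$scale,
    window = if (!is.null(x$window))
      list(start = x$window$start, end = x$window$end) else NULL,
    bin_sets = x$bin_sets,
    null_quantiles = as.list(stats::quantile(fin, c(.025, .5, .975)))
  )
  if (include_null_draws) out$null_draws <- x$null_draws
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
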