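#' Build a peri-event time histogram (PSTH)
#'
#' Bins spike times relative to each alignment event (call onset = time 0)
#' and sums the counts over events. With the defaults — 10 ms bins and a
#' window from -2 s to +2 s — this is a 400-bin histogram with 200 bins
#' before and 200 after onset. Bins are half-open `[t, t + bin_width)`, so
#' the first post-onset bin is bin index 200 when counting from 0. A spike
#' contributes once per event whose window contains it, so overlapping
#' windows are counted per pair.
#'
#' @param spike_times Sorted spike times (s).
#' @param event_onsets Sorted alignment event times (s).
#' @param bin_width Bin width (s).
#' @param window `c(t_pre, t_post)` around the event (s), spanning 0.
#' @return An object of class `psth`: `counts` (integer per bin), `edges`
#'   (bin left edges, length `n_bins`), `bin_width`, `window`, `n_events`.
#' @export
build_psth <- function(spike_times, event_onsets, bin_width = 0.010,
                       window = c(-2, 2)) {
  if (is.unsorted(spike_times)) stopf("spike_times must be sorted")
  if (is.unsorted(event_onsets)) stopf("event_onsets must be sorted")
  if (window[1] >= 0 || window[2] <= 0) stopf("window must span time 0")
  n_bins <- round((window[2] - window[1]) / bin_width)
  if (n_bins < 2) stopf("window/bin_width give fewer than 2 bins")
  counts <- integer(n_bins)
  ns <- length(spike_times)
  for (t in event_onsets) {
    lo <- findInterval(t + window[1], spike_times, left.open = TRUE) + 1L
    hi <- findInterval(t + window[2], spike_times, left.open = TRUE)
    if (hi < lo) next
    off <- spike_times[lo:hi] - t
    bin <- floor((off - window[1]) / bin_width) + 1L
    bin <- bin[bin >= 1L & bin <= n_bins]
    counts <- counts + tabulate(bin, nbins = n_bins)
  }
  structure(list(counts = counts,
                 edges = window[1] + bin_width * (seq_len(n_bins) - 1L),
                 bin_width = bin_width, window = window,
                 n_events = length(event_onsets)),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("PSTH: %d bins of %g ms on [%g, %g) s, %d events, %d spikes\n",
              length(x$counts), x$bin_width * 1000, x$window[1], x$window[2],
              x$n_events, sum(x$counts)))
  invisible(x)
}

#' Z-score a PSTH over its own bins
#'
#' Standardizes the bin counts by their mean and sample SD computed over all
#' bins of the histogram window (no separate baseline period). A flat
#' histogram (zero SD) maps to all-zero z-scores.
#'
#' @param psth A [build_psth()] result with at least 2 bins.
#' @return An object of class `zscored_psth`: `z` per bin, `mean`, `sd`, and
#'   the `source` PSTH.
#' @export
zscore_psth <- function(psth) {
  stopifnot(inherits(psth, "psth"))
  if (length(psth$counts) < 2) stopf("z-scoring needs at least 2 bins")
  m <- mean(psth$counts)
  s <- stats::sd(psth$counts)
  z <- if (s > 0) (psth$counts - m) / s else rep(0, length(psth$counts))
  structure(list(z = z, mean = m, sd = s, source = psth),
            class = "zscored_psth")
}

#' Test whether a unit's activity is associated with call production
#'
#' A unit counts as call-associated when any bin with center within
#' `window` seconds of call onset has `|z| > threshold` (default 1.73;
#' two-sided, so pre-onset inhibition counts as a change in activity just as
#' the onset burst does).
#'
#' @param zpsth A [zscore_psth()] result whose window covers `±window` s.
#' @param threshold z-score magnitude defining a change in activity.
#' @param window Half-width (s) of the peri-onset test region.
#' @param two_sided If `FALSE`, only positive excursions (rate increases)
#'   count.
#' @return List: `associated` (logical), `peak_abs_z`, `peak_time` (center
#'   of the extremal bin, s).
#' @export
detect_call_association <- function(zpsth, threshold = 1.73, window = 0.5,
                                    two_sided = TRUE) {
  stopifnot(inherits(zpsth, "zscored_psth"))
  src <- zpsth$source
  if (src$window[1] > -window || src$window[2] < window) {
    stopf("PSTH window [%g, %g] does not cover +/-%g s", src$window[1],
          src$window[2], window)
  }
  centers <- src$edges + src$bin_width / 2
  in_win <- centers >= -window & centers <= window
  zz <- if (two_sided) abs(zpsth$z[in_win]) else zpsth$z[in_win]
  i <- which.max(zz)
  list(associated = zz[i] > threshold,
       peak_abs_z = abs(zpsth$z[in_win][i]),
       peak_time = centers[in_win][i])
}

#' Convert a PSTH to a probability density over bins
#'
#' @param psth A [build_psth()] result with at least one spike.
#' @return Numeric vector: `counts / sum(counts)`, summing to 1.
#' @export
psth_density <- function(psth) {
  stopifnot(inherits(psth, "psth"))
  total <- sum(psth$counts)
  if (total == 0) stopf("cannot form a density from an all-zero PSTH")
  psth$counts / total
}

#' Early/late analysis windows on the 400-bin PSTH
#'
#' The standard windows of the analysis, as inclusive 0-based bin indices on
#' the default 400 x 10 ms histogram: early activity spans bins 199-203
#' (-10 ms to +40 ms around call onset) and late activity bins 225-250
#' (+250 to +500 ms after onset). Two wider z-score windows used for
#' per-bird summaries are also provided: from onset to +125 ms, and +150 to
#' +750 ms.
#'
#' @param n_bins,bin_width,window PSTH geometry the windows refer to.
#' @return An object of class `density_windows` with 0-based inclusive bin
#'   index pairs `early`, `late`, `summary_early`, `summary_late`, and the
#'   geometry.
#' @export
density_windows <- function(n_bins = 400L, bin_width = 0.010,
                            window = c(-2, 2)) {
  w <- structure(list(
    early = c(199L, 203L),
    late = c(225L, 250L),
    summary_early = c(200L, 212L),   # onset to +125 ms
    summary_late = c(215L, 275L),    # +150 to +750 ms
    n_bins = as.integer(n_bins), bin_width = bin_width, window = window
  ), class = "density_windows")
  if (!identical(as.integer(n_bins), 400L) || bin_width != 0.010 ||
      !isTRUE(all.equal(window, c(-2, 2)))) {
    # recompute indices from times for non-default geometry
    bin_of <- function(t) as.integer(floor((t - window[1]) / bin_width))
    w$early <- c(bin_of(-0.010), bin_of(0.040) - 1L)
    w$late <- c(bin_of(0.250), bin_of(0.500))
    w$summary_early <- c(bin_of(0), bin_of(0.125))
    w$summary_late <- c(bin_of(0.150), bin_of(0.750))
    w$n_bins <- as.integer(n_bins)
  }
  stopifnot(w$late[1] > w$early[2])  # early and late disjoint
  stopifnot(w$early[1] >= 0, w$late[2] < w$n_bins)
  w
}

#' Mean spike proportion in an analysis window
#'
#' Averages the PSTH density over the requested window's bins and multiplies
#' by 100, giving the mean proportion of spikes (times 100) per bin in that
#' window — the early/late activity statistic.
#'
#' @param density A [psth_density()] vector.
#' @param windows A [density_windows()] matching the density length.
#' @param which One of `"early"`, `"late"`, `"summary_early"`,
#'   `"summary_late"`.
#' @param scale Multiplier applied to the mean density (default 100).
#' @return A single number.
#' @export
window_density <- function(density, windows = density_windows(),
                           which = c("early", "late", "summary_early",
                                     "summary_late"),
                           scale = 100) {
  which <- match.arg(which)
  stopifnot(inherits(windows, "density_windows"))
  idx0 <- windows[[which]]
  if (idx0[2] < idx0[1]) stopf("empty window %s", sQuote(which))
  if (idx0[2] + 1L > length(density)) {
    stopf("window %s (bins %d-%d) exceeds the density length %d",
          sQuote(which), idx0[1], idx0[2], length(density))
  }
  mean(density[(idx0[1] + 1L):(idx0[2] + 1L)]) * scale
}

#' Time for call-locked activity to return to baseline
#'
#' Scans the z-scored PSTH from call onset forward and reports the time at
#' which the z-score first falls below `threshold` and stays there for at
#' least 3 consecutive bins — the return-to-baseline duration. A unit whose
#' activity never rises above threshold at onset returns 0. If the activity
#' is still elevated at the window end, the window end is returned with
#' attribute `censored = TRUE`.
#'
#' @param zpsth A [zscore_psth()] result covering post-onset time.
#' @param threshold z-score defining elevated activity (default 2).
#' @return Duration (s) from call onset; attribute `censored` flags
#'   truncation at the window end.
#' @export
elevated_duration <- function(zpsth, threshold = 2) {
  stopifnot(inherits(zpsth, "zscored_psth"))
  src <- zpsth$source
  post <- which(src$edges >= -src$bin_width / 2)  # bins starting at/after 0
  z <- zpsth$z[post]
  below <- c(z < threshold, TRUE, TRUE)  # activity is baseline after the window
  run3 <- below[seq_along(z)] & below[seq_along(z) + 1L] & below[seq_along(z) + 2L]
  i <- which(run3)[1]
  if (!is.na(i)) {
    structure(src$edges[post[i]], censored = FALSE)
  } else {
    structure(src$window[2], censored = TRUE)
  }
}
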