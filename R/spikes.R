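#' Spike detection parameters
#'
#' Threshold crossing detection with a robust noise estimate: the threshold
#' is `threshold_multiplier` times the noise SD estimated as
#' `MAD / 0.6745` (i.e. [stats::mad()] with its default consistency
#' constant), so large spikes do not inflate the noise estimate. Each
#' above-threshold excursion yields one event at its extremal sample,
#' respecting a dead time; a 64-sample snippet is cut with the peak at sample
#' `pre_peak + 1`.
#'
#' @param threshold_multiplier Threshold in robust noise SDs.
#' @param polarity `"negative"`, `"positive"` or `"both"`: which excursions
#'   count. Extracellular somatic spikes are dominantly negative.
#' @param dead_time Minimum separation between detected events (s).
#' @param pre_peak,post_peak Samples before/after the peak in the snippet;
#'   must sum to 64.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(threshold_multiplier = 4.5,
                             polarity = c("negative", "positive", "both"),
                             dead_time = 0.0005,
                             pre_peak = 20L, post_peak = 44L) {
  polarity <- match.arg(polarity)
  pre_peak <- as.integer(pre_peak); post_peak <- as.integer(post_peak)
  if (pre_peak + post_peak != 64L) {
    stopf("pre_peak + post_peak must equal 64 (got %d + %d)", pre_peak, post_peak)
  }
  if (dead_time < 0) stopf("dead_time must be nonnegative")
  if (threshold_multiplier <= 0) stopf("threshold_multiplier must be positive")
  structure(list(threshold_multiplier = threshold_multiplier,
                 polarity = polarity, dead_time = dead_time,
                 pre_peak = pre_peak, post_peak = post_peak),
            class = "detection_params")
}

#' Detect spikes in a continuous trace
#'
#' Finds every excursion of the trace beyond
#' `threshold_multiplier x robust noise SD` (MAD-based), takes the extremal
#' sample of each excursion as the event peak, enforces the dead time
#' (earlier peaks win), and cuts a 64-sample snippet around each surviving
#' peak. Peaks too close to the trace edges for a full snippet are skipped.
#' The timestamp is the 0-based peak sample divided by the sampling rate.
#'
#' @param trace A [waveform_recording()] of at least 64 samples.
#' @param params A [detection_params()].
#' @return A [spike_records()] object (possibly empty).
#' @export
detect_spikes <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "waveform_recording"),
            inherits(params, "detection_params"))
  x <- trace$samples
  if (length(x) < 64L) stopf("trace must contain at least 64 samples")
  sigma <- stats::mad(x)  # MAD / 0.6745
  empty <- spike_records(numeric(0), matrix(integer(0), 0, 64))
  if (sigma == 0) return(empty)
  thr <- params$threshold_multiplier * sigma
  signal <- switch(params$polarity,
                   negative = -x, positive = x, both = abs(x))
  above <- signal > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_start <- starts[r$values]
  run_end <- ends[r$values]
  peaks <- integer(length(run_start))
  for (i in seq_along(run_start)) {
    seg <- run_start[i]:run_end[i]
    peaks[i] <- seg[which.max(signal[seg])]
  }
  # dead time: keep a peak only if far enough from the last kept one
  dead_samples <- params$dead_time * trace$sampling_rate
  keep <- logical(length(peaks))
  last <- -Inf
  for (i in seq_along(peaks)) {
    if (peaks[i] - last >= dead_samples) {
      keep[i] <- TRUE
      last <- peaks[i]
    }
  }
  peaks <- peaks[keep]
  # edge rule: full snippet must fit
  peaks <- peaks[peaks > params$pre_peak &
                   peaks <= length(x) - params$post_peak + 1L]
  if (length(peaks) == 0) return(empty)
  wf <- matrix(0L, nrow = length(peaks), ncol = 64L)
  for (i in seq_along(peaks)) {
    wf[i, ] <- as.integer(round(
      x[(peaks[i] - params$pre_peak):(peaks[i] + params$post_peak - 1L)]))
  }
  spike_records((peaks - 1L) / trace$sampling_rate, wf)
}

#' Sort spike waveforms with k-means
#'
#' Clusters the 64-dimensional waveform snippets into `k` putative units
#' with [stats::kmeans()], taking the best of `n_restarts` random starts by
#' within-cluster sum of squares. Deterministic given `seed`.
#'
#' @param records A [spike_records()] object with at least `k` events.
#' @param k Number of clusters (>= 1).
#' @param seed Integer seed for the restarts.
#' @param n_restarts Number of random starts.
#' @param normalize If `TRUE`, scale each waveform to unit peak amplitude
#'   before clustering (shape-only sorting).
#' @return An object of class `sort_result`: `labels` (cluster id per
#'   record, in `1..k`), `centroids` (`k x 64`), `k`, and `inertia` (total
#'   within-cluster sum of squares).
#' @export
sort_waveforms <- function(records, k, seed = 1L, n_restarts = 10L,
                           normalize = FALSE) {
  stopifnot(inherits(records, "spike_records"))
  n <- length(records$timestamps)
  if (k < 1) stopf("k must be at least 1")
  if (k > n) stopf("k = %d exceeds the number of records (%d)", k, n)
  x <- records$waveforms
  storage.mode(x) <- "double"
  if (normalize) {
    amp <- apply(abs(x), 1, max)
    amp[amp == 0] <- 1
    x <- x / amp
  }
  fit <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(max(1L, n_restarts))) {
      f <- suppressWarnings(stats::kmeans(x, centers = k, iter.max = 100L))
      if (is.null(best) || f$tot.withinss < best$tot.withinss) best <- f
    }
    best
  })
  structure(list(labels = as.integer(fit$cluster),
                 centroids = unname(fit$centers), k = as.integer(k),
                 inertia = fit$tot.withinss),
            class = "sort_result")
}

#' Within-cluster sum of squares over a range of k
#'
#' Companion report for choosing `k` by the elbow heuristic; no automatic
#' selection is performed.
#'
#' @param records A [spike_records()] object.
#' @param k_range Candidate cluster counts.
#' @param seed,n_restarts Passed to [sort_waveforms()].
#' @return Data frame with columns `k` and `inertia`.
#' @export
elbow_report <- function(records, k_range = 1:8, seed = 1L, n_restarts = 5L) {
  k_range <- k_range[k_range <= length(records$timestamps)]
  data.frame(
    k = k_range,
    inertia = vapply(k_range, function(k) {
      sort_waveforms(records, k, seed = substream_seed(seed, paste0("k", k)),
                     n_restarts = n_restarts)$inertia
    }, numeric(1))
  )
}

#' Classify a unit's firing regularity from its ISI distribution
#'
#' Computes the interspike intervals of a sorted unit, their histogram and
#' coefficient of variation (SD/mean), and labels the unit `regular` (tonic,
#' clock-like firing as in RA projection neurons) when the CV falls below
#' `cv_threshold`, `irregular` when it does not, and `undetermined` when
#' fewer than `min_spikes` spikes (or fewer than 2) are available.
#'
#' @param spike_times Sorted spike times (s).
#' @param cv_threshold CV below which firing counts as regular.
#' @param min_spikes Minimum spikes for a determinate label.
#' @param bin_width ISI histogram bin width (s).
#' @param max_isi Upper edge of the ISI histogram (s); longer ISIs are
#'   counted in the last bin.
#' @return An object of class `isi_profile`: `isis`, `histogram` (counts),
#'   `breaks`, `cv`, `n_spikes`, `regularity`.
#' @export
classify_regularity <- function(spike_times, cv_threshold = 0.35,
                                min_spikes = 100L, bin_width = 0.001,
                                max_isi = 0.5) {
  if (is.unsorted(spike_times)) stopf("spike_times must be sorted")
  n <- length(spike_times)
  isis <- if (n >= 2) diff(spike_times) else numeric(0)
  breaks <- seq(0, max_isi, by = bin_width)
  counts <- if (length(isis) > 0) {
    bin <- pmin(findInterval(isis, breaks, left.open = FALSE),
                length(breaks) - 1L)
    tabulate(bin, nbins = length(breaks) - 1L)
  } else {
    integer(length(breaks) - 1L)
  }
  cv <- if (length(isis) >= 2 && mean(isis) > 0) {
    stats::sd(isis) / mean(isis)
  } else {
    NA_real_
  }
  regularity <- if (n < min_spikes || is.na(cv)) {
    "undetermined"
  } else if (cv < cv_threshold) {
    "regular"
  } else {
    "irregular"
  }
  structure(list(isis = isis, histogram = counts, breaks = breaks,
                 cv = cv, n_spikes = n, regularity = regularity),
            class = "isi_profile")
}

#' @export
print.isi_profile <- function(x, ...) {
  cat(sprintf("ISI profile: %d spikes, CV = %s -> %s\n", x$n_spikes,
              ifelse(is.na(x$cv), "NA", sprintf("%.3f", x$cv)), x$regularity))
  invisible(x)
}
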