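#' Scenario configuration for a synthetic recording session
#'
#' Collects every parameter of the synthetic-session generator: the two
#' birds' call processes and their answer coupling, the call-locked firing
#' modulation, an optional regular (tonic) unit, and the continuous-trace
#' synthesis. Defaults emulate a quiet aviary session: soft contact calls at
#' a few per minute, an answer window of half a second, multiunit baseline
#' firing of tens of spikes per second, and 16-bit traces at 22,050 Hz.
#'
#' @param seed Root seed; all stage randomness derives from it.
#' @param duration Session length (s).
#' @param focal_call_rate,partner_baseline_rate Call rates (events/s) of the
#'   focal bird and of the partner's spontaneous (non-answer) calling.
#' @param p_answer Probability that a focal call is answered by the partner.
#' @param answer_latency_dist Latency distribution of answers, a list with
#'   `name` `"uniform"` (`min`, `max`) or `"constant"` (`value`); support must
#'   lie within `(0, answer_window]` when coupling is enabled.
#' @param answer_window Coupling window (s) used throughout the analysis.
#' @param call_type_mix Proportion of stack calls (the rest are tets).
#' @param stack_duration,tet_duration Call durations (s).
#' @param kernel_stack,kernel_tet [modulation_kernel()]s applied around stack
#'   and tet call onsets.
#' @param baseline_spike_rate Multiunit baseline firing rate (spikes/s).
#' @param regular_unit_rate Firing rate of the optional regular unit
#'   (spikes/s); 0 disables it.
#' @param regular_unit_isi_cv ISI coefficient of variation of the regular unit.
#' @param sampling_rate Trace sampling rate (Hz).
#' @param template_set List of 64-sample spike waveform templates (signed
#'   16-bit scale), one per unit; see [default_spike_templates()].
#' @param noise_sd Trace noise standard deviation (16-bit sample units).
#' @param refractory Spike dead time (s).
#' @param max_gain Ceiling on the combined kernel gain (multiples of
#'   baseline) when call windows overlap.
#' @return An object of class `scenario_config` (a validated list).
#' @export
scenario_config <- function(seed = 1L,
                            duration = 1200,
                            focal_call_rate = 0.1,
                            partner_baseline_rate = 0.05,
                            p_answer = 0.5,
                            answer_latency_dist = list(name = "uniform",
                                                       min = 0.05, max = 0.45),
                            answer_window = 0.5,
                            call_type_mix = 0.6,
                            stack_duration = 0.09,
                            tet_duration = 0.05,
                            kernel_stack = default_stack_kernel(),
                            kernel_tet = default_tet_kernel(),
                            baseline_spike_rate = 40,
                            regular_unit_rate = 8,
                            regular_unit_isi_cv = 0.2,
                            sampling_rate = 22050,
                            template_set = default_spike_templates(),
                            noise_sd = 200,
                            refractory = 0.0005,
                            max_gain = 20) {
  cfg <- list(seed = as.integer(seed), duration = duration,
              focal_call_rate = focal_call_rate,
              partner_baseline_rate = partner_baseline_rate,
              p_answer = p_answer, answer_latency_dist = answer_latency_dist,
              answer_window = answer_window, call_type_mix = call_type_mix,
              stack_duration = stack_duration, tet_duration = tet_duration,
              kernel_stack = kernel_stack, kernel_tet = kernel_tet,
              baseline_spike_rate = baseline_spike_rate,
              regular_unit_rate = regular_unit_rate,
              regular_unit_isi_cv = regular_unit_isi_cv,
              sampling_rate = sampling_rate, template_set = template_set,
              noise_sd = noise_sd, refractory = refractory,
              max_gain = max_gain)
  if (cfg$duration <= 0) stopf("duration must be positive")
  rates <- c(cfg$focal_call_rate, cfg$partner_baseline_rate,
             cfg$baseline_spike_rate, cfg$regular_unit_rate)
  if (any(rates < 0)) stopf("rates must be nonnegative")
  if (cfg$p_answer < 0 || cfg$p_answer > 1) stopf("p_answer must be in [0, 1]")
  if (cfg$call_type_mix < 0 || cfg$call_type_mix > 1) {
    stopf("call_type_mix must be in [0, 1]")
  }
  if (cfg$sampling_rate <= 0) stopf("sampling_rate must be positive")
  if (cfg$refractory < 0) stopf("refractory must be nonnegative")
  if (cfg$p_answer > 0) {
    sup <- latency_support(cfg$answer_latency_dist)
    if (sup[1] <= 0 || sup[2] > cfg$answer_window) {
      stopf("answer latency support (%g, %g] must lie within (0, %g] when answer coupling is requested",
            sup[1], sup[2], cfg$answer_window)
    }
  }
  structure(cfg, class = "scenario_config")
}

latency_support <- function(dist) {
  switch(dist$name,
         uniform = c(dist$min, dist$max),
         constant = c(dist$value, dist$value),
         stopf("unknown latency distribution %s (use 'uniform' or 'constant')",
               sQuote(dist$name)))
}

draw_latency <- function(dist, n) {
  switch(dist$name,
         uniform = stats::runif(n, dist$min, dist$max),
         constant = rep(dist$value, n),
         stopf("unknown latency distribution %s", sQuote(dist$name)))
}

# Homogeneous Poisson call train with dead time equal to each call's
# duration: an exponential gap separates one call's offset from the next
# call's onset. Types are assigned i.i.d. from the stack/tet mix.
sim_call_train <- function(rate, duration, mix, stack_dur, tet_dur, bird_id) {
  if (rate <= 0) {
    return(call_train(numeric(0), numeric(0), character(0), bird_id))
  }
  onsets <- numeric(0)
  types <- character(0)
  t <- 0
  repeat {
    chunk <- max(16L, ceiling((duration - t) * rate * 1.5))
    gaps <- stats::rexp(chunk, rate)
    tp <- ifelse(stats::runif(chunk) < mix, "stack", "tet")
    durs <- ifelse(tp == "stack", stack_dur, tet_dur)
    # onset_i = t + gap_1 + sum_{j<i} (dur_j + gap_{j+1})
    on <- t + cumsum(c(gaps[1], gaps[-1] + durs[-chunk]))
    keep <- (on + durs) <= duration
    onsets <- c(onsets, on[keep])
    types <- c(types, tp[keep])
    if (!all(keep) || length(on) == 0) break
    t <- on[chunk] + durs[chunk]
  }
  call_train(onsets, onsets + ifelse(types == "stack", stack_dur, tet_dur),
             types, bird_id)
}

#' Generate a coupled two-bird call exchange
#'
#' Simulates the focal bird's calls as a homogeneous Poisson process with
#' dead time equal to the call duration, and the partner's calls as an
#' independent baseline Poisson process plus answer events: each focal call
#' is answered with probability `p_answer` at a latency drawn from
#' `answer_latency_dist`. Partner calls that would overlap (onsets closer
#' than the earlier call's duration) are merged, keeping the earliest onset.
#'
#' @param config A [scenario_config()].
#' @return A list with `focal` and `partner` [call_train()]s and `truth`, a
#'   `ground_truth` list holding both trains, the surviving
#'   `answer_links` (data frame `focal_index`, `partner_index`, `latency`)
#'   and the generator configuration. Deterministic given `config$seed`.
#' @export
generate_call_exchange <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  focal <- with_seed(substream_seed(config$seed, "focal_calls"),
                     sim_call_train(config$focal_call_rate, config$duration,
                                    config$call_type_mix,
                                    config$stack_duration, config$tet_duration,
                                    "focal"))
  base <- with_seed(substream_seed(config$seed, "partner_calls"),
                    sim_call_train(config$partner_baseline_rate,
                                   config$duration, config$call_type_mix,
                                   config$stack_duration, config$tet_duration,
                                   "partner"))
  n_f <- nrow(focal)
  ans <- with_seed(substream_seed(config$seed, "answers"), {
    is_ans <- stats::runif(n_f) < config$p_answer
    lat <- draw_latency(config$answer_latency_dist, n_f)
    tp <- ifelse(stats::runif(n_f) < config$call_type_mix, "stack", "tet")
    data.frame(focal_index = which(is_ans),
               onset = focal$onset[is_ans] + lat[is_ans],
               call_type = tp[is_ans], latency = lat[is_ans])
  })
  dur_of <- function(tp) ifelse(tp == "stack", config$stack_duration,
                                config$tet_duration)
  all_on <- c(base$onset, ans$onset)
  all_tp <- c(base$call_type, ans$call_type)
  src <- c(rep(NA_integer_, nrow(base)), ans$focal_index)
  ord <- order(all_on)
  all_on <- all_on[ord]; all_tp <- all_tp[ord]; src <- src[ord]
  keep <- rep(TRUE, length(all_on))
  if (length(all_on) > 1) {
    last_end <- all_on[1] + dur_of(all_tp[1])
    for (i in seq_along(all_on)[-1]) {
      if (all_on[i] < last_end) {
        keep[i] <- FALSE  # merged into the earlier partner call
      } else {
        last_end <- all_on[i] + dur_of(all_tp[i])
      }
    }
  }
  in_session <- all_on + dur_of(all_tp) <= config$duration
  keep <- keep & in_session
  partner <- call_train(all_on[keep], all_on[keep] + dur_of(all_tp[keep]),
                        all_tp[keep], "partner")
  kept_src <- src[keep]
  link_rows <- which(!is.na(kept_src))
  answer_links <- data.frame(
    focal_index = kept_src[link_rows],
    partner_index = link_rows,
    latency = partner$onset[link_rows] - focal$onset[kept_src[link_rows]]
  )
  truth <- structure(
    list(focal_calls = focal, partner_calls = partner,
         answer_links = answer_links, config = config),
    class = "ground_truth"
  )
  list(focal = focal, partner = partner, truth = truth)
}

#' Simulate a call-modulated spike train
#'
#' Inhomogeneous Poisson spike train whose rate is
#' `baseline_rate * prod(kernel gains of nearby calls)`: around each call
#' onset the matching call type's [modulation_kernel()] multiplies the
#' baseline. Gains of overlapping call windows combine multiplicatively, and
#' the combined rate is capped at `max_gain * baseline_rate` (with a warning)
#' to guard against rate explosions. Because the kernels are piecewise
#' constant, the rate function is piecewise constant and is simulated exactly
#' segment by segment; a refractory dead time is then enforced.
#'
#' @param calls A [call_train()] giving the modulating call onsets.
#' @param kernel_by_type Named list of [modulation_kernel()]s, one per call
#'   type present in `calls` (or per value of `kernel_key`).
#' @param kernel_key Optional character vector, one entry per call, naming
#'   the kernel in `kernel_by_type` that applies to that call; defaults to
#'   the call types. Lets e.g. interaction context modulate the kernel.
#' @param baseline_rate Baseline firing rate (spikes/s).
#' @param duration Session length (s).
#' @param refractory Dead time (s) between successive spikes.
#' @param seed Integer seed; output is deterministic given it.
#' @param max_gain Rate ceiling in multiples of baseline.
#' @return Strictly increasing spike times (s) within `[0, duration]`.
#' @export
generate_modulated_spike_train <- function(calls, kernel_by_type,
                                           baseline_rate, duration,
                                           refractory = 0.0005, seed = 1L,
                                           max_gain = 20, kernel_key = NULL) {
  stopifnot(inherits(calls, "call_train"))
  if (duration <= 0) stopf("duration must be positive")
  if (is.null(kernel_key)) kernel_key <- calls$call_type
  if (length(kernel_key) != nrow(calls)) {
    stopf("kernel_key must have one entry per call")
  }
  missing_k <- setdiff(unique(kernel_key), names(kernel_by_type))
  if (length(missing_k) > 0) {
    stopf("no modulation kernel supplied for call type(s): %s",
          paste(missing_k, collapse = ", "))
  }
  # Collect kernel segments as absolute intervals [start, end) with a gain.
  seg_start <- numeric(0); seg_end <- numeric(0); seg_gain <- numeric(0)
  for (i in seq_len(nrow(calls))) {
    k <- kernel_by_type[[kernel_key[i]]]
    s <- calls$onset[i] + k$breaks[-length(k$breaks)]
    e <- calls$onset[i] + k$breaks[-1]
    nontrivial <- k$gains != 1
    seg_start <- c(seg_start, s[nontrivial])
    seg_end <- c(seg_end, e[nontrivial])
    seg_gain <- c(seg_gain, k$gains[nontrivial])
  }
  seg_start <- pmax(0, pmin(duration, seg_start))
  seg_end <- pmax(0, pmin(duration, seg_end))
  ok <- seg_end > seg_start
  seg_start <- seg_start[ok]; seg_end <- seg_end[ok]; seg_gain <- seg_gain[ok]

  breaks <- sort(unique(c(0, duration, seg_start, seg_end)))
  n_piece <- length(breaks) - 1L
  log_gain <- numeric(n_piece)
  zero_cover <- integer(n_piece)
  if (length(seg_start) > 0) {
    i1 <- findInterval(seg_start, breaks)
    i2 <- findInterval(seg_end, breaks, left.open = TRUE)
    for (j in seq_along(seg_start)) {
      idx <- i1[j]:i2[j]
      if (seg_gain[j] == 0) {
        zero_cover[idx] <- zero_cover[idx] + 1L
      } else {
        log_gain[idx] <- log_gain[idx] + log(seg_gain[j])
      }
    }
  }
  rate <- baseline_rate * exp(log_gain)
  rate[zero_cover > 0] <- 0
  ceiling_rate <- baseline_rate * max_gain
  if (any(rate > ceiling_rate)) {
    warnf("combined kernel gain exceeded the ceiling of %g x baseline in %d segment(s); rate capped",
          max_gain, sum(rate > ceiling_rate))
    rate <- pmin(rate, ceiling_rate)
  }

  with_seed(seed, {
    lens <- diff(breaks)
    counts <- stats::rpois(n_piece, rate * lens)
    spikes <- numeric(sum(counts))
    pos <- 0L
    for (p in which(counts > 0)) {
      n <- counts[p]
      spikes[pos + seq_len(n)] <- breaks[p] + stats::runif(n) * lens[p]
      pos <- pos + n
    }
    spikes <- sort(spikes)
    apply_refractory(spikes, refractory)
  })
}

# Sequential dead-time filter: drop any spike closer than `refractory` to the
# previously kept spike.
apply_refractory <- function(times, refractory) {
  if (refractory <= 0 || length(times) < 2) return(times)
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Simulate a regular-firing (tonic) spike train
#'
#' Gamma-renewal process uncoupled from any call: interspike intervals are
#' i.i.d. gamma with shape `1 / isi_cv^2` and scale chosen so the mean ISI is
#' `1 / rate`. `isi_cv = 1` recovers a homogeneous Poisson process; small CVs
#' give the clock-like firing typical of RA projection neurons.
#'
#' @param rate Mean firing rate (spikes/s).
#' @param isi_cv ISI coefficient of variation, in `(0, 1]`.
#' @param duration Session length (s).
#' @param seed Integer seed.
#' @return Strictly increasing spike times in `[0, duration]`; possibly
#'   empty if the duration is shorter than a typical ISI.
#' @export
generate_regular_spike_train <- function(rate, isi_cv, duration, seed = 1L) {
  if (isi_cv <= 0 || isi_cv > 1) stopf("isi_cv must be in (0, 1]")
  if (rate <= 0) return(numeric(0))
  if (duration <= 0) stopf("duration must be positive")
  shape <- 1 / isi_cv^2
  scale <- 1 / (rate * shape)
  with_seed(seed, {
    times <- numeric(0)
    t <- 0
    repeat {
      chunk <- max(16L, ceiling((duration - t) * rate * 1.5))
      isis <- stats::rgamma(chunk, shape = shape, scale = scale)
      tt <- t + cumsum(isis)
      keep <- tt <= duration
      times <- c(times, tt[keep])
      if (!all(keep)) break
      t <- tt[chunk]
    }
    times
  })
}

#' Default spike waveform templates
#'
#' Two biphasic 64-sample extracellular spike shapes on the signed 16-bit
#' scale, each with a sharp negative trough (SD ~0.09 ms) at sample 21 so
#' that detection with the default 20/44 pre/post alignment reproduces the
#' embedding position to within a couple of samples even in noise. The
#' shapes differ in their positive afterwave — one narrow and pronounced,
#' one broad and flat — which is what the waveform sorting separates.
#'
#' @param amplitude Trough magnitude (16-bit sample units).
#' @return List of two integer vectors of length 64.
#' @export
default_spike_templates <- function(amplitude = 2000) {
  i <- seq_len(64)
  narrow <- -amplitude * exp(-((i - 21)^2) / (2 * 2^2)) +
    0.35 * amplitude * exp(-((i - 29)^2) / (2 * 4^2))
  broad <- -amplitude * exp(-((i - 21)^2) / (2 * 2^2)) +
    0.15 * amplitude * exp(-((i - 38)^2) / (2 * 10^2))
  list(narrow = as.integer(round(narrow)), broad = as.integer(round(broad)))
}

#' Synthesize a continuous extracellular trace
#'
#' Builds a Gaussian-noise trace and adds each unit's 64-sample waveform
#' template at the sample nearest every spike time, with the template's peak
#' landing on that sample. This provides ground-truth input for the
#' detection and sorting stages.
#'
#' @param spike_times_by_unit Named list of sorted spike-time vectors (s).
#' @param template_set Named list of 64-sample templates, one per unit (names
#'   must match).
#' @param noise_sd Noise standard deviation (16-bit sample units).
#' @param sampling_rate Sampling rate (Hz).
#' @param duration Trace length (s).
#' @param seed Integer seed for the noise.
#' @return A [waveform_recording()] of `round(duration * sampling_rate)`
#'   samples, clamped to the signed 16-bit range.
#' @export
synthesize_trace <- function(spike_times_by_unit, template_set, noise_sd,
                             sampling_rate = 22050, duration, seed = 1L) {
  n <- round(duration * sampling_rate)
  if (any(vapply(template_set, length, 1L) > n)) {
    stopf("template longer than the trace (%d samples)", n)
  }
  trace <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(n, 0, noise_sd))
  } else {
    numeric(n)
  }
  for (unit in names(spike_times_by_unit)) {
    tpl <- template_set[[unit]]
    if (is.null(tpl)) stopf("no template for unit %s", sQuote(unit))
    tpl <- as.numeric(tpl)
    peak_at <- which.max(abs(tpl))
    for (t in spike_times_by_unit[[unit]]) {
      centre <- round(t * sampling_rate) + 1L
      lo <- centre - (peak_at - 1L)
      hi <- lo + length(tpl) - 1L
      if (lo < 1L || hi > n) next
      trace[lo:hi] <- trace[lo:hi] + tpl
    }
  }
  waveform_recording(pmax(-32768, pmin(32767, trace)), sampling_rate,
                     channel_id = "synthetic")
}

#' Write a ground-truth record as JSON
#'
#' @param truth The `truth` element returned by [generate_call_exchange()],
#'   optionally augmented with `spike_times_by_unit` and `unit_regularity`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(
    focal_calls = as.data.frame(truth$focal_calls),
    partner_calls = as.data.frame(truth$partner_calls),
    answer_links = truth$answer_links
  )
  if (!is.null(truth$spike_times_by_unit)) {
    out$spike_times_by_unit <- truth$spike_times_by_unit
  }
  if (!is.null(truth$unit_regularity)) {
    out$unit_regularity <- truth$unit_regularity
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
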