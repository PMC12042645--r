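# Shared fixtures, built in code.

default_kernels <- function() {
  list(stack = default_stack_kernel(), tet = default_tet_kernel())
}

# Poisson call train of a single type with dead time = call duration.
fixture_calls <- function(type = "stack", n = 100, rate = 0.2, seed = 11) {
  dur <- if (type == "stack") 0.09 else 0.05
  set.seed(seed)
  gaps <- rexp(n, rate)
  on <- cumsum(gaps + dur)
  call_train(on, on + dur, rep(type, n))
}

# Brute-force PSTH: explicit double loop over (event, spike) pairs.
oracle_psth_counts <- function(spikes, events, bin_width, window) {
  n_bins <- round((window[2] - window[1]) / bin_width)
  counts <- integer(n_bins)
  for (t in events) {
    for (s in spikes) {
      off <- s - t
      if (off >= window[1] && off < window[2]) {
        b <- floor((off - window[1]) / bin_width) + 1L
        if (b >= 1 && b <= n_bins) counts[b] <- counts[b] + 1L
      }
    }
  }
  counts
}

# Simulated cohort: per animal, a coupled call exchange, a modulated
# multiunit train, and context-labeled calls; returns the activity table
# inputs. `kernels` picks the per-type kernels; `answered_gain` optionally
# scales the kernel of answered calls (context-dependent firing).
fixture_cohort <- function(n_animals = 8, seed = 1, duration = 600,
                           kernels = default_kernels(),
                           answered_gain = NULL) {
  spikes <- list()
  labeled <- list()
  for (i in seq_len(n_animals)) {
    aid <- sprintf("a%02d", i)
    cfg <- scenario_config(seed = seed * 1000 + i, duration = duration,
                           focal_call_rate = 0.25, p_answer = 0.4,
                           partner_baseline_rate = 0.1)
    ex <- generate_call_exchange(cfg)
    lab <- label_call_context(ex$focal, ex$partner)
    kern <- kernels
    key <- ex$focal$call_type
    if (!is.null(answered_gain)) {
      boost <- function(k, g) modulation_kernel(k$breaks, pmax(0, k$gains * g))
      kern <- c(kernels, list(stack_ans = boost(kernels$stack, answered_gain),
                              tet_ans = boost(kernels$tet, answered_gain)))
      key <- ifelse(lab$context == "answered", paste0(key, "_ans"), key)
    }
    spikes[[aid]] <- suppressWarnings(generate_modulated_spike_train(
      ex$focal, kern, baseline_rate = 40, duration = duration,
      seed = seed * 1000 + 500 + i, kernel_key = key))
    labeled[[aid]] <- lab
  }
  list(spikes = spikes, labeled = labeled)
}

# Spike trains for the detection/sorting benchmark: two units with a global
# minimum separation so no two spikes superimpose within a snippet.
fixture_two_unit_trains <- function(duration = 30, rate_per_unit = 10,
                                    min_sep = 0.004, seed = 5) {
  set.seed(seed)
  n <- rpois(2, rate_per_unit * duration)
  all_t <- sort(runif(sum(n), 0.01, duration - 0.01))
  unit <- sample(rep(1:2, c(n[1], sum(n) - n[1])))
  keep <- c(TRUE, diff(all_t) >= min_sep)
  # drop the later spike of any too-close pair, then re-check
  while (!all(keep)) {
    all_t <- all_t[keep]
    unit <- unit[keep]
    keep <- c(TRUE, diff(all_t) >= min_sep)
  }
  list(narrow = all_t[unit == 1], broad = all_t[unit == 2])
}
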