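test_that("detection finds embedded templates and nothing in silence", {
  zero <- waveform_recording(numeric(1000))
  expect_length(detect_spikes(zero)$timestamps, 0)

  # noiseless trace with 3 embedded spikes: noise floor comes from a weak
  # dither so the MAD threshold is defined
  tpl <- default_spike_templates(amplitude = 2000)
  times <- c(0.02, 0.05, 0.08)
  tr <- synthesize_trace(list(narrow = times), tpl["narrow"], noise_sd = 20,
                         duration = 0.1, seed = 1)
  det <- detect_spikes(tr, detection_params(polarity = "negative"))
  expect_length(det$timestamps, 3)
  truth_samples <- round(times * 22050)
  expect_true(all(abs(det$timestamps * 22050 - truth_samples) <= 1))
  # peak sits at snippet sample 21 (pre_peak = 20)
  expect_true(all(apply(det$waveforms, 1, which.min) == 21))
})

test_that("dead time merges near-coincident threshold crossings", {
  fs <- 10000
  x <- numeric(2000)
  x[1000] <- -3000
  x[1002] <- -2500  # 0.2 ms later
  x <- x + sin(seq_len(2000)) * 10  # noise floor for MAD
  tr <- waveform_recording(x, sampling_rate = fs)
  det <- detect_spikes(tr, detection_params(polarity = "negative",
                                            dead_time = 0.0005))
  expect_length(det$timestamps, 1)
  # and with no dead time, both crossings are separate events
  det2 <- detect_spikes(tr, detection_params(polarity = "negative",
                                             dead_time = 0))
  expect_length(det2$timestamps, 2)
})

test_that("edge peaks without room for a full snippet are skipped", {
  x <- sin(seq_len(500)) * 10
  x[10] <- -5000   # too close to the start (< pre_peak)
  x[250] <- -5000
  x[495] <- -5000  # too close to the end (< post_peak)
  tr <- waveform_recording(x, sampling_rate = 10000)
  det <- detect_spikes(tr, detection_params(polarity = "negative"))
  expect_length(det$timestamps, 1)
  expect_equal(det$timestamps * 10000 + 1, 250)
})

test_that("k-means sorting separates distinct templates", {
  tpl <- default_spike_templates()
  trains <- fixture_two_unit_trains(duration = 20, rate_per_unit = 8)
  tr <- synthesize_trace(trains, tpl, noise_sd = 200, duration = 20, seed = 9)
  det <- detect_spikes(tr, detection_params(polarity = "negative"))
  srt <- sort_waveforms(det, k = 2, seed = 1)
  expect_setequal(unique(srt$labels), 1:2)

  # truth by nearest-template assignment of each detected snippet
  truth <- apply(det$waveforms, 1, function(w) {
    which.min(c(sum((w - tpl$narrow)^2), sum((w - tpl$broad)^2)))
  })
  agree <- max(mean(truth == srt$labels), mean(truth == 3 - srt$labels))
  expect_gte(agree, 0.95)

  # k = 1: centroid is the mean waveform
  one <- sort_waveforms(det, k = 1, seed = 1)
  expect_equal(as.numeric(one$centroids),
               as.numeric(colMeans(det$waveforms)), tolerance = 1e-9)
  expect_error(sort_waveforms(det, k = length(det) + 1), "exceeds")
})

test_that("sorting is order-invariant up to label permutation", {
  tpl <- default_spike_templates()
  trains <- fixture_two_unit_trains(duration = 10, rate_per_unit = 8)
  tr <- synthesize_trace(trains, tpl, noise_sd = 150, duration = 10, seed = 2)
  det <- detect_spikes(tr, detection_params(polarity = "negative"))
  srt1 <- sort_waveforms(det, k = 2, seed = 1)
  perm <- rev(seq_along(det$timestamps))
  det_rev <- spike_records(det$timestamps[perm], det$waveforms[perm, ])
  srt2 <- sort_waveforms(det_rev, k = 2, seed = 1)
  back <- srt2$labels[order(perm)]
  agree <- max(mean(back == srt1$labels), mean(back == 3 - srt1$labels))
  expect_equal(agree, 1)
})

test_that("ISI regularity classification follows the CV threshold", {
  reg <- generate_regular_spike_train(20, 0.2, 100, seed = 31)
  p_reg <- classify_regularity(reg)
  expect_equal(p_reg$regularity, "regular")
  expect_lt(abs(p_reg$cv - 0.2), 0.05)

  pois <- generate_regular_spike_train(20, 1, 100, seed = 32)
  p_irr <- classify_regularity(pois)
  expect_equal(p_irr$regularity, "irregular")
  expect_lt(abs(p_irr$cv - 1), 0.1)

  expect_equal(classify_regularity(c(1.0))$regularity, "undetermined")
  expect_length(classify_regularity(c(1.0))$isis, 0)
  expect_equal(classify_regularity(reg[1:50])$regularity, "undetermined")
})

test_that("regularity is invariant to time rescaling", {
  st <- generate_regular_spike_train(15, 0.3, 80, seed = 33)
  a <- classify_regularity(st)
  b <- classify_regularity(st * 3.7)
  expect_equal(a$cv, b$cv, tolerance = 1e-12)
  expect_equal(a$regularity, b$regularity)
})

test_that("isi profile bookkeeping is consistent", {
  st <- generate_regular_spike_train(30, 0.4, 50, seed = 34)
  p <- classify_regularity(st)
  expect_length(p$isis, p$n_spikes - 1)
  expect_equal(sum(p$histogram), length(p$isis))
  expect_gte(p$cv, 0)
})
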