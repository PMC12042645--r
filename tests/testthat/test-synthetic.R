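test_that("call exchange is deterministic and respects coupling switches", {
  cfg <- scenario_config(seed = 42, duration = 600)
  a <- generate_call_exchange(cfg)
  b <- generate_call_exchange(cfg)
  expect_identical(a, b)

  off <- generate_call_exchange(scenario_config(seed = 42, duration = 600,
                                                p_answer = 0))
  expect_equal(nrow(off$truth$answer_links), 0)

  forced <- generate_call_exchange(scenario_config(
    seed = 7, duration = 600, p_answer = 1, partner_baseline_rate = 0,
    answer_latency_dist = list(name = "constant", value = 0.2)))
  expect_equal(nrow(forced$partner), nrow(forced$focal))
  expect_equal(forced$partner$onset, forced$focal$onset + 0.2)
})

test_that("focal call count matches an independent inverse-CDF regeneration", {
  cfg <- scenario_config(seed = 3, duration = 14400, focal_call_rate = 0.1,
                         p_answer = 0)
  ex <- generate_call_exchange(cfg)
  n <- nrow(ex$focal)
  # oracle: renewal process with exponential gaps (inverse-CDF sampling) and
  # dead time equal to the mean call duration of the stack/tet mix
  mean_dur <- 0.6 * 0.09 + 0.4 * 0.05
  set.seed(99)
  counts <- replicate(200, {
    t <- 0; k <- 0
    repeat {
      t <- t - log(runif(1)) / 0.1 + mean_dur
      if (t > 14400) break
      k <- k + 1
    }
    k
  })
  expect_lt(abs(n - mean(counts)), 3 * sd(counts))
  # and within 3 sigma of the nominal Poisson scale
  expect_lt(abs(n - 1440), 3 * sqrt(1440))
})

test_that("answer links are conserved and latencies stay in support", {
  for (seed in 1:5) {
    cfg <- scenario_config(seed = seed, duration = 2400, p_answer = 0.4)
    ex <- generate_call_exchange(cfg)
    nf <- nrow(ex$focal)
    links <- ex$truth$answer_links
    expect_lte(nrow(links), nf)
    expect_lt(abs(nrow(links) - 0.4 * nf), 3 * sqrt(nf * 0.4 * 0.6) + 1)
    expect_true(all(links$latency > 0 & links$latency <= 0.5))
    expect_true(all(diff(ex$partner$onset) > 0))
  }
})

test_that("latency support outside the answer window is rejected", {
  expect_error(scenario_config(answer_latency_dist =
                                 list(name = "uniform", min = 0.1, max = 0.9)),
               "support")
  expect_error(scenario_config(duration = -1), "duration")
  # no coupling requested: wide latency support is irrelevant and accepted
  expect_s3_class(scenario_config(p_answer = 0, answer_latency_dist =
                                    list(name = "uniform", min = 0.1, max = 0.9)),
                  "scenario_config")
})

test_that("identity kernel gives a homogeneous Poisson train", {
  calls <- fixture_calls("stack", n = 50)
  flat <- list(stack = modulation_kernel(c(-0.1, 0.1), 1))
  dur <- max(calls$offset) + 1
  st <- generate_modulated_spike_train(calls, flat, baseline_rate = 30,
                                       duration = dur, refractory = 0,
                                       seed = 8)
  expect_false(is.unsorted(st, strictly = TRUE))
  expect_lt(abs(length(st) - 30 * dur), 3 * sqrt(30 * dur))
})

test_that("zero-gain kernel segments silence the train there", {
  calls <- fixture_calls("stack", n = 80, seed = 2)
  ker <- list(stack = modulation_kernel(c(-0.05, -0.01), 0))
  st <- generate_modulated_spike_train(calls, ker, 40, max(calls$offset) + 1,
                                       seed = 3)
  for (t in calls$onset) {
    expect_equal(sum(st >= t - 0.05 & st < t - 0.01), 0)
  }
})

test_that("modulated PSTH density tracks the kernel by numeric integration", {
  calls <- fixture_calls("stack", n = 500, seed = 11)
  ker <- default_kernels()
  st <- suppressWarnings(generate_modulated_spike_train(
    calls, ker, 40, max(calls$offset) + 2, seed = 5))
  ps <- build_psth(st, calls$onset)
  d <- psth_density(ps)
  # oracle: expected rate per bin is the integral of the (piecewise-constant)
  # kernel over the bin, here evaluated exactly at bin midpoints
  expected <- kernel_gain(ker$stack, ps$edges + ps$bin_width / 2)
  expect_gt(cor(d, expected), 0.9)
})

test_that("refractory period is enforced", {
  calls <- fixture_calls("stack", n = 20)
  st <- generate_modulated_spike_train(calls, default_kernels(), 200,
                                       max(calls$offset) + 1,
                                       refractory = 0.002, seed = 4)
  expect_true(all(diff(st) >= 0.002))
})

test_that("gamma-renewal train recovers the requested ISI CV", {
  st <- generate_regular_spike_train(rate = 20, isi_cv = 0.2, duration = 150,
                                     seed = 21)
  expect_gt(length(st), 2000)
  isis <- diff(st)
  expect_lt(abs(sd(isis) / mean(isis) - 0.2), 0.03)
  expect_lt(abs(mean(isis) - 1 / 20), 0.005)
  # cv = 1 is exponential: Poisson count statistics
  pois <- generate_regular_spike_train(20, 1, 150, seed = 22)
  expect_lt(abs(sd(diff(pois)) / mean(diff(pois)) - 1), 0.08)
  # degenerate duration: empty train, no error
  expect_length(generate_regular_spike_train(20, 0.2, 0.001, seed = 1), 0)
  expect_error(generate_regular_spike_train(20, 0, 10), "isi_cv")
})

test_that("trace synthesis embeds templates sample-exactly without noise", {
  tpl <- default_spike_templates()
  none <- synthesize_trace(list(), tpl, noise_sd = 0, duration = 0.1, seed = 1)
  expect_true(all(none$samples == 0))

  times <- c(0.02, 0.05, 0.08)
  tr <- synthesize_trace(list(narrow = times), tpl["narrow"], noise_sd = 0,
                         duration = 0.1, seed = 1)
  peak_at <- which.max(abs(tpl$narrow))
  for (t in times) {
    centre <- round(t * 22050) + 1
    seg <- tr$samples[(centre - peak_at + 1):(centre - peak_at + 64)]
    expect_equal(seg, as.numeric(tpl$narrow))
  }
  expect_equal(sum(tr$samples != 0), 3 * sum(tpl$narrow != 0))
  expect_error(synthesize_trace(list(), tpl, 0, duration = 0.002, seed = 1),
               "template")
})
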