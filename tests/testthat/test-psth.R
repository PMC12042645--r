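test_that("default PSTH geometry is 400 bins of 10 ms spanning [-2, 2)", {
  ps <- build_psth(numeric(0), c(10, 20))
  expect_length(ps$counts, 400)
  expect_equal(ps$edges[1], -2)
  expect_equal(ps$edges[400], 2 - 0.01)
  expect_true(all(ps$counts == 0))
  expect_equal(ps$n_events, 2)
})

test_that("a spike exactly at onset lands in the first post-onset bin", {
  ps <- build_psth(spike_times = 10, event_onsets = 10)
  expect_equal(sum(ps$counts), 1)
  expect_equal(which(ps$counts == 1), 201)  # 0-based bin index 200
  expect_equal(ps$edges[201], 0)
})

test_that("PSTH counts equal the brute-force double loop on random cases", {
  set.seed(50)
  for (i in 1:20) {
    spikes <- sort(runif(80, 0, 60))
    events <- sort(runif(6, 2, 58))
    bw <- sample(c(0.01, 0.05, 0.1), 1)
    win <- c(-sample(1:3, 1), sample(1:3, 1))
    ps <- build_psth(spikes, events, bw, win)
    expect_identical(ps$counts, oracle_psth_counts(spikes, events, bw, win))
  }
})

test_that("PSTH is invariant to a common time shift", {
  set.seed(51)
  spikes <- sort(runif(200, 0, 100))
  events <- sort(runif(10, 5, 95))
  a <- build_psth(spikes, events)
  b <- build_psth(spikes + 1234.5, events + 1234.5)
  expect_identical(a$counts, b$counts)
})

test_that("z-scoring matches hand arithmetic and normalizes exactly", {
  counts <- c(0, 0, 10, 0, 0)
  ps <- structure(list(counts = counts, edges = seq(-0.02, 0.02, 0.01),
                       bin_width = 0.01, window = c(-0.02, 0.03),
                       n_events = 1), class = "psth")
  zp <- zscore_psth(ps)
  m <- mean(counts); s <- sd(counts)
  expect_equal(zp$z, (counts - m) / s, tolerance = 1e-12)
  expect_lt(abs(mean(zp$z)), 1e-9)
  expect_equal(sd(zp$z), 1, tolerance = 1e-9)

  flat <- structure(list(counts = rep(4L, 10), edges = seq(0, 9) * 0.01 - 0.05,
                         bin_width = 0.01, window = c(-0.05, 0.05),
                         n_events = 2), class = "psth")
  expect_true(all(zscore_psth(flat)$z == 0))
})

test_that("association detection reacts to modulation and not to silence", {
  flat <- structure(list(counts = rep(7L, 400),
                         edges = seq(-2, 1.99, 0.01), bin_width = 0.01,
                         window = c(-2, 2), n_events = 5), class = "psth")
  a <- detect_call_association(zscore_psth(flat))
  expect_false(a$associated)

  calls <- fixture_calls("stack", n = 300, seed = 12)
  st <- suppressWarnings(generate_modulated_spike_train(
    calls, default_kernels(), 40, max(calls$offset) + 2, seed = 6))
  zp <- zscore_psth(build_psth(st, calls$onset))
  a2 <- detect_call_association(zp)
  expect_true(a2$associated)
  expect_true(abs(a2$peak_time) <= 0.5)
})

test_that("association window must be covered by the PSTH", {
  ps <- build_psth(numeric(0), 5, bin_width = 0.01, window = c(-0.2, 0.2))
  expect_error(detect_call_association(zscore_psth(ps)), "cover")
})

test_that("densities normalize and window means follow the bin arithmetic", {
  uni <- structure(list(counts = rep(3L, 400), edges = seq(-2, 1.99, 0.01),
                        bin_width = 0.01, window = c(-2, 2), n_events = 10),
                   class = "psth")
  d <- psth_density(uni)
  expect_equal(sum(d), 1, tolerance = 1e-12)
  expect_equal(window_density(d, which = "early"), 0.25)
  expect_equal(window_density(d, which = "late"), 0.25)

  point <- uni
  point$counts <- rep(0L, 400); point$counts[201] <- 5L  # 0-based bin 200
  dp <- psth_density(point)
  expect_equal(window_density(dp, which = "early"), 100 / 5)
  expect_equal(window_density(dp, which = "late"), 0)

  zero <- uni; zero$counts <- rep(0L, 400)
  expect_error(psth_density(zero), "all-zero")
})

test_that("early and late windows map to the documented bin indices", {
  w <- density_windows()
  expect_equal(w$early, c(199L, 203L))
  expect_equal(w$late, c(225L, 250L))
  # -10 ms to +40 ms and +250 to +500 ms at 10 ms bins from -2 s
  expect_equal(-2 + 0.01 * w$early[1], -0.010)
  expect_equal(-2 + 0.01 * (w$early[2] + 1), 0.040)
  expect_equal(-2 + 0.01 * w$late[1], 0.250)
  expect_equal(-2 + 0.01 * w$late[2], 0.500)
  expect_gt(w$late[1], w$early[2])
})

test_that("late activity and return-to-baseline are longer for tet calls", {
  ker <- default_kernels()
  res <- lapply(c("stack", "tet"), function(tp) {
    calls <- fixture_calls(tp, n = 400, seed = 13)
    st <- suppressWarnings(generate_modulated_spike_train(
      calls, ker, 40, max(calls$offset) + 2, seed = 7))
    ps <- build_psth(st, calls$onset)
    list(ed = as.numeric(elevated_duration(zscore_psth(ps))),
         late = window_density(psth_density(ps), which = "late"))
  })
  expect_gt(res[[2]]$ed, res[[1]]$ed)
  expect_gt(res[[2]]$late, res[[1]]$late)
})

test_that("elevated duration handles flat and censored activity", {
  flat <- structure(list(counts = rep(2L, 400), edges = seq(-2, 1.99, 0.01),
                         bin_width = 0.01, window = c(-2, 2), n_events = 3),
                    class = "psth")
  ed <- elevated_duration(zscore_psth(flat))
  expect_equal(as.numeric(ed), 0)
  expect_false(attr(ed, "censored"))

  # every post-onset bin elevated through the window end
  rising <- structure(list(counts = c(rep(0L, 200), rep(50L, 25)),
                           edges = seq(-2, 0.24, 0.01), bin_width = 0.01,
                           window = c(-2, 0.25), n_events = 3),
                      class = "psth")
  ed2 <- elevated_duration(zscore_psth(rising))
  expect_true(attr(ed2, "censored"))
  expect_equal(as.numeric(ed2), 0.25)
})
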