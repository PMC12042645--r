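test_that("uniform firing gives identical early and late cell densities", {
  # deterministic 'spikes': a regular grid, far denser than the calls
  spikes <- seq(0.0005, 600, by = 0.001)
  calls <- call_train(seq(10, 580, by = 10), seq(10, 580, by = 10) + 0.09,
                      rep(c("stack", "tet"), length.out = 58))
  partner <- call_train(seq(10.2, 580.2, by = 20), seq(10.25, 580.25, by = 20),
                        rep("stack", 29))
  lab <- label_call_context(calls, partner)
  tab <- suppressMessages(build_activity_table(
    list(a1 = spikes), list(a1 = lab)))
  expect_s3_class(tab, "activity_table")
  expect_equal(tab$early_density, rep(0.25, nrow(tab)), tolerance = 1e-9)
  expect_equal(tab$late_density, rep(0.25, nrow(tab)), tolerance = 1e-9)
  expect_true(all(tab$low_n == (tab$n_calls < 10)))
})

test_that("permutation p-value equals the direct count on a tiny instance", {
  tab <- structure(data.frame(
    animal_id = rep(c("a", "b"), each = 4),
    call_type = rep(c("stack", "stack", "tet", "tet"), 2),
    context = "none",
    early_density = c(1, 2, 3, 4, 2, 1, 5, 3),
    late_density = c(1, 2, 3, 4, 2, 1, 5, 3),
    n_calls = 20L, low_n = FALSE),
    class = c("activity_table", "data.frame"))
  fit <- suppressWarnings(fit_activity_model(tab, "late", "identity",
                                             n_permutations = 500, seed = 3))
  y <- tab$late_density
  obs <- abs(mean(y[tab$call_type == "tet"]) - mean(y[tab$call_type == "stack"]))
  # direct enumeration of the within-animal label shuffles: each animal has
  # choose(4,2) = 6 assignments of which two rows are 'stack'
  combos_a <- utils::combn(1:4, 2, simplify = FALSE)
  stats <- c()
  for (ca in combos_a) for (cb in combos_a) {
    lab <- rep("tet", 8)
    lab[ca] <- "stack"; lab[4 + cb] <- "stack"
    stats <- c(stats, abs(mean(y[lab == "tet"]) - mean(y[lab == "stack"])))
  }
  exact_p <- mean(stats >= obs - 1e-12)
  expect_lt(abs(fit$permutation$p_value - exact_p), 3 * sqrt(exact_p / 500))
  expect_equal(fit$permutation$observed, obs)
})

test_that("constant response gives zero effect and permutation p of 1", {
  tab <- structure(data.frame(
    animal_id = rep(c("a", "b", "c"), each = 2),
    call_type = rep(c("stack", "tet"), 3),
    context = "none",
    early_density = 0.25, late_density = 0.25,
    n_calls = 20L, low_n = FALSE),
    class = c("activity_table", "data.frame"))
  fit <- suppressWarnings(fit_activity_model(tab, "late", "identity",
                                             n_permutations = 99, seed = 1))
  expect_equal(fit$permutation$estimate, 0)
  expect_equal(fit$permutation$p_value, 1)
})

test_that("model results are invariant to table row order", {
  cohort <- fixture_cohort(n_animals = 4, seed = 6, duration = 300)
  tab <- suppressMessages(build_activity_table(cohort$spikes, cohort$labeled))
  fit1 <- fit_activity_model(tab, "late", n_permutations = 199, seed = 5)
  perm <- sample(nrow(tab))
  tab2 <- structure(tab[perm, ], class = class(tab))
  fit2 <- fit_activity_model(tab2, "late", n_permutations = 199, seed = 5)
  expect_equal(fit1$permutation$estimate, fit2$permutation$estimate,
               tolerance = 1e-12)
  expect_equal(unname(fit1$term_p), unname(fit2$term_p), tolerance = 1e-6)
})

test_that("the late-tail call-type effect is detected in a cohort", {
  cohort <- fixture_cohort(n_animals = 8, seed = 2)
  tab <- suppressMessages(build_activity_table(cohort$spikes, cohort$labeled))
  # tet late activity exceeds stack late activity within almost every animal
  by_animal <- vapply(split(tab, tab$animal_id), function(df) {
    mean(df$late_density[df$call_type == "tet"]) -
      mean(df$late_density[df$call_type == "stack"])
  }, numeric(1))
  expect_gte(sum(by_animal > 0), length(by_animal) - 1)
  fit <- fit_activity_model(tab, "late", n_permutations = 999, seed = 4)
  expect_gt(fit$permutation$estimate, 0)
  expect_lt(fit$permutation$p_value, 0.05)
  expect_equal(fit$model_type, "mixed")
  expect_true(all(fit$term_p >= 0 & fit$term_p <= 1))
})

test_that("context invariance holds under context-free kernels and breaks
           under a context-dependent gain", {
  cohort <- fixture_cohort(n_animals = 6, seed = 8, duration = 400)
  tab <- suppressMessages(build_activity_table(cohort$spikes, cohort$labeled))
  inv <- compare_context_invariance(tab, "late", n_permutations = 499,
                                    seed = 11)
  expect_gt(inv$permutation$p_value, 0.05)

  dep <- fixture_cohort(n_animals = 6, seed = 8, duration = 400,
                        answered_gain = 1.5)
  tab2 <- suppressMessages(build_activity_table(dep$spikes, dep$labeled))
  sens <- compare_context_invariance(tab2, "late", n_permutations = 499,
                                     seed = 11)
  expect_lt(sens$permutation$p_value, 0.05)
})

test_that("single-animal tables fall back to a fixed-effects model", {
  cohort <- fixture_cohort(n_animals = 1, seed = 3, duration = 400)
  tab <- suppressMessages(build_activity_table(cohort$spikes, cohort$labeled))
  w <- capture_warnings(fit <- fit_activity_model(tab, "late",
                                                  n_permutations = 99,
                                                  seed = 1))
  expect_match(w, "one animal", all = FALSE)
  expect_equal(fit$model_type, "fixed")
})
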