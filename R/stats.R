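#' Build the per-cell early/late activity table
#'
#' For every animal and every (call type, interaction context) cell with at
#' least one call, builds a PSTH of that animal's spikes aligned to the
#' cell's call onsets, converts it to a density, and records the early and
#' late window means (x 100, see [window_density()]). Cells with zero calls
#' are omitted with a message; cells with fewer than `min_calls` calls are
#' kept but flagged `low_n`.
#'
#' @param spikes_by_animal Named list: animal id -> sorted spike times (s).
#' @param labeled_calls_by_animal Named list: animal id ->
#'   [label_call_context()] result (same names).
#' @param windows A [density_windows()].
#' @param bin_width,window PSTH geometry.
#' @param min_calls Cells with fewer calls are flagged.
#' @return A data frame of class `activity_table` with columns `animal_id`,
#'   `call_type`, `context`, `early_density`, `late_density`, `n_calls`,
#'   `low_n`.
#' @export
build_activity_table <- function(spikes_by_animal, labeled_calls_by_animal,
                                 windows = density_windows(),
                                 bin_width = 0.010, window = c(-2, 2),
                                 min_calls = 10L) {
  animals <- names(labeled_calls_by_animal)
  if (is.null(animals) || !all(animals %in% names(spikes_by_animal))) {
    stopf("spikes_by_animal and labeled_calls_by_animal must share animal names")
  }
  rows <- list()
  for (a in animals) {
    spikes <- spikes_by_animal[[a]]
    calls <- labeled_calls_by_animal[[a]]
    for (tp in call_types()) {
      for (ctx in c("answer", "answered", "none")) {
        on <- calls$onset[calls$call_type == tp & calls$context == ctx]
        if (length(on) == 0) {
          message(sprintf("animal %s: no %s calls in context %s; cell omitted",
                          a, tp, ctx))
          next
        }
        ps <- build_psth(spikes, on, bin_width = bin_width, window = window)
        if (sum(ps$counts) == 0) {
          message(sprintf("animal %s: no spikes in the %s/%s PSTH; cell omitted",
                          a, tp, ctx))
          next
        }
        d <- psth_density(ps)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = a, call_type = tp, context = ctx,
          early_density = window_density(d, windows, "early"),
          late_density = window_density(d, windows, "late"),
          n_calls = length(on), low_n = length(on) < min_calls,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(animal_id = character(0), call_type = character(0),
               context = character(0), early_density = numeric(0),
               late_density = numeric(0), n_calls = integer(0),
               low_n = logical(0))
  structure(out, class = c("activity_table", "data.frame"))
}

prepare_response <- function(table, response, transform) {
  col <- paste0(response, "_density")
  y <- table[[col]]
  if (transform == "log") {
    if (any(y <= 0)) {
      stopf("log transform requires strictly positive %s values; use transform = 'identity'",
            col)
    }
    y <- log(y)
  }
  y
}

# Within-animal label permutation test of a factor's effect on the response.
# statistic: for a 2-level factor the absolute difference of level means; for
# more levels the F statistic of the factor after adjusting for `covariate`
# in a fixed-effects linear model. p-value is
# (1 + #{permuted >= observed}) / (1 + n_permutations).
permutation_test <- function(y, labels, animal, n_permutations, seed,
                             covariate = NULL) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  stat <- if (length(lev) == 2) {
    function(lab) {
      mns <- vapply(lev, function(l) mean(y[lab == l]), numeric(1))
      abs(unname(diff(mns)))
    }
  } else {
    function(lab) {
      df <- data.frame(y = y, lab = factor(lab))
      fit <- if (is.null(covariate)) stats::lm(y ~ lab, data = df) else {
        df$cov <- factor(covariate)
        stats::lm(y ~ cov + lab, data = df)
      }
      an <- stats::anova(fit)
      an["lab", "F value"]
    }
  }
  shuffle_within <- function(lab) {
    for (a in unique(animal)) {
      idx <- which(animal == a)
      lab[idx] <- lab[sample(idx)]
    }
    lab
  }
  observed <- stat(labels)
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) stat(shuffle_within(labels)),
           numeric(1))
  })
  list(observed = observed,
       p_value = (1 + sum(perm >= observed)) / (1 + n_permutations),
       n_permutations = n_permutations,
       permuted = perm)
}

fit_lmm_terms <- function(table, y) {
  df <- data.frame(y = y,
                   call_type = factor(table$call_type, call_types()),
                   context = factor(table$context,
                                    c("answer", "answered", "none")),
                   animal_id = factor(table$animal_id))
  df$context <- droplevels(df$context)
  n_animals <- nlevels(df$animal_id)
  one_context <- nlevels(df$context) < 2
  form_fixed <- if (one_context) y ~ call_type else y ~ call_type * context
  if (n_animals < 2) {
    warnf("only one animal: falling back to a fixed-effects model")
    fit <- stats::lm(form_fixed, data = df)
    an <- stats::anova(fit)
    pv <- stats::setNames(an[["Pr(>F)"]], rownames(an))
    return(list(model_type = "fixed", fit = fit,
                fixed_effects = stats::coef(summary(fit)),
                term_p = pv[!is.na(pv)], ranef_variance = NA_real_))
  }
  form <- stats::update(form_fixed, . ~ . + (1 | animal_id))
  mixed <- tryCatch({
    fit <- suppressMessages(lmerTest::lmer(form, data = df))
    an <- suppressMessages(stats::anova(fit))  # Satterthwaite F tests
    vc <- as.data.frame(lme4::VarCorr(fit))
    list(model_type = "mixed", fit = fit,
         fixed_effects = stats::coef(summary(fit)),
         term_p = stats::setNames(an[["Pr(>F)"]], rownames(an)),
         ranef_variance = vc$vcov[vc$grp == "animal_id"][1])
  }, error = function(e) NULL)
  if (is.null(mixed)) {
    # degenerate responses (e.g. zero variance) can break the mixed fit;
    # report the fixed-effects analogue instead
    warnf("mixed-model fit failed; falling back to a fixed-effects model")
    fit <- stats::lm(form_fixed, data = df)
    an <- suppressWarnings(stats::anova(fit))
    pv <- stats::setNames(an[["Pr(>F)"]], rownames(an))
    mixed <- list(model_type = "fixed", fit = fit,
                  fixed_effects = suppressWarnings(stats::coef(summary(fit))),
                  term_p = pv[!is.na(pv)], ranef_variance = NA_real_)
  }
  mixed
}

#' Fit the call-type-by-context activity model
#'
#' Fits the linear mixed model
#' `response ~ call_type * context + (1 | animal_id)` on the per-cell
#' activity table (separately for the early or late response), and runs a
#' seeded within-animal permutation test of the call-type main effect as a
#' distribution-free companion — the mixed model is fitted on only a few
#' dozen cells, where its asymptotic p-values are fragile.
#'
#' @param table An [build_activity_table()] result.
#' @param response `"early"` or `"late"`.
#' @param transform `"identity"` or `"log"` applied to the response.
#' @param n_permutations Number of label permutations (>= 1999 recommended).
#' @param seed Integer seed for the permutations.
#' @return An object of class `model_result`: `model_type`, `fixed_effects`,
#'   `term_p` (per-term p-values), `ranef_variance`, `permutation` (list with
#'   `estimate` = mean(tet) - mean(stack) on the transformed scale,
#'   `observed` statistic, `p_value`, `n_permutations`), `response`,
#'   `transform`.
#' @export
fit_activity_model <- function(table, response = c("late", "early"),
                               transform = c("identity", "log"),
                               n_permutations = 1999L, seed = 1L) {
  response <- match.arg(response)
  transform <- match.arg(transform)
  stopifnot(inherits(table, "activity_table"))
  if (length(unique(table$animal_id)) < 1 || nrow(table) < 4) {
    stopf("activity table too small to fit")
  }
  if (!all(call_types() %in% table$call_type)) {
    stopf("both call types must be present")
  }
  y <- prepare_response(table, response, transform)
  mm <- fit_lmm_terms(table, y)
  perm <- permutation_test(y, table$call_type, table$animal_id,
                           n_permutations, substream_seed(seed, "call_type"))
  est <- mean(y[table$call_type == "tet"]) -
    mean(y[table$call_type == "stack"])
  structure(list(model_type = mm$model_type,
                 fixed_effects = mm$fixed_effects, term_p = mm$term_p,
                 ranef_variance = mm$ranef_variance,
                 permutation = list(estimate = est, observed = perm$observed,
                                    p_value = perm$p_value,
                                    n_permutations = perm$n_permutations),
                 response = response, transform = transform),
            class = "model_result")
}

#' Test invariance of call-locked activity to interaction context
#'
#' Tests whether the early/late activity depends on the interaction context
#' (answer / answered / none) or on its interaction with call type, using the
#' same mixed model as [fit_activity_model()] plus a within-animal
#' permutation test of the context effect. The response is log transformed
#' by default.
#'
#' @inheritParams fit_activity_model
#' @return A `model_result` whose `permutation` element tests the context
#'   main effect.
#' @export
compare_context_invariance <- function(table, response = c("late", "early"),
                                       transform = c("log", "identity"),
                                       n_permutations = 1999L, seed = 1L) {
  response <- match.arg(response)
  transform <- match.arg(transform)
  stopifnot(inherits(table, "activity_table"))
  present <- unique(table$context)
  if (length(present) < 2) stopf("need at least 2 contexts present")
  missing_ctx <- setdiff(c("answer", "answered", "none"), present)
  if (length(missing_ctx) > 0) {
    warnf("context level(s) %s absent from the table; dropped",
          paste(missing_ctx, collapse = ", "))
  }
  y <- prepare_response(table, response, transform)
  mm <- fit_lmm_terms(table, y)
  perm <- permutation_test(y, table$context, table$animal_id,
                           n_permutations, substream_seed(seed, "context"),
                           covariate = table$call_type)
  structure(list(model_type = mm$model_type,
                 fixed_effects = mm$fixed_effects, term_p = mm$term_p,
                 ranef_variance = mm$ranef_variance,
                 permutation = list(estimate = NA_real_,
                                    observed = perm$observed,
                                    p_value = perm$p_value,
                                    n_permutations = perm$n_permutations),
                 response = response, transform = transform),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("Activity model (%s response, %s transform, %s model)\n",
              x$response, x$transform, x$model_type))
  cat("Term p-values:\n")
  for (nm in names(x$term_p)) cat(sprintf("  %-22s %.4g\n", nm, x$term_p[nm]))
  cat(sprintf("Permutation test: statistic %.4g, p = %.4g (%d permutations)\n",
              x$permutation$observed, x$permutation$p_value,
              x$permutation$n_permutations))
  invisible(x)
}
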