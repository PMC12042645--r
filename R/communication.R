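#' Cross-correlogram of two birds' call trains
#'
#' Histogram of partner call onsets relative to each focal call onset — a
#' PSTH of one point process aligned to the other — over a ±4 s window,
#' z-scored over the full window. Call types of either bird can be
#' restricted so all pairings (stack-stack, stack-tet, tet-tet, tet-stack)
#' can be examined.
#'
#' @param focal,partner [call_train()]s on a common session clock.
#' @param focal_type,partner_type Optional call-type filters (`"stack"` or
#'   `"tet"`; `NULL` keeps all calls).
#' @param bin_width Bin width (s); default 0.1 s resolves the half-second
#'   answer window into 5 bins per side.
#' @param window Symmetric window `c(-w, w)` (s).
#' @return An object of class `cross_correlogram`: `psth`, `z`
#'   (a [zscore_psth()] result), the type filters, and `empty` (TRUE when no
#'   focal calls of the requested type exist, in which case the correlogram
#'   is all-zero).
#' @export
call_cross_correlogram <- function(focal, partner, focal_type = NULL,
                                   partner_type = NULL, bin_width = 0.1,
                                   window = c(-4, 4)) {
  stopifnot(inherits(focal, "call_train"), inherits(partner, "call_train"))
  if (!isTRUE(all.equal(-window[1], window[2]))) {
    stopf("correlogram window must be symmetric about 0")
  }
  if (!is.null(focal_type)) assert_call_types(focal_type)
  if (!is.null(partner_type)) assert_call_types(partner_type)
  f_on <- if (is.null(focal_type)) focal$onset else
    focal$onset[focal$call_type == focal_type]
  p_on <- if (is.null(partner_type)) partner$onset else
    partner$onset[partner$call_type == partner_type]
  empty <- length(f_on) == 0
  ps <- build_psth(p_on, f_on, bin_width = bin_width, window = window)
  structure(list(psth = ps, z = zscore_psth(ps), focal_type = focal_type,
                 partner_type = partner_type, empty = empty),
            class = "cross_correlogram")
}

#' @export
print.cross_correlogram <- function(x, ...) {
  cat(sprintf("Cross-correlogram (%s -> %s): %d focal calls, %d partner onsets in window%s\n",
              x$focal_type %||% "all", x$partner_type %||% "all",
              x$psth$n_events, sum(x$psth$counts),
              if (x$empty) " [empty: no focal calls of this type]" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect antiphonal calling from a cross-correlogram
#'
#' Communication between the two birds is declared when the partner's call
#' count rises above the confidence band — here `z > z_threshold`
#' (one-sided: only a rise counts) — within half a second before or after
#' the focal bird's calls.
#'
#' @param cc A [call_cross_correlogram()] covering ±`window` s.
#' @param z_threshold One-sided z threshold (default 2, matching ±2 z-score
#'   confidence lines).
#' @param window Half-width (s) of the peri-zero region tested.
#' @return `TRUE` if the maximum z within ±`window` of zero lag exceeds
#'   `z_threshold`; `FALSE` otherwise (always `FALSE` for an empty
#'   correlogram). Attributes `peak_z` and `peak_lag` report the maximum.
#' @export
detect_antiphonal <- function(cc, z_threshold = 2, window = 0.5) {
  stopifnot(inherits(cc, "cross_correlogram"))
  src <- cc$psth
  if (src$window[1] > -window || src$window[2] < window) {
    stopf("correlogram does not cover +/-%g s", window)
  }
  if (cc$empty) {
    return(structure(FALSE, peak_z = NA_real_, peak_lag = NA_real_))
  }
  centers <- src$edges + src$bin_width / 2
  in_win <- centers >= -window & centers <= window
  z <- cc$z$z[in_win]
  i <- which.max(z)
  structure(z[i] > z_threshold, peak_z = z[i], peak_lag = centers[in_win][i])
}

#' Surrogate-null antiphonal detection by circular shifts
#'
#' Distribution-free companion to [detect_antiphonal()]: the partner train
#' is circularly shifted by random offsets (destroying any fine-time
#' coupling while preserving both trains' structure), and the observed
#' peri-zero peak count is compared with the surrogate distribution.
#'
#' @param focal,partner [call_train()]s.
#' @param n_surrogates Number of circular shifts.
#' @param seed Integer seed.
#' @param window Peri-zero window half-width (s).
#' @param bin_width Correlogram bin width (s).
#' @param alpha Significance level.
#' @return List: `detected`, `p_value` (permutation-style, `(1 + #{surrogate
#'   >= observed}) / (1 + n)`), `observed_peak`, `surrogate_peaks`.
#' @export
detect_antiphonal_surrogate <- function(focal, partner, n_surrogates = 199L,
                                        seed = 1L, window = 0.5,
                                        bin_width = 0.1, alpha = 0.05) {
  stopifnot(inherits(focal, "call_train"), inherits(partner, "call_train"))
  session_end <- max(focal$offset, partner$offset, 1e-9)
  peak_count <- function(p_on) {
    ps <- build_psth(sort(p_on), focal$onset, bin_width = bin_width,
                     window = c(-4, 4))
    centers <- ps$edges + ps$bin_width / 2
    max(ps$counts[centers >= -window & centers <= window])
  }
  observed <- peak_count(partner$onset)
  surr <- with_seed(seed, {
    shifts <- stats::runif(n_surrogates, 0.05 * session_end,
                           0.95 * session_end)
    vapply(shifts, function(s) peak_count((partner$onset + s) %% session_end),
           numeric(1))
  })
  p <- (1 + sum(surr >= observed)) / (1 + n_surrogates)
  list(detected = p <= alpha, p_value = p, observed_peak = observed,
       surrogate_peaks = surr)
}

#' Label each focal call's interaction context
#'
#' Assigns every focal call exactly one of three contexts relative to the
#' partner's calls: `"answer"` when a partner call onset falls within
#' `answer_window` seconds *before* the focal call (the focal call answers
#' the partner), `"answered"` when a partner onset falls within
#' `answer_window` seconds *after* it, and `"none"` otherwise. When partner
#' calls occur on both sides, `"answer"` takes precedence; a partner onset
#' exactly simultaneous with the focal onset is ignored. The matched partner
#' call is the nearest qualifying onset.
#'
#' @param focal,partner [call_train()]s on a common clock.
#' @param answer_window Coupling window (s), default 0.5.
#' @return An object of class `context_labeled_calls`: the focal calls with
#'   added columns `context` and `partner_index` (NA for `"none"`), plus
#'   attribute `answer_window`.
#' @export
label_call_context <- function(focal, partner, answer_window = 0.5) {
  stopifnot(inherits(focal, "call_train"), inherits(partner, "call_train"))
  if (answer_window <= 0) stopf("answer_window must be positive")
  p_on <- partner$onset
  n <- nrow(focal)
  context <- rep("none", n)
  matched <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    t <- focal$onset[i]
    before <- which(p_on >= t - answer_window & p_on < t)
    after <- which(p_on > t & p_on <= t + answer_window)
    if (length(before) > 0) {
      context[i] <- "answer"
      matched[i] <- before[which.min(t - p_on[before])]
    } else if (length(after) > 0) {
      context[i] <- "answered"
      matched[i] <- after[which.min(p_on[after] - t)]
    }
  }
  out <- as.data.frame(focal)
  out$context <- context
  out$partner_index <- matched
  structure(out, bird_id = attr(focal, "bird_id"),
            answer_window = answer_window,
            class = c("context_labeled_calls", "data.frame"))
}

#' @export
print.context_labeled_calls <- function(x, ...) {
  tab <- table(factor(x$context, c("answer", "answered", "none")))
  cat(sprintf("Context-labeled calls for %s: %d answer, %d answered, %d none (window %.2f s)\n",
              sQuote(attr(x, "bird_id")), tab[1], tab[2], tab[3],
              attr(x, "answer_window")))
  invisible(x)
}
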