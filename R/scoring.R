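#' Visibility-masked, normalized area under an emotion channel
#'
#' The intensity curve is integrated with the trapezoid rule between
#' consecutive samples, restricted to the sub-intervals of `window`
#' whose left sample is visible; invisible time contributes neither
#' area nor duration.  The integral is divided by the visible seconds in
#' the window and multiplied by 10, giving the average AUC per 10 s of
#' visible time.  With maximum intensity 5 the score lies in `[0, 50]`.
#'
#' @param trace An `emotion_trace`.
#' @param channel One of `"sadness"`, `"anger"`, `"contempt"`.
#' @param window Numeric `c(t0, t1)`, the half-open integration window
#'   in seconds (usually a period window of the schedule).
#' @return Normalized AUC (intensity-seconds per 10 s of visible time).
#' @export
channel_auc <- function(trace, channel, window) {
  stopifnot(inherits(trace, "emotion_trace"))
  if (!channel %in% c("sadness", "anger", "contempt")) {
    stop("`channel` must be one of sadness, anger, contempt")
  }
  res <- masked_trapezoid(trace$time_s, trace[[channel]], trace$visible, window)
  if (res$visible_s <= 0) {
    stop("zero visible time in window: AUC undefined (child should be QC-excluded)")
  }
  10 * res$area / res$visible_s
}

# Trapezoid integral of a piecewise-linear curve over the visible part
# of [w0, w1), plus the visible duration.  The left sample's visibility
# flag governs each inter-sample interval; beyond the last sample the
# curve and flag are extended as constants.
masked_trapezoid <- function(time_s, value, visible, window) {
  n <- length(time_s)
  t0 <- time_s
  t1 <- c(time_s[-1L], max(time_s[n], window[2L]))
  v0 <- value
  v1 <- c(value[-1L], value[n])
  slope <- ifelse(t1 > t0, (v1 - v0) / (t1 - t0), 0)

  a <- pmax(t0, window[1L])
  b <- pmin(t1, window[2L])
  len <- pmax(b - a, 0)
  keep <- visible & len > 0
  if (!any(keep)) return(list(area = 0, visible_s = 0))
  fa <- v0[keep] + slope[keep] * (a[keep] - t0[keep])
  fb <- v0[keep] + slope[keep] * (b[keep] - t0[keep])
  list(area = sum(0.5 * (fa + fb) * len[keep]),
       visible_s = sum(len[keep]))
}

#' Per-period AUC scores for one trace
#'
#' Applies [channel_auc()] per channel to the inclusion and exclusion
#' windows of the schedule; the total negative emotion AUC is the sum of
#' the three channel AUCs.
#'
#' @param trace An `emotion_trace` (should have passed [qc_filter()]).
#' @param schedule A `game_schedule`.
#' @return List with elements `inclusion` and `exclusion`, each a list
#'   of `sadness_auc`, `anger_auc`, `contempt_auc`, `total_auc`,
#'   `visible_s`.
#' @export
score_periods <- function(trace, schedule) {
  one <- function(period) {
    w <- period_window(schedule, period)
    s <- channel_auc(trace, "sadness", w)
    a <- channel_auc(trace, "anger", w)
    c_ <- channel_auc(trace, "contempt", w)
    vis <- masked_trapezoid(trace$time_s, trace$sadness, trace$visible, w)$visible_s
    list(sadness_auc = s, anger_auc = a, contempt_auc = c_,
         total_auc = s + a + c_, visible_s = vis)
  }
  list(inclusion = one("inclusion"), exclusion = one("exclusion"))
}

#' Baseline adjustment by residualization
#'
#' The exclusion-phase score of each child is adjusted for their
#' baseline expressiveness by taking the residual from an ordinary
#' least-squares regression (with intercept) of the exclusion scores on
#' the inclusion scores, fitted over the analysis sample.  Residuals
#' have mean zero and are orthogonal to the baseline.  If the baseline
#' is (numerically) constant the slope is undefined and the function
#' falls back to mean-centering the exclusion scores.
#'
#' @param exclusion_scores,inclusion_scores Equal-length numeric vectors
#'   over the same children (n >= 3).
#' @return Numeric vector of residuals.
#' @export
residualize_on_baseline <- function(exclusion_scores, inclusion_scores) {
  if (length(exclusion_scores) != length(inclusion_scores)) {
    stop("score vectors must have equal length")
  }
  n <- length(exclusion_scores)
  if (n < 3L) stop("residualization needs at least 3 children")
  if (any(!is.finite(exclusion_scores)) || any(!is.finite(inclusion_scores))) {
    stop("scores must be finite")
  }
  sxx <- sum((inclusion_scores - mean(inclusion_scores))^2)
  if (sxx < 1e-12 * max(1, mean(inclusion_scores)^2)) {
    return(exclusion_scores - mean(exclusion_scores))
  }
  beta <- sum((inclusion_scores - mean(inclusion_scores)) *
                (exclusion_scores - mean(exclusion_scores))) / sxx
  resid <- exclusion_scores - mean(exclusion_scores) -
    beta * (inclusion_scores - mean(inclusion_scores))
  resid
}

#' Log scaling of right-skewed residualized scores
#'
#' Residualized AUC distributions are positively skewed; they are
#' compressed with a shifted common logarithm,
#' `log10(x + 1 - min(x))`, so the sample minimum maps to 0 and all
#' arguments are at least 1.  The transform is monotone (rank
#' preserving).  Note the shift is sample dependent, so the transformed
#' values are relative to the analysis sample.
#'
#' @param values Non-empty numeric vector.
#' @return Log-scaled vector of the same length.
#' @export
log_scale <- function(values) {
  if (!length(values)) stop("`values` must be non-empty")
  if (any(!is.finite(values))) stop("`values` must be finite")
  log10(values + 1 - min(values))
}

#' Dichotomize contempt scores
#'
#' Contempt AUCs are bimodal, with a dominant peak at children who never
#' showed contempt; the score is therefore collapsed to an indicator of
#' any contempt expression during the exclusion phase (strictly positive
#' AUC).
#'
#' @param exclusion_contempt_aucs Non-negative numeric vector.
#' @return Integer vector of 0/1.
#' @export
dichotomize_contempt <- function(exclusion_contempt_aucs) {
  if (any(!is.finite(exclusion_contempt_aucs)) ||
      any(exclusion_contempt_aucs < 0)) {
    stop("contempt AUCs must be finite and non-negative")
  }
  as.integer(exclusion_contempt_aucs > 0)
}

#' Group-level moving-average time course
#'
#' For each bin start on a regular grid, each child's visible-time
#' weighted mean intensity over the window `[bin, bin + window_s)` is
#' computed per channel (total = sadness + anger + contempt); the curve
#' is the mean over the children visible in that window.  Bins in which
#' no child is visible are `NA`.
#'
#' @param traces List of `emotion_trace` objects.
#' @param schedule Reference `game_schedule` (defines the time grid).
#' @param window_s Moving-average window length in seconds (default 3).
#' @param step_s Grid step in seconds; defaults to `window_s`
#'   (non-overlapping bins).
#' @return Data frame with `bin_start_s`, mean `sadness`, `anger`,
#'   `contempt`, `total`, and `n_children_visible`.
#' @export
group_timecourse <- function(traces, schedule, window_s = 3, step_s = window_s) {
  if (!length(traces)) stop("`traces` must contain at least one trace")
  starts <- seq(0, schedule$total_duration_s - 1e-9, by = step_s)
  acc <- matrix(0, nrow = length(starts), ncol = 4L,
                dimnames = list(NULL, c("sadness", "anger", "contempt", "total")))
  nvis <- integer(length(starts))
  for (tr in traces) {
    for (i in seq_along(starts)) {
      w <- c(starts[i], min(starts[i] + window_s, schedule$total_duration_s))
      m <- masked_trapezoid(tr$time_s, tr$sadness, tr$visible, w)
      if (m$visible_s <= 0) next
      s <- m$area / m$visible_s
      a <- masked_trapezoid(tr$time_s, tr$anger, tr$visible, w)$area / m$visible_s
      c_ <- masked_trapezoid(tr$time_s, tr$contempt, tr$visible, w)$area / m$visible_s
      acc[i, ] <- acc[i, ] + c(s, a, c_, s + a + c_)
      nvis[i] <- nvis[i] + 1L
    }
  }
  out <- as.data.frame(sweep(acc, 1, pmax(nvis, 1L), "/"))
  out[nvis == 0L, ] <- NA_real_
  cbind(data.frame(bin_start_s = starts), out,
        data.frame(n_children_visible = nvis))
}

#' Per-child peak intensities and group medians
#'
#' The peak is the maximum visible sampled intensity per channel over
#' the whole game; the group summary is the median over children.
#'
#' @param traces List of `emotion_trace` objects.
#' @return List with `per_child` (data frame: child_id, max per channel
#'   and total) and `median` (named numeric vector).
#' @export
peak_summary <- function(traces) {
  if (!length(traces)) stop("`traces` must contain at least one trace")
  per <- do.call(rbind, lapply(traces, function(tr) {
    vis <- tr$visible
    if (!any(vis)) vis <- rep(TRUE, length(tr$visible))
    data.frame(
      child_id = tr$child_id,
      sadness = max(tr$sadness[vis]),
      anger = max(tr$anger[vis]),
      contempt = max(tr$contempt[vis]),
      total = max(tr$sadness[vis] + tr$anger[vis] + tr$contempt[vis]),
      stringsAsFactors = FALSE
    )
  }))
  list(per_child = per,
       median = vapply(per[c("sadness", "anger", "contempt", "total")],
                       stats::median, numeric(1)))
}

#' Group-level inclusion vs exclusion contrast
#'
#' Tests whether expression was stronger during exclusion than during
#' inclusion: per emotion, a paired t-test of the log-scaled AUC vectors
#' of the two periods ([log_scale()] applied to each period's raw AUC
#' vector separately), plus the fraction of children with a higher
#' exclusion than inclusion AUC among those who expressed the emotion at
#' all.
#'
#' @param scores Data frame of raw period AUCs as produced by
#'   [score_cohort()] (columns `inc_<ch>`, `exc_<ch>` for `sadness`,
#'   `anger`, `contempt`, `total`).
#' @return Data frame with one row per emotion: `t`, `df`, `p`,
#'   `frac_higher_exclusion`.
#' @export
inclusion_exclusion_contrast <- function(scores) {
  n <- nrow(scores)
  if (is.null(n) || n < 3L) stop("need at least 3 children")
  emos <- c("sadness", "anger", "contempt", "total")
  rows <- lapply(emos, function(e) {
    inc <- scores[[paste0("inc_", e)]]
    exc <- scores[[paste0("exc_", e)]]
    d <- log_scale(exc) - log_scale(inc)
    if (stats::sd(d) < 1e-12) {
      if (all(abs(d) < 1e-12)) {
        # identical period scores: no evidence either way
        expressed <- (inc + exc) > 0
        return(data.frame(emotion = e, t = 0, df = n - 1, p = 1,
                          frac_higher_exclusion = if (any(expressed)) 0 else NA_real_,
                          stringsAsFactors = FALSE))
      }
      stop(sprintf("degenerate paired differences for %s (zero variance)", e))
    }
    tt <- stats::t.test(log_scale(exc), log_scale(inc), paired = TRUE)
    expressed <- (inc + exc) > 0
    data.frame(
      emotion = e,
      t = unname(tt$statistic),
      df = unname(tt$parameter),
      p = tt$p.value,
      frac_higher_exclusion = if (any(expressed)) {
        mean(exc[expressed] > inc[expressed])
      } else {
        NA_real_
      },
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Score a set of traces against one schedule
#'
#' Convenience wrapper: applies [qc_filter()] and [score_periods()] to
#' each trace and returns one row per child with raw period AUCs and the
#' QC decision.
#'
#' @param traces List of `emotion_trace` objects.
#' @param schedules A single `game_schedule` or a list of them (one per
#'   trace).
#' @return Data frame with child_id, per-period channel AUCs
#'   (`inc_*`/`exc_*`), visible seconds, `eligible` flag and
#'   comma-separated QC `reasons`.
#' @export
score_cohort <- function(traces, schedules) {
  single <- inherits(schedules, "game_schedule")
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    sch <- if (single) schedules else schedules[[i]]
    qc <- qc_filter(tr, sch)
    row <- data.frame(child_id = tr$child_id,
                      eligible = qc$eligible,
                      reasons = paste(qc$reasons, collapse = ","),
                      stringsAsFactors = FALSE)
    if (qc$eligible) {
      p <- score_periods(tr, sch)
      row$inc_sadness <- p$inclusion$sadness_auc
      row$inc_anger <- p$inclusion$anger_auc
      row$inc_contempt <- p$inclusion$contempt_auc
      row$inc_total <- p$inclusion$total_auc
      row$exc_sadness <- p$exclusion$sadness_auc
      row$exc_anger <- p$exclusion$anger_auc
      row$exc_contempt <- p$exclusion$contempt_auc
      row$exc_total <- p$exclusion$total_auc
      row$visible_s_inclusion <- qc$visibility$visible_s_inclusion
      row$visible_s_exclusion <- qc$visibility$visible_s_exclusion
    } else {
      row[c("inc_sadness", "inc_anger", "inc_contempt", "inc_total",
            "exc_sadness", "exc_anger", "exc_contempt", "exc_total",
            "visible_s_inclusion", "visible_s_exclusion")] <- NA_real_
    }
    row
  })
  do.call(rbind, rows)
}

#' Residualize, log-scale and dichotomize a scored cohort
#'
#' Takes the raw period AUCs of the eligible children and produces the
#' per-child analysis scores: exclusion-on-inclusion residuals for
#' sadness, anger and total negative emotion, their log-scaled versions,
#' and the contempt indicator.  All sample-level transforms (the
#' residualizing regression and the log shift) are fitted on the rows
#' passed in, i.e. on the analysis sample.
#'
#' @param scores Data frame from [score_cohort()]; ineligible rows are
#'   dropped.
#' @return The eligible rows with columns `resid_sadness`,
#'   `resid_anger`, `resid_total`, `log_sadness`, `log_anger`,
#'   `log_total`, `contempt_binary` appended.
#' @export
process_scores <- function(scores) {
  d <- scores[scores$eligible, , drop = FALSE]
  if (nrow(d) < 3L) stop("fewer than 3 eligible children")
  d$resid_sadness <- residualize_on_baseline(d$exc_sadness, d$inc_sadness)
  d$resid_anger <- residualize_on_baseline(d$exc_anger, d$inc_anger)
  d$resid_total <- residualize_on_baseline(d$exc_total, d$inc_total)
  d$log_sadness <- log_scale(d$resid_sadness)
  d$log_anger <- log_scale(d$resid_anger)
  d$log_total <- log_scale(d$resid_total)
  d$contempt_binary <- dichotomize_contempt(d$exc_contempt)
  d
}
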