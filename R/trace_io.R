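#' Continuous emotion-coding traces
#'
#' A trace holds the continuous micro-coding of one child's video by one
#' coder: three emotion-intensity channels (sadness, anger, contempt,
#' each on the 0-5 joystick/throttle scale) sampled over time, together
#' with a per-sample visibility flag recording whether the child's face
#' could be seen.  Time is in seconds from game onset.
#'
#' @param child_id,coder_id Identifiers (coerced to character).
#' @param time_s Strictly increasing sample times in seconds.
#' @param sadness,anger,contempt Intensity samples, each in `[0, 5]`.
#' @param visible Logical (or 0/1) visibility flags.
#' @return An object of class `emotion_trace`.
#' @export
emotion_trace <- function(child_id, coder_id, time_s, sadness, anger,
                          contempt, visible) {
  tr <- structure(
    list(child_id = as.character(child_id)[1L],
         coder_id = as.character(coder_id)[1L],
         time_s = as.numeric(time_s),
         sadness = as.numeric(sadness),
         anger = as.numeric(anger),
         contempt = as.numeric(contempt),
         visible = as.logical(visible)),
    class = "emotion_trace"
  )
  validate_trace(tr)
  tr
}

validate_trace <- function(trace) {
  n <- length(trace$time_s)
  if (n < 2L) stop("a trace needs at least 2 samples")
  lens <- vapply(trace[c("sadness", "anger", "contempt", "visible")],
                 length, integer(1))
  if (any(lens != n)) stop("all sample columns must have equal length")
  if (any(!is.finite(trace$time_s)) || any(diff(trace$time_s) <= 0)) {
    bad <- which(diff(trace$time_s) <= 0)[1L] + 1L
    stop(sprintf("time_s must be strictly increasing (violated at row %d)", bad))
  }
  for (ch in c("sadness", "anger", "contempt")) {
    v <- trace[[ch]]
    if (any(!is.finite(v)) || any(v < 0 | v > 5)) {
      bad <- which(!is.finite(v) | v < 0 | v > 5)[1L]
      stop(sprintf("%s intensity outside [0, 5] at row %d", ch, bad))
    }
  }
  if (any(is.na(trace$visible))) stop("visible flags must be 0/1")
  invisible(trace)
}

#' @export
print.emotion_trace <- function(x, ...) {
  cat(sprintf(
    "emotion_trace: child %s, coder %s, %d samples over [%.2f, %.2f] s, %.1f%% visible\n",
    x$child_id, x$coder_id, length(x$time_s), x$time_s[1L],
    x$time_s[length(x$time_s)], 100 * mean(x$visible)
  ))
  invisible(x)
}

#' @export
as.data.frame.emotion_trace <- function(x, ...) {
  data.frame(time_s = x$time_s, sadness = x$sadness, anger = x$anger,
             contempt = x$contempt, visible = as.integer(x$visible))
}

#' Read / write a trace file
#'
#' Trace files are plain CSV with the exact header
#' `time_s,sadness,anger,contempt,visible`; visibility is encoded 0/1.
#' One file holds one child-by-coder trace; child and coder identifiers
#' live in the cohort manifest, not in the file, but can be supplied
#' here.
#'
#' @param path File location.
#' @param child_id,coder_id Identifiers to attach to the trace read.
#' @param trace An `emotion_trace` to write.
#' @return `read_trace()` returns a validated `emotion_trace`;
#'   `write_trace()` returns `path` invisibly and guarantees the
#'   round trip `read_trace(write_trace(tr, p))` reproduces the samples
#'   to full stored precision.
#' @export
read_trace <- function(path, child_id = "unknown", coder_id = "unknown") {
  if (!file.exists(path)) stop(sprintf("trace file not found: %s", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_s", "sadness", "anger", "contempt", "visible")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop(sprintf("trace file %s is missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  emotion_trace(child_id, coder_id, d$time_s, d$sadness, d$anger,
                d$contempt, d$visible != 0)
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "emotion_trace"))
  validate_trace(trace)
  d <- as.data.frame(trace)
  # full precision so the round trip is exact
  d$time_s <- format(d$time_s, digits = 17, trim = TRUE, scientific = FALSE)
  for (ch in c("sadness", "anger", "contempt")) {
    d[[ch]] <- format(d[[ch]], digits = 17, trim = TRUE, scientific = FALSE)
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Inter-sample intervals of a trace, extended to cover the game window:
# [0, t1) counts as invisible lead-in, the tail [tN, total) carries the
# last sample's visibility (constant extrapolation).  Visibility of an
# interval is the flag of its left sample (step-function semantics).
trace_intervals <- function(trace, total_duration_s) {
  t <- trace$time_s
  n <- length(t)
  start <- t
  end <- c(t[-1L], max(t[n], total_duration_s))
  list(start = start, end = end, visible = trace$visible)
}

#' Visible seconds per game period
#'
#' Sums the durations of inter-sample intervals whose left sample is
#' visible, clipped to each period window.  The AUC scores are later
#' normalized by exactly these visible durations.
#'
#' @param trace An `emotion_trace`.
#' @param schedule A `game_schedule`.
#' @return List with `visible_s_inclusion`, `visible_s_exclusion` and
#'   `invisible_s_total` (all seconds; they sum with the visible time to
#'   the total game duration).
#' @export
visibility_summary <- function(trace, schedule) {
  stopifnot(inherits(trace, "emotion_trace"), inherits(schedule, "game_schedule"))
  total <- schedule$total_duration_s
  if (trace$time_s[1L] >= total || max(trace$time_s) < 0) {
    stop("trace lies entirely outside the game window")
  }
  iv <- trace_intervals(trace, total)
  vis_in_window <- function(w) {
    a <- pmax(iv$start, w[1L])
    b <- pmin(iv$end, w[2L])
    sum(pmax(b - a, 0)[iv$visible])
  }
  vi <- vis_in_window(period_window(schedule, "inclusion"))
  ve <- vis_in_window(period_window(schedule, "exclusion"))
  list(visible_s_inclusion = vi,
       visible_s_exclusion = ve,
       invisible_s_total = total - vi - ve)
}

#' Visibility-based eligibility filter
#'
#' A child's coding is usable only if the face was visible for at least
#' 8 s during the Inclusion Period and at least 30 s during the
#' Exclusion Period, and the child was not invisible for more than 30 s
#' in total.  Equality passes the "at least" rules; the total-invisible
#' rule excludes strictly above 30 s.
#'
#' @param trace An `emotion_trace`.
#' @param schedule A `game_schedule`.
#' @param min_inclusion_s,min_exclusion_s,max_invisible_s Thresholds in
#'   seconds (defaults as stated above).
#' @return List with `eligible` (logical) and `reasons` (character
#'   vector, empty when eligible; subset of `"invisible_total"`,
#'   `"inclusion_visibility"`, `"exclusion_visibility"`).
#' @export
qc_filter <- function(trace, schedule, min_inclusion_s = 8,
                      min_exclusion_s = 30, max_invisible_s = 30) {
  vs <- visibility_summary(trace, schedule)
  reasons <- character(0)
  if (vs$invisible_s_total > max_invisible_s) reasons <- c(reasons, "invisible_total")
  if (vs$visible_s_inclusion < min_inclusion_s) reasons <- c(reasons, "inclusion_visibility")
  if (vs$visible_s_exclusion < min_exclusion_s) reasons <- c(reasons, "exclusion_visibility")
  list(eligible = length(reasons) == 0L, reasons = reasons,
       visibility = vs)
}
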