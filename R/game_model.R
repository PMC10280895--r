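#' Cyberball toss schedule
#'
#' The Cyberball game used here consists of 42 continuous ball tosses.
#' The Inclusion Period is made up of the first six tosses, two of which
#' (tosses 3 and 6) are received by the participating child.  The
#' Exclusion Period follows seamlessly with 36 tosses, of which the child
#' receives only tosses 15 and 25 (counted over the whole game), so that
#' the child is effectively ostracized while attention is retained.
#'
#' `build_schedule()` constructs such a schedule from the two period
#' durations.  Toss onsets partition each period uniformly, optionally
#' perturbed by multiplicative jitter; gaps are renormalized so that the
#' period durations are exact.
#'
#' @param inclusion_duration_s Duration of the Inclusion Period in
#'   seconds (must be positive).
#' @param exclusion_duration_s Duration of the Exclusion Period in
#'   seconds (must be positive).
#' @param jitter_fraction Fraction in `[0, 1)` controlling multiplicative
#'   jitter of the inter-toss gaps: each gap is scaled by a factor drawn
#'   uniformly from `[1 - jitter_fraction, 1 + jitter_fraction]` before
#'   renormalization.  `0` gives exactly uniform spacing.
#' @param seed Optional integer seed for the jitter draws; with a seed
#'   the schedule is reproducible.
#' @return An object of class `game_schedule`: a list with elements
#'   `tosses` (data frame with columns `index`, `onset_s`, `thrower`,
#'   `receiver`), `inclusion_end_s` and `total_duration_s`.
#' @examples
#' sch <- build_schedule(12, 54)
#' participant_receive_times(sch)
#' @export
build_schedule <- function(inclusion_duration_s, exclusion_duration_s,
                           jitter_fraction = 0, seed = NULL) {
  if (!is.numeric(inclusion_duration_s) || length(inclusion_duration_s) != 1L ||
      !is.finite(inclusion_duration_s) || inclusion_duration_s <= 0) {
    stop("`inclusion_duration_s` must be a single positive number")
  }
  if (!is.numeric(exclusion_duration_s) || length(exclusion_duration_s) != 1L ||
      !is.finite(exclusion_duration_s) || exclusion_duration_s <= 0) {
    stop("`exclusion_duration_s` must be a single positive number")
  }
  if (!is.numeric(jitter_fraction) || length(jitter_fraction) != 1L ||
      jitter_fraction < 0 || jitter_fraction >= 1) {
    stop("`jitter_fraction` must lie in [0, 1)")
  }
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }

  gaps_for <- function(n_tosses, duration) {
    g <- rep(1, n_tosses)
    if (jitter_fraction > 0) {
      g <- g * stats::runif(n_tosses, 1 - jitter_fraction, 1 + jitter_fraction)
    }
    g * duration / sum(g)
  }

  # A toss's onset is the start of its animation; toss i of a period ends
  # where toss i+1 begins, and the last toss ends at the period boundary.
  inc_gaps <- gaps_for(6L, inclusion_duration_s)
  exc_gaps <- gaps_for(36L, exclusion_duration_s)
  onsets <- c(cumsum(c(0, inc_gaps))[1:6],
              inclusion_duration_s + cumsum(c(0, exc_gaps))[1:36])

  receive_idx <- c(3L, 6L, 15L, 25L)
  receiver <- rep(c("avatarA", "avatarB"), length.out = 42L)
  receiver[receive_idx] <- "participant"
  # Thrower of toss i is the receiver of toss i-1 when that was an avatar;
  # after a participant receive the participant throws the next toss.
  thrower <- c("avatarA", receiver[-42L])
  thrower[thrower == receiver] <- "avatarB"  # avoid self-tosses

  structure(
    list(
      tosses = data.frame(
        index = 1:42,
        onset_s = onsets,
        thrower = thrower,
        receiver = receiver,
        stringsAsFactors = FALSE
      ),
      inclusion_end_s = inclusion_duration_s,
      total_duration_s = inclusion_duration_s + exclusion_duration_s
    ),
    class = "game_schedule"
  )
}

#' @export
print.game_schedule <- function(x, ...) {
  cat(sprintf(
    "Cyberball schedule: 42 tosses, inclusion [0, %.2f) s, exclusion [%.2f, %.2f) s\n",
    x$inclusion_end_s, x$inclusion_end_s, x$total_duration_s
  ))
  cat(sprintf("participant receives at t = %s s\n",
              paste(sprintf("%.2f", participant_receive_times(x)), collapse = ", ")))
  invisible(x)
}

#' Half-open time window of a game period
#'
#' @param schedule A `game_schedule`.
#' @param period `"inclusion"` or `"exclusion"`.
#' @return Numeric vector `c(t0, t1)`; the window is the half-open
#'   interval `[t0, t1)`, so that the two periods partition the game
#'   exactly with no overlap.
#' @export
period_window <- function(schedule, period) {
  stopifnot(inherits(schedule, "game_schedule"))
  if (!is.character(period) || length(period) != 1L ||
      !period %in% c("inclusion", "exclusion")) {
    stop("`period` must be \"inclusion\" or \"exclusion\"")
  }
  if (period == "inclusion") {
    c(0, schedule$inclusion_end_s)
  } else {
    c(schedule$inclusion_end_s, schedule$total_duration_s)
  }
}

#' Times at which the participant receives the ball
#'
#' @param schedule A `game_schedule`.
#' @return Onset times (seconds) of the tosses whose receiver is the
#'   participant: tosses 3 and 6 (inclusion) and 15 and 25 (exclusion).
#' @export
participant_receive_times <- function(schedule) {
  stopifnot(inherits(schedule, "game_schedule"))
  schedule$tosses$onset_s[schedule$tosses$receiver == "participant"]
}

#' Serialize / restore a schedule as YAML
#'
#' @param schedule A `game_schedule`.
#' @param path File to write to / read from.
#' @return `read_schedule()` returns a `game_schedule`;
#'   `write_schedule()` returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "game_schedule"))
  doc <- list(
    inclusion_end_s = schedule$inclusion_end_s,
    total_duration_s = schedule$total_duration_s,
    tosses = lapply(seq_len(nrow(schedule$tosses)), function(i) {
      as.list(schedule$tosses[i, , drop = FALSE])
    })
  )
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  doc <- yaml::read_yaml(path)
  tosses <- do.call(rbind, lapply(doc$tosses, function(t) {
    data.frame(index = as.integer(t$index), onset_s = as.numeric(t$onset_s),
               thrower = t$thrower, receiver = t$receiver,
               stringsAsFactors = FALSE)
  }))
  sch <- structure(
    list(tosses = tosses,
         inclusion_end_s = as.numeric(doc$inclusion_end_s),
         total_duration_s = as.numeric(doc$total_duration_s)),
    class = "game_schedule"
  )
  validate_schedule(sch)
  sch
}

validate_schedule <- function(schedule) {
  t <- schedule$tosses
  if (nrow(t) != 42L || !identical(t$index, 1:42)) {
    stop("schedule must contain tosses 1..42 without gaps")
  }
  if (any(diff(t$onset_s) <= 0)) stop("toss onsets must be strictly increasing")
  if (!identical(which(t$receiver == "participant"), c(3L, 6L, 15L, 25L))) {
    stop("participant must receive exactly tosses 3, 6, 15 and 25")
  }
  if (!(schedule$inclusion_end_s > 0 &&
        schedule$inclusion_end_s < schedule$total_duration_s)) {
    stop("0 < inclusion_end_s < total_duration_s violated")
  }
  invisible(schedule)
}

# Seed scoping helpers: save the caller's RNG state, seed, and restore.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
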