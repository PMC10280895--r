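#' Inter-coder reliability: ICC, single measure, absolute agreement
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation (McGraw-Wong ICC(A,1)): with n subjects and k coders and
#' the two-way ANOVA mean squares MSR (between subjects), MSC (between
#' coders) and MSE (residual),
#'
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`
#'
#' i.e. coder disagreement counts whether it is systematic (a strict or
#' lenient coder) or idiosyncratic.  Scores entering the ICC here are
#' per-child normalized AUCs, before any sample-level residualization:
#' reliability concerns the raw coding.
#'
#' @param panel Numeric matrix, subjects x coders, complete (no missing
#'   cells), at least 3 subjects and 2 coders.
#' @return List with `icc`, the mean squares (`msr`, `msc`, `mse`) and
#'   the panel dimensions.
#' @export
icc_single_absolute <- function(panel) {
  panel <- as.matrix(panel)
  n <- nrow(panel)
  k <- ncol(panel)
  if (n < 3L || k < 2L) stop("panel needs >= 3 subjects and >= 2 coders")
  if (any(!is.finite(panel))) stop("panel must be complete (no missing cells)")

  row_means <- rowMeans(panel)
  col_means <- colMeans(panel)
  grand <- mean(panel)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((panel - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr < 1e-12) stop("zero between-subject variance: ICC undefined")
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  list(icc = icc, msr = msr, msc = msc, mse = mse, n_subjects = n, n_coders = k)
}

#' Pivot a long coder-score table into a rating panel
#'
#' @param long Data frame with columns `child_id`, `coder_id`, `score`
#'   (one row per rating; every child must be scored by every coder).
#' @return Numeric matrix subjects x coders.
#' @export
panel_from_long <- function(long) {
  stopifnot(all(c("child_id", "coder_id", "score") %in% names(long)))
  children <- unique(long$child_id)
  coders <- sort(unique(long$coder_id))
  m <- matrix(NA_real_, length(children), length(coders),
              dimnames = list(as.character(children), as.character(coders)))
  m[cbind(match(long$child_id, children), match(long$coder_id, coders))] <-
    long$score
  if (any(is.na(m))) stop("panel is incomplete: some child/coder cells missing")
  m
}
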