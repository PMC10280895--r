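test_that("channel AUC matches closed forms for constant and ramp traces", {
  sch <- ref_schedule()
  expect_equal(channel_auc(constant_trace(2), "sadness", c(0, 66)), 20)
  expect_equal(channel_auc(constant_trace(2), "anger", period_window(sch, "exclusion")), 20)

  # linear ramp 0 -> 5 over a fully visible 10-s window: mean 2.5 -> AUC 25
  t <- seq(0, 10, by = 0.5)
  ramp <- emotion_trace("c", "k", t, t / 2, rep(0, 21), rep(0, 21),
                        rep(TRUE, 21))
  expect_equal(channel_auc(ramp, "sadness", c(0, 10)), 25)
})

test_that("channel AUC agrees with a 1 ms Riemann-sum oracle on random traces", {
  set.seed(41)
  for (i in 1:100) {
    tr <- random_trace(n = sample(20:200, 1), p_visible = 0.4)
    w <- sort(round(runif(2, 0, 66), 3))
    if (diff(w) < 2) w <- c(w[1], w[1] + 2)
    got <- tryCatch(channel_auc(tr, "anger", w), error = function(e) NULL)
    if (is.null(got)) next  # no visible time in window
    want <- riemann_auc_oracle(tr, "anger", w)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("trapezoid integration is exact under piecewise-linear refinement", {
  set.seed(42)
  tr <- random_trace(n = 50, p_visible = 1)
  w <- c(5, 60)
  base <- channel_auc(tr, "sadness", w)
  # insert collinear midpoints: same piecewise-linear curve, more samples
  tm <- (tr$time_s[-50] + tr$time_s[-1]) / 2
  sm <- (tr$sadness[-50] + tr$sadness[-1]) / 2
  am <- (tr$anger[-50] + tr$anger[-1]) / 2
  cm <- (tr$contempt[-50] + tr$contempt[-1]) / 2
  ord <- order(c(tr$time_s, tm))
  tr2 <- emotion_trace("c", "k", c(tr$time_s, tm)[ord],
                       c(tr$sadness, sm)[ord], c(tr$anger, am)[ord],
                       c(tr$contempt, cm)[ord],
                       rep(TRUE, 99))
  expect_equal(channel_auc(tr2, "sadness", w), base, tolerance = 1e-9)
})

test_that("AUCs are homogeneous of degree one in intensity", {
  set.seed(43)
  tr <- random_trace(n = 80, p_visible = 0.7)
  lam <- 0.37
  tr2 <- emotion_trace("c", "k", tr$time_s, lam * tr$sadness, lam * tr$anger,
                       lam * tr$contempt, tr$visible)
  w <- c(0, 66)
  for (ch in c("sadness", "anger", "contempt")) {
    expect_equal(channel_auc(tr2, ch, w), lam * channel_auc(tr, ch, w),
                 tolerance = 1e-10)
  }
})

test_that("period scores decompose the game and total sums the channels", {
  sch <- ref_schedule()
  zero <- constant_trace(0)
  p0 <- score_periods(zero, sch)
  expect_equal(p0$inclusion$total_auc, 0)
  expect_equal(p0$exclusion$total_auc, 0)

  # nonzero only during exclusion
  t <- seq(0, 65.9, by = 0.1)
  s <- ifelse(t > 12, 1.5, 0)
  tr <- emotion_trace("c", "k", t, s, rep(0, 660), rep(0, 660), rep(TRUE, 660))
  p <- score_periods(tr, sch)
  expect_equal(p$inclusion$sadness_auc, 0)
  expect_gt(p$exclusion$sadness_auc, 0)

  set.seed(44)
  rt <- random_trace(n = 150, p_visible = 0.8)
  pr <- score_periods(rt, sch)
  expect_equal(pr$exclusion$total_auc,
               pr$exclusion$sadness_auc + pr$exclusion$anger_auc +
                 pr$exclusion$contempt_auc)
})

test_that("residualization reproduces OLS residuals and their orthogonality", {
  # perfect linear relation: all residuals zero
  inc <- c(1, 2, 3, 4, 5)
  expect_equal(residualize_on_baseline(2 * inc, inc), rep(0, 5))

  # constant baseline: intercept-only fallback, i.e. mean-centering
  exc <- c(4, 7, 1, 8)
  expect_equal(residualize_on_baseline(exc, rep(3, 4)), exc - mean(exc))

  # bivariate normal sample against the normal-equations oracle
  set.seed(45)
  x <- rnorm(200)
  y <- 1 + 0.6 * x + rnorm(200, 0, 0.5)
  got <- residualize_on_baseline(y, x)
  X <- cbind(1, x)
  want <- y - X %*% solve(t(X) %*% X, t(X) %*% y)
  expect_equal(got, drop(want), tolerance = 1e-8)
  expect_lt(abs(mean(got)), 1e-8)
  expect_lt(abs(sum(got * x)), 1e-8)

  expect_error(residualize_on_baseline(1:4, 1:3), "equal length")
  expect_error(residualize_on_baseline(1:2, 1:2), "at least 3")
})

test_that("log scaling maps the minimum to zero and tames right skew", {
  expect_equal(log_scale(c(0, 9, 99)), c(0, 1, 2))

  set.seed(46)
  v <- rexp(500)^1.5 - 0.4  # right-skewed residual-like values
  lv <- log_scale(v)
  expect_identical(order(v), order(lv))
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  expect_lt(abs(skew(lv)), abs(skew(v)))
  expect_equal(min(lv), 0)
})

test_that("contempt dichotomization is a strict positivity indicator", {
  expect_identical(dichotomize_contempt(c(0, 0.001, 7.2)), c(0L, 1L, 1L))
  expect_identical(dichotomize_contempt(rep(0, 4)), rep(0L, 4))
  expect_error(dichotomize_contempt(c(-0.1, 1)), "non-negative")
})

test_that("group time course is flat for constant cohorts and tracks a step", {
  sch <- ref_schedule()
  tc <- group_timecourse(list(constant_trace(1.2), constant_trace(1.2)), sch)
  expect_true(all(abs(tc$sadness - 1.2) < 1e-9))
  expect_true(all(tc$n_children_visible == 2L))

  # single child stepping up at exclusion onset: curve rises within 3 s
  t <- seq(0, 65.9, by = 0.1)
  s <- ifelse(t > 12, 3, 0)
  tr <- emotion_trace("c", "k", t, s, rep(0, 660), rep(0, 660), rep(TRUE, 660))
  tc1 <- group_timecourse(list(tr), sch, window_s = 3, step_s = 3)
  expect_equal(tc1$sadness[tc1$bin_start_s < 9], rep(0, 3))
  expect_gt(tc1$sadness[tc1$bin_start_s == 12], 2.5)
  expect_true(all(tc1$sadness[tc1$bin_start_s >= 15] == 3))

  # a cohort of identical traces equals the single-trace moving average
  tc2 <- group_timecourse(list(tr, tr, tr), sch, window_s = 3, step_s = 3)
  expect_equal(tc2$sadness, tc1$sadness)
})

test_that("peak summaries report per-child maxima and group medians", {
  t <- seq(0, 65.9, by = 0.1)
  mk <- function(peak, ch = "anger") {
    v <- rep(0, 660); v[300] <- peak
    args <- list(sadness = rep(0, 660), anger = rep(0, 660),
                 contempt = rep(0, 660))
    args[[ch]] <- v
    emotion_trace(paste0("c", peak), "k", t, args$sadness, args$anger,
                  args$contempt, rep(TRUE, 660))
  }
  ps <- peak_summary(list(mk(1), mk(2), mk(5)))
  expect_equal(ps$per_child$anger, c(1, 2, 5))
  expect_equal(unname(ps$median["anger"]), 2)
  zero <- peak_summary(list(constant_trace(0), constant_trace(0)))
  expect_equal(unname(zero$median), rep(0, 4))
})

test_that("inclusion-exclusion contrast handles identity and degenerate shifts", {
  scores <- data.frame(
    inc_sadness = c(1, 2, 3), inc_anger = c(1, 2, 3),
    inc_contempt = c(1, 2, 3), inc_total = c(3, 6, 9),
    exc_sadness = c(1, 2, 3), exc_anger = c(1, 2, 3),
    exc_contempt = c(1, 2, 3), exc_total = c(3, 6, 9)
  )
  ct <- inclusion_exclusion_contrast(scores)
  expect_equal(ct$t, rep(0, 4))
  expect_equal(ct$p, rep(1, 4))

  # constant shift: log-scale maps both periods to the same values only
  # when they are identical; a pure location shift of raw AUCs leaves
  # zero-variance nonzero differences on the raw scale
  shifted <- scores
  for (e in c("sadness", "anger", "contempt", "total")) {
    shifted[[paste0("exc_", e)]] <- scores[[paste0("inc_", e)]] * 2
  }
  # doubling is not degenerate after log scaling of distinct values
  expect_silent(inclusion_exclusion_contrast(shifted))
})
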