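cfg <- default_config()

test_that("sampled covariates match the configured marginals", {
  cov <- sample_covariates(4813, cfg, seed = 81)
  se_p <- function(p) sqrt(p * (1 - p) / 4813)
  expect_lt(abs(mean(cov$sex_girl) - 0.508), 3 * se_p(0.508))
  expect_lt(abs(mean(cov$maternal_university) - 0.266), 3 * se_p(0.266))
  expect_lt(abs(mean(cov$origin == "nondutch_nonwestern") - 0.317),
            3 * se_p(0.317))
  expect_lt(abs(mean(cov$nonverbal_iq) - 101.70), 3 * 14.97 / sqrt(4813))
  expect_lt(abs(mean(cov$age_years) - 9.80), 3 * 0.34 / sqrt(4813))
  expect_identical(cov, sample_covariates(4813, cfg, seed = 81))
})

null_config <- function(base) {
  paths <- base$paths
  for (nm in names(paths)) paths[[nm]] <- 0
  base$paths <- paths
  base
}

test_that("latents are unit variance, and independent when all paths are zero", {
  cov <- sample_covariates(4000, cfg, seed = 82)
  # a distinct seed: reusing one seed across samplers would replay the
  # same underlying uniforms and couple the streams
  lat <- sample_latents(cov, cfg, seed = 182)
  expect_lt(abs(var(lat$E) - 1), 0.1)
  expect_lt(abs(var(lat$R) - 1), 0.1)
  expect_lt(abs(var(lat$A) - 1), 0.1)
  expect_lt(abs(cor(lat$R, lat$A) - cfg$paths$during_after_cor), 0.05)

  lat0 <- sample_latents(cov, null_config(cfg), seed = 83)
  expect_lt(abs(cor(lat0$E, lat0$R)), 0.05)
  expect_lt(abs(cor(lat0$R, lat0$A)), 0.05)
  expect_lt(abs(cor(lat0$E, cov$sex_girl)), 0.05)
})

test_that("impossible path systems are rejected", {
  bad <- with_config(cfg, paths.E_to_during = 0.9, paths.sex_to_during = -0.9,
                     paths.iq_to_during = 0.9)
  expect_error(sample_latents(sample_covariates(10, cfg, seed = 1), bad),
               "variance")
  bad2 <- with_config(cfg, paths.during_after_cor = 1.2)
  expect_error(cyberscore:::validate_config(bad2), "correlation")
})

test_that("noise-free traces rise monotonically during exclusion", {
  quiet <- with_config(cfg, trace.dip_depth = 0, trace.noise_sd = 0,
                       trace.baseline_expresser_fraction = 0,
                       trace.expresser_fraction = list(sadness = 1, anger = 1,
                                                       contempt = 1))
  sch <- build_schedule(11.6, 52.4)
  tr <- simulate_trace(0, sch, quiet, seed = 84)
  exc <- tr$sadness[tr$time_s >= sch$inclusion_end_s]
  expect_true(all(diff(exc) >= -1e-9))
  expect_true(all(tr$sadness[tr$time_s < sch$inclusion_end_s] == 0))
})

test_that("higher expressivity yields a larger exclusion AUC, reproducibly", {
  sch <- build_schedule(11.6, 52.4)
  all_express <- with_config(cfg, trace.expresser_fraction =
                               list(sadness = 1, anger = 1, contempt = 1))
  hi <- simulate_trace(qnorm(0.99), sch, all_express, seed = 85)
  lo <- simulate_trace(qnorm(0.01), sch, all_express, seed = 85)
  w <- period_window(sch, "exclusion")
  auc <- function(tr) channel_auc(tr, "sadness", w) + channel_auc(tr, "anger", w)
  expect_gt(auc(hi), auc(lo))
  expect_identical(as.data.frame(simulate_trace(1, sch, cfg, seed = 86)),
                   as.data.frame(simulate_trace(1, sch, cfg, seed = 86)))
})

test_that("contempt prevalence follows the configured expresser fraction", {
  co <- simulate_cohort(1500, cfg, seed = 87)
  d <- analysis_table(co)
  se <- sqrt(0.255 * 0.745 / nrow(d))
  expect_lt(abs(mean(d$contempt_binary) - 0.255), 3.5 * se)
})

test_that("cohorts are mostly QC-eligible and expressivity drives the scores", {
  co <- simulate_cohort(600, cfg, seed = 88)
  expect_gt(mean(co$scores$eligible), 0.85)
  d <- analysis_table(co)
  E <- co$latents$E[match(d$child_id, co$covariates$child_id)]
  expect_gt(cor(d$exc_total, E), 0.15)
  # questionnaire scale means sit near the published marginals
  expect_lt(abs(mean(d$negative_during) - 2.85), 0.1)
  expect_lt(abs(mean(d$negative_after) - 1.57), 0.1)
})

test_that("lockstep items give alpha near 1; planted structure is recovered", {
  n <- 3000
  set.seed(89)
  R <- rnorm(n); A <- 0.3 * R + sqrt(1 - 0.09) * rnorm(n)
  lock <- with_config(cfg, questionnaire.during_loading = 0.995)
  resp_lock <- simulate_questionnaire(R, A, lock, seed = 90)
  specs <- item_specs()
  rec <- recode_items(resp_lock, specs)
  expect_gt(cronbach_alpha(rec[, specs$scale == "during_scale"]), 0.95)

  # full recovery loop: EFA + varimax + threshold assignment finds the
  # 6/7 item split and flags the two low-loading items
  resp <- simulate_questionnaire(R, A, cfg, seed = 91)
  rec <- recode_items(resp, specs)
  retained <- rec[, specs$included]
  L <- varimax_rotate(efa_principal_axis(retained, 2))
  asg <- assign_items(L, threshold = 0.40)
  spec_ret <- specs[specs$included, ]
  expect_false(any(asg$low_loading))
  during_factors <- unique(asg$factor[spec_ret$phase == "during"])
  after_factors <- unique(asg$factor[spec_ret$phase == "after"])
  expect_length(during_factors, 1L)
  expect_length(after_factors, 1L)
  expect_true(during_factors != after_factors)

  # the two dropped items fall below the loading threshold
  Lall <- varimax_rotate(efa_principal_axis(rec, 2))
  asg_all <- assign_items(Lall, threshold = 0.40)
  expect_true(all(asg_all$low_loading[!specs$included]))
})

test_that("zero generating paths imply null pipeline associations", {
  co <- simulate_cohort(1200, null_config(cfg), seed = 92)
  pe <- pipeline_estimates(co)
  mc3 <- 3 / sqrt(attr(pe, "n"))
  for (nm in c("beta_total_during", "beta_sex_during", "beta_iq_during",
               "beta_total_internalizing")) {
    expect_lt(abs(pe[[nm]]), mc3 + 0.02)
  }
})

test_that("a noiseless coder panel yields identical scores and ICC 1", {
  exact <- with_config(cfg, coder.severity_sd = 0, trace.noise_sd = 0,
                       coder.gain_sd = list(sadness = 0, anger = 0,
                                            contempt = 0))
  panel <- simulate_coder_panel(12, exact, seed = 93)
  expect_equal(panel$anger[, 1], panel$anger[, 4], tolerance = 1e-12)
  expect_equal(icc_single_absolute(panel$anger)$icc, 1, tolerance = 1e-9)
  p2 <- simulate_coder_panel(12, exact, seed = 93)
  expect_identical(panel, p2)
})

test_that("the calibration update has the analytic linear fixed point", {
  # a system whose pipeline attenuates the knob by a factor 0.8 must
  # converge to knob = target / 0.8
  target <- 0.09
  knob <- 0.02
  for (i in 1:40) {
    est <- 0.8 * knob
    knob <- cyberscore:::update_knob(knob, est, target, "linear", 0.5)
  }
  expect_equal(knob, target / 0.8, tolerance = 1e-6)
  # already-on-target systems stay put
  expect_equal(cyberscore:::update_knob(0.3, 0.09, 0.09, "linear", 0.5), 0.3)
})

test_that("the group time course dips after the two exclusion-phase receives", {
  sch <- build_schedule(11.6, 52.4)  # uniform spacing: receive times known
  set.seed(94)
  traces <- lapply(1:150, function(i) simulate_trace(rnorm(1), sch, cfg))
  tc <- group_timecourse(traces, sch, window_s = 2, step_s = 1)
  rt <- participant_receive_times(sch)
  for (t_r in rt[rt >= sch$inclusion_end_s]) {
    before <- mean(tc$total[tc$bin_start_s >= t_r - 4 & tc$bin_start_s < t_r - 1],
                   na.rm = TRUE)
    dip <- min(tc$total[tc$bin_start_s >= t_r & tc$bin_start_s <= t_r + 3],
               na.rm = TRUE)
    after <- mean(tc$total[tc$bin_start_s >= t_r + 6 & tc$bin_start_s <= t_r + 9],
                  na.rm = TRUE)
    expect_lt(dip, before)
    expect_lt(dip, after)
  }
  # and the overall exclusion-phase level rises over inclusion
  inc_level <- mean(tc$total[tc$bin_start_s < 10], na.rm = TRUE)
  late_exc <- mean(tc$total[tc$bin_start_s > 40], na.rm = TRUE)
  expect_gt(late_exc, inc_level)
})
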