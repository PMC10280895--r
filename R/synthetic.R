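#' Default synthetic-cohort configuration
#'
#' Reads the calibrated generator configuration shipped with the
#' package (`inst/extdata/default_config.yaml`).  Marginals (covariate
#' distributions, period timing, expresser fractions, contempt
#' prevalence) are set to the published cohort description; the latent
#' path coefficients are calibrated so that the full pipeline -- trace
#' generation, QC, AUC scoring, residualization, log scaling,
#' questionnaire scoring and standardized regression -- reproduces the
#' published standardized estimates (see the calibration audit table in
#' `inst/extdata/calibration_audit.csv`).
#'
#' @return Nested list of generator parameters.
#' @export
default_config <- function() {
  path <- system.file("extdata", "default_config.yaml",
                      package = "cyberscore", mustWork = TRUE)
  validate_config(yaml::read_yaml(path))
}

# ---- internal: covariance structure of the centered covariate design ----
# order: sex_girl, z(age), maternal_university, z(iq), origin_western,
# origin_nonwestern
covariate_cov <- function(config) {
  cv <- config$covariates
  pg <- cv$girl_fraction; pu <- cv$university_fraction
  pw <- cv$origin_fractions$nondutch_western
  pn <- cv$origin_fractions$nondutch_nonwestern
  S <- diag(c(pg * (1 - pg), 1, pu * (1 - pu), 1, pw * (1 - pw), pn * (1 - pn)))
  S[5, 6] <- S[6, 5] <- -pw * pn
  S
}

path_vec <- function(paths, suffix) {
  unname(vapply(c("sex", "age", "edu", "iq", "western", "nonwestern"),
                function(p) as.numeric(paths[[paste0(p, "_to_", suffix)]]),
                numeric(1)))
}

# derived variance components of the latent system; errors if any
# residual variance would be negative
latent_variances <- function(config) {
  S <- covariate_cov(config)
  a <- path_vec(config$paths, "E")
  b <- path_vec(config$paths, "during")
  pE <- config$paths$E_to_during
  var_E_sys <- drop(t(a) %*% S %*% a)
  if (var_E_sys >= 1) stop("covariate paths to expressivity imply variance > 1")
  sig2_E <- 1 - var_E_sys
  cvec <- b + pE * a
  var_R_sys <- drop(t(cvec) %*% S %*% cvec) + pE^2 * sig2_E
  if (var_R_sys >= 1) stop("paths into the during-report factor imply variance > 1")
  sig2_R <- 1 - var_R_sys
  cov_RE <- drop(t(cvec) %*% S %*% a) + pE * sig2_E
  qR_i <- config$paths$during_to_internalizing
  qE_i <- config$paths$E_to_internalizing
  qR_x <- config$paths$during_to_externalizing
  qE_x <- config$paths$E_to_externalizing
  sig2_int <- 1 - (qR_i^2 + qE_i^2 + 2 * qR_i * qE_i * cov_RE)
  sig2_ext <- 1 - (qR_x^2 + qE_x^2 + 2 * qR_x * qE_x * cov_RE)
  if (sig2_int <= 0 || sig2_ext <= 0) {
    stop("outcome paths imply negative residual variance")
  }
  rho <- config$paths$during_after_cor
  if (abs(rho) >= 1) stop("during-after factor correlation must lie in (-1, 1)")
  list(sig2_E = sig2_E, sig2_R = sig2_R, cov_RE = cov_RE,
       sig2_int = sig2_int, sig2_ext = sig2_ext)
}

validate_config <- function(config) {
  cv <- config$covariates
  fr <- unlist(cv$origin_fractions)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-6) {
    stop("origin fractions must be non-negative and sum to 1")
  }
  for (f in c(cv$girl_fraction, cv$university_fraction)) {
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  }
  if (cv$age_sd <= 0 || cv$iq_sd <= 0) stop("covariate SDs must be positive")
  tr <- config$trace
  if (tr$dip_depth < 0 || tr$dip_depth > 1) stop("dip_depth must lie in [0, 1]")
  w2 <- tr$expressivity_weight^2
  rho_u <- (tr$sad_anger_cor - w2) / (1 - w2)
  if (abs(rho_u) > 0.999) {
    stop("sad_anger_cor is unreachable given expressivity_weight")
  }
  latent_variances(config)  # errors on impossible path systems
  config
}

# centered standardized design matrix (n x 6) from a covariate frame
centered_design <- function(covariates, config) {
  cv <- config$covariates
  d <- cbind(
    covariates$sex_girl - cv$girl_fraction,
    (covariates$age_years - cv$age_mean) / cv$age_sd,
    covariates$maternal_university - cv$university_fraction,
    (covariates$nonverbal_iq - cv$iq_mean) / cv$iq_sd,
    (covariates$origin == "nondutch_western") - cv$origin_fractions$nondutch_western,
    (covariates$origin == "nondutch_nonwestern") - cv$origin_fractions$nondutch_nonwestern
  )
  colnames(d) <- c("sex", "age", "edu", "iq", "western", "nonwestern")
  d
}

#' Sample child covariates
#'
#' Independent draws matching the configured marginals: sex,
#' maternal university education and parental national origin as
#' categorical draws, age at assessment and non-verbal IQ as normals.
#'
#' @param n Number of children.
#' @param config Generator configuration (see [default_config()]).
#' @param seed Optional integer seed.
#' @return Data frame with `child_id`, `sex_girl`, `age_years`,
#'   `maternal_university`, `nonverbal_iq`, `origin`.
#' @export
sample_covariates <- function(n, config = default_config(), seed = NULL) {
  if (n < 1L) stop("`n` must be at least 1")
  if (!is.null(seed)) {
    old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
  }
  cv <- config$covariates
  fr <- cv$origin_fractions
  data.frame(
    child_id = sprintf("c%05d", seq_len(n)),
    sex_girl = stats::rbinom(n, 1L, cv$girl_fraction),
    age_years = stats::rnorm(n, cv$age_mean, cv$age_sd),
    maternal_university = stats::rbinom(n, 1L, cv$university_fraction),
    nonverbal_iq = stats::rnorm(n, cv$iq_mean, cv$iq_sd),
    origin = sample(c("dutch", "nondutch_western", "nondutch_nonwestern"), n,
                    replace = TRUE,
                    prob = c(fr$dutch, fr$nondutch_western, fr$nondutch_nonwestern)),
    stringsAsFactors = FALSE
  )
}

#' Sample the latent ground truth
#'
#' Three unit-variance latents per child: expressivity `E` (drives the
#' facial-expression traces), the during-game report factor `R` and the
#' after-game report factor `A`.  `E` and `R` receive the configured
#' standardized covariate paths; `R` additionally loads on `E`; `A`
#' correlates with `R` at the configured level.  Residual noise is
#' scaled analytically so each latent has exactly unit population
#' variance, which is an error if the paths make that impossible.
#'
#' @param covariates Data frame from [sample_covariates()].
#' @param config Generator configuration.
#' @param seed Optional integer seed.
#' @return Data frame with columns `E`, `R`, `A`.
#' @export
sample_latents <- function(covariates, config = default_config(), seed = NULL) {
  if (!is.null(seed)) {
    old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
  }
  n <- nrow(covariates)
  vv <- latent_variances(config)
  X <- centered_design(covariates, config)
  a <- path_vec(config$paths, "E")
  b <- path_vec(config$paths, "during")
  pE <- config$paths$E_to_during
  eE <- stats::rnorm(n)
  E <- drop(X %*% a) + sqrt(vv$sig2_E) * eE
  R <- drop(X %*% b) + pE * E + sqrt(vv$sig2_R) * stats::rnorm(n)
  rho <- config$paths$during_after_cor
  A <- rho * R + sqrt(1 - rho^2) * stats::rnorm(n)
  data.frame(E = E, R = R, A = A)
}

# ---- trace generation ----------------------------------------------------

# Child-level expression parameters derived from expressivity E.
# Channels share E through `expressivity_weight`; sadness and anger are
# additionally coupled so their latent correlation is `sad_anger_cor`.
child_expression_params <- function(E, config) {
  tr <- config$trace
  w <- tr$expressivity_weight
  w2 <- w^2
  rho_u <- (tr$sad_anger_cor - w2) / (1 - w2)
  u_s <- stats::rnorm(1)
  u_a <- rho_u * u_s + sqrt(1 - rho_u^2) * stats::rnorm(1)
  u_c <- stats::rnorm(1)
  z <- c(sadness = w * E + sqrt(1 - w2) * u_s,
         anger = w * E + sqrt(1 - w2) * u_a,
         contempt = u_c)
  expr <- c(
    sadness = stats::rbinom(1, 1, tr$expresser_fraction$sadness),
    anger = stats::rbinom(1, 1, tr$expresser_fraction$anger),
    contempt = stats::rbinom(1, 1, tr$expresser_fraction$contempt)
  )
  amp_scale <- c(tr$amplitude_scale$sadness, tr$amplitude_scale$anger,
                 tr$amplitude_scale$contempt)
  amp <- expr * amp_scale * exp(tr$amplitude_log_sd * z)
  # Baseline (inclusion-phase) expression is only loosely coupled to the
  # exclusion response: it has its own presence indicator and mostly
  # independent magnitude, so the inclusion/exclusion AUC correlation
  # stays modest, as observed.
  base_expr <- stats::rbinom(3, 1, tr$baseline_expresser_fraction)
  base <- expr * base_expr * tr$baseline_scale * amp_scale *
    exp(tr$baseline_amp_weight * z +
          tr$baseline_log_sd * stats::rnorm(3))
  list(amplitude = amp, baseline = base)
}

# Latent (noise-free, coder-free) intensity curves on the sampling grid:
# flat baseline during inclusion, exponential approach from the baseline
# to the child's asymptote during exclusion, multiplicative recovery
# dips after each toss the participant receives.
latent_curves <- function(params, schedule, config) {
  fs <- config$sampling_rate_hz
  total <- schedule$total_duration_s
  t <- seq(0, total - 1e-9, by = 1 / fs)
  t_e <- schedule$inclusion_end_s
  tr <- config$trace
  rise <- ifelse(t < t_e, 0, 1 - exp(-(t - t_e) / tr$rise_tau_s))
  dipf <- rep(1, length(t))
  for (t_r in participant_receive_times(schedule)) {
    after <- t >= t_r
    dipf[after] <- dipf[after] *
      (1 - tr$dip_depth * exp(-(t[after] - t_r) / tr$dip_tau_s))
  }
  curves <- vapply(1:3, function(j) {
    b <- params$baseline[j]; a <- params$amplitude[j]
    (b + pmax(a - b, 0) * rise) * dipf
  }, numeric(length(t)))
  colnames(curves) <- c("sadness", "anger", "contempt")
  list(time_s = t, curves = curves)
}

# Two-state visibility process simulated as alternating geometric
# episode lengths (visible hazard `p_drop_per_s`, invisible episodes
# with mean `mean_invisible_s`).
simulate_visibility <- function(n_samples, config) {
  vis <- config$visibility
  fs <- config$sampling_rate_hz
  p_vi <- min(vis$p_drop_per_s / fs, 0.999)     # visible -> invisible
  p_iv <- min(1 / (vis$mean_invisible_s * fs), 0.999)  # invisible -> visible
  frac_invis <- (vis$p_drop_per_s * vis$mean_invisible_s) /
    (1 + vis$p_drop_per_s * vis$mean_invisible_s)
  state <- stats::runif(1) > frac_invis  # TRUE = visible
  out <- logical(0)
  while (length(out) < n_samples) {
    len <- 1L + stats::rgeom(1, if (state) p_vi else p_iv)
    out <- c(out, rep(state, len))
    state <- !state
  }
  out[seq_len(n_samples)]
}

# One coder's observation of latent curves: a lognormal gain per
# channel (coder severity + idiosyncratic disagreement), smooth AR(1)
# tracking noise while the child is expressing, clipped to the 0-5
# joystick range.  Coders watching a video that shows nothing record
# nothing, so channels with zero latent stay exactly zero.
observe_curves <- function(lat, visible, config, coder_severity = 0,
                           child_id = "c00001", coder_id = "coder1") {
  tr <- config$trace
  n <- length(lat$time_s)
  obs <- lat$curves
  gain_sd <- c(config$coder$gain_sd$sadness, config$coder$gain_sd$anger,
               config$coder$gain_sd$contempt)
  for (j in 1:3) {
    g <- exp(coder_severity + gain_sd[j] * stats::rnorm(1))
    x <- lat$curves[, j]
    if (any(x > 0)) {
      ar <- tr$noise_ar
      noise <- stats::filter(stats::rnorm(n, 0, tr$noise_sd * sqrt(1 - ar^2)),
                             ar, method = "recursive")
      obs[, j] <- pmin(pmax(g * x + as.numeric(noise) * (x > 0.02), 0), 5)
    }
  }
  emotion_trace(child_id, coder_id, lat$time_s, obs[, "sadness"],
                obs[, "anger"], obs[, "contempt"], visible)
}

#' Simulate one child's coding trace
#'
#' Generates the latent expression dynamics implied by the child's
#' expressivity `E` (near-zero inclusion baseline, exclusion-phase rise
#' toward a child-specific asymptote, recovery dips after each ball
#' receive), overlays a coder observation model and a visibility
#' process, and returns the result as an [emotion_trace()].
#'
#' @param E Latent expressivity (standard-normal scale).
#' @param schedule A `game_schedule`.
#' @param config Generator configuration.
#' @param seed Optional integer seed.
#' @param coder_severity Log-gain offset of the observing coder.
#' @param child_id,coder_id Identifiers for the trace.
#' @return An `emotion_trace`.
#' @export
simulate_trace <- function(E, schedule, config = default_config(),
                           seed = NULL, coder_severity = 0,
                           child_id = "c00001", coder_id = "coder1") {
  if (!is.null(seed)) {
    old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
  }
  params <- child_expression_params(E, config)
  lat <- latent_curves(params, schedule, config)
  visible <- simulate_visibility(length(lat$time_s), config)
  observe_curves(lat, visible, config, coder_severity, child_id, coder_id)
}

# truncated-normal period durations
rtruncnorm1 <- function(mean, sd, lower, upper) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
}

sample_schedule <- function(config) {
  tm <- config$timing
  build_schedule(
    rtruncnorm1(tm$inclusion_mean_s, tm$inclusion_sd_s,
                tm$inclusion_min_s, tm$inclusion_max_s),
    rtruncnorm1(tm$exclusion_mean_s, tm$exclusion_sd_s,
                tm$exclusion_min_s, tm$exclusion_max_s),
    jitter_fraction = tm$toss_jitter
  )
}

#' Simulate the post-game questionnaire
#'
#' Graded-response item model: each retained item loads on its phase
#' factor (`R` for the six during-game items, `A` for the seven
#' after-game items) with unique noise scaled to unit variance; the two
#' dropped items load weakly on a blend of both factors.  Latent item
#' values are shifted by a phase-specific offset (chosen so the recoded
#' scale means sit at the published marginals) and cut at fixed
#' thresholds into Likert categories 1-5 on the negative-feelings
#' metric; positively phrased items are stored flipped (`6 - value`) so
#' that [reverse_code()] recovers the negative-metric value.
#'
#' @param R,A Latent factor scores per child.
#' @param config Generator configuration.
#' @param seed Optional integer seed.
#' @return Integer matrix children x 15 of raw Likert responses,
#'   columns ordered as [item_specs()].
#' @export
simulate_questionnaire <- function(R, A, config = default_config(),
                                   seed = NULL) {
  if (!is.null(seed)) {
    old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
  }
  q <- config$questionnaire
  specs <- item_specs()
  n <- length(R)
  cuts <- as.numeric(q$thresholds)
  out <- matrix(NA_integer_, n, nrow(specs))
  colnames(out) <- specs$item_id
  drop_factor <- (R + A) / sqrt(2 + 2 * config$paths$during_after_cor)
  for (i in seq_len(nrow(specs))) {
    if (!specs$included[i]) {
      lam <- q$dropped_loading
      f <- drop_factor
      off <- q$after_offset
    } else if (specs$phase[i] == "during") {
      lam <- q$during_loading
      f <- R
      off <- q$during_offset
    } else {
      lam <- q$after_loading
      f <- A
      off <- q$after_offset
    }
    ystar <- lam * f + sqrt(1 - lam^2) * stats::rnorm(n) + off
    cat_neg <- findInterval(ystar, cuts) + 1L
    out[, i] <- if (specs$polarity[i] == "positive") 6L - cat_neg else cat_neg
  }
  out
}

#' Simulate CBCL broadband item responses
#'
#' A latent problem score per scale (standardized paths from the
#' during-report factor `R` and expressivity `E`, residual scaled to
#' unit variance) is expressed through 32 (internalizing) or 35
#' (externalizing) congeneric 3-level items cut at thresholds that give
#' the sums the right-skewed, floor-heavy distribution typical of
#' problem-behavior checklists.
#'
#' @param R,E Latent scores per child.
#' @param covariates Accepted for interface symmetry; no direct
#'   covariate paths into the outcomes are configured.
#' @param config Generator configuration.
#' @param seed Optional integer seed.
#' @return List with item matrices `internalizing_items`,
#'   `externalizing_items` and the weighted sums `internalizing`,
#'   `externalizing` (via [cbcl_sum()]).
#' @export
simulate_outcomes <- function(R, E, covariates = NULL,
                              config = default_config(), seed = NULL) {
  if (!is.null(seed)) {
    old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
  }
  vv <- latent_variances(config)
  n <- length(R)
  cb <- config$cbcl
  one_scale <- function(qR, qE, sig2, k, cuts) {
    lat <- qR * R + qE * E + sqrt(sig2) * stats::rnorm(n)
    gam <- cb$item_loading
    items <- matrix(stats::rnorm(n * k, 0, sqrt(1 - gam^2)), n, k) + gam * lat
    m <- matrix(findInterval(items, as.numeric(cuts)), n, k)
    list(items = m, sum = apply(m, 1L, cbcl_sum))
  }
  int <- one_scale(config$paths$during_to_internalizing,
                   config$paths$E_to_internalizing, vv$sig2_int,
                   cb$n_internalizing, cb$thresholds_internalizing)
  ext <- one_scale(config$paths$during_to_externalizing,
                   config$paths$E_to_externalizing, vv$sig2_ext,
                   cb$n_externalizing, cb$thresholds_externalizing)
  list(internalizing_items = int$items, externalizing_items = ext$items,
       internalizing = int$sum, externalizing = ext$sum)
}

#' Simulate a complete synthetic cohort
#'
#' Draws covariates and latents, simulates one primary coding trace per
#' child on a child-specific toss schedule, scores it (QC + period
#' AUCs), and generates questionnaire and CBCL outcome data.  Traces are
#' scored on the fly and discarded unless `keep_traces = TRUE`.
#'
#' @param n Number of children (default from config).
#' @param config Generator configuration.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param keep_traces Retain the generated traces and schedules
#'   (memory-heavy for large n).
#' @return List of class `synthetic_cohort` with elements `covariates`,
#'   `latents`, `scores` (raw [score_cohort()]-format data frame),
#'   `responses`, `cbcl`, `coder_severity`, and optionally `traces`,
#'   `schedules`.
#' @export
simulate_cohort <- function(n = NULL, config = default_config(), seed = NULL,
                            keep_traces = FALSE) {
  if (!is.null(seed)) {
    old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
  }
  if (is.null(n)) n <- config$n_children
  covariates <- sample_covariates(n, config)
  latents <- sample_latents(covariates, config)
  severities <- stats::rnorm(config$coder$n_coders, 0, config$coder$severity_sd)
  coder_of <- sample.int(config$coder$n_coders, n, replace = TRUE)

  rows <- vector("list", n)
  traces <- if (keep_traces) vector("list", n) else NULL
  schedules <- if (keep_traces) vector("list", n) else NULL
  for (i in seq_len(n)) {
    sch <- sample_schedule(config)
    tr <- simulate_trace(latents$E[i], sch, config,
                         coder_severity = severities[coder_of[i]],
                         child_id = covariates$child_id[i],
                         coder_id = paste0("coder", coder_of[i]))
    if (keep_traces) {
      traces[[i]] <- tr
      schedules[[i]] <- sch
    }
    qc <- qc_filter(tr, sch)
    row <- list(child_id = tr$child_id, eligible = qc$eligible,
                reasons = paste(qc$reasons, collapse = ","))
    if (qc$eligible) {
      p <- score_periods(tr, sch)
      row <- c(row, list(
        inc_sadness = p$inclusion$sadness_auc, inc_anger = p$inclusion$anger_auc,
        inc_contempt = p$inclusion$contempt_auc, inc_total = p$inclusion$total_auc,
        exc_sadness = p$exclusion$sadness_auc, exc_anger = p$exclusion$anger_auc,
        exc_contempt = p$exclusion$contempt_auc, exc_total = p$exclusion$total_auc,
        visible_s_inclusion = qc$visibility$visible_s_inclusion,
        visible_s_exclusion = qc$visibility$visible_s_exclusion))
    } else {
      row <- c(row, stats::setNames(
        as.list(rep(NA_real_, 10L)),
        c("inc_sadness", "inc_anger", "inc_contempt", "inc_total",
          "exc_sadness", "exc_anger", "exc_contempt", "exc_total",
          "visible_s_inclusion", "visible_s_exclusion")))
    }
    rows[[i]] <- row
  }
  scores <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  responses <- simulate_questionnaire(latents$R, latents$A, config)
  outcomes <- simulate_outcomes(latents$R, latents$E, covariates, config)

  structure(
    list(covariates = covariates, latents = latents, scores = scores,
         responses = responses,
         cbcl = data.frame(child_id = covariates$child_id,
                           internalizing = outcomes$internalizing,
                           externalizing = outcomes$externalizing,
                           stringsAsFactors = FALSE),
         coder_severity = severities,
         traces = traces, schedules = schedules, config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d children, %d eligible (%.1f%%)\n",
              nrow(x$scores), sum(x$scores$eligible),
              100 * mean(x$scores$eligible)))
  invisible(x)
}

#' Simulate a multi-coder reliability panel
#'
#' A subset of videos scored by all coders: each child's latent
#' expression curves and visibility are generated once (the video), and
#' every coder observes them with their own severity and idiosyncratic
#' gain/noise.  Exclusion-phase AUCs per coder form the rating panels.
#'
#' @param subset_n Number of children in the panel (default 129).
#' @param config Generator configuration.
#' @param seed Optional integer seed.
#' @param n_coders Number of coders (default from config).
#' @return List of subjects x coders AUC matrices, one per channel plus
#'   `total`.
#' @export
simulate_coder_panel <- function(subset_n = 129, config = default_config(),
                                 seed = NULL, n_coders = config$coder$n_coders) {
  if (!is.null(seed)) {
    old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
  }
  severities <- stats::rnorm(n_coders, 0, config$coder$severity_sd)
  panels <- lapply(1:4, function(j) matrix(NA_real_, subset_n, n_coders))
  names(panels) <- c("sadness", "anger", "contempt", "total")
  for (i in seq_len(subset_n)) {
    E <- stats::rnorm(1)
    sch <- sample_schedule(config)
    params <- child_expression_params(E, config)
    lat <- latent_curves(params, sch, config)
    visible <- simulate_visibility(length(lat$time_s), config)
    if (!any(visible)) visible[] <- TRUE
    w <- period_window(sch, "exclusion")
    for (j in seq_len(n_coders)) {
      tr <- observe_curves(lat, visible, config, severities[j],
                           child_id = sprintf("p%04d", i),
                           coder_id = paste0("coder", j))
      panels$sadness[i, j] <- channel_auc(tr, "sadness", w)
      panels$anger[i, j] <- channel_auc(tr, "anger", w)
      panels$contempt[i, j] <- channel_auc(tr, "contempt", w)
      panels$total[i, j] <- panels$sadness[i, j] + panels$anger[i, j] +
        panels$contempt[i, j]
    }
  }
  panels
}
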