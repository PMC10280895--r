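#' Assemble the per-child analysis table of a cohort
#'
#' Restricts to QC-eligible children and joins the processed emotion
#' scores ([process_scores()]), the questionnaire subscale scores
#' ([scale_scores()]), the CBCL outcome sums and the covariates into
#' one analysis data frame.
#'
#' @param cohort A `synthetic_cohort` (or any list with the same
#'   `scores`, `responses`, `cbcl`, `covariates` elements).
#' @return Data frame, one row per eligible child.
#' @export
analysis_table <- function(cohort) {
  sc <- process_scores(cohort$scores)
  idx <- match(sc$child_id, cohort$covariates$child_id)
  scales <- scale_scores(cohort$responses[idx, , drop = FALSE])
  cbind(sc,
        cohort$covariates[idx, c("sex_girl", "age_years",
                                 "maternal_university", "nonverbal_iq",
                                 "origin")],
        scales,
        cohort$cbcl[idx, c("internalizing", "externalizing")])
}

#' Headline pipeline estimates for one cohort
#'
#' Runs the full analysis on one cohort and returns the quantities the
#' study design targets: the covariate-adjusted standardized
#' coefficient of observed total negative emotion for the during-game
#' scale and for internalizing problems, the mutually adjusted child
#' characteristic coefficients for the during-game scale, the
#' sadness-anger and during-after correlations, and Cronbach's alpha of
#' the during-game items.
#'
#' @param cohort A `synthetic_cohort`.
#' @return Named numeric vector, plus attribute `n` (analysis sample
#'   size).
#' @export
pipeline_estimates <- function(cohort) {
  d <- analysis_table(cohort)
  cov_d <- d[c("sex_girl", "age_years", "maternal_university",
               "nonverbal_iq", "origin")]
  mut <- mutual_adjust_model(d$negative_during, cov_d)
  idx <- match(d$child_id, cohort$covariates$child_id)
  specs <- item_specs()
  rec <- recode_items(cohort$responses[idx, , drop = FALSE], specs)
  during_items <- rec[, specs$scale == "during_scale", drop = FALSE]
  est <- c(
    beta_total_during = standardized_ols(d$negative_during, d$log_total,
                                         cov_d)$beta,
    beta_sex_during = mut$beta[mut$predictor == "sex_girl"],
    beta_nonwestern_during = mut$beta[mut$predictor == "origin_nonwestern"],
    beta_iq_during = mut$beta[mut$predictor == "nonverbal_iq"],
    beta_total_internalizing = standardized_ols(d$internalizing, d$log_total,
                                                cov_d)$beta,
    r_sadness_anger = pearson_r(d$log_sadness, d$log_anger)$r,
    r_during_after = pearson_r(d$negative_during, d$negative_after)$r,
    alpha_during = cronbach_alpha(during_items)
  )
  attr(est, "n") <- nrow(d)
  est
}

#' Tidy association tables for a cohort
#'
#' Reproduces the structure of the study's inferential output: the
#' covariate-adjusted regressions of each questionnaire scale on each
#' observed emotion score, the mutually adjusted child-characteristics
#' models for observed total negative emotion and the during-game
#' scale, and the behavior-problem models, in one tidy data frame.
#'
#' @param cohort A `synthetic_cohort`.
#' @param model `"ols"` or `"robust"`.
#' @return Data frame with columns `outcome`, `predictor`, `beta`,
#'   `ci_low`, `ci_high`, `p`, `n`, `model`.
#' @export
association_tables <- function(cohort, model = "ols") {
  d <- analysis_table(cohort)
  cov_d <- d[c("sex_girl", "age_years", "maternal_university",
               "nonverbal_iq", "origin")]
  out <- list()
  exposures <- c(total = "log_total", sadness = "log_sadness",
                 anger = "log_anger", contempt = "contempt_binary")
  for (sc in c("negative_during", "negative_after")) {
    for (ex in names(exposures)) {
      r <- standardized_ols(d[[sc]], d[[exposures[[ex]]]], cov_d, model = model)
      r$outcome <- sc
      r$predictor <- ex
      out[[length(out) + 1L]] <- r
    }
  }
  for (oc in c("log_total", "negative_during")) {
    r <- mutual_adjust_model(d[[oc]], cov_d, model = model)
    r$outcome <- oc
    out[[length(out) + 1L]] <- r
  }
  for (oc in c("internalizing", "externalizing")) {
    for (ex in c("log_total", "negative_during")) {
      r <- standardized_ols(d[[oc]], d[[ex]], cov_d, model = model)
      r$outcome <- oc
      r$predictor <- ex
      out[[length(out) + 1L]] <- r
    }
  }
  res <- do.call(rbind, out)
  res[c("outcome", "predictor", "beta", "ci_low", "ci_high", "p", "n", "model")]
}

# knob behind each calibratable estimand and its update law
calibration_knobs <- function() {
  list(
    beta_total_during = list(path = c("paths", "E_to_during"), type = "linear"),
    beta_sex_during = list(path = c("paths", "sex_to_during"), type = "linear"),
    beta_nonwestern_during = list(path = c("paths", "nonwestern_to_during"),
                                  type = "linear"),
    beta_iq_during = list(path = c("paths", "iq_to_during"), type = "linear"),
    beta_total_internalizing = list(path = c("paths", "E_to_internalizing"),
                                    type = "linear"),
    r_sadness_anger = list(path = c("trace", "sad_anger_cor"), type = "linear"),
    r_during_after = list(path = c("paths", "during_after_cor"),
                          type = "linear"),
    alpha_during = list(path = c("questionnaire", "during_loading"),
                        type = "alpha"),
    icc_anger = list(path = c("coder", "gain_sd", "anger"), type = "icc")
  )
}

get_knob <- function(config, path) {
  for (p in path) config <- config[[p]]
  config
}

set_knob <- function(config, path, value) {
  expr <- paste0("config", paste0("[['", path, "']]", collapse = ""))
  eval(parse(text = paste0(expr, " <- value")))
  config
}

update_knob <- function(old, est, target, type, damping, k_items = 6) {
  switch(type,
    linear = {
      if (sign(est) == sign(target) && abs(est) > 0.005) {
        old * abs(target / est)^damping
      } else {
        old + damping * (target - est)
      }
    },
    alpha = {
      # item loading scales with sqrt of the mean inter-item correlation
      rbar <- function(a) a / (k_items - (k_items - 1) * a)
      re <- rbar(min(max(est, 0.05), 0.99))
      rt <- rbar(min(max(target, 0.05), 0.99))
      min(max(old * (rt / re)^(damping / 2), 0.05), 0.95)
    },
    icc = {
      # noise variance scales with 1/ICC - 1
      v <- function(icc) 1 / min(max(icc, 0.01), 0.99) - 1
      min(max(old * (v(target) / v(est))^(damping / 2), 0.01), 2)
    }
  )
}

#' Calibrate the generator to target pipeline estimates
#'
#' The generator's path coefficients are *generating* values; Likert
#' discretization, intensity clipping, coder noise, AUC nonlinearity
#' and scale unreliability attenuate what the analysis pipeline
#' recovers.  `calibrate()` absorbs that attenuation: it repeatedly
#' simulates pilot cohorts, runs the full pipeline, compares each
#' estimate with its target, and nudges the knob behind it (damped
#' multiplicative update for paths and correlations, a monotone
#' transform-space update for the alpha and ICC knobs) until every
#' estimate is within `tol` of its target or `max_rounds` is reached.
#'
#' @param config Starting configuration.
#' @param target_table Named numeric vector of target estimates; names
#'   must be a subset of the estimands of [pipeline_estimates()] plus
#'   `icc_anger`.
#' @param pilot_n Cohort size per pilot replicate.
#' @param n_replicates Pilot cohorts per round (estimates are averaged).
#' @param seed Integer seed.
#' @param damping Step damping in (0, 1]; default 0.5.
#' @param max_rounds Round cap; default 25.
#' @param tol Convergence tolerance per estimand (default 0.01 for
#'   coefficients/correlations, 0.03 for alpha and ICC).
#' @param verbose Print round-by-round progress.
#' @return List with the adjusted `config`, an `audit` data frame
#'   (round, estimand, estimate, target, knob value) and `converged`.
#' @export
calibrate <- function(config, target_table, pilot_n = 1000,
                      n_replicates = 2, seed = 1, damping = 0.5,
                      max_rounds = 25, tol = NULL, verbose = FALSE) {
  knobs <- calibration_knobs()
  unknown <- setdiff(names(target_table), names(knobs))
  if (length(unknown)) {
    stop(sprintf("no calibration knob for: %s", paste(unknown, collapse = ", ")))
  }
  if (is.null(tol)) {
    tol <- ifelse(names(target_table) %in% c("alpha_during", "icc_anger"),
                  0.03, 0.01)
    names(tol) <- names(target_table)
  }
  audit <- list()
  old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
  for (round in seq_len(max_rounds)) {
    ests <- matrix(NA_real_, n_replicates, length(target_table),
                   dimnames = list(NULL, names(target_table)))
    for (r in seq_len(n_replicates)) {
      rep_seed <- sample.int(.Machine$integer.max, 1)
      if (any(names(target_table) != "icc_anger")) {
        co <- simulate_cohort(pilot_n, config, seed = rep_seed)
        pe <- pipeline_estimates(co)
        common <- intersect(names(target_table), names(pe))
        ests[r, common] <- pe[common]
      }
      if ("icc_anger" %in% names(target_table)) {
        panel <- simulate_coder_panel(config$coder$reliability_subset, config,
                                      seed = rep_seed + 1)
        ests[r, "icc_anger"] <- icc_single_absolute(panel$anger)$icc
      }
    }
    est <- colMeans(ests)
    dev <- abs(est - target_table)
    audit[[round]] <- data.frame(round = round,
                                 estimand = names(target_table),
                                 estimate = unname(est),
                                 target = unname(target_table),
                                 knob = vapply(names(target_table), function(nm) {
                                   get_knob(config, knobs[[nm]]$path)
                                 }, numeric(1)),
                                 stringsAsFactors = FALSE)
    if (verbose) {
      message(sprintf("round %d: max deviation %.4f (%s)", round, max(dev),
                      names(target_table)[which.max(dev)]))
    }
    if (all(dev <= tol[names(target_table)])) {
      return(list(config = config, audit = do.call(rbind, audit),
                  converged = TRUE, rounds = round))
    }
    for (nm in names(target_table)) {
      kn <- knobs[[nm]]
      old_val <- get_knob(config, kn$path)
      new_val <- update_knob(old_val, est[[nm]], target_table[[nm]], kn$type,
                             damping)
      cand <- set_knob(config, kn$path, new_val)
      config <- tryCatch({ validate_config(cand) },
                         error = function(e) config)  # reject infeasible steps
    }
  }
  warning("calibration did not converge; returning last config")
  list(config = config, audit = do.call(rbind, audit), converged = FALSE,
       rounds = max_rounds)
}

#' Replicate the full pipeline over seeded cohorts
#'
#' Simulates `n_replicates` independent cohorts (and coder-reliability
#' panels), runs the complete scoring-and-analysis pipeline on each,
#' and returns the per-replicate estimates.  Stochastic study-level
#' quantities are reported as means over such replicates.
#'
#' @param n_replicates Number of cohorts (default 20).
#' @param seed Master seed; per-replicate seeds are drawn from it.
#' @param n Children per cohort (default: the configured cohort size).
#' @param config Generator configuration.
#' @param verbose Print one progress line per replicate.
#' @return Matrix (replicates x estimands) with the
#'   [pipeline_estimates()] columns plus `icc_anger`; attribute
#'   `n_analysis` holds the mean analysis sample size.
#' @export
replicate_estimates <- function(n_replicates = 20, seed = 1, n = NULL,
                                config = default_config(), verbose = FALSE) {
  old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_replicates)
  out <- NULL
  n_an <- numeric(n_replicates)
  for (i in seq_len(n_replicates)) {
    co <- simulate_cohort(n, config, seed = rep_seeds[i])
    pe <- pipeline_estimates(co)
    panel <- simulate_coder_panel(config$coder$reliability_subset, config,
                                  seed = rep_seeds[n_replicates + i])
    est <- c(pe, icc_anger = icc_single_absolute(panel$anger)$icc)
    if (is.null(out)) {
      out <- matrix(NA_real_, n_replicates, length(est),
                    dimnames = list(NULL, names(est)))
    }
    out[i, ] <- est
    n_an[i] <- attr(pe, "n")
    if (verbose) {
      message(sprintf("replicate %d/%d (analysis n = %d)", i, n_replicates,
                      attr(pe, "n")))
    }
  }
  attr(out, "n_analysis") <- mean(n_an)
  out
}

#' Read / write a generator configuration
#'
#' @param path YAML file.
#' @param config Configuration list.
#' @return `read_config()` returns a validated configuration;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 12L)
  invisible(path)
}
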