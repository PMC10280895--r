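#' CBCL broadband scale sum with missing-item reweighting
#'
#' The Child Behavior Checklist broadband scales are sums of 0/1/2
#' items (32 items for Internalizing, 35 for Externalizing).  Up to 25%
#' of a scale's items may be missing; the observed sum is then rescaled
#' by `k/m` (k scale items, m observed) so scores remain comparable.
#' With more than 25% missing the score is undefined (`NA`).
#'
#' @param items Numeric vector of one child's item responses on one
#'   scale, values in `{0, 1, 2}` or `NA`.
#' @param max_missing_fraction Largest tolerated missing fraction
#'   (default 0.25).
#' @return Weighted sum, or `NA` when too much is missing.
#' @export
cbcl_sum <- function(items, max_missing_fraction = 0.25) {
  obs <- !is.na(items)
  if (any(!(items[obs] %in% 0:2))) stop("CBCL items must be 0, 1 or 2")
  k <- length(items)
  m <- sum(obs)
  if (m < (1 - max_missing_fraction) * k) return(NA_real_)
  sum(items[obs]) * k / m
}

# Build the standardized design data frame used by the regression
# functions: z-scored outcome, z-scored continuous regressors, binary
# and indicator regressors left at 0/1 (so their coefficients are
# group differences in outcome-SD units).  `standardize_binary = TRUE`
# switches to z-scoring everything.
standardize_frame <- function(df, standardize_binary = FALSE) {
  is_binary <- function(x) all(x %in% c(0, 1, NA))
  out <- df
  for (nm in names(df)) {
    x <- df[[nm]]
    if (standardize_binary || !is_binary(x)) {
      s <- stats::sd(x, na.rm = TRUE)
      if (is.na(s) || s < 1e-12) stop(sprintf("zero variance in `%s`", nm))
      out[[nm]] <- (x - mean(x, na.rm = TRUE)) / s
    }
  }
  out
}

covariate_design <- function(covariates) {
  stopifnot(all(c("sex_girl", "age_years", "maternal_university",
                  "nonverbal_iq", "origin") %in% names(covariates)))
  data.frame(
    sex_girl = as.numeric(covariates$sex_girl),
    age_years = as.numeric(covariates$age_years),
    maternal_university = as.numeric(covariates$maternal_university),
    nonverbal_iq = as.numeric(covariates$nonverbal_iq),
    origin_western = as.numeric(covariates$origin == "nondutch_western"),
    origin_nonwestern = as.numeric(covariates$origin == "nondutch_nonwestern")
  )
}

extract_terms <- function(fit, terms, n) {
  cf <- summary(fit)$coefficients
  missing_terms <- setdiff(terms, rownames(cf))
  if (length(missing_terms)) {
    stop(sprintf("collinear or aliased design: no estimate for %s",
                 paste(missing_terms, collapse = ", ")))
  }
  df_resid <- fit$df.residual
  tcrit <- stats::qt(0.975, df_resid)
  do.call(rbind, lapply(terms, function(tm) {
    est <- cf[tm, "Estimate"]
    se <- cf[tm, "Std. Error"]
    tval <- est / se
    data.frame(
      predictor = tm,
      beta = est,
      ci_low = est - tcrit * se,
      ci_high = est + tcrit * se,
      p = 2 * stats::pt(-abs(tval), df_resid),
      n = n,
      stringsAsFactors = FALSE
    )
  }))
}

#' Covariate-adjusted standardized regression
#'
#' Ordinary least squares of a z-scored outcome on an exposure,
#' adjusted for the five child characteristics (sex, age, maternal
#' education, non-verbal IQ, parental national origin with Dutch as
#' reference).  Continuous variables (outcome, continuous exposures,
#' age, IQ) are z-scored; binary and indicator regressors stay 0/1, so
#' a continuous exposure's coefficient is a standardized beta and a
#' binary one is a group difference in outcome SD units.  Wald 95% CI
#' and two-sided p from the t distribution with n - p df.
#'
#' @param outcome Numeric outcome vector.
#' @param exposure Numeric exposure vector.
#' @param covariates Data frame with columns `sex_girl`, `age_years`,
#'   `maternal_university`, `nonverbal_iq`, `origin` (levels `dutch`,
#'   `nondutch_western`, `nondutch_nonwestern`), or `NULL` for an
#'   unadjusted fit (whose standardized beta equals the Pearson
#'   correlation).
#' @param standardize_binary Also z-score binary regressors (default
#'   FALSE).
#' @param model `"ols"` (default) or `"robust"` for a Huber M-estimator
#'   refit (see [huber_ols()]).
#' @return One-row data frame: `predictor`, `beta`, `ci_low`,
#'   `ci_high`, `p`, `n`.
#' @export
standardized_ols <- function(outcome, exposure, covariates = NULL,
                             standardize_binary = FALSE, model = "ols") {
  d <- data.frame(.outcome = outcome, exposure = exposure)
  if (!is.null(covariates)) d <- cbind(d, covariate_design(covariates))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 20L) stop("fewer than 20 complete rows")
  d <- standardize_frame(d, standardize_binary)
  res <- fit_standardized(d, "exposure", model)
  res
}

# shared fitting core: OLS with collinearity detection, optionally a
# Huber M-estimator refit (falling back to OLS on an exact fit, where
# the MAD scale degenerates and all Huber weights would be 1 anyway)
fit_standardized <- function(d, terms, model) {
  fit <- stats::lm(.outcome ~ ., data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("collinear design: aliased column(s) %s",
                 paste(bad, collapse = ", ")))
  }
  if (model == "robust" && stats::sd(stats::residuals(fit)) > 1e-10) {
    rfit <- MASS::rlm(.outcome ~ ., data = d, psi = MASS::psi.huber,
                      k = 1.345, scale.est = "MAD", maxit = 100)
    if (!rfit$converged) stop("Huber IRLS did not converge")
    res <- extract_terms_rlm(rfit, terms, nrow(d))
  } else {
    res <- extract_terms(fit, terms, nrow(d))
  }
  res$model <- model
  res
}

extract_terms_rlm <- function(fit, terms, n) {
  cf <- summary(fit)$coefficients
  df_resid <- n - length(stats::coef(fit))
  tcrit <- stats::qt(0.975, df_resid)
  do.call(rbind, lapply(terms, function(tm) {
    est <- cf[tm, "Value"]
    se <- cf[tm, "Std. Error"]
    data.frame(predictor = tm, beta = est,
               ci_low = est - tcrit * se, ci_high = est + tcrit * se,
               p = 2 * stats::pt(-abs(est / se), df_resid), n = n,
               stringsAsFactors = FALSE)
  }))
}

#' Mutually adjusted child-characteristics model
#'
#' All five child characteristics enter one standardized regression of
#' the outcome, so each coefficient is adjusted for all the others.
#' Origin expands to two indicator contrasts (reference: Dutch).
#'
#' @inheritParams standardized_ols
#' @return Data frame with one row per non-reference predictor term.
#' @export
mutual_adjust_model <- function(outcome, covariates,
                                standardize_binary = FALSE, model = "ols") {
  d <- cbind(data.frame(.outcome = outcome), covariate_design(covariates))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 20L) stop("fewer than 20 complete rows")
  d <- standardize_frame(d, standardize_binary)
  terms <- c("sex_girl", "age_years", "maternal_university", "nonverbal_iq",
             "origin_western", "origin_nonwestern")
  fit_standardized(d, terms, model)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors of equal length (n >= 3, positive
#'   variance).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    stop("zero variance: correlation undefined")
  }
  r <- stats::cor(x, y)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), n - 2), n = n)
}

#' Robust (Huber) sensitivity refit
#'
#' The covariate-adjusted regression refitted as a Huber M-estimator
#' (tuning constant 1.345, MAD residual scale, iteratively reweighted
#' least squares), used to check that conclusions are not driven by
#' residual non-normality.
#'
#' @inheritParams standardized_ols
#' @return One-row data frame as in [standardized_ols()].
#' @export
huber_ols <- function(outcome, exposure, covariates,
                      standardize_binary = FALSE) {
  standardized_ols(outcome, exposure, covariates,
                   standardize_binary = standardize_binary, model = "robust")
}
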