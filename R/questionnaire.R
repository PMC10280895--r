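#' Item specification of the post-social-exclusion questionnaire
#'
#' The questionnaire has 15 Likert items (1 = "Not at all" to 5 = "Very
#' much").  The first nine concern feelings at the moment of reporting
#' (after the game), the last six concern feelings during the game.
#' Two "after" items with figurative phrasing load weakly on every
#' factor and are excluded, leaving a six-item "Negative feelings during
#' the game" scale and a seven-item "Negative feelings after the game"
#' scale.  Positively phrased items are reverse coded so that higher
#' always means more negative.
#'
#' The polarity column is a package convention for the synthetic
#' instrument (the computation only needs phase, polarity and
#' inclusion); it is shipped as `inst/extdata/item_specs.csv`.
#'
#' @return Data frame with columns `item_id`, `phase` (`after`/
#'   `during`), `polarity` (`positive`/`negative`), `included`
#'   (logical), `scale` (`during_scale`/`after_scale`/`none`).
#' @export
item_specs <- function() {
  path <- system.file("extdata", "item_specs.csv", package = "cyberscore",
                      mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$included <- as.logical(d$included)
  stopifnot(nrow(d) == 15L,
            sum(d$phase == "after") == 9L,
            sum(d$phase == "during") == 6L,
            sum(!d$included) == 2L,
            sum(d$scale == "during_scale") == 6L,
            sum(d$scale == "after_scale") == 7L)
  d
}

#' Reverse-code a Likert response
#'
#' Positively phrased items are reversed (`6 - value`) so that high
#' scores always express negative feelings; negatively phrased items
#' are returned unchanged.  Missing values pass through.
#'
#' @param value Likert responses in `{1..5}` (NA allowed).
#' @param polarity `"positive"` or `"negative"` (recycled).
#' @return Recoded responses.
#' @export
reverse_code <- function(value, polarity) {
  ok <- is.na(value) | (value %in% 1:5)
  if (!all(ok)) stop("Likert values must be in {1..5}")
  if (!all(polarity %in% c("positive", "negative"))) {
    stop("`polarity` must be \"positive\" or \"negative\"")
  }
  ifelse(rep_len(polarity, length(value)) == "positive", 6 - value, value)
}

#' Recode a response matrix to the negative-feelings metric
#'
#' Applies [reverse_code()] column-wise: positively phrased items are
#' flipped, negatively phrased items pass through.
#'
#' @param responses Children x items matrix of raw Likert responses,
#'   columns ordered as in `specs`.
#' @param specs Item specification data frame, see [item_specs()].
#' @return Matrix of the same shape on the recoded metric, columns
#'   named by item id.
#' @export
recode_items <- function(responses, specs = item_specs()) {
  stopifnot(ncol(responses) == nrow(specs))
  out <- responses
  pos <- specs$polarity == "positive"
  out[, pos] <- 6 - out[, pos, drop = FALSE]
  colnames(out) <- specs$item_id
  out
}

#' Questionnaire subscale scores
#'
#' Each scale score is the mean of its recoded constituent items;
#' missing items are omitted from the mean.  With all items missing on a
#' scale the score is undefined (error).
#'
#' @param responses Numeric matrix (children x 15) or vector (one
#'   child) of raw Likert responses, columns ordered as in `specs`.
#' @param specs Item specification data frame, see [item_specs()].
#' @return Data frame with `negative_during` and `negative_after`, one
#'   row per child, both on the 1-5 item metric.
#' @export
scale_scores <- function(responses, specs = item_specs()) {
  if (is.null(dim(responses))) responses <- matrix(responses, nrow = 1L)
  rec <- recode_items(responses, specs)
  score_one <- function(scale_name) {
    items <- rec[, specs$scale == scale_name, drop = FALSE]
    m <- rowMeans(items, na.rm = TRUE)
    if (any(is.nan(m))) stop("a child has all items missing on a scale")
    m
  }
  data.frame(negative_during = score_one("during_scale"),
             negative_after = score_one("after_scale"))
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(row sums))`,
#' computed on complete cases with n-1 denominators.
#'
#' @param item_matrix Numeric matrix, children x items (k >= 2).
#' @return Alpha (scalar).
#' @export
cronbach_alpha <- function(item_matrix) {
  item_matrix <- as.matrix(item_matrix)
  if (ncol(item_matrix) < 2L) stop("alpha needs at least 2 items")
  cc <- stats::complete.cases(item_matrix)
  if (sum(cc) < 3L) stop("alpha needs at least 3 complete rows")
  m <- item_matrix[cc, , drop = FALSE]
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var < 1e-12) stop("zero total variance: alpha undefined")
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Principal-axis exploratory factor analysis
#'
#' Extracts factors from the item correlation matrix by iterated
#' principal-axis factoring: communalities start at the squared multiple
#' correlations, the reduced correlation matrix (communalities on the
#' diagonal) is eigendecomposed, loadings are the leading eigenvectors
#' scaled by the square roots of their eigenvalues, and the implied
#' communalities are fed back until the largest change is below `tol`.
#'
#' @param item_matrix Children x items matrix (complete cases used), or
#'   a correlation matrix (symmetric with unit diagonal).
#' @param n_factors Number of factors to extract (< number of items).
#' @param tol Convergence tolerance on communalities (default 1e-3;
#'   communality iteration is sub-linear when a near-null factor is
#'   extracted, so much tighter tolerances rarely converge on sample
#'   data while leaving the loadings unchanged to ~1e-4).
#' @param max_iter Iteration cap (default 200); non-convergence is an
#'   error reporting the iteration count.
#' @return Matrix of unrotated loadings (items x factors).
#' @export
efa_principal_axis <- function(item_matrix, n_factors, tol = 1e-3,
                               max_iter = 200L) {
  item_matrix <- as.matrix(item_matrix)
  p <- ncol(item_matrix)
  if (n_factors >= p) stop("`n_factors` must be smaller than the number of items")
  is_cor <- nrow(item_matrix) == p &&
    isTRUE(all.equal(unname(diag(item_matrix)), rep(1, p), tolerance = 1e-8)) &&
    isTRUE(all.equal(item_matrix, t(item_matrix), tolerance = 1e-8))
  R <- if (is_cor) item_matrix else {
    stats::cor(item_matrix[stats::complete.cases(item_matrix), , drop = FALSE])
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation matrix is not positive semi-definite")

  # squared multiple correlations as starting communalities
  Rinv <- tryCatch(solve(R), error = function(e) NULL)
  h <- if (is.null(Rinv)) rep(0.5, p) else pmin(pmax(1 - 1 / diag(Rinv), 0), 1)

  for (iter in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h
    ed <- eigen(Rr, symmetric = TRUE)
    lam <- pmax(ed$values[seq_len(n_factors)], 0)
    L <- ed$vectors[, seq_len(n_factors), drop = FALSE] %*% diag(sqrt(lam), n_factors)
    h_new <- rowSums(L^2)
    if (any(h_new > 1)) {
      warning("Heywood case: communality > 1 clipped to 1")
      h_new <- pmin(h_new, 1)
    }
    if (max(abs(h_new - h)) < tol) {
      rownames(L) <- colnames(R)
      colnames(L) <- paste0("F", seq_len(n_factors))
      return(L)
    }
    h <- h_new
  }
  stop(sprintf("principal-axis factoring did not converge in %d iterations",
               max_iter))
}

#' Varimax rotation
#'
#' Orthogonal rotation maximizing the varimax simplicity criterion with
#' Kaiser row normalization, via pairwise Givens sweeps using Kaiser's
#' quartic angle formula (this pairwise form also handles perfectly
#' clustered loading patterns, which defeat the SVD-update
#' implementation in [stats::varimax()]).  Per-item communalities are
#' preserved exactly.  Columns are sign-flipped so each factor's
#' loading sum is positive, and returned in decreasing order of
#' explained variance.
#'
#' @param loadings Items x factors loading matrix.
#' @param max_sweeps,tol Sweep cap and rotation-angle convergence
#'   tolerance.
#' @return Rotated loading matrix of the same shape.
#' @export
varimax_rotate <- function(loadings, max_sweeps = 100L, tol = 1e-10) {
  loadings <- as.matrix(loadings)
  m <- ncol(loadings)
  if (m < 2L) return(loadings)
  # Kaiser row normalization
  h <- sqrt(rowSums(loadings^2))
  h[h < 1e-12] <- 1
  Z <- loadings / h
  p <- nrow(Z)
  # pairwise Givens sweeps with Kaiser's quartic angle formula; each
  # step is accepted only if it raises the simplicity criterion, which
  # makes the ascent monotone whatever the angle-sign convention
  pair_crit <- function(x, y) {
    sum(x^4) - sum(x^2)^2 / p + sum(y^4) - sum(y^2)^2 / p
  }
  for (sweep in seq_len(max_sweeps)) {
    moved <- 0
    for (j in seq_len(m - 1L)) {
      for (k in (j + 1L):m) {
        x <- Z[, j]; y <- Z[, k]
        u <- x^2 - y^2
        v <- 2 * x * y
        A <- sum(u); B <- sum(v)
        C <- sum(u^2 - v^2); D <- sum(2 * u * v)
        num <- D - 2 * A * B / p
        den <- C - (A^2 - B^2) / p
        if (abs(num) < 1e-14 && abs(den) < 1e-14) next
        phi <- atan2(num, den) / 4
        if (abs(phi) < tol) next
        base <- pair_crit(x, y)
        best_gain <- 0
        for (s in c(phi, -phi)) {
          xs <- x * cos(s) + y * sin(s)
          ys <- -x * sin(s) + y * cos(s)
          gain <- pair_crit(xs, ys) - base
          if (gain > best_gain) {
            best_gain <- gain
            Z[, j] <- xs; Z[, k] <- ys
          }
        }
        if (best_gain > 1e-15) moved <- max(moved, abs(phi))
      }
    }
    if (moved < tol) break
  }
  L <- Z * h
  dimnames(L) <- dimnames(loadings)
  flip <- colSums(L) < 0
  L[, flip] <- -L[, flip, drop = FALSE]
  L[, order(colSums(L^2), decreasing = TRUE), drop = FALSE]
}

#' Assign items to factors by their rotated loadings
#'
#' An item belongs to the factor with its largest absolute loading,
#' provided that loading reaches `threshold`; otherwise it is flagged as
#' low loading (the criterion used to drop items from the instrument).
#' Items reaching the threshold on more than one factor are additionally
#' flagged as cross-loading.
#'
#' @param rotated_loadings Items x factors matrix.
#' @param threshold Minimum absolute loading (default 0.40).
#' @return Data frame with `item`, `factor` (NA when below threshold),
#'   `loading` (the signed largest-in-magnitude loading),
#'   `low_loading`, `cross_loading`.
#' @export
assign_items <- function(rotated_loadings, threshold = 0.40) {
  L <- as.matrix(rotated_loadings)
  idx <- apply(abs(L), 1L, which.max)
  best <- L[cbind(seq_len(nrow(L)), idx)]
  low <- abs(best) < threshold
  data.frame(
    item = rownames(L) %||% as.character(seq_len(nrow(L))),
    factor = ifelse(low, NA_integer_, idx),
    loading = best,
    low_loading = low,
    cross_loading = rowSums(abs(L) >= threshold) > 1L,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
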