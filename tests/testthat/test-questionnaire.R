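test_that("reverse coding flips positive items and is an involution", {
  expect_equal(reverse_code(5, "positive"), 1)
  expect_equal(reverse_code(3, "positive"), 3)
  expect_equal(reverse_code(2, "negative"), 2)
  for (v in 1:5) {
    expect_equal(reverse_code(reverse_code(v, "positive"), "positive"), v)
  }
  expect_error(reverse_code(6, "positive"), "1..5")
  expect_error(reverse_code(3, "sideways"), "polarity")
})

test_that("the shipped item table has the instrument's structure", {
  specs <- item_specs()
  expect_equal(nrow(specs), 15L)
  expect_equal(sum(specs$phase == "after"), 9L)
  expect_equal(sum(specs$phase == "during"), 6L)
  expect_equal(sum(!specs$included), 2L)
  expect_true(all(specs$scale[!specs$included] == "none"))
})

test_that("scale scores are item means after recoding, robust to item order", {
  specs <- item_specs()
  # most negative possible answers: 1 on negative items, 5 on positive
  resp <- ifelse(specs$polarity == "positive", 5, 1)
  s <- scale_scores(resp, specs)
  expect_equal(s$negative_during, 1)
  expect_equal(s$negative_after, 1)

  s3 <- scale_scores(rep(3, 15), specs)
  expect_equal(s3$negative_during, 3)
  expect_equal(s3$negative_after, 3)

  set.seed(51)
  m <- matrix(sample(1:5, 30, replace = TRUE), 2, 15)
  perm <- sample(15)
  a <- scale_scores(m, specs)
  b <- scale_scores(m[, perm, drop = FALSE], specs[perm, ])
  expect_equal(a, b)

  # missing items drop out of the mean
  m2 <- rep(3, 15)
  m2[specs$scale == "during_scale"][1] <- NA
  expect_equal(scale_scores(m2, specs)$negative_during, 3)
})

test_that("Cronbach's alpha matches closed forms", {
  set.seed(52)
  x <- rnorm(100)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1)

  noise <- matrix(rnorm(4000 * 4), 4000, 4)
  expect_lt(abs(cronbach_alpha(noise)), 0.06)

  # exact sample covariance: 3 items, var 1, pairwise cov 0.5
  # alpha = (3/2) (1 - 3/6) = 0.75
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  m <- MASS::mvrnorm(50, mu = rep(0, 3), Sigma = S, empirical = TRUE)
  expect_equal(cronbach_alpha(m), 0.75, tolerance = 1e-10)

  expect_error(cronbach_alpha(matrix(1, 10, 2)), "zero total variance")
})

test_that("principal-axis factoring recovers planted single-factor structure", {
  set.seed(53)
  n <- 20000
  f <- rnorm(n)
  m <- sapply(1:6, function(i) 0.8 * f + sqrt(1 - 0.64) * rnorm(n))
  L <- efa_principal_axis(m, 2)
  expect_true(all(abs(abs(L[, 1]) - 0.8) < 0.03))
  expect_true(all(abs(L[, 2]) < 0.1))
})

test_that("factoring independent items yields near-zero loadings", {
  set.seed(54)
  m <- matrix(rnorm(5000 * 5), 5000, 5)
  L <- efa_principal_axis(m, 2)
  expect_true(all(abs(L) < 0.25))
})

test_that("loadings plus uniqueness reconstruct the correlation matrix", {
  # exact two-factor population correlation matrix
  lam <- matrix(0, 8, 2)
  lam[1:4, 1] <- 0.7
  lam[5:8, 2] <- 0.6
  R <- lam %*% t(lam)
  diag(R) <- 1
  # exact structure converges cleanly, so a tight tolerance is usable
  L <- efa_principal_axis(R, 2, tol = 1e-8, max_iter = 2000)
  fit <- L %*% t(L)
  diag(fit) <- 1
  expect_lt(max(abs(fit - R)), 1e-4)

  # independent route: ML factor analysis on the same matrix agrees on
  # the recovered structure (up to column order/sign)
  ml <- stats::factanal(covmat = R, factors = 2, n.obs = 1000,
                        rotation = "none")
  cross <- abs(t(L) %*% matrix(as.numeric(ml$loadings), 8, 2))
  # each PAF factor matches one ML factor almost perfectly
  expect_true(all(apply(cross, 1, max) > 0.95 * colSums(L^2)))
})

test_that("varimax preserves communalities and fixes simple structure", {
  lam <- matrix(0, 8, 2)
  lam[1:4, 1] <- c(0.72, 0.66, 0.61, 0.55)  # heterogeneous loadings, as
  lam[5:8, 2] <- c(0.68, 0.62, 0.58, 0.52)  # real instruments have
  # rotate away from simple structure, then varimax should restore it
  th <- pi / 7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  mixed <- lam %*% rot
  back <- varimax_rotate(mixed)
  expect_equal(rowSums(back^2), rowSums(mixed^2), tolerance = 1e-8)
  expect_equal(abs(back), abs(lam), tolerance = 1e-6)

  # already-simple loadings are a fixed point (up to sign/order)
  again <- varimax_rotate(lam)
  expect_equal(abs(again), abs(lam), tolerance = 1e-6)

  # single factor: no-op
  expect_identical(varimax_rotate(lam[, 1, drop = FALSE]),
                   lam[, 1, drop = FALSE])
})

test_that("pairwise varimax agrees with the reference rotation generically", {
  set.seed(55)
  L <- matrix(rnorm(24, 0, 0.4), 12, 2) +
    cbind(c(rep(0.6, 6), rep(0, 6)), c(rep(0, 6), rep(0.5, 6)))
  mine <- varimax_rotate(L)
  ref <- stats::varimax(L, normalize = TRUE)$loadings
  ref <- matrix(as.numeric(ref), 12, 2)
  crit <- function(M) {
    h <- sqrt(rowSums(M^2))
    sum(apply((M / h)^2, 2, stats::var))
  }
  expect_equal(crit(mine), crit(ref), tolerance = 1e-6)
  # columns agree up to permutation and sign
  for (j in 1:2) {
    diffs <- apply(ref, 2, function(rc) {
      min(max(abs(mine[, j] - rc)), max(abs(mine[, j] + rc)))
    })
    expect_lt(min(diffs), 1e-3)
  }
})

test_that("items are assigned by largest absolute loading over the threshold", {
  L <- rbind(c(0.7, 0.1), c(0.35, 0.30), c(0.5, -0.6))
  rownames(L) <- c("a", "b", "c")
  asg <- assign_items(L)
  expect_equal(asg$factor, c(1L, NA, 2L))
  expect_identical(asg$low_loading, c(FALSE, TRUE, FALSE))
  expect_identical(asg$cross_loading, c(FALSE, FALSE, TRUE))
  expect_equal(asg$loading[3], -0.6)
})
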