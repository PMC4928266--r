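test_that("log transform hits its fixed points and rejects nonpositive values", {
  d <- tibble::tibble(specimen_id = c("a", "b", "c"), species = "s",
                      body_weight = c(exp(1), 1, NA), body_length = c(2, 3, 4),
                      wing_length = 1, tail_length = 1, tarsus_length = 1,
                      culmen_length = 1)
  out <- log_transform(d)
  expect_equal(out$body_weight, c(1, 0, NA))
  d$body_weight[[2L]] <- 0
  expect_error(log_transform(d), "body_weight.*specimen b")
})

test_that("standardization centres and scales with the n-1 denominator", {
  d <- tibble::tibble(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- standardize(d)
  expect_equal(z$a, c(-1, 0, 1))
  expect_lt(max(abs(colMeans(as.matrix(z)))), 1e-12)
  expect_equal(unname(apply(as.matrix(z), 2L, var)), c(1, 1), tolerance = 1e-12)
  expect_error(standardize(tibble::tibble(a = c(1, 1, 1))), "constant column: a")
})

test_that("species means average complete rows in first-appearance order", {
  d <- tibble::tibble(species = c("b", "a", "b", "a"),
                      t1 = c(1, 9, 3, NA), t2 = c(3, 7, 5, 8))
  m <- species_means(d)
  expect_equal(m$species, c("b", "a"))     # first appearance, not alphabetical
  expect_equal(m$t1, c(2, 9))              # the incomplete 'a' row is dropped
  expect_equal(m$t2, c(4, 7))
  single <- species_means(tibble::tibble(species = c("x", "y", "y"), t = c(5, 1, 3)))
  expect_equal(single$t[single$species == "x"], 5)
  expect_error(species_means(tibble::tibble(species = "z", t = NA_real_)), "no complete rows: z")
})

test_that("PCA reconstructs its input and orders components", {
  line <- tibble::tibble(x = 1:6, y = 1:6 + 0)
  p <- morpho_pca(line)
  expect_equal(p$variance_fraction[[1L]], 1, tolerance = 1e-12)

  set.seed(20)
  m <- matrix(rnorm(24L), 6L, 4L)
  p2 <- morpho_pca(m)
  expect_equal(sum(p2$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(p2$variance_fraction) <= 1e-12))
  centered <- scale(m, center = TRUE, scale = FALSE)
  recon <- as.matrix(p2$scores) %*% t(p2$loadings)
  expect_lt(max(abs(recon - centered)), 1e-9)
  # scores are the centered data times the loadings
  expect_lt(max(abs(as.matrix(p2$scores) - centered %*% p2$loadings)), 1e-9)
  # sign convention: dominant loading positive
  for (j in seq_len(ncol(p2$loadings))) {
    expect_gt(p2$loadings[which.max(abs(p2$loadings[, j])), j], 0)
  }
  expect_error(morpho_pca(m[1L, , drop = FALSE]), "two rows")

  # correlation mode equals covariance mode on standardized data
  p3 <- morpho_pca(m, mode = "correlation")
  p4 <- morpho_pca(scale(m))
  expect_equal(p3$variance_fraction, p4$variance_fraction, tolerance = 1e-9)
})

test_that("one-way ANOVA matches the hand sums-of-squares oracle", {
  res <- one_way_anova(value = c(1, 2, 3, 4, 5, 6), group = rep(c("a", "b"), each = 3L))
  # oracle: SSB = 13.5 (df 1), SSW = 4 (df 4), MSW = 1 -> F = 13.5
  expect_equal(res$F, 13.5, tolerance = 1e-12)
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 4L)
  expect_equal(res$p, pf(13.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)

  flat <- one_way_anova(value = c(1, 2, 1, 2), group = c("a", "a", "b", "b"))
  expect_equal(flat$F, 0)

  # p decreases monotonically with group separation
  set.seed(21)
  base <- rnorm(10L)
  ps <- vapply(c(0, 0.5, 1, 2, 4), function(delta) {
    one_way_anova(value = c(base, base + delta), group = rep(c("a", "b"), each = 10L))$p
  }, numeric(1L))
  expect_true(all(diff(ps) < 0))

  expect_error(one_way_anova(value = c(1, 2), group = c("a", "b")), "degrees of freedom")
})

test_that("CVA reduces to Euclidean distance under identity within-covariance", {
  set.seed(22)
  # construct two groups whose pooled within-group covariance is exactly I
  n <- 12L
  raw <- matrix(rnorm(n * 3L), n, 3L)
  raw <- scale(raw, center = TRUE, scale = FALSE)
  whitened <- raw %*% solve(chol(crossprod(raw) / (2L * n - 2L)))
  X <- rbind(whitened[1:6, ] - matrix(colMeans(whitened[1:6, ]), 6L, 3L, byrow = TRUE),
             whitened[7:12, ] - matrix(colMeans(whitened[7:12, ]), 6L, 3L, byrow = TRUE))
  shift <- c(2, -1, 0.5)
  X[7:12, ] <- X[7:12, ] + matrix(shift, 6L, 3L, byrow = TRUE)
  # pooled within covariance of X is whitened'whitened/(n-2): close to I after
  # regrouping; rebuild it exactly
  g <- rep(c("a", "b"), each = 6L)
  W <- (crossprod(X[1:6, ] - matrix(colMeans(X[1:6, ]), 6L, 3L, byrow = TRUE)) +
        crossprod(X[7:12, ] - matrix(colMeans(X[7:12, ]), 6L, 3L, byrow = TRUE))) / 10
  Xw <- X %*% solve(chol(W))
  res <- morpho_cva(Xw, g)
  mu <- rowsum(Xw, g) / 6
  expect_equal(res$mahalanobis["a", "b"], sqrt(sum((mu[1L, ] - mu[2L, ])^2)),
               tolerance = 1e-9)
})

test_that("CVA distance matrices are symmetric, zero-diagonal and transform-invariant", {
  set.seed(23)
  X <- matrix(rnorm(60L), 20L, 3L)
  g <- rep(c("a", "b", "c", "d"), each = 5L)
  X[g == "b", 1L] <- X[g == "b", 1L] + 2
  X[g == "c", 2L] <- X[g == "c", 2L] - 3
  res <- morpho_cva(X, g)
  expect_equal(res$mahalanobis, t(res$mahalanobis))
  expect_equal(unname(diag(res$mahalanobis)), rep(0, 4L))
  expect_true(all(res$mahalanobis >= 0))
  # invariance under an invertible linear transform of all specimens
  A <- matrix(c(2, 0.5, -1, 0.3, 1.5, 0.2, 0, -0.7, 3), 3L, 3L)
  res2 <- morpho_cva(X %*% A, g)
  expect_equal(res2$mahalanobis, res$mahalanobis, tolerance = 1e-6)
  # independent direct-formula oracle for the Mahalanobis matrix
  mu <- rowsum(X, g) / 5
  W <- crossprod(X - mu[match(g, rownames(mu)), ]) / (20L - 4L)
  Winv <- solve(W)
  for (i in 1:3) for (j in (i + 1L):4L) {
    dm <- mu[i, ] - mu[j, ]
    expect_equal(res$mahalanobis[i, j], sqrt(drop(t(dm) %*% Winv %*% dm)), tolerance = 1e-9)
  }
})

test_that("shuffling group labels shrinks the between-group eigenvalue sum", {
  set.seed(24)
  X <- matrix(rnorm(90L), 30L, 3L)
  g <- rep(c("a", "b", "c"), each = 10L)
  X[g == "b", ] <- X[g == "b", ] + 3
  X[g == "c", 1L] <- X[g == "c", 1L] - 3
  obs <- sum(morpho_cva(X, g)$eigenvalues)
  worse <- vapply(1:100, function(i) {
    sum(morpho_cva(X, sample(g))$eigenvalues)
  }, numeric(1L))
  expect_true(all(worse < obs))
})

test_that("Goodall's shape F equals the classical F under univariate embedding", {
  set.seed(25)
  v <- rnorm(18L)
  g <- rep(c("a", "b", "c"), each = 6L)
  v[g == "b"] <- v[g == "b"] + 1.5
  classical <- one_way_anova(value = v, group = g)
  goodall <- procrustes_anova(matrix(v, ncol = 1L), group = g, shape_dim = 1L)
  expect_equal(goodall$shape$F, classical$F, tolerance = 1e-12)
  expect_equal(goodall$shape$df_between, classical$df_between)
  expect_equal(goodall$shape$p, classical$p, tolerance = 1e-12)
})

test_that("Procrustes ANOVA uses shape-space dimensions and flags degenerate cases", {
  set.seed(26)
  g <- gpa(outline_set(8L, noise = 0.04))
  tg <- tangent_project(g)
  tg$species <- rep(c("a", "b"), each = 4L)
  res <- procrustes_anova(tg)
  expect_equal(res$shape$df_between, 1L * (2L * 21L - 4L))
  expect_equal(res$shape$df_within, 6L * (2L * 21L - 4L))
  expect_equal(res$size$df_between, 1L)
  # rotation of the whole coordinate frame leaves the shape F unchanged
  M <- tangent_matrix(tg)
  Q <- qr.Q(qr(matrix(rnorm(ncol(M)^2), ncol(M))))
  res_rot <- procrustes_anova(M %*% Q, group = tg$species)
  expect_equal(res_rot$shape$F, res$shape$F, tolerance = 1e-9)
  # zero within-group variation diverges with a warning
  X0 <- rbind(matrix(1, 3L, 4L), matrix(2, 3L, 4L))
  expect_warning(r0 <- procrustes_anova(X0, group = rep(c("a", "b"), each = 3L)),
                 "infinite")
  expect_identical(r0$shape$F, Inf)
})

test_that("OLS regression matches exact lines and the normal-equations oracle", {
  x <- c(1, 2, 3, 4, 5)
  res <- suppressWarnings(ols_regression(y = 2 * x + 1, x = x))  # exact fit
  expect_equal(res$slope, 2, tolerance = 1e-12)
  expect_equal(res$intercept, 1, tolerance = 1e-12)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)

  flat <- ols_regression(y = rep(3, 5L), x = x)
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r_squared, 0)

  set.seed(27)
  xr <- rnorm(15L); yr <- rnorm(15L)
  res2 <- ols_regression(y = yr, x = xr)
  X <- cbind(1, xr)
  beta <- solve(crossprod(X), crossprod(X, yr))
  expect_equal(res2$intercept, beta[[1L]], tolerance = 1e-9)
  expect_equal(res2$slope, beta[[2L]], tolerance = 1e-9)

  expect_error(ols_regression(y = yr, x = rep(1, 15L)), "constant")
  expect_error(ols_regression(y = 1:2, x = 1:2), "three")
})

test_that("size correction leaves residuals centred and orthogonal to log weight", {
  set.seed(28)
  d <- tibble::tibble(
    species = letters[1:8],
    body_weight = rnorm(8L, 3, 0.4)
  )
  d$culmen_length <- 0.3 * d$body_weight + 1     # exactly proportional on log scale
  d$tarsus_length <- rnorm(8L, 2, 0.2)
  out <- size_correct(d, cols = c("culmen_length", "tarsus_length"))
  expect_lt(max(abs(out$culmen_length)), 1e-12)
  expect_lt(abs(mean(out$tarsus_length)), 1e-12)
  expect_lt(abs(cor(out$tarsus_length, d$body_weight)), 1e-9)
})
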