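test_that("the Brownian covariance matrix matches the printed toy trees", {
  C1 <- phylo_vcv(read_newick("(A:1,B:1);"))
  expect_equal(unname(C1), diag(2L))
  C2 <- phylo_vcv(read_newick("((A:1,B:1):0.5,C:1.5);"))
  expect_equal(C2["A", "B"], 0.5)
  expect_equal(C2["A", "C"], 0)
  expect_equal(unname(diag(C2)), rep(1.5, 3L))
  expect_error(phylo_vcv(structure(list(edge = C1), class = "phylo")), "branch lengths")
})

test_that("the Brownian covariance agrees with ape and stays PSD on random trees", {
  set.seed(30)
  for (i in 1:100) {
    tr <- ape::rtree(sample(4:20, 1L))
    C <- phylo_vcv(tr)
    ref <- ape::vcv(tr)[rownames(C), colnames(C)]
    expect_lt(max(abs(C - ref)), 1e-12)
    expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("Blomberg's K matches picante and respects the permutation-p bounds", {
  tr <- simulate_tree(12L, seed = 31L)
  x <- simulate_bm_traits(tr, 0, 1, seed = 32L)
  ours <- blomberg_k(tr, x, n_perm = 999L, seed = 1L)
  expect_equal(ours$estimate, as.numeric(picante::Kcalc(x[tr$tip.label], tr)), tolerance = 1e-9)
  expect_gte(ours$p, 1 / 1000)
  expect_lte(ours$p, 1)
  # affine invariance of the statistic
  shifted <- blomberg_k(tr, 5 - 2 * x, n_perm = 0L)
  expect_equal(shifted$estimate, ours$estimate, tolerance = 1e-9)
  expect_error(blomberg_k(tr, setNames(rep(1, 12L), tr$tip.label)), "constant")
  expect_error(blomberg_k(tr, x[-1L]), "do not match")
})

test_that("tip-shuffled traits lose their K signal", {
  tr <- simulate_tree(16L, seed = 33L)
  set.seed(34)
  res <- vapply(1:200, function(i) {
    x <- simulate_bm_traits(tr, 0, 1)
    names(x) <- sample(names(x))
    k <- blomberg_k(tr, x, n_perm = 199L)
    c(k$estimate, k$p)
  }, numeric(2L))
  expect_lt(median(res[1L, ]), 1)
  expect_gte(mean(res[2L, ] > 0.05), 0.9)
})

test_that("Pagel's lambda likelihood has the right endpoints and matches phytools", {
  tr <- simulate_tree(12L, seed = 35L)
  x <- simulate_bm_traits(tr, 0, 1, seed = 36L)
  C <- phylo_vcv(tr)
  # lambda = 0: iid normal with variances diag(C), GLS mean = weighted mean
  l0 <- paridmorph:::lambda_loglik(0, C, x)
  v <- diag(C)
  mu <- sum(x / v) / sum(1 / v)
  s2 <- sum((x - mu)^2 / v) / length(x)
  ll_iid <- sum(dnorm(x, mu, sqrt(s2 * v), log = TRUE))
  expect_equal(l0, ll_iid, tolerance = 1e-9)

  ours <- pagel_lambda(tr, x)
  ph <- phytools::phylosig(tr, x, method = "lambda", test = TRUE)
  expect_equal(ours$estimate, ph$lambda, tolerance = 1e-3)
  # the likelihood functions agree exactly; the optima may differ only by
  # optimizer resolution near the positive-definiteness boundary
  expect_equal(paridmorph:::lambda_loglik(ph$lambda, C, x), ph$logL, tolerance = 1e-6)
  expect_gte(ours$logL, ph$logL - 1e-9)
  # an interior optimum matches phytools tightly
  set.seed(99)
  xi <- x + rnorm(length(x), 0, 0.8 * sd(x))
  oi <- pagel_lambda(tr, xi)
  pi_ <- phytools::phylosig(tr, xi, method = "lambda", test = TRUE)
  expect_equal(oi$estimate, pi_$lambda, tolerance = 1e-4)
  expect_equal(oi$logL, pi_$logL, tolerance = 1e-6)
  expect_equal(oi$p, pi_$P, tolerance = 1e-4)
  # optimizer sanity: the optimum beats both endpoints
  expect_gte(ours$logL, paridmorph:::lambda_loglik(0, C, x) - 1e-9)
  expect_gte(ours$logL, paridmorph:::lambda_loglik(1, C, x) - 1e-9)
  # affine invariance of the estimate
  expect_equal(pagel_lambda(tr, 3 * x + 7)$estimate, ours$estimate, tolerance = 1e-6)
})

test_that("PGLS reduces to OLS on a star tree and is branch-scale invariant", {
  star <- read_newick(paste0("(", paste(sprintf("t%d:1", 1:8), collapse = ","), ");"))
  set.seed(37)
  x <- setNames(rnorm(8L), star$tip.label)
  y <- setNames(2 + 0.5 * x + rnorm(8L, 0, 0.3), star$tip.label)
  ours <- pgls(y = y, x = x, tree = star)
  ols <- lm(y ~ x)
  expect_equal(ours$slope, unname(coef(ols)[[2L]]), tolerance = 1e-9)
  expect_equal(ours$intercept, unname(coef(ols)[[1L]]), tolerance = 1e-9)

  tr <- simulate_tree(10L, seed = 38L)
  xt <- simulate_bm_traits(tr, 0, 1, seed = 39L)
  yt <- 1.2 * xt + simulate_bm_traits(tr, 0, 0.4, seed = 40L)
  fit1 <- pgls(y = yt, x = xt, tree = tr)
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 2
  fit2 <- pgls(y = yt, x = xt, tree = tr2)
  expect_equal(fit2$slope, fit1$slope, tolerance = 1e-9)
  expect_equal(fit2$t, fit1$t, tolerance = 1e-9)

  # independent oracle: nlme::gls with a Brownian correlation structure
  d <- data.frame(x = xt[tr$tip.label], y = yt[tr$tip.label], species = tr$tip.label)
  ref <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corBrownian(phy = tr, form = ~species),
                   method = "ML")
  expect_equal(fit1$slope, unname(coef(ref)[[2L]]), tolerance = 1e-6)
  expect_equal(fit1$t, unname(summary(ref)$tTable[2L, 3L]), tolerance = 1e-6)

  expect_error(pgls(y = yt, x = setNames(rep(1, 10L), names(xt)), tree = tr), "singular")
})

test_that("squared-change parsimony solves the weighted-average system exactly", {
  expect_equal(squared_change_parsimony(read_newick("(A:1,B:1);"), c(A = 0, B = 4))$value, 2)
  # weighted cherry: (0/1 + 4/3) / (1 + 1/3) = 1
  expect_equal(squared_change_parsimony(read_newick("(A:1,B:3);"), c(A = 0, B = 4))$value, 1)

  # matches a generic numerical minimizer of the weighted sum of squared changes
  set.seed(41)
  for (i in 1:20) {
    tr <- ape::rtree(sample(4:10, 1L))
    tr$edge.length <- tr$edge.length + 0.1
    x <- setNames(rnorm(ape::Ntip(tr)), tr$tip.label)
    ours <- squared_change_parsimony(tr, x)
    ntip <- ape::Ntip(tr)
    obj <- function(v) {
      all_vals <- c(x[tr$tip.label], v)
      sum((all_vals[tr$edge[, 1L]] - all_vals[tr$edge[, 2L]])^2 / tr$edge.length)
    }
    opt <- optim(rep(mean(x), tr$Nnode), obj, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 2000L))
    expect_lt(max(abs(ours$value - opt$par)), 1e-6)
    # convexity: every reconstruction inside the tip range
    expect_true(all(ours$value >= min(x) - 1e-9 & ours$value <= max(x) + 1e-9))
  }
})

test_that("the root reconstruction equals the GLS mean under Brownian motion", {
  tr <- simulate_tree(9L, seed = 42L)
  x <- simulate_bm_traits(tr, 1, 1, seed = 43L)
  scp <- squared_change_parsimony(tr, x)
  C <- phylo_vcv(tr)
  Cinv <- solve(C)
  gls_root <- sum(Cinv %*% x[rownames(C)]) / sum(Cinv)
  root_node <- ape::Ntip(tr) + 1L
  expect_equal(scp$value[scp$node == root_node], unname(gls_root), tolerance = 1e-9)
})

test_that("zero-length internal edges merge their endpoint values", {
  tr <- read_newick("((A:1,B:1):0,C:1);")
  scp <- squared_change_parsimony(tr, c(A = 0, B = 4, C = 2))
  expect_equal(scp$value[[1L]], scp$value[[2L]])
})

test_that("phylomorphospace places tips exactly and reconstructions inside the hull", {
  tr <- simulate_tree(10L, seed = 44L)
  set.seed(45)
  sc <- tibble::tibble(species = tr$tip.label,
                       PC1 = rnorm(10L), PC2 = rnorm(10L))
  pm <- phylomorphospace(tr, sc)
  tips <- pm$nodes[pm$nodes$type == "tip", ]
  expect_equal(tips$PC1[match(sc$species, tips$label)], sc$PC1)
  expect_equal(tips$PC2[match(sc$species, tips$label)], sc$PC2)
  internal <- pm$nodes[pm$nodes$type == "internal", ]
  expect_true(all(internal$PC1 >= min(sc$PC1) & internal$PC1 <= max(sc$PC1)))
  expect_true(all(internal$PC2 >= min(sc$PC2) & internal$PC2 <= max(sc$PC2)))
  expect_equal(nrow(pm$edges), 2L * 10L - 2L)
  expect_error(phylomorphospace(tr, sc[-1L, ]), "missing tip scores")
})

test_that("signal and PGLS statistics are invariant to affine trait transforms", {
  tr <- simulate_tree(12L, seed = 46L)
  x <- simulate_bm_traits(tr, 0, 1, seed = 47L)
  k1 <- blomberg_k(tr, x, n_perm = 99L, seed = 5L)
  k2 <- blomberg_k(tr, 10 * x - 3, n_perm = 99L, seed = 5L)
  expect_equal(k2$estimate, k1$estimate, tolerance = 1e-9)
  expect_equal(k2$p, k1$p)
  l1 <- pagel_lambda(tr, x)
  l2 <- pagel_lambda(tr, 10 * x - 3)
  expect_equal(l2$estimate, l1$estimate, tolerance = 1e-6)
})
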