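# Phylogenetic comparative stage: Brownian-motion covariance, Blomberg's K
# with a permutation test, Pagel's lambda by maximum likelihood, PGLS,
# squared-change parsimony ancestral states, phylomorphospace coordinates.

#' Phylogenetic variance-covariance matrix under Brownian motion
#'
#' `C[i, j]` is the shared root-to-tip path length of tips `i` and `j` (the
#' depth of their most recent common ancestor); `C[i, i]` is the depth of tip
#' `i`. Under Brownian motion with rate `sigma^2`, tip trait values are
#' multivariate normal with covariance `sigma^2 * C`.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @return labelled symmetric positive semidefinite matrix.
#' @export
phylo_vcv <- function(tree) {
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (any(tree$edge.length < 0)) abort("negative branch length")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  depth <- numeric(nnode)
  # preorder traversal for node depths
  eo <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(eo$edge))) {
    depth[eo$edge[e, 2L]] <- depth[eo$edge[e, 1L]] + eo$edge.length[[e]]
  }
  # postorder accumulation of descendant tip sets
  tips_below <- vector("list", nnode)
  for (i in seq_len(ntip)) tips_below[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  C <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  kids <- split(po$edge[, 2L], po$edge[, 1L])
  for (node in unique(po$edge[, 1L])) {
    ch <- kids[[as.character(node)]]
    sets <- lapply(ch, function(c) tips_below[[c]])
    # tip pairs split across different children share this node as MRCA
    if (length(sets) > 1L) {
      for (a in seq_len(length(sets) - 1L)) for (b in (a + 1L):length(sets)) {
        C[sets[[a]], sets[[b]]] <- depth[[node]]
        C[sets[[b]], sets[[a]]] <- depth[[node]]
      }
    }
    tips_below[[node]] <- unlist(sets)
  }
  diag(C) <- depth[seq_len(ntip)]
  C
}

#' @keywords internal
match_tips <- function(tree, x) {
  nm <- trimws(names(x))
  tips <- trimws(tree$tip.label)
  if (is.null(nm)) {
    if (length(x) != length(tips)) abort("unnamed trait of wrong length")
    return(setNames(x, tree$tip.label))
  }
  missing <- setdiff(tips, nm)
  extra <- setdiff(nm, tips)
  if (length(missing) > 0L || length(extra) > 0L) {
    abort(paste0(
      "trait and tree tips do not match",
      if (length(missing) > 0L) paste0("; tips without data: ", paste(missing, collapse = ", ")),
      if (length(extra) > 0L) paste0("; data without tips: ", paste(extra, collapse = ", "))
    ))
  }
  setNames(x[match(tips, nm)], tree$tip.label)
}

# GLS (phylogenetically corrected) mean and the two mean squared errors of
# the Blomberg et al. formulation, computed from a Cholesky factor of C.
#' @keywords internal
.k_mse <- function(x, L) {
  n <- length(x)
  z <- backsolve(L, x, transpose = TRUE)
  o <- backsolve(L, rep(1, n), transpose = TRUE)
  ahat <- sum(o * z) / sum(o * o)
  r <- x - ahat
  mse0 <- sum(r^2) / (n - 1)
  rz <- z - ahat * o
  mse <- sum(rz^2) / (n - 1)
  c(mse0 = mse0, mse = mse)
}

#' Blomberg's K with a permutation test
#'
#' K compares the observed partitioning of trait variance on the tree with
#' its Brownian-motion expectation: `K = (MSE0 / MSE)_observed /
#' (MSE0 / MSE)_expected`, where `MSE0` is the mean squared deviation of tip
#' values from the phylogenetically corrected (GLS) mean and `MSE` the GLS
#' mean squared error. `K = 1` matches Brownian motion on the given tree,
#' `K < 1` indicates less, `K > 1` more resemblance among relatives than
#' Brownian motion predicts. The p-value is the proportion of tip
#' permutations whose `MSE` is at most the observed one (+1 correction).
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param x named tip trait vector.
#' @param n_perm number of permutations (default 999).
#' @param seed optional RNG seed.
#' @return object of class `parid_signal`: tibble row with `statistic`,
#'   `estimate`, `p`, `n_perm`.
#' @export
blomberg_k <- function(tree, x, n_perm = 999L, seed = NULL) {
  x <- match_tips(tree, x)
  if (sd(x) == 0) abort("trait is constant")
  C <- phylo_vcv(tree)
  n <- length(x)
  L <- chol(C)
  obs <- .k_mse(x, L)
  Cinv1 <- backsolve(L, backsolve(L, rep(1, n), transpose = TRUE))
  expected <- (sum(diag(C)) - n / sum(Cinv1)) / (n - 1)
  k <- (obs[["mse0"]] / obs[["mse"]]) / expected
  p <- NA_real_
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    hits <- 0L
    for (b in seq_len(n_perm)) {
      mseb <- .k_mse(x[sample.int(n)], L)[["mse"]]
      if (mseb <= obs[["mse"]]) hits <- hits + 1L
    }
    p <- (hits + 1L) / (n_perm + 1L)
  }
  out <- tibble::tibble(statistic = "K", estimate = unname(k), p = p,
                        n_perm = as.integer(n_perm), logL = NA_real_)
  class(out) <- c("parid_signal", class(out))
  out
}

#' @keywords internal
lambda_transform <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' @keywords internal
lambda_loglik <- function(lambda, C, x) {
  n <- length(x)
  L <- tryCatch(chol(lambda_transform(C, lambda)), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  z <- backsolve(L, x, transpose = TRUE)
  o <- backsolve(L, rep(1, n), transpose = TRUE)
  ahat <- sum(o * z) / sum(o * o)
  rz <- z - ahat * o
  s2 <- sum(rz^2) / n
  -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(L))) + n)
}

#' Pagel's lambda by maximum likelihood
#'
#' Lambda scales the off-diagonal entries of the Brownian-motion covariance
#' `C`; `lambda = 0` gives phylogenetic independence (diagonal covariance),
#' `lambda = 1` plain Brownian motion. The estimate maximizes the
#' multivariate-normal log-likelihood over `[0, lambda_max]`, where
#' `lambda_max` is the largest value keeping the transformed matrix positive
#' definite (at least 1). The p-value is a likelihood-ratio test against
#' `lambda = 0` (chi-squared, 1 df).
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param x named tip trait vector.
#' @return object of class `parid_signal`: tibble row with `statistic`,
#'   `estimate`, `p`, `logL`.
#' @export
pagel_lambda <- function(tree, x) {
  x <- match_tips(tree, x)
  if (sd(x) == 0) abort("trait is constant")
  C <- phylo_vcv(tree)
  # largest lambda keeping C_lambda positive definite, by bisection
  pd <- function(l) !is.null(tryCatch(chol(lambda_transform(C, l)), error = function(e) NULL))
  if (!pd(1)) abort("Brownian covariance not positive definite; check the tree")
  lo <- 1; hi <- 2
  while (pd(hi) && hi < 64) { lo <- hi; hi <- hi * 2 }
  for (i in 1:40) { mid <- (lo + hi) / 2; if (pd(mid)) lo <- mid else hi <- mid }
  lambda_max <- max(lo, 1)
  opt <- optimize(lambda_loglik, c(0, lambda_max), C = C, x = x,
                  maximum = TRUE, tol = 1e-8)
  # guard the interior optimum against the boundaries
  cand <- c(opt$maximum, 0, 1, lambda_max)
  ll <- vapply(cand, lambda_loglik, numeric(1L), C = C, x = x)
  best <- which.max(ll)
  est <- cand[[best]]
  logl <- ll[[best]]
  l0 <- lambda_loglik(0, C, x)
  p <- pchisq(2 * (logl - l0), df = 1L, lower.tail = FALSE)
  out <- tibble::tibble(statistic = "lambda", estimate = est, p = p,
                        n_perm = NA_integer_, logL = logl)
  class(out) <- c("parid_signal", class(out))
  out
}

#' @export
tidy.parid_signal <- function(x, ...) tibble::as_tibble(unclass(x))

#' Phylogenetic generalized least squares
#'
#' Linear regression of one tip trait on another with residual covariance
#' proportional to the Brownian-motion matrix `C` of the tree:
#' `beta = (X' C^-1 X)^-1 X' C^-1 y`. The slope is tested with a t statistic
#' on `n - 2` degrees of freedom. The overall scale of the branch lengths
#' cancels, so doubling all branch lengths leaves slope and t unchanged; on a
#' star phylogeny the fit reduces to OLS.
#'
#' @param data tibble keyed by `species`, or `NULL` when `y`/`x` are named
#'   vectors.
#' @param y,x response and predictor: column names or named tip vectors.
#' @param tree rooted `phylo` with branch lengths.
#' @return object of class `parid_pgls`: tibble row with `slope`,
#'   `intercept`, `slope_se`, `t`, `p`, `sigma2`, `n`.
#' @export
pgls <- function(data = NULL, y, x, tree) {
  if (!is.null(data)) {
    yv <- setNames(data[[y]], data$species)
    xv <- setNames(data[[x]], data$species)
  } else {
    yv <- y; xv <- x
  }
  yv <- match_tips(tree, yv)
  xv <- match_tips(tree, xv)
  n <- length(yv)
  if (n < 4L) abort("need at least four tips")
  C <- phylo_vcv(tree)
  L <- chol(C)
  X <- cbind(intercept = 1, slope = xv)
  Xt <- backsolve(L, X, transpose = TRUE)
  yt <- backsolve(L, yv, transpose = TRUE)
  XtX <- crossprod(Xt)
  if (rcond(XtX) < 1e-12) abort("singular design (constant predictor?)")
  beta <- solve(XtX, crossprod(Xt, yt))
  r <- yt - Xt %*% beta
  sigma2 <- sum(r^2) / (n - 2L)
  vc <- sigma2 * solve(XtX)
  se <- sqrt(vc[2L, 2L])
  tval <- beta[[2L]] / se
  out <- tibble::tibble(
    slope = beta[[2L]], intercept = beta[[1L]], slope_se = se,
    t = tval, p = 2 * pt(abs(tval), df = n - 2L, lower.tail = FALSE),
    sigma2 = sigma2, n = n
  )
  class(out) <- c("parid_pgls", class(out))
  out
}

#' @export
tidy.parid_pgls <- function(x, ...) tibble::as_tibble(unclass(x))

#' Squared-change parsimony ancestral states
#'
#' Internal node values minimizing the sum over edges of squared changes
#' divided by branch length — identical to the joint Brownian-motion maximum
#' likelihood reconstruction. The minimizer solves a sparse linear system
#' (each internal node is the branch-length-weighted average of its
#' neighbours), so every reconstructed value lies within the range of the tip
#' values. Zero-length internal edges merge their endpoints, which then share
#' one value.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param x named tip vector, or a matrix/data frame with one named row per
#'   tip (one reconstruction per column).
#' @return tibble with `node` (ape node number), one column per trait.
#' @export
squared_change_parsimony <- function(tree, x) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  if (is.vector(x)) x <- matrix(match_tips(tree, x), ncol = 1L,
                                dimnames = list(tree$tip.label, "value"))
  else {
    x <- as.matrix(x)
    x <- x[match(tree$tip.label, trimws(rownames(x))), , drop = FALSE]
    if (anyNA(rownames(x))) abort("tip values and tree tips do not match")
  }
  bl <- tree$edge.length
  if (any(bl[tree$edge[, 2L] > ntip] == 0)) {
    # contract zero-length internal-internal edges: endpoints share a value
    cluster <- seq_len(nnode)
    find <- function(i) { while (cluster[[i]] != i) i <- cluster[[i]] <- cluster[[cluster[[i]]]]; i }
    for (e in which(bl == 0)) {
      a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
      if (b > ntip) cluster[find(b)] <- find(a)
    }
    group <- vapply(seq_len(nnode), find, integer(1L))
  } else {
    group <- seq_len(nnode)
  }
  internal_groups <- unique(group[(ntip + 1L):nnode])
  gidx <- match(group, internal_groups)   # NA for tip-only groups (none: tips map to themselves)
  ni <- length(internal_groups)
  A <- matrix(0, ni, ni)
  b <- matrix(0, ni, ncol(x))
  for (e in seq_along(bl)) {
    if (bl[[e]] == 0) next
    w <- 1 / bl[[e]]
    pa <- group[[tree$edge[e, 1L]]]
    ch <- group[[tree$edge[e, 2L]]]
    if (pa == ch) next
    pi_ <- match(pa, internal_groups)
    if (ch <= ntip) {
      A[pi_, pi_] <- A[pi_, pi_] + w
      b[pi_, ] <- b[pi_, ] + w * x[ch, ]
    } else {
      ci <- match(ch, internal_groups)
      A[pi_, pi_] <- A[pi_, pi_] + w
      A[ci, ci] <- A[ci, ci] + w
      A[pi_, ci] <- A[pi_, ci] - w
      A[ci, pi_] <- A[ci, pi_] - w
    }
  }
  v <- solve(A, b)
  nodes <- (ntip + 1L):nnode
  vals <- v[match(group[nodes], internal_groups), , drop = FALSE]
  out <- tibble::as_tibble(as.data.frame(vals))
  names(out) <- colnames(x)
  dplyr::bind_cols(tibble::tibble(node = nodes), out)
}

#' Phylomorphospace coordinates
#'
#' Projects a phylogeny into a two-axis morphometric ordination: tips sit at
#' their observed scores, internal nodes at squared-change-parsimony
#' reconstructions, and edges connect parent and child coordinates.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param scores tibble with `species` and two score columns (or a matrix
#'   with rownames).
#' @param axes names of the two score columns (default: the first two
#'   numeric columns).
#' @return object of class `parid_phylomorphospace`: list with `nodes`
#'   (tibble: `node`, `type`, `label`, one column per axis) and `edges`
#'   (tibble: `parent`, `child`, `x`, `y`, `xend`, `yend`).
#' @export
phylomorphospace <- function(tree, scores, axes = NULL) {
  if (is.matrix(scores)) {
    scores <- dplyr::bind_cols(tibble::tibble(species = rownames(scores)),
                               tibble::as_tibble(scores))
  }
  axes <- axes %||% head(names(scores)[vapply(scores, is.numeric, logical(1L))], 2L)
  if (length(axes) != 2L) abort("need exactly two score axes")
  miss <- setdiff(tree$tip.label, scores$species)
  if (length(miss) > 0L) abort(paste0("missing tip scores: ", paste(miss, collapse = ", ")))
  m <- as.matrix(scores[match(tree$tip.label, scores$species), axes])
  rownames(m) <- tree$tip.label
  anc <- squared_change_parsimony(tree, m)
  ntip <- length(tree$tip.label)
  nodes <- dplyr::bind_rows(
    tibble::tibble(node = seq_len(ntip), type = "tip", label = tree$tip.label,
                   !!axes[[1L]] := unname(m[, 1L]), !!axes[[2L]] := unname(m[, 2L])),
    tibble::tibble(node = anc$node, type = "internal", label = NA_character_,
                   !!axes[[1L]] := anc[[axes[[1L]]]], !!axes[[2L]] := anc[[axes[[2L]]]])
  )
  co <- as.matrix(nodes[order(nodes$node), axes])
  edges <- tibble::tibble(
    parent = tree$edge[, 1L], child = tree$edge[, 2L],
    x = co[tree$edge[, 1L], 1L], y = co[tree$edge[, 1L], 2L],
    xend = co[tree$edge[, 2L], 1L], yend = co[tree$edge[, 2L], 2L]
  )
  structure(list(nodes = nodes, edges = edges, axes = axes),
            class = "parid_phylomorphospace")
}

#' @export
print.parid_phylomorphospace <- function(x, ...) {
  cat(sprintf("Phylomorphospace on (%s, %s): %d nodes, %d edges\n",
              x$axes[[1L]], x$axes[[2L]], nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
tidy.parid_phylomorphospace <- function(x, ...) x$nodes

#' Phylogenetic signal table for a set of traits
#'
#' Runs [blomberg_k()] and [pagel_lambda()] on every numeric column of a
#' species-level trait table.
#'
#' @param tree rooted `phylo`.
#' @param data tibble keyed by `species` with numeric trait columns.
#' @param n_perm permutations for the K test.
#' @param seed RNG seed for the K permutations.
#' @return tibble with one row per trait x statistic: `trait`, `statistic`,
#'   `estimate`, `p`.
#' @export
signal_table <- function(tree, data, n_perm = 999L, seed = NULL) {
  traits <- setdiff(names(data)[vapply(data, is.numeric, logical(1L))], "species")
  purrr::map_dfr(traits, function(v) {
    xv <- setNames(data[[v]], data$species)
    dplyr::bind_rows(
      dplyr::mutate(tidy(blomberg_k(tree, xv, n_perm = n_perm, seed = seed)), trait = v, .before = 1L),
      dplyr::mutate(tidy(pagel_lambda(tree, xv)), trait = v, .before = 1L)
    )
  }) |>
    dplyr::select("trait", "statistic", "estimate", "p")
}
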