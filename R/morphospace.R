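# Multivariate morphometrics: trait preprocessing, one-way ANOVA, PCA, CVA
# with Mahalanobis distances, Goodall's Procrustes ANOVA, OLS regression,
# size correction.

#' Log-transform measurement columns
#'
#' Natural log of every trait column, applied to normalize the typically
#' right-skewed linear measurements. Missing values propagate; nonpositive
#' values are an error naming the specimen and trait.
#'
#' @param data measurement tibble (see [read_measurements()]).
#' @param cols columns to transform; defaults to the six linear traits.
#' @return tibble with the named columns replaced by their logs.
#' @export
log_transform <- function(data, cols = intersect(trait_names(), names(data))) {
  for (v in cols) {
    bad <- which(!is.na(data[[v]]) & data[[v]] <= 0)
    if (length(bad) > 0L) {
      id <- if ("specimen_id" %in% names(data)) data$specimen_id[[bad[[1L]]]] else bad[[1L]]
      abort(sprintf("nonpositive value of %s for specimen %s", v, id))
    }
    data[[v]] <- log(data[[v]])
  }
  data
}

#' Standardize columns to zero mean and unit variance
#'
#' Each column is centred and divided by its sample standard deviation
#' (n - 1 denominator), removing the effect of different measurement units.
#'
#' @param data tibble or matrix; non-numeric columns pass through untouched.
#' @return object of the same shape.
#' @export
standardize <- function(data) {
  is_df <- is.data.frame(data)
  cols <- if (is_df) names(data)[vapply(data, is.numeric, logical(1L))] else colnames(data) %||% seq_len(ncol(data))
  if ((if (is_df) nrow(data) else nrow(data)) < 2L) abort("need at least two rows")
  for (v in cols) {
    x <- if (is_df) data[[v]] else data[, v]
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) abort(sprintf("constant column: %s", v))
    z <- (x - mean(x, na.rm = TRUE)) / s
    if (is_df) data[[v]] <- z else data[, v] <- z
  }
  data
}

#' Per-species means over complete rows
#'
#' Arithmetic mean of every numeric column within species, computed over rows
#' with no missing value in those columns. Output rows follow the first
#' appearance of each species in the input.
#'
#' @param data tibble with a `species` column.
#' @param cols numeric columns to average; defaults to all numeric columns.
#' @return tibble with one row per species.
#' @export
species_means <- function(data, cols = NULL) {
  if (!"species" %in% names(data)) abort("data must have a species column")
  cols <- cols %||% setdiff(names(data)[vapply(data, is.numeric, logical(1L))], "point")
  complete <- stats::complete.cases(data[, cols, drop = FALSE])
  lvls <- unique(data$species)
  dropped <- setdiff(lvls, unique(data$species[complete]))
  if (length(dropped) > 0L) {
    abort(paste0("species with no complete rows: ", paste(dropped, collapse = ", ")))
  }
  data[complete, c("species", cols)] |>
    dplyr::mutate(species = factor(.data$species, levels = lvls)) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean), .groups = "drop") |>
    dplyr::mutate(species = as.character(.data$species))
}

#' Principal component analysis
#'
#' Eigen-decomposition (via [stats::prcomp()]) of the covariance or
#' correlation matrix of the column-centered data. Components are ordered by
#' decreasing eigenvalue, and each component's sign is fixed so that its
#' largest-magnitude loading is positive, giving a reproducible orientation.
#'
#' @param data tibble or matrix of observations x variables; an optional
#'   `species` (or other id) column is carried into the scores.
#' @param mode `"covariance"` (default) or `"correlation"`.
#' @return object of class `parid_pca`: list with `scores` (tibble),
#'   `loadings` (variables x components matrix), `variance_fraction`,
#'   `sdev`, `center`, `mode`.
#' @export
morpho_pca <- function(data, mode = c("covariance", "correlation")) {
  mode <- match.arg(mode)
  if (is.data.frame(data)) {
    id_cols <- names(data)[!vapply(data, is.numeric, logical(1L))]
    ids <- data[, id_cols, drop = FALSE]
    m <- as.matrix(data[, setdiff(names(data), id_cols), drop = FALSE])
  } else {
    ids <- NULL
    m <- as.matrix(data)
  }
  if (nrow(m) < 2L) abort("need at least two rows for a PCA")
  p <- prcomp(m, center = TRUE, scale. = mode == "correlation")
  # sign convention: largest-magnitude loading positive per component
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  vf <- p$sdev^2 / sum(p$sdev^2)
  scores <- tibble::as_tibble(p$x)
  if (!is.null(ids) && ncol(ids) > 0L) scores <- dplyr::bind_cols(tibble::as_tibble(ids), scores)
  structure(
    list(scores = scores, loadings = p$rotation, variance_fraction = vf,
         sdev = p$sdev, center = p$center,
         scale = if (mode == "correlation") p$scale else NULL, mode = mode),
    class = "parid_pca"
  )
}

#' @export
print.parid_pca <- function(x, ...) {
  cat(sprintf("PCA (%s matrix): %d components\n", x$mode, length(x$variance_fraction)))
  pct <- sprintf("%.2f%%", 100 * head(x$variance_fraction, 5L))
  cat("  variance fractions:", paste(pct, collapse = ", "),
      if (length(x$variance_fraction) > 5L) "..." else "", "\n")
  invisible(x)
}

#' @describeIn morpho_pca tidy scores (one row per observation).
#' @param x a `parid_pca` object.
#' @param ... unused.
#' @export
tidy.parid_pca <- function(x, ...) x$scores

#' @describeIn morpho_pca one-row-per-component summary (`component`,
#'   `std_dev`, `variance_fraction`, `cumulative`).
#' @export
glance.parid_pca <- function(x, ...) {
  tibble::tibble(
    component = paste0("PC", seq_along(x$variance_fraction)),
    std_dev = x$sdev,
    variance_fraction = x$variance_fraction,
    cumulative = cumsum(x$variance_fraction)
  )
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition, fitted through [stats::aov()].
#'
#' @param data tibble holding the value and group columns, or `NULL` when
#'   `value`/`group` are vectors.
#' @param value column name (string) or numeric vector.
#' @param group column name (string) or vector of group labels.
#' @return object of class `parid_anova`: tibble row with `F`, `df_between`,
#'   `df_within`, `p`, `ss_between`, `ss_within`.
#' @export
one_way_anova <- function(data = NULL, value, group) {
  if (!is.null(data)) {
    value <- data[[value]]
    group <- data[[group]]
  }
  keep <- !is.na(value) & !is.na(group)
  value <- value[keep]
  group <- factor(group[keep])
  if (nlevels(group) < 2L) abort("need at least two groups")
  if (length(value) - nlevels(group) < 1L) abort("zero within-group degrees of freedom")
  s <- summary(aov(value ~ group))[[1L]]
  out <- tibble::tibble(
    F = s$`F value`[[1L]],
    df_between = s$Df[[1L]],
    df_within = s$Df[[2L]],
    p = s$`Pr(>F)`[[1L]],
    ss_between = s$`Sum Sq`[[1L]],
    ss_within = s$`Sum Sq`[[2L]]
  )
  class(out) <- c("parid_anova", class(out))
  out
}

#' @export
tidy.parid_anova <- function(x, ...) tibble::as_tibble(unclass(x))

#' Canonical variate analysis with Mahalanobis distances
#'
#' Extracts the axes that best discriminate among groups: eigenvectors of
#' `W^-1 B` where `W` is the pooled within-group covariance and `B` the
#' between-group covariance of the group means. Because superimposed shape
#' coordinates have a singular within-group covariance (superimposition and
#' sliding remove degrees of freedom), the data are first reduced to the
#' principal components carrying eigenvalues above `rank_tol` times the
#' largest (and at most `n - g` of them); the canonical analysis and the
#' pairwise group Mahalanobis distances are computed in that subspace.
#'
#' @param data tibble or matrix of observations x variables (non-numeric
#'   columns are dropped from the variables).
#' @param group vector of group labels, or the name of a column of `data`.
#' @param rank_tol relative eigenvalue tolerance for the rank-reduction step.
#' @return object of class `parid_cva`: list with `scores` (tibble of
#'   canonical scores plus group), `mahalanobis` (labelled distance matrix
#'   over groups), `eigenvalues`, `group_means`, `dims_used`.
#' @export
morpho_cva <- function(data, group, rank_tol = 1e-10) {
  if (is.character(group) && length(group) == 1L && is.data.frame(data) && group %in% names(data)) {
    g <- data[[group]]
    data <- data[, setdiff(names(data), group), drop = FALSE]
  } else {
    g <- group
  }
  if (is.data.frame(data)) {
    data <- as.matrix(data[, vapply(data, is.numeric, logical(1L)), drop = FALSE])
  }
  keep <- stats::complete.cases(data) & !is.na(g)
  X <- data[keep, , drop = FALSE]
  g <- factor(g[keep], levels = unique(g[keep]))
  n <- nrow(X); ng <- nlevels(g)
  if (ng < 2L) abort("need at least two groups")
  if (any(table(g) < 2L)) {
    abort(paste0("groups with fewer than two members: ",
                 paste(names(which(table(g) < 2L)), collapse = ", ")))
  }
  # rank reduction by PCA of the total covariance
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  ev <- sv$d^2
  d <- min(sum(ev > rank_tol * max(ev)), n - ng)
  basis <- sv$v[, seq_len(d), drop = FALSE]
  Z <- Xc %*% basis
  means <- rowsum(Z, g) / as.vector(table(g))
  Zw <- Z - means[as.integer(g), , drop = FALSE]
  W <- crossprod(Zw) / (n - ng)
  grand <- colMeans(Z)
  B <- crossprod(sqrt(as.vector(table(g))) * sweep(means, 2L, grand)) / (ng - 1L)
  L <- chol(W + diag(1e-12 * max(diag(W)), d))
  M <- backsolve(L, t(backsolve(L, B, transpose = TRUE)), transpose = TRUE)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  n_axes <- min(ng - 1L, d)
  vec <- backsolve(L, e$vectors[, seq_len(n_axes), drop = FALSE])
  scores <- Z %*% vec
  colnames(scores) <- paste0("CV", seq_len(n_axes))
  Winv <- chol2inv(L)
  mah <- matrix(0, ng, ng)
  for (i in seq_len(ng - 1L)) for (j in (i + 1L):ng) {
    dm <- means[i, ] - means[j, ]
    mah[i, j] <- mah[j, i] <- sqrt(drop(t(dm) %*% Winv %*% dm))
  }
  dimnames(mah) <- list(levels(g), levels(g))
  structure(
    list(scores = dplyr::bind_cols(tibble::tibble(group = as.character(g)),
                                   tibble::as_tibble(scores)),
         mahalanobis = mah,
         eigenvalues = pmax(e$values[seq_len(n_axes)], 0),
         group_means = means, dims_used = d),
    class = "parid_cva"
  )
}

#' @export
print.parid_cva <- function(x, ...) {
  cat(sprintf("CVA: %d groups, %d canonical axes (computed in %d dimensions)\n",
              nrow(x$mahalanobis), length(x$eigenvalues), x$dims_used))
  invisible(x)
}

#' @describeIn morpho_cva tidy canonical scores.
#' @param x a `parid_cva` object.
#' @param ... unused.
#' @export
tidy.parid_cva <- function(x, ...) x$scores

#' @describeIn morpho_cva axis eigenvalue summary.
#' @export
glance.parid_cva <- function(x, ...) {
  tibble::tibble(axis = paste0("CV", seq_along(x$eigenvalues)),
                 eigenvalue = x$eigenvalues)
}

#' Procrustes ANOVA (Goodall-style F) for shape, classical ANOVA for size
#'
#' Decomposes the summed squared tangent-space deviations into between- and
#' within-group parts. Goodall's F uses degrees of freedom multiplied by the
#' shape-space dimension — `2k - 4` for `k` two-dimensional landmarks after
#' superimposition (2 translations, 1 rotation and 1 scaling removed). Size is
#' tested by a classical one-way ANOVA on log centroid size.
#'
#' @param shapes matrix (or tangent tibble from [tangent_project()]) of
#'   specimens x shape coordinates.
#' @param sizes per-specimen centroid sizes (taken from the tangent tibble if
#'   `NULL` there).
#' @param group per-specimen group labels (taken from the `species` column of
#'   a tangent tibble if omitted).
#' @param shape_dim shape-space dimension per specimen; default `2k - 4`
#'   inferred from the coordinate count (use `shape_dim = ncol` semantics,
#'   e.g. 1, to embed plain multivariate data).
#' @param n_perm if > 0, also compute a permutation p-value for the shape F
#'   from `n_perm` random relabellings.
#' @param seed RNG seed for the permutation test.
#' @return list of class `parid_panova` with elements `shape` and `size`
#'   (each a `parid_anova` row; the shape row gains `p_perm` when requested).
#' @export
procrustes_anova <- function(shapes, sizes = NULL, group = NULL, shape_dim = NULL,
                             n_perm = 0L, seed = NULL) {
  if (is.data.frame(shapes)) {
    if (is.null(group) && "species" %in% names(shapes)) group <- shapes$species
    if (is.null(sizes) && "centroid_size" %in% names(shapes)) sizes <- shapes$centroid_size
    shapes <- tangent_matrix(shapes)
  }
  shapes <- as.matrix(shapes)
  if (is.null(group)) abort("group labels required")
  g <- factor(group, levels = unique(group))
  n <- nrow(shapes); ng <- nlevels(g)
  if (ng < 2L) abort("need at least two groups")
  m <- shape_dim %||% max(ncol(shapes) - 4L, 1L)
  if (n - ng < 1L) abort("zero within-group degrees of freedom")
  means <- rowsum(shapes, g) / as.vector(table(g))
  grand <- colMeans(shapes)
  ssb <- sum(as.vector(table(g)) * rowSums(sweep(means, 2L, grand)^2))
  ssw <- sum((shapes - means[as.integer(g), , drop = FALSE])^2)
  df_b <- (ng - 1L) * m
  df_w <- (n - ng) * m
  if (ssw == 0) {
    warn("zero within-group shape variation: F is infinite")
    Fs <- Inf; p <- 0
  } else {
    Fs <- (ssb / df_b) / (ssw / df_w)
    p <- pf(Fs, df_b, df_w, lower.tail = FALSE)
  }
  shape_row <- tibble::tibble(F = Fs, df_between = df_b, df_within = df_w, p = p,
                              ss_between = ssb, ss_within = ssw)
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    ssb_obs <- ssb
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      gp <- g[sample.int(n)]
      mp <- rowsum(shapes, gp) / as.vector(table(gp))
      ssb_p <- sum(as.vector(table(gp)) * rowSums(sweep(mp, 2L, grand)^2))
      if (ssb_p >= ssb_obs) exceed <- exceed + 1L
    }
    shape_row$p_perm <- (exceed + 1L) / (n_perm + 1L)
  }
  class(shape_row) <- c("parid_anova", class(shape_row))
  size_row <- NULL
  if (!is.null(sizes)) {
    size_row <- one_way_anova(value = log(sizes), group = g)
  }
  structure(list(shape = shape_row, size = size_row), class = "parid_panova")
}

#' @export
print.parid_panova <- function(x, ...) {
  cat(sprintf("Procrustes ANOVA  shape: F(%d, %d) = %.4g, p = %.3g\n",
              x$shape$df_between, x$shape$df_within, x$shape$F, x$shape$p))
  if (!is.null(x$size)) {
    cat(sprintf("                  size:  F(%d, %d) = %.4g, p = %.3g\n",
                x$size$df_between, x$size$df_within, x$size$F, x$size$p))
  }
  invisible(x)
}

#' @export
tidy.parid_panova <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(unclass(x$shape)), effect = "shape", .before = 1L),
    if (!is.null(x$size)) dplyr::mutate(tibble::as_tibble(unclass(x$size)), effect = "size", .before = 1L)
  )
}

#' Ordinary least-squares regression of one trait on one predictor
#'
#' Wrapper around [stats::lm()] returning the quantities the pipeline
#' tabulates: slope, intercept, r-squared and the two-sided t-test p-value on
#' the slope.
#'
#' @param data tibble, or `NULL` when `y`/`x` are vectors.
#' @param y response column name or numeric vector.
#' @param x predictor column name or numeric vector.
#' @return tibble row with `slope`, `intercept`, `r_squared`, `p`, `n`.
#' @export
ols_regression <- function(data = NULL, y, x) {
  if (!is.null(data)) {
    y <- data[[y]]
    x <- data[[x]]
  }
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  if (length(y) < 3L) abort("need at least three paired observations")
  if (sd(x) == 0) abort("constant predictor")
  if (sd(y) == 0) {
    return(tibble::tibble(slope = 0, intercept = y[[1L]], r_squared = 0,
                          p = 1, n = length(y)))
  }
  fit <- lm(y ~ x)
  s <- summary(fit)
  tibble::tibble(
    slope = unname(coef(fit)[[2L]]),
    intercept = unname(coef(fit)[[1L]]),
    r_squared = s$r.squared,
    p = s$coefficients[2L, 4L],
    n = length(y)
  )
}

#' Size-corrected traits as residuals on log body weight
#'
#' For each trait column, returns the residuals of its OLS regression on log
#' body weight, the standard size correction when overall body size must be
#' removed before comparing trait proportions.
#'
#' @param data tibble of log-transformed traits including `body_weight`
#'   (already on the log scale).
#' @param weight_col column holding log body weight.
#' @param cols trait columns to correct; defaults to the remaining linear
#'   traits present.
#' @return tibble with the same identifier columns and residual trait columns.
#' @export
size_correct <- function(data, weight_col = "body_weight",
                         cols = setdiff(intersect(trait_names(), names(data)), weight_col)) {
  w <- data[[weight_col]]
  if (anyNA(w)) abort("log body weight required for every row")
  out <- data[, setdiff(names(data), c(cols, weight_col)), drop = FALSE]
  for (v in cols) {
    fit <- lm(data[[v]] ~ w)
    out[[v]] <- as.numeric(data[[v]] - (coef(fit)[[1L]] + coef(fit)[[2L]] * w))
  }
  tibble::as_tibble(out)
}
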