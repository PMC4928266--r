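# Geometric core: centroid size, ordinary and generalized Procrustes
# superimposition, sliding semilandmarks, tangent-space projection.

#' Centroid size of landmark configurations
#'
#' Centroid size is the square root of the summed squared distances of a
#' configuration's points from their centroid — the standard geometric size
#' measure, invariant to translation and rotation and scaling linearly with
#' the configuration.
#'
#' @param x a landmark tibble (one or more specimens) or a single k x 2
#'   coordinate matrix.
#' @return for a matrix, a positive scalar; for a landmark tibble, a tibble
#'   with columns `specimen_id`, `species`, `centroid_size`.
#' @examples
#' centroid_size(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # sqrt(2)
#' @export
centroid_size <- function(x) {
  if (is.matrix(x)) return(.centroid_size(x))
  arr <- lm_array(x)
  info <- lm_info(x)
  cs <- apply(arr, 3L, .centroid_size)
  dplyr::mutate(info, centroid_size = unname(cs[match(info$specimen_id, names(cs))]))
}

#' @keywords internal
.centroid_size <- function(m) {
  if (nrow(m) < 2L) abort("need at least two points")
  m <- sweep(m, 2L, colMeans(m))
  s <- sqrt(sum(m^2))
  if (s < 1e-12) abort("all points coincident: centroid size is zero")
  s
}

#' @keywords internal
.center_unit <- function(m) {
  m <- sweep(m, 2L, colMeans(m))
  m / sqrt(sum(m^2))
}

# Optimal rotation (det +1, no reflection) of m onto ref.
#' @keywords internal
.rotate_onto <- function(m, ref) {
  s <- svd(crossprod(m, ref))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, d)) %*% t(s$v)
  m %*% R
}

#' Ordinary Procrustes fit of one configuration onto a reference
#'
#' Translates the moving configuration to the origin, scales it to unit
#' centroid size, and rotates it (rotation only; reflections are disallowed
#' because all outlines are digitized in one orientation) to minimize the
#' summed squared point-wise differences from the reference.
#'
#' @param moving k x 2 coordinate matrix.
#' @param reference k x 2 matrix, centered and of unit centroid size.
#' @return list with `aligned` (k x 2 matrix) and `distance` (the minimized
#'   root-sum-of-squares).
#' @export
procrustes_fit <- function(moving, reference) {
  if (!all(dim(moving) == dim(reference))) {
    abort(sprintf("point-count mismatch: %d vs %d", nrow(moving), nrow(reference)))
  }
  aligned <- .rotate_onto(.center_unit(moving), reference)
  list(aligned = aligned, distance = sqrt(sum((aligned - reference)^2)))
}

#' Procrustes distance between two configurations
#'
#' Full Procrustes distance: the root-sum-of-squared differences after
#' optimal translation, scaling and rotation of `a` onto `b`. Both
#' configurations are reduced to preshapes (centered, unit centroid size)
#' first; with preshapes the distance is `sqrt(1 - s^2)` where `s` is the sum
#' of (sign-adjusted) singular values of the cross-product matrix.
#'
#' @param a,b k x 2 coordinate matrices with equal point counts.
#' @return nonnegative scalar.
#' @export
procrustes_distance <- function(a, b) {
  if (!all(dim(a) == dim(b))) abort("point-count mismatch")
  sa <- .center_unit(a)
  sb <- .center_unit(b)
  sv <- svd(crossprod(sa, sb))
  flip <- sign(det(sv$u %*% t(sv$v)))
  s <- sv$d[1L] + sv$d[2L] * flip
  # residual computed by direct subtraction (sqrt(1 - s^2) loses precision
  # near identical shapes)
  R <- sv$u %*% diag(c(1, flip)) %*% t(sv$v)
  sqrt(sum((s * sa %*% R - sb)^2))
}

#' Generalized Procrustes analysis
#'
#' Iteratively superimposes a set of configurations: every configuration is
#' centered and scaled to unit centroid size, rotated onto the current
#' consensus, and the consensus is recomputed as the mean of the aligned
#' configurations rescaled to unit centroid size, until the consensus
#' stabilizes. Full Procrustes scaling (every aligned shape keeps unit
#' centroid size).
#'
#' @param landmarks landmark tibble (see [read_tps()]) or k x 2 x n array.
#' @param tol convergence tolerance on the root-mean-square change of the
#'   consensus between iterations.
#' @param max_iter iteration cap; exceeding it is an error.
#' @return an object of class `parid_gpa`: list with `coords` (k x 2 x n
#'   array of aligned shapes), `consensus` (k x 2), `centroid_size` (named
#'   vector of the original sizes), `roles`, `curves`, `info` (specimen
#'   metadata tibble), `iterations`, `sum_sq` (total Procrustes sum of
#'   squares about the consensus).
#' @export
gpa <- function(landmarks, tol = 1e-8, max_iter = 200L) {
  if (is.array(landmarks) && length(dim(landmarks)) == 3L) {
    arr <- landmarks
    info <- tibble::tibble(specimen_id = dimnames(arr)[[3L]] %||% sprintf("spec_%03d", seq_len(dim(arr)[3L])),
                           species = NA_character_)
    roles <- default_roles(dim(arr)[1L])
  } else {
    arr <- lm_array(landmarks)
    info <- lm_info(landmarks)
    if (!"species" %in% names(info)) info$species <- NA_character_
    roles <- lm_roles(landmarks)
  }
  n <- dim(arr)[3L]
  if (n < 2L) abort("need at least two configurations")
  cs <- apply(arr, 3L, .centroid_size)
  shapes <- arr
  for (i in seq_len(n)) shapes[, , i] <- .center_unit(arr[, , i])
  # initial consensus from the (input-order-independent) mean preshape, so the
  # alignment is equivariant under permutation of the inputs
  m0 <- apply(shapes, c(1L, 2L), mean)
  consensus <- if (sqrt(sum(m0^2)) > 1e-6) .center_unit(m0) else .center_unit(shapes[, , 1L])
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    for (i in seq_len(n)) shapes[, , i] <- .rotate_onto(shapes[, , i], consensus)
    new_consensus <- .center_unit(apply(shapes, c(1L, 2L), mean))
    change <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (change < tol) break
    if (iterations >= max_iter) {
      abort(sprintf("GPA did not converge in %d iterations (last change %.3g)", max_iter, change))
    }
  }
  # final rotation pass onto the converged consensus
  for (i in seq_len(n)) shapes[, , i] <- .rotate_onto(shapes[, , i], consensus)
  structure(
    list(coords = shapes, consensus = consensus,
         centroid_size = setNames(cs, dimnames(arr)[[3L]]),
         roles = roles, curves = default_curves(dim(arr)[1L]),
         info = info, iterations = iterations,
         sum_sq = sum((shapes - array(consensus, dim(shapes)))^2)),
    class = "parid_gpa"
  )
}

#' @export
print.parid_gpa <- function(x, ...) {
  cat(sprintf("Generalized Procrustes analysis: %d configurations, %d landmarks (%d sliding)\n",
              dim(x$coords)[3L], dim(x$coords)[1L], sum(x$roles == "semi")))
  cat(sprintf("  iterations: %d, total Procrustes SS: %.6g\n", x$iterations, x$sum_sq))
  invisible(x)
}

#' Tidy aligned coordinates
#'
#' @param x a `parid_gpa` object.
#' @param ... unused.
#' @return landmark tibble of aligned coordinates plus `centroid_size`.
#' @export
tidy.parid_gpa <- function(x, ...) {
  out <- lm_tibble(x$coords, info = x$info, roles = x$roles)
  out$centroid_size <- x$centroid_size[match(out$specimen_id, names(x$centroid_size))]
  out
}

#' Slide semilandmarks along the outline
#'
#' Semilandmarks lack point-wise homology along the outline; sliding lets
#' each one move along its local tangent direction (the chord between its
#' curve neighbours) to minimize a criterion against the consensus, removing
#' arbitrary spacing variation from the shape analysis. The default criterion
#' is the Procrustes distance to the consensus; `"bending"` minimizes
#' thin-plate-spline bending energy relative to the consensus instead.
#' Sliding alternates with GPA consensus updates until the total Procrustes
#' sum of squares stabilizes. Fixed landmarks never move, and under the
#' Procrustes criterion each specimen's update is only accepted if it does
#' not increase that specimen's distance to the consensus (slid points are
#' re-projected onto the specimen's outline polyline, which can otherwise
#' lose optimality).
#'
#' @param aligned a `parid_gpa` object whose roles flag at least one `"semi"`
#'   point.
#' @param method `"procrustes"` (default), `"bending"`, or `"none"` (no-op).
#' @param curves list of integer vectors giving point order along each
#'   outline curve; default taken from the object (beak scheme for 21
#'   points).
#' @param tol convergence tolerance on the relative change of the total
#'   Procrustes sum of squares.
#' @param max_iter outer iteration cap.
#' @param resuperimpose re-run the GPA after each sliding pass (default).
#'   With `FALSE` a single sliding pass is applied against the current
#'   consensus and the configurations are otherwise left untouched, so fixed
#'   landmarks keep their coordinates exactly; the aligned-set invariants
#'   (centering, unit size) then hold only approximately.
#' @return a `parid_gpa` object with slid, re-superimposed coordinates.
#' @export
slide_semilandmarks <- function(aligned, method = c("procrustes", "bending", "none"),
                                curves = NULL, tol = 1e-8, max_iter = 50L,
                                resuperimpose = TRUE) {
  stopifnot(inherits(aligned, "parid_gpa"))
  method <- match.arg(method)
  if (method == "none") return(aligned)
  roles <- aligned$roles
  if (!any(roles == "semi")) abort("no semilandmarks flagged")
  curves <- curves %||% aligned$curves
  if (length(curves) == 0L) abort("no curve structure available to define tangents")
  nbrs <- semi_neighbours(roles, curves)
  shapes <- aligned$coords
  k <- dim(shapes)[1L]; n <- dim(shapes)[3L]
  consensus <- aligned$consensus
  ss <- sum((shapes - array(consensus, dim(shapes)))^2)
  for (iter in seq_len(if (resuperimpose) max_iter else 1L)) {
    for (i in seq_len(n)) {
      shapes[, , i] <- slide_one(shapes[, , i], consensus, nbrs, curves, method)
    }
    if (!resuperimpose) break
    # re-superimpose and update consensus
    g <- gpa(shapes, tol = 1e-10)
    shapes <- g$coords
    consensus <- g$consensus
    new_ss <- sum((shapes - array(consensus, dim(shapes)))^2)
    if (abs(ss - new_ss) <= tol * max(ss, 1e-12)) { ss <- new_ss; break }
    ss <- new_ss
  }
  if (!resuperimpose) ss <- sum((shapes - array(consensus, dim(shapes)))^2)
  out <- aligned
  out$coords <- shapes
  out$consensus <- consensus
  out$iterations <- aligned$iterations
  out$sum_sq <- ss
  out
}

# Map each semilandmark index to its two neighbours along its curve.
#' @keywords internal
semi_neighbours <- function(roles, curves) {
  nbrs <- list()
  for (cv in curves) {
    for (j in seq_along(cv)) {
      pt <- cv[[j]]
      if (roles[[pt]] == "semi") {
        if (j == 1L || j == length(cv)) {
          abort(sprintf("semilandmark %d sits at a curve end with no fixed anchor", pt))
        }
        nbrs[[as.character(pt)]] <- c(cv[[j - 1L]], cv[[j + 1L]])
      }
    }
  }
  semis <- which(roles == "semi")
  missing <- setdiff(semis, as.integer(names(nbrs)))
  if (length(missing) > 0L) {
    abort(paste0("semilandmark(s) not on any curve: ", paste(missing, collapse = ", ")))
  }
  nbrs
}

#' @keywords internal
slide_one <- function(shape, consensus, nbrs, curves, method) {
  semis <- as.integer(names(nbrs))
  tangents <- t(vapply(names(nbrs), function(nm) {
    nb <- nbrs[[nm]]
    v <- shape[nb[[2L]], ] - shape[nb[[1L]], ]
    v / sqrt(sum(v^2))
  }, numeric(2L)))
  if (method == "procrustes") {
    # independent per point: optimal step is the tangential component of the
    # deviation toward the consensus
    alpha <- rowSums(tangents * (consensus[semis, , drop = FALSE] - shape[semis, , drop = FALSE]))
  } else {
    # bending energy: joint least squares in the TPS energy metric at the consensus
    be <- bending_energy_matrix(consensus)
    k <- nrow(shape)
    y <- c(shape[, 1L] - consensus[, 1L], shape[, 2L] - consensus[, 2L])
    U <- matrix(0, 2L * k, length(semis))
    for (j in seq_along(semis)) {
      U[semis[[j]], j] <- tangents[j, 1L]
      U[k + semis[[j]], j] <- tangents[j, 2L]
    }
    E <- rbind(cbind(be, matrix(0, k, k)), cbind(matrix(0, k, k), be))
    A <- crossprod(U, E %*% U)
    alpha <- tryCatch(-solve(A + diag(1e-12, ncol(A)), crossprod(U, E %*% y))[, 1L],
                      error = function(e) rep(0, length(semis)))
  }
  cand <- shape
  cand[semis, ] <- shape[semis, , drop = FALSE] + alpha * tangents
  # keep points on the specimen's outline: project back onto the pre-slide polyline
  for (cv in curves) {
    poly <- shape[cv, , drop = FALSE]
    for (pt in intersect(cv, semis)) {
      cand[pt, ] <- project_on_polyline(cand[pt, ], poly)
    }
  }
  if (method == "procrustes") {
    # monotonicity safeguard: accept only if no farther from the consensus
    d_old <- procrustes_distance(shape, consensus)
    step <- cand
    for (damp in 0:4) {
      if (procrustes_distance(step, consensus) <= d_old + 1e-12) return(step)
      step[semis, ] <- (shape[semis, , drop = FALSE] + step[semis, , drop = FALSE]) / 2
    }
    return(shape)
  }
  cand
}

#' @keywords internal
project_on_polyline <- function(p, poly) {
  best <- poly[1L, ]; best_d <- Inf
  for (s in seq_len(nrow(poly) - 1L)) {
    a <- poly[s, ]; b <- poly[s + 1L, ]
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), 1e-300)
    t <- min(max(t, 0), 1)
    q <- a + t * ab
    d <- sum((p - q)^2)
    if (d < best_d) { best_d <- d; best <- q }
  }
  best
}

# Thin-plate-spline bending energy matrix at a reference configuration.
#' @keywords internal
bending_energy_matrix <- function(ref) {
  k <- nrow(ref)
  d2 <- as.matrix(stats::dist(ref))^2
  K <- ifelse(d2 == 0, 0, d2 * log(d2))
  P <- cbind(1, ref)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3L, 3L)))
  Linv <- solve(L + diag(1e-10, k + 3L))
  Linv[seq_len(k), seq_len(k), drop = FALSE]
}

#' Project aligned shapes into the tangent space at the consensus
#'
#' Orthogonally projects each aligned shape (as a 2k-vector) onto the linear
#' tangent space of shape space at the consensus, in which ordinary
#' multivariate statistics are valid. The consensus maps to the origin, and
#' Euclidean distances in tangent space approximate Procrustes distances to
#' first order.
#'
#' @param aligned a `parid_gpa` object.
#' @return tibble with `specimen_id`, `species`, `centroid_size` and the 2k
#'   tangent coordinates in columns `x1, y1, ..., xk, yk`. The consensus
#'   vector is kept in attribute `consensus`.
#' @export
tangent_project <- function(aligned) {
  stopifnot(inherits(aligned, "parid_gpa"))
  k <- dim(aligned$coords)[1L]
  n <- dim(aligned$coords)[3L]
  cvec <- as.vector(aligned$consensus)      # unit length by construction
  X <- t(apply(aligned$coords, 3L, as.vector))
  proj <- X - tcrossprod(X %*% cvec, cvec)  # x - (x.c) c
  # columns of X are (x1..xk, y1..yk): as.vector on a k x 2 matrix is column-major
  colnames(proj) <- c(paste0("x", seq_len(k)), paste0("y", seq_len(k)))
  ids <- dimnames(aligned$coords)[[3L]] %||% aligned$info$specimen_id
  out <- tibble::tibble(
    specimen_id = ids,
    species = aligned$info$species[match(ids, aligned$info$specimen_id)],
    centroid_size = unname(aligned$centroid_size[ids])
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(proj))
  attr(out, "consensus") <- cvec
  out
}

#' Coordinate columns of a tangent-space tibble
#' @param tangent tibble from [tangent_project()].
#' @return numeric matrix (specimens x coordinates) with specimen ids as rownames.
#' @export
tangent_matrix <- function(tangent) {
  cols <- grep("^[xy][0-9]+$", names(tangent), value = TRUE)
  m <- as.matrix(tangent[, cols])
  rownames(m) <- tangent$specimen_id
  m
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
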