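# Range-overlap distances (Jaccard-type D_O / D_AB) and the partial Mantel
# test of character divergence against distributional distance, controlling
# for phylogenetic distance.

#' Jaccard-type range-overlap index
#'
#' `D_O = O_AB / (S_A + S_B - O_AB)`: the proportion of the union of two
#' species' ranges that both occupy. 1 means identical ranges, 0 disjoint.
#'
#' @param s_a,s_b range areas of the two species (> 0).
#' @param o_ab overlap area, `0 <= o_ab <= min(s_a, s_b)`. Vectorized.
#' @return overlap proportion(s) in `[0, 1]`.
#' @export
overlap_index <- function(s_a, s_b, o_ab) {
  if (any(s_a <= 0) || any(s_b <= 0)) abort("range areas must be positive")
  if (any(o_ab < 0) || any(o_ab > pmin(s_a, s_b) + 1e-9 * pmax(s_a, s_b))) {
    abort("overlap area must lie in [0, min(S_A, S_B)]")
  }
  o_ab / (s_a + s_b - o_ab)
}

#' Geographic range-overlap distance matrix
#'
#' `D_AB = 1 - D_O` for every species pair. Pairs absent from the overlap
#' table are taken as disjoint (overlap 0), with a message, since an absent
#' polygon intersection means the ranges do not meet.
#'
#' @param ranges tibble with `species` and `area`.
#' @param overlaps long-format tibble with `species_a`, `species_b`,
#'   `overlap_area`.
#' @return labelled symmetric distance matrix with zero diagonal.
#' @export
overlap_distance_matrix <- function(ranges, overlaps) {
  sp <- ranges$species
  n <- length(sp)
  O <- matrix(0, n, n, dimnames = list(sp, sp))
  found <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(overlaps))) {
    i <- match(overlaps$species_a[[r]], sp)
    j <- match(overlaps$species_b[[r]], sp)
    if (is.na(i) || is.na(j)) next
    O[i, j] <- O[j, i] <- overlaps$overlap_area[[r]]
    found[i, j] <- found[j, i] <- TRUE
  }
  n_missing <- (sum(!found) - n) / 2
  if (n_missing > 0) {
    inform(sprintf("%d species pair(s) without an overlap entry treated as disjoint", n_missing))
  }
  D <- matrix(0, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- 1 - overlap_index(ranges$area[[i]], ranges$area[[j]], O[i, j])
  }
  D
}

#' Altitudinal overlap distance matrix
#'
#' Applies the same Jaccard-type index to altitudinal intervals: per pair,
#' `S` are the interval lengths, `O` the intersection length, and
#' `D_AB = 1 - O / (S_A + S_B - O)`. When both intervals are degenerate
#' points the distance is 0 if they coincide and 1 otherwise.
#'
#' @param ranges tibble with `species`, `alt_min`, `alt_max` (m).
#' @return labelled symmetric distance matrix with zero diagonal.
#' @export
altitudinal_overlap_distance <- function(ranges) {
  if (any(ranges$alt_min > ranges$alt_max)) abort("alt_min must not exceed alt_max")
  sp <- ranges$species
  n <- length(sp)
  D <- matrix(0, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sa <- ranges$alt_max[[i]] - ranges$alt_min[[i]]
    sb <- ranges$alt_max[[j]] - ranges$alt_min[[j]]
    o <- max(0, min(ranges$alt_max[[i]], ranges$alt_max[[j]]) -
               max(ranges$alt_min[[i]], ranges$alt_min[[j]]))
    if (sa + sb - o <= 0) {
      # both intervals are points: identical -> distance 0, else 1
      d <- if (ranges$alt_min[[i]] == ranges$alt_min[[j]]) 0 else 1
    } else {
      d <- 1 - o / (sa + sb - o)
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Patristic (phylogenetic) distance matrix
#'
#' Sum of branch lengths along the tip-to-tip path, used as the controlled
#' variable in the partial Mantel tests.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @return labelled symmetric distance matrix.
#' @export
phylogenetic_distance_matrix <- function(tree) {
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  cophenetic(tree)
}

#' @keywords internal
lower_vec <- function(m) m[lower.tri(m)]

#' Mantel and partial Mantel permutation tests
#'
#' Correlation between the off-diagonal entries of two distance matrices.
#' With a third matrix `C`, both `A` and `B` are first residualized on `C`
#' (ordinary least squares on the unfolded lower triangles) and the
#' correlation of the residuals is tested — the partial Mantel test.
#' Significance comes from jointly permuting the rows and columns of the
#' (residualized) `A` matrix; the default test is one-tailed for positive
#' association, with a +1-corrected p-value.
#'
#' @param A,B labelled symmetric distance matrices with matching labels.
#' @param C optional control matrix; `NULL` gives the simple Mantel test.
#' @param n_perm number of permutations (>= 99).
#' @param seed optional RNG seed.
#' @param tail `"one"` (positive association, default) or `"two"`.
#' @return object of class `parid_mantel`: tibble row with `r`, `p`,
#'   `n_perm`, `controlled`, `p_se` (binomial standard error of p).
#' @export
partial_mantel <- function(A, B, C = NULL, n_perm = 9999L, seed = NULL,
                           tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (n_perm < 99L) abort("need at least 99 permutations")
  labs <- rownames(A)
  if (is.null(labs) || !identical(labs, rownames(B)) ||
      (!is.null(C) && !identical(labs, rownames(C)))) {
    abort("distance matrices must share identical labels and order")
  }
  n <- nrow(A)
  a <- lower_vec(A)
  b <- lower_vec(B)
  if (sd(a) == 0 || sd(b) == 0) abort("zero variance among off-diagonal distances")
  if (!is.null(C)) {
    cv <- lower_vec(C)
    if (sd(cv) > 0) {
      a <- resid(lm(a ~ cv))
      b <- resid(lm(b ~ cv))
    }
    # a constant control changes nothing: partial reduces to simple Mantel
  }
  # matrices of (residual) values, permuted jointly over rows/columns
  RA <- matrix(0, n, n)
  RA[lower.tri(RA)] <- a
  RA <- RA + t(RA)
  RB <- matrix(0, n, n)
  RB[lower.tri(RB)] <- b
  RB <- RB + t(RB)
  r_obs <- cor(a, b)
  if (!is.null(seed)) set.seed(as.integer(seed))
  hits <- 0L
  lt <- lower.tri(RA)
  bv <- RB[lt]
  for (k in seq_len(n_perm)) {
    idx <- sample.int(n)
    rp <- cor(RA[idx, idx][lt], bv)
    hit <- if (tail == "one") rp >= r_obs else abs(rp) >= abs(r_obs)
    if (hit) hits <- hits + 1L
  }
  p <- (hits + 1L) / (n_perm + 1L)
  out <- tibble::tibble(
    r = r_obs, p = p, n_perm = as.integer(n_perm),
    controlled = !is.null(C),
    p_se = sqrt(p * (1 - p) / (n_perm + 1L))
  )
  class(out) <- c("parid_mantel", class(out))
  out
}

#' @export
tidy.parid_mantel <- function(x, ...) tibble::as_tibble(unclass(x))
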