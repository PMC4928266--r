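#' Default landmark role scheme for 21-point beak outlines
#'
#' The beak outline scheme uses three fixed landmarks (LM1 and LM2 at the
#' posterior intersections of the nares line with the upper-mandible outline,
#' LM3 at the beak tip) followed by nine semilandmarks along the upper profile
#' (LM1 to LM3) and nine along the lower profile (LM2 to LM3).
#'
#' @param n_points number of points per configuration.
#' @return character vector of `"fixed"`/`"semi"` flags. For 21 points the
#'   beak scheme is used; otherwise every point is `"fixed"`.
#' @export
default_roles <- function(n_points) {
  if (n_points == 21L) {
    c(rep("fixed", 3L), rep("semi", 18L))
  } else {
    rep("fixed", n_points)
  }
}

#' Curve structure of the 21-point beak scheme
#'
#' Point order along each outline curve, used to define sliding directions
#' (a semilandmark slides along the chord between its curve neighbours).
#'
#' @param n_points number of points per configuration.
#' @return list of integer vectors (point indices in curve order), or an
#'   empty list when no semilandmarks are defined.
#' @export
default_curves <- function(n_points) {
  if (n_points == 21L) {
    list(upper = c(1L, 4:12, 3L), lower = c(2L, 13:21, 3L))
  } else {
    list()
  }
}

# ---- landmark tibble <-> array ----------------------------------------------

#' Validate a landmark tibble
#'
#' A landmark tibble has one row per (specimen, point) with columns
#' `specimen_id`, `species`, `point`, `x`, `y`, `role`. All specimens must
#' share the same point count and role pattern.
#' @param landmarks landmark tibble.
#' @return the tibble, invisibly.
#' @keywords internal
validate_landmarks <- function(landmarks) {
  need <- c("specimen_id", "point", "x", "y")
  miss <- setdiff(need, names(landmarks))
  if (length(miss) > 0L) {
    abort(paste0("landmark data lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (!all(is.finite(landmarks$x)) || !all(is.finite(landmarks$y))) {
    abort("landmark coordinates must all be finite")
  }
  counts <- table(landmarks$specimen_id)
  if (length(unique(as.integer(counts))) != 1L) {
    abort("all specimens must have the same number of landmarks")
  }
  invisible(landmarks)
}

#' Convert a landmark tibble to a k x 2 x n array
#' @param landmarks landmark tibble.
#' @return array with dimnames on the specimen margin.
#' @keywords internal
lm_array <- function(landmarks) {
  validate_landmarks(landmarks)
  ids <- unique(landmarks$specimen_id)
  k <- sum(landmarks$specimen_id == ids[[1L]])
  ord <- order(match(landmarks$specimen_id, ids), landmarks$point)
  xs <- landmarks$x[ord]
  ys <- landmarks$y[ord]
  arr <- array(NA_real_, dim = c(k, 2L, length(ids)),
               dimnames = list(NULL, c("x", "y"), ids))
  arr[, 1L, ] <- xs
  arr[, 2L, ] <- ys
  arr
}

#' Convert a k x 2 x n array back to a landmark tibble
#' @param arr coordinate array.
#' @param info optional tibble with `specimen_id`, `species`.
#' @param roles per-point role flags.
#' @keywords internal
lm_tibble <- function(arr, info = NULL, roles = NULL) {
  k <- dim(arr)[1L]
  n <- dim(arr)[3L]
  ids <- dimnames(arr)[[3L]]
  if (is.null(ids)) ids <- sprintf("spec_%03d", seq_len(n))
  if (is.null(roles)) roles <- default_roles(k)
  species <- rep(NA_character_, n)
  if (!is.null(info) && "species" %in% names(info)) {
    species <- info$species[match(ids, info$specimen_id)]
  }
  tibble::tibble(
    specimen_id = rep(ids, each = k),
    species = rep(species, each = k),
    point = rep(seq_len(k), times = n),
    x = as.vector(arr[, 1L, ]),
    y = as.vector(arr[, 2L, ]),
    role = rep(roles, times = n)
  )
}

#' Specimen-level metadata of a landmark tibble
#' @keywords internal
lm_info <- function(landmarks) {
  landmarks |>
    dplyr::distinct(.data$specimen_id, .keep_all = TRUE) |>
    dplyr::select(dplyr::any_of(c("specimen_id", "species")))
}

#' Per-point roles of a landmark tibble
#' @keywords internal
lm_roles <- function(landmarks) {
  first <- landmarks$specimen_id == landmarks$specimen_id[[1L]]
  if ("role" %in% names(landmarks)) {
    landmarks$role[first][order(landmarks$point[first])]
  } else {
    default_roles(sum(first))
  }
}

# ---- misc -------------------------------------------------------------------

#' Trait column names used throughout the pipeline
#' @keywords internal
trait_names <- function() {
  c("body_weight", "body_length", "wing_length",
    "tail_length", "tarsus_length", "culmen_length")
}

#' Derive per-stage seeds from one master seed
#'
#' One global stream is seeded once and integer sub-seeds are drawn from it,
#' so stages are reproducible yet statistically independent.
#' @keywords internal
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Build a labelled symmetric distance matrix
#' @keywords internal
as_distance_matrix <- function(values, labels) {
  m <- as.matrix(values)
  dimnames(m) <- list(labels, labels)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 0
  m
}

#' Long-format view of a labelled distance matrix
#'
#' @param d symmetric matrix with dimnames.
#' @return tibble with one row per unordered pair (`item1`, `item2`,
#'   `distance`).
#' @export
tidy_dist <- function(d) {
  labs <- rownames(d)
  idx <- which(lower.tri(d), arr.ind = TRUE)
  tibble::tibble(
    item1 = labs[idx[, 2L]],
    item2 = labs[idx[, 1L]],
    distance = d[idx]
  )
}
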