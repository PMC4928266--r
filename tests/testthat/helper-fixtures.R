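# Shared fixtures, all generated in code.

# A random k-point planar shape (matrix form).
random_shape <- function(k = 12L) {
  matrix(rnorm(2L * k), k, 2L)
}

# Apply a random similarity transform (rotation, scaling, translation).
random_similarity <- function(m) {
  ang <- runif(1L, 0, 2 * pi)
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L, 2L)
  runif(1L, 0.2, 5) * m %*% R + matrix(runif(2L, -10, 10), nrow(m), 2L, byrow = TRUE)
}

# Landmark tibble of n noisy beak outlines (21 points, paper roles).
outline_set <- function(n = 6L, noise = 0.02) {
  purrr::map_dfr(seq_len(n), function(i) {
    cfg <- generate_beak_outline(
      length = 10 * exp(rnorm(1L, 0, 0.08)),
      depth = 4 * exp(rnorm(1L, 0, 0.08)),
      curvature = min(max(rnorm(1L, 0.3, 0.08), 0), 0.8),
      specimen_id = sprintf("s%02d", i)
    )
    cfg$x <- cfg$x + rnorm(21L, 0, noise)
    cfg$y <- cfg$y + rnorm(21L, 0, noise)
    cfg
  })
}

# Landmark tibble from a list of coordinate matrices.
shapes_to_landmarks <- function(mats, roles = NULL) {
  purrr::map2_dfr(mats, seq_along(mats), function(m, i) {
    tibble::tibble(
      specimen_id = sprintf("s%02d", i),
      species = NA_character_,
      point = seq_len(nrow(m)),
      x = m[, 1L], y = m[, 2L],
      role = roles %||% rep("fixed", nrow(m))
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Align one GPA consensus frame onto another and return the rotated coords.
rotate_set_onto <- function(g_from, g_to) {
  R <- svd(crossprod(g_from$consensus, g_to$consensus))
  rot <- R$u %*% diag(c(1, sign(det(R$u %*% t(R$v))))) %*% t(R$v)
  out <- g_from$coords
  for (i in seq_len(dim(out)[3L])) out[, , i] <- out[, , i] %*% rot
  out
}

# A low-noise simulation configuration for recovery experiments.
recovery_config <- function(seed, n_species = 6L, n_per_species = 10L,
                            culmen_slope = 1e-4, landmarks = FALSE) {
  zero <- setNames(rep(0, 6L), c("body_weight", "body_length", "wing_length",
                                 "tail_length", "tarsus_length", "culmen_length"))
  alt <- zero
  alt[["culmen_length"]] <- culmen_slope
  simulation_config(
    n_species = n_species, n_per_species = n_per_species,
    bm_rate_size = 0, bm_rate_trait = 0,
    within_species_sd = 0.05, altitude_slopes = alt,
    landmark_noise_sd = 0, jitter_placement = FALSE,
    generate_landmarks = landmarks, seed = seed
  )
}
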