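# Synthetic study generator: pure-birth trees, Brownian-motion trait and
# beak-parameter evolution, within-species noise, altitudinal clines,
# partially overlapping ranges. Every downstream stage is testable against
# the recorded generating truth without any external data.

#' Simulate a pure-birth phylogeny
#'
#' A rooted, binary, ultrametric Yule tree via [ape::rphylo()]. By default the
#' tree is rescaled to unit root-to-tip depth so Brownian-motion rates are
#' expressed per total tree depth, which keeps simulated trait variances
#' comparable across seeds.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed RNG seed.
#' @param depth total root-to-tip depth to rescale to; `NULL` keeps the
#'   natural depth.
#' @param tip_labels optional tip labels; default `sp01, sp02, ...`.
#' @return an ultrametric `phylo` object with strictly positive branch
#'   lengths.
#' @export
simulate_tree <- function(n_tips, seed = NULL, depth = 1, tip_labels = NULL) {
  if (n_tips < 2L) abort("need at least two tips")
  if (!is.null(seed)) set.seed(as.integer(seed))
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$tip.label <- tip_labels %||% sprintf("sp%02d", seq_len(n_tips))
  if (!is.null(depth)) {
    h <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * (depth / h)
  }
  tree
}

#' Simulate tip values of a trait evolving by Brownian motion
#'
#' Tip values are drawn from a multivariate normal with mean `root_value` and
#' covariance `rate * C(tree)`, where `C` is the shared-path-length matrix of
#' the tree ([phylo_vcv()]). With `rate = 0` every tip equals the root value.
#'
#' @param tree a `phylo` object.
#' @param root_value trait value at the root.
#' @param rate Brownian-motion rate (variance per unit branch length), >= 0.
#' @param seed optional RNG seed.
#' @return named numeric vector of tip values.
#' @export
simulate_bm_traits <- function(tree, root_value = 0, rate = 1, seed = NULL) {
  if (rate < 0) abort("rate must be nonnegative")
  if (!is.null(seed)) set.seed(as.integer(seed))
  C <- phylo_vcv(tree)
  n <- nrow(C)
  if (rate == 0) return(setNames(rep(root_value, n), rownames(C)))
  L <- chol(rate * C + diag(1e-12 * rate * max(diag(C)), n))
  setNames(root_value + drop(crossprod(L, rnorm(n))), rownames(C))
}

#' Generate a parametric beak outline configuration
#'
#' Builds the 21-point beak scheme from three interpretable parameters. LM1
#' sits at the posterior top of the profile `(0, depth)`, LM2 at the
#' posterior bottom `(0, 0)`, LM3 at the tip. The upper (LM1 to LM3) and
#' lower (LM2 to LM3) profiles are quadratic Bezier arcs whose bow is
#' controlled by `curvature` (0 gives straight segments); nine semilandmarks
#' are placed at equal arc-length spacing along each profile (measured on a
#' 512-sample chord-length polyline).
#'
#' @param length beak length (LM2 to tip distance along x), > 0.
#' @param depth posterior profile height (LM2 to LM1 distance), > 0.
#' @param curvature bow of the profiles; larger values bow the upper profile
#'   further from its chord and decurve the tip.
#' @param specimen_id,species labels for the returned tibble.
#' @return landmark tibble of one 21-point configuration (points 1-3 fixed,
#'   4-21 semi).
#' @export
generate_beak_outline <- function(length, depth, curvature = 0,
                                  specimen_id = "spec_001", species = NA_character_) {
  if (length <= 0 || depth <= 0) abort("length and depth must be positive")
  lm1 <- c(0, depth)
  lm2 <- c(0, 0)
  lm3 <- c(length, depth / 2 * (1 - curvature))
  upper <- bezier_points(lm1, lm3, bow = curvature * depth / 2, n_out = 9L)
  lower <- bezier_points(lm2, lm3, bow = curvature * depth / 4, n_out = 9L)
  pts <- unname(rbind(lm1, lm2, lm3, upper, lower))
  tibble::tibble(
    specimen_id = specimen_id, species = species, point = 1:21,
    x = pts[, 1L], y = pts[, 2L], role = default_roles(21L)
  )
}

# Interior points of a quadratic Bezier arc from a to b, control point at the
# chord midpoint offset by `bow` along the left normal, resampled to equal
# arc length on a 512-sample polyline.
#' @keywords internal
bezier_points <- function(a, b, bow, n_out) {
  chord <- b - a
  nrm <- c(-chord[[2L]], chord[[1L]])
  nrm <- nrm / sqrt(sum(nrm^2))
  ctrl <- (a + b) / 2 + bow * nrm
  t <- seq(0, 1, length.out = 512L)
  curve <- cbind(
    (1 - t)^2 * a[[1L]] + 2 * (1 - t) * t * ctrl[[1L]] + t^2 * b[[1L]],
    (1 - t)^2 * a[[2L]] + 2 * (1 - t) * t * ctrl[[2L]] + t^2 * b[[2L]]
  )
  seglen <- sqrt(rowSums(diff(curve)^2))
  s <- c(0, cumsum(seglen))
  targets <- s[[512L]] * seq_len(n_out) / (n_out + 1L)
  t(vapply(targets, function(tt) {
    i <- findInterval(tt, s, rightmost.closed = TRUE)
    w <- (tt - s[[i]]) / max(s[[i + 1L]] - s[[i]], 1e-300)
    curve[i, ] * (1 - w) + curve[i + 1L, ] * w
  }, numeric(2L)))
}

#' Generate species ranges with a controllable overlap level
#'
#' Species ranges are discs: centres sit on a circle whose radius shrinks as
#' `overlap_level` grows, so `overlap_level = 1` gives identical ranges (all
#' pairwise overlap proportions 1) and `overlap_level = 0` gives pairwise
#' disjoint ranges. Pairwise overlap areas are exact disc-intersection (lens)
#' areas, which automatically satisfy `0 <= O_AB <= min(S_A, S_B)`.
#' Altitudinal intervals blend the same way between species-specific and a
#' common interval.
#'
#' @param n_species number of species (>= 2).
#' @param overlap_level in `[0, 1]`.
#' @param seed optional RNG seed.
#' @param species optional species labels.
#' @param base_radius disc radius scale (km); areas come out near
#'   `pi * base_radius^2`.
#' @param alt_base,alt_spread altitudinal midpoints are spread over
#'   `[alt_base, alt_base + alt_spread]` m.
#' @return list with tibbles `ranges` (`species`, `area`, `alt_min`,
#'   `alt_max`) and `overlaps` (`species_a`, `species_b`, `overlap_area`).
#' @export
generate_ranges <- function(n_species, overlap_level = 0.5, seed = NULL,
                            species = NULL, base_radius = 300,
                            alt_base = 200, alt_spread = 3600) {
  if (n_species < 2L) abort("need at least two species")
  if (overlap_level < 0 || overlap_level > 1) abort("overlap_level must be in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  species <- species %||% sprintf("sp%02d", seq_len(n_species))
  L <- overlap_level
  radii <- base_radius * (1 + (1 - L) * runif(n_species, -0.2, 0.2))
  # centres on a circle large enough that L = 0 separates every pair
  theta <- 2 * pi * (seq_len(n_species) - 1L) / n_species
  rho <- 1.3 * base_radius * 1.2 / sin(pi / n_species)
  centres <- (1 - L) * rho * cbind(cos(theta), sin(theta))
  overlaps <- tidyr::expand_grid(i = seq_len(n_species), j = seq_len(n_species)) |>
    dplyr::filter(.data$i < .data$j) |>
    dplyr::mutate(
      species_a = species[.data$i], species_b = species[.data$j],
      overlap_area = purrr::map2_dbl(.data$i, .data$j, function(i, j) {
        disc_lens_area(radii[[i]], radii[[j]], sqrt(sum((centres[i, ] - centres[j, ])^2)))
      })
    ) |>
    dplyr::select("species_a", "species_b", "overlap_area")
  mids <- alt_base + alt_spread * ((seq_len(n_species) - 0.5) / n_species)[sample.int(n_species)]
  halfw <- runif(n_species, 200, 800)
  common_mid <- alt_base + alt_spread / 2
  common_half <- alt_spread / 2
  mids <- (1 - L) * mids + L * common_mid
  halfw <- (1 - L) * halfw + L * common_half
  list(
    ranges = tibble::tibble(
      species = species, area = pi * radii^2,
      alt_min = pmax(mids - halfw, 0), alt_max = mids + halfw
    ),
    overlaps = overlaps
  )
}

# Intersection (lens) area of two discs with radii r1, r2 at centre distance d.
#' @keywords internal
disc_lens_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  tri <- 0.5 * sqrt(pmax(0, (-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2)))
  a1 + a2 - tri
}

#' Configuration of a synthetic study
#'
#' Bundles every generating parameter of [generate_study()]. Defaults emulate
#' a parid-like radiation: ancestral trait means typical of tits, a latent
#' log body size evolving by Brownian motion with allometric scaling of the
#' six linear traits, small independent per-trait Brownian deviations,
#' log-normal within-species measurement noise, altitudinal clines on culmen,
#' tarsus and body weight, and partially overlapping ranges. The paper-scale
#' study is 14 species; within-species variances are unreported there, so the
#' noise defaults are the package's own choices (see the methods vignette).
#'
#' @param n_species,n_per_species study dimensions (each >= 2 and >= 1).
#' @param bm_rate_size Brownian rate of the latent log body size (variance
#'   per unit tree depth).
#' @param bm_rate_trait per-trait independent Brownian rate on the log scale.
#' @param within_species_sd within-species SD of log traits (recycled over
#'   the six traits).
#' @param allometry_slopes log-log slopes of the six traits on the latent log
#'   size (`body_weight` scales with the cube of linear size).
#' @param altitude_slopes change in each log trait per metre of altitude.
#' @param beak_params_mean ancestral `(length, depth, curvature)` of the beak
#'   outline.
#' @param beak_bm_rates Brownian rates for log length, log depth and
#'   curvature of the beak.
#' @param beak_within_sd within-species SD of log length, log depth and
#'   curvature.
#' @param landmark_noise_sd digitization noise SD as a fraction of beak
#'   length, added to every landmark coordinate.
#' @param jitter_placement apply a random rotation/translation/scaling to each
#'   digitized configuration (removed again by superimposition).
#' @param generate_landmarks digitize beak outlines (default). Replicate-heavy
#'   recovery experiments that only use the measurement table can turn this
#'   off for speed; the study then has an empty landmark tibble.
#' @param overlap_level range overlap level in `[0, 1]` (see
#'   [generate_ranges()]).
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `parid_sim_config`.
#' @export
simulation_config <- function(n_species = 14L, n_per_species = 20L,
                              bm_rate_size = 0.03, bm_rate_trait = 0.01,
                              within_species_sd = 0.05,
                              allometry_slopes = c(body_weight = 3, body_length = 1,
                                                   wing_length = 1, tail_length = 1,
                                                   tarsus_length = 1, culmen_length = 1),
                              altitude_slopes = c(body_weight = 2e-5, body_length = 0,
                                                  wing_length = 0, tail_length = 0,
                                                  tarsus_length = 3e-5, culmen_length = 5e-5),
                              beak_params_mean = c(length = 10, depth = 4, curvature = 0.3),
                              beak_bm_rates = c(0.01, 0.01, 0.005),
                              beak_within_sd = c(0.03, 0.03, 0.02),
                              landmark_noise_sd = 0.005,
                              jitter_placement = TRUE,
                              generate_landmarks = TRUE,
                              overlap_level = 0.5, seed = 1L) {
  if (n_species < 2L) abort("n_species must be at least 2")
  if (n_per_species < 1L) abort("n_per_species must be at least 1")
  if (bm_rate_size < 0 || bm_rate_trait < 0) abort("Brownian rates must be nonnegative")
  within_species_sd <- rep_len(within_species_sd, 6L)
  if (any(within_species_sd < 0)) abort("within_species_sd must be nonnegative")
  structure(
    list(n_species = as.integer(n_species), n_per_species = as.integer(n_per_species),
         bm_rate_size = bm_rate_size, bm_rate_trait = bm_rate_trait,
         within_species_sd = setNames(within_species_sd, trait_names()),
         allometry_slopes = allometry_slopes[trait_names()],
         altitude_slopes = altitude_slopes[trait_names()],
         beak_params_mean = beak_params_mean, beak_bm_rates = beak_bm_rates,
         beak_within_sd = beak_within_sd, landmark_noise_sd = landmark_noise_sd,
         jitter_placement = isTRUE(jitter_placement),
         generate_landmarks = isTRUE(generate_landmarks),
         overlap_level = overlap_level, seed = as.integer(seed)),
    class = "parid_sim_config"
  )
}

#' Generate a complete synthetic study
#'
#' Simulates a pure-birth tree, evolves species mean log traits and beak
#' outline parameters by Brownian motion along it, draws individuals with
#' independent Gaussian noise on the log scale, applies allometric scaling to
#' a latent log body size and altitudinal clines to individual altitudes
#' (uniform within each species' altitudinal interval), digitizes one beak
#' outline per individual (with landmark noise and, optionally, a random
#' placement transform), and places partially overlapping ranges. The `truth`
#' element records every generating draw, sufficient to recompute the
#' expected value of every generated quantity.
#'
#' @param config a `parid_sim_config` from [simulation_config()].
#' @return object of class `parid_study`: list with `tree`, `landmarks`,
#'   `measurements`, `ranges`, `overlaps`, `truth`, `config`.
#' @export
generate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "parid_sim_config"))
  seeds <- derive_seeds(config$seed, 6L)
  traits <- trait_names()
  base_log <- log(c(body_weight = 15, body_length = 130, wing_length = 65,
                    tail_length = 55, tarsus_length = 17, culmen_length = 10))

  tree <- simulate_tree(config$n_species, seed = seeds[[1L]])
  sp <- tree$tip.label

  # species-level evolution: latent log size + independent per-trait deviations
  set.seed(seeds[[2L]])
  size_u <- simulate_bm_traits(tree, 0, config$bm_rate_size)
  trait_dev <- vapply(traits, function(v) simulate_bm_traits(tree, 0, config$bm_rate_trait),
                      numeric(config$n_species))
  beak_mean <- cbind(
    length = exp(simulate_bm_traits(tree, log(config$beak_params_mean[["length"]]),
                                    config$beak_bm_rates[[1L]])),
    depth = exp(simulate_bm_traits(tree, log(config$beak_params_mean[["depth"]]),
                                   config$beak_bm_rates[[2L]])),
    curvature = pmin(pmax(simulate_bm_traits(tree, config$beak_params_mean[["curvature"]],
                                             config$beak_bm_rates[[3L]]), 0), 0.9)
  )

  rg <- generate_ranges(config$n_species, config$overlap_level, seed = seeds[[3L]], species = sp)

  # species mean log traits before the altitude term
  mean_log <- sapply(traits, function(v) {
    base_log[[v]] + config$allometry_slopes[[v]] * size_u + trait_dev[, v]
  })
  rownames(mean_log) <- sp

  set.seed(seeds[[4L]])
  n_ind <- config$n_species * config$n_per_species
  meas <- tidyr::expand_grid(species = sp, rep = seq_len(config$n_per_species)) |>
    dplyr::mutate(specimen_id = sprintf("%s_%02d", .data$species, .data$rep))
  alt_lim <- rg$ranges[match(meas$species, rg$ranges$species), ]
  meas$altitude <- runif(n_ind, alt_lim$alt_min, alt_lim$alt_max)
  for (v in traits) {
    mu <- mean_log[meas$species, v] + config$altitude_slopes[[v]] * meas$altitude
    meas[[v]] <- unname(exp(mu + rnorm(n_ind, 0, config$within_species_sd[[v]])))
  }
  measurements <- meas[, c("specimen_id", "species", traits, "altitude")]

  # individual beak outlines
  set.seed(seeds[[5L]])
  ind_len <- exp(log(beak_mean[meas$species, "length"]) + rnorm(n_ind, 0, config$beak_within_sd[[1L]]))
  ind_dep <- exp(log(beak_mean[meas$species, "depth"]) + rnorm(n_ind, 0, config$beak_within_sd[[2L]]))
  ind_cur <- pmin(pmax(beak_mean[meas$species, "curvature"] +
                         rnorm(n_ind, 0, config$beak_within_sd[[3L]]), 0), 0.9)
  set.seed(seeds[[6L]])
  landmarks <- if (!config$generate_landmarks) {
    tibble::tibble(specimen_id = character(0), species = character(0),
                   point = integer(0), x = numeric(0), y = numeric(0),
                   role = character(0))
  } else purrr::map_dfr(seq_len(n_ind), function(i) {
    cfg <- generate_beak_outline(ind_len[[i]], ind_dep[[i]], ind_cur[[i]],
                                 specimen_id = meas$specimen_id[[i]],
                                 species = meas$species[[i]])
    pts <- cbind(cfg$x, cfg$y)
    if (config$landmark_noise_sd > 0) {
      pts <- pts + matrix(rnorm(42L, 0, config$landmark_noise_sd * ind_len[[i]]), 21L, 2L)
    }
    if (config$jitter_placement) {
      ang <- runif(1L, -pi / 6, pi / 6)
      R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L, 2L)
      pts <- runif(1L, 0.9, 1.1) * pts %*% R +
        matrix(runif(2L, -5, 5), 21L, 2L, byrow = TRUE)
    }
    cfg$x <- pts[, 1L]; cfg$y <- pts[, 2L]
    cfg
  })

  structure(
    list(tree = tree, landmarks = landmarks, measurements = measurements,
         ranges = rg$ranges, overlaps = rg$overlaps,
         truth = list(base_log = base_log, size_u = size_u, trait_dev = trait_dev,
                      mean_log = mean_log, beak_mean = beak_mean,
                      beak_individual = tibble::tibble(specimen_id = meas$specimen_id,
                                                       length = ind_len, depth = ind_dep,
                                                       curvature = ind_cur),
                      allometry_slopes = config$allometry_slopes,
                      altitude_slopes = config$altitude_slopes,
                      seeds = seeds),
         config = config),
    class = "parid_study"
  )
}

#' @export
print.parid_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d species x %d individuals (seed %d)\n",
              x$config$n_species, x$config$n_per_species, x$config$seed))
  cat(sprintf("  %d measurement records, %d landmark configurations\n",
              nrow(x$measurements), dplyr::n_distinct(x$landmarks$specimen_id)))
  invisible(x)
}
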