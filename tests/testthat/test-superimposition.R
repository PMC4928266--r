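test_that("centroid size identities hold", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)
  set.seed(1)
  m <- random_shape(9L)
  expect_equal(centroid_size(3.7 * m), 3.7 * centroid_size(m), tolerance = 1e-12)
  expect_equal(centroid_size(m + matrix(c(5, -2), 9L, 2L, byrow = TRUE)),
               centroid_size(m), tolerance = 1e-12)
  expect_error(centroid_size(matrix(1, 4L, 2L)), "coincident")
  # tibble interface
  cs <- centroid_size(shapes_to_landmarks(list(sq, 2 * sq)))
  expect_equal(cs$centroid_size, c(sqrt(2), 2 * sqrt(2)), tolerance = 1e-12)
})

test_that("ordinary Procrustes fit removes similarity transforms but not reflections", {
  set.seed(2)
  ref <- paridmorph:::.center_unit(random_shape(10L))
  ang <- pi / 2
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L, 2L)
  moved <- ref %*% R + matrix(c(3, 4), 10L, 2L, byrow = TRUE)
  fit <- procrustes_fit(moved, ref)
  expect_lt(fit$distance, 1e-12)

  mirrored <- ref %*% diag(c(-1, 1))
  expect_gt(procrustes_fit(mirrored, ref)$distance, 0.1)

  # idempotence
  fit2 <- procrustes_fit(fit$aligned, ref)
  expect_lt(max(abs(fit2$aligned - fit$aligned)), 1e-12)

  expect_error(procrustes_fit(ref[1:5, ], ref), "mismatch")
})

test_that("GPA collapses similarity copies of one shape to the consensus", {
  set.seed(3)
  base <- random_shape(8L)
  g <- gpa(shapes_to_landmarks(lapply(1:5, function(i) random_similarity(base))))
  for (i in 1:5) expect_lt(max(abs(g$coords[, , i] - g$consensus)), 1e-9)
  expect_lt(g$sum_sq, 1e-16)
})

test_that("GPA output satisfies the aligned-set invariants", {
  set.seed(4)
  g <- gpa(outline_set(7L))
  for (i in seq_len(dim(g$coords)[3L])) {
    expect_lt(max(abs(colMeans(g$coords[, , i]))), 1e-9)
  }
  expect_equal(sqrt(sum(paridmorph:::.center_unit(g$consensus)^2)), 1, tolerance = 1e-9)
  expect_equal(sqrt(sum(g$consensus^2)), 1, tolerance = 1e-9)
  expect_equal(length(g$centroid_size), dim(g$coords)[3L])
  expect_true(all(g$centroid_size > 0))
})

test_that("GPA is invariant to random similarity transforms of its inputs", {
  set.seed(5)
  for (trial in 1:50) {
    base <- random_shape(8L)
    mats <- lapply(1:6, function(i) base + 0.1 * random_shape(8L))
    g1 <- gpa(shapes_to_landmarks(mats))
    g2 <- gpa(shapes_to_landmarks(lapply(mats, random_similarity)))
    aligned2 <- rotate_set_onto(g2, g1)
    expect_lt(max(abs(aligned2 - g1$coords)), 1e-6)
  }
})

test_that("GPA is equivariant under permutation of the inputs and idempotent", {
  set.seed(6)
  lms <- outline_set(5L)
  g <- gpa(lms)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  ids <- unique(lms$specimen_id)
  lms_p <- dplyr::arrange(lms, match(specimen_id, ids[perm]), point)
  g_p <- gpa(lms_p)
  expect_equal(g_p$coords[, , ids[perm]], g$coords[, , ids[perm]], tolerance = 1e-9)
  # consensus is a fixed point: re-running on aligned output converges immediately
  g2 <- gpa(g$coords)
  expect_equal(g2$iterations, 1L)
  expect_lt(max(abs(g2$consensus - g$consensus)), 1e-9)
})

test_that("two-shape consensus is Procrustes-equidistant from both", {
  set.seed(7)
  g <- gpa(shapes_to_landmarks(list(random_shape(9L), random_shape(9L))))
  d1 <- procrustes_distance(g$coords[, , 1L], g$consensus)
  d2 <- procrustes_distance(g$coords[, , 2L], g$consensus)
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("Procrustes distance is a pseudometric on configurations", {
  set.seed(8)
  a <- random_shape(8L)
  b <- random_shape(8L)
  expect_equal(procrustes_distance(a, a), 0, tolerance = 1e-12)
  expect_equal(procrustes_distance(a, b), procrustes_distance(b, a), tolerance = 1e-12)
  expect_equal(procrustes_distance(random_similarity(a), b),
               procrustes_distance(a, b), tolerance = 1e-9)
  for (i in 1:1000) {
    x <- random_shape(6L); y <- random_shape(6L); z <- random_shape(6L)
    expect_lte(procrustes_distance(x, z),
               procrustes_distance(x, y) + procrustes_distance(y, z) + 1e-12)
  }
  expect_error(procrustes_distance(a, b[1:5, ]), "mismatch")
})

test_that("sliding is a no-op on identical specimens and never moves fixed landmarks", {
  cfgs <- purrr::map_dfr(1:4, function(i) {
    generate_beak_outline(10, 4, 0.4, specimen_id = sprintf("s%02d", i))
  })
  g <- gpa(cfgs)
  slid <- slide_semilandmarks(g)
  expect_lt(max(abs(slid$coords - g$coords)), 1e-9)

  set.seed(9)
  g2 <- gpa(outline_set(6L))
  slid_once <- slide_semilandmarks(g2, resuperimpose = FALSE)
  fixed <- which(g2$roles == "fixed")
  expect_identical(slid_once$coords[fixed, , ], g2$coords[fixed, , ])
  expect_false(identical(slid_once$coords[-fixed, , ], g2$coords[-fixed, , ]))
})

test_that("sliding never increases the total Procrustes sum of squares", {
  set.seed(10)
  for (i in 1:100) {
    g <- gpa(outline_set(5L, noise = runif(1L, 0.01, 0.08)))
    slid <- slide_semilandmarks(g)
    expect_lte(slid$sum_sq, g$sum_sq + 1e-12)
  }
})

test_that("bending-energy sliding reduces summed bending energy to the consensus", {
  set.seed(11)
  g <- gpa(outline_set(6L, noise = 0.05))
  be <- paridmorph:::bending_energy_matrix(g$consensus)
  energy <- function(coords) {
    sum(vapply(seq_len(dim(coords)[3L]), function(i) {
      d <- coords[, , i] - g$consensus
      sum(diag(t(d) %*% be %*% d))
    }, numeric(1L)))
  }
  slid <- slide_semilandmarks(g, method = "bending", resuperimpose = FALSE)
  expect_lt(energy(slid$coords), energy(g$coords))
  expect_identical(slide_semilandmarks(g, method = "none"), g)
})

test_that("sliding rejects configurations without usable semilandmarks", {
  set.seed(12)
  g <- gpa(shapes_to_landmarks(list(random_shape(6L), random_shape(6L))))
  expect_error(slide_semilandmarks(g), "no semilandmarks")
  # semilandmark at a curve end has no anchor
  lms <- outline_set(3L)
  g2 <- gpa(lms)
  expect_error(
    slide_semilandmarks(g2, curves = list(c(4L, 5L, 6L))),
    "curve end"
  )
})

test_that("tangent projection sends the consensus to zero and is locally isometric", {
  set.seed(13)
  g <- gpa(outline_set(8L, noise = 0.01))
  tg <- tangent_project(g)
  M <- tangent_matrix(tg)
  cvec <- attr(tg, "consensus")
  # the consensus itself projects to the origin
  expect_lt(max(abs(cvec - cvec %*% tcrossprod(cvec))), 1e-12)
  # linearity of the projection operator
  P <- diag(length(cvec)) - tcrossprod(cvec)
  x <- rnorm(length(cvec))
  expect_equal(drop(P %*% (2.5 * x)), 2.5 * drop(P %*% x), tolerance = 1e-12)
  # tangent distances approximate Procrustes distances to first order
  n <- nrow(M)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dp <- procrustes_distance(g$coords[, , i], g$coords[, , j])
    if (dp < 0.05 && dp > 1e-6) {
      dt <- sqrt(sum((M[i, ] - M[j, ])^2))
      expect_lt(abs(dt - dp) / dp, 0.01)
    }
  }
})
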