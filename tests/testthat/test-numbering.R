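test_that("depth arrays are numbered along their axis from the deep end", {
  L <- cbind(seq(0, 45, by = 5), 0, 0)
  sp <- electrode_spec("depth", 1, 10, pitch = 5, prefix = "D")
  es <- number_depth(electrodes(L, sp), deep_end = c(0, 0, 0))
  expect_equal(es$index, 1:10)
  es_rev <- number_depth(electrodes(L, sp), deep_end = c(45, 0, 0))
  expect_equal(es_rev$index, 10:1)

  # permutation invariance of the index-to-coordinate mapping
  withr::with_seed(5, perm <- sample(10))
  es_p <- number_depth(electrodes(L[perm, ], sp), deep_end = c(0, 0, 0))
  expect_equal(es_p$x[order(es_p$index)], es$x[order(es$index)])

  # jitter below half pitch preserves the ordering
  withr::with_seed(8, {
    for (rep in 1:20) {
      Lj <- L + matrix(rnorm(30, 0, 0.3), 10, 3)
      esj <- number_depth(electrodes(Lj, sp), deep_end = c(0, 0, 0))
      expect_equal(order(Lj[, 1]), order(esj$index))
    }
  })

  expect_error(number_depth(electrodes(matrix(1, 4, 3),
                                       electrode_spec("depth", 1, 4, 5)),
                            deep_end = c(0, 0, 0)),
               "coincide")
  expect_error(number_depth(electrodes(L, sp)), "deep_end or mask")
})

test_that("the mask resolves the deep end when no hint is given", {
  mask <- ball_mask(25, 64L)
  # array along +x: tip at the center (deep), tail near the boundary
  L <- cbind(seq(0, 21, by = 3), 0, 0)
  sp <- electrode_spec("depth", 1, 8, pitch = 3, prefix = "D")
  es <- number_depth(electrodes(L, sp), mask = mask)
  expect_equal(es$index[1], 1)           # x = 0 is deepest
  expect_equal(es$index[8], 8)
})

test_that("rank-2 PCA projection preserves planar geometry", {
  g <- as.matrix(expand.grid(x = seq(0, 30, 10), y = seq(0, 40, 10)))
  L <- cbind(g, 0)[, c(1, 2, 3)]
  # rotate into a tilted plane
  th <- 0.7
  R <- rbind(c(cos(th), 0, -sin(th)), c(0, 1, 0), c(sin(th), 0, cos(th)))
  p2 <- project_pca2(L %*% t(R))
  expect_equal(as.matrix(dist(p2)), as.matrix(dist(L)), tolerance = 1e-9,
               ignore_attr = TRUE)

  # shallow spherical cap: pairwise 2D distances within 5% of 3D chords
  tr <- ieegloc:::phantom_truth_coords(
    phantom_grid(4, 4, pitch = 10, sphere_center = c(0, 0, 0),
                 sphere_radius = 80, cap_axis = c(0, 0, 1)),
    c(0, 0, 0), 80)
  Lc <- cbind(tr$x, tr$y, tr$z)
  d3 <- as.matrix(dist(Lc)); d2 <- as.matrix(dist(project_pca2(Lc)))
  rel <- abs(d2 - d3)[upper.tri(d3)] / d3[upper.tri(d3)]
  expect_lt(max(rel), 0.05)

  expect_error(project_pca2(cbind(1:5, 2 * (1:5), 0.5 * (1:5))), "collinear")
  expect_error(project_pca2(matrix(0, 2, 3)), "at least 3")
})

test_that("hull corners are the four largest transition angles", {
  g <- as.matrix(expand.grid(x = seq(0, 40, 10), y = seq(0, 30, 10)))
  hc <- hull_corners(g)
  corner_pts <- g[hc$corner_ids, ]
  expect_setequal(paste(corner_pts[, 1], corner_pts[, 2]),
                  c("0 0", "40 0", "0 30", "40 30"))
  corner_angles <- hc$angles[match(hc$corner_ids, hc$hull_ids)]
  expect_equal(corner_angles, rep(90, 4), tolerance = 1e-6)
  edge_angles <- hc$angles[-match(hc$corner_ids, hc$hull_ids)]
  if (length(edge_angles)) expect_lt(max(edge_angles), 1e-6)
  # convex polygon: exterior turns sum to 360 degrees
  expect_equal(sum(hc$angles), 360, tolerance = 1e-6)

  # an extra point on an edge midpoint has angle ~0 and is never picked
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(5, 0))
  hc2 <- hull_corners(sq)
  expect_false(5 %in% hc2$corner_ids)
  mid_angle <- hc2$angles[match(5, hc2$hull_ids)]
  if (!is.na(mid_angle)) expect_lt(mid_angle, 1e-6)

  expect_error(hull_corners(cbind(1:5, 1:5)), "hull")
})

test_that("ideal grids interpolate their corners bilinearly", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))   # C1->C2 cols, C2->C3 rows
  g22 <- build_ideal_grid(sq, 2, 2)
  expect_equal(g22$coords[order(g22$row_col$row, g22$row_col$col), ],
               rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)),
               ignore_attr = TRUE)

  g23 <- build_ideal_grid(sq, 2, 3)
  expect_true(any(apply(g23$coords, 1, function(p) isTRUE(all.equal(p, c(0.5, 0))))))
  expect_true(any(apply(g23$coords, 1, function(p) isTRUE(all.equal(p, c(0.5, 1))))))

  skew <- rbind(c(0, 0, 0), c(12, 1, 0), c(14, 11, 2), c(-1, 9, 1))
  g33 <- build_ideal_grid(skew, 3, 3)
  expect_equal(g33$coords[5, ], colMeans(skew))    # center = corner mean

  expect_error(build_ideal_grid(sq[1:3, ], 2, 2), "4 corners")
})

test_that("sphere fitting recovers exact and noisy spheres, with planar fallback", {
  withr::with_seed(21, {
    dirs <- matrix(rnorm(60), 20, 3)
  })
  dirs <- dirs / sqrt(rowSums(dirs^2))
  L <- sweep(dirs * 80, 2, c(10, -5, 3), "+")
  sf <- fit_sphere(L)
  expect_false(sf$planar)
  expect_equal(sf$center, c(10, -5, 3), tolerance = 1e-6)
  expect_equal(sf$radius, 80, tolerance = 1e-6)
  expect_lt(sf$rms_residual, 1e-6)

  flat <- cbind(as.matrix(expand.grid(seq(0, 30, 10), seq(0, 30, 10))), 0)
  sff <- fit_sphere(flat)
  expect_true(sff$planar)
  expect_equal(abs(sff$plane_normal), c(0, 0, 1), tolerance = 1e-9)

  # jittered spheres: radius recovered within 3 sd / sqrt(K)
  K <- 40; sig <- 0.5
  errs <- vapply(1:100, function(s) {
    withr::with_seed(1000 + s, {
      dd <- matrix(rnorm(3 * K), K, 3)
      dd <- dd / sqrt(rowSums(dd^2))
      Lj <- dd * 80 + matrix(rnorm(3 * K, 0, sig), K, 3)
    })
    fit_sphere(Lj)$radius - 80
  }, numeric(1))
  expect_gt(mean(abs(errs) <= 3 * sig / sqrt(K)), 0.9)
})

test_that("radial projection lands on the fitted surface", {
  sf <- structure(list(center = c(0, 0, 0), radius = 50, rms_residual = 0,
                       planar = FALSE), class = "iel_sphere")
  on_sphere <- c(30, 40, 0)                    # |p| = 50 already
  expect_equal(radial_project(matrix(on_sphere, 1), sf)[1, ], on_sphere)
  expect_equal(radial_project(matrix(c(25, 0, 0), 1), sf)[1, ], c(50, 0, 0))
  withr::with_seed(3, P <- matrix(rnorm(30, 0, 20), 10, 3))
  pr <- radial_project(P, sf)
  expect_lt(max(abs(sqrt(rowSums(pr^2)) - 50)), 1e-9)
  expect_error(radial_project(matrix(0, 1, 3), sf), "center")
})

test_that("greedy assignment is exact on coincident sets and near-optimal under jitter", {
  g <- cbind(as.matrix(expand.grid(seq(0, 20, 10), c(0, 10))), 0)
  expect_equal(assign_indices(g, g), 1:6)
  # storage order swapped: zero-distance pairs still pair coincident points
  perm <- c(6, 2, 3, 4, 5, 1)
  expect_equal(assign_indices(g[perm, ], g), perm)

  # vs exhaustive optimal assignment on jittered 2x3 grids
  total_dist <- function(m, A, B) sum(sqrt(rowSums((A - B[m, , drop = FALSE])^2)))
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), ]
  hits <- vapply(1:100, function(s) {
    withr::with_seed(400 + s, Aj <- g + matrix(rnorm(18, 0, 2), 6, 3))
    greedy <- assign_indices(Aj, g)
    best <- min(apply(perms, 1, total_dist, A = Aj, B = g))
    isTRUE(all.equal(total_dist(greedy, Aj, g), best))
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("permutation refinement reaches the exhaustive optimum on 2x3 grids", {
  sp <- electrode_spec("grid", 2, 3, pitch = 10, prefix = "T")
  ideal <- as.matrix(expand.grid(col = seq(0, 20, 10), row = c(0, 10)))
  ideal <- cbind(ideal[, "col"], ideal[, "row"], 0)   # row-major lattice order
  colnames(ideal) <- NULL

  # already-optimal mapping is a fixed point
  m_id <- permute_refine(1:6, ideal, ideal, sp)
  expect_equal(as.integer(m_id), 1:6)

  # one adjacent swap is repaired
  m_sw <- c(2L, 1L, 3L, 4L, 5L, 6L)
  expect_equal(as.integer(permute_refine(m_sw, ideal, ideal, sp)), 1:6)

  # jittered instances attain the exhaustive minimum of the ideal-distance
  # objective over all 720 bijections reachable by adjacent swaps
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), ]
  obj <- function(m, A, B) sum(sqrt(rowSums((A - B[m, , drop = FALSE])^2)))
  withr::with_seed(77, {
    for (rep in 1:10) {
      Aj <- ideal + matrix(rnorm(18, 0, 1.5), 6, 3)
      m0 <- assign_indices(Aj, ideal)
      m1 <- permute_refine(m0, Aj, ideal, sp)
      objs <- attr(m1, "objectives")
      expect_lte(objs[["ideal_after"]], objs[["ideal_before"]] + 1e-12)
      best <- min(apply(perms, 1, obj, A = Aj, B = ideal))
      expect_equal(objs[["ideal_after"]], best, tolerance = 1e-9)
    }
  })
})

test_that("flips and rotations are lattice symmetries with the right algebra", {
  sp <- electrode_spec("grid", 2, 4, pitch = 10, prefix = "T")
  L <- cbind(as.matrix(expand.grid(x = seq(0, 30, 10), y = c(0, 10))), 0)
  es <- electrodes(L, sp, index = 1:8)

  expect_equal(flip_rotate(flip_rotate(es, "flip_lr"), "flip_lr")$index, es$index)
  expect_equal(flip_rotate(flip_rotate(es, "flip_ud"), "flip_ud")$index, es$index)
  r4 <- es
  for (i in 1:4) r4 <- flip_rotate(r4, "rot_cw")
  expect_equal(r4$index, es$index)
  expect_equal(flip_rotate(flip_rotate(es, "rot_cw"), "rot_ccw")$index, es$index)

  rc <- flip_rotate(es, "rot_cw")
  expect_equal(el_spec(rc)$rows, 4L)
  expect_equal(el_spec(rc)$cols, 2L)
  # explicit lattice map: (r, c) -> (c, rows + 1 - r)
  r <- (es$index - 1) %/% 4 + 1; cc <- (es$index - 1) %% 4 + 1
  expect_equal(rc$index, (cc - 1) * 2 + (2 + 1 - r))
})

test_that("electrodes are named by prefix-number concatenation or explicit lists", {
  sp <- electrode_spec("depth", 1, 3, pitch = 5, prefix = "Grid")
  es <- electrodes(cbind(c(0, 5, 10), 0, 0), sp, index = 1:3)
  expect_equal(name_electrodes(es)$name, c("Grid1", "Grid2", "Grid3"))
  expect_equal(name_electrodes(es, c("A", "B", "C"))$name, c("A", "B", "C"))
  es_rev <- electrodes(cbind(c(0, 5, 10), 0, 0), sp, index = 3:1)
  expect_equal(name_electrodes(es_rev)$name, c("Grid3", "Grid2", "Grid1"))
  expect_equal(name_electrodes(es_rev, c("A", "B", "C"))$name, c("C", "B", "A"))
  expect_error(name_electrodes(es, c("A", "B")), "expected 3 names")
})

test_that("grid numbering recovers the lattice and ignores storage order", {
  tr <- ieegloc:::phantom_truth_coords(
    phantom_grid(4, 5, pitch = 10, sphere_center = c(0, 0, 0),
                 sphere_radius = 80, cap_axis = c(0.15, -0.1, 1),
                 orientation = 0.9),
    c(0, 0, 0), 80)
  L <- cbind(tr$x, tr$y, tr$z)
  sp <- electrode_spec("grid", 4, 5, pitch = 10, prefix = "G")
  withr::with_seed(12, perm <- sample(nrow(L)))
  es1 <- number_grid(electrodes(L, sp))
  es2 <- number_grid(electrodes(L[perm, ], sp))
  expect_true(matches_up_to_symmetry(es1, tr$index))
  # same index-to-coordinate mapping regardless of row order
  expect_equal(el_coords(es1)[order(es1$index), ],
               el_coords(es2)[order(es2$index), ])
})
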