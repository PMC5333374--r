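test_that("the envelope of a spherical mask hugs the sphere within 1 mm", {
  sce <- test_sce()
  r <- sqrt(rowSums(sce$nodes^2))
  expect_lt(max(abs(r - 25)), 1)
  expect_gt(nrow(sce$nodes) / (4 * pi * 25^2), 0.25)  # >= 1 node per 4 mm^2
  expect_lt(max(abs(sce$centroid)), 1)
  expect_error(build_sce(as_mask(array(FALSE, c(4, 4, 4)), diag(4))), "empty")
})

two_lobe_mask <- function() {
  d <- c(60L, 60L, 40L)
  m <- array(FALSE, dim = d)
  # two 20-voxel-wide lobes separated by a 6 mm slot in x, common base
  m[8:27, 16:45, 6:30] <- TRUE
  m[34:53, 16:45, 6:30] <- TRUE
  m[8:53, 16:45, 6:12] <- TRUE           # joined at the bottom
  aff <- diag(4); aff[1:3, 4] <- c(-30, -30, -10)
  as_mask(m, aff)
}

test_that("the envelope bridges a 6 mm mock sulcus instead of entering it", {
  mask <- two_lobe_mask()
  sce <- build_sce(mask)
  # world x of the slot: voxels 28..33 -> x in [-2, 3]; lobe tops at z = 20,
  # base top at z = 2
  in_slot_col <- abs(sce$nodes[, 1]) < 2 & abs(sce$nodes[, 2]) < 10
  expect_true(any(in_slot_col))
  z <- sce$nodes[in_slot_col, 3]
  expect_true(any(z >= 16))              # envelope passes above the slot
  expect_false(any(z > 0 & z < 16))      # and never descends into it
})

test_that("hemisphere splitting respects the x = 0 midline", {
  mask <- ball_mask(20, 48L)
  left <- build_sce(mask, hemisphere = "left")
  expect_lt(max(left$nodes[, 1]), 1)
  right <- build_sce(mask, hemisphere = "right")
  expect_gt(min(right$nodes[, 1]), -1)
})

test_that("grids already on the envelope are fixed points of the projection", {
  sce <- test_sce()
  # pick 4 nodes near the pole forming a rough 2x2 patch
  ids <- ieegloc:::nearest_nodes(sce, rbind(c(-5, -5, 24), c(5, -5, 24),
                                            c(5, 5, 24), c(-5, 5, 24)))
  L <- sce$nodes[ids, ]
  es <- electrodes(L, electrode_spec("grid", 2, 2, pitch = 10), index = c(1, 2, 4, 3))
  pr <- project_grid(es, sce)
  expect_equal(pr$energy, 0, tolerance = 1e-12)
  expect_equal(max(pr$distances), 0, tolerance = 1e-12)
  expect_equal(pr$L, pr$L0)
  expect_equal(pr$D, pr$L - pr$L0)
})

test_that("a single contact projects to its nearest node", {
  sce <- test_sce()
  es <- electrodes(matrix(c(0, 0, 18), 1), electrode_spec("depth", 1, 1, 5))
  pr <- project_grid(es, sce)
  nid <- ieegloc:::nearest_nodes(sce, matrix(c(0, 0, 18), 1))
  expect_equal(pr$L[1, ], sce$nodes[nid, ])
})

test_that("an inward-pushed grid projects back to the brute-force energy minimum", {
  sce <- test_sce()
  tr <- ieegloc:::phantom_truth_coords(
    phantom_grid(2, 2, pitch = 10, sphere_center = c(0, 0, 0),
                 sphere_radius = 25, cap_axis = c(0, 0, 1)),
    c(0, 0, 0), 25)
  Ltruth <- cbind(tr$x, tr$y, tr$z)
  L <- sweep(Ltruth, 2, c(0, 0, 5))            # rigid 5 mm push inward
  es <- electrodes(L, electrode_spec("grid", 2, 2, pitch = 10), index = 1:4)
  pr <- project_grid(es, sce)
  expect_lt(abs(mean(pr$distances) - 5), 0.5)

  # exhaustive node search over per-contact candidate sets
  nb <- cbind(c(1, 1, 2, 3), c(2, 3, 4, 4))
  d0 <- sqrt(rowSums((L[nb[, 1], ] - L[nb[, 2], ])^2))
  cand <- ieegloc:::candidate_nodes(sce, L, n_cand = 15L)
  combos <- as.matrix(expand.grid(cand[[1]], cand[[2]], cand[[3]], cand[[4]]))
  E <- apply(combos, 1, function(s)
    ieegloc:::grid_energy(sce$nodes[s, ], L, nb, d0))
  expect_equal(pr$energy, min(E), tolerance = 1e-9)
  # constraint: every projected contact coincides with a mesh node
  expect_equal(sce$nodes[pr$node_ids, ], pr$L)
})

test_that("simulated brain shift is recovered to within 1.5 mm", {
  # at the study's brain scale (80 mm sphere), as in the phantom cohort
  sce <- cached("sce80", build_sce(ball_mask(80, 170L)))
  tr <- ieegloc:::phantom_truth_coords(
    phantom_grid(3, 3, pitch = 10, sphere_center = c(0, 0, 0),
                 sphere_radius = 80, cap_axis = c(0, 0, 1)),
    c(0, 0, 0), 80)
  Ltruth <- cbind(tr$x, tr$y, tr$z)
  sp <- electrode_spec("grid", 3, 3, pitch = 10)
  for (delta in c(2, 5, 10)) {
    L <- sweep(Ltruth, 2, c(0, 0, delta))
    pr <- project_grid(electrodes(L, sp, index = 1:9), sce)
    expect_lt(mean(sqrt(rowSums((pr$L - Ltruth)^2))), 1.5)
  }
})

test_that("contacts over a mock sulcus displace farther than gyral contacts", {
  mask <- two_lobe_mask()
  sce <- build_sce(mask)
  # 2x4 grid across the slot at lobe-top level; the two middle columns sag
  # 3 mm into the sulcus
  xs <- c(-12, -2, 2, 12)
  L <- rbind(cbind(xs, -5, c(20, 17, 17, 20)), cbind(xs, 5, c(20, 17, 17, 20)))
  es <- electrodes(L, electrode_spec("grid", 2, 4, pitch = 8), index = 1:8)
  pr <- project_grid(es, sce)
  sulcal <- c(2, 3, 6, 7); gyral <- c(1, 4, 5, 8)
  expect_gt(mean(pr$distances[sulcal]), mean(pr$distances[gyral]))
})

test_that("the displacement field obeys its limiting laws", {
  sce <- test_sce()
  # single grid contact with a known displacement
  g1 <- electrodes(matrix(c(0, 0, 20), 1), electrode_spec("depth", 1, 1, 10,
                                                          prefix = "G"))
  pr1 <- project_grid(g1, sce)
  D1 <- pr1$D[1, ]
  dsp <- electrode_spec("depth", 1, 1, 5, prefix = "D")

  # coincident with the (projected) grid contact: F = D exactly
  dd <- displacement_field(electrodes(matrix(pr1$L[1, ], 1), dsp, index = 1),
                           g1, pr1, sce)
  expect_equal(c(dd$fx, dd$fy, dd$fz), D1, tolerance = 1e-12)

  # far away: F -> 0
  far <- displacement_field(electrodes(matrix(c(500, 500, 500), 1), dsp, index = 1),
                            g1, pr1, sce)
  expect_lt(far$displacement, 1e-8)

  # symmetric opposite displacements cancel: F = 0 midway
  g2 <- electrodes(rbind(c(-6, 0, 24), c(6, 0, 24)),
                   electrode_spec("depth", 1, 2, 12, prefix = "G"), index = 1:2)
  pr2 <- project_grid(g2, sce)
  pr2$D <- rbind(c(0, 0, 3), c(0, 0, -3))      # imposed +-D
  pr2$L <- pr2$L0 + pr2$D
  mid <- displacement_field(electrodes(matrix(c(0, 0, 24), 1), dsp, index = 1),
                            g2, pr2, sce)
  expect_lt(mid$displacement, 1e-10)

  # |F_j| never exceeds max |D_k|
  withr::with_seed(31, {
    for (rep in 1:5) {
      Lg <- cbind(runif(4, -10, 10), runif(4, -10, 10), runif(4, 15, 22))
      g4 <- electrodes(Lg, electrode_spec("grid", 2, 2, 10, prefix = "G"),
                       index = 1:4)
      p4 <- project_grid(g4, sce)
      Ld <- cbind(runif(6, -20, 20), runif(6, -20, 20), runif(6, -20, 20))
      d6 <- displacement_field(electrodes(Ld, electrode_spec("depth", 1, 6, 5),
                                          index = 1:6), g4, p4, sce)
      expect_lte(max(d6$displacement), max(p4$distances) + 1e-9)
    }
  })

  # attenuation variant measures from the envelope centroid
  dc <- displacement_field(electrodes(matrix(pr1$L[1, ], 1), dsp, index = 1),
                           g1, pr1, sce, attenuation = "centroid")
  expect_true(all(is.finite(c(dc$fx, dc$fy, dc$fz))))
})

test_that("meshes round-trip through OFF and export to STL", {
  sce <- build_sce(ball_mask(10, 28L))
  p_off <- withr::local_tempfile(fileext = ".off")
  write_mesh(sce, p_off)
  back <- read_mesh(p_off)
  expect_equal(back$nodes, sce$nodes, tolerance = 1e-6)
  expect_equal(back$faces, sce$faces)
  p_stl <- withr::local_tempfile(fileext = ".stl")
  write_mesh(sce, p_stl)
  expect_gt(file.size(p_stl), 0)
  expect_match(readLines(p_stl, n = 1), "solid")
})
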