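blob_cloud <- function(centers, n_per = 5, spread = 0.5, seed = 3,
                       intensity = 2500) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(r) {
      sweep(matrix(rnorm(n_per * 3, 0, spread), n_per, 3), 2, centers[r, ], "+")
    }))
  })
  tibble::tibble(x = X[, 1], y = X[, 2], z = X[, 3],
                 intensity = rep(intensity, nrow(X)))
}

test_that("K-means partition attains the exhaustive minimum on small instances", {
  cl2 <- blob_cloud(rbind(c(0, 0, 0), c(10, 0, 0)), n_per = 5)
  fit <- cluster_voxels(cl2, 2, seed = 1)
  wss_best <- exhaustive_best_wss(cbind(cl2$x, cl2$y, cl2$z), 2)
  expect_equal(fit$objective, wss_best, tolerance = 1e-8)
  # each cluster is exactly one blob
  expect_equal(length(unique(fit$assignment[1:5])), 1)
  expect_equal(length(unique(fit$assignment[6:10])), 1)
  expect_false(fit$assignment[1] == fit$assignment[6])

  cl3 <- blob_cloud(rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0)), n_per = 3)
  fit3 <- cluster_voxels(cl3, 3, seed = 2)
  expect_equal(fit3$objective,
               exhaustive_best_wss(cbind(cl3$x, cl3$y, cl3$z), 3),
               tolerance = 1e-8)
})

test_that("degenerate K-means cases behave per contract", {
  cl <- blob_cloud(matrix(c(0, 0, 0), 1), n_per = 6)
  fit <- cluster_voxels(cl, 6, seed = 1)        # K = N
  expect_equal(fit$objective, 0)
  expect_equal(sort(fit$assignment), 1:6)
  expect_error(cluster_voxels(cl, 7, seed = 1), "cannot form")
  expect_error(cluster_voxels(cl, 0, seed = 1), ">= 1")
})

test_that("K-means result is a Lloyd fixpoint and deterministic by seed", {
  cl <- blob_cloud(rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0), c(6, 6, 0)),
                   n_per = 8, spread = 1)
  f1 <- cluster_voxels(cl, 4, seed = 9)
  f2 <- cluster_voxels(cl, 4, seed = 9)
  expect_identical(f1$assignment, f2$assignment)
  # every voxel sits in its nearest centroid's cluster
  X <- cbind(cl$x, cl$y, cl$z)
  D2 <- outer(rowSums(X^2), rowSums(f1$centers^2), "+") - 2 * X %*% t(f1$centers)
  own <- D2[cbind(seq_len(nrow(X)), f1$assignment)]
  expect_true(all(own <= apply(D2, 1, min) + 1e-9))
})

test_that("intensity-weighted centers of mass follow the weighted-mean formula", {
  cl <- tibble::tibble(x = c(0, 2), y = c(0, 0), z = c(0, 0),
                       intensity = c(1, 3))
  expect_equal(center_of_mass(1:2, cl), c(1.5, 0, 0))

  # symmetric blob with uniform weights: geometric center
  g <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  cl2 <- tibble::tibble(x = g$x + 5, y = g$y - 2, z = g$z, intensity = rep(7, 27))
  expect_equal(center_of_mass(seq_len(27), cl2), c(5, -2, 0))

  expect_error(center_of_mass(integer(0), cl), "empty")
  cl$intensity[1] <- -1
  expect_error(center_of_mass(1:2, cl), "> 0")
})

test_that("centroids recover a rendered kernel center within 0.25 mm", {
  # noiseless isolated contact at an awkward sub-voxel position
  ph <- make_phantom(list(phantom_depth(1, pitch = 5, tip = c(3.37, -2.81, 4.63),
                                        direction = c(0, 0, 1))),
                     shape = c(40L, 40L, 40L), origin = c(-20, -20, -20),
                     noise_sd = 0, seed = 1, brain_center = c(0, 0, 0),
                     brain_radius = 15, skull_inner = 17, skull_outer = 19)
  cloud <- threshold_ct(ph$ct, ph$mask, 1800)
  est <- center_of_mass(seq_len(nrow(cloud)), cloud)
  # independent oracle: direct weighted sum over the raw volume
  d <- dim(ph$ct$data)
  idx <- which(ph$ct$data >= 1800 & ph$mask$data)
  ijk <- arrayInd(idx, d) - 1
  w <- ph$ct$data[idx]
  oracle <- colSums(sweep(ijk, 1, w, "*")) / sum(w) + c(-20, -20, -20)
  expect_equal(est, oracle, tolerance = 1e-10)
  expect_lt(sqrt(sum((est - c(3.37, -2.81, 4.63))^2)), 0.25)
})

test_that("localization is translation-equivariant and intensity-scale invariant", {
  cl <- blob_cloud(rbind(c(0, 0, 0), c(9, 1, 0), c(1, 9, 2)), n_per = 6)
  sp <- electrode_spec("depth", 1, 3, pitch = 9, prefix = "T")
  base <- localize_array(cl, sp, seed = 4)
  shifted <- cl
  shifted$x <- cl$x + 11.5; shifted$y <- cl$y - 3; shifted$z <- cl$z + 0.25
  es2 <- localize_array(shifted, sp, seed = 4)
  m <- match_coordinates(el_coords(base) + rep(c(11.5, -3, 0.25), each = 3),
                         el_coords(es2))
  expect_lt(max(m$distance), 1e-9)

  scaled <- cl; scaled$intensity <- cl$intensity * 3.7
  es3 <- localize_array(scaled, sp, seed = 4)
  expect_equal(el_coords(es3), el_coords(base), tolerance = 1e-12)
})

test_that("full-array localization matches phantom truth contact for contact", {
  ph <- small_phantom(noise_sd = 0)
  m0 <- morph_adjust(ph$mask, 4L)
  cloud <- threshold_ct(ph$ct, m0, 1800)
  gt <- truth_coords(ph, "G")
  gcl <- remove_components(select_near_points(cloud, gt, 4.5), min_size = 2)
  # every cluster's voxels originate from a single true contact
  fit <- cluster_voxels(gcl, nrow(gt), seed = 1)
  nearest_truth <- apply(cbind(gcl$x, gcl$y, gcl$z), 1, function(p) {
    which.min(colSums((t(gt) - p)^2))
  })
  purity <- tapply(nearest_truth, fit$assignment,
                   function(v) length(unique(v)))
  expect_true(all(purity == 1))

  es <- localize_array(gcl, electrode_spec("grid", 4, 5, 10, "G"), seed = 1)
  mm <- match_coordinates(el_coords(es), gt)
  expect_true(all(table(mm$b) == 1))           # bijection onto distinct contacts
  expect_lt(max(mm$distance), 0.5)

  cl_small <- blob_cloud(matrix(0, 1, 3), n_per = 4)
  expect_error(localize_array(cl_small, electrode_spec("depth", 1, 8, 5, "D")),
               "cannot form")
})
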