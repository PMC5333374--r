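# Synthetic CT phantoms with known ground truth: bright compact contact
# artifacts, a high-intensity skull shell, background tissue, and noise.

#' Describe a phantom grid array
#'
#' Contacts are laid on a spherical cap by the exponential map from the cap
#' center: the geodesic distance from the cap center to contact (r, c) is
#' exactly `pitch * sqrt(dr^2 + dc^2)` (dr, dc lattice offsets from the grid
#' center), so the pitch is exact along the generating geodesics.
#'
#' @param rows,cols lattice dimensions.
#' @param pitch inter-contact spacing, mm (default 10).
#' @param prefix array name prefix.
#' @param sphere_center,sphere_radius the supporting sphere (defaults to the
#'   phantom brain surface).
#' @param cap_axis unit vector from sphere center to the cap center.
#' @param orientation rotation of the grid's lattice axes about the cap axis,
#'   radians.
#' @param peak_hu,kernel_sd artifact kernel peak (HU) and Gaussian sd (mm);
#'   the kernel is truncated at `2 * kernel_sd`.
#' @param marker add a bright marker blob midway between contacts 1 and 2.
#' @return A list of class `iel_phantom_array`.
#' @export
phantom_grid <- function(rows, cols, pitch = 10, prefix = "G",
                         sphere_center = NULL, sphere_radius = NULL,
                         cap_axis = c(0, 0, 1), orientation = 0,
                         peak_hu = 3200, kernel_sd = 1.5, marker = FALSE) {
  structure(list(spec = electrode_spec("grid", rows, cols, pitch, prefix),
                 sphere_center = sphere_center, sphere_radius = sphere_radius,
                 cap_axis = cap_axis / sqrt(sum(cap_axis^2)),
                 orientation = orientation, peak_hu = peak_hu,
                 kernel_sd = kernel_sd, marker = marker),
            class = "iel_phantom_array")
}

#' Describe a phantom depth array
#'
#' Collinear contacts at exact pitch; contact 1 is the deep tip.
#'
#' @param n number of contacts.
#' @param pitch inter-contact spacing, mm.
#' @param prefix array name prefix.
#' @param tip world mm coordinate of contact 1 (deepest).
#' @param direction unit vector from the tip toward the entry point.
#' @param peak_hu,kernel_sd artifact kernel peak (HU) and Gaussian sd (mm).
#' @param marker add a bright marker blob midway between contacts 1 and 2.
#' @return A list of class `iel_phantom_array`.
#' @export
phantom_depth <- function(n, pitch = 5, prefix = "D",
                          tip = c(0, 0, 0), direction = c(0, 0, 1),
                          peak_hu = 3200, kernel_sd = 1.3, marker = FALSE) {
  structure(list(spec = electrode_spec("depth", 1L, n, pitch, prefix),
                 tip = tip, direction = direction / sqrt(sum(direction^2)),
                 peak_hu = peak_hu, kernel_sd = kernel_sd, marker = marker),
            class = "iel_phantom_array")
}

# true contact coordinates for one phantom array
phantom_truth_coords <- function(arr, brain_center, brain_radius) {
  sp <- arr$spec
  if (sp$kind == "grid") {
    ctr <- arr$sphere_center %||% brain_center
    R <- arr$sphere_radius %||% brain_radius
    u <- arr$cap_axis
    e1 <- orthonormal_to(u)
    e2 <- cross3(matrix(u, 1), matrix(e1, 1))[1, ]
    co <- cos(arr$orientation); si <- sin(arr$orientation)
    a1 <- co * e1 + si * e2
    a2 <- -si * e1 + co * e2
    rc <- expand.grid(col = seq_len(sp$cols), row = seq_len(sp$rows))
    dr <- rc$row - (sp$rows + 1) / 2
    dc <- rc$col - (sp$cols + 1) / 2
    V <- outer(dc * sp$pitch, a1) + outer(dr * sp$pitch, a2)  # tangent vectors
    vn <- sqrt(rowSums(V^2))
    theta <- vn / R
    dirs <- matrix(u, nrow(V), 3, byrow = TRUE) * cos(theta)
    nz <- vn > 1e-12
    dirs[nz, ] <- dirs[nz, ] + (V[nz, , drop = FALSE] / vn[nz]) * sin(theta[nz])
    L <- sweep(dirs * R, 2, ctr, "+")
    tibble(index = seq_len(sp$K), row = rc$row, col = rc$col,
           x = L[, 1], y = L[, 2], z = L[, 3])
  } else {
    k <- seq_len(sp$K)
    L <- matrix(arr$tip, sp$K, 3, byrow = TRUE) +
      outer((k - 1) * sp$pitch, arr$direction)
    tibble(index = k, row = 1L, col = k, x = L[, 1], y = L[, 2], z = L[, 3])
  }
}

orthonormal_to <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v / sqrt(sum(v^2))
}

#' Generate a synthetic CT phantom
#'
#' Renders a brain (spherical mask, ~50 HU background), a high-intensity
#' skull shell, and each electrode contact as a truncated-Gaussian intensity
#' kernel at its true position, plus additive Gaussian noise. The kernel
#' produces the partial-volume falloff that exercises intensity-weighted
#' centroids, and is bright enough that every contact survives thresholds up
#' to 2,200 HU while 5 mm-pitch depth arrays merge below ~1,000 HU.
#'
#' @param arrays list of [phantom_grid()] / [phantom_depth()] descriptions.
#' @param shape volume dimensions in voxels (1 mm isotropic).
#' @param origin world mm coordinate of voxel (0,0,0).
#' @param noise_sd additive Gaussian noise sd, HU.
#' @param seed RNG seed; same seed, same phantom, bit for bit.
#' @param brain_center,brain_radius brain mask sphere (mm).
#' @param skull_inner,skull_outer skull shell radii (mm).
#' @param background_hu,skull_hu tissue intensities.
#' @return A list of class `iel_phantom`: `ct` (volume), `mask`, `truth`
#'   (tibble with array, kind, index, row, col, x, y, z), `arrays`, `seed`.
#' @export
make_phantom <- function(arrays, shape = c(124L, 124L, 128L),
                         origin = c(-61, -61, -70), noise_sd = 100,
                         seed = 1L, brain_center = c(0, 0, -35),
                         brain_radius = 80, skull_inner = 90,
                         skull_outer = 93, background_hu = 50,
                         skull_hu = 1500) {
  if (inherits(arrays, "iel_phantom_array")) arrays <- list(arrays)
  affine <- diag(4)
  affine[1:3, 4] <- origin
  d <- as.integer(shape)
  # world coordinate grids
  xs <- origin[1] + seq_len(d[1]) - 1
  ys <- origin[2] + seq_len(d[2]) - 1
  zs <- origin[3] + seq_len(d[3]) - 1
  r2 <- outer(outer((xs - brain_center[1])^2, (ys - brain_center[2])^2, "+"),
              (zs - brain_center[3])^2, "+")
  mask <- r2 <= brain_radius^2
  vol <- array(0, dim = d)
  vol[mask] <- background_hu
  shell <- r2 > skull_inner^2 & r2 <= skull_outer^2
  vol[shell] <- skull_hu
  truth <- purrr::map_dfr(arrays, function(arr) {
    tt <- phantom_truth_coords(arr, brain_center, brain_radius)
    tt$array <- arr$spec$prefix
    tt$kind <- arr$spec$kind
    tt
  })
  # placement checks
  inside <- truth$x >= xs[1] & truth$x <= xs[d[1]] &
    truth$y >= ys[1] & truth$y <= ys[d[2]] &
    truth$z >= zs[1] & truth$z <= zs[d[3]]
  if (!all(inside)) abort("contact placement outside the volume")
  Tm <- cbind(truth$x, truth$y, truth$z)
  if (nrow(Tm) > 1L) {
    dmin <- sqrt(min(dist2_all(Tm)[upper.tri(diag(nrow(Tm)))]))
    if (dmin < 2) abort(sprintf("overlapping contacts: minimum spacing %.2f mm < 2 mm", dmin))
  }
  depth_truth <- truth[truth$kind == "depth", ]
  if (nrow(depth_truth)) {
    dr2 <- (depth_truth$x - brain_center[1])^2 +
      (depth_truth$y - brain_center[2])^2 + (depth_truth$z - brain_center[3])^2
    if (any(dr2 > brain_radius^2)) abort("depth contact placed outside the brain mask")
  }
  # render contact kernels (and optional markers)
  for (ai in seq_along(arrays)) {
    arr <- arrays[[ai]]
    tt <- phantom_truth_coords(arr, brain_center, brain_radius)
    pts <- cbind(tt$x, tt$y, tt$z)
    for (r in seq_len(nrow(pts))) {
      vol <- add_kernel(vol, d, origin, pts[r, ], arr$peak_hu, arr$kernel_sd)
    }
    if (isTRUE(arr$marker)) {
      mid <- (pts[1, ] + pts[2, ]) / 2
      vol <- add_kernel(vol, d, origin, mid, 3000, 1.0)
    }
  }
  if (noise_sd > 0) {
    with_seed(seed, {
      vol <- vol + array(rnorm(prod(d), 0, noise_sd), dim = d)
    })
  }
  truth <- truth[, c("array", "kind", "index", "row", "col", "x", "y", "z")]
  structure(list(ct = as_volume(vol, affine, units = "HU"),
                 mask = as_mask(mask, affine),
                 truth = as_tibble(truth),
                 arrays = arrays, seed = seed),
            class = "iel_phantom")
}

# add a truncated-Gaussian kernel (cutoff 2*sd) at world point p
add_kernel <- function(vol, d, origin, p, peak, sd_mm) {
  cut <- 2 * sd_mm
  v <- p - origin                      # voxel coords (1 mm isotropic, 0-based)
  lo <- pmax(floor(v - cut), 0)
  hi <- pmin(ceiling(v + cut), d - 1)
  if (any(lo > hi)) return(vol)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  dx2 <- (ii - v[1])^2; dy2 <- (jj - v[2])^2; dz2 <- (kk - v[3])^2
  D2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  Kn <- peak * exp(-D2 / (2 * sd_mm^2))
  Kn[D2 > cut^2] <- 0
  vol[ii + 1, jj + 1, kk + 1] <- vol[ii + 1, jj + 1, kk + 1] + Kn
  vol
}

#' @export
print.iel_phantom <- function(x, ...) {
  cat(sprintf("<iel_phantom> %s, %d arrays, %d contacts, seed %d\n",
              paste(dim(x$ct$data), collapse = " x "), length(x$arrays),
              nrow(x$truth), x$seed))
  invisible(x)
}

#' Build a synthetic probabilistic atlas from geometric regions
#'
#' Each region is a predicate (or probability function) of world coordinates;
#' maps record membership probability on the grid, written on a 0-100 scale.
#'
#' @param regions named list of functions `f(x, y, z)` returning membership
#'   probability in 0..1 (logical results are treated as 0/1).
#' @param shape volume dimensions.
#' @param affine 4x4 voxel-to-world transform.
#' @return An [as_atlas()] object.
#' @export
make_synthetic_atlas <- function(regions, shape, affine = diag(4)) {
  if (length(regions) == 0L) abort("need at least one region")
  d <- as.integer(shape)
  ijk <- arrayInd(seq_len(prod(d)), d) - 1L
  xyz <- voxels_to_world_fast(as.matrix(affine), ijk)
  maps <- array(0, dim = c(d, length(regions)))
  for (ri in seq_along(regions)) {
    p <- regions[[ri]](xyz[, 1], xyz[, 2], xyz[, 3])
    maps[, , , ri] <- array(as.numeric(p) * 100, dim = d)
  }
  as_atlas(maps, affine, names(regions))
}

#' Simulate rater localizations around ground truth
#'
#' Adds isotropic Gaussian jitter per rater and contact, emulating
#' independent expert localizations.
#'
#' @param truth K x 3 matrix of true coordinates.
#' @param R number of raters.
#' @param jitter_sd per-component jitter sd, mm (>= 0).
#' @param seed RNG seed.
#' @param method tag for the resulting [rater_localizations()].
#' @return An `iel_raters` object.
#' @export
simulate_raters <- function(truth, R, jitter_sd, seed = 1L,
                            method = "manual") {
  truth <- to_mat3(truth)
  K <- nrow(truth)
  coords <- array(NA_real_, dim = c(K, R, 3))
  with_seed(seed, {
    for (r in seq_len(R)) {
      coords[, r, ] <- truth + matrix(rnorm(K * 3, 0, jitter_sd), K, 3)
    }
  })
  rater_localizations(coords, method = method)
}
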