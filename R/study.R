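# Simulated validation studies on standard phantoms: localization accuracy
# against ground truth, parameter robustness, and reliability across
# parameter configurations.

#' The standard study phantom
#'
#' One subdural grid (8x8 for odd seeds, 4x5 for even) on the 80 mm brain
#' sphere plus one depth array of 8, 9 or 10 contacts (pitch 5, 6 or 10 mm
#' respectively, cycling with the seed). The cap axis tilt, grid orientation
#' and depth entry azimuth vary with the seed so PCA, hull and numbering see
#' general positions.
#'
#' @param seed phantom seed (placement and noise).
#' @param noise_sd additive CT noise sd, HU (default 100).
#' @return An `iel_phantom` (see [make_phantom()]).
#' @export
standard_phantom <- function(seed, noise_sd = 100) {
  grid_dims <- if (seed %% 2 == 1) c(8L, 8L) else c(4L, 5L)
  n_depth <- 8L + (seed %% 3L)
  depth_pitch <- unname(c(`8` = 5, `9` = 6, `10` = 10)[as.character(n_depth)])
  brain_center <- c(0, 0, -35)
  brain_radius <- 80
  with_seed(seed + 777L, {
    # cap axis: up to 10 degrees off vertical, random azimuth
    tilt <- runif(1, 0, 10 * pi / 180)
    az <- runif(1, 0, 2 * pi)
    u <- c(sin(tilt) * cos(az), sin(tilt) * sin(az), cos(tilt))
    orient <- runif(1, 0, 2 * pi)
    # depth entry: 50 degrees from the cap axis (15+ degrees clear of the
    # largest grid corners), random azimuth, radial track staying inside the FOV
    az2 <- runif(1, 0, 2 * pi)
    e1 <- orthonormal_to(u)
    e2 <- cross3(matrix(u, 1), matrix(e1, 1))[1, ]
    w <- cos(50 * pi / 180) * u +
      sin(50 * pi / 180) * (cos(az2) * e1 + sin(az2) * e2)
    entry <- brain_center + 0.85 * brain_radius * w
    tip <- entry - (n_depth - 1) * depth_pitch * w
    arrays <- list(
      phantom_grid(grid_dims[1], grid_dims[2], pitch = 10, prefix = "G",
                   cap_axis = u, orientation = orient),
      phantom_depth(n_depth, pitch = depth_pitch, prefix = "D",
                    tip = tip, direction = w)
    )
    make_phantom(arrays, noise_sd = noise_sd, seed = seed,
                 brain_center = brain_center, brain_radius = brain_radius)
  })
}

#' Localize every array of a phantom semi-automatically
#'
#' The full pipeline on one phantom: per array, adjust the brain mask
#' (grids dilate by `4 + mask_delta` iterations so surface artifacts are
#' inside the mask, depth arrays use `mask_delta` alone), threshold the CT,
#' select the array's voxels near its planned contact positions, drop
#' sub-minimum components (spurious-voxel removal), cluster, and take
#' intensity-weighted centroids; then number the array (grids by the
#' convex-hull procedure, depth arrays along their axis with the mask
#' resolving the deep end).
#'
#' @param ph an `iel_phantom`.
#' @param threshold CT threshold, HU (default 1800).
#' @param mask_delta erosion/dilation iterations relative to the per-kind
#'   baseline (grid +4, depth 0).
#' @param seed clustering seed.
#' @param select_radius per-array voxel selection radius around the planned
#'   contact positions, mm.
#' @param min_component minimum connected-component size kept.
#' @return Named list of numbered [electrodes()] tables, one per array.
#' @export
localize_phantom <- function(ph, threshold = 1800, mask_delta = 0L, seed = 1L,
                             select_radius = 4.5, min_component = 2L) {
  out <- list()
  for (arr in ph$arrays) {
    sp <- arr$spec
    base <- if (sp$kind == "grid") 4L else 0L
    m <- morph_adjust(ph$mask, base + mask_delta)
    cloud <- threshold_ct(ph$ct, m, threshold)
    tt <- ph$truth[ph$truth$array == sp$prefix, ]
    cloud <- select_near_points(cloud, cbind(tt$x, tt$y, tt$z), select_radius)
    cloud <- remove_components(cloud, min_size = min_component)
    es <- localize_array(cloud, sp, seed = seed)
    es <- if (sp$kind == "grid") number_grid(es) else {
      number_depth(es, deep_end = NULL, mask = ph$mask)
    }
    out[[sp$prefix]] <- name_electrodes(es)
  }
  out
}

#' Localization-accuracy study on standard phantoms
#'
#' Generates one standard phantom per seed, runs the semi-automatic pipeline
#' (1,800 HU threshold), and measures each contact's Euclidean distance to
#' the phantom ground truth (bijective nearest matching).
#'
#' @param seeds phantom seeds (one phantom each).
#' @param noise_sd CT noise sd, HU.
#' @param threshold CT threshold, HU.
#' @return A tibble with one row per contact: `seed`, `array`, `kind`,
#'   `contact`, `error` (mm).
#' @export
run_localization_study <- function(seeds = 1:50, noise_sd = 100,
                                   threshold = 1800) {
  purrr::map_dfr(seeds, function(s) {
    ph <- standard_phantom(s, noise_sd = noise_sd)
    ess <- localize_phantom(ph, threshold = threshold, seed = s)
    purrr::map_dfr(names(ess), function(nm) {
      tt <- ph$truth[ph$truth$array == nm, ]
      mm <- match_coordinates(el_coords(ess[[nm]]), cbind(tt$x, tt$y, tt$z))
      tibble(seed = s, array = nm, kind = tt$kind[1],
             contact = tt$index[mm$b], error = mm$distance)
    })
  })
}

#' Parameter-robustness study on one phantom
#'
#' Runs the pipeline on a single fixed phantom under several configurations
#' differing in CT threshold and mask erosion/dilation iterations, aligns
#' contacts across runs, and measures each run's distance to the across-run
#' mean coordinate (`V_k`), plus Krippendorff's interval alpha treating each
#' configuration as a rater and each contact coordinate component as a unit.
#'
#' @param seed phantom seed (default 7).
#' @param noise_sd CT noise sd, HU.
#' @param thresholds CT thresholds, one per configuration.
#' @param mask_deltas mask iteration deltas, one per configuration.
#' @return A list: `errors` (tibble with `config`, `array`, `contact`,
#'   `error` = distance to the across-run mean, mm), `alpha`, `coords`
#'   (K x n_config x 3 array), `mean_error`.
#' @export
run_robustness_study <- function(seed = 7L, noise_sd = 100,
                                 thresholds = c(1200, 1450, 1700, 1950, 2200),
                                 mask_deltas = c(-1L, 0L, 1L, 0L, -1L)) {
  stopifnot(length(thresholds) == length(mask_deltas))
  ph <- standard_phantom(seed, noise_sd = noise_sd)
  truth <- ph$truth
  Tm <- cbind(truth$x, truth$y, truth$z)
  n_cfg <- length(thresholds)
  K <- nrow(truth)
  coords <- array(NA_real_, dim = c(K, n_cfg, 3))
  for (cfg in seq_len(n_cfg)) {
    ess <- localize_phantom(ph, threshold = thresholds[cfg],
                            mask_delta = mask_deltas[cfg], seed = seed)
    for (nm in names(ess)) {
      rows <- which(truth$array == nm)
      mm <- match_coordinates(el_coords(ess[[nm]]), Tm[rows, , drop = FALSE])
      coords[rows[mm$b], cfg, ] <- el_coords(ess[[nm]])[mm$a, , drop = FALSE]
    }
  }
  V <- apply(coords, c(1, 3), mean)              # across-run mean, V_k
  errors <- purrr::map_dfr(seq_len(n_cfg), function(cfg) {
    tibble(config = cfg, array = truth$array, contact = truth$index,
           error = sqrt(rowSums((coords[, cfg, ] - V)^2)))
  })
  alpha <- krippendorff_alpha(coordinate_ratings(coords))
  list(errors = errors, alpha = alpha, coords = coords,
       mean_error = mean(errors$error))
}
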