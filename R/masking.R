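# Mask morphology and CT thresholding: isolate electrode-artifact voxels.

# shift a logical array by s (+1/-1) along dimension d, FALSE-filling
shift_logical <- function(x, d, s) {
  n <- dim(x)[d]
  idx <- seq_len(n) - s
  idx[idx < 1L | idx > n] <- NA_integer_
  args <- rep(list(quote(expr = )), 3L)
  args[[d]] <- idx
  out <- do.call(`[`, c(list(x), args, list(drop = FALSE)))
  out[is.na(out)] <- FALSE
  out
}

dilate_cube <- function(x) {
  for (d in 1:3) x <- x | shift_logical(x, d, 1L) | shift_logical(x, d, -1L)
  x
}

erode_cube <- function(x) !dilate_cube(!x)

#' Morphologically adjust a brain mask
#'
#' Dilates (positive `iterations`) or erodes (negative) the mask with a full
#' 3x3x3 cubical structuring element, the adjustment used to keep bright skull
#' out of the thresholded CT while covering surface electrode artifacts.
#'
#' @param mask an [as_mask()] object.
#' @param iterations signed integer, |iterations| <= 20; 0 returns the mask
#'   unchanged.
#' @return The adjusted `iel_mask`.
#' @export
morph_adjust <- function(mask, iterations) {
  stopifnot(inherits(mask, "iel_mask"))
  iterations <- as.integer(iterations)
  if (abs(iterations) > 20L) abort("|iterations| must be <= 20")
  if (iterations == 0L) return(mask)
  x <- mask$data
  for (it in seq_len(abs(iterations))) {
    x <- if (iterations > 0L) dilate_cube(x) else erode_cube(x)
    if (!any(x)) {
      abort(sprintf("mask emptied by erosion at iteration %d", it))
    }
  }
  as_mask(x, mask$affine)
}

new_cloud <- function(tbl, affine, dims, threshold) {
  tbl <- as_tibble(tbl)
  attr(tbl, "affine") <- affine
  attr(tbl, "vol_dim") <- dims
  attr(tbl, "threshold") <- threshold
  class(tbl) <- c("iel_cloud", class(tbl))
  tbl
}

cloud_meta <- function(cloud) {
  list(affine = attr(cloud, "affine"), vol_dim = attr(cloud, "vol_dim"),
       threshold = attr(cloud, "threshold"))
}

restore_cloud <- function(tbl, template) {
  m <- cloud_meta(template)
  new_cloud(tbl, m$affine, m$vol_dim, m$threshold)
}

#' Threshold a CT volume inside a brain mask
#'
#' Returns every voxel with intensity `>= threshold` that lies inside the mask,
#' as a voxel cloud: a tibble with 0-based voxel indices (`i`,`j`,`k`), world
#' mm coordinates (`x`,`y`,`z`) and `intensity` (HU). The default threshold is
#' 1,800 HU.
#'
#' @param ct CT `iel_volume` (Hounsfield units).
#' @param mask `iel_mask` on the same grid.
#' @param threshold scalar HU, > 0.
#' @return A tibble of class `iel_cloud`. An empty result is returned with a
#'   warning, not an error.
#' @export
threshold_ct <- function(ct, mask, threshold = 1800) {
  stopifnot(inherits(ct, "iel_volume"), inherits(mask, "iel_mask"))
  if (threshold <= 0) abort("threshold must be > 0")
  check_same_grid(ct, mask)
  sel <- which(mask$data & (ct$data >= threshold))
  d <- dim(ct$data)
  if (length(sel) == 0L) {
    warn(sprintf("no voxels at or above %g HU inside the mask", threshold))
    tbl <- tibble(i = integer(), j = integer(), k = integer(),
                  x = double(), y = double(), z = double(),
                  intensity = double())
    return(new_cloud(tbl, ct$affine, d, threshold))
  }
  ijk <- arrayInd(sel, d) - 1L
  xyz <- voxels_to_world_fast(ct$affine, ijk)
  tbl <- tibble(
    i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    intensity = as.numeric(ct$data[sel])
  )
  new_cloud(tbl, ct$affine, d, threshold)
}

#' Label 26-connected components of a voxel cloud
#'
#' Components are labeled deterministically: component 1 contains the smallest
#' linearized voxel index, component 2 the next smallest among the rest, etc.
#'
#' @param cloud an `iel_cloud`.
#' @return The cloud with an integer `component` column.
#' @export
label_components <- function(cloud) {
  stopifnot(inherits(cloud, "iel_cloud"))
  n <- nrow(cloud)
  if (n == 0L) abort("empty voxel cloud")
  d <- attr(cloud, "vol_dim")
  lin <- cloud$i + d[1] * (cloud$j + d[2] * cloud$k)  # 0-based linear index
  # 13 half-neighborhood offsets of the 26-neighborhood
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[off$dx != 0 | off$dy != 0 | off$dz != 0, ]
  off <- off[1:(nrow(off) / 2), ]
  edges <- NULL
  for (r in seq_len(nrow(off))) {
    ni <- cloud$i + off$dx[r]; nj <- cloud$j + off$dy[r]; nk <- cloud$k + off$dz[r]
    ok <- ni >= 0 & ni < d[1] & nj >= 0 & nj < d[2] & nk >= 0 & nk < d[3]
    nl <- ni + d[1] * (nj + d[2] * nk)
    m <- match(nl, lin)
    hit <- ok & !is.na(m)
    if (any(hit)) edges <- rbind(edges, cbind(which(hit), m[hit]))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  first_lin <- vapply(split(lin, memb), min, numeric(1))
  relabel <- rank(first_lin, ties.method = "first")
  cloud$component <- as.integer(relabel[memb])
  restore_cloud(cloud, cloud)
}

#' Select or drop connected components of a voxel cloud
#'
#' Programmatic replacement for interactive removal of spurious non-electrode
#' voxels (connection cables, platinum markers): partition the cloud into
#' 26-connected components and keep a subset.
#'
#' @param cloud an `iel_cloud` (the `component` column is computed if absent).
#' @param keep integer component ids to keep, or a predicate
#'   `function(summary_tibble)` returning ids; `NULL` keeps all.
#' @param drop integer component ids to drop.
#' @param min_size drop components with fewer voxels than this.
#' @return The filtered cloud; original component ids are kept.
#' @export
remove_components <- function(cloud, keep = NULL, drop = NULL, min_size = NULL) {
  if (nrow(cloud) == 0L) abort("empty voxel cloud")
  if (is.null(cloud[["component"]])) cloud <- label_components(cloud)
  ids <- sort(unique(cloud$component))
  if (is.function(keep)) {
    keep <- keep(component_summary(cloud))
  }
  sel <- ids
  if (!is.null(keep)) {
    bad <- setdiff(keep, ids)
    if (length(bad)) abort(sprintf("no such component: %s", paste(bad, collapse = ", ")))
    sel <- intersect(sel, keep)
  }
  if (!is.null(drop)) {
    bad <- setdiff(drop, ids)
    if (length(bad)) abort(sprintf("no such component: %s", paste(bad, collapse = ", ")))
    sel <- setdiff(sel, drop)
  }
  if (!is.null(min_size)) {
    sizes <- table(cloud$component)
    sel <- intersect(sel, as.integer(names(sizes)[sizes >= min_size]))
  }
  restore_cloud(cloud[cloud$component %in% sel, , drop = FALSE], cloud)
}

#' @rdname remove_components
#' @export
component_summary <- function(cloud) {
  if (is.null(cloud[["component"]])) cloud <- label_components(cloud)
  dplyr::summarise(
    dplyr::group_by(as_tibble(cloud), .data$component),
    n_voxels = dplyr::n(),
    x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
    peak_intensity = max(.data$intensity),
    .groups = "drop"
  )
}

#' Spatial voxel selection
#'
#' Programmatic stand-ins for the interactive per-array voxel selection: keep
#' voxels inside a world-space bounding box, or within `radius` mm of any of a
#' set of seed points (e.g. the planned contact positions of one array).
#'
#' @param cloud an `iel_cloud`.
#' @param lower,upper length-3 world mm bounds (box selection).
#' @param points n x 3 matrix of world mm seed points.
#' @param radius selection radius in mm.
#' @return The filtered cloud.
#' @export
select_box <- function(cloud, lower, upper) {
  keep <- cloud$x >= lower[1] & cloud$x <= upper[1] &
    cloud$y >= lower[2] & cloud$y <= upper[2] &
    cloud$z >= lower[3] & cloud$z <= upper[3]
  restore_cloud(cloud[keep, , drop = FALSE], cloud)
}

#' @rdname select_box
#' @export
select_near_points <- function(cloud, points, radius) {
  pts <- to_mat3(points)
  if (is.null(dim(points))) pts <- matrix(points, ncol = 3)
  X <- cbind(cloud$x, cloud$y, cloud$z)
  d2min <- rep(Inf, nrow(X))
  for (r in seq_len(nrow(pts))) {
    d2 <- (X[, 1] - pts[r, 1])^2 + (X[, 2] - pts[r, 2])^2 + (X[, 3] - pts[r, 3])^2
    d2min <- pmin(d2min, d2)
  }
  restore_cloud(cloud[d2min <= radius^2, , drop = FALSE], cloud)
}

#' Write a voxel cloud to TSV
#'
#' Columns `x_mm`, `y_mm`, `z_mm`, `intensity`.
#' @param cloud an `iel_cloud`.
#' @param path output path.
#' @export
write_cloud <- function(cloud, path) {
  readr::write_tsv(
    tibble(x_mm = cloud$x, y_mm = cloud$y, z_mm = cloud$z,
           intensity = cloud$intensity),
    path
  )
  invisible(path)
}
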