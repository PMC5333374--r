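# Ordinal index assignment: PCA ordering for depth/strip arrays; the
# convex-hull / ideal-grid / permutation-refinement procedure for grids.

#' Number a depth or strip array along its principal axis
#'
#' Projects the contact coordinates onto the first principal component of L
#' and numbers contacts 1..K by ordinal position along that axis, with index 1
#' at the end nearer the deep tip.
#'
#' @param es an unnumbered [electrodes()] table of kind depth or strip.
#' @param deep_end world mm coordinate marking the deep end (the tip,
#'   contact 1). If `NULL`, `mask` must be given and the endpoint farther from
#'   the brain-mask boundary is taken as the deep end.
#' @param mask optional `iel_mask` used to resolve the deep end when
#'   `deep_end` is not supplied.
#' @return The electrode table with `index` set.
#' @export
number_depth <- function(es, deep_end = NULL, mask = NULL) {
  sp <- el_spec(es)
  if (!sp$kind %in% c("depth", "strip")) abort("number_depth needs a depth or strip array")
  L <- el_coords(es)
  K <- nrow(L)
  if (K < 2L) abort("need at least 2 contacts to number")
  ctr <- colMeans(L)
  Lc <- sweep(L, 2, ctr)
  sv <- svd(Lc)
  if (sv$d[1] < 1e-9) abort("degenerate array: all contacts coincide")
  axis <- sv$v[, 1]
  t_scores <- Lc %*% axis
  ord <- order(t_scores)
  lo <- ord[1]; hi <- ord[K]           # contacts at the two axis ends
  if (!is.null(deep_end)) {
    d_lo <- sum((L[lo, ] - deep_end)^2)
    d_hi <- sum((L[hi, ] - deep_end)^2)
    if (d_hi < d_lo) ord <- rev(ord)
  } else if (!is.null(mask)) {
    dep <- mask_interior_depth(mask, L[c(lo, hi), , drop = FALSE])
    if (dep[2] > dep[1]) ord <- rev(ord)
  } else {
    abort("supply deep_end or mask to orient the array")
  }
  index <- integer(K)
  index[ord] <- seq_len(K)
  set_el(es, index = index)
}

# distance (mm) of world points to the brain-mask boundary, measured inside
# the mask: EDT of the mask complement sampled at the nearest voxel
mask_interior_depth <- function(mask, pts) {
  d2 <- edt_squared(!mask$data, mask$affine)
  v <- round(world_to_voxel(mask, pts))
  dm <- dim(mask$data)
  v <- pmax(pmin(v, matrix(rep(dm - 1L, each = nrow(v)), ncol = 3)), 0)
  sqrt(d2[v + 1])
}

# squared EDT helper: distance to nearest TRUE voxel, world mm (isotropic
# spacing taken from the affine columns)
edt_squared <- function(feature, affine) {
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  d <- .edt_squared(as.logical(feature), dim(feature), sp)
  array(d, dim = dim(feature))
}

#' Project contacts onto their first two principal components
#'
#' Mean-centered projection onto the top-2 principal axes of L; among all
#' rank-2 linear projections this preserves the most variance.
#'
#' @param L K x 3 matrix of contact coordinates (K >= 3, not all collinear).
#' @return K x 2 matrix of planar coordinates.
#' @export
project_pca2 <- function(L) {
  L <- to_mat3(L)
  if (nrow(L) < 3L) abort("need at least 3 points")
  pc <- prcomp(L, center = TRUE, scale. = FALSE)
  if (pc$sdev[2] < 1e-9 * max(pc$sdev[1], 1e-12)) {
    abort("collinear points: no 2D projection")
  }
  pc$x[, 1:2, drop = FALSE]
}

#' Convex hull corners of a projected grid
#'
#' Computes the convex hull of the 2D contact coordinates, measures the
#' transition angle at every hull vertex (the absolute turn between the
#' incoming and outgoing hull segments, degrees), and returns the 4 vertices
#' with the largest angles as the grid corners. Ties are broken by distance
#' from the hull centroid (farthest wins).
#'
#' @param p2 K x 2 matrix of planar coordinates (>= 4 points, not collinear).
#' @return A list of class `iel_hull`: `hull_ids` (counter-clockwise vertex
#'   row ids into `p2`), `angles` (degrees, per hull vertex), `corner_ids`
#'   (4 row ids into `p2`, in counter-clockwise hull order), `points2d`.
#' @export
hull_corners <- function(p2) {
  p2 <- unname(as.matrix(p2))
  if (ncol(p2) != 2L) abort("expected K x 2 coordinates")
  h <- grDevices::chull(p2)           # clockwise order
  h <- rev(h)                         # counter-clockwise
  M <- length(h)
  if (M < 4L) abort(sprintf("convex hull has %d vertices; need >= 4", M))
  P <- p2[h, , drop = FALSE]
  prv <- P[c(M, seq_len(M - 1L)), , drop = FALSE]
  nxt <- P[c(seq_len(M - 1L) + 1L, 1L), , drop = FALSE]
  s_in <- P - prv
  s_out <- nxt - P
  dotp <- rowSums(s_in * s_out)
  nrm <- sqrt(rowSums(s_in^2) * rowSums(s_out^2))
  ang <- acos(pmin(pmax(dotp / nrm, -1), 1)) * 180 / pi
  ctr <- colMeans(P)
  r2 <- rowSums(sweep(P, 2, ctr)^2)
  pick <- order(-ang, -r2)[1:4]
  pick <- sort(pick)                  # keep counter-clockwise hull order
  structure(list(points2d = P, hull_ids = h, angles = ang,
                 corner_ids = h[pick]),
            class = "iel_hull")
}

#' Model an ideal grid from its four corners
#'
#' Bilinear interpolation of the 4 corner coordinates over a rows x cols
#' lattice; corner contacts of the real and ideal grid coincide. Contact 1
#' sits at the first corner and indices fill row-major.
#'
#' @param corners 4 x d matrix (d = 2 or 3) of corner coordinates, ordered
#'   cyclically so adjacent corners share a grid edge: corner 1 -> 2 spans the
#'   column direction, corner 2 -> 3 the row direction.
#' @param rows,cols lattice dimensions (rows * cols >= 4).
#' @return A list of class `iel_idealgrid`: `coords` (K x d, row-major),
#'   `corners`, `rows`, `cols`, `row_col` (tibble index/row/col).
#' @export
build_ideal_grid <- function(corners, rows, cols) {
  corners <- unname(as.matrix(corners))
  if (nrow(corners) != 4L) abort("need exactly 4 corners")
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows * cols < 4L) abort("rows * cols must be >= 4")
  rc <- expand.grid(col = seq_len(cols), row = seq_len(rows))  # row-major
  s <- if (rows > 1L) (rc$row - 1) / (rows - 1) else rep(0, nrow(rc))
  t <- if (cols > 1L) (rc$col - 1) / (cols - 1) else rep(0, nrow(rc))
  # corners: C1 (s=0,t=0), C2 (s=0,t=1), C3 (s=1,t=1), C4 (s=1,t=0)
  W <- cbind((1 - s) * (1 - t), (1 - s) * t, s * t, s * (1 - t))
  coords <- W %*% corners
  structure(list(coords = coords, corners = corners, rows = rows, cols = cols,
                 row_col = tibble(index = seq_len(rows * cols),
                                  row = rc$row, col = rc$col)),
            class = "iel_idealgrid")
}

#' Least-squares sphere fit
#'
#' Algebraic (linear least-squares) sphere fit refined by geometric residual
#' minimization. Near-planar configurations (fitted radius more than 10x the
#' point-cloud extent, or a degenerate algebraic system) fall back to a plane
#' fit, flagged `planar`; radial projection then becomes orthogonal projection
#' onto the best-fit plane.
#'
#' @param L K x 3 matrix of contact coordinates (K >= 4).
#' @return A list of class `iel_sphere`: `center`, `radius`, `rms_residual`,
#'   `planar`, and for the planar fallback `plane_point`, `plane_normal`.
#' @export
fit_sphere <- function(L) {
  L <- to_mat3(L)
  if (nrow(L) < 4L) abort("need at least 4 points to fit a sphere")
  extent <- sqrt(max(dist2_all(L)))
  A <- cbind(2 * L, 1)
  b <- rowSums(L^2)
  qrA <- qr(A)
  sol <- if (qrA$rank == 4L) qr.coef(qrA, b) else NULL
  planar <- is.null(sol)
  if (!planar) {
    ctr <- sol[1:3]
    r2 <- sol[4] + sum(ctr^2)
    planar <- r2 <= 0
    if (!planar) {
      r <- sqrt(r2)
      # geometric refinement
      obj <- function(p) sum((sqrt(rowSums(sweep(L, 2, p[1:3])^2)) - p[4])^2)
      fit <- optim(c(ctr, r), obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
      ctr <- fit$par[1:3]; r <- fit$par[4]
      planar <- !is.finite(r) || r <= 0 || r > 10 * extent
    }
  }
  if (planar) {
    pc <- prcomp(L, center = TRUE, scale. = FALSE)
    nrml <- pc$rotation[, 3]
    resid <- sweep(L, 2, colMeans(L)) %*% nrml
    return(structure(list(center = NULL, radius = Inf,
                          rms_residual = sqrt(mean(resid^2)), planar = TRUE,
                          plane_point = colMeans(L), plane_normal = nrml),
                     class = "iel_sphere"))
  }
  rms <- sqrt(mean((sqrt(rowSums(sweep(L, 2, ctr)^2)) - r)^2))
  structure(list(center = ctr, radius = r, rms_residual = rms, planar = FALSE),
            class = "iel_sphere")
}

dist2_all <- function(X) {
  s <- rowSums(X^2)
  pmax(outer(s, s, "+") - 2 * X %*% t(X), 0)
}

#' Radially project ideal grid coordinates onto a fitted sphere
#'
#' Each point maps to `center + radius * (p - center) / |p - center|`; for a
#' planar fit, orthogonal projection onto the best-fit plane.
#'
#' @param ideal an [build_ideal_grid()] object (or K x 3 matrix).
#' @param sf an [fit_sphere()] object.
#' @return K x 3 matrix of projected coordinates.
#' @export
radial_project <- function(ideal, sf) {
  P <- if (inherits(ideal, "iel_idealgrid")) ideal$coords else to_mat3(ideal)
  if (ncol(P) != 3L) abort("radial projection needs 3D coordinates")
  if (sf$planar) {
    d <- sweep(P, 2, sf$plane_point) %*% sf$plane_normal
    return(P - d %*% t(sf$plane_normal))
  }
  V <- sweep(P, 2, sf$center)
  nv <- sqrt(rowSums(V^2))
  if (any(nv < 1e-12)) abort("point coincides with sphere center")
  sweep(V * (sf$radius / nv), 2, sf$center, "+")
}

#' Greedy short-to-long index assignment
#'
#' Sorts all real-ideal contact pairs by Euclidean distance (ascending) and
#' assigns ideal indices greedily, skipping pairs whose real contact or ideal
#' index is already taken; exact distance ties are broken by (real id,
#' ideal id). The result is a bijection.
#'
#' @param real K x 3 real contact coordinates.
#' @param ideal_proj K x 3 ideal (projected) coordinates; row r carries ideal
#'   index r.
#' @return Integer vector `mapping` with `mapping[i]` the ideal index assigned
#'   to real contact i.
#' @export
assign_indices <- function(real, ideal_proj) {
  real <- to_mat3(real); ideal_proj <- to_mat3(ideal_proj)
  K <- nrow(real)
  if (nrow(ideal_proj) != K) abort("real and ideal sets must have equal K")
  D <- sqrt(pmax(outer(rowSums(real^2), rowSums(ideal_proj^2), "+") -
                   2 * real %*% t(ideal_proj), 0))
  pairs <- cbind(i = rep(seq_len(K), K), j = rep(seq_len(K), each = K))
  ord <- order(D[pairs], pairs[, 1], pairs[, 2])
  mapping <- integer(K)
  taken_ideal <- logical(K)
  for (p in ord) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    if (mapping[i] == 0L && !taken_ideal[j]) {
      mapping[i] <- j
      taken_ideal[j] <- TRUE
    }
  }
  mapping
}

# lattice-adjacent ideal index pairs (|drow| + |dcol| = 1), row-major indexing
lattice_neighbors <- function(rows, cols) {
  idx <- function(r, c) (r - 1L) * cols + c
  out <- NULL
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) out <- rbind(out, c(idx(r, c), idx(r, c + 1L)))
    if (r < rows) out <- rbind(out, c(idx(r, c), idx(r + 1L, c)))
  }
  out
}

#' Refine an index mapping by adjacent-pair permutations
#'
#' Hill-climbing in two phases. Phase 1: repeatedly try swapping every pair of
#' lattice-adjacent indices; accept a swap iff it strictly decreases the sum
#' of real-ideal distances, restarting the sweep after any acceptance, until a
#' full sweep accepts nothing. Phase 2: the identical procedure minimizing the
#' sum of distances between lattice-adjacent contacts in the real grid. Both
#' objectives strictly decrease, so the procedure terminates.
#'
#' @param mapping bijection from [assign_indices()].
#' @param real,ideal_proj K x 3 coordinate matrices.
#' @param spec the grid's [electrode_spec()] (for rows/cols adjacency).
#' @return The refined mapping, with attribute `objectives` recording the
#'   phase-1 and phase-2 objective values before and after.
#' @export
permute_refine <- function(mapping, real, ideal_proj, spec) {
  real <- to_mat3(real); ideal_proj <- to_mat3(ideal_proj)
  K <- length(mapping)
  check_indices(mapping, K)
  nb <- lattice_neighbors(spec$rows, spec$cols)
  dist_ri <- sqrt(pmax(outer(rowSums(real^2), rowSums(ideal_proj^2), "+") -
                         2 * real %*% t(ideal_proj), 0))
  dist_rr <- sqrt(dist2_all(real))

  obj1 <- function(m) sum(dist_ri[cbind(seq_len(K), m)])
  obj2 <- function(m) {
    inv <- order(m)                     # inv[a] = real contact holding index a
    sum(dist_rr[cbind(inv[nb[, 1]], inv[nb[, 2]])])
  }
  climb <- function(m, f) {
    cur <- f(m)
    repeat {
      improved <- FALSE
      inv <- order(m)
      for (p in seq_len(nrow(nb))) {
        a <- nb[p, 1]; b <- nb[p, 2]
        m2 <- m
        m2[inv[a]] <- b; m2[inv[b]] <- a
        val <- f(m2)
        if (val < cur - 1e-12) {
          m <- m2; cur <- val; improved <- TRUE
          break                          # restart the sweep
        }
      }
      if (!improved) break
    }
    list(m = m, value = cur)
  }
  before1 <- obj1(mapping)
  s1 <- climb(mapping, obj1)
  before2 <- obj2(s1$m)
  s2 <- climb(s1$m, obj2)
  structure(s2$m, objectives = c(ideal_before = before1, ideal_after = s1$value,
                                 neighbor_before = before2, neighbor_after = s2$value))
}

# order hull corners cyclically so corner 1 is nearest the first stored
# contact and corner1 -> corner2 spans the column direction
orient_corners <- function(L, corner_ids, spec) {
  k <- length(corner_ids)
  start <- which.min(rowSums(sweep(L[corner_ids, , drop = FALSE], 2, L[1, ])^2))
  cyc <- corner_ids[((seq_len(k) + start - 2L) %% k) + 1L]
  d12 <- sqrt(sum((L[cyc[2], ] - L[cyc[1], ])^2))
  d14 <- sqrt(sum((L[cyc[4], ] - L[cyc[1], ])^2))
  col_ext <- (spec$cols - 1L) * spec$pitch
  row_ext <- (spec$rows - 1L) * spec$pitch
  keep <- abs(d12 - col_ext) + abs(d14 - row_ext)
  swap <- abs(d12 - row_ext) + abs(d14 - col_ext)
  if (swap < keep) cyc <- cyc[c(1, 4, 3, 2)]   # reverse traversal direction
  cyc
}

#' Number a grid array
#'
#' The full grid numbering procedure: project contacts onto their first two
#' principal components, find the convex-hull corners from the four largest
#' transition angles, model an ideal grid by bilinear interpolation of the
#' corner contacts, radially project it onto the best-fitting sphere (or
#' plane), assign indices greedily from short to long distances, and refine by
#' adjacent-pair permutations. The global flip/rotation remains arbitrary (8
#' lattice symmetries) and is normalized manually with [flip_rotate()].
#'
#' @param es an unnumbered [electrodes()] table of kind grid.
#' @return The electrode table with `index` set; attribute `numbering` records
#'   sphere-fit and refinement diagnostics.
#' @export
number_grid <- function(es) {
  sp <- el_spec(es)
  if (sp$kind != "grid") abort("number_grid needs a grid array")
  L <- el_coords(es)
  p2 <- project_pca2(L)
  hc <- hull_corners(p2)
  cyc <- orient_corners(L, hc$corner_ids, sp)
  ideal <- build_ideal_grid(L[cyc, , drop = FALSE], sp$rows, sp$cols)
  sf <- fit_sphere(L)
  proj <- radial_project(ideal, sf)
  m0 <- assign_indices(L, proj)
  m <- permute_refine(m0, L, proj, sp)
  out <- set_el(es, index = as.integer(m))
  attr(out, "numbering") <- list(sphere = sf,
                                 objectives = attr(m, "objectives"),
                                 corner_ids = cyc)
  out
}

#' Number any electrode array
#'
#' Dispatches to [number_grid()] for grids and [number_depth()] for depth and
#' strip arrays.
#'
#' @inheritParams number_depth
#' @export
number_electrodes <- function(es, deep_end = NULL, mask = NULL) {
  sp <- el_spec(es)
  if (sp$kind == "grid") number_grid(es) else number_depth(es, deep_end, mask)
}

# lattice symmetry re-indexing maps ------------------------------------------

#' Flip or rotate a grid's numbering
#'
#' Re-indexes the contacts via the corresponding rows x cols lattice symmetry;
#' coordinates are untouched. Rotations on a non-square grid exchange rows and
#' cols in the spec.
#'
#' @param es a numbered grid [electrodes()] table.
#' @param op one of `"flip_ud"`, `"flip_lr"`, `"rot_cw"`, `"rot_ccw"`.
#' @return The re-indexed electrode table.
#' @export
flip_rotate <- function(es, op = c("flip_ud", "flip_lr", "rot_cw", "rot_ccw")) {
  op <- match.arg(op)
  sp <- el_spec(es)
  if (sp$kind != "grid") abort("flip/rotate applies to grids")
  check_indices(es$index, sp$K)
  rows <- sp$rows; cols <- sp$cols
  r <- (es$index - 1L) %/% cols + 1L
  c <- (es$index - 1L) %% cols + 1L
  if (op == "flip_ud") {
    r2 <- rows + 1L - r; c2 <- c; nr <- rows; nc <- cols
  } else if (op == "flip_lr") {
    r2 <- r; c2 <- cols + 1L - c; nr <- rows; nc <- cols
  } else if (op == "rot_cw") {
    r2 <- c; c2 <- rows + 1L - r; nr <- cols; nc <- rows
  } else {                              # rot_ccw
    r2 <- cols + 1L - c; c2 <- r; nr <- cols; nc <- rows
  }
  idx2 <- (r2 - 1L) * nc + c2
  sp2 <- sp; sp2$rows <- nr; sp2$cols <- nc
  out <- set_el(es, index = as.integer(idx2))
  attr(out, "spec") <- sp2
  if (!all(is.na(es$name))) out <- name_electrodes(out)
  out
}

# all 8 lattice symmetries as flip/rotate op sequences (identity included)
grid_symmetry_ops <- function() {
  list(character(0), "rot_cw", c("rot_cw", "rot_cw"), "rot_ccw",
       "flip_lr", c("flip_lr", "rot_cw"), c("flip_lr", "rot_cw", "rot_cw"),
       c("flip_lr", "rot_ccw"))
}

#' Match two coordinate sets bijectively
#'
#' Greedy shortest-distance-first bijection between two equal-size coordinate
#' sets; used to compare localized contacts with ground truth or across runs.
#'
#' @param a,b n x 3 coordinate matrices.
#' @return A tibble with columns `a` (row in `a`), `b` (matched row in `b`),
#'   `distance` (mm).
#' @export
match_coordinates <- function(a, b) {
  a <- to_mat3(a); b <- to_mat3(b)
  if (nrow(a) != nrow(b)) abort("coordinate sets must have equal size")
  m <- assign_indices(a, b)
  d <- sqrt(rowSums((a - b[m, , drop = FALSE])^2))
  tibble(a = seq_len(nrow(a)), b = m, distance = d)
}
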