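# Shared fixtures, built in code. Expensive objects are cached per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# spherical brain mask of given radius (mm) on a 1 mm grid centered at 0
ball_mask <- function(radius = 25, n = 64L) {
  org <- -floor(n / 2)
  xs <- org + 0:(n - 1)
  r2 <- outer(outer(xs^2, xs^2, "+"), xs^2, "+")
  aff <- diag(4); aff[1:3, 4] <- rep(org, 3)
  as_mask(r2 <= radius^2, aff)
}

# smoothed envelope of the 25 mm ball, built once
test_sce <- function() cached("sce25", build_sce(ball_mask(25, 64L)))

# a small, fast phantom: 4x5 grid on a 40 mm sphere + 8-contact depth array
small_phantom <- function(noise_sd = 0, seed = 1L, marker = FALSE,
                          depth_pitch = 5) {
  ctr <- c(0, 0, -10)
  w <- c(sin(0.9), 0, cos(0.9))       # depth entry ~52 deg off vertical
  entry <- ctr + 0.8 * 40 * w
  arrays <- list(
    phantom_grid(4, 5, pitch = 10, prefix = "G", cap_axis = c(0.1, 0, 1),
                 orientation = 0.4, marker = marker),
    phantom_depth(8, pitch = depth_pitch, prefix = "D",
                  tip = entry - 7 * depth_pitch * w, direction = w)
  )
  make_phantom(arrays, shape = c(100L, 100L, 100L), origin = c(-50, -50, -60),
               noise_sd = noise_sd, seed = seed, brain_center = ctr,
               brain_radius = 40, skull_inner = 48, skull_outer = 51)
}

# exact truth coordinates of one array as a K x 3 matrix
truth_coords <- function(ph, prefix) {
  tt <- ph$truth[ph$truth$array == prefix, ]
  cbind(tt$x, tt$y, tt$z)
}

# exhaustive best K-partition of points by within-cluster sum of squares
exhaustive_best_wss <- function(X, K) {
  n <- nrow(X)
  best <- Inf
  assign_next <- function(a, i, used) {
    if (i > n) {
      if (length(unique(a)) == K) {
        wss <- 0
        for (k in unique(a)) {
          pts <- X[a == k, , drop = FALSE]
          wss <- wss + sum(sweep(pts, 2, colMeans(pts))^2)
        }
        best <<- min(best, wss)
      }
      return(invisible())
    }
    for (k in seq_len(min(used + 1L, K))) {
      a[i] <- k
      assign_next(a, i + 1L, max(used, k))
    }
  }
  assign_next(integer(n), 1L, 0L)
  best
}

# grid numbering agrees with truth up to the 8 lattice symmetries
matches_up_to_symmetry <- function(es, truth_index) {
  for (ops in ieegloc:::grid_symmetry_ops()) {
    g <- es
    for (op in ops) g <- flip_rotate(g, op)
    if (all(g$index == truth_index)) return(TRUE)
  }
  FALSE
}
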