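# Cluster an array's voxels into K contacts and take intensity-weighted
# centers of mass.

# k-means++ seeding (Arthur & Vassilvitskii 2007) on world coordinates
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  cent <- integer(K)
  cent[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2, X[cent[1], ], "-")^2)
  for (k in seq_len(K - 1L) + 1L) {
    if (sum(d2) <= 0) {
      cent[k] <- sample.int(n, 1L)
    } else {
      cent[k] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[cent[k], ], "-")^2))
  }
  X[cent, , drop = FALSE]
}

# reassign-to-nearest / recompute-means fixpoint polish; guarantees the final
# assignment is a Voronoi partition of its own centroids
lloyd_polish <- function(X, centers, max_iter = 100L) {
  for (it in seq_len(max_iter)) {
    D2 <- outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * X %*% t(centers)
    a <- max.col(-D2, ties.method = "first")
    if (length(unique(a)) < nrow(centers)) break  # refuse to empty a cluster
    newc <- apply_centroids(X, a, nrow(centers))
    if (max(abs(newc - centers)) < 1e-12) { centers <- newc; break }
    centers <- newc
  }
  D2 <- outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * X %*% t(centers)
  a <- max.col(-D2, ties.method = "first")
  list(assignment = a, centers = centers,
       objective = sum(pmax(D2[cbind(seq_len(nrow(X)), a)], 0)))
}

apply_centroids <- function(X, a, K) {
  out <- matrix(NA_real_, K, ncol(X))
  for (k in seq_len(K)) out[k, ] <- colMeans(X[a == k, , drop = FALSE])
  out
}

#' Cluster electrode voxels with K-means
#'
#' Partitions the voxel cloud of one array into `K` clusters (one per contact)
#' by K-means on the unweighted world coordinates, minimizing the
#' within-cluster sum of squares. Initialization is k-means++ with `nstart`
#' restarts under a fixed seed; the best objective is kept and polished to a
#' Lloyd fixpoint so every voxel ends in its nearest centroid's cluster.
#'
#' @param cloud an `iel_cloud` with at least `K` voxels.
#' @param K number of contacts in the array.
#' @param seed RNG seed making the clustering deterministic.
#' @param nstart number of k-means++ restarts (>= 10 by default).
#' @param max_restarts extra re-initializations allowed when a restart
#'   produces an empty cluster.
#' @return A list of class `iel_clusters`: `assignment` (per-voxel cluster id),
#'   `clusters` (list of K voxel-row index vectors), `centers`, `objective`.
#' @export
cluster_voxels <- function(cloud, K, seed = 1L, nstart = 10L, max_restarts = 50L) {
  K <- as.integer(K)
  X <- cbind(cloud$x, cloud$y, cloud$z)
  n <- nrow(X)
  if (K < 1L) abort("K must be >= 1")
  if (n < K) abort(sprintf("cannot form %d clusters from %d voxels", K, n))
  if (K == n) {
    return(structure(list(assignment = seq_len(n),
                          clusters = as.list(seq_len(n)),
                          centers = X, objective = 0),
                     class = "iel_clusters"))
  }
  best <- NULL
  run_start <- function(init) {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = init, iter.max = 100L,
                                     algorithm = "Lloyd")),
      error = function(e) NULL
    )
    # Lloyd leaves NaN centers when a cluster empties: treat as a failed
    # start and re-initialize
    if (is.null(km) || any(!is.finite(km$centers))) return(NULL)
    lloyd_polish(X, km$centers)
  }
  # informed start: when the cloud splits into exactly K connected components
  # (the well-separated regime), their centroids are a deterministic init that
  # avoids the merged-contact local optimum
  comp <- tryCatch({
    cl2 <- if (is.null(cloud[["component"]])) label_components(cloud) else cloud
    cl2$component
  }, error = function(e) NULL)
  if (!is.null(comp) && length(unique(comp)) == K) {
    init <- apply_centroids(X, comp, K)
    if (!anyDuplicated(init)) {
      fit <- run_start(init)
      if (!is.null(fit)) best <- fit
    }
  }
  with_seed(seed, {
    done <- 0L; tries <- 0L
    while (done < nstart && tries < nstart + max_restarts) {
      tries <- tries + 1L
      init <- kmeanspp_centers(X, K)
      if (anyDuplicated(init)) next
      fit <- run_start(init)
      if (is.null(fit)) next
      done <- done + 1L
      if (is.null(best) || fit$objective < best$objective - 1e-12) best <- fit
    }
    if (is.null(best)) {
      abort("K-means failed: empty cluster after maximum restarts")
    }
  })
  structure(list(assignment = best$assignment,
                 clusters = split(seq_len(n), best$assignment),
                 centers = best$centers,
                 objective = best$objective),
            class = "iel_clusters")
}

#' Intensity-weighted center of mass of a voxel cluster
#'
#' `sum(w_i * x_i) / sum(w_i)` over the cluster's voxels with CT intensities
#' as weights.
#'
#' @param cluster integer row indices into `cloud`.
#' @param cloud an `iel_cloud`.
#' @return World mm coordinate triple.
#' @export
center_of_mass <- function(cluster, cloud) {
  if (length(cluster) == 0L) abort("empty cluster")
  w <- cloud$intensity[cluster]
  if (any(w <= 0)) abort("intensities must be > 0 for weighting")
  tw <- sum(w)
  c(sum(w * cloud$x[cluster]), sum(w * cloud$y[cluster]),
    sum(w * cloud$z[cluster])) / tw
}

#' Localize one electrode array
#'
#' Clusters the array's voxel cloud into `spec$K` contacts and returns the
#' intensity-weighted center of mass of each cluster. Row order is cluster
#' label order and carries no meaning until numbering.
#'
#' @param cloud the array's `iel_cloud`.
#' @param spec the array's [electrode_spec()].
#' @param seed RNG seed for the clustering.
#' @return An [electrodes()] table with unset `index`/`name`.
#' @export
localize_array <- function(cloud, spec, seed = 1L) {
  cl <- cluster_voxels(cloud, spec$K, seed = seed)
  L <- t(vapply(cl$clusters, center_of_mass, numeric(3), cloud = cloud))
  es <- electrodes(L, spec)
  attr(es, "clustering") <- list(objective = cl$objective, n_voxels = nrow(cloud))
  es
}
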