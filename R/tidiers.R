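# broom-style tidiers and ggplot2 displays for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a grid projection result
#'
#' One row per contact: original and projected coordinates and the
#' displacement distance `|D_k|`.
#'
#' @param x an `iel_projection`.
#' @param ... unused.
#' @method tidy iel_projection
#' @export
tidy.iel_projection <- function(x, ...) {
  es <- x$electrodes
  tibble(name = es$name, index = es$index,
         x0 = x$L0[, 1], y0 = x$L0[, 2], z0 = x$L0[, 3],
         x = x$L[, 1], y = x$L[, 2], z = x$L[, 3],
         displacement = x$distances)
}

#' @rdname tidy.iel_projection
#' @method glance iel_projection
#' @export
glance.iel_projection <- function(x, ...) {
  tibble(energy = x$energy, mean_displacement = mean(x$distances),
         median_displacement = median(x$distances),
         max_displacement = max(x$distances),
         converged = x$converged, n_contacts = nrow(x$L))
}

#' Tidy a paired permutation test
#'
#' @param x an `iel_permtest`.
#' @param ... unused.
#' @method tidy iel_permtest
#' @export
tidy.iel_permtest <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value,
         n = x$n, n_perm = x$n_perm, method = "paired sign-flip permutation")
}

#' @rdname tidy.iel_permtest
#' @method glance iel_permtest
#' @export
glance.iel_permtest <- function(x, ...) tidy(x)

#' Plot an electrode array in its principal plane
#'
#' Contacts projected onto their first two principal components, labeled by
#' index when numbered.
#'
#' @param es an [electrodes()] table.
#' @return A ggplot object.
#' @export
plot_electrodes <- function(es) {
  L <- el_coords(es)
  p2 <- if (nrow(L) >= 3) {
    pc <- prcomp(L, center = TRUE)
    if (pc$sdev[2] > 1e-9) pc$x[, 1:2] else cbind(pc$x[, 1], 0)
  } else cbind(L[, 1], L[, 2])
  df <- tibble(u = p2[, 1], v = p2[, 2],
               lab = ifelse(is.na(es$index), "", as.character(es$index)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v)) +
    ggplot2::geom_point(size = 3, colour = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = .data$lab), nudge_y = 1.2, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "PC1 (mm)", y = "PC2 (mm)",
                  title = sprintf("%s array, %d contacts",
                                  el_spec(es)$kind, nrow(es))) +
    ggplot2::theme_minimal()
}

#' Histogram of projection displacements
#'
#' Distances of grid contacts to the smoothed cortical envelope, the
#' normalization-performance display.
#'
#' @param object an `iel_projection`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot iel_projection
#' @export
autoplot.iel_projection <- function(object, ...) {
  df <- tibble(displacement = object$distances)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$displacement)) +
    ggplot2::geom_histogram(binwidth = 0.5, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "|D_k| (mm)", y = "contacts",
                  title = "Grid displacement to cortical envelope") +
    ggplot2::theme_minimal()
}

#' Plot a voxel cloud by intensity
#'
#' @param cloud an `iel_cloud`.
#' @return A ggplot object (first two principal components, colored by HU).
#' @export
plot_cloud <- function(cloud) {
  X <- cbind(cloud$x, cloud$y, cloud$z)
  pc <- prcomp(X, center = TRUE)
  df <- tibble(u = pc$x[, 1], v = pc$x[, 2], hu = cloud$intensity)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v, colour = .data$hu)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_viridis_c(name = "HU") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "PC1 (mm)", y = "PC2 (mm)") +
    ggplot2::theme_minimal()
}
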