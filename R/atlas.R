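# Probabilistic-atlas anatomical labeling of contact coordinates.

#' Construct a probabilistic atlas
#'
#' @param maps 4D array, one 3D probability map per region (values 0-100 or
#'   0-1; reported as sampled, never renormalized).
#' @param affine 4x4 voxel-to-world transform.
#' @param region_names character vector, one name per 4th-dimension slice.
#' @return A list of class `iel_atlas`.
#' @export
as_atlas <- function(maps, affine, region_names) {
  if (length(dim(maps)) != 4L) abort("atlas maps must be a 4D array")
  if (dim(maps)[4] != length(region_names)) {
    abort("number of region names must match the 4th map dimension")
  }
  if (any(maps < 0)) abort("probabilities must be >= 0")
  structure(list(maps = maps, affine = unname(as.matrix(affine)),
                 region_names = as.character(region_names)),
            class = "iel_atlas")
}

#' Read a 4D NIfTI atlas with a sidecar label table
#'
#' The label table is a TSV with columns `index` (1-based 4th-dimension slice)
#' and `name`; this layout is compatible with FSL-distributed probabilistic
#' atlas volumes.
#'
#' @param maps_path 4D NIfTI file.
#' @param labels_path TSV label table.
#' @return An [as_atlas()] object.
#' @export
load_atlas <- function(maps_path, labels_path) {
  img <- RNifti::readNifti(maps_path)
  if (length(dim(img)) != 4L) abort("expected a 4D atlas volume")
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  labs <- readr::read_tsv(labels_path, show_col_types = FALSE)
  labs <- labs[order(labs$index), ]
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  as_atlas(arr, aff, labs$name)
}

#' Write an atlas to 4D NIfTI + TSV
#'
#' @param atlas an `iel_atlas`.
#' @param maps_path,labels_path output paths.
#' @export
save_atlas <- function(atlas, maps_path, labels_path) {
  img <- RNifti::asNifti(atlas$maps)
  img <- RNifti::`sform<-`(img, structure(atlas$affine, code = 2L))
  RNifti::writeNifti(img, maps_path)
  readr::write_tsv(tibble(index = seq_along(atlas$region_names),
                          name = atlas$region_names), labels_path)
  invisible(maps_path)
}

#' Label a single coordinate from a probabilistic atlas
#'
#' Samples each region map at the voxel containing the coordinate
#' (nearest-voxel lookup, no interpolation) and returns the regions with
#' probability > 0 in descending order, truncated to `top_n`. Probability ties
#' are broken lexicographically by region name.
#'
#' @param atlas an `iel_atlas`.
#' @param xyz world mm coordinate triple.
#' @param top_n maximum number of regions returned.
#' @return A tibble with columns `region`, `probability`; empty with attribute
#'   `outside = TRUE` when the coordinate falls outside the atlas grid.
#' @export
label_point <- function(atlas, xyz, top_n = 3L) {
  v <- round(solve(atlas$affine) %*% c(xyz, 1))[1:3]
  d <- dim(atlas$maps)[1:3]
  if (any(v < 0) || any(v >= d)) {
    out <- tibble(region = character(), probability = double())
    attr(out, "outside") <- TRUE
    return(out)
  }
  p <- atlas$maps[v[1] + 1, v[2] + 1, v[3] + 1, ]
  keep <- which(p > 0)
  ord <- keep[order(-p[keep], atlas$region_names[keep])]
  ord <- ord[seq_len(min(top_n, length(ord)))]
  tibble(region = atlas$region_names[ord], probability = as.numeric(p[ord]))
}

#' Label every contact of an electrode table
#'
#' Applies [label_point()] (top 3) per contact. Contacts outside the atlas or
#' with all-zero probabilities are flagged in the `label_status` column rather
#' than aborting the table.
#'
#' @param atlas an `iel_atlas`.
#' @param es a named [electrodes()] table.
#' @return A tibble with one row per contact: `name`, `x`, `y`, `z`, `label`,
#'   `probability`, `alternates`, `label_status`.
#' @export
label_set <- function(atlas, es) {
  if (all(is.na(es$name))) abort("name the electrodes before labeling")
  rows <- purrr::map(seq_len(nrow(es)), function(r) {
    lp <- label_point(atlas, c(es$x[r], es$y[r], es$z[r]), top_n = 3L)
    if (isTRUE(attr(lp, "outside"))) {
      tibble(label = NA_character_, probability = NA_real_,
             alternates = NA_character_, label_status = "outside atlas")
    } else if (nrow(lp) == 0L) {
      tibble(label = "unlabeled", probability = 0,
             alternates = NA_character_, label_status = "unlabeled")
    } else {
      alt <- if (nrow(lp) > 1L) {
        paste(sprintf("%s (%g)", lp$region[-1], lp$probability[-1]),
              collapse = "; ")
      } else NA_character_
      tibble(label = lp$region[1], probability = lp$probability[1],
             alternates = alt, label_status = "ok")
    }
  })
  dplyr::bind_cols(
    tibble(name = es$name, index = es$index, x = es$x, y = es$y, z = es$z),
    dplyr::bind_rows(rows)
  )
}
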