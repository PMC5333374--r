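# Electrode array specification and the electrode table (K x 3 coordinates).

#' Describe an electrode array
#'
#' @param kind `"grid"`, `"strip"` or `"depth"`. Grids require
#'   `rows >= 2` and `cols >= 2`; strips and depth arrays use `rows = 1`.
#' @param rows,cols lattice dimensions; `K = rows * cols` contacts.
#' @param pitch inter-contact center-to-center spacing in mm (> 0).
#' @param prefix short name prefix used when naming contacts.
#' @return A list of class `iel_spec`.
#' @export
electrode_spec <- function(kind = c("grid", "strip", "depth"),
                           rows = 1L, cols = 1L, pitch = 10, prefix = "E") {
  kind <- match.arg(kind)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (kind %in% c("strip", "depth")) {
    if (rows > 1L && cols == 1L) { cols <- rows; rows <- 1L }
    if (rows != 1L) abort("strip/depth arrays are 1 x N (rows = 1)")
  } else {
    if (rows < 2L || cols < 2L) abort("grids require rows >= 2 and cols >= 2")
  }
  if (pitch <= 0) abort("pitch must be > 0")
  K <- rows * cols
  if (K < 1L) abort("array must have at least one contact")
  structure(list(kind = kind, rows = rows, cols = cols, pitch = pitch,
                 prefix = prefix, K = K),
            class = "iel_spec")
}

#' @export
print.iel_spec <- function(x, ...) {
  cat(sprintf("<iel_spec> %s %dx%d, pitch %g mm, prefix '%s'\n",
              x$kind, x$rows, x$cols, x$pitch, x$prefix))
  invisible(x)
}

#' Build an electrode table
#'
#' An electrode set is a tibble with one row per contact: `index` (1..K once
#' numbered, NA before), `name` (once named), world mm coordinates `x`,`y`,`z`,
#' and the array spec attached as attribute `spec`.
#'
#' @param coords K x 3 matrix of world mm coordinates.
#' @param spec an [electrode_spec()].
#' @param index optional permutation of 1..K.
#' @param name optional character vector of contact names.
#' @return A tibble of class `iel_electrodes`.
#' @export
electrodes <- function(coords, spec, index = NA_integer_, name = NA_character_) {
  coords <- to_mat3(coords)
  if (!all(is.finite(coords))) abort("electrode coordinates must be finite")
  if (nrow(coords) != spec$K) {
    abort(sprintf("expected %d contacts, got %d", spec$K, nrow(coords)))
  }
  if (!all(is.na(index))) check_indices(index, spec$K)
  tbl <- tibble(index = as.integer(index), name = as.character(name),
                x = coords[, 1], y = coords[, 2], z = coords[, 3])
  attr(tbl, "spec") <- spec
  class(tbl) <- c("iel_electrodes", class(tbl))
  tbl
}

check_indices <- function(index, K) {
  if (length(index) != K || anyNA(index) || !setequal(index, seq_len(K))) {
    abort("indices must be a permutation of 1..K")
  }
  invisible(TRUE)
}

#' @export
print.iel_electrodes <- function(x, ...) {
  sp <- el_spec(x)
  cat(sprintf("<iel_electrodes> %s %dx%d ('%s'), %d contacts\n",
              sp$kind, sp$rows, sp$cols, sp$prefix, nrow(x)))
  NextMethod()
}

#' @rdname electrodes
#' @param es an `iel_electrodes` table.
#' @export
el_spec <- function(es) {
  sp <- attr(es, "spec")
  if (is.null(sp)) abort("electrode table has lost its spec attribute")
  sp
}

#' @rdname electrodes
#' @export
el_coords <- function(es) {
  unname(cbind(es$x, es$y, es$z))
}

set_el <- function(es, ...) {
  sp <- el_spec(es)
  dots <- list(...)
  for (nm in names(dots)) es[[nm]] <- dots[[nm]]
  attr(es, "spec") <- sp
  es
}

#' Name electrodes by index
#'
#' Names are either `prefix` followed by the contact index ("Grid1" ... "GridK")
#' or an explicit ordered list matched by index.
#'
#' @param es a numbered `iel_electrodes` table.
#' @param labels a single prefix string, or a character vector of length K
#'   giving the name of contact 1..K; defaults to the spec prefix.
#' @return The electrode table with the `name` column filled.
#' @export
name_electrodes <- function(es, labels = NULL) {
  sp <- el_spec(es)
  check_indices(es$index, sp$K)
  labels <- labels %||% sp$prefix
  if (length(labels) == 1L) {
    nm <- paste0(labels, es$index)
  } else {
    if (length(labels) != sp$K) {
      abort(sprintf("expected %d names, got %d", sp$K, length(labels)))
    }
    nm <- labels[es$index]
  }
  set_el(es, name = nm)
}

#' Write an electrode table to TSV
#'
#' Columns `name`, `index`, `x_mm`, `y_mm`, `z_mm` (plus any label columns).
#' @param es an `iel_electrodes` table.
#' @param path output path.
#' @export
write_electrodes <- function(es, path) {
  out <- tibble(name = es$name, index = es$index,
                x_mm = es$x, y_mm = es$y, z_mm = es$z)
  extra <- setdiff(names(es), c("name", "index", "x", "y", "z"))
  for (nm in extra) out[[nm]] <- es[[nm]]
  readr::write_tsv(out, path)
  invisible(path)
}
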