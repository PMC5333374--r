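# Declarative end-to-end pipeline: every interactive step (threshold tuning,
# voxel selection, flips, deep-end hints) is a config entry so runs are
# reproducible.

#' Read a pipeline run configuration
#'
#' The config is a single YAML or JSON document:
#' ```yaml
#' ct: phantom_ct.nii.gz
#' mask: phantom_mask.nii.gz
#' atlas:                # optional
#'   maps: atlas.nii.gz
#'   labels: atlas_labels.tsv
#' output_dir: out
#' seed: 1
#' sigma_R: 5            # optional, for projection
#' project: false        # or {hemisphere: left}
#' arrays:
#'   - prefix: D
#'     kind: depth
#'     contacts: 8
#'     pitch: 5
#'     threshold: 1800
#'     mask_iterations: 0
#'     deep_end: [10, 0, -20]        # optional; mask used otherwise
#'     select: {box: [[-20,-20,-60],[30,20,40]]}   # or {near: [[x,y,z],...], radius: 5}
#'     min_component: 2
#'   - prefix: G
#'     kind: grid
#'     rows: 4
#'     cols: 5
#'     pitch: 10
#'     threshold: 1800
#'     mask_iterations: 4
#'     flips: [flip_lr]              # optional normalization ops
#' ```
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @return The config as a named list, validated.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  for (field in c("ct", "mask", "arrays")) {
    if (is.null(cfg[[field]])) abort(sprintf("config field missing: %s", field))
  }
  prefixes <- vapply(cfg$arrays, function(a) a$prefix %||% "", "")
  if (anyDuplicated(prefixes)) abort("array prefixes must be unique")
  for (a in cfg$arrays) {
    if (!is.null(a$threshold) && a$threshold <= 0) {
      abort(sprintf("array %s: threshold must be > 0", a$prefix))
    }
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg$output_dir <- cfg$output_dir %||% "."
  cfg
}

array_spec_from_config <- function(a) {
  kind <- a$kind %||% "depth"
  if (kind == "grid") {
    electrode_spec("grid", a$rows, a$cols, a$pitch %||% 10, a$prefix)
  } else {
    electrode_spec(kind, 1L, a$contacts %||% a$cols, a$pitch %||% 10, a$prefix)
  }
}

apply_selection <- function(cloud, sel) {
  if (is.null(sel)) return(cloud)
  if (!is.null(sel$box)) {
    b <- sel$box
    lower <- as.numeric(b[[1]]); upper <- as.numeric(b[[2]])
    cloud <- select_box(cloud, lower, upper)
  }
  if (!is.null(sel$near)) {
    pts <- do.call(rbind, lapply(sel$near, as.numeric))
    cloud <- select_near_points(cloud, pts, sel$radius %||% 5)
  }
  if (!is.null(sel$components)) {
    cloud <- remove_components(cloud, keep = as.integer(sel$components))
  }
  cloud
}

#' Run the full localization pipeline from a config
#'
#' For every configured array: adjust the brain mask, threshold the CT,
#' apply the configured voxel selection, remove small components, cluster and
#' localize, number (with configured flips), name, and (optionally) label
#' from the atlas. Writes one TSV per array plus a combined table and a JSON
#' log of thresholds, clustering objectives and numbering diagnostics. A
#' failing array is recorded and the remaining arrays still run.
#'
#' @param config a config list or path (see [read_config()]).
#' @return A list of class `iel_run`: `electrodes` (named list of tables),
#'   `labels` (if an atlas was given), `log`, `failed` (named character
#'   vector of per-array error messages), `output_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else validate_config(config)
  ct <- load_volume(cfg$ct)
  mask <- load_mask(cfg$mask)
  atlas <- if (!is.null(cfg$atlas)) load_atlas(cfg$atlas$maps, cfg$atlas$labels)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(); labels <- list(); failed <- character()
  log <- list(seed = cfg$seed)
  for (a in cfg$arrays) {
    res <- tryCatch({
      sp <- array_spec_from_config(a)
      thr <- a$threshold %||% 1800
      m <- morph_adjust(mask, a$mask_iterations %||% 0L)
      cloud <- threshold_ct(ct, m, thr)
      cloud <- apply_selection(cloud, a$select)
      cloud <- remove_components(cloud, min_size = a$min_component %||% 1L)
      es <- localize_array(cloud, sp, seed = cfg$seed)
      es <- if (sp$kind == "grid") {
        g <- number_grid(es)
        for (op in a$flips %||% character()) g <- flip_rotate(g, op)
        g
      } else {
        number_depth(es, deep_end = if (!is.null(a$deep_end)) as.numeric(a$deep_end),
                     mask = mask)
      }
      es <- name_electrodes(es, a$labels)
      log[[a$prefix]] <- list(
        threshold = thr, mask_iterations = a$mask_iterations %||% 0L,
        n_voxels = attr(es, "clustering")$n_voxels,
        kmeans_objective = attr(es, "clustering")$objective,
        numbering = if (!is.null(attr(es, "numbering"))) {
          as.list(attr(es, "numbering")$objectives)
        }
      )
      es
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[a$prefix] <- conditionMessage(res)
      next
    }
    results[[a$prefix]] <- res
    write_electrodes(res, file.path(cfg$output_dir, paste0(a$prefix, "_electrodes.tsv")))
    if (!is.null(atlas)) {
      lab <- label_set(atlas, res)
      labels[[a$prefix]] <- lab
      readr::write_tsv(lab, file.path(cfg$output_dir, paste0(a$prefix, "_labels.tsv")))
    }
  }
  if (length(results)) {
    combined <- purrr::map_dfr(names(results), function(nm) {
      es <- results[[nm]]
      tibble(array = nm, name = es$name, index = es$index,
             x_mm = es$x, y_mm = es$y, z_mm = es$z)
    })
    readr::write_tsv(combined, file.path(cfg$output_dir, "electrodes.tsv"))
  }
  jsonlite::write_json(log, file.path(cfg$output_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(electrodes = results, labels = labels, log = log,
                 failed = failed, output_dir = cfg$output_dir),
            class = "iel_run")
}

#' @export
print.iel_run <- function(x, ...) {
  cat(sprintf("<iel_run> %d arrays localized, %d failed, outputs in %s\n",
              length(x$electrodes), length(x$failed), x$output_dir))
  if (length(x$failed)) {
    for (nm in names(x$failed)) cat(sprintf("  FAILED %s: %s\n", nm, x$failed[nm]))
  }
  invisible(x)
}
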