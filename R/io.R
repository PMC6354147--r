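#' Write a volume as a multi-page TIFF stack with a JSON sidecar
#'
#' Grayscale intensities are rescaled to \[0, 1\] for TIFF storage; the
#' sidecar (`<path>.json`) records the original intensity range, spacing,
#' origin, and (optionally) the generating [phantom_spec()] including its
#' seed, so the stack round-trips and its provenance is preserved. Phase
#' volumes are stored as labels / 2.
#'
#' @param volume A [voxel_volume()] or [phase_volume()].
#' @param path Output `.tiff` path.
#' @param spec Optional [phantom_spec()] to embed in the sidecar.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path, spec = NULL) {
  is_phase <- inherits(volume, "phase_volume")
  arr <- if (is_phase) volume$labels else volume$values
  rng <- if (is_phase) c(0, 2) else range(arr)
  scaled <- if (diff(rng) > 0) (arr - rng[1]) / diff(rng) else arr * 0
  pages <- lapply(seq_len(dim(arr)[3]), function(k) scaled[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(kind = if (is_phase) "phase_volume" else "voxel_volume",
               dim = dim(arr), spacing = volume$spacing,
               origin = volume$origin, value_range = rng)
  if (!is.null(spec)) meta$phantom_spec <- unclass(spec)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a volume written by [write_volume_tiff()]
#'
#' @param path `.tiff` path with its `.json` sidecar alongside.
#' @return A [voxel_volume()] or [phase_volume()] per the sidecar.
#' @export
read_volume_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  rng <- meta$value_range
  arr <- arr * diff(rng) + rng[1]
  if (meta$kind == "phase_volume") {
    phase_volume(array(as.integer(round(arr)), dim = dim(arr)),
                 spacing = meta$spacing, origin = meta$origin)
  } else {
    voxel_volume(arr, spacing = meta$spacing, origin = meta$origin)
  }
}

#' Serialize a section plane to JSON at full precision
#'
#' @param plane A [section_plane()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_plane_json <- function(plane, path) {
  stopifnot(inherits(plane, "section_plane"))
  jsonlite::write_json(unclass(plane), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a section plane serialized by [write_plane_json()]
#'
#' @param path `.json` path.
#' @return A [section_plane()].
#' @export
read_plane_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  section_plane(p$origin, p$normal, p$u_axis, p$v_axis, p$pixel_pitch,
                p$extent)
}

# Fixed 3-color palette for phase maps (noncalcified, bone, graft), chosen
# to mirror color-filled segmented section figures.
phase_palette <- function() {
  rbind(noncalcified = c(0.15, 0.15, 0.15),
        bone = c(0.35, 0.75, 0.95),
        graft = c(0.95, 0.85, 0.25))
}

#' Write a phase map as a color PNG with a JSON sidecar
#'
#' Labels are rendered with a fixed three-color palette (invalid pixels
#' black); the sidecar stores the raw labels, mask, and plane so the map
#' round-trips exactly.
#'
#' @param map A [phase_map()].
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_phase_map_png <- function(map, path) {
  stopifnot(inherits(map, "phase_map"))
  pal <- phase_palette()
  d <- dim(map$labels)
  img <- array(0, dim = c(d[1], d[2], 3))
  for (p in 0:2) {
    sel <- !is.na(map$labels) & map$labels == p
    for (ch in 1:3) {
      plane_ch <- img[, , ch]
      plane_ch[sel] <- pal[p + 1, ch]
      img[, , ch] <- plane_ch
    }
  }
  png::writePNG(img, path)
  labs <- map$labels
  labs[is.na(labs)] <- -1L
  meta <- list(labels = as.vector(labs), dim = d,
               valid = as.vector(map$valid_mask),
               plane = if (!is.null(map$plane)) unclass(map$plane))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a phase map written by [write_phase_map_png()]
#'
#' @param path `.png` path with its `.json` sidecar alongside.
#' @return A [phase_map()].
#' @export
read_phase_map_png <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  labs <- matrix(as.integer(meta$labels), meta$dim[1], meta$dim[2])
  labs[labs < 0L] <- NA_integer_
  plane <- if (!is.null(meta$plane)) {
    section_plane(meta$plane$origin, meta$plane$normal, meta$plane$u_axis,
                  meta$plane$v_axis, meta$plane$pixel_pitch,
                  meta$plane$extent)
  }
  phase_map(labs, valid_mask = matrix(meta$valid, meta$dim[1], meta$dim[2]),
            plane = plane)
}

#' Write the tabular outputs of a study report
#'
#' Writes `measurements.csv`, `table_bone.csv`, `table_graft.csv`, one
#' Bland-Altman point CSV per comparison under `bland_altman/`, and a
#' machine-readable `report.json` (tables plus configuration and seed) into
#' a directory.
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$measurements, file.path(dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(report$table_bone, file.path(dir, "table_bone.csv"),
                   row.names = FALSE)
  utils::write.csv(report$table_graft, file.path(dir, "table_graft.csv"),
                   row.names = FALSE)
  ba_dir <- file.path(dir, "bland_altman")
  dir.create(ba_dir, showWarnings = FALSE)
  for (nm in names(report$bland_altman)) {
    utils::write.csv(report$bland_altman[[nm]],
                     file.path(ba_dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  cfg <- report$config
  cfg$phantom <- unclass(cfg$phantom)
  cfg$roi <- unclass(cfg$roi)
  cfg$search <- unclass(cfg$search)
  jsonlite::write_json(
    list(version = report$version, config = unclass(cfg),
         table_bone = report$table_bone, table_graft = report$table_graft),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = I(17))
  invisible(dir)
}

#' Read a study configuration from YAML or JSON
#'
#' Builds a [study_config()] from a config file with keys matching the
#' constructor's arguments; a nested `phantom` block (and optional `roi`,
#' `search` blocks) is passed to the corresponding constructor. Missing keys
#' fall back to the documented defaults. YAML support requires the `yaml`
#' package.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("read_study_config: the 'yaml' package is required for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- list()
  if (!is.null(cfg$phantom)) {
    ph <- cfg$phantom
    if (!is.null(ph$histology_perturbation)) {
      ph$histology_perturbation <- as.list(ph$histology_perturbation)
    }
    args$phantom <- do.call(phantom_spec, ph)
  }
  if (!is.null(cfg$roi)) args$roi <- do.call(roi_spec, as.list(cfg$roi))
  if (!is.null(cfg$search)) {
    args$search <- do.call(plane_search_spec, as.list(cfg$search))
  }
  for (k in c("n_specimens", "offsets_px", "rotations_deg",
              "bone_fraction_range", "graft_fraction_range", "fast_mode",
              "conf_level", "seed")) {
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  }
  do.call(study_config, args)
}
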