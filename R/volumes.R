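#' Three-dimensional grayscale volume
#'
#' A minimal container for a reconstructed microtomography-like dataset: a 3D
#' array of finite grayscale intensities on an isotropic grid with world
#' spacing in micrometers. The center of voxel `(i, j, k)` (0-based) sits at
#' `origin + c(i, j, k) * spacing` in world coordinates.
#'
#' @param values 3D numeric array of finite intensities.
#' @param spacing Isotropic voxel pitch in micrometers (> 0).
#' @param origin World coordinate (um) of the center of voxel (0, 0, 0).
#'
#' @return An object of class `voxel_volume` with fields `values`, `spacing`,
#'   `origin`.
#' @export
voxel_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (!all(is.finite(values))) {
    stop("voxel_volume: all intensity values must be finite")
  }
  check_geometry(spacing, origin)
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "voxel_volume"
  )
}

#' Three-dimensional phase-label volume
#'
#' Label grid over the three measured phases: 0 = noncalcified tissue,
#' 1 = bone, 2 = graft. Shares the voxel-center geometry convention of
#' [voxel_volume()].
#'
#' @param labels 3D integer array with values in \{0, 1, 2\}.
#' @inheritParams voxel_volume
#'
#' @return An object of class `phase_volume`.
#' @export
phase_volume <- function(labels, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  if (!all(labels %in% c(0L, 1L, 2L))) {
    stop("phase_volume: labels must lie in {0, 1, 2}")
  }
  check_geometry(spacing, origin)
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "phase_volume"
  )
}

check_geometry <- function(spacing, origin) {
  stopifnot(length(spacing) == 1L, is.finite(spacing), spacing > 0,
            length(origin) == 3L, all(is.finite(origin)))
  invisible(TRUE)
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, %.4g um/voxel\n",
              d[1], d[2], d[3], x$spacing))
  invisible(x)
}

#' @export
print.phase_volume <- function(x, ...) {
  d <- dim(x$labels)
  frac <- phase_fractions(x)
  cat(sprintf("<phase_volume> %d x %d x %d voxels, %.4g um/voxel\n",
              d[1], d[2], d[3], x$spacing))
  cat(sprintf("  noncalcified %.3f | bone %.3f | graft %.3f\n",
              frac[1], frac[2], frac[3]))
  invisible(x)
}

#' Exhaustive per-phase voxel fractions
#'
#' Counts voxels of each phase and divides by the total voxel count. This is
#' the exact (rational) tally the phantom generator's realized fractions are
#' checked against.
#'
#' @param phase A [phase_volume()].
#' @return Named numeric vector `c(noncalcified=, bone=, graft=)`.
#' @export
phase_fractions <- function(phase) {
  stopifnot(inherits(phase, "phase_volume"))
  n <- length(phase$labels)
  counts <- tabulate(phase$labels + 1L, nbins = 3L)
  stats::setNames(counts / n, c("noncalcified", "bone", "graft"))
}

dims_of <- function(volume) {
  if (inherits(volume, "phase_volume")) dim(volume$labels) else dim(volume$values)
}
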