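#' Oriented section plane
#'
#' Describes the rectangle of sample points a virtual section is taken over:
#' a world-space origin at the rectangle center, an orthonormal frame
#' `(u, v, normal)` with `normal = u x v`, a pixel pitch, and a pixel extent.
#' The first image index runs along `u` (in-plane horizontal, mesiodistal for
#' the canonical mesiodistal section), the second along `v` (in-plane
#' vertical, apico-occlusal). Positive parallel offsets move along `+normal`
#' (the buccal direction under the study's sign convention) and positive
#' rotations are clockwise as seen from the occlusal view (looking along
#' `-v`).
#'
#' @param origin World coordinates (um) of the rectangle center.
#' @param normal Unit plane normal.
#' @param u_axis,v_axis Unit in-plane axes; the frame must be orthonormal and
#'   right-handed (`normal = u x v`) to within 1e-9.
#' @param pixel_pitch Sample spacing in um (> 0).
#' @param extent Integer pair: number of pixels along `u` and along `v`.
#'
#' @return An object of class `section_plane`.
#' @export
section_plane <- function(origin, normal, u_axis, v_axis, pixel_pitch, extent) {
  origin <- as.numeric(origin); normal <- as.numeric(normal)
  u_axis <- as.numeric(u_axis); v_axis <- as.numeric(v_axis)
  stopifnot(length(origin) == 3L, length(normal) == 3L,
            length(u_axis) == 3L, length(v_axis) == 3L,
            length(pixel_pitch) == 1L, pixel_pitch > 0,
            length(extent) == 2L, all(extent >= 1))
  tol <- 1e-9
  if (abs(sqrt(sum(normal^2)) - 1) > tol ||
      abs(sqrt(sum(u_axis^2)) - 1) > tol ||
      abs(sqrt(sum(v_axis^2)) - 1) > tol) {
    stop("section_plane: axes must be unit vectors (within 1e-9)")
  }
  if (abs(sum(u_axis * v_axis)) > tol ||
      abs(sum(u_axis * normal)) > tol ||
      abs(sum(v_axis * normal)) > tol) {
    stop("section_plane: frame must be orthogonal (within 1e-9)")
  }
  if (max(abs(cross3(u_axis, v_axis) - normal)) > tol) {
    stop("section_plane: normal must equal u x v (within 1e-9)")
  }
  structure(
    list(origin = origin, normal = normal, u_axis = u_axis, v_axis = v_axis,
         pixel_pitch = as.numeric(pixel_pitch),
         extent = as.integer(extent)),
    class = "section_plane"
  )
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.section_plane <- function(x, ...) {
  cat(sprintf(
    "<section_plane> origin (%.2f, %.2f, %.2f) um, normal (%.3f, %.3f, %.3f)\n",
    x$origin[1], x$origin[2], x$origin[3],
    x$normal[1], x$normal[2], x$normal[3]))
  cat(sprintf("  %d x %d px at %.4g um/px\n", x$extent[1], x$extent[2],
              x$pixel_pitch))
  invisible(x)
}

#' Axis-aligned section plane through a volume
#'
#' Constructs the starting (unperturbed) plane for a study: normal along one
#' world axis, origin at the in-plane center of the volume at the given slice
#' index. With `pixel_pitch` equal to the voxel spacing and the default full
#' extent, nearest-neighbor extraction at this plane reproduces the raw array
#' slice exactly.
#'
#' @param volume A [voxel_volume()] or [phase_volume()].
#' @param axis One of `"x"`, `"y"`, `"z"` (world axis of the normal).
#' @param slice_index 0-based voxel index along `axis`.
#' @param extent Pixel extent `(n_u, n_v)`; default spans the two in-plane
#'   voxel dimensions.
#' @param pixel_pitch Sample pitch in um; default the volume's spacing.
#'
#' @return A [section_plane()].
#' @export
axis_aligned_plane <- function(volume, axis = c("z", "x", "y"), slice_index,
                               extent = NULL, pixel_pitch = NULL) {
  axis <- match.arg(axis)
  d <- dims_of(volume)
  ax <- match(axis, c("x", "y", "z"))
  if (slice_index < 0 || slice_index > d[ax] - 1) {
    stop(sprintf("axis_aligned_plane: slice_index %d outside [0, %d]",
                 slice_index, d[ax] - 1))
  }
  # in-plane axes in cyclic order so that u x v = +axis
  in1 <- c(2L, 3L, 1L)[ax]
  in2 <- c(3L, 1L, 2L)[ax]
  if (is.null(extent)) extent <- c(d[in1], d[in2])
  if (is.null(pixel_pitch)) pixel_pitch <- volume$spacing
  e3 <- function(i) { v <- c(0, 0, 0); v[i] <- 1; v }
  origin <- volume$origin
  origin[ax] <- origin[ax] + slice_index * volume$spacing
  origin[in1] <- origin[in1] + (d[in1] - 1) / 2 * volume$spacing
  origin[in2] <- origin[in2] + (d[in2] - 1) / 2 * volume$spacing
  section_plane(origin = origin, normal = e3(ax),
                u_axis = e3(in1), v_axis = e3(in2),
                pixel_pitch = pixel_pitch, extent = extent)
}

#' Parallel offset of a section plane
#'
#' Moves the plane along its normal by an integer number of pixels, the
#' study's parallel movement: `k_pixels = +4` at the reference pitch of
#' 19.75 um gives the 79-um buccal offset, negative values move lingually.
#' The frame and extent are unchanged.
#'
#' @param plane A [section_plane()].
#' @param k_pixels Signed number of pixel pitches to move along `+normal`.
#' @return The offset [section_plane()].
#' @export
offset_plane <- function(plane, k_pixels) {
  stopifnot(inherits(plane, "section_plane"), length(k_pixels) == 1L,
            is.finite(k_pixels))
  if (k_pixels == 0) return(plane)
  plane$origin <- plane$origin + k_pixels * plane$pixel_pitch * plane$normal
  plane
}

#' Rotate a section plane about its vertical in-plane axis
#'
#' Pivots the plane about the apico-occlusal axis (`v_axis`) through the
#' rectangle center, leaving `v_axis` fixed and rotating `normal` and
#' `u_axis`. Positive angles are clockwise as seen from the occlusal view
#' (looking along `-v_axis`), matching the study's '+' convention;
#' orthonormality of the frame is preserved.
#'
#' @param plane A [section_plane()].
#' @param angle_deg Signed rotation in degrees.
#' @return The rotated [section_plane()].
#' @export
rotate_plane <- function(plane, angle_deg) {
  stopifnot(inherits(plane, "section_plane"), length(angle_deg) == 1L,
            is.finite(angle_deg))
  if (angle_deg == 0) return(plane)
  rotate_plane_about(plane, axis = plane$v_axis, angle_deg = -angle_deg)
}

# Right-handed rotation of the plane frame about an arbitrary unit axis
# through the plane origin (Rodrigues). Internal building block shared by
# rotate_plane (about v) and the plane-search tilts (about u / normal).
rotate_plane_about <- function(plane, axis, angle_deg) {
  th <- angle_deg * pi / 180
  rot <- function(x) {
    x * cos(th) + cross3(axis, x) * sin(th) +
      axis * sum(axis * x) * (1 - cos(th))
  }
  renorm <- function(x) x / sqrt(sum(x^2))
  u <- renorm(rot(plane$u_axis))
  v <- renorm(rot(plane$v_axis))
  # re-orthogonalize v against u, then recompute the normal, so that long
  # compositions of perturbations keep the frame orthonormal to 1e-9
  v <- renorm(v - sum(v * u) * u)
  section_plane(plane$origin, cross3(u, v), u, v, plane$pixel_pitch,
                plane$extent)
}

# World coordinates of every sample point on the plane, as an (n_u * n_v) x 3
# matrix in column-major pixel order (u index fastest).
plane_sample_points <- function(plane) {
  n1 <- plane$extent[1]; n2 <- plane$extent[2]
  a <- (seq_len(n1) - 1) - (n1 - 1) / 2
  b <- (seq_len(n2) - 1) - (n2 - 1) / 2
  da <- rep(a, times = n2) * plane$pixel_pitch
  db <- rep(b, each = n1) * plane$pixel_pitch
  cbind(plane$origin[1] + da * plane$u_axis[1] + db * plane$v_axis[1],
        plane$origin[2] + da * plane$u_axis[2] + db * plane$v_axis[2],
        plane$origin[3] + da * plane$u_axis[3] + db * plane$v_axis[3])
}

#' Extract a grayscale section from a volume
#'
#' Samples the volume at every pixel of the plane. Pixel `(a, b)` (0-based)
#' sits at `origin + (a - (n_u-1)/2) * pitch * u + (b - (n_v-1)/2) * pitch * v`.
#' Sample points outside the volume's bounding box are masked invalid (value
#' `NA`), never zero-filled, so that downstream percent areas use valid
#' pixels only.
#'
#' @param volume A [voxel_volume()].
#' @param plane A [section_plane()].
#' @param interpolation `"trilinear"` (default) or `"nearest"`.
#'
#' @return An object of class `slice_image`: `values` (matrix `extent[1] x
#'   extent[2]`, `NA` where invalid), `valid_mask` (logical matrix), `plane`.
#' @export
extract_slice <- function(volume, plane,
                          interpolation = c("trilinear", "nearest")) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(plane, "section_plane"))
  interpolation <- match.arg(interpolation)
  if (any(plane$extent < 1)) stop("extract_slice: empty extent")
  g <- sweep(plane_sample_points(plane), 2, volume$origin) / volume$spacing
  d <- dim(volume$values)
  if (interpolation == "nearest") {
    idx <- round(g)
    valid <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
             idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
             idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
    vals <- rep(NA_real_, nrow(g))
    if (any(valid)) {
      lin <- idx[valid, 1] + d[1] * (idx[valid, 2] + d[2] * idx[valid, 3]) + 1
      vals[valid] <- volume$values[lin]
    }
  } else {
    valid <- g[, 1] >= 0 & g[, 1] <= d[1] - 1 &
             g[, 2] >= 0 & g[, 2] <= d[2] - 1 &
             g[, 3] >= 0 & g[, 3] <= d[3] - 1
    vals <- rep(NA_real_, nrow(g))
    if (any(valid)) {
      gv <- g[valid, , drop = FALSE]
      lo <- pmin(floor(gv), rep(d, each = nrow(gv)) - 2)
      lo <- pmax(lo, 0)
      f <- gv - lo
      corner <- function(dx, dy, dz) {
        lin <- (lo[, 1] + dx) + d[1] * ((lo[, 2] + dy) + d[2] * (lo[, 3] + dz)) + 1
        volume$values[lin]
      }
      vals[valid] <-
        corner(0, 0, 0) * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
        corner(1, 0, 0) * f[, 1]       * (1 - f[, 2]) * (1 - f[, 3]) +
        corner(0, 1, 0) * (1 - f[, 1]) * f[, 2]       * (1 - f[, 3]) +
        corner(1, 1, 0) * f[, 1]       * f[, 2]       * (1 - f[, 3]) +
        corner(0, 0, 1) * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
        corner(1, 0, 1) * f[, 1]       * (1 - f[, 2]) * f[, 3] +
        corner(0, 1, 1) * (1 - f[, 1]) * f[, 2]       * f[, 3] +
        corner(1, 1, 1) * f[, 1]       * f[, 2]       * f[, 3]
    }
  }
  structure(
    list(values = matrix(vals, plane$extent[1], plane$extent[2]),
         valid_mask = matrix(valid, plane$extent[1], plane$extent[2]),
         plane = plane),
    class = "slice_image"
  )
}

#' Extract a phase-label section from a label volume
#'
#' Label counterpart of [extract_slice()]; labels are categorical so only
#' nearest-neighbor sampling is meaningful. Out-of-volume pixels are masked
#' invalid (label `NA`).
#'
#' @param phase A [phase_volume()].
#' @param plane A [section_plane()].
#' @return An object of class `phase_map`: integer `labels` matrix (`NA`
#'   invalid), `valid_mask`, `plane`.
#' @export
extract_phase_slice <- function(phase, plane) {
  stopifnot(inherits(phase, "phase_volume"), inherits(plane, "section_plane"))
  if (any(plane$extent < 1)) stop("extract_phase_slice: empty extent")
  g <- sweep(plane_sample_points(plane), 2, phase$origin) / phase$spacing
  d <- dim(phase$labels)
  idx <- round(g)
  valid <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
           idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
           idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  labs <- rep(NA_integer_, nrow(g))
  if (any(valid)) {
    lin <- idx[valid, 1] + d[1] * (idx[valid, 2] + d[2] * idx[valid, 3]) + 1
    labs[valid] <- phase$labels[lin]
  }
  phase_map(matrix(labs, plane$extent[1], plane$extent[2]),
            valid_mask = matrix(valid, plane$extent[1], plane$extent[2]),
            plane = plane)
}

#' Two-dimensional three-phase label image
#'
#' The unit of morphometry: a label matrix over \{0 = noncalcified, 1 = bone,
#' 2 = graft\} with `NA` marking invalid pixels (outside the volume, or not
#' yet labeled in a manual override), a validity mask, and the provenance
#' plane when known.
#'
#' @param labels Integer matrix with entries in \{0, 1, 2\} or `NA`.
#' @param valid_mask Logical matrix; defaults to `!is.na(labels)`.
#' @param plane Optional [section_plane()] provenance.
#' @return An object of class `phase_map`.
#' @export
phase_map <- function(labels, valid_mask = NULL, plane = NULL) {
  stopifnot(is.matrix(labels))
  ok <- is.na(labels) | labels %in% c(0L, 1L, 2L)
  if (!all(ok)) stop("phase_map: labels must lie in {0, 1, 2} or NA")
  storage.mode(labels) <- "integer"
  if (is.null(valid_mask)) valid_mask <- !is.na(labels)
  stopifnot(is.matrix(valid_mask), all(dim(valid_mask) == dim(labels)))
  structure(list(labels = labels, valid_mask = valid_mask, plane = plane),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d x %d px, %d valid\n",
              nrow(x$labels), ncol(x$labels), sum(x$valid_mask)))
  invisible(x)
}
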