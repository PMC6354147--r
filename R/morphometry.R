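#' Centered region of interest on a section
#'
#' The measurement window: a rectangle of physical size `size_mm` (default
#' the study's 4 x 4 mm), centered on the image center unless an explicit
#' pixel center is given. Pixel bounds are derived from the section's pixel
#' pitch at measurement time and clipped to the image.
#'
#' @param size_mm Height/width pair in millimeters.
#' @param center Optional pixel-coordinate center `(row, col)` (1-based);
#'   default the image center.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(size_mm = c(4, 4), center = NULL) {
  stopifnot(length(size_mm) == 2L, all(size_mm > 0))
  if (!is.null(center)) stopifnot(length(center) == 2L)
  structure(list(size_mm = as.numeric(size_mm), center = center),
            class = "roi_spec")
}

# Logical ROI mask over a phase_map, clipped to the image. Errors if the
# derived pixel bounds miss the image entirely.
roi_mask <- function(map, roi) {
  stopifnot(inherits(map, "phase_map"), inherits(roi, "roi_spec"))
  d <- dim(map$labels)
  pitch <- if (!is.null(map$plane)) map$plane$pixel_pitch else
    stop("roi_mask: map carries no plane provenance; pixel pitch unknown")
  half_px <- roi$size_mm * 1000 / pitch / 2
  ctr <- if (is.null(roi$center)) (d + 1) / 2 else roi$center
  lo <- ceiling(ctr - half_px)
  hi <- floor(ctr + half_px)
  lo <- pmax(lo, 1L)
  hi <- pmin(hi, d)
  if (any(hi < lo)) stop("roi_mask: ROI does not intersect the image")
  m <- matrix(FALSE, d[1], d[2])
  m[lo[1]:hi[1], lo[2]:hi[2]] <- TRUE
  m
}

#' Percent phase areas within the ROI
#'
#' The study's morphometric value: for each phase, 100 times the number of
#' ROI pixels of that phase divided by the number of valid ROI pixels
#' (integer counts followed by a single division, so the three percents sum
#' to 100 exactly up to floating division).
#'
#' @param map A [phase_map()].
#' @param roi An [roi_spec()]; default the 4 x 4 mm centered window.
#' @return A one-row data.frame: `pct_noncalcified`, `pct_bone`,
#'   `pct_graft`, `n_pixels_evaluated`.
#' @export
percent_areas <- function(map, roi = roi_spec()) {
  sel <- roi_mask(map, roi) & map$valid_mask
  n <- sum(sel)
  if (n == 0L) stop("percent_areas: no valid pixels inside the ROI")
  counts <- tabulate(map$labels[sel] + 1L, nbins = 3L)
  data.frame(pct_noncalcified = 100 * counts[1] / n,
             pct_bone = 100 * counts[2] / n,
             pct_graft = 100 * counts[3] / n,
             n_pixels_evaluated = n)
}

#' Per-phase overlap (concordance area) rates of two superimposed sections
#'
#' For each phase, the Jaccard rate |both| / |either| over jointly valid ROI
#' pixels, plus the Dice variant 2|both| / (|A| + |B|). This measures how
#' precisely two segmentations overlap in superimposition, which equal
#' cumulative percent areas do not guarantee. Phases absent from both maps
#' get `NA` (undefined), not 0 or 1, and should be excluded from averages.
#'
#' @param map_a,map_b [phase_map()]s of identical shape.
#' @param roi An [roi_spec()].
#' @return data.frame with columns `phase`, `jaccard`, `dice`.
#' @export
concordance_area_rate <- function(map_a, map_b, roi = roi_spec()) {
  stopifnot(inherits(map_a, "phase_map"), inherits(map_b, "phase_map"))
  if (!all(dim(map_a$labels) == dim(map_b$labels))) {
    stop("concordance_area_rate: shape mismatch")
  }
  sel <- roi_mask(map_a, roi) & map_a$valid_mask & map_b$valid_mask
  if (!any(sel)) stop("concordance_area_rate: no jointly valid ROI pixels")
  a <- map_a$labels[sel]; b <- map_b$labels[sel]
  res <- lapply(0:2, function(p) {
    ina <- a == p; inb <- b == p
    inter <- sum(ina & inb); uni <- sum(ina | inb)
    if (uni == 0L) {
      data.frame(phase = p, jaccard = NA_real_, dice = NA_real_)
    } else {
      data.frame(phase = p, jaccard = inter / uni,
                 dice = 2 * inter / (sum(ina) + sum(inb)))
    }
  })
  out <- do.call(rbind, res)
  out$phase <- c("noncalcified", "bone", "graft")[out$phase + 1L]
  out
}
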