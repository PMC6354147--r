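#' Specification of a synthetic three-phase specimen
#'
#' Collects every parameter of the phantom generator: grid geometry, target
#' phase fractions, the spatial correlation scale of the trabecular bone
#' field, graft particle size, grayscale rendering parameters, and the
#' perturbation applied when producing the histology-proxy reference section.
#'
#' Defaults emulate a grafted extraction-socket biopsy imaged at 19.75 um
#' isotropic pitch: ~30% bone, ~15% particulate graft, bone correlation
#' length about three voxels, graft particles with ~55 um mean radius.
#'
#' @param shape Integer triple, voxels per axis (each >= 8). The default
#'   160^3 (~3.2 mm cube) keeps the 4 x 4 mm ROI clipped to the volume; see
#'   [phantom_spec_full_roi()] for a 256^3 preset.
#' @param spacing Isotropic voxel pitch, um.
#' @param bone_fraction_target Target bone volume fraction in \[0, 1).
#' @param graft_fraction_target Target graft volume fraction in \[0, 1);
#'   `bone_fraction_target + graft_fraction_target` must be < 1.
#' @param correlation_length Gaussian smoothing scale of the bone field, um.
#' @param graft_radius_mean,graft_radius_sd Graft particle radius
#'   distribution, um (normal, truncated at one voxel).
#' @param phase_means Grayscale mean per phase, named
#'   `c(noncalcified=, bone=, graft=)`; must be pairwise distinct. The
#'   default places the narrow contrast gap between bone and the slightly
#'   denser hydroxyapatite graft, with noncalcified tissue far darker, as in
#'   micro-CT of grafted bone.
#' @param noise_sd Additive Gaussian grayscale noise, gray levels.
#' @param blur_sigma Gaussian blur width applied after noise, um (0 = none).
#' @param histology_perturbation List with `offset_um` (parallel offset of
#'   the histology-proxy plane along the section normal), `tilt_deg`
#'   (rotation about the vertical in-plane axis), and `label_noise` (fraction
#'   of proxy pixels whose label is flipped to a different phase).
#' @param seed Integer seed; all phantom randomness derives from it.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(160L, 160L, 160L),
                         spacing = 19.75,
                         bone_fraction_target = 0.30,
                         graft_fraction_target = 0.15,
                         correlation_length = 60,
                         graft_radius_mean = 55,
                         graft_radius_sd = 15,
                         phase_means = c(noncalcified = 50, bone = 160,
                                         graft = 230),
                         noise_sd = 10,
                         blur_sigma = 0,
                         histology_perturbation = list(offset_um = 0,
                                                       tilt_deg = 0,
                                                       label_noise = 0.05),
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L),
            spacing > 0, correlation_length > 0,
            graft_radius_mean > 0, graft_radius_sd >= 0,
            bone_fraction_target >= 0, graft_fraction_target >= 0,
            bone_fraction_target + graft_fraction_target < 1,
            length(phase_means) == 3L,
            noise_sd >= 0, blur_sigma >= 0,
            is.list(histology_perturbation),
            all(c("offset_um", "tilt_deg", "label_noise") %in%
                  names(histology_perturbation)),
            histology_perturbation$label_noise >= 0,
            histology_perturbation$label_noise <= 1)
  structure(
    list(shape = shape, spacing = spacing,
         bone_fraction_target = bone_fraction_target,
         graft_fraction_target = graft_fraction_target,
         correlation_length = correlation_length,
         graft_radius_mean = graft_radius_mean,
         graft_radius_sd = graft_radius_sd,
         phase_means = phase_means, noise_sd = noise_sd,
         blur_sigma = blur_sigma,
         histology_perturbation = histology_perturbation,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Full-ROI phantom preset
#'
#' A 256^3 grid (~5.06 mm cube at 19.75 um) in which the whole 4 x 4 mm
#' region of interest fits inside every section.
#'
#' @param ... Overrides passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
phantom_spec_full_roi <- function(...) {
  phantom_spec(shape = c(256L, 256L, 256L), ...)
}

# Periodic Gaussian smoothing of a 3D array via the n-dimensional FFT.
# sigma is in voxels; the kernel is normalized to unit sum so constants are
# preserved exactly up to FFT round-off.
gaussian_smooth3 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  k1 <- lapply(d, function(n) {
    r <- pmin(0:(n - 1), n - (0:(n - 1)))
    exp(-0.5 * (r / sigma)^2)
  })
  kern <- outer(outer(k1[[1]], k1[[2]]), k1[[3]])
  dim(kern) <- d
  kern <- kern / sum(kern)
  Re(fft(fft(x) * fft(kern), inverse = TRUE)) / length(x)
}

#' Generate a three-phase phantom volume
#'
#' Bone is a thresholded Gaussian random field: white noise smoothed with a
#' Gaussian kernel of width `correlation_length`, cut at the empirical
#' quantile that realizes `bone_fraction_target`. Graft particles are hard
#' spheres rejection-sampled into the remaining (non-bone) space until
#' `graft_fraction_target` is approached; placement fails explicitly, naming
#' the realized fraction, if the target cannot be approached within a bounded
#' number of attempts. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A [phase_volume()] with attributes `realized_fractions` (exact
#'   voxel tallies) and `generator_version`.
#' @export
generate_phase_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  n <- prod(d)
  labels <- array(0L, dim = d)

  if (spec$bone_fraction_target > 0) {
    field <- array(stats::rnorm(n), dim = d)
    field <- gaussian_smooth3(field, spec$correlation_length / spec$spacing)
    thr <- stats::quantile(field, 1 - spec$bone_fraction_target, names = FALSE)
    labels[field > thr] <- 1L
  }

  if (spec$graft_fraction_target > 0) {
    target_vox <- round(spec$graft_fraction_target * n)
    placed <- 0L
    mean_r_vox <- max(1, spec$graft_radius_mean / spec$spacing)
    expected_spheres <- ceiling(target_vox / (4 / 3 * pi * mean_r_vox^3))
    max_attempts <- 500L + 400L * expected_spheres
    attempts <- 0L
    while (placed < target_vox && attempts < max_attempts) {
      attempts <- attempts + 1L
      r_um <- stats::rnorm(1, spec$graft_radius_mean, spec$graft_radius_sd)
      r <- max(1, r_um / spec$spacing)
      ctr <- c(stats::runif(1, 1, d[1]), stats::runif(1, 1, d[2]),
               stats::runif(1, 1, d[3]))
      rng <- function(ax) {
        max(1L, ceiling(ctr[ax] - r)):min(d[ax], floor(ctr[ax] + r))
      }
      ix <- rng(1); iy <- rng(2); iz <- rng(3)
      if (!length(ix) || !length(iy) || !length(iz)) next
      dx2 <- (ix - ctr[1])^2
      dy2 <- (iy - ctr[2])^2
      dz2 <- (iz - ctr[3])^2
      inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
      if (!any(inside)) next
      sub <- labels[ix, iy, iz, drop = FALSE]
      if (any(sub[inside] != 0L)) next  # overlaps bone or another particle
      sub[inside] <- 2L
      labels[ix, iy, iz] <- sub
      placed <- placed + sum(inside)
    }
    realized <- placed / n
    if (realized < spec$graft_fraction_target - 0.02) {
      stop(sprintf(paste0(
        "generate_phase_volume: graft target %.3f unreachable after %d ",
        "placement attempts (realized fraction %.4f)"),
        spec$graft_fraction_target, attempts, realized))
    }
  }

  out <- phase_volume(labels, spacing = spec$spacing)
  attr(out, "realized_fractions") <- phase_fractions(out)
  attr(out, "generator_version") <- "secmorph-phantom-1"
  out
}

#' Render a phase volume to grayscale
#'
#' Assigns each voxel its phase mean, adds Gaussian noise of width
#' `noise_sd`, then applies a Gaussian blur of width `blur_sigma` (um).
#' Emulates a reconstructed tomography dataset well enough that luminance
#' thresholding of sections is exercisable. Deterministic given `spec$seed`.
#'
#' @param phase A [phase_volume()].
#' @param spec The governing [phantom_spec()].
#' @return A [voxel_volume()].
#' @export
render_grayscale <- function(phase, spec) {
  stopifnot(inherits(phase, "phase_volume"), inherits(spec, "phantom_spec"))
  if (anyDuplicated(spec$phase_means)) {
    stop("render_grayscale: phase means must be pairwise distinct")
  }
  set.seed(spec$seed + 1L)
  vals <- spec$phase_means[phase$labels + 1L]
  dim(vals) <- dim(phase$labels)
  if (spec$noise_sd > 0) {
    vals <- vals + stats::rnorm(length(vals), 0, spec$noise_sd)
  }
  if (spec$blur_sigma > 0) {
    vals <- gaussian_smooth3(vals, spec$blur_sigma / spec$spacing)
  }
  voxel_volume(vals, spacing = phase$spacing, origin = phase$origin)
}

#' Histology-proxy reference section
#'
#' Stands in for the stained physical section the virtual sections are
#' matched against. The phase volume is sectioned at `plane` perturbed by
#' `spec$histology_perturbation` (parallel offset in um along the normal plus
#' a tilt about the vertical in-plane axis), then a stated fraction of pixel
#' labels is flipped to a different phase, modeling inter-modality
#' disagreement at the label level. Deterministic given `spec$seed`.
#'
#' @param phase A [phase_volume()].
#' @param plane The nominal [section_plane()] (the "true" histology plane).
#' @param spec The governing [phantom_spec()].
#' @return A [phase_map()].
#' @export
make_histology_proxy <- function(phase, plane, spec) {
  stopifnot(inherits(phase, "phase_volume"),
            inherits(plane, "section_plane"),
            inherits(spec, "phantom_spec"))
  pert <- spec$histology_perturbation
  p <- offset_plane(plane, pert$offset_um / plane$pixel_pitch)
  if (pert$tilt_deg != 0) p <- rotate_plane(p, pert$tilt_deg)
  map <- extract_phase_slice(phase, p)
  if (!any(map$valid_mask)) {
    stop("make_histology_proxy: perturbed plane lies outside the volume")
  }
  if (pert$label_noise > 0) {
    set.seed(spec$seed + 2L)
    idx <- which(map$valid_mask)
    flip <- idx[stats::runif(length(idx)) < pert$label_noise]
    if (length(flip)) {
      # flip to one of the two other labels, uniformly
      shift <- sample(c(1L, 2L), length(flip), replace = TRUE)
      map$labels[flip] <- (map$labels[flip] + shift) %% 3L
    }
  }
  map
}
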