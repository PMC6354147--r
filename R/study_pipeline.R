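#' Configuration of a full in-silico section-plane study
#'
#' One object describing the whole experiment: how many synthetic specimens,
#' the phantom generator settings, the plane variants (parallel offsets in
#' pixels and rotations in degrees), the measurement ROI, whether the
#' original section plane is recovered by search or taken as known
#' ("fast mode"), and the master seed.
#'
#' Between-specimen biological variation is emulated by drawing each
#' specimen's bone and graft volume-fraction targets uniformly from
#' `bone_fraction_range` and `graft_fraction_range`; the study's per-specimen
#' measurements are otherwise unavailable.
#'
#' @param n_specimens Number of specimens (default 16, the study's count).
#' @param phantom A [phantom_spec()] template; its `seed`,
#'   `bone_fraction_target` and `graft_fraction_target` are overridden per
#'   specimen. The default study phantom is a 64^3 grid at 19.75 um, sized
#'   for tractable replicated experiments.
#' @param offsets_px Parallel-offset variants in pixels (default `c(4, -4)`,
#'   i.e. +/-79 um at the default pitch).
#' @param rotations_deg Rotation variants in degrees (default `c(10, -10)`).
#' @param roi Measurement window, an [roi_spec()].
#' @param bone_fraction_range,graft_fraction_range Per-specimen target
#'   ranges.
#' @param fast_mode If `TRUE` (default) the original section plane is the
#'   known generating plane; if `FALSE` it is recovered with
#'   [search_best_plane()].
#' @param search A [plane_search_spec()] used when `fast_mode = FALSE`.
#' @param conf_level Confidence level for agreement intervals.
#' @param seed Master seed; specimen `i` uses phantom seed
#'   `seed + 10 * i` (sub-streams +0 field, +1 rendering, +2 proxy noise).
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_specimens = 16L,
                         phantom = phantom_spec(shape = c(64L, 64L, 64L)),
                         offsets_px = c(4, -4),
                         rotations_deg = c(10, -10),
                         roi = roi_spec(),
                         bone_fraction_range = c(0.20, 0.40),
                         graft_fraction_range = c(0.08, 0.18),
                         fast_mode = TRUE,
                         search = plane_search_spec(),
                         conf_level = 0.95,
                         seed = 42L) {
  stopifnot(n_specimens >= 2L, inherits(phantom, "phantom_spec"),
            length(offsets_px) >= 1L, length(rotations_deg) >= 1L,
            inherits(roi, "roi_spec"),
            diff(bone_fraction_range) >= 0, diff(graft_fraction_range) >= 0)
  structure(
    list(n_specimens = as.integer(n_specimens), phantom = phantom,
         offsets_px = offsets_px, rotations_deg = rotations_deg, roi = roi,
         bone_fraction_range = bone_fraction_range,
         graft_fraction_range = graft_fraction_range,
         fast_mode = isTRUE(fast_mode), search = search,
         conf_level = conf_level, seed = as.integer(seed)),
    class = "study_config"
  )
}

variant_name <- function(kind, level) {
  if (kind == "offset") sprintf("offset%+d", level)
  else sprintf("rot%+d", level)
}

# Generate, section, segment and measure one specimen. Returns the
# measurement rows (HM proxy + original + each plane variant).
measure_specimen <- function(config, index) {
  ph <- config$phantom
  spec_seed <- config$seed + 10L * index
  set.seed(spec_seed + 3L)
  ph$bone_fraction_target <- stats::runif(1, config$bone_fraction_range[1],
                                          config$bone_fraction_range[2])
  ph$graft_fraction_target <- stats::runif(1, config$graft_fraction_range[1],
                                           config$graft_fraction_range[2])
  ph$seed <- spec_seed
  phase <- generate_phase_volume(ph)
  gray <- render_grayscale(phase, ph)

  d <- ph$shape
  true_plane <- axis_aligned_plane(phase, "z", d[3] %/% 2)
  hm <- make_histology_proxy(phase, true_plane, ph)

  original <- if (config$fast_mode) {
    true_plane
  } else {
    search_best_plane(phase, hm, true_plane, config$search)$best_plane
  }

  planes <- list(original = original)
  for (k in config$offsets_px) {
    planes[[variant_name("offset", k)]] <- offset_plane(original, k)
  }
  for (a in config$rotations_deg) {
    planes[[variant_name("rot", a)]] <- rotate_plane(original, a)
  }

  rows <- list(cbind(data.frame(specimen = index, variant = "HM"),
                     percent_areas(hm, config$roi)))
  for (nm in names(planes)) {
    sl <- extract_slice(gray, planes[[nm]], interpolation = "trilinear")
    map <- threshold_segment(sl, auto_thresholds(sl))
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(specimen = index, variant = nm),
            percent_areas(map, config$roi))
  }
  do.call(rbind, rows)
}

#' Run the full in-silico study
#'
#' For every specimen: generate a phantom, take a mesiodistal generating
#' plane, produce the histology-proxy reference at the (possibly perturbed)
#' plane, fix the "original" virtual section (known plane in fast mode,
#' recovered by search otherwise), derive the parallel-offset and rotation
#' variants independently from the original plane, segment each grayscale
#' section by per-image automatic luminance thresholds, and measure percent
#' areas in the ROI. Then build the two per-phase agreement tables
#' (histology-proxy block and original-section block) and Bland-Altman
#' point sets. Fully deterministic given `config$seed`.
#'
#' @param config A [study_config()].
#' @return A list of class `study_report`: `measurements` (long data.frame),
#'   `table_bone`, `table_graft` (see [agreement_table()]), `bland_altman`
#'   (named list of per-comparison point sets), `config`, `version`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  meas <- do.call(rbind, lapply(seq_len(config$n_specimens),
                                function(i) measure_specimen(config, i)))
  rownames(meas) <- NULL
  table_bone <- agreement_table(meas, "bone", conf_level = config$conf_level)
  table_graft <- agreement_table(meas, "graft", conf_level = config$conf_level)
  ba <- list()
  specimens <- sort(unique(meas$specimen))
  get_series <- function(vv, col) {
    sub <- meas[meas$variant == vv, ]
    sub[[col]][match(specimens, sub$specimen)]
  }
  for (phase in c("bone", "graft")) {
    col <- paste0("pct_", phase)
    tb <- if (phase == "bone") table_bone else table_graft
    for (r in seq_len(nrow(tb))) {
      key <- sprintf("%s_vs_%s_%s", tb$reference[r], tb$comparator[r], phase)
      ba[[key]] <- bland_altman(get_series(tb$reference[r], col),
                                get_series(tb$comparator[r], col))$points
    }
  }
  structure(list(measurements = meas, table_bone = table_bone,
                 table_graft = table_graft, bland_altman = ba,
                 config = config, version = "secmorph-study-1"),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d specimens, %d measurement rows\n",
              x$config$n_specimens, nrow(x$measurements)))
  cat("Bone-area agreement (reference vs comparator):\n")
  print(x$table_bone[, c("reference", "comparator", "ccc", "ci_lower",
                         "ci_upper", "mean_diff", "sd_diff")],
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' Sensitivity sweep over perturbation magnitude
#'
#' Generalizes the fixed +/-4-pixel / +/-10-degree design to a curve:
#' for each replicate study and each offset (pixels) or rotation (degrees)
#' level, measures percent areas at the original plane and at the perturbed
#' plane for every specimen, then summarizes between-plane agreement
#' (concordance coefficient, mean difference, mean absolute difference)
#' across specimens.
#'
#' @param config A [study_config()]; replicate `r` uses master seed
#'   `config$seed + 1000 * (r - 1)`.
#' @param offsets Offset levels in pixels (may be empty).
#' @param angles Rotation levels in degrees (may be empty).
#' @param n_replicates Number of replicate studies.
#' @return Long data.frame: `replicate`, `kind`, `level`, `phase`, `ccc`,
#'   `mean_diff`, `sd_diff`, `mean_abs_diff`, `n`.
#' @export
sweep_perturbation <- function(config = study_config(), offsets = c(1, 2, 4, 8),
                               angles = numeric(0), n_replicates = 1L) {
  stopifnot(length(offsets) + length(angles) >= 1L)
  levels <- rbind(
    if (length(offsets)) data.frame(kind = "offset", level = offsets),
    if (length(angles)) data.frame(kind = "rotation", level = angles))
  out <- list()
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * (r - 1L)
    per_spec <- lapply(seq_len(cfg$n_specimens), function(i) {
      ph <- cfg$phantom
      spec_seed <- cfg$seed + 10L * i
      set.seed(spec_seed + 3L)
      ph$bone_fraction_target <- stats::runif(1, cfg$bone_fraction_range[1],
                                              cfg$bone_fraction_range[2])
      ph$graft_fraction_target <- stats::runif(1, cfg$graft_fraction_range[1],
                                               cfg$graft_fraction_range[2])
      ph$seed <- spec_seed
      phase <- generate_phase_volume(ph)
      gray <- render_grayscale(phase, ph)
      base <- axis_aligned_plane(phase, "z", ph$shape[3] %/% 2)
      measure_at <- function(pl) {
        sl <- extract_slice(gray, pl, interpolation = "trilinear")
        percent_areas(threshold_segment(sl, auto_thresholds(sl)), cfg$roi)
      }
      res <- list(original = measure_at(base))
      for (li in seq_len(nrow(levels))) {
        pl <- if (levels$kind[li] == "offset") {
          offset_plane(base, levels$level[li])
        } else {
          rotate_plane(base, levels$level[li])
        }
        res[[paste0("L", li)]] <- measure_at(pl)
      }
      res
    })
    for (li in seq_len(nrow(levels))) {
      for (phase in c("bone", "graft")) {
        col <- paste0("pct_", phase)
        x <- vapply(per_spec, function(s) s$original[[col]], numeric(1))
        y <- vapply(per_spec, function(s) s[[paste0("L", li)]][[col]],
                    numeric(1))
        cc <- if (isTRUE(all.equal(x, y))) 1 else ccc(x, y)$ccc
        md <- mean_diff_sd(x, y)
        out[[length(out) + 1L]] <- data.frame(
          replicate = r, kind = levels$kind[li], level = levels$level[li],
          phase = phase, ccc = cc, mean_diff = md$mean_diff,
          sd_diff = md$sd_diff, mean_abs_diff = mean(abs(x - y)),
          n = length(x))
      }
    }
  }
  do.call(rbind, out)
}
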