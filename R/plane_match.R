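#' Similarity between a reference section and a candidate section
#'
#' The objective of the plane search (the study's by-eye similarity
#' judgment, made explicit). For phase maps, `mean_phase_dice`: the
#' unweighted mean of per-phase Dice coefficients over the phases present in
#' the reference, computed on jointly valid pixels; in \[0, 1\], equal to 1
#' exactly when the maps agree on every jointly valid pixel over those
#' phases. For grayscale sections, `mutual_information` on a binned joint
#' histogram (nats).
#'
#' @param ref Reference [phase_map()] (or `slice_image` for MI).
#' @param cand Candidate of the same class and shape.
#' @param metric `"mean_phase_dice"` or `"mutual_information"`.
#' @param n_bins Histogram bins per margin for mutual information.
#' @return Scalar score.
#' @export
plane_similarity <- function(ref, cand,
                             metric = c("mean_phase_dice",
                                        "mutual_information"),
                             n_bins = 32L) {
  metric <- match.arg(metric)
  if (metric == "mean_phase_dice") {
    stopifnot(inherits(ref, "phase_map"), inherits(cand, "phase_map"))
    if (!all(dim(ref$labels) == dim(cand$labels))) {
      stop("plane_similarity: shape mismatch")
    }
    sel <- ref$valid_mask & cand$valid_mask
    if (!any(sel)) return(0)
    a <- ref$labels[sel]; b <- cand$labels[sel]
    phases <- sort(unique(ref$labels[ref$valid_mask]))
    dices <- vapply(phases, function(p) {
      na <- sum(a == p); nb <- sum(b == p)
      if (na + nb == 0L) return(NA_real_)
      2 * sum(a == p & b == p) / (na + nb)
    }, numeric(1))
    mean(dices, na.rm = TRUE)
  } else {
    stopifnot(inherits(ref, "slice_image"), inherits(cand, "slice_image"))
    if (!all(dim(ref$values) == dim(cand$values))) {
      stop("plane_similarity: shape mismatch")
    }
    sel <- ref$valid_mask & cand$valid_mask
    x <- ref$values[sel]; y <- cand$values[sel]
    bx <- cut(x, n_bins, labels = FALSE)
    by <- cut(y, n_bins, labels = FALSE)
    p <- table(bx, by) / length(x)
    px <- rowSums(p); py <- colSums(p)
    nz <- p > 0
    sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
  }
}

#' Plane-search configuration
#'
#' Bounds and coarse grid steps for the five plane parameters relative to
#' the initial plane: parallel offset along the normal (um), tilts about the
#' in-plane axes (deg), in-plane rotation about the normal (deg), and
#' in-plane translation along `u` (um). A zero-width range pins that
#' parameter at its single value. Defaults search offset and the
#' apico-occlusal tilt, the two perturbations the study applies.
#'
#' @param offset_range,offset_step Offset bounds and grid step, um.
#' @param tilt_u_range,tilt_v_range,tilt_step Tilt bounds about `u` and `v`
#'   and their common grid step, degrees.
#' @param rot_range,rot_step In-plane rotation bounds/step, degrees.
#' @param trans_u_range,trans_step In-plane translation bounds/step, um.
#' @param metric Similarity metric, see [plane_similarity()].
#' @param refine_iter Nelder-Mead iteration cap for local refinement.
#' @param seed Seed for the (deterministic) refiner bookkeeping.
#' @return An object of class `plane_search_spec`.
#' @export
plane_search_spec <- function(offset_range = c(-120, 120),
                              offset_step = 19.75,
                              tilt_u_range = c(0, 0),
                              tilt_v_range = c(-15, 15),
                              tilt_step = 2.5,
                              rot_range = c(0, 0), rot_step = 2.5,
                              trans_u_range = c(0, 0), trans_step = 19.75,
                              metric = "mean_phase_dice",
                              refine_iter = 200L,
                              seed = 1L) {
  stopifnot(offset_step > 0, tilt_step > 0, rot_step > 0, trans_step > 0,
            diff(offset_range) >= 0, diff(tilt_u_range) >= 0,
            diff(tilt_v_range) >= 0, diff(rot_range) >= 0,
            diff(trans_u_range) >= 0)
  structure(
    list(offset_range = offset_range, offset_step = offset_step,
         tilt_u_range = tilt_u_range, tilt_v_range = tilt_v_range,
         tilt_step = tilt_step, rot_range = rot_range, rot_step = rot_step,
         trans_u_range = trans_u_range, trans_step = trans_step,
         metric = metric, refine_iter = as.integer(refine_iter),
         seed = as.integer(seed)),
    class = "plane_search_spec"
  )
}

# Candidate plane from the 5-parameter vector
# (offset_um, tilt_u_deg, tilt_v_deg, rot_deg, trans_u_um) relative to init.
candidate_plane <- function(init, par) {
  p <- init
  p$origin <- p$origin + par[1] * p$normal + par[5] * p$u_axis
  if (par[2] != 0) p <- rotate_plane_about(p, p$u_axis, par[2])
  if (par[3] != 0) p <- rotate_plane(p, par[3])
  if (par[4] != 0) p <- rotate_plane_about(p, p$normal, par[4])
  p
}

#' Search for the section plane best matching a reference image
#'
#' Formalizes the study's trial-and-error selection of the virtual section
#' most similar to the histology image: a coarse grid over the search bounds
#' followed by derivative-free (Nelder-Mead) local refinement of the free
#' parameters from the best grid point. Every evaluation is logged;
#' deterministic given the spec.
#'
#' @param volume A [phase_volume()] (Dice metric) or [voxel_volume()]
#'   (mutual information).
#' @param ref Reference section ([phase_map()] or `slice_image`).
#' @param init Initial [section_plane()]; search parameters are relative to
#'   it.
#' @param spec A [plane_search_spec()].
#' @return A list of class `plane_search_result`: `best_plane`, `score`,
#'   `par` (named best parameter vector), `n_evaluations`, `trace`
#'   (data.frame of every evaluated parameter vector and score).
#' @export
search_best_plane <- function(volume, ref, init, spec = plane_search_spec()) {
  stopifnot(inherits(init, "section_plane"),
            inherits(spec, "plane_search_spec"))
  extract <- if (inherits(volume, "phase_volume")) {
    function(pl) extract_phase_slice(volume, pl)
  } else {
    function(pl) extract_slice(volume, pl, interpolation = "trilinear")
  }
  trace <- list()
  evaluate <- function(par) {
    pl <- candidate_plane(init, par)
    cand <- extract(pl)
    sc <- if (!any(cand$valid_mask)) -Inf else
      plane_similarity(ref, cand, metric = spec$metric)
    trace[[length(trace) + 1L]] <<-
      c(offset_um = par[1], tilt_u_deg = par[2], tilt_v_deg = par[3],
        rot_deg = par[4], trans_u_um = par[5], score = sc)
    sc
  }
  grid_axis <- function(range, step) {
    if (diff(range) == 0) return(range[1])
    seq(range[1], range[2], by = step)
  }
  grid <- expand.grid(offset = grid_axis(spec$offset_range, spec$offset_step),
                      tilt_u = grid_axis(spec$tilt_u_range, spec$tilt_step),
                      tilt_v = grid_axis(spec$tilt_v_range, spec$tilt_step),
                      rot = grid_axis(spec$rot_range, spec$rot_step),
                      trans_u = grid_axis(spec$trans_u_range, spec$trans_step))
  scores <- apply(as.matrix(grid), 1, evaluate)
  if (all(!is.finite(scores))) {
    stop("search_best_plane: no candidate plane intersects the volume")
  }
  best_i <- which.max(scores)
  best_par <- as.numeric(grid[best_i, ])
  best_score <- scores[best_i]

  free <- c(diff(spec$offset_range), diff(spec$tilt_u_range),
            diff(spec$tilt_v_range), diff(spec$rot_range),
            diff(spec$trans_u_range)) > 0
  if (sum(free) >= 2 && spec$refine_iter > 0) {
    set.seed(spec$seed)
    lower <- c(spec$offset_range[1], spec$tilt_u_range[1],
               spec$tilt_v_range[1], spec$rot_range[1],
               spec$trans_u_range[1])
    upper <- c(spec$offset_range[2], spec$tilt_u_range[2],
               spec$tilt_v_range[2], spec$rot_range[2],
               spec$trans_u_range[2])
    obj <- function(pf) {
      par <- best_par
      par[free] <- pmin(pmax(pf, lower[free]), upper[free])
      -evaluate(par)
    }
    fit <- stats::optim(best_par[free], obj, method = "Nelder-Mead",
                        control = list(maxit = spec$refine_iter,
                                       reltol = 1e-8))
    ref_par <- best_par
    ref_par[free] <- pmin(pmax(fit$par, lower[free]), upper[free])
    ref_score <- -fit$value
    if (ref_score > best_score) {
      best_par <- ref_par
      best_score <- ref_score
    }
  }
  tr <- as.data.frame(do.call(rbind, trace))
  structure(
    list(best_plane = candidate_plane(init, best_par), score = best_score,
         par = stats::setNames(best_par, c("offset_um", "tilt_u_deg",
                                           "tilt_v_deg", "rot_deg",
                                           "trans_u_um")),
         n_evaluations = nrow(tr), trace = tr),
    class = "plane_search_result"
  )
}

#' @export
print.plane_search_result <- function(x, ...) {
  cat(sprintf("<plane_search_result> score %.4f after %d evaluations\n",
              x$score, x$n_evaluations))
  cat(sprintf("  offset %.2f um, tilt_u %.2f, tilt_v %.2f, rot %.2f deg, trans_u %.2f um\n",
              x$par[1], x$par[2], x$par[3], x$par[4], x$par[5]))
  invisible(x)
}
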