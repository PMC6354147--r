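#' Two-threshold luminance partition
#'
#' Holds the pair of luminance thresholds that splits a grayscale section
#' into three intensity bands, and the band-to-phase mapping. Classification
#' is by `value < t_low`, `t_low <= value < t_high`, `value >= t_high`.
#'
#' @param t_low,t_high Threshold gray values, `t_low < t_high`.
#' @param phase_order Integer vector of length 3: the phase label assigned to
#'   the dark, middle and bright bands. Must be a permutation of `0:2`. The
#'   default maps dark to noncalcified (0), middle to bone (1), bright to
#'   graft (2), matching the usual micro-CT contrast of hydroxyapatite
#'   particles over mineralized bone over soft tissue.
#' @return An object of class `threshold_pair`.
#' @export
threshold_pair <- function(t_low, t_high, phase_order = c(0L, 1L, 2L)) {
  stopifnot(is.finite(t_low), is.finite(t_high), t_low < t_high,
            length(phase_order) == 3L, setequal(phase_order, 0:2))
  structure(list(t_low = t_low, t_high = t_high,
                 phase_order = as.integer(phase_order)),
            class = "threshold_pair")
}

#' Automatic two-threshold selection (multi-class Otsu)
#'
#' Chooses the pair of luminance thresholds that maximizes the between-class
#' variance of the three resulting bands over the valid pixels of a section
#' (the three-class generalization of Otsu's method), computed on a 256-bin
#' histogram. Thresholds are selected per image, standing in for the study's
#' manual per-image luminance selection.
#'
#' @param slice A `slice_image` from [extract_slice()].
#' @param phase_order Band-to-phase mapping, as in [threshold_pair()].
#' @param n_bins Histogram resolution.
#' @return A [threshold_pair()].
#' @export
auto_thresholds <- function(slice, phase_order = c(0L, 1L, 2L),
                            n_bins = 256L) {
  stopifnot(inherits(slice, "slice_image"))
  v <- slice$values[slice$valid_mask]
  nu <- length(unique(v))
  if (nu < 3L) {
    stop(sprintf(
      "auto_thresholds: need >= 3 distinct intensities, found %d", nu))
  }
  rng <- range(v)
  # bin index in 1..n_bins; bin b covers [edge[b], edge[b+1])
  b <- pmin(n_bins, 1L + floor((v - rng[1]) / diff(rng) * n_bins))
  counts <- tabulate(b, nbins = n_bins)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * diff(rng) / n_bins
  W <- cumsum(counts)                 # pixels in bins 1..b
  S <- cumsum(counts * mids)          # intensity mass in bins 1..b
  n <- W[n_bins]; total <- S[n_bins]
  # between-class variance for splits (i, j): classes 1..i, i+1..j, j+1..end.
  # Vectorized over j for each candidate i.
  best <- c(-Inf, NA, NA)
  for (i in seq_len(n_bins - 2L)) {
    if (counts[i] == 0L && i > 1L && counts[i - 1L] == 0L) next
    w1 <- W[i]; s1 <- S[i]
    if (w1 == 0L) next
    j <- (i + 1L):(n_bins - 1L)
    w2 <- W[j] - w1; w3 <- n - W[j]
    ok <- w2 > 0L & w3 > 0L
    if (!any(ok)) next
    s2 <- S[j] - s1; s3 <- total - S[j]
    bcv <- s1^2 / w1 + ifelse(ok, s2^2 / w2 + s3^2 / w3, -Inf)
    jb <- which.max(bcv)
    if (bcv[jb] > best[1]) best <- c(bcv[jb], i, j[jb])
  }
  if (!is.finite(best[1])) {
    stop("auto_thresholds: degenerate histogram, no valid three-band split")
  }
  edge <- function(bin) rng[1] + bin * diff(rng) / n_bins
  threshold_pair(edge(best[2]), edge(best[3]), phase_order = phase_order)
}

#' Segment a grayscale section into three phases
#'
#' Assigns every valid pixel its intensity band's phase label; invalid
#' pixels stay invalid. Deterministic.
#'
#' @param slice A `slice_image`.
#' @param thresholds A [threshold_pair()].
#' @return A [phase_map()] carrying the slice's plane provenance and a
#'   `thresholds` attribute.
#' @export
threshold_segment <- function(slice, thresholds) {
  stopifnot(inherits(slice, "slice_image"),
            inherits(thresholds, "threshold_pair"))
  if (!any(slice$valid_mask)) stop("threshold_segment: no valid pixels")
  band <- matrix(NA_integer_, nrow(slice$values), ncol(slice$values))
  v <- slice$values
  band[slice$valid_mask] <-
    1L + (v[slice$valid_mask] >= thresholds$t_low) +
         (v[slice$valid_mask] >= thresholds$t_high)
  lab <- matrix(thresholds$phase_order[band], nrow(band), ncol(band))
  out <- phase_map(lab, valid_mask = slice$valid_mask, plane = slice$plane)
  attr(out, "thresholds") <- thresholds
  out
}

#' Overlay manual phase designations onto an automatic segmentation
#'
#' Replaces automatic labels wherever the override map carries a label
#' (non-`NA`), mirroring the study's manual designation of pixels whose
#' phase borderline was unclear. All other pixels are unchanged.
#'
#' @param map Automatic [phase_map()].
#' @param override [phase_map()] of the same shape; `NA` where no manual
#'   designation applies.
#' @return The merged [phase_map()].
#' @export
apply_manual_override <- function(map, override) {
  stopifnot(inherits(map, "phase_map"), inherits(override, "phase_map"))
  if (!all(dim(map$labels) == dim(override$labels))) {
    stop("apply_manual_override: shape mismatch")
  }
  sel <- !is.na(override$labels)
  map$labels[sel] <- override$labels[sel]
  map$valid_mask <- map$valid_mask | sel
  map
}
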