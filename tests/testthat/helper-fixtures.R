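# Shared fixtures: small phantoms and hand-built maps used across test files.

small_spec <- function(shape = c(32L, 32L, 32L), seed = 1L, ...) {
  phantom_spec(shape = shape, seed = seed, ...)
}

# A tiny deterministic gray section wrapped as a slice_image (no volume).
as_slice <- function(values, pitch = 19.75) {
  pl <- section_plane(origin = c(0, 0, 0), normal = c(0, 0, 1),
                      u_axis = c(1, 0, 0), v_axis = c(0, 1, 0),
                      pixel_pitch = pitch, extent = dim(values))
  structure(list(values = values, valid_mask = !is.na(values), plane = pl),
            class = "slice_image")
}

as_map <- function(labels, pitch = 19.75) {
  pl <- section_plane(origin = c(0, 0, 0), normal = c(0, 0, 1),
                      u_axis = c(1, 0, 0), v_axis = c(0, 1, 0),
                      pixel_pitch = pitch, extent = dim(labels))
  phase_map(labels, plane = pl)
}

# ROI spanning the whole image regardless of pitch.
full_roi <- function() roi_spec(size_mm = c(1e6, 1e6))

# Independent direct-formula oracle for Lin's concordance coefficient and
# its transformed CI, written from the defining formulas with explicit sums
# (kept separate from the package implementation on purpose).
oracle_ccc <- function(x, y, conf_level = 0.95) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  pc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2) / sqrt(sy2)
  u <- (mx - my) / sqrt(sqrt(sx2) * sqrt(sy2))
  v2 <- (1 / (n - 2)) * (
    (1 - r^2) * pc^2 / ((1 - pc^2) * r^2) +
    (4 * pc^3 * (1 - pc) * u^2) / (r * (1 - pc^2)^2) -
    (2 * pc^4 * u^4) / (r^2 * (1 - pc^2)^2))
  z <- 0.5 * log((1 + pc) / (1 - pc))
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(ccc = pc, r = r,
       lo = tanh(z - q * sqrt(v2)), hi = tanh(z + q * sqrt(v2)))
}

# ANOVA-decomposition oracle for ICC(A,1) with k = 2, via stats::aov.
oracle_icc_a1 <- function(x, y) {
  n <- length(x)
  df <- data.frame(score = c(x, y),
                   subject = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(c("a", "b"), each = n)))
  ms <- summary(stats::aov(score ~ subject + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 / n * (msc - mse))
}
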