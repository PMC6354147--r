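test_that("phantom spec validates its invariants", {
  expect_error(phantom_spec(bone_fraction_target = 0.6,
                            graft_fraction_target = 0.5))
  expect_error(phantom_spec(shape = c(4, 64, 64)))
  expect_error(phantom_spec(correlation_length = 0))
})

test_that("zero bone target yields a volume with no bone voxels", {
  sp <- small_spec(bone_fraction_target = 0, graft_fraction_target = 0.05)
  pv <- generate_phase_volume(sp)
  expect_equal(sum(pv$labels == 1L), 0L)
})

test_that("realized fractions match targets and exhaustive voxel tallies", {
  sp <- phantom_spec(shape = c(64L, 64L, 64L), bone_fraction_target = 0.30,
                     graft_fraction_target = 0.15, seed = 1L)
  pv <- generate_phase_volume(sp)
  # brute-force voxel count, independent of phase_fractions()
  n <- prod(dim(pv$labels))
  bone_frac <- sum(pv$labels == 1L) / n
  graft_frac <- sum(pv$labels == 2L) / n
  expect_lt(abs(bone_frac - 0.30), 0.02)
  expect_lt(abs(graft_frac - 0.15), 0.02)
  rf <- attr(pv, "realized_fractions")
  expect_identical(unname(rf["bone"]), bone_frac)
  expect_identical(unname(rf["graft"]), graft_frac)
  expect_identical(unname(rf["noncalcified"]), sum(pv$labels == 0L) / n)
})

test_that("generation is bitwise deterministic under a fixed seed", {
  sp <- small_spec(seed = 7L)
  expect_identical(generate_phase_volume(sp)$labels,
                   generate_phase_volume(sp)$labels)
  gv1 <- render_grayscale(generate_phase_volume(sp), sp)
  gv2 <- render_grayscale(generate_phase_volume(sp), sp)
  expect_identical(gv1$values, gv2$values)
})

test_that("noiseless rendering produces exactly the three phase means and inverts", {
  sp <- small_spec(noise_sd = 0, blur_sigma = 0, seed = 3L)
  pv <- generate_phase_volume(sp)
  gv <- render_grayscale(pv, sp)
  expect_setequal(unique(as.vector(gv$values)), unname(sp$phase_means))
  # thresholding midway between phase means recovers the labels exactly
  m <- sort(unname(sp$phase_means))
  rec <- array(0L, dim = dim(gv$values))
  rec[gv$values >= mean(m[1:2])] <- 1L
  rec[gv$values >= mean(m[2:3])] <- 2L
  expect_identical(rec, pv$labels)
})

test_that("rendering with distinct-mean check and noise model hold", {
  sp <- small_spec(noise_sd = 12, blur_sigma = 0, seed = 5L)
  pv <- generate_phase_volume(sp)
  bad <- sp; bad$phase_means <- c(noncalcified = 50, bone = 50, graft = 230)
  expect_error(render_grayscale(pv, bad), "distinct")
  gv <- render_grayscale(pv, sp)
  for (p in 0:2) {
    vals <- gv$values[pv$labels == p]
    se <- sp$noise_sd / sqrt(length(vals))
    expect_lt(abs(mean(vals) - sp$phase_means[p + 1]), 3 * se)
  }
})

test_that("histology proxy reduces to the exact slice when unperturbed", {
  sp <- small_spec(seed = 11L)
  sp$histology_perturbation <- list(offset_um = 0, tilt_deg = 0,
                                    label_noise = 0)
  pv <- generate_phase_volume(sp)
  pl <- axis_aligned_plane(pv, "z", 16L)
  expect_identical(make_histology_proxy(pv, pl, sp)$labels,
                   extract_phase_slice(pv, pl)$labels)
})

test_that("proxy label-flip fraction sits within binomial bounds of its rate", {
  sp <- small_spec(shape = c(48L, 48L, 48L), seed = 13L)
  sp$histology_perturbation <- list(offset_um = 0, tilt_deg = 0,
                                    label_noise = 0.05)
  pv <- generate_phase_volume(sp)
  pl <- axis_aligned_plane(pv, "z", 24L)
  base <- extract_phase_slice(pv, pl)
  prox <- make_histology_proxy(pv, pl, sp)
  n <- sum(base$valid_mask)
  flipped <- sum(prox$labels != base$labels, na.rm = TRUE)
  bounds <- stats::qbinom(c(0.005, 0.995), n, 0.05)
  expect_gte(flipped, bounds[1])
  expect_lte(flipped, bounds[2])
})

test_that("a 79-um proxy offset equals the +4-pixel offset plane at 19.75 um pitch", {
  sp <- small_spec(seed = 17L)
  sp$histology_perturbation <- list(offset_um = 79, tilt_deg = 0,
                                    label_noise = 0)
  pv <- generate_phase_volume(sp)
  pl <- axis_aligned_plane(pv, "z", 10L)
  expect_identical(make_histology_proxy(pv, pl, sp)$labels,
                   extract_phase_slice(pv, offset_plane(pl, 4))$labels)
})

test_that("proxy fails when the perturbed plane leaves the volume", {
  sp <- small_spec(seed = 19L)
  sp$histology_perturbation <- list(offset_um = 5000, tilt_deg = 0,
                                    label_noise = 0)
  pv <- generate_phase_volume(sp)
  pl <- axis_aligned_plane(pv, "z", 16L)
  expect_error(make_histology_proxy(pv, pl, sp), "outside")
})

test_that("graft placement fails explicitly when the target is unreachable", {
  sp <- small_spec(bone_fraction_target = 0.55, graft_fraction_target = 0.42,
                   graft_radius_mean = 140, graft_radius_sd = 0, seed = 23L)
  expect_error(generate_phase_volume(sp), "realized fraction")
})

test_that("smoother structure gives higher agreement between nearby planes", {
  # percent bone at two planes 4 px apart, 20 matched-seed replicates per
  # correlation length: concordance between the planes must not fall as the
  # structure becomes smoother
  plane_ccc <- function(corr_len) {
    pcts <- vapply(1:20, function(s) {
      sp <- small_spec(shape = c(24L, 24L, 24L), graft_fraction_target = 0,
                       correlation_length = corr_len, seed = 100L + s)
      pv <- generate_phase_volume(sp)
      p0 <- axis_aligned_plane(pv, "z", 10L)
      c(percent_areas(extract_phase_slice(pv, p0), full_roi())$pct_bone,
        percent_areas(extract_phase_slice(pv, offset_plane(p0, 4)),
                      full_roi())$pct_bone)
    }, numeric(2))
    ccc(pcts[1, ], pcts[2, ])$ccc
  }
  expect_gte(plane_ccc(90), plane_ccc(30))
})
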