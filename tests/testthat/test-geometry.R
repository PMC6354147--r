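make_volume <- function(d = c(12, 10, 8), seed = 1) {
  set.seed(seed)
  voxel_volume(array(rnorm(prod(d)), dim = d), spacing = 19.75)
}

test_that("axis-aligned plane construction places origin and normal correctly", {
  vol <- make_volume()
  pl <- axis_aligned_plane(vol, "z", 3L)
  expect_equal(pl$normal, c(0, 0, 1))
  expect_equal(pl$origin[3], vol$origin[3] + 3 * vol$spacing)
  pl2 <- axis_aligned_plane(vol, "z", 7L)
  expect_equal(sqrt(sum((pl2$origin - pl$origin)^2)), 4 * vol$spacing)
  expect_error(axis_aligned_plane(vol, "z", 8L), "outside")
})

test_that("extraction at an axis-aligned plane reproduces the raw array slice", {
  vol <- make_volume()
  for (k in c(0L, 4L, 7L)) {
    pl <- axis_aligned_plane(vol, "z", k)
    sl <- extract_slice(vol, pl, interpolation = "nearest")
    expect_identical(sl$values, vol$values[, , k + 1])
    expect_true(all(sl$valid_mask))
    # trilinear sampling exactly at voxel centers is exact too
    sl_t <- extract_slice(vol, pl, interpolation = "trilinear")
    expect_lt(max(abs(sl_t$values - vol$values[, , k + 1])), 1e-12)
  }
  pv <- phase_volume(array(sample(0:2, 12 * 10 * 8, TRUE), dim = c(12, 10, 8)),
                     spacing = 19.75)
  pl <- axis_aligned_plane(pv, "x", 5L)
  expect_identical(extract_phase_slice(pv, pl)$labels, pv$labels[6, , ])
})

test_that("parallel offset moves 4 pixels = 79 um and inverts exactly", {
  vol <- make_volume()
  pl <- axis_aligned_plane(vol, "z", 4L)
  p4 <- offset_plane(pl, 4)
  expect_equal(sqrt(sum((p4$origin - pl$origin)^2)), 79)
  expect_identical(offset_plane(pl, 0), pl)
  back <- offset_plane(p4, -4)
  expect_lt(max(abs(back$origin - pl$origin)), 1e-9)
  expect_identical(back$u_axis, pl$u_axis)
})

test_that("rotation pivots about v, preserves v, and inverts", {
  vol <- make_volume()
  pl <- axis_aligned_plane(vol, "z", 4L)
  r10 <- rotate_plane(pl, 10)
  expect_identical(rotate_plane(pl, 0), pl)
  expect_equal(r10$v_axis, pl$v_axis)
  expect_lt(abs(sum(r10$normal * pl$normal) - cos(10 * pi / 180)), 1e-12)
  back <- rotate_plane(r10, -10)
  for (f in c("origin", "normal", "u_axis", "v_axis")) {
    expect_lt(max(abs(back[[f]] - pl[[f]])), 1e-9)
  }
})

test_that("frame stays orthonormal through 100 composed perturbations", {
  vol <- make_volume()
  pl <- axis_aligned_plane(vol, "z", 4L)
  set.seed(99)
  for (i in 1:100) {
    pl <- if (runif(1) < 0.5) offset_plane(pl, sample(-3:3, 1))
          else rotate_plane(pl, runif(1, -12, 12))
  }
  expect_lt(abs(sqrt(sum(pl$u_axis^2)) - 1), 1e-9)
  expect_lt(abs(sqrt(sum(pl$v_axis^2)) - 1), 1e-9)
  expect_lt(abs(sum(pl$u_axis * pl$v_axis)), 1e-9)
  expect_lt(max(abs(secmorph:::cross3(pl$u_axis, pl$v_axis) - pl$normal)),
            1e-9)
})

test_that("trilinear extraction is linear in the volume and exact on constants", {
  d <- c(12, 10, 8)
  v1 <- make_volume(d, seed = 2)
  v2 <- make_volume(d, seed = 3)
  pl <- rotate_plane(offset_plane(axis_aligned_plane(v1, "z", 4L), 1.3), 7)
  a <- 0.7; b <- -2.1
  mix <- voxel_volume(a * v1$values + b * v2$values, spacing = v1$spacing)
  s1 <- extract_slice(v1, pl)$values
  s2 <- extract_slice(v2, pl)$values
  sm <- extract_slice(mix, pl)$values
  sel <- !is.na(sm)
  expect_lt(max(abs(sm[sel] - (a * s1 + b * s2)[sel])), 1e-9)

  const <- voxel_volume(array(3.25, dim = d), spacing = 19.75)
  sc <- extract_slice(const, pl)
  expect_true(all(abs(sc$values[sc$valid_mask] - 3.25) < 1e-12))
})

test_that("out-of-volume samples are masked rather than filled", {
  vol <- make_volume()
  pl <- axis_aligned_plane(vol, "z", 4L)
  pl$extent <- c(30L, 30L)  # larger than the volume cross-section
  sl <- extract_slice(vol, pl, interpolation = "nearest")
  expect_true(any(!sl$valid_mask))
  expect_true(all(is.na(sl$values[!sl$valid_mask])))
  expect_true(all(!is.na(sl$values[sl$valid_mask])))
})

test_that("rotated-plane label extraction matches a brute-force per-pixel oracle", {
  sp <- small_spec(shape = c(64L, 64L, 64L), seed = 31L)
  pv <- generate_phase_volume(sp)
  pl <- rotate_plane(axis_aligned_plane(pv, "z", 32L), 10)
  got <- extract_phase_slice(pv, pl)
  # explicit scalar loop: world point of each pixel, nearest voxel lookup
  n1 <- pl$extent[1]; n2 <- pl$extent[2]
  want <- matrix(NA_integer_, n1, n2)
  d <- dim(pv$labels)
  for (a in seq_len(n1)) {
    for (b in seq_len(n2)) {
      p <- pl$origin +
        ((a - 1) - (n1 - 1) / 2) * pl$pixel_pitch * pl$u_axis +
        ((b - 1) - (n2 - 1) / 2) * pl$pixel_pitch * pl$v_axis
      ijk <- round((p - pv$origin) / pv$spacing)
      if (all(ijk >= 0) && all(ijk <= d - 1)) {
        want[a, b] <- pv$labels[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1]
      }
    }
  }
  expect_identical(got$labels, want)
  expect_identical(got$valid_mask, !is.na(want))
})
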