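noiseless_config <- function(n = 5L, seed = 7L) {
  ph <- phantom_spec(shape = c(32L, 32L, 32L), noise_sd = 0, blur_sigma = 0,
                     histology_perturbation = list(offset_um = 0,
                                                   tilt_deg = 0,
                                                   label_noise = 0))
  study_config(n_specimens = n, phantom = ph, seed = seed)
}

test_that("a noiseless self-comparison study yields perfect original-plane agreement", {
  rep <- run_study(noiseless_config())
  for (tab in list(rep$table_bone, rep$table_graft)) {
    row <- tab[tab$reference == "HM" & tab$comparator == "original", ]
    expect_equal(row$ccc, 1)
    expect_equal(row$mean_diff, 0)
    expect_equal(row$sd_diff, 0)
  }
  expect_identical(nrow(rep$measurements), 5L * 6L)
})

test_that("studies are byte-identical under a fixed master seed", {
  cfg <- study_config(n_specimens = 3L,
                      phantom = phantom_spec(shape = c(32L, 32L, 32L)),
                      seed = 42L)
  r1 <- run_study(cfg)
  r2 <- run_study(cfg)
  expect_identical(r1$measurements, r2$measurements)
  expect_identical(r1$table_bone, r2$table_bone)
  expect_identical(r1$table_graft, r2$table_graft)
})

test_that("specimens are independent: extending the study preserves early specimens", {
  cfg3 <- study_config(n_specimens = 3L,
                       phantom = phantom_spec(shape = c(32L, 32L, 32L)),
                       seed = 9L)
  cfg5 <- cfg3; cfg5$n_specimens <- 5L
  m3 <- run_study(cfg3)$measurements
  m5 <- run_study(cfg5)$measurements
  expect_identical(m3, m5[m5$specimen <= 3, ])
})

test_that("every table number is recomputable from config + seed alone", {
  cfg <- study_config(n_specimens = 3L,
                      phantom = phantom_spec(shape = c(32L, 32L, 32L)),
                      seed = 27L)
  rep1 <- run_study(cfg)
  dir <- withr::local_tempdir()
  write_study_report(rep1, dir)
  stored <- jsonlite::read_json(file.path(dir, "report.json"),
                                simplifyVector = TRUE)
  cfg2 <- study_config(
    n_specimens = stored$config$n_specimens,
    phantom = do.call(phantom_spec, stored$config$phantom),
    offsets_px = stored$config$offsets_px,
    rotations_deg = stored$config$rotations_deg,
    seed = stored$config$seed)
  rep2 <- run_study(cfg2)
  expect_equal(rep2$table_bone$ccc, stored$table_bone$ccc)
  expect_equal(rep2$table_graft$mean_diff, stored$table_graft$mean_diff)
  expect_true(file.exists(file.path(dir, "measurements.csv")))
  expect_true(file.exists(file.path(dir, "bland_altman",
                                    "HM_vs_original_bone.csv")))
})

test_that("report row counts and Bland-Altman sets match the design", {
  rep <- run_study(noiseless_config(n = 4L, seed = 3L))
  expect_identical(length(rep$bland_altman), 18L)  # 9 rows x 2 phases
  expect_true(all(vapply(rep$bland_altman, nrow, integer(1)) == 4L))
})

test_that("a zero-offset sweep reports perfect agreement only", {
  cfg <- study_config(n_specimens = 3L,
                      phantom = phantom_spec(shape = c(32L, 32L, 32L)),
                      seed = 5L)
  sw <- sweep_perturbation(cfg, offsets = 0, n_replicates = 1L)
  expect_true(all(sw$ccc == 1))
  expect_true(all(sw$mean_abs_diff == 0))
})

test_that("sweeps cover requested levels for both perturbation kinds", {
  cfg <- study_config(n_specimens = 3L,
                      phantom = phantom_spec(shape = c(32L, 32L, 32L)),
                      seed = 8L)
  sw <- sweep_perturbation(cfg, offsets = c(1, 4), angles = 10,
                           n_replicates = 2L)
  expect_identical(nrow(sw), 2L * 3L * 2L)  # replicates x levels x phases
  expect_setequal(unique(sw$kind), c("offset", "rotation"))
})

test_that("search mode recovers the matched plane and agrees with fast mode", {
  ph <- phantom_spec(shape = c(32L, 32L, 32L),
                     histology_perturbation = list(offset_um = 0,
                                                   tilt_deg = 0,
                                                   label_noise = 0.02))
  cfg <- study_config(
    n_specimens = 3L, phantom = ph, seed = 63L, fast_mode = FALSE,
    search = plane_search_spec(offset_range = c(-39.5, 39.5),
                               offset_step = 19.75,
                               tilt_v_range = c(-5, 5), tilt_step = 2.5))
  rep_search <- run_study(cfg)
  cfg$fast_mode <- TRUE
  rep_fast <- run_study(cfg)
  # the proxy sits at the generating plane, so the search should land there
  # and both modes should report identical matched-plane agreement
  row_s <- rep_search$table_bone[1, ]
  row_f <- rep_fast$table_bone[1, ]
  expect_equal(row_s$ccc, row_f$ccc, tolerance = 1e-6)
  expect_equal(row_s$mean_diff, row_f$mean_diff, tolerance = 1e-6)
})
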