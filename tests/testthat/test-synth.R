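test_that("temporal scenes are deterministic and honour explicit schedules", {
  p <- scene_params(seed = 99)
  s1 <- generate_temporal_scene(p)
  s2 <- generate_temporal_scene(p)
  expect_identical(s1$masks, s2$masks)
  expect_identical(s1$truth, s2$truth)

  # no events: constant sequence, all-zero records
  quiet <- scene_params(n_timepoints = 5,
                        growth_schedule = replicate(4, data.frame(area = integer()),
                                                    simplify = FALSE),
                        decay_schedule = rep(0L, 4), seed = 1)
  s <- generate_temporal_scene(quiet)
  expect_true(all(vapply(s$masks[-1], identical, logical(1), s$masks[[1]])))
  rec <- udt_series(s$masks)
  expect_true(all(rec$change_pos_area == 0L))
  expect_true(all(rec$nchange_pos == 0L))

  # three planted disks of areas 5, 9, 13 in one step
  sched <- list(data.frame(area = c(5L, 9L, 13L)))
  s <- generate_temporal_scene(scene_params(n_timepoints = 2,
                                            growth_schedule = sched,
                                            decay_schedule = 0L, seed = 4))
  expect_equal(s$truth$nchange_pos, 3L)
  expect_equal(s$truth$maxchange_pos, 13)
  rec <- udt_series(s$masks)
  expect_equal(rec$nchange_pos, 3L)
  expect_equal(rec$maxchange_pos, 13L)
  expect_equal(rec$change_pos_area, 27L)
})

test_that("planted components stay separable: pipeline recovers truth exactly", {
  for (seed in 1:6) {
    s <- generate_temporal_scene(scene_params(seed = seed))
    rec <- udt_series(s$masks)
    expect_identical(rec$nchange_pos, as.integer(s$truth$nchange_pos))
    expect_identical(rec$nchange_neg, as.integer(s$truth$nchange_neg))
    expect_identical(rec$maxchange_pos, as.integer(s$truth$maxchange_pos))
    expect_identical(rec$maxchange_neg, as.integer(s$truth$maxchange_neg))
    expect_identical(rec$change_pos_area, as.integer(s$truth$change_pos_area))
    expect_equal(rec$dispersion_pos, s$truth$dispersion_pos, tolerance = 1e-12)
  }
})

test_that("infeasible placements raise a placement error", {
  sched <- list(data.frame(area = 64L))
  expect_error(
    generate_temporal_scene(scene_params(image_shape = c(8L, 8L),
                                         n_timepoints = 2,
                                         base_area = 16L,
                                         growth_schedule = sched,
                                         decay_schedule = 0L, seed = 1)),
    "placement error")
})

test_that("modality pairs plant exact degenerate couplings", {
  p1 <- generate_modality_pair(scene_params(rho_target = 1, seed = 8))
  pr <- prepare_pair(modality_crop(p1$x_img), modality_crop(p1$y_img))
  expect_equal(intermodal_correlation(pr)$ic, 1)

  m1 <- generate_modality_pair(scene_params(rho_target = -1, seed = 8))
  pr <- prepare_pair(modality_crop(m1$x_img), modality_crop(m1$y_img))
  expect_equal(intermodal_correlation(pr)$ic, -1)

  # determinism
  a <- generate_modality_pair(scene_params(rho_target = 0.5, seed = 12))
  b <- generate_modality_pair(scene_params(rho_target = 0.5, seed = 12))
  expect_identical(a$x_img, b$x_img)
  expect_identical(a$y_img, b$y_img)
  # background zero, foreground in [1, 255]
  expect_true(all(a$x_img[a$fg == 0L] == 0))
  expect_true(all(a$x_img[a$fg == 1L] >= 1))
  expect_true(all(a$x_img[a$fg == 1L] <= 255))
})

test_that("cohorts write a rescannable tree with plants as replicates", {
  td <- tempfile()
  r <- generate_cohort(td, n_per_treatment = 3,
                       params = scene_params(n_timepoints = 4, seed = 2))
  idx <- scan_dataset(r$root, r$manifest)
  expect_equal(nrow(idx), 2 * 3 * 4)
  expect_setequal(unique(idx$treatment), c("control", "drought"))
  # convention scan agrees with the manifest scan
  idx2 <- scan_dataset(r$root)
  expect_equal(nrow(idx2), nrow(idx))
  expect_setequal(idx2$relpath, idx$relpath)
  # per-plant seeds derive from the plant label: plants differ
  s1 <- mask_sequence(idx, "c01")
  s2 <- mask_sequence(idx, "c02")
  expect_false(identical(s1$masks, s2$masks))
})
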