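test_that("modality crops trim to the plant bounding box", {
  img <- matrix(0, 8, 8); img[3:5, 4:6] <- 100
  cr <- modality_crop(img)
  expect_equal(dim(cr$image), c(3L, 3L))
  expect_true(all(cr$fg == 1L))
  # explicit mask wins over the threshold rule
  fg <- matrix(0L, 8, 8); fg[3:4, 4] <- 1L
  expect_equal(dim(modality_crop(img, fg_mask = fg)$image), c(2L, 1L))
})

test_that("pair alignment resamples to the smaller crop and pairs overlap values", {
  img <- matrix(0, 10, 10); img[3:8, 3:8] <- 50
  cr <- modality_crop(img)
  same <- prepare_pair(cr, cr)
  expect_equal(same$n, 36L)
  expect_identical(same$x_vals, same$y_vals)

  # 10x10 and 20x20 crops of the same disk -> output at 10x10
  small <- matrix(0, 12, 12); small[2:11, 2:11] <- 80
  big <- matrix(0, 24, 24); big[3:22, 3:22] <- 80
  pr <- prepare_pair(modality_crop(small), modality_crop(big))
  expect_equal(dim(pr$x_img), c(10L, 10L))
  expect_gt(pr$n, 0L)

  # disjoint foregrounds after alignment -> insufficient overlap
  a <- matrix(0, 6, 6); a[1, 1:6] <- 5   # 1x6 crop
  b <- matrix(0, 6, 6); b[1:6, 1] <- 5   # 6x1 crop
  am <- modality_crop(a); bm <- modality_crop(b)
  am$fg[] <- c(1L, rep(0L, 5))           # single off-centre overlap pixel
  bm$fg[] <- c(0L, rep(1L, 5))
  expect_error(prepare_pair(am, bm), "insufficient overlap")
})

test_that("intermodal correlation hits its closed-form limits", {
  set.seed(3)
  x <- sample(0:255, 400, TRUE)
  expect_equal(intermodal_correlation(pair_from_values(x, x))$ic, 1)
  expect_equal(intermodal_correlation(pair_from_values(x, 255 - x))$ic, -1)
  y <- sample(0:255, 400, TRUE)
  expect_equal(intermodal_correlation(pair_from_values(x, y))$ic,
               pearson_oracle(x, y), tolerance = 1e-12)
  expect_error(intermodal_correlation(pair_from_values(rep(7, 10), 1:10)),
               "degenerate variance")
})

test_that("correlation is symmetric and affine invariant", {
  set.seed(19)
  x <- runif(300, 0, 255); y <- runif(300, 0, 255)
  ab <- intermodal_correlation(pair_from_values(x, y))
  ba <- intermodal_correlation(pair_from_values(y, x))
  expect_equal(ab$ic, ba$ic, tolerance = 1e-12)
  shifted <- intermodal_correlation(pair_from_values(0.5 * x + 30, y))
  expect_equal(ab$ic, shifted$ic, tolerance = 1e-9)
})

test_that("histogram entropy uses 64 fixed-width bins in bits", {
  expect_equal(histogram_entropy(rep(100, 50)), 0)
  expect_equal(histogram_entropy(rep(c(10, 200), 25)), 1)
  # one value in each of the 64 bins, equally often: log2(64) bits
  expect_equal(histogram_entropy(0:255), 6)
  expect_equal(histogram_entropy(seq(0, 252, by = 4)), 6)
})

test_that("mutual information obeys its information-theoretic identities", {
  set.seed(23)
  x <- sample(0:255, 500, TRUE)
  self <- intermodal_mutual_information(pair_from_values(x, x))
  expect_equal(self$imi, self$h_x, tolerance = 1e-12)
  expect_equal(self$h_x, histogram_entropy(x), tolerance = 1e-12)

  const <- intermodal_mutual_information(pair_from_values(x, rep(9, 500)))
  expect_equal(const$imi, 0, tolerance = 1e-12)

  # joint counts [[2,0],[0,2]] across two bins each: 1 bit
  hand <- intermodal_mutual_information(pair_from_values(c(0, 0, 100, 100),
                                                         c(30, 30, 220, 220)))
  expect_equal(hand$imi, 1)
  expect_equal(hand$h_xy, 1)

  # probability tables sum to one; symmetry; bounds
  y <- sample(0:255, 500, TRUE)
  mi <- intermodal_mutual_information(pair_from_values(x, y))
  expect_equal(sum(mi$p_x), 1)
  expect_equal(sum(mi$p_y), 1)
  expect_equal(sum(mi$p_xy), 1)
  expect_identical(mi$imi,
                   intermodal_mutual_information(pair_from_values(y, x))$imi)
  expect_gte(mi$imi, -1e-9)
  expect_lte(mi$imi, min(mi$h_x, mi$h_y) + 1e-9)
})

test_that("independent channels lose apparent information as overlap grows", {
  # finite-sample MI bias shrinks with n for planted-independent images
  set.seed(29)
  mean_mi <- vapply(c(100, 1000, 10000), function(n) {
    mean(vapply(1:20, function(i) {
      x <- sample(0:255, n, TRUE); y <- sample(0:255, n, TRUE)
      intermodal_mutual_information(pair_from_values(x, y))$imi
    }, numeric(1)))
  }, numeric(1))
  # estimates decay toward 0; at n = 1e4 the residual is the classic
  # (Bx-1)(By-1)/(2 n ln 2) joint-histogram bias (~0.29 bits for 64x64 bins)
  expect_true(all(diff(mean_mi) < 0))
  expect_lt(mean_mi[3], 0.5)
})

test_that("udm_series pairs modalities per time point and skips partial coverage", {
  root <- tempfile()
  pairdat <- generate_modality_pair(scene_params(fg_area = 400,
                                                 image_shape = c(30, 30),
                                                 rho_target = 0.9, seed = 5))
  for (t in 0:2) {
    for (mod in c("vis", "fluo")) {
      d <- file.path(root, "sunflower", "control", "c01", mod)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      img <- if (mod == "vis") pairdat$x_img else pairdat$y_img
      write_intensity(img, file.path(d, sprintf("%d.png", t)))
    }
  }
  # infrared present only at t = 0: pairing vi must skip t = 1
  d <- file.path(root, "sunflower", "control", "c01", "ir")
  dir.create(d, recursive = TRUE)
  write_intensity(pairdat$y_img, file.path(d, "0.png"))

  idx <- scan_dataset(root)
  vf <- udm_series(idx, "c01", "vf")
  expect_equal(nrow(vf), 3L)
  expect_true(all(vf$ic > 0.5))
  expect_true(all(vf$n_overlap >= 2))

  expect_warning(vi <- udm_series(idx, "c01", "vi"), "skipped") |>
    suppressWarnings()
  expect_equal(vi$t, 0L)

  suppressWarnings(
    expect_error(udm_series(idx[is.na(idx$modality) | idx$modality != "infrared", ],
                            "c01", "if"),
                 "no common time points"))
})
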