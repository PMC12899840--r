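test_that("mask loading thresholds intensities and round-trips through PNG", {
  f <- tempfile(fileext = ".png")
  png::writePNG(matrix(0, 4, 4), f)
  expect_equal(sum(load_mask(f)), 0L)

  png::writePNG(matrix(c(0, 1, 1, 0), 2, 2), f)
  expect_equal(load_mask(f), matrix(c(0L, 1L, 1L, 0L), 2, 2))

  # values {0, 1, 128, 255} at threshold 0: three foreground pixels
  png::writePNG(matrix(c(0, 1, 128, 255) / 255, 2, 2), f)
  expect_equal(sum(load_mask(f, foreground_threshold = 0)), 3L)

  # round-trip: write_mask then load_mask is the identity
  set.seed(42)
  m <- random_mask(13, 9)
  write_mask(m, f)
  expect_identical(load_mask(f), m)

  # RGB input reduces by any-channel > threshold
  arr <- array(0, c(2, 2, 3)); arr[1, 1, 2] <- 0.5
  png::writePNG(arr, f)
  expect_equal(which(load_mask(f) == 1L), 1L)
})

test_that("mask validation rejects non-binary and zero-size input", {
  expect_error(change_masks(matrix(2L, 2, 2), matrix(0L, 2, 2)), "0 and 1")
  expect_error(load_mask(tempfile(fileext = ".png")), "does not exist")
})

test_that("intensity images load on the 0-255 scale with luminance reduction", {
  f <- tempfile(fileext = ".png")
  write_intensity(matrix(c(0, 128, 200, 255), 2, 2), f)
  expect_equal(load_intensity(f), matrix(c(0, 128, 200, 255), 2, 2))
  arr <- array(0, c(1, 1, 3)); arr[1, 1, ] <- c(1, 0, 0)
  png::writePNG(arr, f)
  expect_equal(load_intensity(f), matrix(0.299 * 255, 1, 1))
  expect_equal(load_intensity(f, band = "r"), matrix(255, 1, 1))
})

make_toy_tree <- function(root) {
  m <- matrix(0L, 4, 4); m[2, 2] <- 1L
  for (t in 0:2) {
    d <- file.path(root, "sunflower", "control", "c01", "deg000")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_mask(m, file.path(d, sprintf("%d.png", t)))
  }
  root
}

test_that("scan_dataset indexes directory trees and manifests, idempotently", {
  empty <- tempfile(); dir.create(empty)
  expect_equal(nrow(scan_dataset(empty)), 0L)

  root <- make_toy_tree(tempfile())
  idx <- scan_dataset(root)
  expect_s3_class(idx, "pheno_index")
  expect_equal(nrow(idx), 3L)
  expect_equal(idx$view_deg, rep(0L, 3))
  expect_identical(as.data.frame(scan_dataset(root)), as.data.frame(idx))

  mf <- tempfile(fileext = ".csv")
  write.csv(data.frame(species = "sunflower", treatment = "control",
                       plant_id = "c01", time_index = 0:1, date = NA,
                       view_deg = 0L, modality = NA,
                       relpath = file.path("sunflower", "control", "c01",
                                           "deg000", c("0.png", "1.png"))),
            mf, row.names = FALSE)
  expect_equal(nrow(scan_dataset(root, mf)), 2L)

  # duplicated key -> index error
  write.csv(data.frame(species = "sunflower", treatment = "control",
                       plant_id = "c01", time_index = c(0L, 0L), date = NA,
                       view_deg = 0L, modality = NA,
                       relpath = file.path("sunflower", "control", "c01",
                                           "deg000", c("0.png", "0.png"))),
            mf, row.names = FALSE)
  expect_error(scan_dataset(root, mf), "duplicate")

  # missing file -> error
  write.csv(data.frame(species = "sunflower", treatment = "control",
                       plant_id = "c01", time_index = 9L, date = NA,
                       view_deg = 0L, modality = NA, relpath = "nope.png"),
            mf, row.names = FALSE)
  expect_error(scan_dataset(root, mf), "missing")
})

test_that("mask_sequence sorts by time and enforces shared dimensions", {
  root <- tempfile()
  d <- file.path(root, "sunflower", "control", "c01", "deg000")
  dir.create(d, recursive = TRUE)
  m <- matrix(0L, 4, 4)
  # write out of order: times 0, 2, 1
  for (t in c(0, 2, 1)) {
    m[1, 1] <- as.integer(t == 2)
    write_mask(m, file.path(d, sprintf("%d.png", t)))
  }
  seq <- mask_sequence(scan_dataset(root), "c01", view_deg = 0)
  expect_equal(seq$time_index, 0:2)
  expect_equal(vapply(seq$masks, sum, integer(1L)), c(0L, 0L, 1L))

  # single-frame sequence is valid and yields no change pairs
  d1 <- file.path(root, "sunflower", "control", "c02", "deg000")
  dir.create(d1, recursive = TRUE)
  write_mask(m, file.path(d1, "0.png"))
  one <- mask_sequence(scan_dataset(root), "c02", view_deg = 0)
  expect_equal(length(one$masks), 1L)
  expect_equal(nrow(udt_series(one)), 0L)

  # mismatched dimensions -> error, never padding
  write_mask(matrix(0L, 4, 5), file.path(d1, "1.png"))
  expect_error(mask_sequence(scan_dataset(root), "c02", view_deg = 0),
               "dimensions")
})
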