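# Modality phenotypes: intermodal Pearson correlation (IC) and
# histogram-based mutual information (IMI, bits) between two same-scene,
# same-view images in different modalities, evaluated over the overlap of
# their plant masks after alignment to a common resolution.

#' Crop a modality image to the plant's tight bounding box
#'
#' The plant foreground defaults to pixels with intensity above `threshold`
#' (modality images here carry no separate ground-truth mask); an explicit
#' `fg_mask` overrides that.
#'
#' @param image numeric matrix, intensities in \[0, 255\].
#' @param fg_mask optional 0/1 matrix marking plant pixels.
#' @param threshold foreground threshold used when `fg_mask` is absent.
#' @return a `modality_crop`: list with `image` and `fg` (0/1 matrix), both
#'   cropped to the foreground bounding box.
#' @export
modality_crop <- function(image, fg_mask = NULL, threshold = 0) {
  stopifnot(is.matrix(image))
  if (is.null(fg_mask)) {
    fg_mask <- (image > threshold) * 1L
    mode(fg_mask) <- "integer"
  } else {
    fg_mask <- check_mask(fg_mask, "fg_mask")
    if (!identical(dim(fg_mask), dim(image)))
      stop("fg_mask and image must share dimensions")
  }
  e <- bounding_extent(fg_mask)
  rr <- (e$row_range[1L]:e$row_range[2L]) + 1L
  cc <- (e$col_range[1L]:e$col_range[2L]) + 1L
  structure(list(image = image[rr, cc, drop = FALSE],
                 fg = fg_mask[rr, cc, drop = FALSE]),
            class = "modality_crop")
}

resample_bilinear <- function(m, out_dim) {
  if (identical(dim(m), out_dim)) return(m)
  as.matrix(EBImage::resize(m, w = out_dim[1L], h = out_dim[2L],
                            filter = "bilinear"))
}

#' Align two modality crops to a common resolution
#'
#' Both crops are resampled with bilinear interpolation to the dimensions of
#' the smaller crop (the lower-resolution modality); resampled foreground
#' masks are re-binarized at 0.5. Paired intensity values are read in raster
#' order over the overlap of the two aligned masks.
#'
#' @param a,b `modality_crop` objects from [modality_crop()].
#' @return an `aligned_pair`: list with `x_img`, `y_img` (aligned
#'   intensities), `overlap` (0/1 matrix), `x_vals`, `y_vals` (paired
#'   intensities at overlap pixels) and `n` (overlap size).
#' @export
prepare_pair <- function(a, b) {
  stopifnot(inherits(a, "modality_crop"), inherits(b, "modality_crop"))
  target <- if (prod(dim(a$image)) <= prod(dim(b$image))) dim(a$image) else dim(b$image)
  x_img <- resample_bilinear(a$image, target)
  y_img <- resample_bilinear(b$image, target)
  x_fg <- (resample_bilinear(a$fg * 1.0, target) >= 0.5) * 1L
  y_fg <- (resample_bilinear(b$fg * 1.0, target) >= 0.5) * 1L
  overlap <- x_fg * y_fg
  mode(overlap) <- "integer"
  ov <- which(overlap == 1L)
  if (length(ov) < 2L)
    stop("insufficient overlap: aligned plant masks share ",
         length(ov), " pixel(s), need >= 2")
  # raster order: row by row, left to right
  ord <- order((ov - 1L) %% nrow(overlap), (ov - 1L) %/% nrow(overlap))
  ov <- ov[ord]
  structure(list(x_img = x_img, y_img = y_img, overlap = overlap,
                 x_vals = x_img[ov], y_vals = y_img[ov], n = length(ov)),
            class = "aligned_pair")
}

#' Intermodal correlation (IC)
#'
#' Pearson correlation between the paired overlap intensities of the two
#' modalities: IC = s_xy / (s_x s_y) with sample standard deviations and
#' covariance. A zero-variance channel leaves the correlation undefined and
#' raises an error (callers report such time points as missing rather
#' than 0).
#'
#' @param pair an `aligned_pair` from [prepare_pair()].
#' @return list with `ic` (in \[-1, 1\]), `s_x`, `s_y`, `s_xy`, `n`.
#' @export
intermodal_correlation <- function(pair) {
  stopifnot(inherits(pair, "aligned_pair"))
  s_x <- sd(pair$x_vals)
  s_y <- sd(pair$y_vals)
  if (s_x == 0 || s_y == 0)
    stop("degenerate variance: a modality channel is constant over the overlap")
  s_xy <- stats::cov(pair$x_vals, pair$y_vals)
  ic <- s_xy / (s_x * s_y)
  ic <- min(1, max(-1, ic))  # trim float residue only
  list(ic = ic, s_x = s_x, s_y = s_y, s_xy = s_xy, n = pair$n)
}

# Bin index in 1..bins for 8-bit intensities: the 64 width-4 intervals
# [0,4), [4,8), ..., [252,256); the top edge of the range falls in the last
# bin. Fixed binning keeps entropies comparable across time points.
bin_index <- function(values, bins = 64L, range = c(0, 255)) {
  width <- (range[2L] + 1 - range[1L]) / bins
  idx <- floor((values - range[1L]) / width) + 1L
  pmin(pmax(idx, 1L), bins)
}

#' Histogram entropy in bits
#'
#' Bins values into `bins` equal-width intensity bins spanning `range`
#' (the 8-bit scale by default) and returns the Shannon entropy of the bin
#' frequencies, in bits, with 0 log 0 taken as 0.
#'
#' @param values numeric vector of intensities.
#' @param bins number of bins (64 by default).
#' @param range intensity range covered by the bins.
#' @return entropy in bits.
#' @export
#' @examples
#' histogram_entropy(rep(c(10, 200), 50))  # two equally likely bins: 1 bit
histogram_entropy <- function(values, bins = 64L, range = c(0, 255)) {
  stopifnot(length(values) >= 1L)
  p <- tabulate(bin_index(values, bins, range), nbins = bins) / length(values)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Intermodal mutual information (IMI)
#'
#' IMI = H(X) + H(Y) - H(X,Y) in bits, with marginal entropies from 64-bin
#' intensity histograms and the joint entropy from the corresponding 64 x 64
#' joint histogram over the paired overlap intensities.
#'
#' @param pair an `aligned_pair` from [prepare_pair()].
#' @param bins number of bins per channel (64 by default).
#' @return list with `imi`, `h_x`, `h_y`, `h_xy` (bits), `bins`, and the
#'   probability tables `p_x`, `p_y`, `p_xy`.
#' @export
intermodal_mutual_information <- function(pair, bins = 64L) {
  stopifnot(inherits(pair, "aligned_pair"))
  bx <- bin_index(pair$x_vals, bins)
  by <- bin_index(pair$y_vals, bins)
  n <- pair$n
  p_x <- tabulate(bx, nbins = bins) / n
  p_y <- tabulate(by, nbins = bins) / n
  joint <- tabulate((by - 1L) * bins + bx, nbins = bins * bins) / n
  p_xy <- matrix(joint, bins, bins)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  h_x <- ent(p_x); h_y <- ent(p_y); h_xy <- ent(joint)
  list(imi = h_x + h_y - h_xy, h_x = h_x, h_y = h_y, h_xy = h_xy,
       bins = bins, p_x = p_x, p_y = p_y, p_xy = p_xy)
}

PAIRINGS <- list(vf = c("visible", "fluorescence"),
                 vi = c("visible", "infrared"),
                 `if` = c("infrared", "fluorescence"))

#' Intermodal phenotype series for one plant
#'
#' For each time point at which both modalities of the pairing are on
#' record, loads the two images, crops each to its plant bounding box
#' (foreground = intensity above `threshold`), aligns them and computes IC
#' and IMI. Time points with only one modality are skipped with a warning;
#' time points where IC is degenerate (constant channel) report `ic = NA`.
#'
#' @param index a `pheno_index` from [scan_dataset()].
#' @param plant_id plant identifier.
#' @param pairing `"vf"` (visible-fluorescence), `"vi"` (visible-infrared)
#'   or `"if"` (infrared-fluorescence).
#' @param threshold foreground threshold for the modality crops.
#' @return data frame, one row per usable time point: `t`, `pairing`, `ic`,
#'   `s_x`, `s_y`, `s_xy`, `imi`, `h_x`, `h_y`, `h_xy`, `n_overlap`.
#' @export
udm_series <- function(index, plant_id, pairing = c("vf", "vi", "if"),
                       threshold = 0) {
  pairing <- match.arg(pairing)
  mods <- PAIRINGS[[pairing]]
  rec <- index[index$plant_id == plant_id & !is.na(index$modality) &
                 index$modality %in% mods, , drop = FALSE]
  t_a <- rec$time_index[rec$modality == mods[1L]]
  t_b <- rec$time_index[rec$modality == mods[2L]]
  common <- sort(intersect(t_a, t_b))
  for (t in sort(setdiff(union(t_a, t_b), common)))
    warning("plant ", plant_id, " t=", t, ": only one of ",
            paste(mods, collapse = "/"), " present; time point skipped",
            call. = FALSE)
  if (!length(common))
    stop("no common time points for plant ", plant_id, ", pairing ", pairing)
  rows <- lapply(common, function(t) {
    pa <- rec$path[rec$modality == mods[1L] & rec$time_index == t]
    pb <- rec$path[rec$modality == mods[2L] & rec$time_index == t]
    a <- modality_crop(load_intensity(pa), threshold = threshold)
    b <- modality_crop(load_intensity(pb), threshold = threshold)
    pr <- prepare_pair(a, b)
    icr <- tryCatch(intermodal_correlation(pr), error = function(e) {
      warning("plant ", plant_id, " t=", t, ": ", conditionMessage(e),
              "; ic reported missing", call. = FALSE)
      list(ic = NA_real_, s_x = sd(pr$x_vals), s_y = sd(pr$y_vals),
           s_xy = stats::cov(pr$x_vals, pr$y_vals))
    })
    mi <- intermodal_mutual_information(pr)
    data.frame(t = t, pairing = pairing, ic = icr$ic, s_x = icr$s_x,
               s_y = icr$s_y, s_xy = icr$s_xy, imi = mi$imi, h_x = mi$h_x,
               h_y = mi$h_y, h_xy = mi$h_xy, n_overlap = pr$n)
  })
  do.call(rbind, rows)
}
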