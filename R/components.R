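#' Label 8-connected components of a binary mask
#'
#' Pixels belong to the same component when they touch by edge or corner
#' (8-connectivity). Component ids are assigned in raster-scan order (row by
#' row, left to right) of each component's first-encountered pixel, so the
#' labeling is deterministic. Centroids are unweighted means of the member
#' pixels' 0-based (row, col) coordinates.
#'
#' @param mask 0/1 matrix.
#' @return a `component_set`: list with `labels` (integer matrix, 0 =
#'   background) and `components` (data frame: `id`, `area_px`,
#'   `centroid_row`, `centroid_col`).
#' @export
#' @examples
#' m <- matrix(0L, 3, 3); m[1, 1] <- 1L; m[2, 2] <- 1L; m[1, 3] <- 1L
#' label_components(m)$components
label_components <- function(mask) {
  mask <- check_mask(mask)
  labels <- cc_label8(mask)
  n <- max(labels)
  if (n == 0L) {
    comp <- data.frame(id = integer(), area_px = integer(),
                       centroid_row = numeric(), centroid_col = numeric())
  } else {
    fg <- which(labels > 0L)
    lab <- labels[fg]
    row0 <- (fg - 1L) %% nrow(mask)       # 0-based row
    col0 <- (fg - 1L) %/% nrow(mask)      # 0-based col
    area <- tabulate(lab, nbins = n)
    comp <- data.frame(
      id = seq_len(n),
      area_px = area,
      centroid_row = as.numeric(rowsum(row0, lab)) / area,
      centroid_col = as.numeric(rowsum(col0, lab)) / area)
  }
  structure(list(labels = labels, components = comp), class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d component(s), %d foreground px\n",
              nrow(x$components), sum(x$components$area_px)))
  invisible(x)
}

#' Mean nearest-neighbour distance between centroids
#'
#' For each centroid, the Euclidean distance to its nearest other centroid;
#' the mean of those distances summarises how dispersed the points are.
#' Ties in the nearest neighbour do not affect the mean (tied distances are
#' equal by definition).
#'
#' @param centroids numeric matrix with one (row, col) coordinate per row.
#' @return mean nearest-neighbour distance, or `NA_real_` with fewer than
#'   two points (a nearest neighbour is then undefined).
#' @export
nn_centroid_dispersion <- function(centroids) {
  centroids <- as.matrix(centroids)
  k <- nrow(centroids)
  if (k < 2L) return(NA_real_)
  d <- as.matrix(stats::dist(centroids))
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}
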