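# Temporal phenotypes from consecutive binary masks: the change masks
# Change+(t) = max(S[t+1] - S[t], 0) and Change-(t) = max(S[t] - S[t+1], 0),
# and descriptors of their 8-connected components.

#' Positive and negative change masks between consecutive frames
#'
#' `change_pos` marks pixels present in `next_mask` but not `prev`
#' (new growth or newly visible material); `change_neg` marks pixels present
#' in `prev` but not `next_mask` (decay or occlusion). Both are computed by
#' the elementwise `max(difference, 0)` rule, so they are disjoint and
#' satisfy `next = (prev \ change_neg) U change_pos`.
#'
#' @param prev,next_mask 0/1 matrices of identical dimensions; the frames at
#'   time t and t+1.
#' @param t optional time index of the earlier frame, carried in the result.
#' @return a `change_pair`: list with `change_pos`, `change_neg` (0/1
#'   matrices) and `t`.
#' @export
#' @examples
#' a <- matrix(0L, 3, 3); a[1, 1] <- a[1, 2] <- a[3, 3] <- 1L
#' b <- matrix(0L, 3, 3); b[1, 2] <- b[2, 2] <- 1L
#' p <- change_masks(a, b)
#' which(p$change_pos == 1L)  # pixel (2,2) appeared
change_masks <- function(prev, next_mask, t = NA_integer_) {
  prev <- check_mask(prev, "prev")
  next_mask <- check_mask(next_mask, "next_mask")
  if (!identical(dim(prev), dim(next_mask)))
    stop("prev and next_mask must share dimensions")
  structure(list(
    change_pos = pmax(next_mask - prev, 0L),
    change_neg = pmax(prev - next_mask, 0L),
    t = t
  ), class = "change_pair")
}

#' Temporal phenotypes of one change pair
#'
#' Computes, for the positive and negative change masks:
#' the changed areas in pixels; `nchange_pos`/`nchange_neg`, the number of
#' 8-connected components; `maxchange_pos`/`maxchange_neg`, the area of the
#' largest component (0 when there is none); and `dispersion_pos`, the mean
#' Euclidean distance from each positive component's centroid to the
#' centroid of its nearest other component. Dispersion is `NA` with fewer
#' than two positive components, where a nearest neighbour is undefined.
#'
#' @param pair a `change_pair` from [change_masks()].
#' @return one-row data frame with columns `t`, `change_pos_area`,
#'   `change_neg_area`, `nchange_pos`, `nchange_neg`, `maxchange_pos`,
#'   `maxchange_neg`, `dispersion_pos`.
#' @export
udt_record <- function(pair) {
  stopifnot(inherits(pair, "change_pair"))
  cp <- label_components(pair$change_pos)$components
  cn <- label_components(pair$change_neg)$components
  data.frame(
    t = pair$t,
    change_pos_area = sum(cp$area_px),
    change_neg_area = sum(cn$area_px),
    nchange_pos = nrow(cp),
    nchange_neg = nrow(cn),
    maxchange_pos = if (nrow(cp)) max(cp$area_px) else 0L,
    maxchange_neg = if (nrow(cn)) max(cn$area_px) else 0L,
    dispersion_pos = nn_centroid_dispersion(
      cbind(cp$centroid_row, cp$centroid_col))
  )
}

#' Projected area of a plant silhouette
#'
#' @param mask 0/1 matrix.
#' @return foreground pixel count.
#' @export
projected_area <- function(mask) {
  mask <- check_mask(mask)
  sum(mask)
}

#' Temporal phenotype series for a mask sequence
#'
#' Applies [change_masks()] and [udt_record()] to every consecutive frame
#' pair of the sequence. With n frames the result has n - 1 rows (none for a
#' single frame). Projected areas of the earlier and later frame accompany
#' each record.
#'
#' @param seq a `mask_sequence` from [mask_sequence()], or a plain list of
#'   0/1 matrices (time order, shared dimensions).
#' @return data frame, one row per consecutive pair: the [udt_record()]
#'   columns plus `area_t` and `area_t1`.
#' @export
udt_series <- function(seq) {
  if (inherits(seq, "mask_sequence")) {
    masks <- seq$masks
    times <- seq$time_index
  } else {
    masks <- seq
    times <- seq_along(masks) - 1L
  }
  n <- length(masks)
  if (n == 0L) stop("empty mask sequence")
  if (n == 1L) {
    out <- udt_record(change_masks(masks[[1L]], masks[[1L]]))[0L, ]
    out$area_t <- integer(); out$area_t1 <- integer()
    return(out)
  }
  areas <- vapply(masks, projected_area, integer(1L))
  rows <- lapply(seq_len(n - 1L), function(i) {
    rec <- udt_record(change_masks(masks[[i]], masks[[i + 1L]], t = times[i]))
    rec$area_t <- areas[i]
    rec$area_t1 <- areas[i + 1L]
    rec
  })
  do.call(rbind, rows)
}
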