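# Perspective phenotypes: silhouette extents per view and the true aspect
# ratios TARmax = Wmax / h, TARmin = Wmin / h, TWR = Wmin / Wmax across
# same-time side views.

#' Tight bounding-box extents of a silhouette
#'
#' @param mask 0/1 matrix with at least one foreground pixel.
#' @return list with `h` (max foreground row - min + 1), `w` (same for
#'   columns), and the 0-based `row_range`, `col_range`.
#' @export
bounding_extent <- function(mask) {
  mask <- check_mask(mask)
  fg <- which(mask == 1L)
  if (!length(fg)) stop("empty silhouette: mask has no foreground pixels")
  r <- range((fg - 1L) %% nrow(mask))
  cl <- range((fg - 1L) %/% nrow(mask))
  list(h = r[2L] - r[1L] + 1L, w = cl[2L] - cl[1L] + 1L,
       row_range = r, col_range = cl)
}

#' True aspect ratios from multi-view silhouette extents
#'
#' Across n >= 2 same-time views with widths w_i and heights h_i, computes
#' TARmax = Wmax / h, TARmin = Wmin / h and TWR = Wmin / Wmax, where
#' Wmax/Wmin are the extreme widths over views. Side views of one plant
#' share their height in principle; in practice silhouettes deviate
#' slightly, so h is taken as the maximum height over views (the
#' least-occluded estimate, which reduces to the shared height when heights
#' agree) and the observed height spread is reported as a diagnostic.
#'
#' @param views data frame with one row per view and columns `h`, `w`
#'   (pixels); a `view_deg` column is carried through if present.
#' @return list with `h`, `w_min`, `w_max`, `tar_max`, `tar_min`, `twr`,
#'   and `h_spread` (max - min view height).
#' @export
#' @examples
#' v <- data.frame(view_deg = c(0, 72, 144, 216),
#'                 h = 40, w = c(10, 20, 16, 8))
#' true_aspect_ratios(v)
true_aspect_ratios <- function(views) {
  stopifnot(is.data.frame(views), all(c("h", "w") %in% names(views)))
  if (nrow(views) < 2L)
    stop("insufficient views: true aspect ratios need at least 2 views")
  if (any(views$h < 1) || any(views$w < 1))
    stop("views must have h >= 1 and w >= 1")
  h <- max(views$h)
  w_min <- min(views$w)
  w_max <- max(views$w)
  list(h = h, w_min = w_min, w_max = w_max,
       tar_max = w_max / h, tar_min = w_min / h, twr = w_min / w_max,
       h_spread = max(views$h) - min(views$h))
}

#' Single-view aspect ratio of a silhouette
#'
#' Height over width of the tight bounding box. The height-over-width
#' orientation makes vertically dominant plants (e.g. sunflower during
#' elongation) exceed 1.
#'
#' @param mask 0/1 matrix with at least one foreground pixel.
#' @return h / w, dimensionless.
#' @export
aspect_ratio <- function(mask) {
  e <- bounding_extent(mask)
  e$h / e$w
}

#' Perspective phenotype series for one plant
#'
#' For every time point at which the plant has at least two views on
#' record, loads the view silhouettes, measures their extents and computes
#' the true aspect ratios. Time points with an empty silhouette in any view
#' or with fewer than two views are skipped with a warning.
#'
#' @param index a `pheno_index` from [scan_dataset()].
#' @param plant_id plant identifier.
#' @param foreground_threshold passed to [load_mask()].
#' @return list with `ratios` (data frame: `t`, `h`, `w_min`, `w_max`,
#'   `tar_min`, `tar_max`, `twr`, `h_spread`, `n_views`) and `extents`
#'   (long data frame: `t`, `view_deg`, `h_i`, `w_i`).
#' @export
udp_series <- function(index, plant_id, foreground_threshold = 0) {
  rec <- index[index$plant_id == plant_id & !is.na(index$view_deg), , drop = FALSE]
  if (!nrow(rec)) stop("no view records for plant ", plant_id)
  ext_rows <- list(); ratio_rows <- list()
  for (t in sort(unique(rec$time_index))) {
    rt <- rec[rec$time_index == t, , drop = FALSE]
    ext <- tryCatch(
      do.call(rbind, lapply(seq_len(nrow(rt)), function(i) {
        e <- bounding_extent(load_mask(rt$path[i], foreground_threshold))
        data.frame(t = t, view_deg = rt$view_deg[i], h_i = e$h, w_i = e$w)
      })),
      error = function(e) {
        warning("plant ", plant_id, " t=", t, ": ", conditionMessage(e),
                "; time point skipped", call. = FALSE)
        NULL
      })
    if (is.null(ext)) next
    if (nrow(ext) < 2L) {
      warning("plant ", plant_id, " t=", t,
              ": fewer than 2 views; time point skipped", call. = FALSE)
      next
    }
    ratios <- true_aspect_ratios(data.frame(h = ext$h_i, w = ext$w_i))
    ext_rows[[length(ext_rows) + 1L]] <- ext
    ratio_rows[[length(ratio_rows) + 1L]] <- data.frame(
      t = t, h = ratios$h, w_min = ratios$w_min, w_max = ratios$w_max,
      tar_min = ratios$tar_min, tar_max = ratios$tar_max, twr = ratios$twr,
      h_spread = ratios$h_spread, n_views = nrow(ext))
  }
  list(
    ratios = if (length(ratio_rows)) do.call(rbind, ratio_rows) else
      data.frame(t = integer(), h = integer(), w_min = integer(),
                 w_max = integer(), tar_min = numeric(), tar_max = numeric(),
                 twr = numeric(), h_spread = integer(), n_views = integer()),
    extents = if (length(ext_rows)) do.call(rbind, ext_rows) else
      data.frame(t = integer(), view_deg = integer(), h_i = integer(),
                 w_i = integer())
  )
}
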