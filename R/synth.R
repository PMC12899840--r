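# Synthetic concurrent-imaging scenes with planted ground truth.
# Planted components keep a >= 2-pixel Chebyshev gap from everything else,
# so 8-connectivity can never merge them and component counts, areas and
# centroids are recovered exactly by the pipeline.

#' Parameters of a synthetic scene
#'
#' Bundles the knobs of the generators. Events can be prescribed exactly
#' via schedules (for planted-truth tests) or drawn from ranges under the
#' scene seed (for cohorts).
#'
#' @param image_shape (rows, cols) of every frame.
#' @param n_timepoints number of frames in a temporal scene.
#' @param base_area pixel area of the static central blob present in every
#'   frame (a stand-in for the established plant body).
#' @param growth_schedule `NULL`, or a list with one element per frame pair:
#'   a data frame with columns `area` (px) and optionally `shape`
#'   (`"disk"`/`"rect"`), `row`, `col` (0-based anchor; `NA` = random
#'   placement). When `NULL`, event counts and areas are drawn from the
#'   ranges below.
#' @param decay_schedule `NULL`, or an integer vector (one entry per frame
#'   pair) of how many previously planted components to remove.
#' @param growth_count_range,growth_area_range integer ranges used when
#'   `growth_schedule` is `NULL`.
#' @param decay_count_range integer range used when `decay_schedule` is
#'   `NULL` (capped at the number of removable components).
#' @param view_widths per-view silhouette widths (px): a vector (one time
#'   point) or a matrix with one row per time point.
#' @param shared_height silhouette height (px): scalar or one value per
#'   time point.
#' @param rho_target latent correlation planted between the two modality
#'   channels, in \[-1, 1\].
#' @param noise_sd standard deviation of extra independent latent noise
#'   added to the second channel (attenuates the planted correlation;
#'   default 0).
#' @param fg_area foreground pixel count of the modality-pair mask.
#' @param seed RNG seed; identical parameters give bit-identical scenes.
#' @return a `scene_params` list.
#' @export
scene_params <- function(image_shape = c(80L, 80L),
                         n_timepoints = 8L,
                         base_area = 120L,
                         growth_schedule = NULL,
                         decay_schedule = NULL,
                         growth_count_range = c(1L, 4L),
                         growth_area_range = c(15L, 45L),
                         decay_count_range = c(0L, 2L),
                         view_widths = c(10L, 20L, 16L, 8L),
                         shared_height = 40L,
                         rho_target = 0.8,
                         noise_sd = 0,
                         fg_area = 2500L,
                         seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 8L),
            n_timepoints >= 1L, abs(rho_target) <= 1, noise_sd >= 0)
  structure(list(image_shape = as.integer(image_shape),
                 n_timepoints = as.integer(n_timepoints),
                 base_area = as.integer(base_area),
                 growth_schedule = growth_schedule,
                 decay_schedule = decay_schedule,
                 growth_count_range = as.integer(growth_count_range),
                 growth_area_range = as.integer(growth_area_range),
                 decay_count_range = as.integer(decay_count_range),
                 view_widths = view_widths,
                 shared_height = shared_height,
                 rho_target = rho_target,
                 noise_sd = noise_sd,
                 fg_area = as.integer(fg_area),
                 seed = as.integer(seed)),
            class = "scene_params")
}

# deterministic connected pixel blob of exactly `area` px:
# disk = nearest `area` offsets to the origin; rect = raster fill of a
# near-square box. Offsets are 0-based (row, col) relative to the anchor.
shape_offsets <- function(area, shape = "disk") {
  stopifnot(area >= 1L)
  if (shape == "rect") {
    a <- max(1L, floor(sqrt(area)))
    b <- ceiling(area / a)
    g <- expand.grid(col = 0:(b - 1L), row = 0:(a - 1L))
    g <- g[order(g$row, g$col), ]
    return(as.matrix(g[seq_len(area), c("row", "col")]))
  }
  r <- ceiling(sqrt(area / pi)) + 2L
  g <- expand.grid(row = -r:r, col = -r:r)
  d2 <- g$row^2 + g$col^2
  g <- g[order(d2, g$row, g$col), ]
  off <- as.matrix(g[seq_len(area), c("row", "col")])
  off[, 1L] <- off[, 1L] - min(off[, 1L])
  off[, 2L] <- off[, 2L] - min(off[, 2L])
  off
}

# mark a pixel set and its Chebyshev-2 neighbourhood in a logical matrix
mark_dilated <- function(occ, px) {
  nr <- nrow(occ); nc <- ncol(occ)
  for (dr in -2:2) for (dc in -2:2) {
    r <- px[, 1L] + dr; c <- px[, 2L] + dc
    keep <- r >= 1L & r <= nr & c >= 1L & c <= nc
    occ[cbind(r[keep], c[keep])] <- TRUE
  }
  occ
}

place_component <- function(occ_dil, off, anchor = NULL, max_tries = 500L) {
  nr <- nrow(occ_dil); nc <- ncol(occ_dil)
  hr <- max(off[, 1L]); hc <- max(off[, 2L])
  if (hr + 1L > nr || hc + 1L > nc)
    stop("placement error: component does not fit inside the frame")
  if (!is.null(anchor)) {
    px <- cbind(off[, 1L] + anchor[1L] + 1L, off[, 2L] + anchor[2L] + 1L)
    if (any(px[, 1L] > nr) || any(px[, 2L] > nc))
      stop("placement error: anchored component exceeds the frame")
    if (any(occ_dil[px])) stop("placement error: anchored component too close ",
                               "to existing material")
    return(px)
  }
  for (i in seq_len(max_tries)) {
    r0 <- sample.int(nr - hr, 1L)
    c0 <- sample.int(nc - hc, 1L)
    px <- cbind(off[, 1L] + r0, off[, 2L] + c0)
    if (!any(occ_dil[px])) return(px)
  }
  stop("placement error: no free location found after ", max_tries, " tries")
}

px_centroid <- function(px) c(mean(px[, 1L]) - 1, mean(px[, 2L]) - 1) # 0-based

#' Generate a temporal mask sequence with planted change events
#'
#' Frame 1 holds a static central blob. Between consecutive frames, decay
#' events remove previously planted components in full and growth events add
#' new ones, every component keeping a >= 2-pixel Chebyshev gap from all
#' other material, so each frame pair's change masks decompose into exactly
#' the planted components. The returned log records the exact truth per
#' pair, including Dispersion+ computed from the planted pixel centroids.
#'
#' @param params a [scene_params()] object.
#' @return list with `masks` (list of 0/1 matrices), `truth` (data frame:
#'   `t`, `nchange_pos`, `nchange_neg`, `maxchange_pos`, `maxchange_neg`,
#'   `change_pos_area`, `change_neg_area`, `dispersion_pos`) and `events`
#'   (list per pair of planted areas and centroids).
#' @export
generate_temporal_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(params$seed)
  nr <- params$image_shape[1L]; nc <- params$image_shape[2L]
  n <- params$n_timepoints
  S <- matrix(0L, nr, nc)
  base_off <- shape_offsets(params$base_area, "disk")
  anchor <- c((nr - max(base_off[, 1L])) %/% 2L,
              (nc - max(base_off[, 2L])) %/% 2L) - 1L
  base_px <- place_component(matrix(FALSE, nr, nc), base_off, anchor = anchor)
  S[base_px] <- 1L
  planted <- list()   # removable components currently in the scene
  masks <- vector("list", n)
  masks[[1L]] <- S
  truth <- list(); events <- list()
  if (n >= 2L) for (step in seq_len(n - 1L)) {
    # decay: remove whole planted components
    n_dec <- if (!is.null(params$decay_schedule)) params$decay_schedule[step]
             else sample(params$decay_count_range[1L]:params$decay_count_range[2L], 1L)
    n_dec <- min(n_dec, length(planted))
    removed <- list()
    if (n_dec > 0L) {
      pick <- sample.int(length(planted), n_dec)
      removed <- planted[pick]
      for (cmp in removed) S[cmp$px] <- 0L
      planted <- planted[-pick]
    }
    # growth: occupancy freezes the pre-decay scene plus this step's events,
    # so new components can never reuse just-freed pixels (which would
    # corrupt the planted change masks)
    occ_dil <- matrix(FALSE, nr, nc)
    occ_dil <- mark_dilated(occ_dil, which(S == 1L, arr.ind = TRUE))
    for (cmp in removed) occ_dil <- mark_dilated(occ_dil, cmp$px)
    if (!is.null(params$growth_schedule)) {
      ev <- params$growth_schedule[[step]]
      areas <- ev$area
      shapes <- if ("shape" %in% names(ev)) ev$shape else rep("disk", nrow(ev))
      anchors <- if (all(c("row", "col") %in% names(ev)))
        lapply(seq_len(nrow(ev)), function(i)
          if (is.na(ev$row[i])) NULL else c(ev$row[i], ev$col[i]))
        else rep(list(NULL), nrow(ev))
    } else {
      k <- sample(params$growth_count_range[1L]:params$growth_count_range[2L], 1L)
      areas <- if (k > 0L)
        sample(params$growth_area_range[1L]:params$growth_area_range[2L], k,
               replace = TRUE) else integer()
      shapes <- rep("disk", length(areas))
      anchors <- rep(list(NULL), length(areas))
    }
    added <- list()
    for (i in seq_along(areas)) {
      off <- shape_offsets(areas[i], shapes[i])
      px <- place_component(occ_dil, off, anchor = anchors[[i]])
      S[px] <- 1L
      occ_dil <- mark_dilated(occ_dil, px)
      added[[i]] <- list(px = px, area = nrow(px), centroid = px_centroid(px))
    }
    planted <- c(planted, added)
    masks[[step + 1L]] <- S
    g_areas <- vapply(added, `[[`, numeric(1L), "area")
    d_areas <- vapply(removed, `[[`, numeric(1L), "area")
    cent <- do.call(rbind, lapply(added, `[[`, "centroid"))
    truth[[step]] <- data.frame(
      t = step - 1L,
      nchange_pos = length(added), nchange_neg = length(removed),
      maxchange_pos = if (length(g_areas)) max(g_areas) else 0,
      maxchange_neg = if (length(d_areas)) max(d_areas) else 0,
      change_pos_area = sum(g_areas), change_neg_area = sum(d_areas),
      dispersion_pos = if (length(added) >= 2L) nn_centroid_dispersion(cent)
                       else NA_real_)
    events[[step]] <- list(growth_areas = g_areas, decay_areas = d_areas,
                           growth_centroids = cent)
  }
  list(masks = masks,
       truth = if (length(truth)) do.call(rbind, truth) else NULL,
       events = events)
}

#' Generate multi-view silhouettes with exact extents
#'
#' Renders each view as a solid rectangle of the prescribed width and the
#' shared height, so tight bounding boxes recover the planted (h, w_i)
#' exactly and the downstream true aspect ratios are known in closed form.
#'
#' @param params a [scene_params()] object; `view_widths` may be a vector
#'   (one time point) or a matrix with one row per time point, and
#'   `shared_height` a scalar or per-time vector.
#' @return list with `masks` (list over time of lists over views) and
#'   `truth` (data frame: `t`, `view`, `w`, `h`).
#' @export
generate_view_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  nr <- params$image_shape[1L]; nc <- params$image_shape[2L]
  W <- params$view_widths
  if (is.vector(W)) W <- matrix(W, nrow = 1L)
  H <- rep_len(params$shared_height, nrow(W))
  if (any(W > nc) || any(H > nr))
    stop("placement error: silhouette exceeds the frame")
  masks <- vector("list", nrow(W)); truth <- list()
  for (t in seq_len(nrow(W))) {
    masks[[t]] <- lapply(seq_len(ncol(W)), function(v) {
      m <- matrix(0L, nr, nc)
      r0 <- (nr - H[t]) %/% 2L; c0 <- (nc - W[t, v]) %/% 2L
      m[(r0 + 1L):(r0 + H[t]), (c0 + 1L):(c0 + W[t, v])] <- 1L
      m
    })
    truth[[t]] <- data.frame(t = t - 1L, view = seq_len(ncol(W)),
                             w = W[t, ], h = H[t])
  }
  list(masks = masks, truth = do.call(rbind, truth))
}

#' Generate a coupled modality image pair
#'
#' Over a shared disk foreground, draws latent standard bivariate normal
#' pairs with correlation `rho_target` (plus optional independent noise on
#' the second channel) and maps each channel through the normal CDF onto the
#' intensity range \[1, 255\]; background is 0. With `rho_target = 1` and no
#' noise the two channels are identical, so downstream IC is exactly 1.
#'
#' @param params a [scene_params()] object (`fg_area`, `rho_target`,
#'   `noise_sd`, `image_shape`, `seed`).
#' @return list with `x_img`, `y_img` (matrices in \[0, 255\]), `fg`
#'   (0/1 matrix) and `rho_target`.
#' @export
generate_modality_pair <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(params$seed)
  nr <- params$image_shape[1L]; nc <- params$image_shape[2L]
  off <- shape_offsets(params$fg_area, "disk")
  if (max(off[, 1L]) + 1L > nr || max(off[, 2L]) + 1L > nc)
    stop("placement error: foreground disk exceeds the frame")
  anchor <- c((nr - max(off[, 1L])) %/% 2L, (nc - max(off[, 2L])) %/% 2L) - 1L
  px <- cbind(off[, 1L] + anchor[1L] + 1L, off[, 2L] + anchor[2L] + 1L)
  n <- nrow(px)
  rho <- params$rho_target
  z1 <- stats::rnorm(n)
  z2 <- if (abs(rho) == 1 && params$noise_sd == 0) sign(rho) * z1
        else rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  if (params$noise_sd > 0) z2 <- z2 + stats::rnorm(n, 0, params$noise_sd)
  to_intensity <- function(z) pmin(255, 1 + floor(stats::pnorm(z) * 255))
  x_img <- matrix(0, nr, nc); y_img <- matrix(0, nr, nc)
  x_img[px] <- to_intensity(z1)
  y_img[px] <- if (rho == -1 && params$noise_sd == 0)
    256 - x_img[px] else to_intensity(z2)
  fg <- matrix(0L, nr, nc); fg[px] <- 1L
  list(x_img = x_img, y_img = y_img, fg = fg, rho_target = rho)
}

# deterministic per-plant seed: polynomial rolling hash of the label,
# folded with the cohort seed, kept below 2^31
stable_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Generate a synthetic cohort on disk
#'
#' Writes a full dataset tree (`<species>/<treatment>/<plant>/deg000/<t>.png`)
#' plus a manifest CSV, with independent temporal scenes per plant (seeds
#' derived by stable hashing of the plant label, so plants are independent
#' replicates). Drought plants receive a planted suppression of their
#' growth-event areas; `suppression = 1` plants no treatment effect.
#'
#' @param out_dir output directory (created if needed).
#' @param n_per_treatment plants per treatment (>= 2).
#' @param suppression multiplier in (0, 1\] applied to drought growth-event
#'   areas.
#' @param params a [scene_params()] object giving the per-plant scene
#'   conditions; `params$seed` seeds the whole cohort.
#' @param species species label used in the tree.
#' @return list with `root`, `manifest` (paths) and `truth` (per-plant list
#'   of planted-event logs), invisibly.
#' @export
generate_cohort <- function(out_dir, n_per_treatment = 8L, suppression = 1,
                            params = scene_params(), species = "sunflower") {
  stopifnot(n_per_treatment >= 2L, suppression > 0, suppression <= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); truths <- list()
  for (treatment in c("control", "drought")) {
    fac <- if (treatment == "drought") suppression else 1
    for (p in seq_len(n_per_treatment)) {
      plant_id <- sprintf("%s%02d", substr(treatment, 1L, 1L), p)
      pp <- params
      pp$seed <- stable_seed(params$seed, paste(species, treatment, plant_id))
      if (fac < 1) {
        pp$growth_area_range <- pmax(1L, as.integer(round(pp$growth_area_range * fac)))
        pp$base_area <- max(4L, as.integer(round(pp$base_area * fac)))
      }
      scene <- generate_temporal_scene(pp)
      pdir <- file.path(out_dir, species, treatment, plant_id, "deg000")
      dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
      for (t in seq_along(scene$masks)) {
        rel <- file.path(species, treatment, plant_id, "deg000",
                         sprintf("%d.png", t - 1L))
        write_mask(scene$masks[[t]], file.path(out_dir, rel))
        rows[[length(rows) + 1L]] <- data.frame(
          species = species, treatment = treatment, plant_id = plant_id,
          time_index = t - 1L, date = NA_character_, view_deg = 0L,
          modality = NA_character_, relpath = rel)
      }
      truths[[paste(treatment, plant_id)]] <- scene$truth
    }
  }
  manifest <- file.path(out_dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE, na = "")
  invisible(list(root = out_dir, manifest = manifest, truth = truths))
}
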