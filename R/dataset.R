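# Dataset index: one row per observation, keyed by
# (species, treatment, plant_id, time_index, view_deg | modality).

MANIFEST_COLS <- c("species", "treatment", "plant_id", "time_index",
                   "date", "view_deg", "modality", "relpath")

AXIS_LABELS <- c(deg000 = "0", deg072 = "72", deg144 = "144", deg216 = "216",
                 vis = "visible", ir = "infrared", fluo = "fluorescence")

key_string <- function(idx) {
  paste(idx$species, idx$treatment, idx$plant_id, idx$time_index,
        ifelse(is.na(idx$view_deg), "-", idx$view_deg),
        ifelse(is.na(idx$modality), "-", idx$modality), sep = "/")
}

#' Index a dataset of plant images
#'
#' Builds a validated index of mask/modality images, either from a manifest
#' CSV (columns `species, treatment, plant_id, time_index, date, view_deg,
#' modality, relpath`; `relpath` relative to `root`) or, when no manifest is
#' given, from the directory convention
#' `root/<species>/<treatment>/<plant_id>/<axis>/<time_index>.png` with
#' `axis` one of `deg000, deg072, deg144, deg216` (views) or
#' `vis, ir, fluo` (modalities).
#'
#' @param root dataset root directory.
#' @param manifest optional path to a manifest CSV.
#' @return a `pheno_index`: data frame with the manifest columns plus `path`
#'   (absolute path), sorted by key; attribute `root`.
#' @export
scan_dataset <- function(root, manifest = NULL) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  if (!is.null(manifest)) {
    mf <- read.csv(manifest, stringsAsFactors = FALSE,
                   colClasses = c(plant_id = "character"))
    missing_cols <- setdiff(MANIFEST_COLS, names(mf))
    if (length(missing_cols))
      stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
    idx <- mf[MANIFEST_COLS]
    idx$view_deg <- suppressWarnings(as.integer(idx$view_deg))
    idx$modality <- ifelse(is.na(idx$modality) | idx$modality == "",
                           NA_character_, idx$modality)
  } else {
    files <- list.files(root, pattern = "\\.png$", recursive = TRUE)
    if (!length(files)) {
      idx <- data.frame(species = character(), treatment = character(),
                        plant_id = character(), time_index = integer(),
                        date = character(), view_deg = integer(),
                        modality = character(), relpath = character(),
                        stringsAsFactors = FALSE)
    } else {
      parts <- strsplit(files, "/", fixed = TRUE)
      ok <- lengths(parts) == 5L
      if (any(!ok))
        stop("paths not matching <species>/<treatment>/<plant>/<axis>/<t>.png: ",
             paste(utils::head(files[!ok], 3L), collapse = ", "))
      parts <- do.call(rbind, parts)
      axis <- parts[, 4L]
      bad_axis <- !axis %in% names(AXIS_LABELS)
      if (any(bad_axis))
        stop("unknown axis label(s): ", paste(unique(axis[bad_axis]), collapse = ", "))
      axis_val <- AXIS_LABELS[axis]
      is_view <- startsWith(axis, "deg")
      idx <- data.frame(
        species = parts[, 1L], treatment = parts[, 2L],
        plant_id = parts[, 3L],
        time_index = as.integer(sub("\\.png$", "", parts[, 5L])),
        date = NA_character_,
        view_deg = ifelse(is_view, as.integer(axis_val), NA_integer_),
        modality = ifelse(is_view, NA_character_, axis_val),
        relpath = files, stringsAsFactors = FALSE)
    }
  }
  idx$path <- file.path(root, idx$relpath)
  if (nrow(idx)) {
    ks <- key_string(idx)
    dup <- duplicated(ks)
    if (any(dup))
      stop("duplicate observation keys in index: ",
           paste(unique(ks[dup]), collapse = "; "))
    gone <- !file.exists(idx$path)
    if (any(gone))
      stop("manifest references missing files: ",
           paste(utils::head(idx$relpath[gone], 5L), collapse = ", "))
    idx <- idx[order(ks), , drop = FALSE]
    rownames(idx) <- NULL
  }
  structure(idx, root = normalizePath(root), class = c("pheno_index", "data.frame"))
}

#' @export
print.pheno_index <- function(x, ...) {
  cat(sprintf("<pheno_index> %d records under %s\n", nrow(x), attr(x, "root")))
  if (nrow(x)) {
    cat(sprintf("  species: %s | treatments: %s | plants: %d | times: %d\n",
                paste(unique(x$species), collapse = ","),
                paste(unique(x$treatment), collapse = ","),
                length(unique(x$plant_id)),
                length(unique(x$time_index))))
    nv <- sum(!is.na(x$view_deg)); nm <- sum(!is.na(x$modality))
    cat(sprintf("  view records: %d | modality records: %d\n", nv, nm))
  }
  invisible(x)
}

#' Extract a time-ordered mask sequence for one plant and view
#'
#' @param index a `pheno_index` from [scan_dataset()].
#' @param plant_id plant identifier.
#' @param view_deg view angle in degrees (0, 72, 144 or 216); `NULL` matches
#'   records without a view axis.
#' @param foreground_threshold passed to [load_mask()].
#' @return a `mask_sequence`: list with `masks` (list of 0/1 matrices, time
#'   order), `time_index`, and `key` (species/treatment/plant/view).
#' @export
mask_sequence <- function(index, plant_id, view_deg = 0,
                          foreground_threshold = 0) {
  sel <- index$plant_id == plant_id &
    (if (is.null(view_deg)) is.na(index$view_deg)
     else !is.na(index$view_deg) & index$view_deg == view_deg)
  rec <- index[sel, , drop = FALSE]
  if (!nrow(rec))
    stop("no records for plant ", plant_id, ", view ",
         if (is.null(view_deg)) "<none>" else view_deg)
  rec <- rec[order(rec$time_index), , drop = FALSE]
  if (anyDuplicated(rec$time_index))
    stop("duplicate time indices for plant ", plant_id,
         "; plant ids must be unique within a view")
  masks <- lapply(rec$path, load_mask, foreground_threshold = foreground_threshold)
  dims <- vapply(masks, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("masks in sequence for plant ", plant_id,
         " have mismatched dimensions; refusing to pad or resize")
  structure(list(
    masks = masks,
    time_index = rec$time_index,
    key = list(species = rec$species[1L], treatment = rec$treatment[1L],
               plant_id = plant_id, view_deg = view_deg)
  ), class = "mask_sequence")
}

#' @export
print.mask_sequence <- function(x, ...) {
  d <- dim(x$masks[[1L]])
  cat(sprintf("<mask_sequence> plant %s, view %s: %d frames of %dx%d\n",
              x$key$plant_id,
              if (is.null(x$key$view_deg)) "<none>" else x$key$view_deg,
              length(x$masks), d[1L], d[2L]))
  invisible(x)
}
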