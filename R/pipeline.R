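# Orchestration: dataset -> phenotype tables -> comparison CSVs.

UDT_PHENOTYPES <- c("change_pos_area", "change_neg_area", "nchange_pos",
                    "nchange_neg", "maxchange_pos", "maxchange_neg",
                    "dispersion_pos")

# CSVs are written with a fixed numeric format so identical runs are
# byte-identical.
format_num <- function(x) {
  out <- ifelse(is.na(x), "", sprintf("%.12g", x))
  out
}

write_csv12 <- function(df, path) {
  for (nm in names(df)) if (is.numeric(df[[nm]])) df[[nm]] <- format_num(df[[nm]])
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Run configuration for the phenotype pipeline
#'
#' @param root dataset root directory.
#' @param manifest optional manifest CSV path.
#' @param families phenotype families to compute, subset of
#'   `c("udt", "udp", "udm")`.
#' @param view view angle feeding the temporal phenotypes (default 0).
#' @param pairings modality pairings for the intermodal phenotypes.
#' @param compare whether to run the treatment comparison on the temporal
#'   table.
#' @param out_dir output directory for the CSV reports.
#' @return a `run_config` list.
#' @export
run_config <- function(root, manifest = NULL,
                       families = c("udt", "udp", "udm"),
                       view = 0L, pairings = c("vf", "vi", "if"),
                       compare = TRUE, out_dir = ".") {
  families <- match.arg(families, several.ok = TRUE)
  if (!length(families)) stop("at least one phenotype family must be selected")
  structure(list(root = root, manifest = manifest, families = families,
                 view = as.integer(view), pairings = pairings,
                 compare = isTRUE(compare), out_dir = out_dir),
            class = "run_config")
}

#' Run the phenotype pipeline over a dataset
#'
#' Scans the dataset, computes the selected phenotype families for every
#' plant, and writes tidy CSVs to the output directory: `udt.csv` (one row
#' per plant/view/time pair, with projected areas), `udp.csv` +
#' `udp_views.csv` (ratios and per-view extents), `udm.csv` (IC/IMI per
#' plant, time and pairing), and `compare_udt.csv` (Welch comparison of the
#' temporal phenotypes between treatments within species). Numeric cells
#' use a fixed `%.12g` format, so repeated runs on the same data are
#' byte-identical. Plants that cannot be processed are reported as warnings
#' naming the plant, never silent.
#'
#' @param config a [run_config()] object.
#' @return list of written file paths and per-stage record counts,
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  index <- scan_dataset(config$root, config$manifest)
  if (!nrow(index)) stop("no records: dataset index is empty")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- list(); counts <- list(records = nrow(index))
  meta_of <- function(pid) {
    r <- index[index$plant_id == pid, , drop = FALSE][1L, ]
    data.frame(species = r$species, treatment = r$treatment, plant_id = pid)
  }
  plants <- sort(unique(index$plant_id))

  if ("udt" %in% config$families) {
    rows <- list(); failed <- character()
    for (pid in plants) {
      res <- tryCatch({
        seq <- mask_sequence(index, pid, view_deg = config$view)
        cbind(meta_of(pid), view_deg = config$view, udt_series(seq))
      }, error = function(e) {
        warning("udt: plant ", pid, ": ", conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(res)) failed <- c(failed, pid) else
        rows[[length(rows) + 1L]] <- res
    }
    if (!length(rows)) stop("udt: no plant produced a temporal series")
    udt <- do.call(rbind, rows)
    f <- file.path(config$out_dir, "udt.csv")
    write_csv12(udt, f)
    written$udt <- f; counts$udt_rows <- nrow(udt)
    if (config$compare) {
      cmp <- compare_treatments(udt, UDT_PHENOTYPES)
      f <- file.path(config$out_dir, "compare_udt.csv")
      write_csv12(cmp, f)
      written$compare_udt <- f; counts$compare_rows <- nrow(cmp)
    }
  }

  if ("udp" %in% config$families) {
    rts <- list(); exts <- list()
    for (pid in plants) {
      res <- tryCatch(udp_series(index, pid), error = function(e) {
        warning("udp: plant ", pid, ": ", conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(res) || !nrow(res$ratios)) next
      rts[[length(rts) + 1L]] <- cbind(meta_of(pid), res$ratios)
      exts[[length(exts) + 1L]] <- cbind(meta_of(pid), res$extents)
    }
    if (length(rts)) {
      f1 <- file.path(config$out_dir, "udp.csv")
      f2 <- file.path(config$out_dir, "udp_views.csv")
      write_csv12(do.call(rbind, rts), f1)
      write_csv12(do.call(rbind, exts), f2)
      written$udp <- f1; written$udp_views <- f2
      counts$udp_rows <- sum(vapply(rts, nrow, integer(1L)))
    }
  }

  if ("udm" %in% config$families) {
    rows <- list()
    for (pid in plants) for (pg in config$pairings) {
      res <- tryCatch(cbind(meta_of(pid), udm_series(index, pid, pg)),
                      error = function(e) {
                        warning("udm: plant ", pid, " pairing ", pg, ": ",
                                conditionMessage(e), call. = FALSE)
                        NULL
                      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
    if (length(rows)) {
      udm <- do.call(rbind, rows)
      f <- file.path(config$out_dir, "udm.csv")
      write_csv12(udm, f)
      written$udm <- f; counts$udm_rows <- nrow(udm)
    }
  }

  invisible(list(written = written, counts = counts))
}

#' Change-overlay visualization of a frame pair
#'
#' Renders the later silhouette in gray with newly appeared pixels
#' (Change+) in green and disappeared pixels (Change-) in red; optionally
#' writes the RGB raster to a PNG.
#'
#' @param prev,next_mask 0/1 matrices of identical dimensions.
#' @param path optional output PNG path.
#' @return RGB array (rows x cols x 3, values in \[0, 1\]), invisibly when
#'   `path` is given.
#' @export
change_overlay <- function(prev, next_mask, path = NULL) {
  pair <- change_masks(prev, next_mask)
  keep <- prev * next_mask
  rgb <- array(0, c(nrow(prev), ncol(prev), 3L))
  for (k in 1:3) rgb[, , k] <- keep * 0.6
  rgb[, , 2L] <- rgb[, , 2L] + pair$change_pos          # green: growth
  rgb[, , 1L] <- rgb[, , 1L] + pair$change_neg          # red: decay
  rgb <- pmin(rgb, 1)
  if (!is.null(path)) {
    png::writePNG(rgb, path)
    return(invisible(rgb))
  }
  rgb
}
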