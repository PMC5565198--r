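## -------------------------------------------------------------------------
## File round-tripping: scenes/annotations (PNG/TIFF), maps, trial tables,
## insertion CSVs, epoch containers.
## -------------------------------------------------------------------------

#' Read a grayscale scene image
#'
#' 8/16-bit grayscale PNG or TIFF; pixel values in [0, 1] are mapped
#' linearly onto the luminance range of the geometry.
#'
#' @param path file path (.png or .tif/.tiff).
#' @param geometry optional [scene_geometry]; derived from the image if
#'   NULL.
#' @param normalize passed to [gray_image()].
#' @return a [gray_image].
#' @export
read_scene_image <- function(path, geometry = NULL, normalize = TRUE) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                sp_input_error(sprintf("unsupported image format: %s", ext)))
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (is.null(geometry)) geometry <- scene_geometry(nrow(img), ncol(img))
  lum <- geometry$lum_range[1] + img * diff(geometry$lum_range)
  gray_image(lum, geometry, normalize = normalize)
}

#' Write a scene image
#'
#' Luminance is mapped linearly from the geometry's range to [0, 1] and
#' written as PNG.
#'
#' @param scene a [gray_image].
#' @param path output path (.png).
#' @export
write_scene_image <- function(scene, path) {
  geom <- scene$geometry
  x <- (scene$values - geom$lum_range[1]) / diff(geom$lum_range)
  png::writePNG(pmin(pmax(x, 0), 1), path)
  invisible(path)
}

#' Read annotator masks
#'
#' Either one binary PNG per annotator or a single multi-page TIFF.
#'
#' @param paths character vector of PNG paths, or one TIFF path.
#' @return list of binary matrices.
#' @export
read_annotations <- function(paths) {
  if (length(paths) == 1 && tolower(tools::file_ext(paths)) %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(paths, all = TRUE)
    return(lapply(pages, function(p) {
      if (length(dim(p)) == 3) p <- p[, , 1]
      (p > 0.5) + 0
    }))
  }
  lapply(paths, function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 3) img <- img[, , 1]
    (img > 0.5) + 0
  })
}

#' Write/read a feature map as CSV (full precision) and a PNG preview
#'
#' @param map numeric matrix in [0, 1].
#' @param path output CSV path; the preview (if requested) replaces the
#'   extension with .png.
#' @param preview logical, also write an 8-bit PNG preview.
#' @return the CSV path, invisibly.
#' @export
write_map <- function(map, path, preview = FALSE) {
  data.table::fwrite(data.table::as.data.table(map), path)
  if (preview)
    png::writePNG(pmin(pmax(map, 0), 1),
                  paste0(tools::file_path_sans_ext(path), ".png"))
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  as.matrix(data.table::fread(path))
}

trial_cols <- c("observer_id", "scene_id", "insertion_id", "td_label",
                "bu_label", "condition", "cue", "q", "response", "z",
                "block_id", "pass_id", "stim_id", "flipped",
                sprintf("n%02d", 1:16))

#' Write/read a trial table
#'
#' CSV with one row per trial and the noise vector spread over columns
#' n01..n16, written at full double precision so records round-trip
#' losslessly.
#'
#' @param trials trial-record data.frame.
#' @param path CSV path.
#' @export
write_trial_table <- function(trials, path) {
  missing <- setdiff(trial_cols, names(trials))
  if (length(missing) > 0)
    sp_input_error(paste("trial table missing columns:",
                         paste(missing, collapse = ", ")))
  data.table::fwrite(trials[, trial_cols], path)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = c("pass_id")))
  missing <- setdiff(trial_cols, names(dt))
  if (length(missing) > 0)
    sp_input_error(paste("malformed trial table, missing:",
                         paste(missing, collapse = ", ")))
  bad <- which(!dt$q %in% c(0, 1) |
                 !dt$response %in% c("congruent", "incongruent"))
  if (length(bad) > 0)
    sp_input_error(sprintf("malformed trial record at row %d", bad[1]))
  as.data.frame(dt)
}

#' Write/read insertion points CSV
#'
#' @param df data.frame as from [insertion_points_df()].
#' @param path CSV path.
#' @export
write_insertion_csv <- function(df, path) {
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_insertion_csv
#' @export
read_insertion_csv <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Save/load ERP epochs
#'
#' Raw little-endian doubles plus a JSON sidecar carrying dimensions,
#' sampling parameters and per-trial metadata.
#'
#' @param dataset an [erp_dataset].
#' @param path output path for the binary array; the sidecar takes
#'   \code{.json} appended.
#' @export
save_epochs <- function(dataset, path) {
  con <- file(path, "wb")
  writeBin(as.vector(dataset$waveforms), con, size = 8, endian = "little")
  close(con)
  meta <- list(dim = dim(dataset$waveforms), srate = dataset$srate,
               t_start = dataset$times[1], meta = dataset$meta,
               layout = dataset$layout)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(path, "rb")
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  close(con)
  erp_dataset(array(x, meta$dim), as.data.frame(meta$meta),
              srate = meta$srate, t_start = meta$t_start,
              layout = as.data.frame(meta$layout))
}
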