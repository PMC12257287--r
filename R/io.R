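read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext, call. = FALSE))
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Read a design mask from PNG or TIFF
#'
#' Nonzero pixels are ON (exposed). Multichannel images use the first
#' channel.
#'
#' @param path PNG or TIFF file.
#' @param pixel_pitch_um Physical size of one design pixel, um.
#' @param origin_um Stage coordinate of the top-left corner.
#' @return A [design()].
#' @export
read_design <- function(path, pixel_pitch_um, origin_um = c(0, 0)) {
  design(read_raster(path) > 0, pixel_pitch_um, origin_um)
}

#' Write a design mask as PNG
#'
#' @param dsn A [design()] (or a logical matrix).
#' @param path Output PNG path.
#' @export
write_design <- function(dsn, path) {
  mask <- if (inherits(dsn, "design")) dsn$mask else dsn
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Serialize a tile plan
#'
#' The plan metadata and stage list go to JSON; the binary DMD frames go to
#' a multi-page TIFF (one page per exposure, referenced by page number from
#' the JSON).
#'
#' @param plan A `"tile_plan"`.
#' @param json_path Output JSON path.
#' @param frames_path Output multi-page TIFF path; defaults to the JSON path
#'   with extension `.frames.tif`.
#' @return `json_path`, invisibly.
#' @seealso [read_tile_plan()]
#' @export
write_tile_plan <- function(plan, json_path, frames_path = NULL) {
  stopifnot(inherits(plan, "tile_plan"))
  if (is.null(frames_path))
    frames_path <- paste0(sub("\\.json$", "", json_path), ".frames.tif")
  exposures <- lapply(seq_along(plan$exposures), function(i) {
    e <- plan$exposures[[i]]
    list(index = i, stage_x_um = e$stage_x_um, stage_y_um = e$stage_y_um,
         origin_x_um = e$origin_x_um, origin_y_um = e$origin_y_um,
         tile_row = e$tile_row, tile_col = e$tile_col,
         time_ms = e$time_ms, frame_page = i)
  })
  obj <- list(objective_name = plan$objective_name,
              dmd = list(rows = plan$dmd$rows, cols = plan$dmd$cols),
              pixel_size_um = plan$pixel_size_um,
              frames_file = basename(frames_path),
              exposures = exposures)
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  frames <- lapply(plan$exposures, function(e) e$frame * 1)
  if (length(frames))
    tiff::writeTIFF(frames, frames_path, bits.per.sample = 8L)
  invisible(json_path)
}

#' Read a tile plan written by [write_tile_plan()]
#'
#' @param json_path Plan JSON path.
#' @param frames_path Frames TIFF path; defaults to the `frames_file`
#'   recorded in the JSON, resolved next to it.
#' @return A `"tile_plan"`.
#' @export
read_tile_plan <- function(json_path, frames_path = NULL) {
  obj <- jsonlite::read_json(json_path)
  if (is.null(frames_path))
    frames_path <- file.path(dirname(json_path), obj$frames_file)
  frames <- if (length(obj$exposures) && file.exists(frames_path)) {
    pages <- tiff::readTIFF(frames_path, all = TRUE)
    if (is.matrix(pages)) pages <- list(pages)
    pages
  } else list()
  exposures <- lapply(obj$exposures, function(e) {
    list(stage_x_um = e$stage_x_um, stage_y_um = e$stage_y_um,
         origin_x_um = e$origin_x_um, origin_y_um = e$origin_y_um,
         tile_row = e$tile_row, tile_col = e$tile_col,
         frame = frames[[e$frame_page]] > 0.5, time_ms = e$time_ms)
  })
  new_tile_plan(exposures, obj$objective_name,
                dmd_spec(obj$dmd$rows, obj$dmd$cols), obj$pixel_size_um)
}

#' Export stage positions as CSV
#'
#' @param plan A `"tile_plan"`.
#' @param path Output CSV with columns `index,x_um,y_um,time_ms`.
#' @export
write_stage_csv <- function(plan, path) {
  stopifnot(inherits(plan, "tile_plan"))
  d <- data.frame(
    index = seq_along(plan$exposures),
    x_um = vapply(plan$exposures, `[[`, 0, "stage_x_um"),
    y_um = vapply(plan$exposures, `[[`, 0, "stage_y_um"),
    time_ms = vapply(plan$exposures, `[[`, 0, "time_ms"))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a dose map as 32-bit float TIFF
#'
#' Float TIFF samples are stored on a 0-1 scale, so the grid is normalized
#' by its maximum and the scale factor recorded in a JSON sidecar
#' (`<path>.json`) together with the cell pitch and origin;
#' [read_dose_map()] reconstructs the original values.
#'
#' @param dose A `"dose_map"`.
#' @param path Output TIFF path.
#' @export
write_dose_map <- function(dose, path) {
  stopifnot(inherits(dose, "dose_map"))
  scale <- max(dose$grid, .Machine$double.eps)
  tiff::writeTIFF(dose$grid / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(scale_mJ_mm2 = scale, pixel_pitch_um = dose$pixel_pitch_um,
         origin_um = dose$origin_um),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dose map written by [write_dose_map()]
#'
#' @param path TIFF path (sidecar `<path>.json` must sit next to it).
#' @return A `"dose_map"`.
#' @export
read_dose_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  grid <- tiff::readTIFF(path) * meta$scale_mJ_mm2
  new_dose_map(grid, meta$pixel_pitch_um, unlist(meta$origin_um))
}

#' Write a cure map as 8-bit TIFF
#'
#' Cured cells are white (255), washed-away cells black. The threshold,
#' pitch and origin go to a JSON sidecar.
#'
#' @param cm A `"cure_map"`.
#' @param path Output TIFF path.
#' @export
write_cure_map <- function(cm, path) {
  stopifnot(inherits(cm, "cure_map"))
  tiff::writeTIFF(cm$grid * 1, path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(threshold_mJ_mm2 = cm$threshold_mJ_mm2,
         pixel_pitch_um = cm$pixel_pitch_um, origin_um = cm$origin_um),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cure map written by [write_cure_map()]
#'
#' @param path TIFF path.
#' @return A `"cure_map"`.
#' @export
read_cure_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(list(grid = tiff::readTIFF(path) > 0.5,
                 pixel_pitch_um = meta$pixel_pitch_um,
                 origin_um = unlist(meta$origin_um),
                 threshold_mJ_mm2 = meta$threshold_mJ_mm2),
            class = "cure_map")
}

#' Write a grid QC report as JSON
#'
#' @param report A `"grid_qc_report"`.
#' @param path Output JSON path.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "grid_qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
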