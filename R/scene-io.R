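#' Read or write a 16-bit grayscale TIFF
#'
#' Thin wrappers around the tiff package keeping everything in integer
#' counts (0-65535) rather than the [0, 1] doubles tiff uses natively.
#'
#' @param img integer matrix in `[0, 65535]`.
#' @param path file path.
#' @return `readTiff16` returns an integer matrix.
#' @export
writeTiff16 <- function(img, path) {
  stopIfNot16bit(img)
  tiff::writeTIFF(matrix(img / 65535, nrow(img), ncol(img)), path,
                  bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname writeTiff16
#' @export
readTiff16 <- function(path) {
  x <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(x) <- "integer"
  x
}

#' Save a scene to a directory
#'
#' Writes `brightfield.tif`, `fluorescence.tif`, `labels.tif` (all 16-bit
#' grayscale), `droplets.csv` and `scene.json` (calibration, labels, seed).
#' [readScene()] restores the scene exactly.
#'
#' @param scene a [Scene-class].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeScene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTiff16(scene@brightfield, file.path(dir, "brightfield.tif"))
  writeTiff16(scene@fluorescence, file.path(dir, "fluorescence.tif"))
  if (max(scene@labelImage) > 65535) stop("more than 65535 cells")
  writeTiff16(scene@labelImage, file.path(dir, "labels.tif"))
  utils::write.csv(scene@droplets, file.path(dir, "droplets.csv"),
                   row.names = FALSE)
  meta <- list(pixel_size_um = scene@calibration@pixelSizeUm,
               bit_depth = scene@calibration@bitDepth,
               strain_tag = scene@strainTag,
               experiment_id = scene@experimentId,
               field_id = scene@fieldId, seed = scene@seed)
  jsonlite::write_json(meta, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeScene
#' @export
readScene <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scene.json"),
                              simplifyVector = TRUE)
  drops <- utils::read.csv(file.path(dir, "droplets.csv"))
  lab <- readTiff16(file.path(dir, "labels.tif"))
  new("Scene",
      brightfield = readTiff16(file.path(dir, "brightfield.tif")),
      fluorescence = readTiff16(file.path(dir, "fluorescence.tif")),
      labelImage = lab, droplets = drops,
      calibration = calibration(meta$pixel_size_um),
      strainTag = meta$strain_tag, experimentId = meta$experiment_id,
      fieldId = meta$field_id, seed = as.integer(meta$seed))
}
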