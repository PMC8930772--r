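# Minimal ImageJ .roi polygon codec and a store-only ZIP writer. Only the
# polygon record subset needed for convex-hull cell ROIs is implemented:
# big-endian header ("Iout", version, type 0 = polygon, bounds, n) followed
# by x and y vertex offsets as 16-bit integers. Coordinates follow ImageJ
# conventions: x = column - 1, y = row - 1 (0-based).

writeImageJRoi <- function(hull, path, name = NULL) {
  x <- as.integer(round(hull[, "col"] - 1L))
  y <- as.integer(round(hull[, "row"] - 1L))
  n <- length(x)
  left <- min(x); top <- min(y)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("Iout", con, 4, eos = NULL)
  writeBin(c(228L, 0L), con, size = 2, endian = "big")    # version, type=polygon
  writeBin(c(top, left, max(y) + 1L, max(x) + 1L, n), con,
           size = 2, endian = "big")                      # bounds + n
  writeBin(raw(64 - 18), con)                             # rest of header zero
  writeBin(c(x - left, y - top), con, size = 2, endian = "big")
  invisible(path)
}

readImageJRoi <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(raw[1:4]) != "Iout") stop("not an ImageJ ROI file: ", path)
  hdr <- function(off) {  # big-endian unsigned short at 0-based offset
    as.integer(raw[off + 1]) * 256L + as.integer(raw[off + 2])
  }
  type <- as.integer(raw[7])
  if (type != 0L) stop("only polygon ROIs are supported (type ", type, ")")
  top <- hdr(8); left <- hdr(10); n <- hdr(16)
  rd <- function(k) hdr(64 + 2 * k)
  x <- vapply(seq_len(n) - 1L, rd, integer(1)) + left
  y <- vapply(seq_len(n) + n - 1L, rd, integer(1)) + top
  cbind(row = y + 1L, col = x + 1L)
}

# ---- store-only ZIP (deterministic: fixed timestamps, no compression) ----

crc32Table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (i in 0:255) {
        c <- i
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L) {
            bitwXor(bitwShiftR(c, 1), -306674912L)  # 0xEDB88320
          } else bitwShiftR(c, 1)
        }
        t[i + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32Table()
  crc <- -1L
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8),
                   tab[bitwXor(bitwAnd(crc, 255L), b) + 1L])
  }
  bitwXor(crc, -1L)
}

writeStoredZip <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  offsets <- integer(length(entries))
  crcs <- integer(length(entries))
  pos <- 0L
  for (i in seq_along(entries)) {
    name <- names(entries)[i]; data <- entries[[i]]
    offsets[i] <- pos
    crcs[i] <- crc32(data)
    w4(67324752L)                      # local header signature
    w2(20L); w2(0L); w2(0L)            # version, flags, method = stored
    w2(0L); w2(33L)                    # time, date (fixed: 1980-01-01)
    w4(crcs[i]); w4(length(data)); w4(length(data))
    w2(nchar(name, "bytes")); w2(0L)
    writeChar(name, con, eos = NULL)
    writeBin(data, con)
    pos <- pos + 30L + nchar(name, "bytes") + length(data)
  }
  cdStart <- pos
  for (i in seq_along(entries)) {
    name <- names(entries)[i]; data <- entries[[i]]
    w4(33639248L)                      # central directory signature
    w2(20L); w2(20L); w2(0L); w2(0L)
    w2(0L); w2(33L)
    w4(crcs[i]); w4(length(data)); w4(length(data))
    w2(nchar(name, "bytes")); w2(0L); w2(0L)
    w2(0L); w2(0L); w4(0L)
    w4(offsets[i])
    writeChar(name, con, eos = NULL)
    pos <- pos + 46L + nchar(name, "bytes")
  }
  w4(101010256L)                       # end of central directory
  w2(0L); w2(0L); w2(length(entries)); w2(length(entries))
  w4(pos - cdStart); w4(cdStart); w2(0L)
  invisible(path)
}

#' Export a segmentation as ImageJ ROIs, polygon JSON and a label TIFF
#'
#' Writes `rois.zip` (one ImageJ polygon `.roi` record per retained
#' instance), `polygons.json` (the same hull vertices in plain JSON),
#' `labels.tif` (the hull-rendered label image) and `removals.csv`.
#' [readRois()] reads the archive back; the round trip reproduces the hull
#' vertices exactly.
#'
#' @param result a [SegmentationResult-class].
#' @param dir output directory (created if missing).
#' @return invisible character vector of file paths written.
#' @export
exportRois <- function(result, dir) {
  stopifnot(is(result, "SegmentationResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  polys <- list()
  for (inst in result@instances) {
    nm <- sprintf("cell-%04d.roi", inst$id)
    tmp <- tempfile(fileext = ".roi")
    writeImageJRoi(inst$hull, tmp)
    entries[[nm]] <- readBin(tmp, "raw", file.info(tmp)$size)
    unlink(tmp)
    polys[[length(polys) + 1L]] <- list(
      id = inst$id, row = as.numeric(round(inst$hull[, "row"])),
      col = as.numeric(round(inst$hull[, "col"])))
  }
  zipPath <- file.path(dir, "rois.zip")
  writeStoredZip(entries, zipPath)
  jsonlite::write_json(polys, file.path(dir, "polygons.json"),
                       auto_unbox = TRUE, digits = NA)
  labPath <- file.path(dir, "labels.tif")
  writeTiff16(result@labelImage, labPath)
  remPath <- file.path(dir, "removals.csv")
  utils::write.csv(result@removed, remPath, row.names = FALSE)
  invisible(c(zipPath, file.path(dir, "polygons.json"), labPath, remPath))
}

#' @param zipPath path to a `rois.zip` written by [exportRois()].
#' @rdname exportRois
#' @return `readRois` returns a named list of hull vertex matrices
#'   (row, col), one per ROI record.
#' @export
readRois <- function(zipPath) {
  exdir <- tempfile("rois")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- tryCatch(
    suppressWarnings(utils::unzip(zipPath, exdir = exdir,
                                  unzip = "internal")),
    error = function(e) character(0))  # an empty archive holds no members
  if (!is.character(files) || length(files) == 0) return(list())
  files <- sort(files)
  out <- lapply(files, readImageJRoi)
  names(out) <- sub("\\.roi$", "", basename(files))
  out
}
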