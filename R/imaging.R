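#' Sensor-patch image handling
#'
#' Images are carried as height x width x 3 arrays on the 0-255 scale,
#' together with their source path and optional capture metadata (ISO mode,
#' shutter speed, exposure compensation, illumination in lux). The region of
#' interest (ROI) is a square pixel window, 16 x 16 by default, from which
#' the mean RGB triple and its per-channel SD are taken.
#'
#' @name imaging
NULL

#' Construct an image record
#'
#' @param pixels height x width x 3 numeric array, values in \[0, 255\].
#' @param path source path (or a label for in-memory images).
#' @param metadata named list of capture metadata (free-form; e.g.
#'   `shutter_s = 1/60`, `ev = 0`, `illumination_lux = 170`).
#' @return An object of class `image_record`.
#' @export
image_record <- function(pixels, path = "<in-memory>", metadata = list()) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stop("pixels must be a height x width x 3 array", call. = FALSE)
  if (any(pixels < 0) || any(pixels > 255))
    stop("pixel values must be in [0, 255]", call. = FALSE)
  structure(list(pixels = pixels, path = path, metadata = metadata),
            class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_record> %d x %d RGB, source: %s\n", d[1], d[2], x$path))
  invisible(x)
}

#' Load a sensor-patch photograph
#'
#' Reads PNG, TIFF or JPEG into an `image_record` on the 0-255 scale. JPEG
#' is accepted with a warning: lossy compression perturbs channel
#' statistics, so calibration fixtures should be lossless. An alpha channel,
#' if present, is dropped. Grayscale or otherwise non-RGB images are
#' rejected with an error naming the offending mode.
#'
#' @param path path to a PNG/TIFF/JPEG file.
#' @param metadata optional named list of capture metadata attached to the
#'   record.
#' @return An `image_record`.
#' @export
load_image <- function(path, metadata = list()) {
  if (!file.exists(path))
    stop("cannot read image: file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      jpg = ,
      jpeg = {
        if (!requireNamespace("jpeg", quietly = TRUE))
          stop("the 'jpeg' package is required to read JPEG files",
               call. = FALSE)
        warning("JPEG input is lossy; channel statistics may be perturbed ",
                "relative to the captured scene", call. = FALSE)
        jpeg::readJPEG(path)
      },
      stop("unsupported image format: .", ext, call. = FALSE)
    ),
    error = function(e) stop("cannot decode ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(dim(px)) < 3)
    stop("non-RGB image (mode: grayscale): ", path, call. = FALSE)
  nch <- dim(px)[3]
  if (nch == 4) px <- px[, , 1:3, drop = FALSE]
  else if (nch != 3)
    stop("non-RGB image (", nch, " channel(s)): ", path, call. = FALSE)
  image_record(px * 255, path = path, metadata = metadata)
}

#' Write an image record as PNG
#'
#' @param image an `image_record`.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  stopifnot(inherits(image, "image_record"))
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Specify a square region of interest
#'
#' Coordinates are 0-based and row-major. The window is half-open:
#' rows `[center_row - side %/% 2, center_row - side %/% 2 + side)` and
#' likewise for columns, so an even side length places the center at the
#' top-left pixel of the central 2 x 2 block.
#'
#' @param center_row,center_col 0-based pixel coordinates of the ROI center.
#'   `NULL` (default) means the image center, the standard placement for a
#'   fixed sample-holder geometry.
#' @param side window side length in pixels (default 16).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center_row = NULL, center_col = NULL, side = 16) {
  if (side < 1) stop("ROI side must be >= 1", call. = FALSE)
  structure(list(center_row = center_row, center_col = center_col,
                 side = as.integer(side)),
            class = "roi_spec")
}

#' Extract the ROI pixel block
#'
#' @param image an `image_record`.
#' @param roi an `roi_spec`; defaults to a centered 16 x 16 window.
#' @return A side x side x 3 array (0-255 scale).
#' @export
extract_roi <- function(image, roi = roi_spec()) {
  stopifnot(inherits(image, "image_record"), inherits(roi, "roi_spec"))
  d <- dim(image$pixels)
  cr <- roi$center_row %||% (d[1] %/% 2)
  cc <- roi$center_col %||% (d[2] %/% 2)
  r0 <- cr - roi$side %/% 2          # 0-based start, inclusive
  c0 <- cc - roi$side %/% 2
  r1 <- r0 + roi$side                # 0-based end, exclusive
  c1 <- c0 + roi$side
  if (r0 < 0 || c0 < 0 || r1 > d[1] || c1 > d[2])
    stop(sprintf(
      "ROI [%d,%d) x [%d,%d) exceeds image bounds %d x %d",
      r0, r1, c0, c1, d[1], d[2]), call. = FALSE)
  image$pixels[(r0 + 1):r1, (c0 + 1):c1, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean RGB and per-channel SD of a pixel block
#'
#' The arithmetic mean and the n-1 (sample) standard deviation per channel,
#' matching the replicate-SD semantics of triplicate channel tables.
#'
#' @param block a h x w x 3 pixel array, e.g. from [extract_roi()].
#' @return A list with numeric length-3 vectors `mean` and `sd`
#'   (names R, G, B).
#' @export
roi_mean_rgb <- function(block) {
  if (length(dim(block)) != 3 || dim(block)[3] != 3 || length(block) == 0)
    stop("block must be a non-empty h x w x 3 array", call. = FALSE)
  m <- apply(block, 3, mean)
  s <- apply(block, 3, stats::sd)
  if (length(block[, , 1]) == 1) s <- rep(0, 3)
  names(m) <- names(s) <- c("R", "G", "B")
  list(mean = m, sd = s)
}

#' Read / write channel tables
#'
#' The channel-table CSV schema is
#' `sample_id,concentration,R,G,B,I,H,S,V,L`, one row per sample;
#' `concentration` is blank (`NA`) for unknowns.
#'
#' @param path CSV path.
#' @return `read_channel_table`: a data frame with the schema above.
#' @export
read_channel_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "concentration", CHANNEL_NAMES)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0)
    stop("channel table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab[, need]
}

#' @rdname read_channel_table
#' @param tab a channel-table data frame.
#' @export
write_channel_table <- function(tab, path) {
  need <- c("sample_id", "concentration", CHANNEL_NAMES)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0)
    stop("channel table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.csv(tab[, need], path, row.names = FALSE, na = "")
  invisible(path)
}
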