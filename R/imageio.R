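#' Construct an image frame
#'
#' A single grayscale frame with its physical pixel size and acquisition
#' timestamp.  Intensities are stored on the unit interval; 8- or 16-bit
#' integer data are rescaled on construction.
#'
#' @param data numeric matrix (unit interval) or integer matrix (0..255 or
#'   0..65535).
#' @param pixel_size pixel edge length in micrometres per pixel.
#' @param timestamp acquisition time in hours.
#' @return an object of class `image_frame`.
#' @export
image_frame <- function(data, pixel_size, timestamp = 0) {
  stop_if(!is.matrix(data) || length(data) == 0L, "frame data must be a non-empty matrix")
  stop_if(!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0,
          "pixel_size must be a single positive number (um/px)")
  x <- data
  if (max(x) > 1) {
    denom <- if (max(x) > 255) 65535 else 255
    x <- x / denom
  }
  structure(list(data = x, pixel_size = as.numeric(pixel_size),
                 timestamp = as.numeric(timestamp)),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame %d x %d px, %.3g um/px, t = %g h>\n",
              nrow(x$data), ncol(x$data), x$pixel_size, x$timestamp))
  invisible(x)
}

## accept either an image_frame or a bare matrix
frame_data <- function(frame) {
  if (inherits(frame, "image_frame")) frame$data
  else if (is.matrix(frame)) frame
  else stop("expected an image_frame or a matrix", call. = FALSE)
}

frame_pixel_size <- function(frame, default = NULL) {
  if (inherits(frame, "image_frame")) frame$pixel_size
  else default %||% stop("pixel_size required for a bare matrix", call. = FALSE)
}

#' Write an image stack as multi-page 16-bit TIFF with a JSON sidecar
#'
#' The sidecar (`<stem>.json`) records the pixel size (um/px) and per-frame
#' timestamps (hours).
#'
#' @param frames list of numeric matrices on the unit interval.
#' @param path output TIFF path.
#' @param pixel_size um/px.
#' @param timestamps hours, one per frame.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(frames, path, pixel_size, timestamps) {
  stop_if(length(frames) != length(timestamps),
          "need one timestamp per frame (%d frames, %d timestamps)",
          length(frames), length(timestamps))
  frames <- lapply(frames, function(f) clamp(f, 0, 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  sidecar <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(pixel_size_um = pixel_size,
                            timestamps_h = timestamps),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF path; the JSON sidecar is looked up next to it.
#' @return list of [image_frame()] objects.
#' @export
read_image_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  sidecar <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  stop_if(!file.exists(sidecar), "missing JSON sidecar for %s", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  stop_if(length(meta$timestamps_h) != length(frames),
          "sidecar lists %d timestamps for %d frames",
          length(meta$timestamps_h), length(frames))
  Map(function(f, t) image_frame(f, meta$pixel_size_um, t),
      frames, meta$timestamps_h)
}
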