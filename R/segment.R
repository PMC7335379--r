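#' Segmentation configuration
#'
#' Tunable parameters of the silhouette segmentation.  The validity
#' heuristics decide when strategy A's result is rejected and the
#' edge-detection fallback (strategy B) is attempted:
#' a mask is rejected when its area fraction falls outside
#' `[min_area_frac, max_area_frac]`, when it does not intersect a central
#' region of interest covering `roi_frac` of each image dimension, when it
#' occupies more than `border_touch_frac` of the image border, or when
#' automatic thresholding is degenerate.
#'
#' @param threshold intensity threshold or `"auto"` (between-class variance).
#' @param tissue_dark tissue darker than background (brightfield default).
#' @param min_area_frac,max_area_frac plausible mask area as a fraction of the
#'   frame (defaults 0.005 and 0.8).
#' @param roi_frac central region of interest, as a fraction of each dimension,
#'   that a plausible silhouette must intersect (default 0.5).
#' @param border_touch_frac maximum fraction of border pixels the component
#'   may occupy (default 0.05).
#' @param edge_threshold threshold for the binarized edge map in strategy B
#'   (`"auto"` default).
#' @param b_residual_frac strategy B's final binarization keeps pixels at or
#'   below this fraction of the frame maximum: after subtracting the
#'   full-scale edge mask and clamping at zero, boundary pixels sit exactly at
#'   zero (default 0.02).
#' @return a list of class `seg_config`.
#' @export
seg_config <- function(threshold = "auto", tissue_dark = TRUE,
                       min_area_frac = 0.005, max_area_frac = 0.8,
                       roi_frac = 0.5, border_touch_frac = 0.05,
                       edge_threshold = "auto", b_residual_frac = 0.02) {
  stop_if(min_area_frac < 0 || max_area_frac > 1 || min_area_frac >= max_area_frac,
          "need 0 <= min_area_frac < max_area_frac <= 1")
  structure(list(threshold = threshold, tissue_dark = tissue_dark,
                 min_area_frac = min_area_frac, max_area_frac = max_area_frac,
                 roi_frac = roi_frac, border_touch_frac = border_touch_frac,
                 edge_threshold = edge_threshold,
                 b_residual_frac = b_residual_frac),
            class = "seg_config")
}

#' Convert a pixel count to an absolute area
#'
#' @param pixel_count number of silhouette pixels.
#' @param pixel_size pixel edge length in um/px.
#' @return area in mm^2 (`pixel_count * pixel_size^2 * 1e-6`).
#' @export
pixels_to_area <- function(pixel_count, pixel_size) {
  stop_if(any(pixel_count < 0), "negative pixel count")
  stop_if(pixel_size <= 0, "pixel_size must be positive")
  pixel_count * pixel_size^2 * 1e-6
}

#' 3x3 gradient-magnitude (Sobel) edge map
#'
#' @param x numeric matrix.
#' @return numeric matrix of gradient magnitudes, same shape (replicated
#'   border padding).
#' @export
sobel_magnitude <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  ## replicate-pad by one pixel
  p <- rbind(x[1, , drop = FALSE], x, x[nr, , drop = FALSE])
  p <- cbind(p[, 1, drop = FALSE], p, p[, nc, drop = FALSE])
  sh <- function(dr, dc) p[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  gx <- (sh(0, 2) + 2 * sh(1, 2) + sh(2, 2)) - (sh(0, 0) + 2 * sh(1, 0) + sh(2, 0))
  gy <- (sh(2, 0) + 2 * sh(2, 1) + sh(2, 2)) - (sh(0, 0) + 2 * sh(0, 1) + sh(0, 2))
  sqrt(gx^2 + gy^2)
}

seg_result <- function(mask, pixel_size, strategy, threshold, flags) {
  pc <- sum(mask)
  structure(list(mask = mask, pixel_count = pc,
                 area_mm2 = pixels_to_area(pc, pixel_size),
                 strategy_used = strategy,
                 threshold_used = threshold,
                 quality_flags = flags),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation strategy %s: %d px = %.4g mm^2%s>\n",
              x$strategy_used, x$pixel_count, x$area_mm2,
              if (length(x$quality_flags))
                paste0(" [", paste(x$quality_flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

## validity heuristics shared by both strategies
mask_quality_flags <- function(mask, config) {
  flags <- character()
  nr <- nrow(mask); nc <- ncol(mask)
  frac <- sum(mask) / length(mask)
  if (sum(mask) == 0L) return("no-tissue")
  if (frac < config$min_area_frac || frac > config$max_area_frac)
    flags <- c(flags, "implausible-area")
  ## central region of interest
  rr <- round(nr / 2 + c(-1, 1) * nr * config$roi_frac / 2)
  cc <- round(nc / 2 + c(-1, 1) * nc * config$roi_frac / 2)
  rr <- clamp(rr, 1, nr); cc <- clamp(cc, 1, nc)
  if (!any(mask[rr[1]:rr[2], cc[1]:cc[2]]))
    flags <- c(flags, "off-center")
  border <- sum(mask[1, ]) + sum(mask[nr, ]) + sum(mask[, 1]) + sum(mask[, nc])
  if (border > config$border_touch_frac * (2 * nr + 2 * nc))
    flags <- c(flags, "touches-border")
  flags
}

#' Segment a frame by intensity thresholding (strategy A)
#'
#' Threshold the frame, keep the largest 8-connected component, fill holes,
#' count pixels and convert to absolute area.  Validity heuristics (see
#' [seg_config()]) are attached as quality flags rather than raised as
#' errors, so the caller can decide to fall back to strategy B.
#'
#' @param frame an [image_frame()].
#' @param config a [seg_config()].
#' @return a `segmentation_result`.
#' @export
segment_strategy_a <- function(frame, config = seg_config()) {
  x <- frame_data(frame)
  ps <- frame_pixel_size(frame)
  bm <- binarize(x, config$threshold, config$tissue_dark)
  if (isTRUE(attr(bm, "degenerate"))) {
    return(seg_result(matrix(FALSE, nrow(x), ncol(x)), ps, "A", NA_real_,
                      "degenerate-threshold"))
  }
  mask <- largest_component_fill(bm)
  flags <- mask_quality_flags(mask, config)
  seg_result(mask, ps, "A", attr(bm, "threshold"), flags)
}

#' Segment a frame via edge detection (strategy B)
#'
#' Gradient-magnitude edge map, binarized; the binary edge mask is scaled to
#' the frame's intensity maximum and subtracted from the original frame
#' (clamped at zero), which stamps the silhouette boundary to zero; the
#' residual image is binarized at a near-zero threshold, and the largest
#' component (the boundary ring) is kept and hole-filled into the silhouette.
#'
#' @inheritParams segment_strategy_a
#' @return a `segmentation_result`.
#' @export
segment_strategy_b <- function(frame, config = seg_config()) {
  x <- frame_data(frame)
  ps <- frame_pixel_size(frame)
  edges <- sobel_magnitude(x)
  em <- binarize(edges, config$edge_threshold, tissue_dark = FALSE)
  if (isTRUE(attr(em, "degenerate"))) {
    return(seg_result(matrix(FALSE, nrow(x), ncol(x)), ps, "B", NA_real_,
                      "degenerate-threshold"))
  }
  residual <- pmax(x - em * max(x), 0)
  thr <- config$b_residual_frac * max(x)
  ring <- residual <= thr
  if (!any(ring)) {
    return(seg_result(matrix(FALSE, nrow(x), ncol(x)), ps, "B", thr, "no-tissue"))
  }
  mask <- largest_component_fill(ring)
  flags <- mask_quality_flags(mask, config)
  seg_result(mask, ps, "B", thr, flags)
}

#' Segment a frame with automatic fallback
#'
#' Runs strategy A; when any quality flag is raised, strategy B is run and
#' returned instead.  When both strategies raise flags, a failure result is
#' returned whose flags carry both flag sets (`A:` / `B:` prefixed).
#'
#' @inheritParams segment_strategy_a
#' @return a `segmentation_result`.
#' @export
segment_frame <- function(frame, config = seg_config()) {
  a <- segment_strategy_a(frame, config)
  if (length(a$quality_flags) == 0L) return(a)
  b <- segment_strategy_b(frame, config)
  if (length(b$quality_flags) == 0L) return(b)
  flags <- c(paste0("A:", a$quality_flags), paste0("B:", b$quality_flags))
  res <- seg_result(matrix(FALSE, nrow(frame_data(frame)), ncol(frame_data(frame))),
                    frame_pixel_size(frame), "none", NA_real_, flags)
  res
}
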