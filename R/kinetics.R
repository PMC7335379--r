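#' Per-tissue area time series
#'
#' @param tendon_id identifier.
#' @param timestamps hours, strictly increasing, starting at 0 (the moment
#'   the outer post constraints are released).
#' @param areas_mm2 absolute silhouette areas, mm^2.
#' @param flags character vector of per-frame quality flags (`""` = clean).
#' @return an object of class `area_series`.
#' @export
area_series <- function(tendon_id, timestamps, areas_mm2,
                        flags = rep("", length(timestamps))) {
  stop_if(length(timestamps) != length(areas_mm2),
          "timestamps and areas differ in length")
  stop_if(length(timestamps) < 2L, "need at least 2 frames")
  stop_if(any(diff(timestamps) <= 0), "timestamps must be strictly increasing")
  stop_if(timestamps[1] != 0, "series must start at 0 h (constraint release)")
  stop_if(length(flags) != length(timestamps), "one flag string per frame required")
  structure(list(tendon_id = tendon_id, timestamps = timestamps,
                 areas_mm2 = areas_mm2, flags = flags),
            class = "area_series")
}

## index of the frame nearest `t`, required within +/- tol hours
nearest_frame <- function(series, t, tol = 1) {
  d <- abs(series$timestamps - t)
  i <- which.min(d)
  stop_if(d[i] > tol, "no frame within %g h of t = %g h", tol, t)
  i
}

#' Relative surface area at 48 h
#'
#' 100 times the area at 48 h over the area at 0 h, with endpoint frames
#' matched within +/- 1 h.
#'
#' @param series an [area_series()].
#' @param t_end end of the remodeling window, hours (default 48).
#' @return relative area in percent.
#' @export
relative_area <- function(series, t_end = 48) {
  stop_if(!inherits(series, "area_series"), "series must come from area_series()")
  i0 <- nearest_frame(series, 0)
  i1 <- nearest_frame(series, t_end)
  stop_if(nzchar(series$flags[i0]), "0 h frame is flagged: %s", series$flags[i0])
  stop_if(nzchar(series$flags[i1]), "%g h frame is flagged: %s", t_end, series$flags[i1])
  stop_if(series$areas_mm2[i0] <= 0, "zero area at 0 h")
  100 * series$areas_mm2[i1] / series$areas_mm2[i0]
}

## linear pixel indices of each anchored post disc, for a nr x nc mask
post_disc_indices <- function(post_layout, nr, nc) {
  anchored <- post_layout[!post_layout$released, , drop = FALSE]
  lapply(seq_len(nrow(anchored)), function(k) {
    x0 <- anchored$x[k]; y0 <- anchored$y[k]; r <- anchored$r[k]
    rows <- max(1, floor(y0 - r)):min(nr, ceiling(y0 + r))
    cols <- max(1, floor(x0 - r)):min(nc, ceiling(x0 + r))
    g <- expand.grid(row = rows, col = cols)
    g <- g[(g$col - x0)^2 + (g$row - y0)^2 <= r^2, ]
    (g$col - 1L) * nr + g$row
  })
}

## number of anchored posts whose disc overlaps the mask
count_post_overlaps <- function(mask, post_layout,
                                discs = post_disc_indices(post_layout,
                                                          nrow(mask), ncol(mask))) {
  sum(vapply(discs, function(idx) any(mask[idx]), logical(1)))
}

#' Classify a micro-tissue as intact or released
#'
#' A tissue is *released* at the first frame whose silhouette mask overlaps
#' fewer than two anchored post regions, sustained for at least two
#' consecutive frames (for a 2-frame endpoint series, detachment at the final
#' frame suffices).  Detachment already present at the 0 h frame is reported
#' as released with `release_time = 0` and a `pre-release` flag, since the
#' assay clock cannot attribute an earlier time.
#'
#' @param series an [area_series()].
#' @param masks list of logical silhouette masks aligned to the series frames.
#' @param post_layout data.frame with columns `x`, `y`, `r`, `released`
#'   (see [default_post_layout()]); classification is refused without it.
#' @return list of class `compaction_result`: `tendon_id`, `status`
#'   (`"intact"`/`"released"`), `release_time_h` (`NA` when intact),
#'   `relative_area_pct` (`NA` when released or endpoints unavailable),
#'   `flags`.
#' @export
classify_release <- function(series, masks, post_layout) {
  stop_if(!inherits(series, "area_series"), "series must come from area_series()")
  stop_if(missing(masks) || is.null(masks), "masks are required")
  stop_if(length(masks) != length(series$timestamps),
          "need one mask per frame (%d masks, %d frames)",
          length(masks), length(series$timestamps))
  stop_if(missing(post_layout) || is.null(post_layout) ||
            !all(c("x", "y", "r", "released") %in% names(post_layout)),
          "post layout unknown: classification refused, not guessed")

  n <- length(masks)
  discs <- post_disc_indices(post_layout, nrow(masks[[1]]), ncol(masks[[1]]))
  detached <- vapply(masks, function(m) count_post_overlaps(m, post_layout, discs) < 2L,
                     logical(1))
  release_idx <- NA_integer_
  if (n == 2L) {
    if (detached[2L]) release_idx <- 2L
    if (detached[1L]) release_idx <- 1L
  } else {
    runs <- which(detached & c(detached[-1], FALSE))
    if (length(runs)) release_idx <- runs[1]
  }

  flags <- character()
  if (!is.na(release_idx)) {
    status <- "released"
    release_time <- series$timestamps[release_idx]
    if (release_idx == 1L) flags <- c(flags, "pre-release")
    rel_area <- NA_real_
  } else {
    status <- "intact"
    release_time <- NA_real_
    rel_area <- tryCatch(relative_area(series), error = function(e) NA_real_)
  }
  structure(list(tendon_id = series$tendon_id, status = status,
                 release_time_h = release_time,
                 relative_area_pct = rel_area, flags = flags),
            class = "compaction_result")
}

#' @export
print.compaction_result <- function(x, ...) {
  cat(sprintf("<compaction %s: %s%s%s>\n", x$tendon_id, x$status,
              if (x$status == "released") sprintf(" at %g h", x$release_time_h)
              else sprintf(", %.1f%% relative area", x$relative_area_pct),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Build a 2-frame area series from endpoint images
#'
#' Segments the 0 h and 48 h frames with [segment_frame()] (strategy A with
#' automatic fallback) and assembles them into an [area_series()]; the
#' segmentation masks are attached as attribute `masks` for
#' [classify_release()].
#'
#' @param frame0,frame48 [image_frame()] objects at 0 h and 48 h.
#' @param config a [seg_config()].
#' @return an `area_series` of 2 frames, flags carrying any segmentation
#'   failure.
#' @export
endpoint_series <- function(frame0, frame48, config = seg_config()) {
  stop_if(!inherits(frame0, "image_frame") || !inherits(frame48, "image_frame"),
          "endpoint frames must be image_frame objects")
  s0 <- segment_frame(frame0, config)
  s1 <- segment_frame(frame48, config)
  flag_of <- function(s) paste(s$quality_flags, collapse = ";")
  ser <- area_series(tendon_id = NA_character_,
                     timestamps = c(frame0$timestamp, frame48$timestamp),
                     areas_mm2 = c(s0$area_mm2, s1$area_mm2),
                     flags = c(flag_of(s0), flag_of(s1)))
  attr(ser, "masks") <- list(s0$mask, s1$mask)
  attr(ser, "strategies") <- c(s0$strategy_used, s1$strategy_used)
  ser
}
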