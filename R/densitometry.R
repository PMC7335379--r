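#' Fit a log-linear migration map from a marker lane
#'
#' Least-squares fit of `row ~ log(kDa)` through the marker band positions;
#' the map predicts the row of any molecular weight and, inversely, the
#' molecular weight at any row.
#'
#' @param ladder_rows row positions (pixels) of the marker bands, increasing.
#' @param ladder_weights molecular weights (kDa), strictly decreasing with
#'   row (heavy proteins migrate least).
#' @return an object of class `migration_map` with fields `intercept`,
#'   `slope`, `residuals`, and functions `predict_row(kda)` /
#'   `predict_kda(row)`.
#' @export
calibrate_migration <- function(ladder_rows, ladder_weights) {
  stop_if(length(ladder_rows) != length(ladder_weights),
          "ladder_rows and ladder_weights must have equal length")
  stop_if(length(ladder_rows) < 2L, "need at least 2 ladder points")
  o <- order(ladder_rows)
  stop_if(any(diff(ladder_weights[o]) >= 0),
          "ladder weights must strictly decrease with row")
  lx <- log(ladder_weights)
  fit <- lm(ladder_rows ~ lx)
  b <- unname(coef(fit))
  structure(list(intercept = b[1], slope = b[2],
                 residuals = unname(resid(fit)),
                 predict_row = function(kda) b[1] + b[2] * log(kda),
                 predict_kda = function(row) exp((row - b[1]) / b[2])),
            class = "migration_map")
}

#' @export
print.migration_map <- function(x, ...) {
  cat(sprintf("<migration_map row = %.3g %+.3g log(kDa), rms residual %.3g px>\n",
              x$intercept, x$slope, sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Densitometry configuration
#'
#' @param window_kda_halfwidth band window half-width in kDa-equivalents
#'   (default 3): the row window spans the migration positions of
#'   `kda - hw` to `kda + hw`.
#' @param local_bg_offset,local_bg_depth flanking-row margin: local background
#'   is the per-pixel median over lane rows `offset..offset+depth-1` away
#'   from both window edges.
#' @param detection_k below-detection multiple: a band is flagged when its
#'   corrected intensity does not exceed `detection_k * mad(flank) *
#'   sqrt(n_window_pixels)`.
#' @return list of class `densito_config`.
#' @export
densito_config <- function(window_kda_halfwidth = 3,
                           local_bg_offset = 4, local_bg_depth = 6,
                           detection_k = 3) {
  structure(list(window_kda_halfwidth = window_kda_halfwidth,
                 local_bg_offset = local_bg_offset,
                 local_bg_depth = local_bg_depth,
                 detection_k = detection_k),
            class = "densito_config")
}

## orient intensities so bands are positive deviations
orient_signal <- function(image, polarity) {
  stop_if(!polarity %in% c("bright", "dark"), "polarity must be 'bright' or 'dark'")
  if (polarity == "bright") image else 1 - image
}

## rows covered by a target's band window (kda may be a length-2 range,
## e.g. tubulin's 50-55 kDa doublet)
band_window_rows <- function(kda, map, halfwidth, n_rows) {
  k_lo <- min(kda) - halfwidth
  k_hi <- max(kda) + halfwidth
  stop_if(k_lo <= 0, "band window reaches non-positive molecular weight")
  r <- sort(c(map$predict_row(k_hi), map$predict_row(k_lo)))
  r1 <- floor(r[1]); r2 <- ceiling(r[2])
  stop_if(r1 < 1 || r2 > n_rows,
          "band window for %.3g kDa clipped by the image edge", min(kda))
  r1:r2
}

#' Quantify one gel/blot band
#'
#' Two-stage background correction: the per-pixel *global* background (median
#' intensity outside every lane window) is subtracted from the whole oriented
#' image; the band's raw intensity is then the sum over its window, from
#' which the per-pixel *local* background (the smaller of the two one-sided
#' medians over lane rows flanking the window, so that a neighbouring band
#' bleeding into one flank cannot inflate the estimate) times the window
#' pixel count is subtracted.  Corrected intensity
#' clamps at zero; a `below-detection` flag is attached when the corrected
#' signal does not rise above the flanking noise floor.
#'
#' @param image unit-interval intensity matrix.
#' @param lane_cols `c(first, last)` columns of the lane.
#' @param target_kda molecular weight (kDa), or a length-2 range for a
#'   doublet target.
#' @param map a [calibrate_migration()] map.
#' @param polarity `"bright"` or `"dark"` (explicit, never inferred).
#' @param all_lane_cols list of `c(first, last)` for every lane on the image
#'   (defines the between-lane region used for the global background);
#'   defaults to `lane_cols` only.
#' @param target name of the quantified protein.
#' @param lane lane identifier.
#' @param config a [densito_config()].
#' @return data.frame of class `band_measurement` with one row: lane, target,
#'   kda, raw/global/local/corrected intensities, and flags.
#' @export
quantify_band <- function(image, lane_cols, target_kda, map,
                          polarity = "bright",
                          all_lane_cols = list(lane_cols),
                          target = NA_character_, lane = NA_character_,
                          config = densito_config()) {
  stop_if(!is.matrix(image), "image must be a matrix")
  stop_if(lane_cols[1] < 1 || lane_cols[2] > ncol(image) || lane_cols[1] > lane_cols[2],
          "lane window outside image")
  sig <- orient_signal(image, polarity)

  in_lane <- rep(FALSE, ncol(image))
  for (w in all_lane_cols) in_lane[w[1]:w[2]] <- TRUE
  global_bg <- if (all(in_lane)) 0 else median(sig[, !in_lane])
  sig <- sig - global_bg

  rows <- band_window_rows(target_kda, map, config$window_kda_halfwidth, nrow(image))
  cols <- lane_cols[1]:lane_cols[2]
  raw <- sum(sig[rows, cols])

  flank_lo <- (min(rows) - config$local_bg_offset - config$local_bg_depth + 1L):
    (min(rows) - config$local_bg_offset)
  flank_hi <- (max(rows) + config$local_bg_offset):
    (max(rows) + config$local_bg_offset + config$local_bg_depth - 1L)
  flank_lo <- flank_lo[flank_lo >= 1 & flank_lo <= nrow(image)]
  flank_hi <- flank_hi[flank_hi >= 1 & flank_hi <= nrow(image)]
  stop_if(length(flank_lo) + length(flank_hi) == 0L,
          "no flanking rows available for local background")
  ## per-side medians; the smaller side wins, so a neighbouring band bleeding
  ## into one flank does not inflate the local background estimate
  side_medians <- c(if (length(flank_lo)) median(sig[flank_lo, cols]),
                    if (length(flank_hi)) median(sig[flank_hi, cols]))
  local_bg <- min(side_medians)
  flank_px <- sig[c(flank_lo, flank_hi), cols]

  n_px <- length(rows) * length(cols)
  corrected <- max(raw - local_bg * n_px, 0)

  floor_ <- config$detection_k * mad(flank_px) * sqrt(n_px)
  flags <- if (corrected <= floor_) "below-detection" else ""

  structure(data.frame(lane = lane, target = target,
                       kda = mean(range(target_kda)),
                       raw_intensity = raw, global_background = global_bg,
                       local_background = local_bg,
                       corrected_intensity = corrected,
                       flags = flags, stringsAsFactors = FALSE),
            class = c("band_measurement", "data.frame"))
}

#' Housekeeping-normalized band ratio
#'
#' @param target,tubulin `band_measurement` rows (target and loading
#'   control from the same lane).
#' @return the ratio `target / tubulin`, or `NA` with attribute
#'   `flag = "tubulin-below-detection"` when the control signal is zero or
#'   below detection.
#' @export
housekeeping_ratio <- function(target, tubulin) {
  if (tubulin$corrected_intensity <= 0 ||
      identical(tubulin$flags, "below-detection")) {
    return(structure(NA_real_, flag = "tubulin-below-detection"))
  }
  target$corrected_intensity / tubulin$corrected_intensity
}

#' MMP2 active fraction
#'
#' Active-band intensity divided by total (active plus latent pro-MMP2).
#'
#' @param active,pro `band_measurement` rows for the 62 kDa and 72 kDa bands.
#' @return fraction in `[0, 1]`, or `NA` with attribute
#'   `flag = "below-detection"` when both bands are zero.
#' @export
mmp2_active_fraction <- function(active, pro) {
  a <- active$corrected_intensity
  p <- pro$corrected_intensity
  if (a + p <= 0) return(structure(NA_real_, flag = "below-detection"))
  a / (a + p)
}

#' Flag loading-control outliers by Tukey fences
#'
#' Flags intensities below `Q1 - 1.5 IQR` or above `Q3 + 1.5 IQR`, with
#' quartiles computed by linear interpolation of the sorted order statistics
#' (type-7 quantiles).  Flagged samples are annotated, not removed: exclusion
#' is a downstream choice.
#'
#' @param tubulin_intensities numeric vector (length >= 4).
#' @return logical vector of flags with attribute `fences = c(lower, upper)`.
#' @export
loading_outliers <- function(tubulin_intensities) {
  x <- tubulin_intensities
  stop_if(length(x) < 4L, "need at least 4 loading-control values")
  stop_if(anyNA(x), "loading-control values must not be missing")
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
  structure(x < fences[1] | x > fences[2], fences = fences)
}
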