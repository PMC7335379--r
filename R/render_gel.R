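#' Gel/blot scene parameters
#'
#' One renderer serves both Western-blot and zymograph fixtures via the
#' `polarity` flag (chemiluminescent blot bands and cleared zymograph bands
#' are bright-on-dark; a stained-gel view is dark-on-light).  Band positions
#' follow a log-linear migration map `row = intercept + slope * log(kDa)`;
#' the integrated intensity of a band is proportional to its programmed
#' amount.
#'
#' @param lanes list of lanes; each lane is
#'   `list(id = ..., bands = data.frame(kda, amount))`.
#' @param image_rows image height, pixels (width follows from the lane count).
#' @param lane_width,lane_gap pixels.
#' @param ladder_weights kDa of the marker lane rendered left of the sample
#'   lanes (`NULL` omits it).
#' @param ladder_amount programmed amount for marker bands.
#' @param migration_calibration `c(intercept, slope)` of the log-linear
#'   migration map (slope negative: heavy proteins stay near the top).
#' @param band_sigma Gaussian band spread along the migration axis, pixels.
#' @param amount_gain peak intensity per unit amount.
#' @param background_level base intensity of the band-free image.
#' @param background_gradient peak-to-peak linear shading across the width,
#'   fraction of full scale.
#' @param polarity `"bright"` (bands brighter than background) or `"dark"`.
#' @param noise_sd additive Gaussian noise.
#' @param seed integer seed.
#' @return a list of class `gel_scene_params`.
#' @export
gel_scene_params <- function(lanes,
                             image_rows = 360L,
                             lane_width = 36L, lane_gap = 10L,
                             ladder_weights = c(250, 150, 100, 75, 50, 37, 25),
                             ladder_amount = 50,
                             migration_calibration = c(intercept = 787.5, slope = -139),
                             band_sigma = 3,
                             amount_gain = 6e-4,
                             background_level = 0.12,
                             background_gradient = 0,
                             polarity = c("bright", "dark"),
                             noise_sd = 0.01,
                             seed = 1L) {
  polarity <- match.arg(polarity)
  stop_if(!is.list(lanes) || length(lanes) == 0L, "lanes must be a non-empty list")
  for (ln in lanes) {
    stop_if(is.null(ln$bands) || !all(c("kda", "amount") %in% names(ln$bands)),
            "each lane needs a bands data.frame with columns kda, amount")
    stop_if(any(ln$bands$kda <= 0), "molecular weights must be positive")
    stop_if(any(ln$bands$amount < 0), "programmed amounts must be non-negative")
  }
  structure(list(lanes = lanes, image_rows = as.integer(image_rows),
                 lane_width = as.integer(lane_width), lane_gap = as.integer(lane_gap),
                 ladder_weights = ladder_weights, ladder_amount = ladder_amount,
                 migration_calibration = migration_calibration,
                 band_sigma = band_sigma, amount_gain = amount_gain,
                 background_level = background_level,
                 background_gradient = background_gradient,
                 polarity = polarity, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "gel_scene_params")
}

#' Row position of a molecular weight under a log-linear migration map
#'
#' @param kda molecular weight(s), kDa.
#' @param calibration `c(intercept, slope)`.
#' @return row position(s), pixels.
#' @export
migration_row <- function(kda, calibration) {
  calibration[[1]] + calibration[[2]] * log(kda)
}

#' Render a gel/blot image with ground truth
#'
#' Bands are Gaussian intensity bumps along the migration axis, flat across
#' the lane with raised-cosine shoulders, with peak intensity
#' `amount * amount_gain`, superimposed on a background with optional linear
#' shading and additive noise.  The `"dark"` polarity renders the
#' photometric negative (`1 - bright image`).
#'
#' @param scene a [gel_scene_params()].
#' @return list of class `gel_image` with elements `image` (unit-interval
#'   matrix), `truth` (data.frame: lane, kda, amount, row_center),
#'   `layout` (lane column windows, incl. the ladder lane) and `params`.
#' @export
render_gel <- function(scene) {
  stop_if(!inherits(scene, "gel_scene_params"), "scene must come from gel_scene_params()")
  p <- scene
  has_ladder <- !is.null(p$ladder_weights) && length(p$ladder_weights) > 0
  n_lanes <- length(p$lanes) + has_ladder
  nc <- n_lanes * (p$lane_width + p$lane_gap) + p$lane_gap
  nr <- p$image_rows

  lane_cols <- lapply(seq_len(n_lanes), function(i) {
    from <- p$lane_gap + (i - 1L) * (p$lane_width + p$lane_gap) + 1L
    c(from, from + p$lane_width - 1L)
  })
  ids <- c(if (has_ladder) "ladder", vapply(p$lanes, function(l) as.character(l$id), ""))
  names(lane_cols) <- ids

  ## cross-lane profile: flat with 4-px raised-cosine shoulders
  col_profile <- function(cols) {
    prof <- numeric(nc)
    w <- 4
    x <- seq_len(nc)
    core <- x >= cols[1] & x <= cols[2]
    prof[core] <- 1
    left <- x >= cols[1] - w & x < cols[1]
    prof[left] <- 0.5 * (1 + cos(pi * (cols[1] - x[left]) / w))
    right <- x > cols[2] & x <= cols[2] + w
    prof[right] <- 0.5 * (1 + cos(pi * (x[right] - cols[2]) / w))
    prof
  }

  bands <- list()
  add_band <- function(lane_id, kda, amount) {
    bands[[length(bands) + 1L]] <<- data.frame(
      lane = lane_id, kda = kda, amount = amount,
      row_center = migration_row(kda, p$migration_calibration))
  }
  if (has_ladder) for (w in p$ladder_weights) add_band("ladder", w, p$ladder_amount)
  for (ln in p$lanes) for (k in seq_len(nrow(ln$bands)))
    add_band(as.character(ln$id), ln$bands$kda[k], ln$bands$amount[k])
  truth <- do.call(rbind, bands)
  stop_if(any(truth$row_center < 1 + 3 * p$band_sigma |
                truth$row_center > nr - 3 * p$band_sigma),
          "band at %.3g kDa falls outside the image", truth$kda[
            which(truth$row_center < 1 + 3 * p$band_sigma |
                    truth$row_center > nr - 3 * p$band_sigma)[1]])

  rows <- seq_len(nr)
  signal <- matrix(0, nr, nc)
  for (k in seq_len(nrow(truth))) {
    cols <- lane_cols[[truth$lane[k]]]
    rowprof <- exp(-(rows - truth$row_center[k])^2 / (2 * p$band_sigma^2))
    signal <- signal + (truth$amount[k] * p$amount_gain) *
      outer(rowprof, col_profile(cols))
  }

  shade <- p$background_gradient *
    matrix((seq_len(nc) - 1) / (nc - 1) - 0.5, nr, nc, byrow = TRUE)
  img <- p$background_level + shade + signal
  if (p$noise_sd > 0) {
    img <- img + with_seed(derive_seed(p$seed, "gelnoise"),
                           matrix(rnorm(nr * nc, 0, p$noise_sd), nr, nc))
  }
  img <- clamp(img, 0, 1)
  if (p$polarity == "dark") img <- 1 - img

  structure(list(image = img, truth = truth,
                 layout = list(lane_cols = lane_cols, image_rows = nr,
                               image_cols = nc, polarity = p$polarity,
                               migration_calibration = p$migration_calibration,
                               ladder_weights = p$ladder_weights),
                 params = p),
            class = "gel_image")
}

#' @export
print.gel_image <- function(x, ...) {
  cat(sprintf("<gel_image %d x %d px, %d lanes, %d bands, %s-bands>\n",
              nrow(x$image), ncol(x$image), length(x$layout$lane_cols),
              nrow(x$truth), x$layout$polarity))
  invisible(x)
}
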