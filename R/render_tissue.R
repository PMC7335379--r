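#' Default micro-post layout
#'
#' A 2 x 4 array of posts centred in the frame; the four outermost (corner)
#' posts are flagged as released at t = 0, so the tissue stays anchored to
#' the four inner posts.  The post count and geometry are configurable
#' because the physical platform's layout is a design choice of the assay,
#' not of this package.
#'
#' @param frame_size `c(rows, cols)` in pixels.
#' @param post_radius_px post radius, pixels.
#' @param spacing_px `c(col_spacing, row_offset)`: horizontal post pitch and
#'   vertical half-distance between the two rows, pixels.
#' @return data.frame with columns `x` (col), `y` (row), `r` (px), `released`.
#' @export
default_post_layout <- function(frame_size = c(256, 320), post_radius_px = 8,
                                spacing_px = c(60, 35)) {
  cy <- frame_size[1] / 2; cx <- frame_size[2] / 2
  xs <- cx + c(-1.5, -0.5, 0.5, 1.5) * spacing_px[1]
  ys <- cy + c(-1, 1) * spacing_px[2]
  g <- expand.grid(x = xs, y = ys)
  g$r <- post_radius_px
  ## the four outermost = the corner posts of the 2 x 4 array
  g$released <- g$x %in% range(xs)
  g
}

#' Time-lapse scene parameters
#'
#' Defaults emulate hourly brightfield imaging over 48 h (49 frames) of a
#' compacting micro-tissue: the silhouette area decays from `initial_area`
#' towards `plateau_area` as
#' `A(t) = plateau + (initial - plateau) * exp(-rate * t)`; a programmed
#' `release_time` detaches the tissue from every anchoring post from that
#' time on and collapses the silhouette.
#'
#' @param frame_size `c(rows, cols)` pixels.
#' @param pixel_size um/px.
#' @param post_layout data.frame as from [default_post_layout()].
#' @param initial_area,plateau_area mm^2 (plateau < initial).
#' @param compaction_rate per hour.
#' @param release_time hours, or `NULL` for an intact tissue.
#' @param frame_interval hours between frames.
#' @param n_frames number of frames (>= 2).
#' @param noise_sd additive Gaussian intensity noise (fraction of full scale).
#' @param illumination_gradient peak-to-peak additive linear shading across
#'   the frame width, as a fraction of full scale (0 = even illumination).
#' @param background_level,tissue_level,post_level nominal intensities on the
#'   unit interval (tissue darker than background in brightfield).
#' @param boundary_softness edge transition width, pixels.
#' @param seed integer seed (controls the silhouette shape perturbation and
#'   the noise field).
#' @return a list of class `tissue_scene_params`.
#' @export
tissue_scene_params <- function(frame_size = c(256, 320), pixel_size = 12,
                                post_layout = default_post_layout(frame_size),
                                initial_area = 4.0, plateau_area = 1.6,
                                compaction_rate = 0.08,
                                release_time = NULL,
                                frame_interval = 1, n_frames = 49L,
                                noise_sd = 0.02, illumination_gradient = 0,
                                background_level = 0.85, tissue_level = 0.35,
                                post_level = 0.2,
                                boundary_softness = 1.2,
                                seed = 1L) {
  stop_if(plateau_area >= initial_area, "plateau_area must be below initial_area")
  stop_if(plateau_area <= 0, "plateau_area must be positive")
  stop_if(!is_count(n_frames) || n_frames < 2, "n_frames must be a count >= 2")
  stop_if(pixel_size <= 0, "pixel_size must be positive")
  stop_if(compaction_rate < 0, "compaction_rate must be non-negative")
  duration <- (n_frames - 1) * frame_interval
  if (!is.null(release_time)) {
    stop_if(release_time < 0 || release_time > duration,
            "release_time must lie within [0, %g] h", duration)
  }
  structure(list(frame_size = frame_size, pixel_size = pixel_size,
                 post_layout = post_layout, n_posts = nrow(post_layout),
                 initial_area = initial_area, plateau_area = plateau_area,
                 compaction_rate = compaction_rate, release_time = release_time,
                 frame_interval = frame_interval, n_frames = as.integer(n_frames),
                 noise_sd = noise_sd, illumination_gradient = illumination_gradient,
                 background_level = background_level, tissue_level = tissue_level,
                 post_level = post_level, boundary_softness = boundary_softness,
                 seed = as.integer(seed)),
            class = "tissue_scene_params")
}

#' Closed-form compaction decay law
#'
#' @param t hours.
#' @param initial,plateau mm^2.
#' @param rate per hour.
#' @return area in mm^2.
#' @export
compaction_area <- function(t, initial, plateau, rate) {
  plateau + (initial - plateau) * exp(-rate * t)
}

## star-convex radius profile: ellipse base times low-order harmonic
## perturbation; returns a function of theta with unit mean-square radius
silhouette_profile <- function(aspect, eps, phase) {
  a <- sqrt(aspect); b <- 1 / sqrt(aspect)
  function(theta) {
    base <- 1 / sqrt((cos(theta) / a)^2 + (sin(theta) / b)^2)
    pert <- 1 + eps[1] * cos(2 * theta + phase[1]) +
      eps[2] * cos(3 * theta + phase[2]) +
      eps[3] * cos(4 * theta + phase[3])
    base * pert
  }
}

## numeric scale s so that the polygon r = s * g(theta) has area S (px^2)
profile_scale <- function(g, S) {
  th <- seq(0, 2 * pi, length.out = 1441L)[-1441L]
  sqrt(2 * S / sum(g(th)^2 * (2 * pi / 1440)))
}

#' Render a compacting micro-tissue time-lapse with ground truth
#'
#' Each frame holds a dark, smooth, star-convex silhouette spanning the
#' anchored posts over an (optionally shaded) background, with the anchoring
#' posts drawn as dark discs and additive Gaussian noise.  Until
#' `release_time` the silhouette area follows the closed-form decay law and
#' overlaps every anchored post; from `release_time` on, the tissue is
#' rendered as a small detached elongated blob overlapping no post (the
#' anisotropic collapse after release).
#'
#' @param scene a [tissue_scene_params()].
#' @return list of class `timelapse_scene` with elements `frames` (list of
#'   unit-interval matrices), `masks` (ground-truth silhouette masks),
#'   `areas_mm2` (ground-truth mask areas: pixel count times pixel area),
#'   `areas_model` (the closed-form decay law at the frame times, `NA` after
#'   release), `times` (h), `released_frame` (index of first post-release
#'   frame or `NA`) and `params`.
#' @export
render_timelapse <- function(scene = tissue_scene_params()) {
  stop_if(!inherits(scene, "tissue_scene_params"),
          "scene must come from tissue_scene_params()")
  p <- scene
  nr <- p$frame_size[1]; nc <- p$frame_size[2]
  px_per_mm2 <- 1e6 / p$pixel_size^2
  times <- (seq_len(p$n_frames) - 1) * p$frame_interval
  cy <- nr / 2; cx <- nc / 2

  row_i <- matrix(seq_len(nr), nr, nc)
  col_i <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dx <- col_i - cx; dy <- row_i - cy
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)

  shape <- with_seed(derive_seed(p$seed, "shape"), {
    list(eps = runif(3, 0, 0.03), phase = runif(3, 0, 2 * pi))
  })
  grad <- p$illumination_gradient * ((col_i - 1) / (nc - 1) - 0.5)

  anchored <- p$post_layout[!p$post_layout$released, , drop = FALSE]
  post_alpha <- matrix(0, nr, nc)
  for (k in seq_len(nrow(anchored))) {
    d <- sqrt((col_i - anchored$x[k])^2 + (row_i - anchored$y[k])^2)
    post_alpha <- pmax(post_alpha,
                       clamp((anchored$r[k] - d) / p$boundary_softness + 0.5, 0, 1))
  }

  released_at <- if (is.null(p$release_time)) NA_integer_ else
    which(times >= p$release_time)[1]

  ## detached silhouette: fixed elongated blob between the anchor rows
  detached_a_px <- 600 / p$pixel_size
  detached_b_px <- 240 / p$pixel_size

  frames <- vector("list", p$n_frames)
  masks <- vector("list", p$n_frames)
  areas_mm2 <- numeric(p$n_frames)
  areas_model <- numeric(p$n_frames)

  noise_seed <- derive_seed(p$seed, "noise")
  for (i in seq_len(p$n_frames)) {
    t <- times[i]
    post_release <- !is.na(released_at) && i >= released_at
    if (!post_release) {
      A <- compaction_area(t, p$initial_area, p$plateau_area, p$compaction_rate)
      progress <- if (p$initial_area > p$plateau_area)
        1 - (A - p$plateau_area) / (p$initial_area - p$plateau_area) else 0
      aspect <- 1.05 + 0.3 * progress
      g <- silhouette_profile(aspect, shape$eps, shape$phase)
      s <- profile_scale(g, A * px_per_mm2)
      edge <- s * g(theta) - rho
      areas_model[i] <- A
    } else {
      edge <- 1 - sqrt((dx / detached_a_px)^2 + (dy / detached_b_px)^2)
      ## signed distance approximation near the ellipse boundary
      edge <- edge * min(detached_a_px, detached_b_px)
      areas_model[i] <- NA_real_
    }
    alpha <- clamp(edge / p$boundary_softness + 0.5, 0, 1)
    mask <- edge >= 0
    img <- p$background_level * (1 - alpha) + p$tissue_level * alpha
    img <- img * (1 - post_alpha) + p$post_level * post_alpha
    img <- img + grad
    if (p$noise_sd > 0) {
      img <- img + with_seed(noise_seed + i, matrix(rnorm(nr * nc, 0, p$noise_sd), nr, nc))
    }
    frames[[i]] <- clamp(img, 0, 1)
    masks[[i]] <- mask
    areas_mm2[i] <- sum(mask) / px_per_mm2
  }

  structure(list(frames = frames, masks = masks, areas_mm2 = areas_mm2,
                 areas_model = areas_model, times = times,
                 released_frame = released_at, params = p),
            class = "timelapse_scene")
}

#' @export
print.timelapse_scene <- function(x, ...) {
  cat(sprintf("<timelapse_scene: %d frames %dx%d px, %s>\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              if (is.na(x$released_frame)) "intact"
              else sprintf("release at frame %d", x$released_frame)))
  invisible(x)
}
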