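#' Automatic grey-value threshold by between-class variance maximization
#'
#' Builds an intensity histogram over the frame's own range and returns the
#' threshold that maximizes the between-class variance (Otsu's criterion);
#' ties are broken towards the lowest threshold.  Because the histogram is
#' built on the frame's own min-max range, the selected *class partition* is
#' invariant under any positive affine rescaling of the intensities.
#'
#' @param x numeric matrix or vector of intensities.
#' @param levels number of histogram bins (default 256).
#' @return the threshold intensity, with attribute `degenerate = TRUE` and an
#'   `NA` value when the frame has no intensity spread to separate.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  stop_if(length(v) == 0L, "no finite intensities")
  lo <- min(v); hi <- max(v)
  if (hi - lo <= .Machine$double.eps * max(abs(hi), 1)) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  bin <- pmin(pmax(floor((v - lo) / (hi - lo) * levels) + 1L, 1L), levels)
  cnt <- tabulate(bin, nbins = levels)
  p <- cnt / sum(cnt)
  mids <- lo + (seq_len(levels) - 0.5) * (hi - lo) / levels
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_tot <- mu0[levels]
  ## between-class variance for thresholds after bin k = 1..levels-1
  k <- seq_len(levels - 1L)
  w <- w0[k]; m <- mu0[k]
  valid <- w > 0 & w < 1
  sb <- rep(-Inf, levels - 1L)
  sb[valid] <- (mu_tot * w[valid] - m[valid])^2 / (w[valid] * (1 - w[valid]))
  if (!any(is.finite(sb))) return(structure(NA_real_, degenerate = TRUE))
  kbest <- which.max(sb)  # first maximum: lowest threshold on ties
  thr <- lo + kbest * (hi - lo) / levels
  structure(thr, degenerate = FALSE)
}

#' Binarize an image frame at a grey-value threshold
#'
#' @param frame an [image_frame()] or a numeric matrix.
#' @param threshold a numeric intensity, or `"auto"` for between-class
#'   variance maximization via [otsu_threshold()].
#' @param tissue_dark logical; `TRUE` (brightfield default) marks pixels at or
#'   below the threshold as tissue, `FALSE` flips the side.
#' @return logical mask with attributes `threshold` and `degenerate`.
#' @export
binarize <- function(frame, threshold = "auto", tissue_dark = TRUE) {
  x <- frame_data(frame)
  degenerate <- FALSE
  if (identical(threshold, "auto")) {
    thr <- otsu_threshold(x)
    if (isTRUE(attr(thr, "degenerate"))) {
      degenerate <- TRUE
      thr <- NA_real_
    }
  } else {
    stop_if(!is.numeric(threshold) || length(threshold) != 1L,
            "threshold must be a single number or \"auto\"")
    rng <- range(x)
    stop_if(threshold < rng[1] || threshold > rng[2],
            "fixed threshold %.4g outside frame intensity range [%.4g, %.4g]",
            threshold, rng[1], rng[2])
    thr <- as.numeric(threshold)
  }
  mask <- if (degenerate) {
    matrix(FALSE, nrow(x), ncol(x))
  } else if (tissue_dark) x <= thr else x >= thr
  structure(mask, threshold = as.numeric(thr), degenerate = degenerate)
}
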