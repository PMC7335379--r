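# Independent brute-force oracles used to cross-check the package's
# implementations.  These deliberately use naive algorithms (stack-based
# flood fill, explicit normal equations, iteratively refined grid search)
# that share no code with the package.

# -- flood-fill connected components (8-connectivity) ------------------------
oracle_label_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  if (connectivity == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1); dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 0, 0, 1); dc <- c(0, -1, 1, 0)
  }
  ## visit in row-major order so labels are comparable to the package's
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_along(dr)) {
        r <- p[1] + dr[k]; c <- p[2] + dc[k]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# largest component + hole fill, entirely via the flood-fill labeler
oracle_largest_component_fill <- function(mask) {
  lab <- oracle_label_components(mask, 8)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  comp <- lab == which.max(sizes)
  bg <- oracle_label_components(!comp, 4)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border != 0L]
  comp | (bg != 0L & !(bg %in% border))
}

# -- ordinary least squares by explicit normal equations ---------------------
oracle_ols <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  tval <- beta / se
  p <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(estimate = as.numeric(beta), se = as.numeric(se), p = as.numeric(p), r2 = r2)
}

# -- logistic MLE by iteratively refined grid search (2 parameters) ----------
oracle_logit_grid <- function(y, x, span = 5, steps = 4, n_grid = 81) {
  nll <- function(b0, b1) {
    eta <- b0 + b1 * x
    -sum(y * eta - log1p(exp(eta)))
  }
  centre <- c(0, 0); width <- span
  for (s in seq_len(steps)) {
    g0 <- seq(centre[1] - width, centre[1] + width, length.out = n_grid)
    g1 <- seq(centre[2] - width, centre[2] + width, length.out = n_grid)
    vals <- outer(g0, g1, Vectorize(nll))
    best <- arrayInd(which.min(vals), dim(vals))
    centre <- c(g0[best[1]], g1[best[2]])
    width <- width * 2 / (n_grid - 1) * 4   # shrink around the best cell
  }
  centre
}

# -- Tukey-fence outliers with hand-rolled interpolated quartiles ------------
oracle_tukey_outliers <- function(x) {
  s <- sort(x)
  n <- length(s)
  interp_q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  q1 <- interp_q(0.25); q3 <- interp_q(0.75)
  iqr <- q3 - q1
  x < q1 - 1.5 * iqr | x > q3 + 1.5 * iqr
}

# -- shared fixture builders -------------------------------------------------
# a default log-linear migration map matching the renderer's calibration
default_map <- function() {
  w <- c(250, 150, 100, 75, 50, 37, 25)
  calibrate_migration(migration_row(w, c(787.5, -139)), w)
}

# deterministic programmed release time for scene batteries
runif_release <- function(seed) {
  set.seed(seed)
  runif(1, 5, 40)
}

# a small, quick scene for segmentation tests
quick_scene <- function(seed = 1, ...) {
  tissue_scene_params(n_frames = 2L, frame_interval = 48, seed = seed, ...)
}

render_frame <- function(scene, index = 1) {
  rt <- render_timelapse(scene)
  image_frame(rt$frames[[index]], scene$pixel_size, rt$times[index])
}
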