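#' Label connected components of a binary mask
#'
#' Run-based two-pass labeling with union-find.  Components are numbered in
#' order of their first pixel in a row-major (top-left to bottom-right) scan,
#' so label 1 always contains the lexicographically smallest pixel of any
#' component — this is the documented tie-break used when two components have
#' equal size.
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 8 (default, diagonal neighbours connect) or 4.
#' @return integer matrix of the same shape; 0 is background.
#' @export
label_components <- function(mask, connectivity = 8) {
  stop_if(!is.matrix(mask), "mask must be a matrix")
  stop_if(!connectivity %in% c(4L, 8L), "connectivity must be 4 or 8")
  m <- mask
  storage.mode(m) <- "logical"
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  if (!any(m)) return(out)

  ## row-major traversal with one padding cell after each row, so runs never
  ## wrap across rows
  v <- as.logical(rbind(t(m), FALSE))
  dstart <- diff(c(FALSE, v))
  starts <- which(dstart == 1L)
  ends <- which(diff(c(v, FALSE)) == -1L)
  run_row <- (starts - 1L) %/% (nc + 1L) + 1L
  c1 <- (starts - 1L) %% (nc + 1L) + 1L
  c2 <- (ends - 1L) %% (nc + 1L) + 1L
  n_run <- length(starts)

  parent <- seq_len(n_run)
  uf_find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  uf_union <- function(i, j) {
    ri <- uf_find(i); rj <- uf_find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }

  slack <- if (connectivity == 8L) 1L else 0L
  by_row <- split(seq_len(n_run), run_row)
  row_ids <- as.integer(names(by_row))
  for (k in seq_along(row_ids)[-1]) {
    if (row_ids[k] - row_ids[k - 1L] != 1L) next
    a <- by_row[[k - 1L]]; b <- by_row[[k]]
    i <- 1L; j <- 1L
    while (i <= length(a) && j <= length(b)) {
      ai <- a[i]; bj <- b[j]
      if (c1[ai] <= c2[bj] + slack && c1[bj] <= c2[ai] + slack) uf_union(ai, bj)
      if (c2[ai] < c2[bj]) i <- i + 1L
      else if (c2[bj] < c2[ai]) j <- j + 1L
      else { i <- i + 1L; j <- j + 1L }
    }
  }

  roots <- vapply(seq_len(n_run), uf_find, integer(1))
  ## relabel so components appear in order of first run (row-major scan)
  lab_of_root <- integer(n_run)
  nxt <- 0L
  run_lab <- integer(n_run)
  for (i in seq_len(n_run)) {
    r <- roots[i]
    if (lab_of_root[r] == 0L) { nxt <- nxt + 1L; lab_of_root[r] <- nxt }
    run_lab[i] <- lab_of_root[r]
  }

  padded <- integer((nc + 1L) * nr)
  lens <- ends - starts + 1L
  padded[sequence(lens, from = starts)] <- rep(run_lab, lens)
  out <- t(matrix(padded, nrow = nc + 1L)[seq_len(nc), , drop = FALSE])
  out
}

#' Fill interior holes of a binary mask
#'
#' Background regions (4-connected) that do not touch the image border are
#' considered holes and set to foreground.
#'
#' @param mask logical matrix.
#' @return logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  m <- mask
  storage.mode(m) <- "logical"
  bg <- label_components(!m, connectivity = 4)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels != 0L]
  holes <- bg != 0L & !(bg %in% border_labels)
  m | holes
}

#' Keep the largest connected component and fill its holes
#'
#' Selects the largest 8-connected component (ties broken by the component
#' containing the smallest row-major pixel index) and fills interior holes
#' (4-connected background regions not reaching the image border).
#'
#' @param mask logical matrix.
#' @return logical matrix: one filled component, or an all-`FALSE` matrix with
#'   attribute `flag = "no-tissue"` when the input has no foreground pixel.
#' @export
largest_component_fill <- function(mask) {
  m <- mask
  storage.mode(m) <- "logical"
  if (!any(m)) {
    attr(m, "flag") <- "no-tissue"
    return(m)
  }
  lab <- label_components(m, connectivity = 8)
  sizes <- tabulate(lab[lab != 0L])
  keep <- which.max(sizes)  # first maximum = smallest row-major first pixel
  fill_holes(lab == keep)
}
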