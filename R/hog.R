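# Histogram-of-oriented-gradients features. Unsigned orientations, square
# cells, 2x2-cell blocks with L2 normalization, per-channel extraction and
# channel-wise concatenation.

#' HOG descriptor configuration
#'
#' Defaults follow the standard pedestrian-detection setup: a 64 x 128 pixel
#' canonical window, 8 x 8 pixel cells, 2 x 2 cell blocks (stride one cell)
#' and 9 unsigned orientation bins, giving 3780 features per channel.
#'
#' @param window_w,window_h canonical window size in pixels.
#' @param cell_size_px square cell side in pixels.
#' @param block_size_cells block side in cells.
#' @param n_orientations number of unsigned orientation bins over \[0, pi).
#' @param per_channel extract each color channel separately and concatenate?
#' @return object of class `hog_descriptor`.
#' @export
hog_descriptor <- function(window_w = 64, window_h = 128, cell_size_px = 8,
                           block_size_cells = 2, n_orientations = 9,
                           per_channel = TRUE) {
  stopifnot(window_w >= cell_size_px, window_h >= cell_size_px,
            cell_size_px >= 2, block_size_cells >= 1, n_orientations >= 2)
  if (window_w %% cell_size_px != 0 || window_h %% cell_size_px != 0)
    stop("window must be a whole number of cells")
  structure(list(window_w = window_w, window_h = window_h,
                 cell_size_px = cell_size_px,
                 block_size_cells = block_size_cells,
                 n_orientations = n_orientations,
                 per_channel = per_channel),
            class = "hog_descriptor")
}

#' Length of the descriptor produced by [extract_hog()]
#' @param desc a [hog_descriptor()].
#' @param n_channels number of image channels.
#' @return integer.
#' @export
hog_length <- function(desc, n_channels = 1) {
  cw <- desc$window_w / desc$cell_size_px
  ch <- desc$window_h / desc$cell_size_px
  b <- desc$block_size_cells
  nb <- max(0, cw - b + 1) * max(0, ch - b + 1)
  as.integer(nb * b * b * desc$n_orientations * n_channels)
}

# resize an h x w matrix (rows = y) to nr x nc using EBImage
.resize_mat <- function(m, nr, nc) {
  if (nrow(m) == nr && ncol(m) == nc) return(m)
  out <- EBImage::resize(m, w = nr, h = nc)
  matrix(as.numeric(out), nr, nc)
}

# cell orientation histograms of one channel; returns [ch_cells, cw_cells, nb]
.hog_cells <- function(m, cell, nbins) {
  h <- nrow(m); w <- ncol(m)
  # central differences, replicated borders
  gx <- (m[, c(2:w, w)] - m[, c(1, 1:(w - 1))]) / 2
  gy <- (m[c(2:h, h), ] - m[c(1, 1:(h - 1)), ]) / 2
  mag <- sqrt(gx * gx + gy * gy)
  ang <- atan2(gy, gx) %% pi                     # unsigned orientation
  bin <- pmin(nbins - 1, floor(ang / (pi / nbins)))
  ch <- h %/% cell; cw <- w %/% cell
  row_cell <- (seq_len(h) - 1) %/% cell
  col_cell <- (seq_len(w) - 1) %/% cell
  cell_id <- outer(row_cell, col_cell, function(r, c) r + c * ch)
  idx <- cell_id * nbins + bin + 1
  keep <- row_cell[row(m)] < ch & col_cell[col(m)] < cw  # drop partial cells
  acc <- numeric(ch * cw * nbins)
  sums <- rowsum(as.numeric(mag[keep]), as.integer(idx[keep]))
  acc[as.integer(rownames(sums))] <- sums
  array(acc, dim = c(nbins, ch, cw))  # [bin, cell_row, cell_col]
}

# block-normalized descriptor from cell histograms
.hog_blocks <- function(cells, b) {
  nbins <- dim(cells)[1]; ch <- dim(cells)[2]; cw <- dim(cells)[3]
  nby <- ch - b + 1; nbx <- cw - b + 1
  out <- numeric(nby * nbx * b * b * nbins)
  k <- 0L
  for (bx in seq_len(nbx)) for (by in seq_len(nby)) {
    v <- as.numeric(cells[, by:(by + b - 1), bx:(bx + b - 1)])
    nrm <- sqrt(sum(v * v))
    if (nrm > 1e-12) v <- v / nrm
    out[k + seq_along(v)] <- v
    k <- k + length(v)
  }
  out
}

#' Extract a HOG feature vector from an image region
#'
#' The region is resampled to the descriptor's canonical window, gradient
#' orientation histograms are accumulated per cell, block-normalized (L2)
#' and concatenated; multi-channel input is processed per channel and the
#' channel descriptors concatenated.
#'
#' @param region grayscale matrix (rows = y) or `h x w x channels` array,
#'   values in \[0, 1\].
#' @param desc a [hog_descriptor()].
#' @return nonnegative numeric feature vector.
#' @export
extract_hog <- function(region, desc = hog_descriptor()) {
  stopifnot(inherits(desc, "hog_descriptor"))
  dm <- dim(region)
  if (is.null(dm) || dm[1] < 2 || dm[2] < 2)
    stop("region must be at least one cell in each dimension")
  chans <- if (length(dm) == 3 && desc$per_channel) {
    lapply(seq_len(dm[3]), function(k) region[, , k])
  } else if (length(dm) == 3) {
    list(apply(region, c(1, 2), mean))
  } else list(region)
  unlist(lapply(chans, function(m) {
    m <- .resize_mat(m, desc$window_h, desc$window_w)
    .hog_blocks(.hog_cells(m, desc$cell_size_px, desc$n_orientations),
                desc$block_size_cells)
  }), use.names = FALSE)
}
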