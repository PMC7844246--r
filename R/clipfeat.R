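# Fixed-length clip feature vectors: per-frame HOG concatenated over a
# canonical number of frames, optionally PCA-projected, with physics-based
# fall parameters appended as extra design-matrix columns.

# physics columns: max V, max |a|, final theta, final H / H_0, duration of
# the true-fall (high-velocity) phase in seconds
.physics_columns <- function(series) {
  if (is.null(series) || nrow(series) < 2)
    return(c(v_max = 0, a_max = 0, theta_final = 90, h_final_ratio = 1,
             true_fall_s = 0))
  V <- series$V; a <- series$a
  v_max <- if (all(is.na(V))) 0 else max(V, na.rm = TRUE)
  a_max <- if (all(is.na(a))) 0 else max(abs(a), na.rm = TRUE)
  nlast <- nrow(series)
  theta_final <- series$theta[nlast]
  H_0 <- attr(series, "H_0")
  h_final_ratio <- series$H[nlast] / H_0
  dur <- 0
  if (v_max > 0.3) {
    hi <- which(!is.na(V) & V > 0.5 * v_max)
    if (length(hi)) dur <- series$T[max(hi)] - series$T[min(hi)] +
        (attr(series, "dT") %||% 0)
  }
  c(v_max = v_max, a_max = a_max, theta_final = theta_final,
    h_final_ratio = h_final_ratio, true_fall_s = dur)
}

`%||%` <- function(a, b)
  if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Fixed-length feature vector for a cropped clip
#'
#' Resamples the cropped frame sequence to a canonical frame count
#' (uniform temporal resampling), extracts per-frame HOG descriptors,
#' concatenates them, optionally projects with a fitted PCA projector, and
#' appends five physics columns derived from the fall-parameter series:
#' max `V_i`, max `|a_i|`, final `theta_i`, final `H_i / H_0` and the
#' duration of the high-velocity (true fall) phase. Physics columns are
#' standardized by the training-set center/scale when supplied.
#'
#' @param crops list of grayscale matrices (the per-frame crops of a path).
#' @param desc a [hog_descriptor()].
#' @param projector optional [fit_pca()] projector for the HOG block.
#' @param series optional [extract_series()] result for the same path.
#' @param n_frames canonical clip length (frames).
#' @param physics_center,physics_scale optional numeric(5) standardization.
#' @return numeric feature vector of length `k + 5` (projected) or
#'   `n_frames * hog_length + 5`.
#' @export
clip_features <- function(crops, desc = hog_descriptor(), projector = NULL,
                          series = NULL, n_frames = 16,
                          physics_center = NULL, physics_scale = NULL) {
  if (length(crops) == 0) stop("empty clip")
  idx <- round(seq(1, length(crops), length.out = n_frames))
  hog <- unlist(lapply(crops[idx], extract_hog, desc = desc),
                use.names = FALSE)
  if (!is.null(projector)) hog <- drop(predict(projector, hog))
  phys <- .physics_columns(series)
  if (!is.null(physics_center)) phys <- phys - physics_center
  if (!is.null(physics_scale)) {
    sc <- ifelse(physics_scale > 1e-12, physics_scale, 1)
    phys <- phys / sc
  }
  c(hog, phys)
}
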