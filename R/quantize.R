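#' Lloyd-Max scalar quantization
#'
#' MSE-optimal scalar quantizer fitted to the ROI's intensities by Lloyd's
#' iteration: centroids are conditional means of their cells, cell boundaries
#' are centroid midpoints. Initialization is at equal-probability quantiles;
#' iteration stops when the relative change in within-cell MSE falls below
#' `tol` or after `max_iter` sweeps. Fitted per ROI and per subject, so all
#' downstream texture features are invariant to global affine intensity
#' rescaling.
#'
#' @param values Numeric vector of ROI voxel intensities.
#' @param n_levels Number of gray levels `Ng` (default 64).
#' @param tol Relative MSE convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 500).
#' @return A `lloyd_quantizer`: list with `levels` (integer codes 1..Ng per
#'   input value), `boundaries` (length Ng - 1), `centroids` (length Ng),
#'   `n_levels`, `mse` and `degenerate` (TRUE when the input is constant,
#'   in which case a single level is used).
#' @export
lloyd_max_quantize <- function(values, n_levels = 64, tol = 1e-6,
                               max_iter = 500) {
  stopifnot(n_levels >= 2)
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty input", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite intensities", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) {
    return(structure(list(
      levels = rep(1L, length(values)), boundaries = numeric(0),
      centroids = rng[1], n_levels = 1L, mse = 0, degenerate = TRUE
    ), class = "lloyd_quantizer"))
  }
  uq <- sort(unique(values))
  ng <- min(n_levels, length(uq))
  # equal-probability quantile initialization
  cent <- as.numeric(quantile(values, probs = (seq_len(ng) - 0.5) / ng,
                              type = 8))
  cent <- sort(unique(cent))
  ng <- length(cent)
  mse_prev <- Inf
  # cell statistics via order statistics: with values sorted once, each
  # centroid/MSE sweep reduces to cumulative-sum differences at the
  # boundary positions (values tied with a boundary belong to the upper
  # cell, matching findInterval(values, bounds) + 1)
  xs <- sort(values)
  n <- length(xs)
  cs1 <- c(0, cumsum(xs))
  cs2 <- c(0, cumsum(xs * xs))
  cell_cuts <- function(centers) {
    bounds <- (centers[-length(centers)] + centers[-1]) / 2
    idx <- findInterval(bounds, xs, left.open = TRUE)
    list(starts = c(0L, idx), ends = c(idx, n))
  }
  for (it in seq_len(max_iter)) {
    cut <- cell_cuts(cent)
    cnt <- cut$ends - cut$starts
    s1 <- cs1[cut$ends + 1L] - cs1[cut$starts + 1L]
    means <- s1 / cnt
    # empty cells inherit their previous centroid
    means[cnt == 0] <- cent[cnt == 0]
    cent_new <- sort(means)
    cut2 <- cell_cuts(cent_new)
    cnt2 <- cut2$ends - cut2$starts
    ss1 <- cs1[cut2$ends + 1L] - cs1[cut2$starts + 1L]
    ss2 <- cs2[cut2$ends + 1L] - cs2[cut2$starts + 1L]
    mse <- max(sum(ss2 - 2 * cent_new * ss1 + cnt2 * cent_new^2) / n, 0)
    cent <- cent_new
    if (mse == 0 ||
        (is.finite(mse_prev) &&
         abs(mse_prev - mse) <= tol * max(mse_prev, .Machine$double.eps))) {
      mse_prev <- mse
      break
    }
    mse_prev <- mse
  }
  bounds <- (cent[-length(cent)] + cent[-1]) / 2
  code <- findInterval(values, bounds) + 1L
  structure(list(
    levels = code, boundaries = bounds, centroids = cent,
    n_levels = as.integer(ng), mse = mse_prev, degenerate = FALSE
  ), class = "lloyd_quantizer")
}

# Build the quantized-ROI integer array (0 outside the ROI) for the texture
# matrix routines.
quantized_roi_array <- function(vol, voxels, n_levels = 64) {
  q <- lloyd_max_quantize(vol$data[voxels], n_levels = n_levels)
  d <- dim(vol$data)
  # crop to the ROI bounding box to keep matrix passes cheap
  coords <- arrayInd(voxels, d)
  lo <- apply(coords, 2, min); hi <- apply(coords, 2, max)
  sub_dim <- hi - lo + 1L
  arr <- array(0L, dim = sub_dim)
  sub_idx <- (coords[, 1] - lo[1] + 1L) +
    sub_dim[1] * ((coords[, 2] - lo[2] + 1L) - 1L) +
    sub_dim[1] * sub_dim[2] * ((coords[, 3] - lo[3] + 1L) - 1L)
  arr[sub_idx] <- q$levels
  list(levels = arr, n_levels = q$n_levels, quantizer = q)
}
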