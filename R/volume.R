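#' 3D image volumes
#'
#' A `pet_volume` is a 3D numeric array with per-axis voxel spacing in mm.
#' Volumes are the currency of every pipeline stage: all stages require
#' matching geometry (identical dimensions and spacing) and refuse to resample
#' silently.
#'
#' @param data 3D numeric array.
#' @param spacing Numeric length-3, voxel size in mm (all > 0).
#' @return A `pet_volume` object.
#' @export
#' @examples
#' v <- pet_volume(array(1, dim = c(4, 4, 4)), spacing = c(2, 2, 2))
#' dim(v$data)
pet_volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive finite values (mm)", call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("volume contains non-finite values", call. = FALSE)
  }
  structure(list(data = data, spacing = spacing), class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf(
    "<pet_volume> %s voxels @ %s mm, range [%.4g, %.4g]\n",
    paste(dim(x$data), collapse = "x"),
    paste(signif(x$spacing, 4), collapse = "x"),
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads a single 3D volume (NIfTI-1/2, optionally gzipped). Trailing
#' singleton dimensions (e.g. a 4D file with one time point) are squeezed;
#' more than three non-singleton dimensions is an error.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A [pet_volume()] with spacing taken from the header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d)) stop("not a volumetric image: ", path, call. = FALSE)
  nonsingleton <- which(d > 1L)
  if (length(nonsingleton) > 3L) {
    stop("image has ", length(nonsingleton),
         " non-singleton dimensions; expected <= 3", call. = FALSE)
  }
  arr <- array(as.numeric(img), dim = d)
  if (length(d) > 3L) {
    keep <- d[seq_len(3L)]
    arr <- array(as.numeric(arr), dim = keep)
    d <- keep
  }
  if (length(d) < 3L) {
    arr <- array(as.numeric(arr), dim = c(d, rep(1L, 3L - length(d))))
  }
  sp <- RNifti::pixdim(img)[seq_len(3)]
  sp[!is.finite(sp) | sp <= 0] <- 1
  pet_volume(arr, spacing = sp)
}

#' Write a volume to NIfTI
#'
#' Data are stored as float32; internal computation stays in double.
#'
#' @param vol A [pet_volume()] (or a 3D array of labels for masks/atlases).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param datatype NIfTI storage type, `"float"` (default) or `"int16"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "float") {
  stopifnot(inherits(vol, "pet_volume") || inherits(vol, "label_map"))
  arr <- if (inherits(vol, "label_map")) vol$labels else vol$data
  img <- RNifti::asNifti(arr)
  img$pixdim <- c(-1, vol$spacing, 1, 1, 1, 1)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

same_geometry <- function(a, b, tol = 1e-6) {
  da <- if (inherits(a, "label_map")) dim(a$labels) else dim(a$data)
  db <- if (inherits(b, "label_map")) dim(b$labels) else dim(b$data)
  identical(da, db) && all(abs(a$spacing - b$spacing) < tol)
}

check_geometry <- function(a, b, what = "inputs") {
  if (!same_geometry(a, b)) {
    stop("geometry mismatch between ", what,
         " (dimensions/spacing must agree exactly)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian convolution with the kernel width given as full width
#' at half maximum in mm (the neuroimaging convention); per-axis sigma in
#' voxels is `fwhm / (2 * sqrt(2 * log(2))) / spacing`. The boundary is
#' handled by nearest-edge replication, so total intensity is conserved for
#' structure away from the edges.
#'
#' @param vol A [pet_volume()].
#' @param fwhm_mm Kernel FWHM in mm (default 8, the usual PET smoothing).
#' @param boundary `"replicate"` (default) or `"zero"`.
#' @return Smoothed [pet_volume()].
#' @export
gaussian_smooth <- function(vol, fwhm_mm = 8, boundary = c("replicate", "zero")) {
  stopifnot(inherits(vol, "pet_volume"))
  boundary <- match.arg(boundary)
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || !is.finite(fwhm_mm) ||
      fwhm_mm <= 0) {
    stop("`fwhm_mm` must be a positive scalar", call. = FALSE)
  }
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vol$spacing
  arr <- vol$data
  for (axis in 1:3) {
    arr <- convolve_axis(arr, sigma_vox[axis], axis, boundary)
  }
  pet_volume(arr, spacing = vol$spacing)
}

# 1D Gaussian convolution along one axis via a banded operator matrix;
# replicate boundary folds clamped taps back into the edge rows.
convolve_axis <- function(arr, sigma, axis, boundary) {
  n <- dim(arr)[axis]
  radius <- max(1L, ceiling(4 * sigma))
  taps <- stats::dnorm(seq(-radius, radius), sd = sigma)
  taps <- taps / sum(taps)
  K <- matrix(0, n, n)
  for (k in seq(-radius, radius)) {
    w <- taps[k + radius + 1L]
    for_out <- seq_len(n)
    src <- for_out + k
    if (boundary == "replicate") {
      src <- pmin(pmax(src, 1L), n)
      for (o in for_out) K[o, src[o]] <- K[o, src[o]] + w
    } else {
      ok <- src >= 1L & src <= n
      K[cbind(for_out[ok], src[ok])] <- K[cbind(for_out[ok], src[ok])] + w
    }
  }
  apply_axis_operator(arr, K, axis)
}

# Multiply a (n_out x n_in) operator along the given axis of a 3D array.
apply_axis_operator <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  res <- K %*% m
  d_out <- d
  d_out[axis] <- nrow(K)
  out <- array(res, dim = c(nrow(K), d[setdiff(1:3, axis)]))
  aperm(out, order(perm))
}

#' Resample a volume to an isotropic grid
#'
#' Trilinear interpolation (or nearest neighbor, for label images) onto a
#' cell-centered grid with identical physical extent. If the volume is
#' already at the target spacing the data are returned unchanged.
#'
#' @param vol A [pet_volume()] or [label_map()].
#' @param iso_mm Target isotropic voxel size in mm (default 2).
#' @param method `"trilinear"` (default; forced to `"nearest"` for label maps).
#' @return Resampled object of the same class.
#' @export
resample_isotropic <- function(vol, iso_mm = 2,
                               method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  if (!is.numeric(iso_mm) || length(iso_mm) != 1L || !is.finite(iso_mm) ||
      iso_mm <= 0) {
    stop("`iso_mm` must be a positive scalar", call. = FALSE)
  }
  is_labels <- inherits(vol, "label_map")
  if (is_labels) method <- "nearest"
  arr <- if (is_labels) vol$labels else vol$data
  sp <- vol$spacing
  if (all(abs(sp - iso_mm) < 1e-9)) return(vol)
  d <- dim(arr)
  extent <- d * sp
  d_out <- pmax(1L, as.integer(round(extent / iso_mm)))
  if (any(extent < iso_mm / 2)) {
    stop("degenerate extent: axis shorter than half a target voxel",
         call. = FALSE)
  }
  # cell-centered physical coordinate of output voxel o: (o - 0.5) * iso
  # fractional input index: coord / spacing + 0.5 (1-based)
  out <- interp3(arr, d_out, iso_mm, sp, nearest = (method == "nearest"))
  if (is_labels) {
    label_map(out, spacing = rep(iso_mm, 3), lookup = vol$lookup)
  } else {
    pet_volume(out, spacing = rep(iso_mm, 3))
  }
}

interp3 <- function(arr, d_out, iso, sp, nearest = FALSE) {
  d <- dim(arr)
  fx <- pmin(pmax(((seq_len(d_out[1]) - 0.5) * iso) / sp[1] + 0.5, 1), d[1])
  fy <- pmin(pmax(((seq_len(d_out[2]) - 0.5) * iso) / sp[2] + 0.5, 1), d[2])
  fz <- pmin(pmax(((seq_len(d_out[3]) - 0.5) * iso) / sp[3] + 0.5, 1), d[3])
  if (nearest) {
    out <- arr[round(fx), round(fy), round(fz), drop = FALSE]
    return(array(out, dim = d_out))
  }
  x0 <- pmin(floor(fx), d[1] - 1L); wx <- fx - x0
  y0 <- pmin(floor(fy), d[2] - 1L); wy <- fy - y0
  z0 <- pmin(floor(fz), d[3] - 1L); wz <- fz - z0
  if (d[1] == 1L) { x0 <- rep(1, d_out[1]); wx <- rep(0, d_out[1]) }
  if (d[2] == 1L) { y0 <- rep(1, d_out[2]); wy <- rep(0, d_out[2]) }
  if (d[3] == 1L) { z0 <- rep(1, d_out[3]); wz <- rep(0, d_out[3]) }
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  WX <- array(wx, dim = d_out)
  WY <- array(rep(wy, each = d_out[1]), dim = d_out)
  WZ <- array(rep(wz, each = d_out[1] * d_out[2]), dim = d_out)
  g <- function(xi, yi, zi) array(arr[xi, yi, zi, drop = FALSE], dim = d_out)
  (1 - WX) * (1 - WY) * (1 - WZ) * g(x0, y0, z0) +
    WX * (1 - WY) * (1 - WZ) * g(x1, y0, z0) +
    (1 - WX) * WY * (1 - WZ) * g(x0, y1, z0) +
    WX * WY * (1 - WZ) * g(x1, y1, z0) +
    (1 - WX) * (1 - WY) * WZ * g(x0, y0, z1) +
    WX * (1 - WY) * WZ * g(x1, y0, z1) +
    (1 - WX) * WY * WZ * g(x0, y1, z1) +
    WX * WY * WZ * g(x1, y1, z1)
}
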