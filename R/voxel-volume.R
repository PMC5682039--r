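#' Voxel volume objects
#'
#' A `voxel_volume` is the unit of image I/O in npairspls: a 3-D scalar grid
#' (e.g. a parametric BP_ND image) together with its isotropic voxel size in
#' millimetres and a free-form metadata list (NIfTI header passthrough).
#' Voxel coordinates are 1-based array indices throughout the package.
#'
#' @param values numeric 3-D array of finite voxel values.
#' @param voxel_size_mm positive scalar, isotropic voxel edge length in mm.
#' @param meta optional list of metadata carried through I/O.
#'
#' @return An object of class `voxel_volume` with fields `values`,
#'   `voxel_size_mm` and `meta`.
#' @export
voxel_volume <- function(values, voxel_size_mm = 1, meta = list()) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array, got ", length(dim(values)), " dims")
  if (!all(is.finite(values)))
    stop("voxel values must all be finite")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      voxel_size_mm <= 0)
    stop("`voxel_size_mm` must be a single positive number")
  structure(
    list(values = values, voxel_size_mm = as.numeric(voxel_size_mm),
         meta = meta),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, %.3g mm isotropic\n",
              d[1], d[2], d[3], x$voxel_size_mm))
  cat(sprintf("  value range: [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$values)

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file (`.nii` or `.nii.gz`) into a [voxel_volume()].
#' The image must be 3-D with isotropic voxels; anisotropic input is an
#' error rather than being silently resampled.
#'
#' @param path path to a NIfTI file.
#' @param tol relative tolerance for the isotropy check on the header pixdims.
#' @return A [voxel_volume()]; the NIfTI header is kept in `meta$nifti_header`.
#' @export
read_volume <- function(path, tol = 1e-4) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D volume in ", path, ", got dims ",
         paste(dim(arr), collapse = " x "))
  pd <- RNifti::pixdim(img)[seq_len(3)]
  if (diff(range(pd)) > tol * mean(pd))
    stop("anisotropic voxels (", paste(signif(pd, 4), collapse = " x "),
         " mm) are not supported")
  voxel_volume(arr, voxel_size_mm = mean(pd),
               meta = list(nifti_header = RNifti::niftiHeader(img)))
}

#' Write a NIfTI volume
#'
#' @param v a [voxel_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "voxel_volume"))
  img <- RNifti::asNifti(v$values)
  RNifti::pixdim(img) <- rep(v$voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Truncated, renormalized 1-D Gaussian kernel (half-width 4 sigma).
gaussian_kernel_1d <- function(sigma_voxels) {
  r <- max(1L, ceiling(4 * sigma_voxels))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma_voxels^2))
  k / sum(k)
}

# Map out-of-range positions back into 1..n by half-sample reflection
# (... 2 1 | 1 2 ... n | n n-1 ...), valid for any overhang.
reflect_index <- function(pos, n) {
  if (n == 1L) return(rep(1L, length(pos)))
  m <- (pos - 1L) %% (2L * n)
  ifelse(m < n, m + 1L, 2L * n - m)
}

# Convolve a vector with a symmetric odd-length kernel, reflecting at edges.
convolve_reflect <- function(x, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  n <- length(x)
  pad <- x[reflect_index(seq.int(1L - r, n + r), n)]
  out <- stats::filter(pad, kernel, method = "convolution", sides = 2L)
  as.numeric(out[seq.int(r + 1L, r + n)])
}

#' Smooth a volume with an isotropic 3-D Gaussian filter
#'
#' Applies a separable Gaussian convolution with
#' `sigma_mm = fwhm_mm / (2 * sqrt(2 * log(2)))` and
#' `sigma_voxels = sigma_mm / voxel_size_mm`.  Edges are handled by
#' reflection.  `fwhm_mm = 0` returns the input unchanged.
#'
#' @param v a [voxel_volume()].
#' @param fwhm_mm full width at half maximum of the kernel, in mm (>= 0).
#' @return A smoothed [voxel_volume()] with the same grid and voxel size.
#' @export
gaussian_smooth <- function(v, fwhm_mm) {
  stopifnot(inherits(v, "voxel_volume"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0)
    stop("`fwhm_mm` must be a single non-negative number")
  if (fwhm_mm == 0) return(v)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / v$voxel_size_mm
  k <- gaussian_kernel_1d(sigma_vox)
  a <- v$values
  d <- dim(a)
  for (axis in 1:3) {
    a <- apply(a, setdiff(1:3, axis), convolve_reflect, kernel = k)
    # apply() returns the filtered axis first; rotate back into place
    perm <- order(c(axis, setdiff(1:3, axis)))
    a <- aperm(array(a, dim = c(d[axis], d[setdiff(1:3, axis)])), perm)
  }
  voxel_volume(a, v$voxel_size_mm, v$meta)
}
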