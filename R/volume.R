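#' Axis-aligned 3D volume with voxel spacing and world origin
#'
#' Lightweight container for CT intensities, probability maps and label
#' volumes. The world coordinate of voxel `(i, j, k)` (1-based) is
#' `origin + (c(i, j, k) - 1) * spacing`, i.e. an axis-aligned scaled grid;
#' rigid pose differences between volumes are represented by transforms
#' (see [affine_transform()]), not by oblique voxel grids.
#'
#' @param data numeric or integer 3D array.
#' @param spacing voxel spacing in mm, length 3.
#' @param origin world coordinate (mm) of the first voxel centre, length 3.
#' @return An object of class `ct_volume` with elements `data`, `spacing`,
#'   `origin`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got ", length(dim(data)), " dims")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' @export
as.array.ct_volume <- function(x, ...) x$data

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 3), collapse = " x ")))
  rng <- range(x$data, na.rm = TRUE)
  cat(sprintf("  intensity range [%.4g, %.4g], origin (%s) mm\n",
              rng[1], rng[2],
              paste(format(x$origin, digits = 3), collapse = ", ")))
  invisible(x)
}

is_ct_volume <- function(x) inherits(x, "ct_volume")

#' Check that two volumes share grid shape, spacing and origin
#' @param a,b `ct_volume` objects.
#' @param tol numeric tolerance on spacing/origin.
#' @return `TRUE` or `FALSE`.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) stop(what, " must share grid shape, spacing and origin")
  invisible(TRUE)
}

#' Voxel volume in millilitres
#' @param x a `ct_volume`.
#' @return Scalar voxel volume in ml (1 ml = 1000 mm^3).
#' @export
voxel_volume_ml <- function(x) prod(x$spacing) / 1000

#' Replace the data array of a volume, keeping its grid
#' @param x a `ct_volume`.
#' @param data replacement array with the same dimensions.
#' @return A new `ct_volume`.
#' @export
with_data <- function(x, data) {
  if (!identical(dim(data), dim(x$data))) stop("replacement dims differ")
  ct_volume(data, x$spacing, x$origin)
}

#' Read a NIfTI file as a `ct_volume`
#'
#' Spacing and origin are taken from the stored transform (sform/qform);
#' oblique orientations are not supported by this container and raise an
#' error.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @return A `ct_volume`.
#' @export
read_volume <- function(path) {
  im <- RNifti::readNifti(path)
  xf <- RNifti::xform(im)
  rot <- xf[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-4 * max(abs(rot)))
    stop("oblique NIfTI orientations are not supported: ", path)
  spacing <- abs(diag(rot))
  if (any(spacing == 0)) spacing <- RNifti::pixdim(im)[1:3]
  ct_volume(array(as.numeric(im), dim(im)[1:3]),
            spacing = spacing, origin = xf[1:3, 4])
}

#' Write a `ct_volume` to a NIfTI file
#'
#' @param x a `ct_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; use `"int16"` for label volumes to
#'   keep them bit-exact, `"double"` (default) for continuous maps.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, datatype = "double") {
  im <- RNifti::asNifti(x$data, datatype = datatype)
  aff <- diag(c(x$spacing, 1))
  aff[1:3, 4] <- x$origin
  im <- RNifti::`sform<-`(im, structure(aff, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Dice overlap between two binary masks
#' @param a,b binary arrays or `ct_volume`s on a common grid.
#' @return Dice coefficient `2|A n B| / (|A| + |B|)`; 1 when both are empty.
#' @export
dice <- function(a, b) {
  if (is_ct_volume(a)) a <- a$data
  if (is_ct_volume(b)) b <- b$data
  a <- a != 0
  b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' World coordinates of every voxel centre
#' @param x a `ct_volume`.
#' @return An `n x 3` matrix of world coordinates (mm), voxels in
#'   column-major order.
#' @export
voxel_world_coords <- function(x) {
  d <- dim(x$data)
  i <- (seq_len(d[1]) - 1) * x$spacing[1] + x$origin[1]
  j <- (seq_len(d[2]) - 1) * x$spacing[2] + x$origin[2]
  k <- (seq_len(d[3]) - 1) * x$spacing[3] + x$origin[3]
  cbind(rep(i, times = d[2] * d[3]),
        rep(rep(j, each = d[1]), times = d[3]),
        rep(k, each = d[1] * d[2]))
}

#' Gaussian smoothing of a volume
#' @param x a `ct_volume`.
#' @param sigma_vox standard deviation in voxels (scalar or length 3).
#' @return Smoothed `ct_volume`.
#' @export
smooth_gaussian <- function(x, sigma_vox = 1) {
  sigma_vox <- rep_len(as.numeric(sigma_vox), 3L)
  with_data(x, .cq_gauss3(x$data * 1.0, sigma_vox))
}
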