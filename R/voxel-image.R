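#' 3-D voxel image with physical geometry
#'
#' A minimal container for a scalar 3-D image on a regular grid: a numeric
#' array together with its voxel spacing (mm) and world origin (mm, position
#' of the centre of voxel `[1,1,1]`). It carries cT1 maps (ms), relative
#' electron density (unitless) or dose (Gy). Axis convention: the first array
#' dimension is left-right (x), the second anterior-posterior (y, 0 =
#' anterior face), the third superior-inferior (z, slice direction).
#'
#' @param data numeric (or logical) 3-D array.
#' @param spacing numeric length-3, voxel spacing in mm, strictly positive.
#' @param origin numeric length-3, world coordinate (mm) of the first voxel
#'   centre.
#' @param units optional free-text unit label ("ms", "rED", "Gy").
#' @return An object of class `voxel_image`.
#' @export
voxel_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        units = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers (mm)", call. = FALSE)
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin,
                 units = units), class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_image> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm%s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              if (is.null(x$units)) "" else paste0(" [", x$units, "]")))
  rng <- range(x$data)
  cat(sprintf("  value range [%.4g, %.4g], origin (%.3g, %.3g, %.3g) mm\n",
              rng[1], rng[2], x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
dim.voxel_image <- function(x) dim(x$data)

is_voxel_image <- function(x) inherits(x, "voxel_image")

#' Volume of one voxel in cc
#' @param spacing voxel spacing in mm (length 3) or a `voxel_image`.
#' @return volume of a single voxel in cubic centimetres.
#' @export
voxel_cc <- function(spacing) {
  if (is_voxel_image(spacing)) spacing <- spacing$spacing
  prod(spacing) / 1000
}

#' World coordinates of voxel centres
#'
#' @param img a `voxel_image` (or a list with `spacing`/`origin` and dims).
#' @param axis 1, 2 or 3.
#' @return numeric vector of voxel-centre coordinates (mm) along `axis`.
#' @export
voxel_centres <- function(img, axis) {
  img$origin[axis] + (seq_len(dim(img$data)[axis]) - 1) * img$spacing[axis]
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

## ---- separable truncated-Gaussian convolution -----------------------------

gaussian_kernel_1d <- function(sigma, truncate = 6) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(1)
  r <- ceiling(truncate * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

## zero-padded 1-D convolution along a chosen array axis, via band-matrix
## multiplication (the kernel is small relative to typical axis lengths, but
## a dense n x n operator keeps this simple and fast at the sizes used here)
conv_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr)
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  ## operator K[i, j] = kernel[i - j + r + 1], zero outside support
  idx <- outer(seq_len(n), seq_len(n), "-") + r + 1L
  K <- matrix(0, n, n)
  ok <- idx >= 1L & idx <= length(kernel)
  K[ok] <- kernel[idx[ok]]
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- K %*% matrix(a, nrow = n)
  out <- array(m, dim = d[perm])
  aperm(out, order(perm))
}

#' Separable Gaussian smoothing of a 3-D array
#'
#' Convolution with a truncated Gaussian kernel (support cut at
#' `truncate * sigma`, kernel renormalised to unit mass), applied separably
#' along the requested axes with zero padding outside the array.
#'
#' @param arr 3-D numeric array.
#' @param sigma standard deviation(s) in voxels; a scalar is recycled over
#'   `axes`. `sigma = 0` on an axis is the identity.
#' @param axes integer axes to smooth along (default in-plane, `c(1, 2)`).
#' @param truncate kernel support half-width in units of sigma.
#' @return smoothed array, same dimensions.
#' @export
gaussian_smooth <- function(arr, sigma, axes = c(1, 2), truncate = 6) {
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  sigma <- rep_len(sigma, length(axes))
  out <- arr
  for (i in seq_along(axes))
    out <- conv_axis(out, gaussian_kernel_1d(sigma[i], truncate), axes[i])
  out
}

## ---- mask utilities -------------------------------------------------------

#' Isotropic Euclidean expansion of a binary mask
#'
#' Dilates a mask by a physical margin: a voxel is in the output if its
#' centre lies within `margin_mm` of some input voxel centre. Used for
#' GTV -> PTV and OAR -> PRV margins.
#'
#' @param mask logical 3-D array.
#' @param spacing voxel spacing (mm, length 3).
#' @param margin_mm margin in mm (>= 0).
#' @return logical array of the same dimensions.
#' @export
dilate_mask <- function(mask, spacing, margin_mm) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, margin_mm >= 0)
  if (margin_mm == 0) return(mask != 0)
  d <- dim(mask)
  rad <- floor(margin_mm / spacing)
  offs <- expand.grid(i = -rad[1]:rad[1], j = -rad[2]:rad[2], k = -rad[3]:rad[3])
  keep <- sqrt((offs$i * spacing[1])^2 + (offs$j * spacing[2])^2 +
                 (offs$k * spacing[3])^2) <= margin_mm
  offs <- offs[keep, , drop = FALSE]
  out <- array(FALSE, d)
  m <- mask != 0
  for (r in seq_len(nrow(offs))) {
    oi <- offs$i[r]; oj <- offs$j[r]; ok <- offs$k[r]
    xs <- max(1, 1 + oi):min(d[1], d[1] + oi)
    ys <- max(1, 1 + oj):min(d[2], d[2] + oj)
    zs <- max(1, 1 + ok):min(d[3], d[3] + ok)
    out[xs, ys, zs] <- out[xs, ys, zs] | m[xs - oi, ys - oj, zs - ok]
  }
  out
}

#' Nearest-neighbour resampling onto a new grid
#'
#' Samples `img` at the voxel centres of a target grid defined by shape,
#' spacing and origin. Points falling outside the source extent take the
#' value `outside`. Used to move masks and density maps between the
#' acquisition and planning grids while keeping masks binary.
#'
#' @param img a `voxel_image`.
#' @param shape integer length-3 target dimensions.
#' @param spacing target spacing (mm).
#' @param origin target origin (mm); default matches the source origin.
#' @param outside fill value outside the source grid.
#' @return a `voxel_image` on the target grid.
#' @export
resample_nearest <- function(img, shape, spacing, origin = img$origin,
                             outside = 0) {
  stopifnot(is_voxel_image(img))
  shape <- as.integer(shape)
  src <- dim(img$data)
  cx <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  cy <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  cz <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
  ix <- round((cx - img$origin[1]) / img$spacing[1]) + 1
  iy <- round((cy - img$origin[2]) / img$spacing[2]) + 1
  iz <- round((cz - img$origin[3]) / img$spacing[3]) + 1
  out <- array(outside, shape)
  okx <- ix >= 1 & ix <= src[1]; oky <- iy >= 1 & iy <= src[2]
  okz <- iz >= 1 & iz <= src[3]
  out[okx, oky, okz] <- img$data[ix[okx], iy[oky], iz[okz], drop = FALSE]
  if (is.logical(img$data)) out <- out != 0
  voxel_image(out, spacing, origin, units = img$units)
}

## ---- structure sets -------------------------------------------------------

#' Named set of binary masks sharing one grid
#'
#' @param masks named list of logical 3-D arrays with identical dimensions.
#' @param spacing shared voxel spacing (mm).
#' @param origin shared origin (mm).
#' @return an object of class `structure_set`; masks are accessed with `$masks`
#'   or `[[`.
#' @export
structure_set <- function(masks, spacing, origin = c(0, 0, 0)) {
  if (length(masks) == 0 || is.null(names(masks)) || any(names(masks) == ""))
    stop("`masks` must be a non-empty named list", call. = FALSE)
  d <- dim(masks[[1]])
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), d))
      stop("mask '", nm, "' is not on the shared grid", call. = FALSE)
    masks[[nm]] <- masks[[nm]] != 0
  }
  structure(list(masks = masks, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)), class = "structure_set")
}

#' @export
`[[.structure_set` <- function(x, name) x$masks[[name]]

#' @export
names.structure_set <- function(x) names(x$masks)

#' @export
print.structure_set <- function(x, ...) {
  d <- dim(x$masks[[1]])
  cat(sprintf("<structure_set> %d structures on a %d x %d x %d grid (%.3g x %.3g x %.3g mm)\n",
              length(x$masks), d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  vc <- voxel_cc(x$spacing)
  for (nm in names(x$masks))
    cat(sprintf("  %-14s %8.1f cc\n", nm, sum(x$masks[[nm]]) * vc))
  invisible(x)
}

## ---- NIfTI I/O ------------------------------------------------------------

#' Read / write voxel images as NIfTI
#'
#' Thin wrappers around RNifti preserving spacing. Masks are written as
#' 0/1 integer volumes.
#'
#' @param img a `voxel_image` (or logical/numeric 3-D array for masks).
#' @param path file path (`.nii` or `.nii.gz`).
#' @param spacing,origin geometry used when `img` is a bare array.
#' @return `read_nifti_image` returns a `voxel_image`; `write_nifti_image`
#'   returns `path` invisibly.
#' @export
write_nifti_image <- function(img, path, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0)) {
  if (is_voxel_image(img)) {
    spacing <- img$spacing; origin <- img$origin; arr <- img$data
  } else arr <- img
  if (is.logical(arr)) arr <- array(as.integer(arr), dim(arr))
  nim <- RNifti::asNifti(arr)
  RNifti::pixdim(nim) <- spacing
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' @rdname write_nifti_image
#' @export
read_nifti_image <- function(path) {
  nim <- RNifti::readNifti(path)
  arr <- array(as.numeric(nim), dim(nim)[1:3])
  voxel_image(arr, spacing = RNifti::pixdim(nim)[1:3])
}
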