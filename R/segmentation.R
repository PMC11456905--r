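#' Parameters of the functional-liver segmentation
#'
#' The segmentation chain is: in-plane downsampling of the cT1 map, cropping
#' to the liver-in-FOV region of interest, thresholding below
#' `ct1_threshold_ms` (strict `<`), then Gaussian smoothing of the binary
#' mask followed by thresholding at the median of the smoothed values to
#' remove small speckle regions.
#'
#' `smoothing_sigma` is interpreted in voxels of the downsampled grid by
#' default (`sigma_units = "voxels"`, smoothing applied in-plane only); with
#' `sigma_units = "mm"` it is isotropic in physical units and applied along
#' all three axes.
#'
#' `median_scope` selects the voxel set over which the median of the
#' smoothed values is taken: `"mask"` (the default: voxels of the raw
#' thresholded mask, so the cut removes regions whose smoothed support is
#' weak relative to the bulk of the functional tissue) or `"positive"`
#' (all ROI voxels with strictly positive smoothed value; with a wide
#' truncated kernel the low-valued halo dominates that median, which lets
#' small speckle regions survive). `smooth_target = "mask"` smooths the
#' binary mask (the default); `"image"` smooths the cT1 map itself before
#' thresholding.
#'
#' @param ct1_threshold_ms functional threshold in ms (default 800).
#' @param downsample_factor integer in-plane downsampling factor (default 2).
#' @param smoothing_sigma Gaussian sigma (default 4).
#' @param sigma_units `"voxels"` or `"mm"`.
#' @param median_scope `"mask"` or `"positive"`.
#' @param smooth_target `"mask"` or `"image"`.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(ct1_threshold_ms = 800,
                                downsample_factor = 2L,
                                smoothing_sigma = 4,
                                sigma_units = c("voxels", "mm"),
                                median_scope = c("mask", "positive"),
                                smooth_target = c("mask", "image")) {
  if (ct1_threshold_ms <= 0) stop("ct1_threshold_ms must be > 0", call. = FALSE)
  if (downsample_factor < 1 || downsample_factor != round(downsample_factor))
    stop("downsample_factor must be an integer >= 1", call. = FALSE)
  if (smoothing_sigma < 0) stop("smoothing_sigma must be >= 0", call. = FALSE)
  structure(list(ct1_threshold_ms = ct1_threshold_ms,
                 downsample_factor = as.integer(downsample_factor),
                 smoothing_sigma = smoothing_sigma,
                 sigma_units = match.arg(sigma_units),
                 median_scope = match.arg(median_scope),
                 smooth_target = match.arg(smooth_target)),
            class = "segmentation_params")
}

#' In-plane block-mean downsampling
#'
#' Reduces the first two (left-right, anterior-posterior) dimensions by an
#' integer factor, each output voxel being the mean of its factor x factor
#' in-plane block. The slice direction is untouched and in-plane spacing is
#' multiplied by the factor. If the in-plane dimensions are not divisible by
#' the factor the image is padded by edge replication first; the padding is
#' recorded in the result.
#'
#' @param img a `voxel_image`.
#' @param factor integer >= 1.
#' @return a `voxel_image` with attribute `"pad"` (in-plane voxels added).
#' @export
downsample_inplane <- function(img, factor) {
  stopifnot(is_voxel_image(img))
  if (factor < 1 || factor != round(factor))
    stop("factor must be an integer >= 1", call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) { attr(img, "pad") <- c(0L, 0L); return(img) }
  arr <- img$data
  d <- dim(arr)
  pad <- (factor - d[1:2] %% factor) %% factor
  if (pad[1] > 0) arr <- arr[c(seq_len(d[1]), rep(d[1], pad[1])), , , drop = FALSE]
  if (pad[2] > 0) arr <- arr[, c(seq_len(d[2]), rep(d[2], pad[2])), , drop = FALSE]
  d2 <- dim(arr)
  n1 <- d2[1] %/% factor; n2 <- d2[2] %/% factor
  ## average factor x factor in-plane blocks
  a <- array(arr, c(factor, n1, factor, n2, d2[3]))
  out <- apply(a, c(2, 4, 5), mean)
  res <- voxel_image(out, spacing = img$spacing * c(factor, factor, 1),
                     origin = img$origin + c((factor - 1) / 2 * img$spacing[1:2], 0),
                     units = img$units)
  attr(res, "pad") <- pad
  res
}

## downsample a binary mask onto the working grid by in-plane block majority
downsample_mask_inplane <- function(mask, spacing, factor) {
  ds <- downsample_inplane(voxel_image(mask * 1, spacing), factor)
  ds$data >= 0.5
}

## nearest-neighbour inverse of downsample_inplane for masks: replicate each
## working-grid voxel over its factor x factor block, trimming the padding
upsample_mask_inplane <- function(mask, factor, orig_shape) {
  if (factor == 1L) return(mask)
  d <- dim(mask)
  big <- mask[rep(seq_len(d[1]), each = factor),
              rep(seq_len(d[2]), each = factor), , drop = FALSE]
  big[seq_len(orig_shape[1]), seq_len(orig_shape[2]), , drop = FALSE]
}

#' Crop an image to the bounding box of a region of interest
#'
#' @param img a `voxel_image`.
#' @param roi logical array on the same grid, non-empty.
#' @return a `voxel_image` covering the axis-aligned bounding box of `roi`,
#'   with attribute `"bbox"` (a 3 x 2 matrix of index ranges in the input
#'   frame) so results can be mapped back.
#' @export
crop_to_roi <- function(img, roi) {
  stopifnot(is_voxel_image(img))
  if (!identical(dim(roi), dim(img$data)))
    stop("roi is not on the image grid", call. = FALSE)
  if (!any(roi)) stop("empty roi", call. = FALSE)
  idx <- which(roi != 0, arr.ind = TRUE)
  bbox <- apply(idx, 2, range)            # 2 x 3
  out <- img$data[bbox[1, 1]:bbox[2, 1], bbox[1, 2]:bbox[2, 2],
                  bbox[1, 3]:bbox[2, 3], drop = FALSE]
  res <- voxel_image(out, spacing = img$spacing,
                     origin = img$origin + (bbox[1, ] - 1) * img$spacing,
                     units = img$units)
  attr(res, "bbox") <- t(bbox)
  res
}

#' Threshold a cT1 map into a functional mask
#'
#' A voxel is functional when its cT1 value is strictly below the threshold
#' and it lies inside the region of interest.
#'
#' @param ct1 a `voxel_image` (ms) or numeric array.
#' @param roi logical array on the same grid.
#' @param threshold_ms threshold in ms.
#' @return logical array.
#' @export
threshold_functional <- function(ct1, roi, threshold_ms) {
  arr <- if (is_voxel_image(ct1)) ct1$data else ct1
  if (!identical(dim(arr), dim(roi)))
    stop("roi is not on the image grid", call. = FALSE)
  (arr < threshold_ms) & (roi != 0)
}

## sigma per axis (voxels) and smoothing axes for the working grid
sigma_axes <- function(params, spacing) {
  if (params$sigma_units == "mm")
    list(sigma = params$smoothing_sigma / spacing, axes = 1:3)
  else
    list(sigma = rep(params$smoothing_sigma, 2), axes = c(1, 2))
}

#' Smooth a binary mask and re-threshold at the median
#'
#' The 0/1 mask is Gaussian-smoothed with normalisation over the scope
#' (smoothed mask divided by the smoothed scope indicator), so that a mask
#' filling the whole scope stays exactly 1 inside it. Voxels whose smoothed
#' value is at least the median of the smoothed values over the selected
#' voxel set are kept; the output is restricted to the scope. An empty mask
#' yields an empty mask.
#'
#' @param mask logical array (working grid).
#' @param params a [segmentation_params()].
#' @param scope logical array: the region of interest (liver-in-FOV).
#' @param spacing voxel spacing of the working grid (mm), used when
#'   `sigma_units = "mm"`.
#' @return logical array.
#' @export
smooth_and_median <- function(mask, params, scope, spacing = c(1, 1, 1)) {
  if (params$smoothing_sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (!any(mask)) return(mask & FALSE)
  sa <- sigma_axes(params, spacing)
  if (params$smoothing_sigma == 0) {
    sm <- mask * 1
  } else {
    num <- gaussian_smooth(mask * 1, sa$sigma, sa$axes)
    den <- gaussian_smooth(scope * 1, sa$sigma, sa$axes)
    sm <- array(0, dim(mask))
    pos <- den > .Machine$double.eps
    sm[pos] <- num[pos] / den[pos]
  }
  sel <- if (params$median_scope == "mask") (mask != 0) else (scope != 0 & sm > 0)
  if (!any(sel)) return(mask & FALSE)
  med <- stats::median(sm[sel])
  (sm >= med) & (scope != 0)
}

#' Segment the functional liver volume from a cT1 map
#'
#' Runs the full chain on the acquisition grid: in-plane downsampling,
#' cropping to the liver-in-FOV bounding box, strict thresholding below
#' `ct1_threshold_ms`, and Gaussian smoothing with median re-thresholding.
#' The resulting mask is mapped back to the acquisition grid by
#' nearest-neighbour (block replication) and intersected with liver-in-FOV
#' so containment holds on both grids.
#'
#' @param ct1 a `voxel_image`: the cT1 map (ms) on the acquisition grid.
#' @param liver_mask,fov_mask logical arrays on the same grid.
#' @param params a [segmentation_params()].
#' @return an object of class `flv_result`: `flv_mask` (acquisition grid),
#'   `flv_work`/`raw_mask`/`roi_work` (working grid), `working_spacing`,
#'   and `volumes_cc` per stage.
#' @export
segment_flv <- function(ct1, liver_mask, fov_mask,
                        params = segmentation_params()) {
  stopifnot(is_voxel_image(ct1), inherits(params, "segmentation_params"))
  roi_full <- (liver_mask != 0) & (fov_mask != 0)
  if (!any(roi_full)) stop("empty roi: liver and FOV do not intersect", call. = FALSE)
  f <- params$downsample_factor
  ds <- downsample_inplane(ct1, f)
  roi_ds <- downsample_mask_inplane(roi_full, ct1$spacing, f)
  cr <- crop_to_roi(ds, roi_ds)
  bbox <- attr(cr, "bbox")
  roi_cr <- roi_ds[bbox[1, 1]:bbox[1, 2], bbox[2, 1]:bbox[2, 2],
                   bbox[3, 1]:bbox[3, 2], drop = FALSE]
  if (params$smooth_target == "image") {
    sa <- sigma_axes(params, cr$spacing)
    smoothed <- gaussian_smooth(cr$data, sa$sigma, sa$axes)
    raw <- threshold_functional(smoothed, roi_cr, params$ct1_threshold_ms)
    p0 <- params; p0$smoothing_sigma <- 0
    flv_cr <- smooth_and_median(raw, p0, roi_cr, cr$spacing)
  } else {
    raw <- threshold_functional(cr, roi_cr, params$ct1_threshold_ms)
    flv_cr <- smooth_and_median(raw, params, roi_cr, cr$spacing)
  }

  ## map back: embed crop into the working grid, replicate in-plane, trim pad
  flv_work <- array(FALSE, dim(roi_ds))
  flv_work[bbox[1, 1]:bbox[1, 2], bbox[2, 1]:bbox[2, 2],
           bbox[3, 1]:bbox[3, 2]] <- flv_cr
  flv_full <- upsample_mask_inplane(flv_work, f, dim(ct1$data)) & roi_full
  vc_work <- voxel_cc(cr$spacing); vc_full <- voxel_cc(ct1$spacing)
  structure(list(
    flv_mask = flv_full, flv_work = flv_work, raw_mask = raw,
    roi_work = roi_cr,
    working_spacing = cr$spacing, bbox = bbox, factor = f, params = params,
    volumes_cc = c(roi = sum(roi_full) * vc_full,
                   raw_threshold = sum(raw) * vc_work,
                   flv_working = sum(flv_cr) * vc_work,
                   flv = sum(flv_full) * vc_full)),
    class = "flv_result")
}

#' @export
print.flv_result <- function(x, ...) {
  cat("<flv_result>\n")
  v <- x$volumes_cc
  cat(sprintf("  liver-in-FOV %.1f cc; raw threshold %.1f cc; FLV %.1f cc (%.0f%% of ROI)\n",
              v[["roi"]], v[["raw_threshold"]], v[["flv"]],
              100 * v[["flv"]] / v[["roi"]]))
  invisible(x)
}
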