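# Independent brute-force oracles for the segmentation chain and the dose
# kernel, deliberately written with direct summation / fine sampling rather
# than the package's separable-convolution and voxel-traversal code paths.

## dense truncated-Gaussian convolution by shift-and-add over every kernel
## offset (2-D in-plane or full 3-D), zero padding outside the array
oracle_convolve <- function(arr, sigma, axes = c(1, 2), truncate = 6) {
  if (all(sigma == 0)) return(arr)
  d <- dim(arr)
  sig <- rep(0, 3)
  sig[axes] <- rep_len(sigma, length(axes))
  r <- ceiling(truncate * sig)
  k1 <- function(s, rr) {
    if (rr == 0) return(1)
    k <- exp(-((-rr:rr)^2) / (2 * s^2)); k / sum(k)
  }
  kx <- k1(sig[1], r[1]); ky <- k1(sig[2], r[2]); kz <- k1(sig[3], r[3])
  out <- array(0, d)
  for (oi in -r[1]:r[1]) for (oj in -r[2]:r[2]) for (ok in -r[3]:r[3]) {
    xlo <- max(1, 1 + oi); xhi <- min(d[1], d[1] + oi)
    ylo <- max(1, 1 + oj); yhi <- min(d[2], d[2] + oj)
    zlo <- max(1, 1 + ok); zhi <- min(d[3], d[3] + ok)
    if (xlo > xhi || ylo > yhi || zlo > zhi) next
    w <- kx[oi + r[1] + 1] * ky[oj + r[2] + 1] * kz[ok + r[3] + 1]
    xs <- xlo:xhi; ys <- ylo:yhi; zs <- zlo:zhi
    out[xs, ys, zs] <- out[xs, ys, zs] + w * arr[xs - oi, ys - oj, zs - ok]
  }
  out
}

## explicit in-plane block mean via nested loops over output voxels
oracle_block_mean <- function(arr, factor) {
  d <- dim(arr)
  pad <- (factor - d[1:2] %% factor) %% factor
  if (pad[1] > 0) arr <- arr[c(seq_len(d[1]), rep(d[1], pad[1])), , , drop = FALSE]
  if (pad[2] > 0) arr <- arr[, c(seq_len(d[2]), rep(d[2], pad[2])), , drop = FALSE]
  d2 <- dim(arr)
  n1 <- d2[1] %/% factor; n2 <- d2[2] %/% factor
  out <- array(NA_real_, c(n1, n2, d2[3]))
  for (i in seq_len(n1)) for (j in seq_len(n2)) for (k in seq_len(d2[3])) {
    blk <- arr[((i - 1) * factor + 1):(i * factor),
               ((j - 1) * factor + 1):(j * factor), k]
    out[i, j, k] <- mean(blk)
  }
  out
}

## exhaustive bounding box of a mask
oracle_bbox <- function(mask) {
  d <- dim(mask)
  lo <- rep(NA_integer_, 3); hi <- rep(NA_integer_, 3)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (mask[i, j, k]) {
      v <- c(i, j, k)
      lo <- pmin(lo, v, na.rm = TRUE); hi <- pmax(hi, v, na.rm = TRUE)
    }
  cbind(lo, hi)
}

## the full segmentation chain with the dense oracle primitives, mirroring
## the documented conventions (block-majority ROI, scope-normalised
## smoothing, median over strictly positive smoothed values in the ROI)
oracle_segment_flv <- function(ct1, liver, fov, params = segmentation_params()) {
  f <- params$downsample_factor
  roi_full <- liver & fov
  ds <- oracle_block_mean(ct1$data, f)
  roi_ds <- oracle_block_mean((roi_full) * 1, f) >= 0.5
  bb <- oracle_bbox(roi_ds)
  ds_c <- ds[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2], bb[3, 1]:bb[3, 2], drop = FALSE]
  roi_c <- roi_ds[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2], bb[3, 1]:bb[3, 2], drop = FALSE]
  raw <- (ds_c < params$ct1_threshold_ms) & roi_c
  if (!any(raw)) {
    flv_c <- raw
  } else if (params$smoothing_sigma == 0) {
    sm <- raw * 1
    sel <- if (params$median_scope == "mask") raw else (roi_c & sm > 0)
    flv_c <- if (any(sel)) (sm >= median(sm[sel])) & roi_c else raw & FALSE
  } else {
    spacing_ds <- ct1$spacing * c(f, f, 1)
    if (params$sigma_units == "mm") {
      sig <- params$smoothing_sigma / spacing_ds; axes <- 1:3
    } else { sig <- rep(params$smoothing_sigma, 2); axes <- c(1, 2) }
    num <- oracle_convolve(raw * 1, sig, axes)
    den <- oracle_convolve(roi_c * 1, sig, axes)
    sm <- array(0, dim(raw))
    pos <- den > .Machine$double.eps
    sm[pos] <- num[pos] / den[pos]
    sel <- if (params$median_scope == "mask") raw else (roi_c & sm > 0)
    flv_c <- if (any(sel)) (sm >= median(sm[sel])) & roi_c else raw & FALSE
  }
  ## map back to the acquisition grid
  flv_ds <- array(FALSE, dim(roi_ds))
  flv_ds[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2], bb[3, 1]:bb[3, 2]] <- flv_c
  d <- dim(flv_ds)
  big <- flv_ds[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), ,
                drop = FALSE]
  big[seq_len(dim(ct1$data)[1]), seq_len(dim(ct1$data)[2]), , drop = FALSE] &
    roi_full
}

## line integral by midpoint quadrature with nearest-voxel sampling
## (independent of the exact voxel-traversal code path)
oracle_path_integral <- function(img, p0, p1, step = 0.05) {
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  if (len == 0) return(0)
  ts <- seq(step / 2, len - step / 2, by = step)
  dims <- dim(img$data)
  ix <- round((p0[1] + d[1] * ts / len - img$origin[1]) / img$spacing[1]) + 1
  iy <- round((p0[2] + d[2] * ts / len - img$origin[2]) / img$spacing[2]) + 1
  iz <- round((p0[3] + d[3] * ts / len - img$origin[3]) / img$spacing[3]) + 1
  ok <- ix >= 1 & ix <= dims[1] & iy >= 1 & iy <= dims[2] &
    iz >= 1 & iz <= dims[3]
  if (!any(ok)) return(0)
  sum(img$data[cbind(ix[ok], iy[ok], iz[ok])]) * step
}

## exact signed-rank two-sided p by enumerating every sign vector
oracle_wilcoxon_p <- function(standard, sparing) {
  d <- standard - sparing
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

## small random segmentation phantom on an arbitrary grid
random_seg_phantom <- function(shape, seed, spacing = c(1.1, 1.1, 8)) {
  set.seed(seed)
  ct1 <- voxel_image(
    array(700 + 200 * sin(seq_len(prod(shape)) / 7) +
            stats::rnorm(prod(shape), 0, 80), shape),
    spacing = spacing, units = "ms")
  ext <- shape * spacing
  centre <- ext * stats::runif(3, 0.4, 0.6)
  semi <- ext * stats::runif(3, 0.25, 0.45)
  liver <- liverspare:::ellipsoid_mask(shape, spacing, centre, semi)
  fov <- array(FALSE, shape)
  keep <- sample(shape[3], max(2, round(0.8 * shape[3])))
  fov[, , sort(keep)] <- TRUE
  if (!any(liver & fov)) fov[] <- TRUE
  list(ct1 = ct1, liver = liver, fov = fov)
}
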