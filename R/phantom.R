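#' Configuration for a synthetic liver patient
#'
#' Describes the geometry and the cT1 statistics of one synthetic patient.
#' Defaults follow a typical axial quantitative-MR liver acquisition: 1.1 mm
#' in-plane resolution, 8 mm slices, and a cT1 field of view (FOV) that may
#' cover only part of the liver in the superior-inferior direction.
#'
#' The cT1 distribution inside the liver is a two-component mixture: a
#' "functional" component below the 800 ms threshold (mean `ct1_low_mean`)
#' and a "non-functional" component above it (mean `ct1_high_mean`), both
#' with 40 ms spread and truncated at the threshold so that the realised
#' functional fraction is controlled exactly by `functional_fraction_target`.
#' Which voxels fall in which component is decided by thresholding a
#' spatially correlated Gaussian field at its empirical quantile, so
#' functional tissue forms contiguous regions rather than salt-and-pepper
#' noise.
#'
#' @param grid_shape integer length-3 voxel grid dimensions.
#' @param spacing_mm voxel spacing in mm; default `c(1.1, 1.1, 8)`.
#' @param functional_fraction_target target fraction (0-1) of liver-in-FOV
#'   voxels with cT1 < 800 ms.
#' @param ct1_low_mean,ct1_high_mean component means in ms.
#' @param ct1_sd component spread in ms.
#' @param ct1_threshold_ms threshold separating the two components.
#' @param correlation_length_mm spatial smoothness of the underlying field.
#' @param gtv_radius_mm radius of the spherical gross tumour volume.
#' @param fov_coverage_fraction fraction of liver-containing slices covered
#'   by the cT1 FOV (truncation removes whole slices from the superior end).
#' @param seed integer RNG seed.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(160, 160, 24),
                           spacing_mm = c(1.1, 1.1, 8.0),
                           functional_fraction_target = 0.6,
                           ct1_low_mean = 700, ct1_high_mean = 950,
                           ct1_sd = 40, ct1_threshold_ms = 800,
                           correlation_length_mm = 25,
                           gtv_radius_mm = 15,
                           fov_coverage_fraction = 0.8,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape <= 0))
    stop("grid_shape must be 3 positive integers", call. = FALSE)
  if (any(spacing_mm <= 0)) stop("spacing must be strictly positive", call. = FALSE)
  if (functional_fraction_target < 0 || functional_fraction_target > 1)
    stop("functional_fraction_target must lie in [0, 1]", call. = FALSE)
  if (correlation_length_mm < 0) stop("correlation_length_mm must be >= 0", call. = FALSE)
  if (fov_coverage_fraction <= 0 || fov_coverage_fraction > 1)
    stop("fov_coverage_fraction must lie in (0, 1]", call. = FALSE)
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 functional_fraction_target = functional_fraction_target,
                 ct1_low_mean = ct1_low_mean, ct1_high_mean = ct1_high_mean,
                 ct1_sd = ct1_sd, ct1_threshold_ms = ct1_threshold_ms,
                 correlation_length_mm = correlation_length_mm,
                 gtv_radius_mm = gtv_radius_mm,
                 fov_coverage_fraction = fov_coverage_fraction,
                 seed = as.integer(seed)), class = "phantom_config")
}

## run `expr` under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Spatially correlated Gaussian random field
#'
#' White Gaussian noise smoothed with a Gaussian kernel whose per-axis sigma
#' (in voxels) is `correlation_length_mm / spacing`, then standardised to
#' zero mean and unit variance. `correlation_length_mm = 0` returns the
#' standardised white noise unchanged. Deterministic for a fixed seed.
#'
#' @param shape integer length-3 grid dimensions.
#' @param spacing voxel spacing (mm).
#' @param correlation_length_mm smoothness scale (>= 0).
#' @param seed integer seed.
#' @return a `voxel_image` holding the standardised field.
#' @export
make_correlated_field <- function(shape, spacing, correlation_length_mm, seed) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape <= 0))
    stop("shape must be 3 positive integers", call. = FALSE)
  if (correlation_length_mm < 0)
    stop("correlation_length_mm must be >= 0", call. = FALSE)
  arr <- with_seed(seed, array(stats::rnorm(prod(shape)), shape))
  if (correlation_length_mm > 0) {
    sig <- correlation_length_mm / spacing
    arr <- gaussian_smooth(arr, sigma = sig, axes = 1:3, truncate = 4)
  }
  arr <- (arr - mean(arr)) / stats::sd(arr)
  voxel_image(arr, spacing = spacing)
}

ellipsoid_mask <- function(shape, spacing, centre_mm, semi_mm) {
  x <- ((seq_len(shape[1]) - 1) * spacing[1] - centre_mm[1]) / semi_mm[1]
  y <- ((seq_len(shape[2]) - 1) * spacing[2] - centre_mm[2]) / semi_mm[2]
  z <- ((seq_len(shape[3]) - 1) * spacing[3] - centre_mm[3]) / semi_mm[3]
  outer(outer(x^2, y^2, "+"), z^2, "+") <= 1
}

cylinder_mask_z <- function(shape, spacing, centre_xy_mm, radius_mm) {
  x <- (seq_len(shape[1]) - 1) * spacing[1] - centre_xy_mm[1]
  y <- (seq_len(shape[2]) - 1) * spacing[2] - centre_xy_mm[2]
  disc <- outer(x^2, y^2, "+") <= radius_mm^2
  array(rep(disc, shape[3]), shape)
}

## draw from N(mean, sd) truncated to (lo, hi) via inverse-CDF; vectorised
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate one synthetic patient
#'
#' Builds the full set of images and structures the downstream pipeline
#' needs: a cT1 map (ms) with controlled functional fraction, plus liver,
#' GTV, body, lung, vertebrae, spinal-canal-like and bowel-like OAR masks
#' and the cT1 field-of-view mask. All anatomy is procedurally simple
#' (ellipsoids and tubes); realism is a non-goal.
#'
#' The realised functional fraction (liver-in-FOV voxels with cT1 below the
#' threshold) equals the target up to the quantile resolution of the
#' correlated field, because component membership is assigned by quantile
#' thresholding and component values are truncated at the threshold.
#'
#' @param config a [phantom_config()].
#' @return an object of class `synthetic_patient` with elements `ct1_map`
#'   (a `voxel_image`), `structures` (a `structure_set`), `seed`,
#'   `realized_fraction` and `config`.
#' @export
generate_patient <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- config$grid_shape; sp <- config$spacing_mm
  ext <- shape * sp                       # physical extent, mm
  cen <- ext / 2

  body <- ellipsoid_mask(shape, sp, cen, ext / 2 * 0.98)
  liver_c <- c(0.40, 0.47, 0.57) * ext
  liver_s <- c(0.38, 0.32, 0.40) * ext
  liver <- ellipsoid_mask(shape, sp, liver_c, liver_s) & body
  lung_l <- ellipsoid_mask(shape, sp, c(0.32, 0.50, 0.08) * ext,
                           c(0.16, 0.18, 0.14) * ext)
  lung_r <- ellipsoid_mask(shape, sp, c(0.68, 0.50, 0.08) * ext,
                           c(0.16, 0.18, 0.14) * ext)
  lung <- (lung_l | lung_r) & body & !liver
  vert <- cylinder_mask_z(shape, sp, c(0.50, 0.84) * ext[1:2], 0.075 * ext[1]) &
    body & !liver
  cord <- cylinder_mask_z(shape, sp, c(0.50, 0.84) * ext[1:2], 0.028 * ext[1]) &
    body
  bowel <- ellipsoid_mask(shape, sp, c(0.62, 0.22, 0.88) * ext,
                          c(0.16, 0.10, 0.11) * ext) & body & !liver

  ## GTV: sphere inside the liver, centre jittered reproducibly within the
  ## margin-eroded liver ellipsoid
  shrink <- liver_s - config$gtv_radius_mm
  if (any(shrink <= 0))
    stop("gtv_radius_mm too large for the liver", call. = FALSE)

  field <- make_correlated_field(shape, sp, config$correlation_length_mm,
                                 config$seed)

  res <- with_seed(config$seed + 1000003L, {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    gtv_c <- liver_c + u * stats::runif(1)^(1 / 3) * 0.6 * shrink
    gtv <- ellipsoid_mask(shape, sp, gtv_c, rep(config$gtv_radius_mm, 3)) & liver

    ## FOV: whole axial slices, truncated from the superior (low-z) end
    liver_z <- which(apply(liver, 3, any))
    n_keep <- max(1L, round(config$fov_coverage_fraction * length(liver_z)))
    keep_z <- liver_z[(length(liver_z) - n_keep + 1L):length(liver_z)]
    fov <- array(FALSE, shape)
    fov[, , keep_z] <- TRUE

    ## cT1 mixture driven by the correlated field quantile
    roi <- liver & fov
    thr <- config$ct1_threshold_ms
    ct1 <- array(0, shape)
    out_liver <- body & !liver
    ct1[out_liver] <- pmax(1, stats::rnorm(sum(out_liver), 1100, 60))
    fl <- field$data[liver]
    q <- stats::quantile(field$data[roi], config$functional_fraction_target,
                         type = 7, names = FALSE)
    low <- if (config$functional_fraction_target >= 1) rep(TRUE, length(fl))
           else if (config$functional_fraction_target <= 0) rep(FALSE, length(fl))
           else fl <= q
    vals <- numeric(length(fl))
    vals[low] <- rtruncnorm(sum(low), config$ct1_low_mean, config$ct1_sd,
                            lo = 1, hi = thr - 1e-9)
    vals[!low] <- rtruncnorm(sum(!low), config$ct1_high_mean, config$ct1_sd,
                             lo = thr)
    ct1[liver] <- vals
    list(gtv = gtv, fov = fov, ct1 = ct1, roi = roi)
  })

  structures <- structure_set(list(
    body = body, liver = liver, gtv = res$gtv, lung = lung,
    vertebrae = vert, spinal_canal = cord, bowel = bowel, fov = res$fov),
    spacing = sp)
  realized <- mean(res$ct1[res$roi] < config$ct1_threshold_ms)
  structure(list(ct1_map = voxel_image(res$ct1, sp, units = "ms"),
                 structures = structures, seed = config$seed,
                 realized_fraction = realized, config = config),
            class = "synthetic_patient")
}

#' @export
print.synthetic_patient <- function(x, ...) {
  vc <- voxel_cc(x$ct1_map$spacing)
  m <- x$structures$masks
  cat(sprintf("<synthetic_patient> seed %d\n", x$seed))
  cat(sprintf("  liver %.0f cc, GTV %.1f cc, liver-in-FOV %.0f cc\n",
              sum(m$liver) * vc, sum(m$gtv) * vc, sum(m$liver & m$fov) * vc))
  cat(sprintf("  realised functional fraction %.3f (target %.2f)\n",
              x$realized_fraction, x$config$functional_fraction_target))
  invisible(x)
}

#' Write a synthetic patient to disk as NIfTI + manifest
#'
#' Writes `ct1.nii.gz`, one NIfTI per mask, and a `manifest.json` echoing
#' the seed, the configuration and the realised functional fraction.
#'
#' @param patient a `synthetic_patient`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_patient <- function(patient, dir) {
  stopifnot(inherits(patient, "synthetic_patient"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_nifti_image(patient$ct1_map, file.path(dir, "ct1.nii.gz"))
  st <- patient$structures
  for (nm in names(st$masks))
    write_nifti_image(st$masks[[nm]], file.path(dir, paste0(nm, ".nii.gz")),
                      spacing = st$spacing)
  cfg <- patient$config; class(cfg) <- NULL
  jsonlite::write_json(
    list(seed = patient$seed, realized_fraction = patient$realized_fraction,
         config = cfg),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
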