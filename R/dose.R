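#' Beam geometry for coplanar IMRT
#'
#' Gantry convention: 0 deg places the source anterior to the patient,
#' angles increase clockwise viewed from the patient's feet; rotation is
#' about the superior-inferior (z) axis. At angle `theta` the unit beam
#' direction (source towards isocentre) is `(-sin(theta), cos(theta), 0)`
#' with y increasing from the anterior face towards posterior. Beamlets are
#' parallel (non-divergent) rays on a regular transverse grid.
#'
#' @param gantry_angles numeric vector of angles in degrees, in `[0, 360)`.
#' @param beamlet_size_mm beamlet grid spacing (mm), default 5.
#' @param margin_mm transverse margin added around the target projection
#'   when laying out beamlets, default 10.
#' @return an object of class `beam_geometry`.
#' @export
beam_geometry <- function(gantry_angles = beam_angles(12, 168, 24),
                          beamlet_size_mm = 5, margin_mm = 10) {
  if (any(gantry_angles < 0 | gantry_angles >= 360))
    stop("gantry angles must lie in [0, 360)", call. = FALSE)
  if (beamlet_size_mm <= 0) stop("beamlet_size_mm must be > 0", call. = FALSE)
  structure(list(gantry_angles = gantry_angles,
                 beamlet_size_mm = beamlet_size_mm, margin_mm = margin_mm),
            class = "beam_geometry")
}

#' Equispaced gantry angles along an arc
#'
#' Returns `n` angles inclusive of both endpoints, equispaced along the arc
#' from `start_deg` to `end_deg` traversed in the direction of increasing
#' gantry angle (wrapping through 360/0). For the default liver geometry the
#' arc from 168 to 24 degrees runs through the posterior and right-lateral
#' sectors, avoiding the anterior-left sector, which keeps beams off
#' contralateral organs at risk.
#'
#' @param n number of beams (>= 2).
#' @param start_deg,end_deg arc endpoints in degrees.
#' @return numeric vector of `n` angles in `[0, 360)`.
#' @export
beam_angles <- function(n, start_deg = 168, end_deg = 24) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  arc <- (end_deg - start_deg) %% 360
  (start_deg + seq(0, arc, length.out = n)) %% 360
}

beam_direction <- function(angle_deg) {
  th <- angle_deg * pi / 180
  c(-sin(th), cos(th), 0)
}

#' Pencil-beam kernel parameters
#'
#' A deliberately simple homogeneous kernel: primary fluence attenuates
#' exponentially with radiological (water-equivalent) depth at rate
#' `mu_eff` per mm, and spreads laterally as a Gaussian with standard
#' deviation `lateral_sigma_mm` around the beamlet axis. These are toy
#' constants for relative plan comparison, not a clinical beam model.
#'
#' @param mu_eff effective attenuation coefficient (1/mm), default 0.005.
#' @param lateral_sigma_mm lateral Gaussian sigma (mm), default 3.
#' @param truncation relative cutoff below which influence-matrix entries
#'   are dropped (fraction of each column's maximum), default 1e-4.
#' @return an object of class `kernel_params`.
#' @export
kernel_params <- function(mu_eff = 0.005, lateral_sigma_mm = 3,
                          truncation = 1e-4) {
  if (mu_eff <= 0 || lateral_sigma_mm <= 0)
    stop("mu_eff and lateral_sigma_mm must be > 0", call. = FALSE)
  structure(list(mu_eff = mu_eff, lateral_sigma_mm = lateral_sigma_mm,
                 truncation = truncation), class = "kernel_params")
}

#' Radiological depth along a ray
#'
#' Exact voxel-traversal line integral of relative electron density (rED)
#' along the segment from `entry_point` to `voxel_centre`, in mm of
#' water-equivalent depth. Portions of the segment outside the grid (or in
#' zero-density voxels outside the body) contribute nothing, so an entry
#' point anywhere upstream of the body surface gives the depth from the
#' surface.
#'
#' @param red_map a `voxel_image` of rED values.
#' @param entry_point,voxel_centre numeric length-3 world coordinates (mm),
#'   or matrices with 3 columns for many rays at once.
#' @return numeric vector of water-equivalent depths (mm).
#' @export
radiological_depth <- function(red_map, entry_point, voxel_centre) {
  stopifnot(is_voxel_image(red_map))
  p0 <- rbind(entry_point); p1 <- rbind(voxel_centre)
  .segment_integrals(as.numeric(red_map$data), dim(red_map$data),
                     red_map$spacing, red_map$origin,
                     matrix(as.numeric(p0), ncol = 3),
                     matrix(as.numeric(p1), ncol = 3))
}

voxel_centre_matrix <- function(img) {
  d <- dim(img$data)
  cx <- voxel_centres(img, 1); cy <- voxel_centres(img, 2)
  cz <- voxel_centres(img, 3)
  cbind(rep(cx, times = d[2] * d[3]),
        rep(rep(cy, each = d[1]), times = d[3]),
        rep(cz, each = d[1] * d[2]))
}

#' Build the sparse dose-influence matrix
#'
#' For every beamlet b and voxel v the influence is
#' `exp(-mu_eff * depth(v, beam)) * exp(-r^2 / (2 * sigma^2))`, where
#' `depth` is the radiological depth of v along the beam direction and `r`
#' the transverse distance of v from the beamlet axis. Entries below
#' `truncation` times their column maximum are dropped. Beamlets tile the
#' target's transverse projection plus `margin_mm` for every beam.
#'
#' @param geometry a [beam_geometry()].
#' @param red_map a `voxel_image` of rED on the dose grid.
#' @param kernel a [kernel_params()].
#' @param target_mask logical array on the dose grid (the PTV); defines the
#'   isocentre (its centroid) and the beamlet extent.
#' @return an object of class `dose_influence`: sparse matrix `D`
#'   (n_voxels x n_beamlets, Gy per unit fluence), `beamlets` data frame
#'   (beam, angle, u, z), grid geometry, and the isocentre.
#' @export
build_dose_influence <- function(geometry, red_map, kernel, target_mask) {
  stopifnot(inherits(geometry, "beam_geometry"), is_voxel_image(red_map),
            inherits(kernel, "kernel_params"))
  if (!any(target_mask)) stop("empty target mask", call. = FALSE)
  d <- dim(red_map$data)
  n_vox <- prod(d)
  centres <- voxel_centre_matrix(red_map)
  tgt <- which(as.vector(target_mask != 0))
  iso <- colMeans(centres[tgt, , drop = FALSE])
  bl_sz <- geometry$beamlet_size_mm
  sig2 <- 2 * kernel$lateral_sigma_mm^2
  cut_r <- kernel$lateral_sigma_mm * sqrt(-2 * log(kernel$truncation)) # abs cutoff

  ii <- list(); jj <- list(); xx <- list()
  bl_beam <- integer(0); bl_u <- numeric(0); bl_z <- numeric(0)
  col0 <- 0L
  for (bi in seq_along(geometry$gantry_angles)) {
    ang <- geometry$gantry_angles[bi]
    dvec <- beam_direction(ang)
    e1 <- c(cos(ang * pi / 180), sin(ang * pi / 180), 0)
    u <- (centres[, 1] - iso[1]) * e1[1] + (centres[, 2] - iso[2]) * e1[2]
    z <- centres[, 3] - iso[3]
    ut <- u[tgt]; zt <- z[tgt]
    ub <- seq(floor((min(ut) - geometry$margin_mm) / bl_sz),
              ceiling((max(ut) + geometry$margin_mm) / bl_sz)) * bl_sz
    zb <- seq(floor((min(zt) - geometry$margin_mm) / bl_sz),
              ceiling((max(zt) + geometry$margin_mm) / bl_sz)) * bl_sz
    depth <- .ray_depths(as.numeric(red_map$data), d, red_map$spacing,
                         red_map$origin, dvec, centres)
    atten <- exp(-kernel$mu_eff * depth)
    for (a in seq_along(ub)) {
      idxu <- which(abs(u - ub[a]) <= cut_r)
      for (b in seq_along(zb)) {
        col0 <- col0 + 1L
        bl_beam <- c(bl_beam, bi); bl_u <- c(bl_u, ub[a]); bl_z <- c(bl_z, zb[b])
        idx <- idxu[abs(z[idxu] - zb[b]) <= cut_r]
        if (length(idx) == 0L) next
        val <- atten[idx] *
          exp(-((u[idx] - ub[a])^2 + (z[idx] - zb[b])^2) / sig2)
        keep <- val >= kernel$truncation * max(val)
        if (!any(keep)) next
        ii[[length(ii) + 1L]] <- idx[keep]
        jj[[length(jj) + 1L]] <- rep.int(col0, sum(keep))
        xx[[length(xx) + 1L]] <- val[keep]
      }
    }
  }
  D <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n_vox, col0))
  structure(list(
    D = D,
    beamlets = data.frame(beam = bl_beam,
                          angle = geometry$gantry_angles[bl_beam],
                          u = bl_u, z = bl_z),
    grid = list(dim = d, spacing = red_map$spacing, origin = red_map$origin),
    isocentre = iso, geometry = geometry, kernel = kernel),
    class = "dose_influence")
}

#' @export
print.dose_influence <- function(x, ...) {
  cat(sprintf("<dose_influence> %d voxels x %d beamlets, %d beams, %.2f%% dense\n",
              nrow(x$D), ncol(x$D), length(unique(x$beamlets$beam)),
              100 * Matrix::nnzero(x$D) / prod(dim(x$D))))
  invisible(x)
}

#' Compute dose from fluence weights
#'
#' @param influence a `dose_influence`.
#' @param fluence non-negative numeric vector, one weight per beamlet.
#' @return a `voxel_image` of dose (Gy) on the influence grid.
#' @export
compute_dose <- function(influence, fluence) {
  stopifnot(inherits(influence, "dose_influence"))
  if (length(fluence) != ncol(influence$D))
    stop("fluence length does not match the beamlet count", call. = FALSE)
  if (any(fluence < 0)) stop("fluence must be non-negative", call. = FALSE)
  dv <- as.numeric(influence$D %*% fluence)
  voxel_image(array(dv, influence$grid$dim), influence$grid$spacing,
              influence$grid$origin, units = "Gy")
}

#' Write / read a dose-influence matrix as sparse triplets
#'
#' Plain-text persistence: a three-column (row, col, value) table plus a
#' JSON header with the grid geometry and beamlet layout.
#'
#' @param influence a `dose_influence`.
#' @param path base path; writes `<path>.triplets.csv` and `<path>.json`.
#' @return the base path, invisibly.
#' @export
write_dose_influence <- function(influence, path) {
  tr <- Matrix::summary(influence$D)
  utils::write.csv(as.data.frame(tr), paste0(path, ".triplets.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(dim = dim(influence$D), grid = influence$grid,
         isocentre = influence$isocentre, beamlets = influence$beamlets,
         gantry_angles = influence$geometry$gantry_angles,
         kernel = unclass(influence$kernel)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
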