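dose_values_in <- function(dose, mask) {
  arr <- if (is_voxel_image(dose)) dose$data else dose
  if (!identical(dim(arr), dim(mask)))
    stop("mask is not on the dose grid", call. = FALSE)
  arr[mask != 0]
}

#' Volume of a binary mask in cc
#'
#' @param mask logical array.
#' @param spacing_mm voxel spacing (mm, length 3).
#' @return voxel count times voxel volume, in cubic centimetres.
#' @export
volume_cc <- function(mask, spacing_mm) {
  sum(mask != 0) * voxel_cc(spacing_mm)
}

## round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Functional ratio as an integer percentage
#'
#' `round(100 * flv / fov)` with halves rounded away from zero: the
#' proportion of the liver inside the cT1 field of view that was segmented
#' as functional.
#'
#' @param flv_cc functional liver volume (cc).
#' @param fov_cc liver-inside-FOV volume (cc), > 0.
#' @return integer percent.
#' @export
functional_ratio_percent <- function(flv_cc, fov_cc) {
  if (fov_cc <= 0) stop("undefined ratio: fov_cc must be > 0", call. = FALSE)
  as.integer(round_half_away(100 * flv_cc / fov_cc))
}

#' Dose covering a percentage of a structure (Dp%)
#'
#' The dose received by at least `p_percent` of the structure volume,
#' computed on sorted voxel doses without binning: the observed dose at
#' the lower `(1 - p/100)` quantile position, so `D100%` is the minimum
#' voxel dose and `Dp%` of a uniform dose is that dose.
#'
#' @param dose a `voxel_image` or numeric array (Gy).
#' @param mask logical array, non-empty.
#' @param p_percent percentage in (0, 100].
#' @return dose in Gy.
#' @export
dose_at_volume_percent <- function(dose, mask, p_percent) {
  if (p_percent <= 0 || p_percent > 100)
    stop("p_percent must lie in (0, 100]", call. = FALSE)
  dv <- dose_values_in(dose, mask)
  if (length(dv) == 0) stop("empty mask", call. = FALSE)
  s <- sort(dv)
  n <- length(s)
  ## index ceil(n * (1 - p/100)), written to be safe against floating-point
  ## noise in p/100 (e.g. n = 100, p = 95 must give position 5, not 6)
  i <- min(max(n - floor(n * p_percent / 100 + 1e-9), 1L), n)
  s[i]
}

#' Dose covering an absolute volume of a structure (Dcc)
#'
#' The dose received by at least `cc` cubic centimetres of the structure.
#' The cumulative volume curve over sorted voxel doses is interpolated
#' linearly between voxels, so `cc -> 0` approaches the maximum voxel dose
#' and `cc` equal to the full structure volume gives the minimum.
#'
#' @param dose a `voxel_image` or numeric array (Gy).
#' @param mask logical array, non-empty.
#' @param cc volume in cc, `0 < cc <=` structure volume.
#' @param spacing_mm voxel spacing; taken from `dose` when it is a
#'   `voxel_image`.
#' @return dose in Gy.
#' @export
dose_at_volume_cc <- function(dose, mask, cc, spacing_mm = NULL) {
  if (is.null(spacing_mm)) {
    if (!is_voxel_image(dose))
      stop("spacing_mm required when dose is a bare array", call. = FALSE)
    spacing_mm <- dose$spacing
  }
  dv <- sort(dose_values_in(dose, mask), decreasing = TRUE)
  if (length(dv) == 0) stop("empty mask", call. = FALSE)
  vc <- voxel_cc(spacing_mm)
  vol <- length(dv) * vc
  if (cc <= 0 || cc > vol + 1e-12)
    stop(sprintf("cc must lie in (0, %.4g]", vol), call. = FALSE)
  v_k <- seq_along(dv) * vc              # cumulative volume at each voxel
  if (cc <= v_k[1]) return(dv[1])
  stats::approx(v_k, dv, xout = min(cc, vol))$y
}

#' Volume of a structure at a dose level (VzGy)
#'
#' Both directions of the criterion are reported: `at_or_above` is the
#' percentage of the structure receiving at least `level_gy`, `below` the
#' percentage receiving less (the direction used by the UK SABR liver
#' V10Gy criterion, which requires a minimum volume *below* 10 Gy).
#'
#' @param dose a `voxel_image` or numeric array (Gy).
#' @param mask logical array, non-empty.
#' @param level_gy dose level (Gy).
#' @return named numeric: `at_or_above` and `below`, both in percent.
#' @export
volume_at_dose_percent <- function(dose, mask, level_gy) {
  dv <- dose_values_in(dose, mask)
  if (length(dv) == 0) stop("empty mask", call. = FALSE)
  up <- 100 * mean(dv >= level_gy)
  c(at_or_above = up, below = 100 - up)
}

#' Mean dose over a structure
#'
#' @param dose a `voxel_image` or numeric array (Gy).
#' @param mask logical array, non-empty.
#' @return mean voxel dose in Gy.
#' @export
mean_dose <- function(dose, mask) {
  dv <- dose_values_in(dose, mask)
  if (length(dv) == 0) stop("empty mask", call. = FALSE)
  mean(dv)
}

#' Cumulative dose-volume histogram
#'
#' @param dose a `voxel_image` or numeric array (Gy).
#' @param mask logical array, non-empty.
#' @param bin_width_gy dose bin width (Gy), default 0.05.
#' @param name optional structure name.
#' @return an object of class `dvh`: `dose_gy` (bin edges from 0),
#'   `volume_fraction` (fraction of the structure receiving at least each
#'   edge; starts at 1), `voxel_cc`, `name`.
#' @export
dvh <- function(dose, mask, bin_width_gy = 0.05, name = NULL) {
  dv <- dose_values_in(dose, mask)
  if (length(dv) == 0) stop("empty mask", call. = FALSE)
  edges <- seq(0, max(dv) + bin_width_gy, by = bin_width_gy)
  frac <- vapply(edges, function(e) mean(dv >= e), numeric(1))
  vc <- if (is_voxel_image(dose)) voxel_cc(dose$spacing) else NA_real_
  structure(list(dose_gy = edges, volume_fraction = frac, voxel_cc = vc,
                 name = name), class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh>%s %d bins to %.4g Gy\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              length(x$dose_gy), max(x$dose_gy)))
  invisible(x)
}

#' @export
plot.dvh <- function(x, ...) {
  graphics::plot(x$dose_gy, 100 * x$volume_fraction, type = "l",
                 xlab = "Dose [Gy]", ylab = "Volume [%]", ...)
  invisible(x)
}

#' Volume bookkeeping for one patient
#'
#' The per-patient volume summary: whole liver, GTV, liver minus GTV (used
#' for prescription setting), liver inside the cT1 field of view, the
#' functional liver volume, the functional ratio and the prescription.
#'
#' @param liver,gtv,fov,flv logical masks on one grid (`fov` is the raw
#'   field-of-view mask; the summary reports liver-inside-FOV).
#' @param spacing_mm voxel spacing (mm).
#' @param rx_gy prescription (Gy), optional.
#' @return an object of class `volume_summary` (also a one-row data frame)
#'   with columns `liver_cc`, `gtv_cc`, `liver_minus_gtv_cc`, `fov_cc`,
#'   `flv_cc`, `ratio_percent`, `rx_gy`.
#' @export
volume_summary <- function(liver, gtv, fov, flv, spacing_mm, rx_gy = NA_real_) {
  liver_cc <- volume_cc(liver, spacing_mm)
  gtv_cc <- volume_cc(gtv, spacing_mm)
  fov_cc <- volume_cc(liver & fov, spacing_mm)
  flv_cc <- volume_cc(flv, spacing_mm)
  out <- data.frame(liver_cc = liver_cc, gtv_cc = gtv_cc,
                    liver_minus_gtv_cc = liver_cc - gtv_cc,
                    fov_cc = fov_cc, flv_cc = flv_cc,
                    ratio_percent = functional_ratio_percent(flv_cc, fov_cc),
                    rx_gy = rx_gy)
  class(out) <- c("volume_summary", class(out))
  out
}
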