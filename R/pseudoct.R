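#' Bulk electron-density override configuration
#'
#' Relative-to-water electron density (rED) values assigned to broad tissue
#' classes for dose calculation on MR: lungs 0.328, vertebrae 1.153 and the
#' remaining tissue 0.988, with 0 outside the body. `override_priority`
#' orders the structures; a voxel takes the value of the first structure in
#' the list that contains it (`"tissue"` matches the whole body).
#'
#' @param lung_red,vertebrae_red,tissue_red,outside_body_red rED values (>= 0).
#' @param override_priority character vector ordering the overrides.
#' @return an object of class `density_config`.
#' @export
density_config <- function(lung_red = 0.328, vertebrae_red = 1.153,
                           tissue_red = 0.988, outside_body_red = 0,
                           override_priority = c("vertebrae", "lung", "tissue")) {
  vals <- c(lung_red, vertebrae_red, tissue_red, outside_body_red)
  if (any(vals < 0)) stop("rED values must be >= 0", call. = FALSE)
  structure(list(lung_red = lung_red, vertebrae_red = vertebrae_red,
                 tissue_red = tissue_red, outside_body_red = outside_body_red,
                 override_priority = override_priority),
            class = "density_config")
}

#' Build the bulk-density pseudo-CT
#'
#' Assigns every body voxel exactly one rED value by first match in the
#' configured priority order; voxels outside the body take
#' `outside_body_red`. Structures named in the priority list but absent from
#' the structure set are skipped (`"tissue"` always matches the body).
#'
#' @param structures a `structure_set` containing at least a `body` mask.
#' @param config a [density_config()].
#' @return a `voxel_image` of rED values on the structure grid.
#' @export
apply_density_overrides <- function(structures, config = density_config()) {
  stopifnot(inherits(structures, "structure_set"),
            inherits(config, "density_config"))
  body <- structures$masks[["body"]]
  if (is.null(body)) stop("missing body mask", call. = FALSE)
  red_of <- c(lung = config$lung_red, vertebrae = config$vertebrae_red,
              tissue = config$tissue_red)
  out <- array(config$outside_body_red, dim(body))
  ## reverse priority so that earlier entries overwrite later ones
  for (nm in rev(config$override_priority)) {
    m <- if (nm == "tissue") body else structures$masks[[nm]]
    if (is.null(m)) next
    if (is.na(red_of[nm])) stop("no rED value for '", nm, "'", call. = FALSE)
    out[m & body] <- red_of[[nm]]
  }
  voxel_image(out, spacing = structures$spacing, origin = structures$origin,
              units = "rED")
}
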