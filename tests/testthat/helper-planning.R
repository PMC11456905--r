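# Shared fixture builders for the planning tests: a coarse patient with all
# planning structures on a small dose grid, cheap enough to rebuild per file.

small_planning_setup <- function(seed = 3, fraction = 0.5,
                                 phantom_shape = c(64, 64, 16),
                                 phantom_spacing = c(2.75, 2.75, 8),
                                 planning_shape = c(32, 32, 16)) {
  pc <- phantom_config(grid_shape = phantom_shape, spacing_mm = phantom_spacing,
                       functional_fraction_target = fraction,
                       correlation_length_mm = 20, gtv_radius_mm = 12,
                       seed = seed)
  pat <- generate_patient(pc)
  st <- pat$structures
  seg <- segment_flv(pat$ct1_map, st$masks$liver, st$masks$fov)
  red <- apply_density_overrides(st)
  sp0 <- st$spacing
  masks <- st$masks
  masks$ptv <- dilate_mask(masks$gtv, sp0, 5)
  masks$spinal_canal_prv <- dilate_mask(masks$spinal_canal, sp0, 5)
  masks$bowel_prv <- dilate_mask(masks$bowel, sp0, 5)
  masks$flv <- seg$flv_mask
  pg <- liverspare:::planning_grid(dim(pat$ct1_map$data), sp0, planning_shape)
  red_p <- resample_nearest(red, pg$shape, pg$spacing, pg$origin)
  masks_p <- lapply(masks, function(m)
    resample_nearest(voxel_image(m, sp0), pg$shape, pg$spacing, pg$origin,
                     outside = FALSE)$data)
  st_p <- structure_set(masks_p, pg$spacing, pg$origin)
  infl <- build_dose_influence(beam_geometry(), red_p, kernel_params(),
                               st_p$masks$ptv)
  obj <- plan_objectives(oar_constraints = list(
    list(structure = "spinal_canal_prv", type = "max_dvh_cc",
         level_gy = 25, volume_cc = 0.5, weight = 20),
    list(structure = "bowel_prv", type = "max_dvh_cc",
         level_gy = 30, volume_cc = 0.5, weight = 20)))
  list(patient = pat, seg = seg, structures = st_p, influence = infl,
       objectives = obj, red_planning = red_p)
}

## a hand-built one-column influence for closed-form optimiser checks
manual_influence <- function(D, dim3, spacing = c(1, 1, 1)) {
  structure(list(D = D,
                 beamlets = data.frame(beam = rep(1L, ncol(D)),
                                       angle = 0, u = 0, z = 0),
                 grid = list(dim = dim3, spacing = spacing,
                             origin = c(0, 0, 0)),
                 isocentre = c(0, 0, 0),
                 geometry = beam_geometry(c(0, 180)),
                 kernel = kernel_params()),
            class = "dose_influence")
}
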