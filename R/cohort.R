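#' Configuration of a synthetic cohort run
#'
#' Bundles every stage's parameters for an end-to-end comparison of
#' standard versus functional-liver-sparing plans on `n_patients` seeded
#' phantoms. Per-patient functional fractions default to an even spread
#' over 0.2-0.85, mirroring the wide range of functional ratios seen
#' across real livers; per-patient seeds are `base_seed + patient - 1`.
#'
#' @param n_patients number of phantoms (>= 1), default 10.
#' @param base_seed integer seed of patient 1.
#' @param functional_fraction_targets numeric vector (recycled to
#'   `n_patients`) of target functional fractions.
#' @param phantom a [phantom_config()] template (its seed and fraction are
#'   overridden per patient).
#' @param seg_params a [segmentation_params()].
#' @param density a [density_config()].
#' @param geometry a [beam_geometry()].
#' @param kernel a [kernel_params()].
#' @param objectives a [plan_objectives()] template; prescription and
#'   liver limit are set per tier. Defaults add D0.5cc limits of 25 Gy on
#'   the spinal-canal PRV and 30 Gy on the bowel PRV.
#' @param tiers a [prescription_tiers()].
#' @param planning_shape dose-grid dimensions, default `c(64, 64, 24)`.
#' @param d95_floor_fraction PTV D95 optimal tolerance as a fraction of
#'   the prescription (default 0.95).
#' @param solver options passed to [optimize_plan()] /
#'   [auto_sparing_weight()].
#' @param out_dir optional output directory for per-patient artifacts.
#' @return an object of class `run_config`.
#' @export
run_config <- function(n_patients = 10, base_seed = 1,
                       functional_fraction_targets =
                         seq(0.2, 0.85, length.out = n_patients),
                       phantom = phantom_config(),
                       seg_params = segmentation_params(),
                       density = density_config(),
                       geometry = beam_geometry(),
                       kernel = kernel_params(),
                       objectives = NULL,
                       tiers = prescription_tiers(),
                       planning_shape = c(64, 64, 24),
                       d95_floor_fraction = 0.95,
                       solver = list(),
                       out_dir = NULL) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (is.null(objectives))
    objectives <- plan_objectives(oar_constraints = list(
      list(structure = "spinal_canal_prv", type = "max_dvh_cc",
           level_gy = 25, volume_cc = 0.5, weight = 20),
      list(structure = "bowel_prv", type = "max_dvh_cc",
           level_gy = 30, volume_cc = 0.5, weight = 20)))
  structure(list(n_patients = as.integer(n_patients),
                 base_seed = as.integer(base_seed),
                 functional_fraction_targets =
                   rep_len(functional_fraction_targets, n_patients),
                 phantom = phantom, seg_params = seg_params,
                 density = density, geometry = geometry, kernel = kernel,
                 objectives = objectives, tiers = tiers,
                 planning_shape = as.integer(planning_shape),
                 d95_floor_fraction = d95_floor_fraction,
                 solver = solver, out_dir = out_dir),
            class = "run_config")
}

## polynomial rolling hash over the serialised configuration (exact in
## doubles: intermediate values stay far below 2^53), for artifact provenance
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL                    # where results land is not what they are
  bytes <- as.integer(serialize(cfg, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## resample the phantom-grid world onto the planning grid (same physical box)
planning_grid <- function(phantom_shape, phantom_spacing, planning_shape) {
  ext <- phantom_shape * phantom_spacing
  sp <- ext / planning_shape
  list(shape = planning_shape, spacing = sp, origin = (sp - phantom_spacing) / 2)
}

#' Run the full pipeline for one synthetic patient
#'
#' simulate -> segment -> pseudo-CT -> dose influence -> standard plan
#' (tier selection) -> sparing plan (weight titration) -> rescaled
#' standard plan -> metrics.
#'
#' @param config a [run_config()].
#' @param patient patient number (1-based); sets the seed and functional
#'   fraction.
#' @return a list with the phantom, segmentation, planning structures,
#'   plans (`standard`, `sparing`, `standard_rescaled`), selected tier,
#'   `table1` row and the long `metrics` data frame for this patient.
#' @export
run_patient <- function(config, patient) {
  stopifnot(inherits(config, "run_config"))
  pc <- config$phantom
  pc$seed <- config$base_seed + patient - 1L
  pc$functional_fraction_target <- config$functional_fraction_targets[patient]
  pat <- generate_patient(pc)
  st <- pat$structures
  seg <- segment_flv(pat$ct1_map, st$masks$liver, st$masks$fov,
                     config$seg_params)
  red <- apply_density_overrides(st, config$density)

  sp0 <- st$spacing
  masks <- st$masks
  masks$ptv <- dilate_mask(masks$gtv, sp0, 5)
  masks$spinal_canal_prv <- dilate_mask(masks$spinal_canal, sp0, 5)
  masks$bowel_prv <- dilate_mask(masks$bowel, sp0, 5)
  masks$flv <- seg$flv_mask

  pg <- planning_grid(dim(pat$ct1_map$data), sp0, config$planning_shape)
  red_p <- resample_nearest(red, pg$shape, pg$spacing, pg$origin)
  masks_p <- lapply(masks, function(m)
    resample_nearest(voxel_image(m, sp0), pg$shape, pg$spacing, pg$origin,
                     outside = FALSE)$data)
  st_p <- structure_set(masks_p, pg$spacing, pg$origin)

  infl <- build_dose_influence(config$geometry, red_p, config$kernel,
                               st_p$masks$ptv)
  sel <- select_prescription(infl, st_p, config$tiers, config$objectives,
                             config$solver)
  obj_rx <- config$objectives
  obj_rx$ptv_prescription_gy <- sel$rx_gy
  obj_rx$liver_mean_limit_gy <- config$tiers[[sel$tier]]$lmd_limit_gy
  d95_floor <- config$d95_floor_fraction * sel$rx_gy
  sparing <- auto_sparing_weight(infl, st_p, obj_rx, d95_floor,
                                 config$solver, standard_plan = sel$plan)
  d95_sparing <- dose_at_volume_percent(sparing$dose, st_p$masks$ptv, 95)
  standard_rescaled <- rescale_to_d95(sel$plan, st_p$masks$ptv, d95_sparing)

  tab1 <- volume_summary(st$masks$liver, st$masks$gtv, st$masks$fov,
                         seg$flv_mask, sp0, rx_gy = sel$rx_gy)
  tab1 <- cbind(patient = patient, tab1,
                realized_fraction = pat$realized_fraction,
                seed = pc$seed)
  m_plain <- patient_plan_metrics(patient, sel$plan, sparing, st_p, sel$rx_gy)
  m_plain$rescaled <- FALSE
  m_resc <- patient_plan_metrics(patient, standard_rescaled, sparing, st_p,
                                 sel$rx_gy)
  m_resc$rescaled <- TRUE
  metrics <- rbind(m_plain, m_resc)
  list(patient = patient, phantom = pat, segmentation = seg,
       structures_planning = st_p, influence = infl, tier = sel$tier,
       rx_gy = sel$rx_gy,
       plans = list(standard = sel$plan, sparing = sparing,
                    standard_rescaled = standard_rescaled),
       table1 = tab1, metrics = metrics)
}

## long-format metric rows comparing two plans on the planning structures
patient_plan_metrics <- function(patient, standard, sparing, st_p, rx_gy) {
  m <- st_p$masks
  lmg <- m$liver & !m$gtv
  one <- function(structure, quantity, fn) {
    data.frame(patient = patient, structure = structure, quantity = quantity,
               standard = fn(standard$dose), sparing = fn(sparing$dose),
               stringsAsFactors = FALSE)
  }
  pct <- function(x) 100 * x / rx_gy
  rows <- list(
    one("ptv", "D95%_pct", function(d) pct(dose_at_volume_percent(d, m$ptv, 95))),
    one("ptv", "D99%_pct", function(d) pct(dose_at_volume_percent(d, m$ptv, 99))),
    one("ptv", "D0.03cc_pct", function(d) pct(dose_at_volume_cc(d, m$ptv, 0.03))),
    one("spinal_canal_prv", "D0.5cc_Gy",
        function(d) dose_at_volume_cc(d, m$spinal_canal_prv, 0.5)),
    one("bowel_prv", "D0.5cc_Gy",
        function(d) dose_at_volume_cc(d, m$bowel_prv, 0.5)),
    one("liver_minus_gtv", "mean_Gy", function(d) mean_dose(d, lmg)),
    one("liver", "V10Gy_below_pct",
        function(d) volume_at_dose_percent(d, m$liver, 10)[["below"]]))
  if (any(m$flv))
    rows <- c(rows, list(one("flv", "mean_Gy", function(d) mean_dose(d, m$flv))))
  do.call(rbind, rows)
}

#' Run the full synthetic cohort comparison
#'
#' Runs [run_patient()] for every phantom and assembles the per-patient
#' volume table, the long metric table and the cohort comparison reports
#' (plain, and with the standard arm rescaled to matched PTV D95). When
#' `config$out_dir` is set, per-patient NIfTI volumes, plan JSONs, a
#' structured JSON-lines stage log and `table1.csv` / `table2.csv` /
#' `table2.json` are written; outputs are a pure function of the
#' configuration.
#'
#' @param config a [run_config()].
#' @param keep_patients keep the full per-patient objects in the return
#'   value (default `FALSE`; they are large).
#' @return an object of class `liverspare_cohort`: `table1`, `metrics`,
#'   `report`, `report_rescaled`, `summary` (per-patient seeds, tiers,
#'   sparing weights), `config_hash`, and optionally `patients`.
#' @export
run_cohort <- function(config, keep_patients = FALSE) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  out_dir <- config$out_dir
  log_path <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_path <- file.path(out_dir, "run.log.jsonl")
    if (file.exists(log_path)) file.remove(log_path)
  }
  log_stage <- function(...) {
    if (is.null(log_path)) return(invisible())
    rec <- list(...)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
        file = log_path, append = TRUE, sep = "")
  }
  tab1 <- list(); metrics <- list(); summaries <- list(); patients <- list()
  for (i in seq_len(config$n_patients)) {
    res <- run_patient(config, i)
    log_stage(stage = "patient", patient = i, seed = res$phantom$seed,
              config_hash = hash,
              functional_fraction_target = config$functional_fraction_targets[i],
              realized_fraction = res$phantom$realized_fraction,
              rx_gy = res$rx_gy, tier = res$tier,
              sparing_weight = res$plans$sparing$sparing_weight,
              sparing_applied = res$plans$sparing$sparing_applied)
    tab1[[i]] <- res$table1
    metrics[[i]] <- res$metrics
    summaries[[i]] <- data.frame(
      patient = i, seed = res$phantom$seed, tier = res$tier,
      rx_gy = res$rx_gy,
      sparing_weight = res$plans$sparing$sparing_weight,
      sparing_applied = res$plans$sparing$sparing_applied,
      flv_mean_standard_gy = mean_dose(res$plans$standard$dose,
                                       res$structures_planning$masks$flv),
      flv_mean_sparing_gy = mean_dose(res$plans$sparing$dose,
                                      res$structures_planning$masks$flv))
    if (!is.null(out_dir)) {
      pdir <- file.path(out_dir, sprintf("patient_%02d", i))
      write_patient(res$phantom, pdir)
      write_nifti_image(res$segmentation$flv_mask,
                        file.path(pdir, "flv.nii.gz"),
                        spacing = res$phantom$structures$spacing)
      write_nifti_image(res$plans$standard$dose,
                        file.path(pdir, "dose_standard.nii.gz"))
      write_nifti_image(res$plans$sparing$dose,
                        file.path(pdir, "dose_sparing.nii.gz"))
      jsonlite::write_json(
        list(seed = res$phantom$seed, config_hash = hash, rx_gy = res$rx_gy,
             tier = res$tier,
             sparing_weight = res$plans$sparing$sparing_weight,
             ladder = res$plans$sparing$ladder,
             fluence_standard = res$plans$standard$fluence,
             fluence_sparing = res$plans$sparing$fluence),
        file.path(pdir, "plan.json"), auto_unbox = TRUE, digits = NA)
    }
    if (keep_patients) patients[[i]] <- res
  }
  tab1 <- do.call(rbind, tab1)
  metrics <- do.call(rbind, metrics)
  plain <- metrics[!metrics$rescaled, setdiff(names(metrics), "rescaled")]
  resc <- metrics[metrics$rescaled, setdiff(names(metrics), "rescaled")]
  report <- compare_cohort(plain)
  report_rescaled <- compare_cohort(resc)
  out <- structure(list(table1 = tab1, metrics = metrics, report = report,
                        report_rescaled = report_rescaled,
                        summary = do.call(rbind, summaries),
                        config_hash = hash, config = config),
                   class = "liverspare_cohort")
  if (keep_patients) out$patients <- patients
  if (!is.null(out_dir)) {
    utils::write.csv(format_csv_num(tab1), file.path(out_dir, "table1.csv"),
                     row.names = FALSE)
    utils::write.csv(format_csv_num(as.data.frame(report)),
                     file.path(out_dir, "table2.csv"), row.names = FALSE)
    jsonlite::write_json(as.data.frame(report),
                         file.path(out_dir, "table2.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

## fixed-format numeric columns so repeated runs are byte-identical
format_csv_num <- function(df) {
  for (nm in names(df))
    if (is.numeric(df[[nm]])) df[[nm]] <- sprintf("%.10g", df[[nm]])
  df
}

#' @export
print.liverspare_cohort <- function(x, ...) {
  cat(sprintf("<liverspare_cohort> %d patients (config %s)\n",
              nrow(x$summary), x$config_hash))
  cat(sprintf("  functional ratios %d-%d%%; sparing applied for %d/%d patients\n",
              min(x$table1$ratio_percent), max(x$table1$ratio_percent),
              sum(x$summary$sparing_applied), nrow(x$summary)))
  flv <- x$report[x$report$structure == "flv" & x$report$quantity == "mean_Gy", ]
  if (nrow(flv) == 1)
    cat(sprintf("  FLV mean dose: standard %.2f Gy vs sparing %.2f Gy (p = %.4g), mean reduction %.2f Gy\n",
                flv$standard_median, flv$sparing_median, flv$p_value,
                flv$mean_diff))
  invisible(x)
}

#' Read a cohort configuration from YAML
#'
#' Reads a flat YAML file whose top-level keys mirror the arguments of
#' [run_config()]; nested sections `phantom`, `seg_params`, `density`,
#' `geometry`, `kernel`, `tiers` are passed to the respective
#' constructors.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("n_patients", "base_seed", "functional_fraction_targets",
               "planning_shape", "d95_floor_fraction", "solver", "out_dir"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$phantom)) args$phantom <- do.call(phantom_config, y$phantom)
  if (!is.null(y$seg_params))
    args$seg_params <- do.call(segmentation_params, y$seg_params)
  if (!is.null(y$density)) args$density <- do.call(density_config, y$density)
  if (!is.null(y$geometry)) args$geometry <- do.call(beam_geometry, y$geometry)
  if (!is.null(y$kernel)) args$kernel <- do.call(kernel_params, y$kernel)
  if (!is.null(y$tiers)) args$tiers <- prescription_tiers(y$tiers)
  do.call(run_config, args)
}
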