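#' Planning objectives for fluence optimization
#'
#' The composite objective is a weighted sum of one-sided quadratic
#' penalties plus, optionally, a parallel-organ term on the functional
#' liver volume (FLV):
#' \itemize{
#'   \item PTV underdose: mean squared shortfall below the prescription;
#'   \item PTV overdose: mean squared excess above
#'     `max_ptv_fraction * prescription`;
#'   \item organ-at-risk constraints of type `"mean"` (squared excess of
#'     the structure mean above `level_gy`) or `"max_dvh_cc"` (squared
#'     excess above `level_gy` for voxels beyond the hottest `volume_cc`);
#'   \item liver mean dose: squared excess of the liver-minus-GTV mean
#'     above `liver_mean_limit_gy`;
#'   \item FLV parallel objective: mean per-voxel functional damage
#'     `1 / (1 + (d_ref / d)^k)`, weighted by `flv_parallel$weight`.
#' }
#'
#' @param ptv_prescription_gy prescription dose (Gy), > 0.
#' @param ptv_underdose_weight,ptv_overdose_weight PTV penalty weights.
#' @param max_ptv_fraction overdose threshold as a fraction of the
#'   prescription (default 1.25).
#' @param oar_constraints list of `list(structure, type, level_gy,
#'   volume_cc, weight)` entries; `volume_cc` only for `"max_dvh_cc"`.
#' @param liver_mean_limit_gy,liver_mean_weight liver mean-dose penalty.
#' @param flv_parallel `NULL` for a standard plan, else
#'   `list(d_ref_gy, k_power, weight)`.
#' @return an object of class `plan_objectives`.
#' @export
plan_objectives <- function(ptv_prescription_gy = 50,
                            ptv_underdose_weight = 100,
                            ptv_overdose_weight = 50,
                            max_ptv_fraction = 1.25,
                            oar_constraints = list(),
                            liver_mean_limit_gy = 13,
                            liver_mean_weight = 50,
                            flv_parallel = NULL) {
  if (ptv_prescription_gy <= 0) stop("prescription must be > 0", call. = FALSE)
  w <- c(ptv_underdose_weight, ptv_overdose_weight, liver_mean_weight,
         vapply(oar_constraints, function(o) o$weight, numeric(1)))
  if (any(w < 0)) stop("weights must be >= 0", call. = FALSE)
  if (!is.null(flv_parallel)) {
    flv_parallel <- utils::modifyList(
      list(d_ref_gy = 15, k_power = 3, weight = 0), flv_parallel)
    if (flv_parallel$weight < 0) stop("weights must be >= 0", call. = FALSE)
  }
  structure(list(ptv_prescription_gy = ptv_prescription_gy,
                 ptv_underdose_weight = ptv_underdose_weight,
                 ptv_overdose_weight = ptv_overdose_weight,
                 max_ptv_fraction = max_ptv_fraction,
                 oar_constraints = oar_constraints,
                 liver_mean_limit_gy = liver_mean_limit_gy,
                 liver_mean_weight = liver_mean_weight,
                 flv_parallel = flv_parallel),
            class = "plan_objectives")
}

#' Parallel-organ damage fraction
#'
#' Mean over voxels of the logistic-in-log-dose response
#' `1 / (1 + (d_ref / d)^k)`, with the zero-dose term defined as 0. At
#' `d = d_ref` a voxel contributes 0.5; the response saturates at 1 for
#' doses well above `d_ref`. Because the per-voxel response is spread
#' across the whole dose range, its gradient lets an optimiser trade low
#' dose to a large volume against high dose to a small volume.
#'
#' @param dose_values numeric vector of voxel doses (Gy), non-empty.
#' @param d_ref_gy reference dose (Gy), > 0.
#' @param k_power steepness exponent, > 0.
#' @return mean damage fraction in `[0, 1]`.
#' @export
parallel_damage <- function(dose_values, d_ref_gy = 15, k_power = 3) {
  if (length(dose_values) == 0) stop("empty dose set", call. = FALSE)
  if (d_ref_gy <= 0 || k_power <= 0)
    stop("d_ref_gy and k_power must be > 0", call. = FALSE)
  g <- numeric(length(dose_values))
  pos <- dose_values > 0
  g[pos] <- 1 / (1 + (d_ref_gy / dose_values[pos])^k_power)
  mean(g)
}

## per-voxel derivative of the parallel damage response
parallel_damage_grad <- function(d, d_ref, k) {
  g <- numeric(length(d))
  pos <- d > 0
  r <- (d_ref / d[pos])^k
  g[pos] <- (k * r / d[pos]) / (1 + r)^2
  g
}

## objective + voxel-space gradient for a dose vector; idx holds voxel
## index vectors per structure, vox_cc the dose-grid voxel volume
plan_objective_terms <- function(dvec, obj, idx, vox_cc) {
  rx <- obj$ptv_prescription_gy
  g <- numeric(length(dvec))
  terms <- c()
  dp <- dvec[idx$ptv]; np <- length(dp)
  under <- pmax(rx - dp, 0)
  terms["ptv_under"] <- obj$ptv_underdose_weight * mean(under^2)
  g[idx$ptv] <- g[idx$ptv] - obj$ptv_underdose_weight * 2 * under / np
  over <- pmax(dp - obj$max_ptv_fraction * rx, 0)
  terms["ptv_over"] <- obj$ptv_overdose_weight * mean(over^2)
  g[idx$ptv] <- g[idx$ptv] + obj$ptv_overdose_weight * 2 * over / np

  if (!is.null(idx$liver_minus_gtv) && obj$liver_mean_weight > 0) {
    dl <- dvec[idx$liver_minus_gtv]; nl <- length(dl)
    exc <- max(mean(dl) - obj$liver_mean_limit_gy, 0)
    terms["liver_mean"] <- obj$liver_mean_weight * exc^2
    if (exc > 0)
      g[idx$liver_minus_gtv] <- g[idx$liver_minus_gtv] +
        obj$liver_mean_weight * 2 * exc / nl
  }
  for (k in seq_along(obj$oar_constraints)) {
    oc <- obj$oar_constraints[[k]]
    iv <- idx[[oc$structure]]
    if (is.null(iv) || length(iv) == 0) next
    ds <- dvec[iv]; ns <- length(ds)
    nm <- paste0(oc$structure, "_", oc$type)
    if (oc$type == "mean") {
      exc <- max(mean(ds) - oc$level_gy, 0)
      terms[nm] <- oc$weight * exc^2
      if (exc > 0) g[iv] <- g[iv] + oc$weight * 2 * exc / ns
    } else {                                       # max_dvh_cc
      n_allow <- floor((oc$volume_cc %||% 0) / vox_cc)
      ord <- order(ds, decreasing = TRUE)
      pen <- ord[-seq_len(min(n_allow, ns))]
      exc <- pmax(ds[pen] - oc$level_gy, 0)
      terms[nm] <- oc$weight * sum(exc^2) / ns
      g[iv[pen]] <- g[iv[pen]] + oc$weight * 2 * exc / ns
    }
  }
  fp <- obj$flv_parallel
  if (!is.null(fp) && fp$weight > 0 && length(idx$flv) > 0) {
    df <- dvec[idx$flv]; nf <- length(df)
    terms["flv_parallel"] <- fp$weight *
      parallel_damage(df, fp$d_ref_gy, fp$k_power)
    g[idx$flv] <- g[idx$flv] +
      fp$weight * parallel_damage_grad(df, fp$d_ref_gy, fp$k_power) / nf
  }
  list(value = sum(terms), terms = terms, grad_dose = g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

structure_indices <- function(structures, extra = character(0)) {
  m <- structures$masks
  need <- unique(c("ptv", "flv", "liver_minus_gtv", extra, names(m)))
  idx <- list()
  for (nm in need) if (!is.null(m[[nm]])) idx[[nm]] <- which(as.vector(m[[nm]]))
  if (is.null(idx$liver_minus_gtv) && !is.null(m$liver) && !is.null(m$gtv))
    idx$liver_minus_gtv <- which(as.vector(m$liver & !m$gtv))
  idx
}

#' Optimise a fluence map
#'
#' Minimises the composite objective of [plan_objectives()] over
#' non-negative beamlet fluence by projected gradient descent with
#' Barzilai-Borwein step proposal and backtracking, accepting only steps
#' that decrease the objective, so the recorded objective trace is
#' non-increasing. Deterministic for fixed inputs and initial fluence.
#'
#' @param influence a `dose_influence`.
#' @param structures a `structure_set` on the influence grid; must contain
#'   `ptv`, and the structures named by the objectives (a
#'   `liver_minus_gtv` index is derived from `liver` and `gtv` when not
#'   supplied directly).
#' @param objectives a [plan_objectives()].
#' @param options list: `max_iter` (default 100), `tol` relative objective
#'   change (1e-7), `init` initial fluence (scalar or vector, default 1).
#' @return an object of class `liver_plan`: `fluence`, `dose`
#'   (`voxel_image`), `rx_gy`, `objective_trace`, `objective_terms`,
#'   `converged`, `constraint_report`, `objectives`.
#' @export
optimize_plan <- function(influence, structures, objectives,
                          options = list()) {
  stopifnot(inherits(influence, "dose_influence"),
            inherits(structures, "structure_set"),
            inherits(objectives, "plan_objectives"))
  opts <- utils::modifyList(list(max_iter = 100L, tol = 1e-7, init = 1),
                            options)
  idx <- structure_indices(structures)
  if (is.null(idx$ptv) || length(idx$ptv) == 0)
    stop("PTV is empty", call. = FALSE)
  D <- influence$D
  if (Matrix::nnzero(D[idx$ptv, , drop = FALSE]) == 0)
    stop("infeasible geometry: PTV outside all beamlets", call. = FALSE)
  vox_cc <- voxel_cc(influence$grid$spacing)
  nb <- ncol(D)
  f <- rep_len(opts$init, nb)

  eval_obj <- function(f) {
    dvec <- as.numeric(D %*% f)
    t <- plan_objective_terms(dvec, objectives, idx, vox_cc)
    t$dose <- dvec
    t
  }
  cur <- eval_obj(f)
  grad_f <- function(gd) as.numeric(Matrix::crossprod(D, gd))
  g <- grad_f(cur$grad_dose)
  trace <- cur$value
  step <- 0.1 * (sqrt(sum(f^2)) + 1) / (sqrt(sum(g^2)) + 1e-12)
  converged <- FALSE
  for (it in seq_len(opts$max_iter)) {
    accepted <- FALSE
    t <- step
    for (bt in 1:40) {
      f_new <- pmax(f - t * g, 0)
      if (all(f_new == f)) break
      cand <- eval_obj(f_new)
      dec <- cur$value - cand$value
      if (dec >= 1e-4 * sum((f_new - f)^2) / t) { accepted <- TRUE; break }
      t <- t / 2
    }
    if (!accepted) { converged <- TRUE; break }
    g_new <- grad_f(cand$grad_dose)
    df <- f_new - f; dg <- g_new - g
    bb <- sum(df * df) / max(sum(df * dg), 1e-300)
    step <- if (is.finite(bb) && bb > 0) min(max(bb, 1e-12), 1e12) else t * 2
    rel <- (cur$value - cand$value) / max(cur$value, 1e-12)
    f <- f_new; g <- g_new; cur <- cand
    trace <- c(trace, cur$value)
    if (rel < opts$tol) { converged <- TRUE; break }
  }
  dose <- voxel_image(array(cur$dose, influence$grid$dim),
                      influence$grid$spacing, influence$grid$origin,
                      units = "Gy")
  plan <- structure(list(
    fluence = f, dose = dose, rx_gy = objectives$ptv_prescription_gy,
    objective_trace = trace, objective_terms = cur$terms,
    converged = converged, objectives = objectives,
    constraint_report = NULL), class = "liver_plan")
  plan$constraint_report <- plan_constraint_report(plan, structures)
  plan
}

plan_constraint_report <- function(plan, structures) {
  m <- structures$masks
  rx <- plan$rx_gy
  rows <- list()
  add <- function(structure, quantity, value, limit = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      structure = structure, quantity = quantity, value = value,
      limit = limit, stringsAsFactors = FALSE)
  }
  if (!is.null(m$ptv)) {
    add("ptv", "D95%_Gy", dose_at_volume_percent(plan$dose, m$ptv, 95), 0.95 * rx)
    add("ptv", "D99%_Gy", dose_at_volume_percent(plan$dose, m$ptv, 99))
  }
  if (!is.null(m$liver) && !is.null(m$gtv)) {
    lmg <- m$liver & !m$gtv
    add("liver_minus_gtv", "mean_Gy", mean_dose(plan$dose, lmg),
        plan$objectives$liver_mean_limit_gy)
  }
  if (!is.null(m$flv) && any(m$flv))
    add("flv", "mean_Gy", mean_dose(plan$dose, m$flv))
  for (oc in plan$objectives$oar_constraints) {
    mk <- m[[oc$structure]]
    if (is.null(mk) || !any(mk)) next
    if (oc$type == "mean")
      add(oc$structure, "mean_Gy", mean_dose(plan$dose, mk), oc$level_gy)
    else
      add(oc$structure, sprintf("D%.2gcc_Gy", oc$volume_cc),
          dose_at_volume_cc(plan$dose, mk, oc$volume_cc), oc$level_gy)
  }
  do.call(rbind, rows)
}

#' @export
print.liver_plan <- function(x, ...) {
  cat(sprintf("<liver_plan> Rx %.4g Gy, %d beamlets, objective %.4g (%s, %d iterations)\n",
              x$rx_gy, length(x$fluence), utils::tail(x$objective_trace, 1),
              if (x$converged) "converged" else "max-iter",
              length(x$objective_trace) - 1L))
  invisible(x)
}

#' @export
summary.liver_plan <- function(object, ...) {
  print(object)
  cat("objective terms:\n")
  print(round(object$objective_terms, 5))
  cat("constraints:\n")
  print(object$constraint_report, row.names = FALSE)
  invisible(object)
}

#' @export
coef.liver_plan <- function(object, ...) object$fluence

#' Plot DVH curves of a plan
#'
#' @param x a `liver_plan`.
#' @param structures a `structure_set` on the plan's dose grid.
#' @param which structure names to draw (default: PTV, FLV, liver-minus-GTV
#'   when present).
#' @param ... passed to [graphics::plot()].
#' @export
plot.liver_plan <- function(x, structures, which = NULL, ...) {
  m <- structures$masks
  if (is.null(which)) {
    which <- intersect(c("ptv", "flv", "liver", "spinal_canal_prv",
                         "bowel_prv"), names(m))
  }
  cols <- grDevices::hcl.colors(max(length(which), 2), "Dark 3")
  graphics::plot(NA, xlim = c(0, max(x$dose$data) * 1.05), ylim = c(0, 100),
                 xlab = "Dose [Gy]", ylab = "Volume [%]", ...)
  for (i in seq_along(which)) {
    dv <- dvh(x$dose, m[[which[i]]])
    graphics::lines(dv$dose_gy, 100 * dv$volume_fraction, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = which, col = cols[seq_along(which)],
                   lwd = 2, bty = "n")
  invisible(x)
}

#' Prescription tiers
#'
#' Ordered prescription levels with the liver-mean-dose (LMD) cap that
#' admits each. Defaults are configurable stand-ins for a five-fraction
#' liver SABR protocol: 50 Gy allowed when the liver-minus-GTV mean stays
#' below 13 Gy, otherwise 40 Gy below 15 Gy.
#'
#' @param tiers list of `list(rx_gy, lmd_limit_gy)`, prescriptions strictly
#'   decreasing.
#' @return an object of class `prescription_tiers`.
#' @export
prescription_tiers <- function(tiers = list(list(rx_gy = 50, lmd_limit_gy = 13),
                                            list(rx_gy = 40, lmd_limit_gy = 15))) {
  rx <- vapply(tiers, function(t) t$rx_gy, numeric(1))
  if (length(rx) == 0 || any(diff(rx) >= 0))
    stop("prescriptions must be strictly decreasing", call. = FALSE)
  structure(tiers, class = "prescription_tiers")
}

#' Select the prescription tier capped by liver mean dose
#'
#' Optimises a standard plan at each tier from the highest prescription
#' down and returns the first whose achieved liver-minus-GTV mean dose
#' meets that tier's cap. If none does, the lowest tier is returned with a
#' warning flag.
#'
#' @param influence a `dose_influence`.
#' @param structures a `structure_set`.
#' @param tiers a [prescription_tiers()].
#' @param objectives a [plan_objectives()] template; the prescription and
#'   liver limit are overridden per tier.
#' @param options solver options, see [optimize_plan()].
#' @return list with `rx_gy`, `tier` (index), `plan` (the accepted
#'   standard plan), `lmd_gy`, and `met_lmd` flag.
#' @export
select_prescription <- function(influence, structures, tiers, objectives,
                                options = list()) {
  stopifnot(inherits(tiers, "prescription_tiers"))
  lmg_idx <- structure_indices(structures)$liver_minus_gtv
  last <- NULL
  for (ti in seq_along(tiers)) {
    obj <- objectives
    obj$ptv_prescription_gy <- tiers[[ti]]$rx_gy
    obj$liver_mean_limit_gy <- tiers[[ti]]$lmd_limit_gy
    plan <- optimize_plan(influence, structures, obj, options)
    lmd <- mean(plan$dose$data[lmg_idx])
    last <- list(rx_gy = obj$ptv_prescription_gy, tier = ti, plan = plan,
                 lmd_gy = lmd, met_lmd = lmd <= tiers[[ti]]$lmd_limit_gy)
    if (last$met_lmd) return(last)
  }
  last
}

#' Titrate the FLV sparing weight against PTV coverage
#'
#' Re-optimises the plan with the parallel FLV objective over a geometric
#' weight ladder (multiplying by `factor` each step) and returns the
#' highest-weight plan whose PTV D95 stays at or above `d95_floor`. The
#' ladder stops at the first coverage failure. If even the smallest weight
#' fails, the standard plan is returned with `sparing_applied = FALSE`.
#'
#' @param influence a `dose_influence`.
#' @param structures a `structure_set` containing a non-empty `flv` mask.
#' @param objectives a [plan_objectives()]; its `flv_parallel$weight` is
#'   replaced by the ladder values (defaults `d_ref_gy = 15`,
#'   `k_power = 3` are used when `flv_parallel` is `NULL`).
#' @param d95_floor minimum admissible PTV D95 (Gy).
#' @param options solver options plus `ladder_start` (default 50),
#'   `ladder_steps` (default 6), `ladder_factor` (default 2).
#' @param standard_plan optionally a pre-computed zero-weight plan to
#'   avoid re-optimising it.
#' @return a `liver_plan` with extra fields `sparing_applied`,
#'   `sparing_weight` and `ladder` (a data frame of weight, D95 and FLV
#'   mean per rung).
#' @export
auto_sparing_weight <- function(influence, structures, objectives, d95_floor,
                                options = list(), standard_plan = NULL) {
  opts <- utils::modifyList(list(ladder_start = 50, ladder_steps = 6,
                                 ladder_factor = 2), options)
  solver_opts <- opts[setdiff(names(opts),
                              c("ladder_start", "ladder_steps", "ladder_factor"))]
  if (is.null(standard_plan)) {
    obj0 <- objectives; obj0$flv_parallel <- NULL
    standard_plan <- optimize_plan(influence, structures, obj0, solver_opts)
  }
  ptv <- structures$masks$ptv
  flv <- structures$masks$flv
  if (is.null(flv) || !any(flv)) {
    standard_plan$sparing_applied <- FALSE
    standard_plan$sparing_weight <- 0
    standard_plan$ladder <- data.frame(weight = numeric(0), d95_gy = numeric(0),
                                       flv_mean_gy = numeric(0))
    return(standard_plan)
  }
  weights <- opts$ladder_start * opts$ladder_factor^(0:(opts$ladder_steps - 1))
  best <- NULL
  ladder <- list()
  for (w in weights) {
    obj <- objectives
    obj$flv_parallel <- utils::modifyList(
      objectives$flv_parallel %||% list(d_ref_gy = 15, k_power = 3),
      list(weight = w))
    plan <- optimize_plan(influence, structures, obj, solver_opts)
    d95 <- dose_at_volume_percent(plan$dose, ptv, 95)
    ladder[[length(ladder) + 1L]] <- data.frame(
      weight = w, d95_gy = d95, flv_mean_gy = mean_dose(plan$dose, flv))
    if (d95 >= d95_floor) best <- list(plan = plan, weight = w) else break
  }
  ladder <- do.call(rbind, ladder)
  if (is.null(best)) {
    out <- standard_plan
    out$sparing_applied <- FALSE
    out$sparing_weight <- 0
  } else {
    out <- best$plan
    out$sparing_applied <- TRUE
    out$sparing_weight <- best$weight
  }
  out$ladder <- ladder
  out
}

#' Rescale a plan to a target PTV D95
#'
#' Multiplies fluence and dose by `target_d95_gy / D95(plan)`; by
#' linearity every dose-volume metric scales by the same factor.
#'
#' @param plan a `liver_plan`.
#' @param ptv logical PTV mask on the plan's dose grid.
#' @param target_d95_gy target D95 (Gy), > 0.
#' @return the rescaled `liver_plan` (with a `rescale_factor` field).
#' @export
rescale_to_d95 <- function(plan, ptv, target_d95_gy) {
  stopifnot(inherits(plan, "liver_plan"))
  cur <- dose_at_volume_percent(plan$dose, ptv, 95)
  if (cur <= 0) stop("plan D95 is zero; cannot rescale", call. = FALSE)
  s <- target_d95_gy / cur
  plan$fluence <- plan$fluence * s
  plan$dose$data <- plan$dose$data * s
  plan$rescale_factor <- s
  plan
}
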