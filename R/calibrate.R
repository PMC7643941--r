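#' Calibrate the reduced simulation temperature against a reference RMSF
#'
#' Runs a short Langevin simulation at each grid temperature, computes the
#' mean C-alpha RMSF, fits the linear relation RMSF = a T + b, and returns
#' the temperature at which the fit matches the reference RMSF (e.g. the
#' mean RMSF of explicit-solvent simulations).
#'
#' @param topology an [sbm_topology].
#' @param coordinates starting coordinates (n x 3).
#' @param temperature_grid temperatures in reduced units, within (0, 1.2].
#' @param reference_rmsf target mean RMSF (A).
#' @param n_steps,output_stride,seed per-point simulation controls.
#' @param selection atom indices over which RMSF is averaged (default: all
#'   atoms named CA, else all atoms).
#' @return list with `temperature` (solving the fit at `reference_rmsf`),
#'   `fit` (lm object), `table` (temperature vs mean RMSF) and a
#'   `monotone` quality flag.
#' @export
calibrate_temperature <- function(topology, coordinates, temperature_grid,
                                  reference_rmsf, n_steps = 20000L,
                                  output_stride = 50L, seed = 1L,
                                  selection = NULL) {
  stopifnot(all(temperature_grid > 0), all(temperature_grid <= 1.2))
  if (is.null(selection)) {
    selection <- if (!is.null(topology$atoms))
      which(topology$atoms$elety == "CA") else seq_along(topology$masses)
    if (!length(selection)) selection <- seq_along(topology$masses)
  }
  rmsf_mean <- vapply(seq_along(temperature_grid), function(g) {
    tr <- run_langevin(topology, coordinates,
                       list(temperature = temperature_grid[g],
                            n_steps = n_steps,
                            output_stride = output_stride,
                            seed = seed + g))
    mean(per_atom_rmsf(tr, selection))
  }, numeric(1))
  fit <- lm(rmsf_mean ~ temperature_grid)
  monotone <- all(diff(rmsf_mean[order(temperature_grid)]) > 0)
  if (!monotone)
    warning("calibration quality: RMSF not monotone across the grid")
  a <- coef(fit)[2]; b <- coef(fit)[1]
  list(temperature = unname((reference_rmsf - b) / a), fit = fit,
       table = data.frame(temperature = temperature_grid,
                          rmsf = rmsf_mean),
       monotone = monotone)
}

# per-atom fluctuation about the mean structure after best-fit
# superposition of every frame on the first
per_atom_rmsf <- function(trajectory, selection = NULL) {
  n <- ncol(trajectory$xyz) / 3
  if (is.null(selection)) selection <- seq_len(n)
  xyz <- superpose_frames(trajectory$xyz, selection)
  cols <- as.vector(rbind(3 * selection - 2, 3 * selection - 1,
                          3 * selection))
  sub <- xyz[, cols, drop = FALSE]
  mean_xyz <- colMeans(sub)
  dev <- sweep(sub, 2, mean_xyz)
  m <- matrix(colMeans(dev^2), nrow = 3)
  sqrt(colSums(m))
}

# rigid-body least-squares superposition of all frames onto the first,
# fitting on `selection`
superpose_frames <- function(xyz, selection) {
  if (nrow(xyz) < 2) return(xyz)
  fixed_inds <- as.vector(rbind(3 * selection - 2, 3 * selection - 1,
                                3 * selection))
  suppressWarnings(
    bio3d::fit.xyz(fixed = xyz[1, ], mobile = xyz,
                   fixed.inds = fixed_inds, mobile.inds = fixed_inds))
}

#' Scan the closed-state-specific contact weight
#'
#' Applies each candidate weight to the beta-only contacts, runs a
#' fixed-length simulation, and reports the closed-state occupancy (the
#' fraction of frames with the chosen reaction coordinate below
#' `threshold`). The weight whose occupancy is nearest `occupancy_target`
#' is selected.
#'
#' @param topology an [sbm_topology] with beta-only contact records.
#' @param coordinates starting coordinates.
#' @param weights candidate weights in (0, 1].
#' @param coordinate function(trajectory) returning the per-frame reaction
#'   coordinate (e.g. a [compute_r_dye] closure).
#' @param threshold closed-state cutoff on the coordinate (default 60 A,
#'   the R_dye closed-conformation criterion).
#' @param occupancy_target desired closed fraction (default 0.5).
#' @param params simulation parameters passed to [run_langevin].
#' @return list with `table` (weight vs occupancy), `weight` (selected).
#' @export
scan_contact_weight <- function(topology, coordinates, weights, coordinate,
                                threshold = 60, occupancy_target = 0.5,
                                params = list()) {
  stopifnot(all(weights > 0), all(weights <= 1))
  beta_rows <- topology$contacts$category == "beta-only"
  occ <- vapply(seq_along(weights), function(k) {
    topo_k <- topology
    topo_k$contacts$weight[beta_rows] <- weights[k]
    p <- modifyList(params, list(seed = (params$seed %||% 1L) + k))
    tr <- run_langevin(topo_k, coordinates, p)
    mean(coordinate(tr) < threshold)
  }, numeric(1))
  if (all(occ %in% c(0, 1)) && length(unique(occ)) == 1 &&
      length(weights) > 1)
    warning("insufficient sampling: no transitions observed at any weight")
  list(table = data.frame(weight = weights, occupancy = occ),
       weight = weights[which.min(abs(occ - occupancy_target))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
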