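#' Inter-chromophore distance series
#'
#' Per-frame Euclidean distance between the mass-weighted centers of mass
#' of the donor and acceptor chromophores (linker atoms excluded by
#' construction of the atom sets).
#'
#' @param trajectory an [sbm_trajectory].
#' @param donor_atoms,acceptor_atoms chromophore atom indices.
#' @param masses optional per-atom masses for the COM weighting; defaults
#'   to the trajectory topology's masses, else unit masses.
#' @return numeric vector of distances (A), one per frame.
#' @export
compute_r_dye <- function(trajectory, donor_atoms, acceptor_atoms,
                          masses = NULL) {
  if (!length(donor_atoms) || !length(acceptor_atoms))
    stop("definition error: empty chromophore atom set")
  n <- ncol(trajectory$xyz) / 3
  if (max(donor_atoms, acceptor_atoms) > n)
    stop("atom index outside trajectory range")
  if (is.null(masses))
    masses <- trajectory$topology$masses %||% rep(1, n)
  com_series <- function(idx) {
    w <- masses[idx] / sum(masses[idx])
    sapply(1:3, function(ax) {
      cols <- 3 * (idx - 1) + ax
      trajectory$xyz[, cols, drop = FALSE] %*% w
    })
  }
  cd <- com_series(donor_atoms)
  ca <- com_series(acceptor_atoms)
  if (n_frames(trajectory) == 1) { cd <- matrix(cd, 1); ca <- matrix(ca, 1) }
  sqrt(rowSums((cd - ca)^2))
}

#' Orientation factor kappa^2 series
#'
#' Per-frame `kappa^2 = (cos(theta_AD) - 3 cos(theta_D) cos(theta_A))^2`,
#' where theta_AD is the angle between the two transition dipoles and
#' theta_D / theta_A the angles of each dipole with the donor-acceptor
#' separation vector.
#'
#' @param trajectory an [sbm_trajectory].
#' @param donor_dipole,acceptor_dipole ordered atom index pairs defining
#'   each transition dipole direction.
#' @param donor_atoms,acceptor_atoms chromophore atom sets used for the
#'   separation vector (defaults to the dipole atoms themselves).
#' @return list with `kappa2` (per-frame series), `mean`, `sd`.
#' @export
compute_kappa2 <- function(trajectory, donor_dipole, acceptor_dipole,
                           donor_atoms = donor_dipole,
                           acceptor_atoms = acceptor_dipole) {
  stopifnot(length(donor_dipole) == 2, length(acceptor_dipole) == 2)
  if (donor_dipole[1] == donor_dipole[2] ||
      acceptor_dipole[1] == acceptor_dipole[2])
    stop("dipole atom pairs must be distinct")
  nf <- n_frames(trajectory)
  k2 <- numeric(nf)
  for (f in seq_len(nf)) {
    fr <- traj_frame(trajectory, f)
    d <- fr[donor_dipole[2], ] - fr[donor_dipole[1], ]
    a <- fr[acceptor_dipole[2], ] - fr[acceptor_dipole[1], ]
    r <- colMeans(fr[acceptor_atoms, , drop = FALSE]) -
      colMeans(fr[donor_atoms, , drop = FALSE])
    nd <- sqrt(sum(d^2)); na_ <- sqrt(sum(a^2)); nr <- sqrt(sum(r^2))
    if (nd < 1e-12 || na_ < 1e-12 || nr < 1e-12)
      stop("geometry error: zero-length dipole or separation vector")
    d <- d / nd; a <- a / na_; r <- r / nr
    k2[f] <- (sum(d * a) - 3 * sum(d * r) * sum(a * r))^2
  }
  list(kappa2 = k2, mean = mean(k2), sd = sd(k2))
}

#' Forster radius
#'
#' Two modes. Compute mode evaluates the standard spectroscopic form
#' `R_0 = 0.2108 (kappa^2 n^-4 Q_D J)^(1/6)` nm with J in
#' M^-1 cm^-1 nm^4, returned in Angstrom. Rescale mode converts a
#' reference R_0 at a reference kappa^2 to a new kappa^2 via
#' `R_ref (kappa^2 / kappa^2_ref)^(1/6)`.
#'
#' @param kappa2 orientation factor (default 2/3).
#' @param Q_D donor quantum yield.
#' @param n refractive index.
#' @param J spectral overlap (M^-1 cm^-1 nm^4); enables compute mode.
#' @param R_ref,kappa2_ref reference Forster radius (A) and its kappa^2;
#'   enables rescale mode.
#' @return R_0 in Angstrom.
#' @export
compute_forster_radius <- function(kappa2 = 2 / 3, Q_D = 0.48, n = 1.33,
                                   J = NULL, R_ref = NULL,
                                   kappa2_ref = NULL) {
  stopifnot(kappa2 >= 0, kappa2 <= 4, Q_D > 0, Q_D <= 1, n >= 1)
  if (!is.null(J)) {
    # 0.2108 nm prefactor absorbs 9000 ln(10) / (128 pi^5 N_A)
    return(10 * 0.2108 * (kappa2 * Q_D * J / n^4)^(1 / 6))
  }
  if (!is.null(R_ref)) {
    if (is.null(kappa2_ref)) stop("rescale mode needs kappa2_ref")
    return(R_ref * (kappa2 / kappa2_ref)^(1 / 6))
  }
  stop("underdetermined: provide either J (compute) or R_ref (rescale)")
}

#' Invert [compute_forster_radius] for the spectral overlap J
#'
#' @param R0 Forster radius (A).
#' @inheritParams compute_forster_radius
#' @return J in M^-1 cm^-1 nm^4.
#' @export
invert_forster_overlap <- function(R0, kappa2 = 2 / 3, Q_D = 0.48,
                                   n = 1.33) {
  (R0 / (10 * 0.2108))^6 * n^4 / (kappa2 * Q_D)
}

#' FRET efficiency from distance
#'
#' `E = 1 / (1 + (r / R_0)^6)`: strictly decreasing in r with
#' E(R_0) = 0.5 exactly.
#'
#' @param r donor-acceptor distance (A), vectorized.
#' @param r0 Forster radius (A).
#' @return Efficiency in (0, 1].
#' @export
fret_efficiency <- function(r, r0) {
  stopifnot(all(r >= 0), r0 > 0)
  1 / (1 + (r / r0)^6)
}

#' Bin a per-step series at a camera exposure time
#'
#' The bin size is `round(exposure / step_duration)`; each output value is
#' the arithmetic mean of one full bin and a trailing partial bin is
#' discarded.
#'
#' @param series per-step values.
#' @param step_duration duration of one step in ns.
#' @param exposure camera exposure in ms.
#' @return list with `binned` (series of bin means) and `bin_size` (steps).
#' @export
bin_exposure <- function(series, step_duration, exposure) {
  bin_size <- round(exposure * 1e6 / step_duration)
  if (bin_size < 1)
    stop("resolution error: exposure shorter than one step")
  n_bins <- length(series) %/% bin_size
  if (n_bins == 0)
    return(list(binned = numeric(), bin_size = bin_size))
  m <- matrix(series[seq_len(n_bins * bin_size)], nrow = bin_size)
  list(binned = colMeans(m), bin_size = bin_size)
}

#' Camera-exposure FRET traces from a trajectory
#'
#' Composes [compute_r_dye] -> [fret_efficiency] (with a single fixed R_0,
#' by convention derived from the mean kappa^2) -> [bin_exposure], one
#' trace per requested exposure. An optional non-default mode applies a
#' per-frame kappa^2-rescaled R_0 instead.
#'
#' @param trajectory an [sbm_trajectory].
#' @param donor_atoms,acceptor_atoms chromophore atom index sets.
#' @param r0 fixed Forster radius (A).
#' @param step_duration calibrated duration of one simulation step (ns).
#' @param exposures exposure times (ms).
#' @param frame_stride how many simulation steps one trajectory frame
#'   represents (default: inferred from the step index).
#' @param kappa2_resolved optional list(donor_dipole, acceptor_dipole,
#'   kappa2_ref) activating the per-frame kappa^2-resolved mode.
#' @param source_id identifier recorded in each trace.
#' @return list of `fret_trace` objects, one per exposure: data.frame
#'   `time_s`, `efficiency` plus exposure/bin-size/step-duration metadata.
#' @export
simulate_camera_trace <- function(trajectory, donor_atoms, acceptor_atoms,
                                  r0, step_duration, exposures,
                                  frame_stride = NULL,
                                  kappa2_resolved = NULL,
                                  source_id = "simulation") {
  if (is.null(frame_stride)) {
    frame_stride <- if (n_frames(trajectory) > 1)
      diff(trajectory$step_index[1:2]) else 1
  }
  r <- compute_r_dye(trajectory, donor_atoms, acceptor_atoms)
  if (!is.null(kappa2_resolved)) {
    k2 <- compute_kappa2(trajectory, kappa2_resolved$donor_dipole,
                         kappa2_resolved$acceptor_dipole,
                         donor_atoms, acceptor_atoms)$kappa2
    r0 <- compute_forster_radius(kappa2 = k2, R_ref = r0,
                                 kappa2_ref = kappa2_resolved$kappa2_ref)
  }
  eff <- fret_efficiency(r, r0)
  eff_step_ns <- step_duration * frame_stride
  lapply(exposures, function(ex) {
    b <- bin_exposure(eff, eff_step_ns, ex)
    fret_trace(efficiency = b$binned, exposure = ex,
               bin_size = b$bin_size * frame_stride,
               step_duration = step_duration, source = source_id)
  })
}

#' FRET trace container
#'
#' @param efficiency per-bin FRET efficiencies in `[0, 1]`.
#' @param exposure exposure time (ms).
#' @param bin_size number of simulation steps averaged per bin.
#' @param step_duration calibrated step duration (ns).
#' @param source source identifier.
#' @return An object of class `fret_trace` (a data.frame with `time_s`
#'   and `efficiency` plus metadata attributes).
#' @export
fret_trace <- function(efficiency, exposure, bin_size,
                       step_duration = NA_real_, source = "unknown") {
  if (length(efficiency) && (min(efficiency) < -1e-9 ||
                             max(efficiency) > 1 + 1e-9))
    stop("efficiencies must lie in [0, 1]")
  df <- data.frame(time_s = (seq_along(efficiency) - 0.5) * exposure / 1e3,
                   efficiency = as.numeric(efficiency))
  structure(df, exposure = exposure, bin_size = bin_size,
            step_duration = step_duration, source = source,
            class = c("fret_trace", "data.frame"))
}

#' Write a FRET trace as TSV (time_s, efficiency)
#' @param trace a [fret_trace].
#' @param path output path.
#' @export
write_trace_tsv <- function(trace, path) {
  write.table(format(as.data.frame(trace), digits = 12, trim = TRUE,
                     scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FRET trace TSV written by [write_trace_tsv]
#' @param path file path.
#' @param exposure exposure time (ms); inferred from time stamps if absent.
#' @export
read_trace_tsv <- function(path, exposure = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (is.null(exposure))
    exposure <- if (nrow(df) > 1) diff(df$time_s[1:2]) * 1e3 else NA_real_
  fret_trace(df$efficiency, exposure = exposure, bin_size = NA_integer_,
             source = path)
}
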