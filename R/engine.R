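#' Trajectory container
#'
#' Frames are stored bio3d-style as an `n_frames x 3n` coordinate matrix in
#' Angstrom with a strictly increasing per-frame step index.
#'
#' @param xyz numeric matrix, one row per frame, columns x1 y1 z1 x2 ...
#' @param step_index integer-ish vector of simulation steps per frame.
#' @param topology optional [sbm_topology] reference.
#' @param seed seed used to generate the trajectory, if any.
#' @param energies optional data.frame of per-frame energy components.
#' @return An object of class `sbm_trajectory`.
#' @export
sbm_trajectory <- function(xyz, step_index = seq_len(nrow(xyz)),
                           topology = NULL, seed = NA_integer_,
                           energies = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) %% 3 != 0) stop("coordinate columns must be a multiple of 3")
  if (length(step_index) != nrow(xyz))
    stop("step_index length must match frame count")
  if (any(diff(step_index) <= 0))
    stop("step_index must be strictly increasing")
  structure(list(xyz = xyz, step_index = as.numeric(step_index),
                 topology = topology, seed = seed, energies = energies),
            class = "sbm_trajectory")
}

#' @export
print.sbm_trajectory <- function(x, ...) {
  cat("sbm_trajectory:", n_frames(x), "frames,", ncol(x$xyz) / 3, "atoms\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory an [sbm_trajectory].
#' @export
n_frames <- function(trajectory) nrow(trajectory$xyz)

#' Extract one frame as an n x 3 coordinate matrix
#' @param trajectory an [sbm_trajectory].
#' @param i frame number.
#' @export
traj_frame <- function(trajectory, i) {
  matrix(trajectory$xyz[i, ], ncol = 3, byrow = TRUE)
}

# flatten an n x 3 matrix into a frame row
as_frame_row <- function(coords) as.numeric(t(coords))

topo_cxx_list <- function(topology) {
  harm <- rbind(
    setNames(topology$impropers, c("i", "j", "k", "l", "x0", "eps")),
    setNames(topology$planars, c("i", "j", "k", "l", "x0", "eps")))
  list(masses = topology$masses,
       bonds = as.matrix(topology$bonds[, c("i", "j", "r0", "eps")]),
       angles = as.matrix(topology$angles[, c("i", "j", "k", "theta0",
                                              "eps")]),
       harm_dihedrals = as.matrix(harm),
       propers = as.matrix(topology$propers[, c("i", "j", "k", "l", "phi0",
                                                "eps")]),
       contacts = as.matrix(topology$contacts[, c("i", "j", "r_alpha",
                                                  "r_beta", "weight")]),
       gauss_A = topology$gauss_A, gauss_sigma = topology$gauss_sigma,
       eps_nc = topology$eps_nc, sigma_nc = topology$sigma_nc)
}

#' Dual-basin Gaussian contact energy for a single pair
#'
#' Evaluates the multibasin contact
#' `C(r) = (1 + (sigma_NC/r)^12)(1 + G(r, r_alpha))(1 + G(r, r_beta)) - 1`
#' with Gaussian wells `G(r, r0) = -A exp(-(r - r0)^2 / (2 sigma^2))`;
#' single-basin records use one Gaussian factor only. With A = 1 each well
#' floor sits at exactly -1.
#'
#' @param r distance (A), vectorized.
#' @param r_alpha,r_beta native distances; `NA` drops that basin.
#' @param A Gaussian amplitude (default 1).
#' @param sigma Gaussian width (default 0.5 A).
#' @param sigma_nc excluded-volume size (default 2.5 A).
#' @return Contact energy in reduced units (per unit weight).
#' @export
contact_energy <- function(r, r_alpha = NA, r_beta = NA, A = 1, sigma = 0.5,
                           sigma_nc = 2.5) {
  if (any(r <= 0)) stop("divergence guard: r must be > 0")
  g <- function(r0) if (is.na(r0)) 0 else
    -A * exp(-(r - r0)^2 / (2 * sigma^2))
  if (is.na(r_alpha) && is.na(r_beta))
    stop("at least one native distance is required")
  (1 + (sigma_nc / r)^12) * (1 + g(r_alpha)) * (1 + g(r_beta)) - 1
}

#' Evaluate the full potential and forces for one frame
#'
#' Energy components follow the structure-based form: harmonic bonds and
#' angles, harmonic improper/planar dihedrals, proper dihedrals
#' `eps[(1 - cos d) + 1/2 (1 - cos 3d)]` with `d = phi - phi0`, weighted
#' multibasin contacts, and `eps_NC (sigma_NC/r)^12` excluded volume over
#' all non-bonded, non-contact pairs. Forces are the exact negative
#' gradient.
#'
#' @param topology an [sbm_topology].
#' @param coordinates n x 3 matrix (A).
#' @return list with `energy` (named components + total) and `forces`
#'   (n x 3 matrix).
#' @export
evaluate_potential <- function(topology, coordinates) {
  coordinates <- as.matrix(coordinates)
  if (anyNA(coordinates) || !all(is.finite(coordinates)))
    stop("invalid state: non-finite coordinates")
  if (nrow(coordinates) != length(topology$masses))
    stop("atom count mismatch between topology and coordinates")
  res <- .sbm_energy_forces(coordinates, topo_cxx_list(topology))
  energy <- c(bond = res$bond, angle = res$angle, dihedral = res$dihedral,
              contact = res$contact, excluded = res$excluded,
              total = res$total)
  list(energy = energy, forces = res$forces)
}

#' Run Langevin dynamics
#'
#' BAOAB-split Langevin integration in reduced units (k_B = 1). With
#' `friction = 0` the scheme reduces to velocity Verlet (NVE). Trajectories
#' are bit-reproducible for a fixed seed.
#'
#' @param topology an [sbm_topology].
#' @param coordinates starting n x 3 coordinates (A).
#' @param params list of simulation parameters: `timestep` (reduced,
#'   default 0.002), `temperature` (reduced, default 0.3), `friction`
#'   (per reduced time, default 1), `n_steps`, `output_stride`, `seed`.
#' @return An [sbm_trajectory] with per-frame energy components attached.
#' @export
run_langevin <- function(topology, coordinates, params = list()) {
  p <- modifyList(list(timestep = 0.002, temperature = 0.3, friction = 1,
                       n_steps = 10000L, output_stride = 100L, seed = 1L),
                  params)
  stopifnot(p$timestep > 0, p$n_steps >= 1, p$output_stride >= 1)
  coordinates <- as.matrix(coordinates)
  res <- .sbm_run_langevin(coordinates, topo_cxx_list(topology),
                           as.integer(p$n_steps), p$timestep, p$temperature,
                           p$friction, as.integer(p$seed),
                           as.integer(p$output_stride),
                           3 * topology$sigma_nc, 20L)
  energies <- data.frame(step = res$step_index, potential = res$potential,
                         kinetic = res$kinetic, bond = res$bond,
                         angle = res$angle, dihedral = res$dihedral,
                         contact = res$contact, excluded = res$excluded)
  sbm_trajectory(res$frames, step_index = res$step_index,
                 topology = topology, seed = p$seed, energies = energies)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param trajectory an [sbm_trajectory] whose topology carries atom
#'   bookkeeping (or plain beads are written as CA atoms).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(trajectory, path) {
  n <- ncol(trajectory$xyz) / 3
  at <- trajectory$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(trajectory))) {
    writeLines(sprintf("MODEL %8d", f), con)
    fr <- traj_frame(trajectory, f)
    for (i in seq_len(n)) {
      nm <- if (!is.null(at)) at$elety[i] else "CA"
      rs <- if (!is.null(at)) at$resid[i] else "GLY"
      rn <- if (!is.null(at)) at$resno[i] else i
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        i, substr(nm, 1, 4), substr(rs, 1, 3), rn %% 10000,
        fr[i, 1], fr[i, 2], fr[i, 3]), con)
    }
    writeLines("ENDMDL", con)
  }
  invisible(path)
}
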