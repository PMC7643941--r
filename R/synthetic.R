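#' Two-state telegraph model
#'
#' Parameters of the telegraph process used to emulate clamshell
#' open/close kinetics at the ligand K_D: exponential dwells in each state,
#' one FRET level per state, optional additive Gaussian read noise.
#'
#' @param k_open_to_closed,k_closed_to_open rates (s^-1). Equal rates of
#'   1000/4.7 s^-1 emulate the reference system's ~4.7 ms mean dwells with
#'   50/50 occupancy.
#' @param E_open,E_closed FRET level of each state (defaults 0.35 / 0.65:
#'   the open conformation has the larger dye separation, hence the lower
#'   efficiency).
#' @param R_open,R_closed inter-dye distances (A) the levels correspond to.
#' @param noise_sd additive Gaussian noise on efficiency (default 0:
#'   idealized efficiencies).
#' @param step_duration step duration in ns.
#' @param seed RNG seed.
#' @return list of class `two_state_model`.
#' @export
two_state_model <- function(k_open_to_closed = 1000 / 4.7,
                            k_closed_to_open = 1000 / 4.7,
                            E_open = 0.35, E_closed = 0.65,
                            R_open = 69, R_closed = 56,
                            noise_sd = 0, step_duration = 1e4,
                            seed = 1L) {
  stopifnot(k_open_to_closed > 0, k_closed_to_open > 0,
            E_open >= 0, E_open <= 1, E_closed >= 0, E_closed <= 1)
  structure(list(k_oc = k_open_to_closed, k_co = k_closed_to_open,
                 E_open = E_open, E_closed = E_closed,
                 R_open = R_open, R_closed = R_closed,
                 noise_sd = noise_sd, step_duration = step_duration,
                 seed = as.integer(seed),
                 occupancy_closed = k_open_to_closed /
                   (k_open_to_closed + k_closed_to_open)),
            class = "two_state_model")
}

#' Generate a telegraph FRET trace
#'
#' Draws exponential dwell times from the stored seed, discretizes the
#' state path at the model's step duration, and emits the efficiency
#' series (state level plus optional Gaussian noise, clipped to `[0, 1]`).
#' The true switch points are returned for oracle tests.
#'
#' @param model a [two_state_model].
#' @param duration total duration in seconds; must cover at least ~10
#'   expected dwell events.
#' @return list: `state` (1 = open, 2 = closed per step), `efficiency`,
#'   `switch_steps` (first step of each new dwell), `dwell_times_s`
#'   (drawn continuous dwells), `model`, `step_duration`.
#' @export
generate_two_state_trace <- function(model, duration) {
  expected_events <- duration / (1 / model$k_oc + 1 / model$k_co) * 2
  if (expected_events < 10)
    stop("insufficient events: duration covers fewer than 10 expected ",
         "dwells")
  set.seed(model$seed)
  # draw dwells until the window is covered (small safety margin)
  states <- integer(0); dwells <- numeric(0)
  cur <- 1L # start open
  total <- 0
  while (total < duration) {
    k <- ceiling((duration - total) *
                   max(model$k_oc, model$k_co) * 1.5) + 10
    # states alternate deterministically; dwells are per-state exponentials
    st <- rep_len(if (cur == 1L) c(1L, 2L) else c(2L, 1L), k)
    dw <- rexp(k, rate = ifelse(st == 1L, model$k_oc, model$k_co))
    states <- c(states, st); dwells <- c(dwells, dw)
    total <- total + sum(dw)
    cur <- if (st[k] == 1L) 2L else 1L
  }
  step_s <- model$step_duration * 1e-9
  n_steps <- floor(duration / step_s)
  edges <- cumsum(dwells)
  t_mid <- (seq_len(n_steps) - 0.5) * step_s
  idx <- findInterval(t_mid, c(0, edges), rightmost.closed = TRUE)
  state <- states[pmin(idx, length(states))]
  eff <- ifelse(state == 1L, model$E_open, model$E_closed)
  if (model$noise_sd > 0)
    eff <- pmin(1, pmax(0, eff + rnorm(n_steps, 0, model$noise_sd)))
  switch_steps <- which(diff(state) != 0) + 1L
  list(state = state, efficiency = eff, switch_steps = switch_steps,
       dwell_times_s = dwells[seq_len(min(length(dwells),
                                          findInterval(duration, c(0, edges)) + 1))],
       model = model, step_duration = model$step_duration)
}

#' Toy dual-basin bead system
#'
#' A 2-10 bead system whose end-to-end pair interaction is exactly the
#' dual-basin Gaussian contact. Beads beyond the first pair form a
#' harmonic chain. For the 2-bead case an analytic Boltzmann occupancy
#' prediction (1-D quadrature over the radial coordinate with the r^2
#' Jacobian) is included.
#'
#' @param r_alpha,r_beta well distances (A), distinct and > sigma_NC.
#' @param depth_alpha,depth_beta well depths in epsilon_0 (positive
#'   numbers; realized via per-well single-basin records when unequal).
#' @param temperature reduced temperature for the occupancy prediction.
#' @param n_beads 2 to 10.
#' @param gauss_sigma Gaussian well width (default 0.5 A).
#' @return list of class `toy_system`: `topology`, `coords_alpha`,
#'   `coords_beta`, `occupancy` (predicted alpha-basin occupancy for
#'   2 beads), `params`.
#' @export
generate_toy_dual_basin <- function(r_alpha = 5, r_beta = 10,
                                    depth_alpha = 1, depth_beta = 1,
                                    temperature = 0.3, n_beads = 2L,
                                    gauss_sigma = 0.5) {
  sigma_nc <- 2.5
  stopifnot(r_alpha != r_beta, r_alpha > sigma_nc, r_beta > sigma_nc,
            n_beads >= 2, n_beads <= 10)
  if (abs(r_alpha - r_beta) < 2 * gauss_sigma)
    warning("resolution warning: wells closer than 2 sigma overlap")
  if (depth_alpha == depth_beta) {
    contacts <- data.frame(i = 1L, j = 2L, r_alpha = r_alpha,
                           r_beta = r_beta, weight = depth_alpha,
                           category = "shared-dual",
                           stringsAsFactors = FALSE)
  } else {
    contacts <- data.frame(i = c(1L, 1L), j = c(2L, 2L),
                           r_alpha = c(r_alpha, NA), r_beta = c(NA, r_beta),
                           weight = c(depth_alpha, depth_beta),
                           category = c("alpha-only", "beta-only"),
                           stringsAsFactors = FALSE)
  }
  bonds <- if (n_beads > 2)
    data.frame(i = 2:(n_beads - 1), j = 3:n_beads,
               r0 = 3.8, eps = 50) else empty_bonds()
  topo <- sbm_topology(masses = rep(1, n_beads), bonds = bonds,
                       contacts = contacts, gauss_sigma = gauss_sigma)
  place <- function(r12) {
    xyz <- matrix(0, n_beads, 3)
    xyz[2, 1] <- r12
    if (n_beads > 2)
      for (b in 3:n_beads) xyz[b, ] <- xyz[b - 1, ] + c(3.8, 0, 0)
    xyz
  }
  pair_energy <- function(r) {
    e <- 0
    for (rr in seq_len(nrow(contacts)))
      e <- e + contacts$weight[rr] *
        contact_energy(r, contacts$r_alpha[rr], contacts$r_beta[rr],
                       sigma = gauss_sigma, sigma_nc = sigma_nc)
    e
  }
  # Boltzmann weight of the alpha basin for the 2-bead radial coordinate
  mid <- (r_alpha + r_beta) / 2
  zr <- function(lo, hi) stats::integrate(function(r)
    r^2 * exp(-vapply(r, pair_energy, numeric(1)) / temperature),
    lo, hi, rel.tol = 1e-9)$value
  lo_a <- min(r_alpha, r_beta) - 2; hi_b <- max(r_alpha, r_beta) + 2
  za <- zr(lo_a, mid); zb <- zr(mid, hi_b)
  structure(list(topology = topo, coords_alpha = place(r_alpha),
                 coords_beta = place(r_beta),
                 occupancy_alpha = za / (za + zb),
                 pair_energy = pair_energy,
                 params = list(r_alpha = r_alpha, r_beta = r_beta,
                               depth_alpha = depth_alpha,
                               depth_beta = depth_beta,
                               temperature = temperature,
                               gauss_sigma = gauss_sigma)),
            class = "toy_system")
}

#' Monte-Carlo isotropic kappa^2 average
#'
#' Draws donor dipole, acceptor dipole and separation directions uniformly
#' on the sphere and averages the orientation factor; the isotropic limit
#' is 2/3.
#'
#' @param n number of draws (>= 100).
#' @param seed RNG seed.
#' @return list: `mean`, `se` (standard error), `kappa2` (per-draw),
#'   `n`.
#' @export
sample_isotropic_kappa2 <- function(n, seed = 1L) {
  stopifnot(n >= 100)
  set.seed(seed)
  unit <- function(n) {
    m <- matrix(rnorm(3 * n), n, 3)
    m / sqrt(rowSums(m^2))
  }
  d <- unit(n); a <- unit(n); r <- unit(n)
  k2 <- (rowSums(d * a) - 3 * rowSums(d * r) * rowSums(a * r))^2
  list(mean = mean(k2), se = sd(k2) / sqrt(n), kappa2 = k2, n = n)
}

#' Pure 1-D Brownian path
#'
#' @param n_steps number of steps.
#' @param D diffusion coefficient (A^2/ns).
#' @param step_duration step length (ns).
#' @param seed RNG seed.
#' @param x0 starting position.
#' @return numeric series of positions (A).
#' @export
generate_brownian_path <- function(n_steps, D, step_duration = 1,
                                   seed = 1L, x0 = 0) {
  set.seed(seed)
  x0 + cumsum(c(0, rnorm(n_steps - 1, 0, sqrt(2 * D * step_duration))))
}
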