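test_that("dual-basin contact energy matches its closed form", {
  # at the alpha floor the (1+G) factor vanishes: exactly -1
  expect_equal(contact_energy(5, 5, 10), -1)
  # far asymptote
  expect_lt(abs(contact_energy(100, 5, 10)), 1e-9)
  # at r = sigma_NC the repulsive factor doubles and Gaussians are tiny
  expect_equal(contact_energy(2.5, 5, 10), 1, tolerance = 1e-4)
  # single-basin records use one Gaussian factor only
  r <- seq(3, 12, by = 0.25)
  manual <- (1 + (2.5 / r)^12) * (1 - exp(-(r - 5)^2 / (2 * 0.5^2))) - 1
  expect_equal(contact_energy(r, 5, NA), manual, tolerance = 1e-12)
  expect_error(contact_energy(0, 5, 10), "divergence")
  expect_error(contact_energy(3, NA, NA), "at least one")
})

test_that("forces are the exact negative gradient for every term type", {
  topo <- all_terms_topology()
  set.seed(42)
  for (rep in 1:4) {
    x <- all_terms_coords() + matrix(rnorm(15, 0, 0.25), 5, 3)
    g_num <- fd_gradient(topo, x)
    g_ana <- -evaluate_potential(topo, x)$forces
    expect_lt(max(abs(g_num - g_ana)), 1e-5)
  }
  # energy report components sum to the total
  e <- evaluate_potential(topo, all_terms_coords())$energy
  expect_equal(e[["total"]],
               sum(e[c("bond", "angle", "dihedral", "contact", "excluded")]),
               tolerance = 1e-10)
  expect_error(evaluate_potential(topo, matrix(NaN, 5, 3)), "invalid state")
})

test_that("reference-conformation energies vanish for bonded terms", {
  set.seed(1)
  xyz <- matrix(runif(30, 0, 12), 10, 3)
  s <- bead_structure(xyz)
  topo <- build_dual_basin_topology(s, s, options = list(
    cutoff = 7, bond_pairs = cbind(1:9, 2:10)))
  e <- evaluate_potential(topo, xyz)$energy
  expect_equal(e[["bond"]], 0, tolerance = 1e-20)
  expect_equal(e[["angle"]], 0, tolerance = 1e-20)
  expect_equal(e[["dihedral"]], 0, tolerance = 1e-12)
  # every contact sits at its well floor: contact energy = -sum(weights)
  expect_equal(e[["contact"]], -sum(topo$contacts$weight),
               tolerance = 1e-9)
})

test_that("NVE limit conserves energy and trajectories are reproducible", {
  toy <- generate_toy_dual_basin()
  run <- function(seed, friction = 0)
    run_langevin(toy$topology, toy$coords_alpha,
                 list(n_steps = 100000L, output_stride = 100L,
                      temperature = 0.3, friction = friction, seed = seed))
  tr <- run(5)
  etot <- tr$energies$potential + tr$energies$kinetic
  drift <- max(abs(etot - etot[1]))
  expect_lt(drift / (abs(etot[1]) + 1), 1e-3)
  # bit-reproducibility under a fixed seed
  tr2 <- run(5)
  expect_identical(tr$xyz, tr2$xyz)
  tr3 <- run(6)
  expect_false(identical(tr$xyz, tr3$xyz))
})

test_that("Langevin sampling satisfies equipartition and bond statistics", {
  # stiff dimer: radial fluctuation variance ~ T / (2 k) with V = k(r-r0)^2
  topo <- sbm_topology(masses = c(1, 1),
                       bonds = data.frame(i = 1, j = 2, r0 = 5, eps = 50))
  x0 <- rbind(c(0, 0, 0), c(5, 0, 0))
  tr <- run_langevin(topo, x0, list(n_steps = 400000L, output_stride = 40L,
                                    temperature = 0.3, friction = 2,
                                    seed = 9))
  burn <- seq_len(500)
  r <- project_coordinate(tr, c(1, 2))[-burn]
  expect_equal(var(r), 0.3 / (2 * 50), tolerance = 0.05)
  # mean kinetic energy per degree of freedom = T/2 within 5%
  ke <- tr$energies$kinetic[-burn]
  expect_equal(mean(ke) / 6, 0.3 / 2, tolerance = 0.05)
})

test_that("two-bead dual basin obeys the Boltzmann occupancy ratio", {
  # equal well depths at 5 and 10 A: the radial Jacobian favors the
  # outer well; compare sampled occupancy with the quadrature prediction
  toy <- generate_toy_dual_basin(r_alpha = 5, r_beta = 10,
                                 temperature = 0.5)
  mid <- 7.5
  occ <- numeric(4)
  for (k in seq_along(occ)) {
    tr <- run_langevin(toy$topology, toy$coords_alpha,
                       list(n_steps = 150000L, output_stride = 25L,
                            temperature = 0.5, friction = 1,
                            seed = 100 + k))
    r <- project_coordinate(tr, c(1, 2))
    occ[k] <- mean(r < mid)
  }
  pred <- generate_toy_dual_basin(r_alpha = 5, r_beta = 10,
                                  temperature = 0.5)$occupancy_alpha
  se <- sd(occ) / sqrt(length(occ))
  expect_lt(abs(mean(occ) - pred), 3 * max(se, 0.03))
})

test_that("temperature calibration inverts a linear RMSF relation", {
  set.seed(2)
  xyz <- matrix(runif(24, 0, 9), 8, 3)
  s <- bead_structure(xyz)
  topo <- build_dual_basin_topology(s, s, options = list(
    cutoff = 7, bond_pairs = cbind(1:7, 2:8), dihedrals = FALSE))
  grid <- c(0.1, 0.3, 0.5)
  cal <- calibrate_temperature(topo, xyz, grid, reference_rmsf = 0.5,
                               n_steps = 12000L, output_stride = 30L,
                               seed = 4)
  # thermal scaling: fluctuations grow with temperature
  expect_true(all(diff(cal$table$rmsf) > 0))
  a <- coef(cal$fit)[2]; b <- coef(cal$fit)[1]
  expect_gt(a, 0)
  # returned temperature solves the fit at the reference (inversion)
  expect_equal(cal$temperature, unname((0.5 - b) / a), tolerance = 1e-12)
  # inversion identity at a grid point's fitted value
  ref_mid <- unname(a * 0.3 + b)
  cal2 <- calibrate_temperature(topo, xyz, grid, reference_rmsf = ref_mid,
                                n_steps = 12000L, output_stride = 30L,
                                seed = 4)
  expect_equal(cal2$temperature, 0.3, tolerance = 1e-9)
  expect_error(calibrate_temperature(topo, xyz, c(0.5, 2), 1), "is not TRUE")
})

test_that("contact-weight scan reports occupancy and nearest weight", {
  toy <- generate_toy_dual_basin(r_alpha = 5, r_beta = 10,
                                 depth_alpha = 1, depth_beta = 0.7,
                                 temperature = 0.5)
  res <- scan_contact_weight(
    toy$topology, toy$coords_beta, weights = c(0.2, 0.6, 1.0),
    coordinate = function(tr) project_coordinate(tr, c(1, 2)),
    threshold = 7.5, occupancy_target = 0.5,
    params = list(n_steps = 80000L, output_stride = 40L,
                  temperature = 0.5, friction = 1))
  expect_equal(nrow(res$table), 3)
  expect_true(res$weight %in% res$table$weight)
  expect_equal(res$weight,
               res$table$weight[which.min(abs(res$table$occupancy - 0.5))])
  # stronger beta-only (closed-specific) weight pulls occupancy down
  # (threshold marks the alpha basin): monotone trend across the scan
  expect_lte(res$table$occupancy[3], res$table$occupancy[1] + 0.1)
  # a single candidate weight is returned unconditionally
  single <- scan_contact_weight(
    toy$topology, toy$coords_beta, weights = 0.4,
    coordinate = function(tr) project_coordinate(tr, c(1, 2)),
    threshold = 7.5,
    params = list(n_steps = 4000L, output_stride = 40L,
                  temperature = 0.5, friction = 1))
  expect_equal(single$weight, 0.4)
})
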