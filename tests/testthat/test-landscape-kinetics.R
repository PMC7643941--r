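test_that("distance-difference matrix finds the planted argmax", {
  # identical structures: all-zero matrix
  set.seed(5)
  xyz <- matrix(runif(30, 0, 20), 10, 3)
  s <- bead_structure(xyz)
  s <- assign_domains(s, 1:5, 6:10)
  dm0 <- distance_delta_matrix(s, s)
  expect_true(all(dm0$delta == 0))
  # toy 2x2: one pair moved 13 A
  open <- bead_structure(rbind(c(0, 0, 0), c(0, 5, 0),
                               c(20, 0, 0), c(20, 5, 0)))
  closed <- open
  closed$xyz[3, 1] <- 33 # residue 3 moves 13 A away from residue 1
  open <- assign_domains(open, 1:2, 3:4)
  closed <- assign_domains(closed, 1:2, 3:4)
  dm <- distance_delta_matrix(open, closed)
  expect_equal(dm$argmax, c(1, 3))
  expect_equal(dm$max_delta, 13)
  expect_error(distance_delta_matrix(open, closed, integer(), 3:4),
               "non-empty")
})

test_that("coordinate projection matches per-frame arithmetic", {
  frames <- lapply(1:4, function(k) rbind(c(0, 0, 0), c(20, 0, 0),
                                          c(1, 2, 3)))
  tr <- frames_trajectory(frames)
  expect_equal(project_coordinate(tr, c(1, 2)), rep(20, 4))
  set.seed(6)
  frames2 <- lapply(1:6, function(k) matrix(rnorm(12, 0, 4), 4, 3))
  tr2 <- frames_trajectory(frames2)
  want <- vapply(frames2, function(f) sqrt(sum((f[2, ] - f[4, ])^2)),
                 numeric(1))
  expect_equal(project_coordinate(tr2, c(2, 4)), want, tolerance = 1e-12)
  # COM-pair on single-atom groups equals the atom-pair definition
  expect_equal(project_coordinate(tr2, list(group_a = 2, group_b = 4)),
               project_coordinate(tr2, c(2, 4)))
})

test_that("Boltzmann landscape applies -kT ln(P/Pmax) with zero minimum", {
  # uniform occupancy: flat at zero
  u <- rep(seq(0.5, 9.5, by = 1), each = 10)
  ls <- boltzmann_landscape(u, bins = 10, temperature = 300)
  expect_true(all(abs(ls$dG) < 1e-12))
  # a bin with P = Pmax e^-2 sits at 2 kT = 1.192 kcal/mol at 300 K
  n2 <- round(1000 * exp(-2))
  x <- c(rep(2, 1000), rep(8, n2))
  ls2 <- boltzmann_landscape(x, bins = 12, temperature = 300)
  expect_equal(min(ls2$dG, na.rm = TRUE), 0)
  hi <- ls2$dG[which.min(abs(ls2$mids - 8))]
  expect_equal(hi, -KB_KCAL * 300 * log(n2 / 1000), tolerance = 1e-9)
  expect_equal(hi, 2 * KB_KCAL * 300, tolerance = 0.01)
  expect_equal(2 * KB_KCAL * 300, 1.192, tolerance = 1e-3)
  # empty bins are undefined, not zero
  expect_true(anyNA(ls2$dG))
  expect_error(boltzmann_landscape(numeric()), "no-data")
})

test_that("landscape reconstruction recovers a generating double well", {
  # draw from a known Boltzmann density on a fine grid and re-derive G
  kT <- KB_KCAL * 300
  G <- function(x) 3 * ((x / 2)^2 - 1)^2 # kcal/mol, wells at +-2
  xs <- seq(-3.4, 3.4, length.out = 2000)
  p <- exp(-G(xs) / kT); p <- p / sum(p)
  set.seed(21)
  draws <- sample(xs, 1e6, replace = TRUE, prob = p)
  ls <- boltzmann_landscape(draws, bins = 40, temperature = 300)
  # oracle: exact binned probability of the generating distribution
  br <- c(ls$mids - diff(ls$mids[1:2]) / 2,
          ls$mids[length(ls$mids)] + diff(ls$mids[1:2]) / 2)
  p_bin <- vapply(seq_along(ls$mids), function(b)
    sum(p[xs >= br[b] & xs < br[b + 1]]), numeric(1))
  ref <- -kT * log(p_bin / max(p_bin))
  ok <- !is.na(ls$dG) & ls$counts > 200
  expect_lt(max(abs(ls$dG[ok] - ref[ok])), 0.1)
})

test_that("pearson correlation matches the product-moment formula", {
  x <- 1:20
  expect_equal(pearson_correlation(x, 2 * x + 1), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  set.seed(9)
  a <- rnorm(20); b <- rnorm(20)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_correlation(a, b), num / den, tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "length")
})

test_that("MSD-based diffusion recovers a known Brownian coefficient", {
  x <- generate_brownian_path(2e5, D = 0.5, step_duration = 1, seed = 31)
  est <- estimate_diffusion(x, step_duration = 1, lags = 1:40)
  expect_equal(est$D, 0.5, tolerance = 0.1)
  expect_gt(est$fit_r2, 0.99)
  # constant series: D ~ 0 with a regime warning
  expect_warning(flat <- estimate_diffusion(rep(3, 1000), 1, lags = 1:20),
                 "regime")
  expect_lt(flat$D, 1e-6)
  # unit conversion: 0.3 um^2/s = 0.03 A^2/ns
  expect_equal(diffusion_um2s_to_A2ns(0.3), 0.03)
  expect_equal(est$D_um2_per_s, est$D * 10)
})

test_that("MFPT rate matches flat-potential and Kramers closed forms", {
  # flat G over length L with constant D: k = 2D/L^2
  L <- 10; D <- 0.5
  mids <- seq(0, L, length.out = 400)
  flat <- list(mids = mids, dG = rep(0, 400))
  k <- mfpt_rate(flat, D, start = 0, end = L)$k
  expect_equal(k, 2 * D / L^2, tolerance = 0.01)
  # doubling D doubles the rate exactly
  expect_equal(mfpt_rate(flat, 2 * D, 0, L)$k, 2 * k, tolerance = 1e-9)
  # harmonic double well with a 5 kT barrier vs the overdamped
  # Kramers rate k = D sqrt(U''_min |U''_max|) / (2 pi kT) e^{-dU/kT}
  kT <- KB_KCAL * 300
  h <- 5 * kT; a <- 2
  G <- function(x) h * ((x / a)^2 - 1)^2
  xs <- seq(-a, a, length.out = 3000)
  ls <- list(mids = xs, dG = G(xs))
  got <- mfpt_rate(ls, D, start = -a, end = a)$k
  upp_min <- 8 * h / a^2; upp_max <- 4 * h / a^2
  kramers <- D * sqrt(upp_min * upp_max) / (2 * pi * kT) * exp(-h / kT)
  expect_equal(got, kramers, tolerance = 0.2)
  # rate decreases monotonically with barrier height
  rates <- vapply(c(2, 4, 6) * kT, function(hh) {
    mfpt_rate(list(mids = xs, dG = hh * ((xs / a)^2 - 1)^2), D, -a, a)$k
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
  expect_error(mfpt_rate(list(mids = xs, dG = c(NA, G(xs)[-1])), D, -a, a),
               "interpolation policy")
})

test_that("RMSD/RMSF vanish for copies and ignore rigid motion", {
  set.seed(15)
  ref <- matrix(runif(24, 0, 10), 8, 3)
  s <- bead_structure(ref)
  copies <- frames_trajectory(replicate(4, ref, simplify = FALSE))
  res <- rmsd_rmsf(copies, s, selection = 1:8)
  expect_true(all(res$rmsd < 1e-8))
  expect_true(all(res$rmsf < 1e-8))
  # rigid translation + rotation: zero RMSD after superposition
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- frames_trajectory(list(ref, t(R %*% t(ref)) + 5))
  res2 <- rmsd_rmsf(moved, s, selection = 1:8)
  expect_true(all(res2$rmsd < 1e-6))
  # one atom displaced by 1 A in one of two frames: hand arithmetic
  f2 <- ref; f2[3, 1] <- f2[3, 1] + 1
  # fit on the unmoved atoms so the displacement is not absorbed
  tr <- frames_trajectory(list(ref, f2))
  res3 <- rmsd_rmsf(tr, s, selection = (1:8)[-3])
  d3 <- sqrt(sum((traj_frame(tr, 2) - ref)[3, ]^2))
  expect_equal(d3, 1, tolerance = 1e-9)
})
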