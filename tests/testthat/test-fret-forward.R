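test_that("inter-chromophore distance is the COM distance per frame", {
  f <- rbind(c(0, 0, 0), c(3, 4, 0))
  tr <- frames_trajectory(list(f))
  expect_equal(compute_r_dye(tr, 1, 2), 5)
  # coincident centers of mass
  f2 <- rbind(c(1, 1, 1), c(1, 1, 1))
  expect_equal(compute_r_dye(frames_trajectory(list(f2)), 1, 2), 0)
  # multi-atom chromophores against brute-force COM arithmetic
  set.seed(3)
  frames <- lapply(1:5, function(k) matrix(rnorm(18, 0, 5), 6, 3))
  tr5 <- frames_trajectory(frames)
  got <- compute_r_dye(tr5, 1:3, 4:6)
  want <- vapply(frames, function(f)
    sqrt(sum((colMeans(f[1:3, ]) - colMeans(f[4:6, ]))^2)), numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(compute_r_dye(tr5, integer(), 4:6), "definition error")
})

test_that("kappa^2 reproduces the canonical orientation geometries", {
  mk <- function(d1, d2, a1, a2) frames_trajectory(list(rbind(d1, d2, a1, a2)))
  k2 <- function(tr) compute_kappa2(tr, c(1, 2), c(3, 4))$kappa2
  # collinear dipoles along the separation axis: (1 - 3)^2 = 4
  expect_equal(k2(mk(c(-0.5, 0, 0), c(0.5, 0, 0),
                     c(9.5, 0, 0), c(10.5, 0, 0))), 4)
  # parallel dipoles perpendicular to the separation: 1
  expect_equal(k2(mk(c(0, -0.5, 0), c(0, 0.5, 0),
                     c(10, -0.5, 0), c(10, 0.5, 0))), 1)
  # mutually perpendicular, both normal to the separation: 0
  expect_equal(k2(mk(c(0, -0.5, 0), c(0, 0.5, 0),
                     c(10, 0, -0.5), c(10, 0, 0.5))), 0)
  expect_error(compute_kappa2(mk(c(0, 0, 0), c(0, 0, 0),
                                 c(10, 0, 0), c(10, 1, 0)),
                              c(1, 2), c(3, 4)), "geometry error")
})

test_that("Forster radius rescaling follows the kappa^2^(1/6) law", {
  expect_equal(compute_forster_radius(kappa2 = 0.58, R_ref = 62,
                                      kappa2_ref = 0.58), 62)
  # moving to the isotropic 2/3 lengthens R0 by about 1 A
  r0_iso <- compute_forster_radius(kappa2 = 2 / 3, R_ref = 62,
                                   kappa2_ref = 0.58)
  expect_equal(r0_iso, 62 * (2 / 3 / 0.58)^(1 / 6), tolerance = 1e-12)
  expect_equal(r0_iso, 63.46, tolerance = 0.01)
  # compute mode round-trips through the spectral overlap
  J <- invert_forster_overlap(62, kappa2 = 0.58)
  expect_equal(compute_forster_radius(kappa2 = 0.58, J = J), 62,
               tolerance = 1e-9)
  expect_error(compute_forster_radius(kappa2 = 0.58), "underdetermined")
})

test_that("FRET efficiency matches the worked distance conversions", {
  expect_equal(fret_efficiency(62, 62), 0.5)
  expect_equal(fret_efficiency(56, 62), 0.648, tolerance = 5e-4)
  expect_equal(fret_efficiency(69, 62), 0.345, tolerance = 5e-4)
  # strictly decreasing in r
  r <- seq(10, 120, by = 1)
  expect_true(all(diff(fret_efficiency(r, 62)) < 0))
})

test_that("exposure binning averages full bins and drops the tail", {
  # 1 ms at 0.25 ns steps: 4 million steps per camera frame
  expect_equal(bin_exposure(numeric(0), 0.25, 1)$bin_size, 4e6)
  # constant series stays constant
  b <- bin_exposure(rep(0.7, 100), 1e6, 5)
  expect_equal(b$bin_size, 5)
  expect_equal(b$binned, rep(0.7, 20))
  # alternating series averages to the midpoint
  b2 <- bin_exposure(rep(c(0, 1), 50), 1e6, 2)
  expect_equal(b2$binned, rep(0.5, 50))
  # trailing partial bin discarded, mean preserved over the kept part
  x <- runif(103)
  b3 <- bin_exposure(x, 1e6, 10)
  expect_length(b3$binned, 10)
  expect_equal(mean(b3$binned), mean(x[1:100]), tolerance = 1e-12)
  expect_error(bin_exposure(1:5, 10, 1e-9), "resolution error")
})

test_that("binned-trace variance shrinks with exposure on stationary input", {
  set.seed(8)
  x <- runif(20000)
  v <- vapply(c(2, 10, 50, 250), function(ex)
    var(bin_exposure(x, 1e6, ex)$binned), numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("camera traces compose distance, efficiency and binning", {
  # two-state square wave slower than the exposure: trace alternates
  # near the worked 0.65 / 0.35 levels
  frames <- lapply(1:40, function(k) {
    d <- if (((k - 1) %/% 10) %% 2 == 0) 56 else 69
    rbind(c(0, 0, 0), c(d, 0, 0))
  })
  tr <- frames_trajectory(frames)
  out <- simulate_camera_trace(tr, 1, 2, r0 = 62, step_duration = 1e6,
                               exposures = c(5, 40), frame_stride = 1)
  fast <- out[[1]]$efficiency
  expect_equal(sort(unique(round(fast, 3))), c(0.345, 0.648),
               tolerance = 5e-3)
  # exposure much longer than the dwell collapses to the mixed mean
  slow <- out[[2]]$efficiency
  expect_equal(slow, mean(c(rep(fret_efficiency(56, 62), 20),
                            rep(fret_efficiency(69, 62), 20))),
               tolerance = 1e-9)
  # single frame at exposure = step: one bin with the instantaneous value
  one <- simulate_camera_trace(frames_trajectory(frames[1]), 1, 2,
                               r0 = 62, step_duration = 1e6,
                               exposures = 1, frame_stride = 1)
  expect_equal(one[[1]]$efficiency, fret_efficiency(56, 62))
})

test_that("trace TSV round-trips", {
  tr <- fret_trace(c(0.2, 0.5, 0.8), exposure = 10, bin_size = 100,
                   step_duration = 0.25, source = "test")
  p <- tempfile(fileext = ".tsv")
  write_trace_tsv(tr, p)
  back <- read_trace_tsv(p)
  expect_equal(back$efficiency, tr$efficiency, tolerance = 1e-9)
  expect_equal(attr(back, "exposure"), 10, tolerance = 1e-9)
})
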