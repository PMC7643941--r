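#' Boltzmann constant in kcal/mol/K
#' @export
KB_KCAL <- 0.0019872

#' Inter-domain C-alpha distance-difference matrix
#'
#' For every C-alpha pair (i in domain 1, j in domain 2), the absolute
#' difference between the open- and closed-conformation distances
#' `|d_open - d_closed|`. The argmax pair defines the maximum-amplitude
#' inter-domain reaction coordinate; ties break to the lowest residue
#' numbers.
#'
#' @param open,closed [sbm_structure] objects with shared residue
#'   numbering.
#' @param domain1,domain2 residue-number vectors (default: from the
#'   structures' domain assignment).
#' @return list of class `distance_delta_matrix`: `delta` (matrix, rows =
#'   domain-1 residues, cols = domain-2 residues), `argmax` (residue pair),
#'   `max_delta`, `skipped` (residues without a C-alpha).
#' @export
distance_delta_matrix <- function(open, closed, domain1 = NULL,
                                  domain2 = NULL) {
  if (is.null(domain1) && !is.null(open$domains)) {
    domain1 <- open$domains$resno[open$domains$domain %in% 1]
    domain2 <- open$domains$resno[open$domains$domain %in% 2]
  }
  if (!length(domain1) || !length(domain2))
    stop("both domains must be non-empty")
  ca_of <- function(s, resnos) {
    idx <- vapply(resnos, function(r) {
      hit <- which(s$atoms$resno == r & s$atoms$elety == "CA")
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
    idx
  }
  i1o <- ca_of(open, domain1); i2o <- ca_of(open, domain2)
  i1c <- ca_of(closed, domain1); i2c <- ca_of(closed, domain2)
  skipped <- c(domain1[is.na(i1o) | is.na(i1c)],
               domain2[is.na(i2o) | is.na(i2c)])
  if (length(skipped))
    warning("residues without C-alpha skipped: ",
            paste(skipped, collapse = ", "))
  k1 <- !is.na(i1o) & !is.na(i1c); k2 <- !is.na(i2o) & !is.na(i2c)
  domain1 <- domain1[k1]; domain2 <- domain2[k2]
  dmat <- function(xyz, ii, jj) {
    a <- xyz[ii, , drop = FALSE]; b <- xyz[jj, , drop = FALSE]
    sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b))
  }
  d_open <- dmat(open$xyz, i1o[k1], i2o[k2])
  d_closed <- dmat(closed$xyz, i1c[k1], i2c[k2])
  delta <- abs(d_open - d_closed)
  dimnames(delta) <- list(domain1, domain2)
  # argmax with ties to lowest residue numbers (row-major over sorted rows)
  best <- which(delta == max(delta), arr.ind = TRUE)
  best <- best[order(domain1[best[, 1]], domain2[best[, 2]]), , drop = FALSE]
  structure(list(delta = delta,
                 argmax = c(domain1[best[1, 1]], domain2[best[1, 2]]),
                 max_delta = max(delta), skipped = skipped),
            class = "distance_delta_matrix")
}

#' @export
print.distance_delta_matrix <- function(x, ...) {
  cat("distance_delta_matrix:", nrow(x$delta), "x", ncol(x$delta),
      "residue pairs; argmax", paste(x$argmax, collapse = "-"),
      "with delta =", signif(x$max_delta, 4), "A\n")
  invisible(x)
}

#' Project a trajectory onto a scalar distance coordinate
#'
#' @param trajectory an [sbm_trajectory].
#' @param definition either a length-2 atom index vector (atom-pair
#'   distance) or a list(group_a, group_b) of atom sets (COM-pair
#'   distance).
#' @return numeric per-frame series (A).
#' @export
project_coordinate <- function(trajectory, definition) {
  if (is.list(definition))
    return(compute_r_dye(trajectory, definition$group_a,
                         definition$group_b,
                         masses = rep(1, ncol(trajectory$xyz) / 3)))
  stopifnot(length(definition) == 2)
  i <- definition[1]; j <- definition[2]
  cols_i <- 3 * (i - 1) + 1:3
  cols_j <- 3 * (j - 1) + 1:3
  d <- trajectory$xyz[, cols_i, drop = FALSE] -
    trajectory$xyz[, cols_j, drop = FALSE]
  sqrt(rowSums(d * d))
}

#' Boltzmann-weighted free-energy landscape
#'
#' Bins one or two coordinate series and converts occupancies to an
#' approximate free energy `dG* = -k_B T ln(P(x_i) / P_max)`, so the most
#' occupied bin sits at exactly zero. Empty bins are `NA` (undefined), not
#' zero.
#'
#' @param series numeric vector, or list of two aligned vectors for a 2-D
#'   landscape.
#' @param bins number of bins per coordinate (default 50); the grid covers
#'   the observed range widened by 5 percent.
#' @param temperature in Kelvin (default 300).
#' @return list of class `free_energy_landscape`: `mids` (vector or list),
#'   `dG` (vector/matrix, kcal/mol), `counts`, `temperature`.
#' @export
boltzmann_landscape <- function(series, bins = 50L, temperature = 300) {
  two_d <- is.list(series)
  if (two_d) {
    stopifnot(length(series) == 2,
              length(series[[1]]) == length(series[[2]]))
    if (!length(series[[1]])) stop("no-data error: empty series")
  } else if (!length(series)) stop("no-data error: empty series")
  grid <- function(v) {
    r <- range(v)
    pad <- 0.05 * max(diff(r), 1e-9)
    seq(r[1] - pad, r[2] + pad, length.out = bins + 1)
  }
  if (!two_d) {
    br <- grid(series)
    counts <- as.integer(table(cut(series, br, include.lowest = TRUE)))
    mids <- head(br, -1) + diff(br) / 2
  } else {
    br1 <- grid(series[[1]]); br2 <- grid(series[[2]])
    b1 <- cut(series[[1]], br1, include.lowest = TRUE, labels = FALSE)
    b2 <- cut(series[[2]], br2, include.lowest = TRUE, labels = FALSE)
    counts <- matrix(0L, bins, bins)
    for (k in seq_along(b1))
      counts[b1[k], b2[k]] <- counts[b1[k], b2[k]] + 1L
    mids <- list(head(br1, -1) + diff(br1) / 2,
                 head(br2, -1) + diff(br2) / 2)
  }
  pmaxv <- max(counts)
  dG <- -KB_KCAL * temperature * log(counts / pmaxv)
  dG[counts == 0] <- NA_real_
  structure(list(mids = mids, dG = dG, counts = counts,
                 temperature = temperature),
            class = "free_energy_landscape")
}

#' Barrier height between two basins on a 1-D landscape
#'
#' @param landscape a 1-D [boltzmann_landscape] result.
#' @param basin_a,basin_b coordinate values near the two minima.
#' @return barrier height (kcal/mol): the maximum dG between the two
#'   basin positions, measured from the shallower of the two basins.
#' @export
landscape_barrier <- function(landscape, basin_a, basin_b) {
  x <- landscape$mids
  g <- landscape$dG
  near <- function(v) which.min(abs(x - v))
  ia <- near(basin_a); ib <- near(basin_b)
  lo <- min(ia, ib); hi <- max(ia, ib)
  seg <- g[lo:hi]
  max(seg, na.rm = TRUE) - max(g[ia], g[ib])
}

#' Pearson product-moment correlation
#'
#' @param x,y equal-length series (n >= 3) with nonzero variance.
#' @return r in [-1, 1].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("series must have equal length >= 3")
  if (var(x) == 0 || var(y) == 0)
    stop("undefined correlation: zero variance")
  cor(x, y)
}

#' Estimate a diffusion coefficient from mean-square displacement
#'
#' Computes MSD(tau) of a 1-D coordinate over a lag window, fits a line,
#' and returns `D = slope / 2` (1-D Einstein relation).
#'
#' @param series coordinate series (A).
#' @param step_duration time per step (ns).
#' @param lags lag window in steps (default 1:50).
#' @return list of class `diffusion_estimate`: `D` (A^2/ns),
#'   `D_um2_per_s` (micrometers^2/s; 1 A^2/ns = 10 um^2/s), `fit_r2`,
#'   `msd` table, `regime_warning`.
#' @export
estimate_diffusion <- function(series, step_duration, lags = 1:50) {
  stopifnot(length(series) > 4 * max(lags))
  msd <- vapply(lags, function(L) {
    d <- series[-(seq_len(L))] - series[seq_len(length(series) - L)]
    mean(d * d)
  }, numeric(1))
  tau <- lags * step_duration
  fit <- lm(msd ~ tau)
  slope <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  regime <- !is.finite(r2) || r2 < 0.9 || slope <= 0
  if (regime)
    warning("regime warning: MSD not linear over the lag window")
  D <- max(slope / 2, .Machine$double.eps)
  structure(list(D = D, D_um2_per_s = D * 10, fit_r2 = r2,
                 msd = data.frame(lag_ns = tau, msd = msd),
                 regime_warning = regime),
            class = "diffusion_estimate")
}

#' Convert a diffusion coefficient in um^2/s to A^2/ns
#' @param D_um2_per_s diffusion coefficient in micrometers^2 per second.
#' @export
diffusion_um2s_to_A2ns <- function(D_um2_per_s) D_um2_per_s / 10

#' Mean-first-passage-time rate over a 1-D free-energy profile
#'
#' Evaluates the overdamped MFPT double integral with constant diffusion
#' coefficient D between a reflecting start and an absorbing end:
#' `MFPT = int_start^end dx e^{G(x)/kBT} / D int_start^x dy e^{-G(y)/kBT}`
#' (trapezoidal quadrature on the bin grid), returning `k = 1 / MFPT`.
#'
#' @param landscape a 1-D [boltzmann_landscape] result (dG in kcal/mol),
#'   or a list(mids, dG) in the same layout.
#' @param D diffusion coefficient (A^2 per unit time); the rate comes out
#'   in inverse units of that time.
#' @param start,end reaction-coordinate bounds (reflecting at `start`,
#'   absorbing at `end`).
#' @param temperature Kelvin.
#' @param fill interpolate across undefined (empty) bins inside the range
#'   instead of raising an error.
#' @return list of class `rate_estimate`: `k`, `mfpt`, `barrier`
#'   (kcal/mol, max G minus G at start inside the range), `D`, `bounds`.
#' @export
mfpt_rate <- function(landscape, D, start, end, temperature = 300,
                      fill = FALSE) {
  stopifnot(D > 0)
  x <- landscape$mids
  g <- landscape$dG
  sel <- x >= min(start, end) & x <= max(start, end)
  xs <- x[sel]; gs <- g[sel]
  if (anyNA(gs)) {
    if (!fill)
      stop("interpolation policy: undefined bins inside the range; ",
           "set fill = TRUE to interpolate")
    ok <- !is.na(gs)
    gs <- stats::approx(xs[ok], gs[ok], xout = xs, rule = 2)$y
  }
  if (end < start) { xs <- rev(xs); gs <- rev(gs) }
  beta <- 1 / (KB_KCAL * temperature)
  ep <- exp(beta * gs)
  em <- exp(-beta * gs)
  h <- abs(diff(xs))
  # inner integral: cumulative trapezoid of e^{-beta G} from start to x
  inner <- c(0, cumsum((head(em, -1) + tail(em, -1)) / 2 * h))
  integrand <- ep * inner / D
  mfpt <- sum((head(integrand, -1) + tail(integrand, -1)) / 2 * h)
  structure(list(k = 1 / mfpt, mfpt = mfpt,
                 barrier = max(gs) - gs[1], D = D,
                 bounds = c(start, end)),
            class = "rate_estimate")
}

#' RMSD series and per-residue RMSF for a trajectory
#'
#' Each frame is superposed on the reference by rigid-body least squares
#' over the selection before the RMSD is taken; RMSF is computed about the
#' mean superposed structure.
#'
#' @param trajectory an [sbm_trajectory].
#' @param reference an [sbm_structure] (or n x 3 matrix).
#' @param selection atom indices used for fitting and measurement
#'   (default: CA atoms of the trajectory topology, else all atoms).
#' @return list: `rmsd` (per-frame, A), `rmsf` (per selected atom, A),
#'   `selection`.
#' @export
rmsd_rmsf <- function(trajectory, reference, selection = NULL) {
  n <- ncol(trajectory$xyz) / 3
  if (is.null(selection)) {
    at <- trajectory$topology$atoms
    selection <- if (!is.null(at)) which(at$elety == "CA") else seq_len(n)
    if (!length(selection)) selection <- seq_len(n)
  }
  ref_xyz <- if (inherits(reference, "sbm_structure")) reference$xyz else
    as.matrix(reference)
  if (max(selection) > n || max(selection) > nrow(ref_xyz))
    stop("alignment error: selection outside atom range")
  cols <- as.vector(rbind(3 * selection - 2, 3 * selection - 1,
                          3 * selection))
  ref_row <- as_frame_row(ref_xyz)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = ref_row, mobile = trajectory$xyz,
                   fixed.inds = cols, mobile.inds = cols))
  fitted <- matrix(fitted, nrow = n_frames(trajectory))
  dev <- sweep(fitted[, cols, drop = FALSE], 2, ref_row[cols])
  rmsd <- sqrt(rowSums(dev^2) / length(selection))
  mean_xyz <- colMeans(fitted[, cols, drop = FALSE])
  dev_m <- sweep(fitted[, cols, drop = FALSE], 2, mean_xyz)
  m <- matrix(colMeans(dev_m^2), nrow = 3)
  rmsf <- sqrt(colSums(m))
  list(rmsd = rmsd, rmsf = rmsf, selection = selection)
}
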