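#' Mean dwell time from a rate
#'
#' @param rate first-order rate constant (s^-1).
#' @return mean dwell in ms (1000 / rate).
#' @export
mean_dwell_from_rate <- function(rate) {
  if (any(rate <= 0)) stop("rate must be > 0")
  1000 / rate
}

#' Detect dwells by threshold crossing
#'
#' Maximal runs of the series satisfying the threshold condition are
#' reported as dwell events. Runs shorter than `min_dwell` are debounced by
#' merging into their neighbors (short-lived barrier-top recrossings are
#' thereby ignored). The first and last runs are truncated by the
#' observation window and are excluded from the mean.
#'
#' @param series reaction-coordinate or efficiency values.
#' @param threshold threshold value.
#' @param direction "below" (e.g. R_dye < 60 A marks the closed
#'   conformation) or "above".
#' @param min_dwell debounce length in steps (1 disables; default 1).
#' @return list of class `dwell_set`: `events` (complete in-state dwell
#'   lengths, steps), `all_runs` (run-length table), `mean`, `sd`,
#'   `threshold`, `direction`, `truncated` flag when no complete event
#'   exists.
#' @export
detect_dwells <- function(series, threshold, direction = c("below", "above"),
                          min_dwell = 1L) {
  direction <- match.arg(direction)
  if (length(series) < 2) stop("series must have length >= 2")
  state <- if (direction == "below") series < threshold else
    series > threshold
  r <- rle(state)
  # debounce: repeatedly flip the shortest run under min_dwell into its
  # neighbors, then recompute runs
  while (min_dwell > 1 && length(r$lengths) > 1 &&
         any(r$lengths < min_dwell)) {
    k <- which.min(r$lengths)
    if (r$lengths[k] >= min_dwell) break
    r$values[k] <- !r$values[k]
    state <- inverse.rle(r)
    r <- rle(state)
  }
  n_runs <- length(r$lengths)
  in_state <- which(r$values)
  complete <- in_state[in_state != 1 & in_state != n_runs]
  events <- r$lengths[complete]
  truncated <- !length(events)
  if (truncated)
    warning("no complete dwell events (runs truncated by the window)")
  structure(list(events = events,
                 all_runs = data.frame(length = r$lengths,
                                       in_state = r$values),
                 mean = if (length(events)) mean(events) else NA_real_,
                 sd = if (length(events) > 1) sd(events) else NA_real_,
                 threshold = threshold, direction = direction,
                 truncated = truncated),
            class = "dwell_set")
}

#' @export
print.dwell_set <- function(x, ...) {
  cat("dwell_set:", length(x$events), "complete events, mean =",
      signif(x$mean, 4), "+/-", signif(x$sd, 3), "steps\n")
  invisible(x)
}

#' Calibrate the physical duration of one simulation step
#'
#' Matching the simulated mean dwell (in steps) to the experimental mean
#' dwell (in seconds) assigns each reduced-time step a physical duration:
#' `step_duration_ns = experimental / simulated * 1e9`.
#'
#' @param simulated_dwell mean dwell in time steps.
#' @param experimental_dwell mean dwell in seconds.
#' @return list: `step_ns`, `simulated_dwell`, `experimental_dwell`.
#' @export
calibrate_timestep <- function(simulated_dwell, experimental_dwell) {
  if (simulated_dwell <= 0 || experimental_dwell <= 0)
    stop("dwell times must be > 0")
  list(step_ns = experimental_dwell / simulated_dwell * 1e9,
       simulated_dwell = simulated_dwell,
       experimental_dwell = experimental_dwell)
}

#' FRET histogram and time-vs-efficiency contour counts
#'
#' @param traces a [fret_trace] or list of them.
#' @param bin_width efficiency bin width in (0, 0.5] (default 0.02).
#' @param n_time_bins number of time columns for the contour (default 20).
#' @return list: `breaks`, `mids`, `counts` (pooled histogram), and
#'   `contour` (matrix of per-time-column histograms, each column
#'   normalized to its own maximum).
#' @export
build_fret_histogram <- function(traces, bin_width = 0.02,
                                 n_time_bins = 20L) {
  stopifnot(bin_width > 0, bin_width <= 0.5)
  if (inherits(traces, "fret_trace")) traces <- list(traces)
  eff <- unlist(lapply(traces, function(t) t$efficiency))
  tim <- unlist(lapply(traces, function(t) t$time_s))
  if (!length(eff)) stop("no-data error: empty trace collection")
  breaks <- seq(0, 1 + bin_width, by = bin_width)
  eff_cl <- pmin(pmax(eff, 0), 1)
  counts <- as.integer(table(cut(eff_cl, breaks, right = FALSE,
                                 include.lowest = TRUE)))
  tb <- cut(tim, breaks = n_time_bins, labels = FALSE)
  contour <- sapply(seq_len(n_time_bins), function(col) {
    v <- eff_cl[tb == col]
    h <- as.integer(table(cut(v, breaks, right = FALSE,
                              include.lowest = TRUE)))
    if (max(h) > 0) h / max(h) else h
  })
  list(breaks = breaks, mids = head(breaks, -1) + bin_width / 2,
       counts = counts, contour = contour)
}

#' Fit a sum of Gaussians to a FRET histogram
#'
#' Least-squares fit of `counts = sum_k A_k exp(-(x - m_k)^2 / (2 s_k^2))`
#' to the histogram bin counts. Components are initialized at the 25th/75th
#' (and 50th) weighted percentiles with sigmas at half the inter-mean gap,
#' and reported sorted by mean.
#'
#' @param histogram result of [build_fret_histogram], or a list with
#'   `mids` and `counts`.
#' @param n_components 1, 2 or 3.
#' @param init optional list(means, sigmas, amplitudes) overriding the
#'   default initialization.
#' @return list of class `gaussian_mixture_fit`: `components` (data.frame
#'   amplitude/mean/sigma sorted by mean), `rss`, `converged`, and
#'   `degenerate` flag (sigma < bin width / 4 or coincident means).
#' @export
fit_gaussian_mixture <- function(histogram, n_components = 2, init = NULL) {
  x <- histogram$mids
  y <- as.numeric(histogram$counts)
  stopifnot(n_components %in% 1:3)
  if (sum(y > 0) < 3 * n_components)
    warning("fewer than 3 non-empty bins per component")
  bw <- diff(x[1:2])
  if (is.null(init)) {
    w <- y / sum(y)
    cdf <- cumsum(w)
    qt <- function(p) x[which.min(abs(cdf - p))]
    means <- switch(n_components, qt(0.5), c(qt(0.25), qt(0.75)),
                    c(qt(0.25), qt(0.5), qt(0.75)))
    gap <- if (n_components > 1) diff(range(means)) / 2 else 4 * bw
    init <- list(means = means, sigmas = rep(max(gap / 2, bw), n_components),
                 amplitudes = rep(max(y), n_components))
  }
  model <- function(p) {
    pred <- 0
    for (k in seq_len(n_components))
      pred <- pred + p[k] *
        exp(-(x - p[n_components + k])^2 / (2 * p[2 * n_components + k]^2))
    pred
  }
  p0 <- c(init$amplitudes, init$means, abs(init$sigmas))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = function(p) y - model(p),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    o <- optim(p0, function(p) sum((y - model(p))^2),
               control = list(maxit = 2000))
    par <- o$par; converged <- o$convergence == 0
  } else {
    par <- fit$par; converged <- fit$info %in% 1:4
  }
  if (!converged)
    warning("fit error: mixture fit did not converge; residuals attached")
  amp <- par[seq_len(n_components)]
  mu <- par[n_components + seq_len(n_components)]
  sg <- abs(par[2 * n_components + seq_len(n_components)])
  ord <- order(mu)
  comps <- data.frame(amplitude = amp[ord], mean = mu[ord],
                      sigma = sg[ord])
  degenerate <- any(sg < bw / 4) ||
    (n_components > 1 && any(diff(sort(mu)) < bw / 2))
  structure(list(components = comps, n_components = n_components,
                 rss = sum((y - model(par))^2), converged = converged,
                 degenerate = degenerate,
                 residuals = y - model(par)),
            class = "gaussian_mixture_fit")
}

#' @export
print.gaussian_mixture_fit <- function(x, ...) {
  cat("gaussian_mixture_fit:", x$n_components, "component(s), rss =",
      signif(x$rss, 4), if (x$degenerate) "(degenerate)" else "", "\n")
  print(x$components, digits = 4)
  invisible(x)
}
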