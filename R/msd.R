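#' Sliding-window time-averaged MSD
#'
#' Scans a trajectory with a sliding window and computes, for each window,
#' the time-averaged mean-square displacement over all pair displacements
#' at each lag. Lags are restricted to at most a quarter of the window span
#' (the usual bias--variance compromise for time-averaged MSD).
#'
#' @param traj Trajectory data frame with columns `time_s`, `x_nm`, `y_nm`.
#' @param window_frames Window length in frames (40 frames = 2.0 s at
#'   20 frames/s).
#' @param stride_frames Window advance in frames.
#' @param max_lag_frames Largest lag in frames; defaults to
#'   `floor(window_frames / 4)`.
#' @return A data frame with one row per window and lag: `window` (index),
#'   `start_frame`, `end_frame`, `center_frame` (0-based trajectory frames),
#'   `lag_s`, `msd_nm2`, `n_pairs`.
#' @export
windowed_msd <- function(traj, window_frames = 40, stride_frames = 1,
                         max_lag_frames = floor(window_frames / 4)) {
  m <- msd_window_matrix(traj, window_frames, stride_frames, max_lag_frames)
  nwin <- length(m$start_frame)
  L <- length(m$lags_s)
  data.frame(window = rep(seq_len(nwin), each = L),
             start_frame = rep(m$start_frame, each = L),
             end_frame = rep(m$end_frame, each = L),
             center_frame = rep(m$center_frame, each = L),
             lag_s = rep(m$lags_s, times = nwin),
             msd_nm2 = as.vector(t(m$msd)),
             n_pairs = rep(m$n_pairs, times = nwin))
}

# Vectorized window MSD: cumulative sums of per-lag squared displacements
# give every window's pair average in O(n) per lag.
msd_window_matrix <- function(traj, window_frames, stride_frames,
                              max_lag_frames) {
  n <- nrow(traj)
  W <- as.integer(window_frames)
  if (n < W) {
    stop("trajectory has ", n, " frames, shorter than one window (", W, ")",
         call. = FALSE)
  }
  lags <- seq_len(max_lag_frames)
  if (length(lags) < 1L) stop("max_lag_frames must be >= 1", call. = FALSE)
  dt <- stats::median(diff(traj$time_s))
  starts <- seq.int(1L, n - W + 1L, by = as.integer(stride_frames))
  nwin <- length(starts)
  msd <- matrix(NA_real_, nwin, length(lags))
  x <- traj$x_nm; y <- traj$y_nm
  for (j in seq_along(lags)) {
    k <- lags[j]
    s <- (x[(1 + k):n] - x[1:(n - k)])^2 + (y[(1 + k):n] - y[1:(n - k)])^2
    cs <- c(0, cumsum(s))
    msd[, j] <- (cs[starts + W - k] - cs[starts]) / (W - k)
  }
  frame0 <- traj$frame[1]
  list(msd = msd,
       lags_s = lags * dt,
       n_pairs = W - lags,
       start_frame = traj$frame[starts],
       end_frame = traj$frame[starts + W - 1L],
       center_frame = frame0 + (starts - 1L) + W %/% 2L,
       dt = dt)
}

# Profiled least squares for MSD(t) = 4 D t^alpha + 2 sigma^2 with sigma
# fixed: for given alpha the optimal (clamped non-negative) D is linear,
# so the fit reduces to a 1-D search over alpha.
msd_rss <- function(alpha, M, tl) {
  u <- tl^alpha
  D4 <- max(0, sum(M * u) / sum(u * u))  # 4D, clamped
  sum((M - D4 * u)^2)
}

#' Fit the anomalous-diffusion MSD model to one window curve
#'
#' Least-squares fit of `MSD(t) = 4 D t^alpha + 2 sigma^2` with the
#' measurement error `sigma` held fixed (not fitted) and `alpha` constrained
#' to `alpha_bounds`. A failed or under-determined fit sets `fit_ok = FALSE`
#' with a reason rather than raising an error.
#'
#' @param curve Data frame with columns `lag_s` and `msd_nm2` for one window
#'   (e.g. one window of [windowed_msd()]).
#' @param sigma Fixed localization error, nm.
#' @param alpha_bounds Allowed range of the scaling exponent.
#' @return A one-row data frame: `alpha`, `D` (nm^2/s^alpha), `sigma`,
#'   `residual` (sum of squared residuals, nm^4), `fit_ok`, `reason`.
#' @export
fit_msd <- function(curve, sigma = 9.8, alpha_bounds = c(0, 2.2)) {
  bad <- function(reason) data.frame(alpha = NA_real_, D = NA_real_,
                                     sigma = sigma, residual = NA_real_,
                                     fit_ok = FALSE, reason = reason,
                                     stringsAsFactors = FALSE)
  keep <- is.finite(curve$lag_s) & is.finite(curve$msd_nm2) & curve$lag_s > 0
  tl <- curve$lag_s[keep]
  M <- curve$msd_nm2[keep] - 2 * sigma^2
  if (length(tl) < 4L) return(bad("fewer than 4 usable lags"))
  grid <- seq(alpha_bounds[1], alpha_bounds[2], by = 0.02)
  rss <- vapply(grid, msd_rss, numeric(1), M = M, tl = tl)
  i <- which.min(rss)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(msd_rss, c(lo, hi), M = M, tl = tl, tol = 1e-10)
  alpha <- opt$minimum
  # boundary grid minimum can beat the local refinement
  if (rss[i] < opt$objective) {
    alpha <- grid[i]
    opt$objective <- rss[i]
  }
  u <- tl^alpha
  D4 <- max(0, sum(M * u) / sum(u * u))
  if (!is.finite(alpha) || !is.finite(D4)) return(bad("fit diverged"))
  data.frame(alpha = alpha, D = D4 / 4, sigma = sigma,
             residual = opt$objective, fit_ok = TRUE, reason = "",
             stringsAsFactors = FALSE)
}

#' Sliding-window MSD fits for a whole trajectory
#'
#' Computes the windowed MSD and fits the fixed-sigma anomalous-diffusion
#' model to every window. The search over the scaling exponent is done on a
#' shared grid for all windows simultaneously (one matrix product per grid
#' point) followed by a parabolic refinement, so whole cohorts can be
#' scanned with stride 1.
#'
#' @param traj Trajectory data frame.
#' @param config An [analysis_config()].
#' @return Data frame with one row per window: `start_frame`, `end_frame`,
#'   `center_frame`, `alpha`, `D`, `residual`, `fit_ok`.
#' @export
fit_windows <- function(traj, config = analysis_config()) {
  m <- msd_window_matrix(traj, config$window_frames, config$stride_frames,
                         config$max_lag_frames)
  ft <- fit_windows_matrix(m$msd, m$lags_s, config$sigma_loc_nm,
                           config$alpha_bounds)
  data.frame(start_frame = m$start_frame, end_frame = m$end_frame,
             center_frame = m$center_frame,
             alpha = ft$alpha, D = ft$D, residual = ft$residual,
             fit_ok = ft$fit_ok)
}

fit_windows_matrix <- function(msd, lags_s, sigma, alpha_bounds,
                               grid_step = 0.01) {
  nwin <- nrow(msd)
  M <- msd - 2 * sigma^2
  C <- rowSums(M * M)
  grid <- seq(alpha_bounds[1], alpha_bounds[2], by = grid_step)
  G <- length(grid)
  bestRSS <- rep(Inf, nwin)
  bestIdx <- rep(0L, nwin)
  rssL <- rep(NA_real_, nwin)
  rssR <- rep(NA_real_, nwin)
  prev <- rep(NA_real_, nwin)
  for (g in seq_len(G)) {
    u <- lags_s^grid[g]
    num <- as.vector(M %*% u)
    den <- sum(u * u)
    D4 <- pmax(0, num / den)
    cur <- C - 2 * D4 * num + D4 * D4 * den
    imp <- cur < bestRSS
    if (any(imp)) {
      bestRSS[imp] <- cur[imp]
      bestIdx[imp] <- g
      rssL[imp] <- prev[imp]
      rssR[imp] <- NA_real_
    }
    fill <- !imp & bestIdx == g - 1L
    if (any(fill)) rssR[fill] <- cur[fill]
    prev <- cur
  }
  alpha <- grid[bestIdx]
  den2 <- rssR - 2 * bestRSS + rssL
  ok <- is.finite(rssL) & is.finite(rssR) & den2 > 0
  alpha[ok] <- alpha[ok] - 0.5 * grid_step * (rssR[ok] - rssL[ok]) / den2[ok]
  alpha <- pmin(pmax(alpha, alpha_bounds[1]), alpha_bounds[2])
  # recompute D and residual at the refined exponent
  U <- exp(outer(alpha, log(lags_s)))
  num <- rowSums(M * U)
  den <- rowSums(U * U)
  D4 <- pmax(0, num / den)
  resid <- rowSums((M - D4 * U)^2)
  list(alpha = alpha, D = D4 / 4, residual = resid,
       fit_ok = is.finite(alpha) & is.finite(D4))
}

#' Dominant peak of a scaling-exponent distribution
#'
#' Location of the mode of a kernel density estimate of the alpha values;
#' used to check that calibration cohorts produce the expected peaks near 1
#' (pure diffusion) and 2 (directed motion).
#'
#' @param alphas Numeric vector of scaling exponents.
#' @param bw Kernel bandwidth.
#' @return The alpha value at the density maximum.
#' @export
alpha_peak <- function(alphas, bw = 0.05) {
  alphas <- alphas[is.finite(alphas)]
  d <- stats::density(alphas, bw = bw, n = 2048)
  d$x[which.max(d$y)]
}
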