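# Shared fixture builders and independent oracles.

# Noise-free constant-velocity trajectory along a given direction.
make_ballistic_traj <- function(v = 500, n = 200, dt = 0.05, theta = 0,
                                sigma = 0, seed = 1) {
  set.seed(seed)
  t <- (0:(n - 1)) * dt
  data.frame(frame = 0:(n - 1), time_s = t,
             x_nm = v * t * cos(theta) + stats::rnorm(n, 0, sigma),
             y_nm = v * t * sin(theta) + stats::rnorm(n, 0, sigma))
}

# Plain Brownian trajectory with optional localization noise.
make_brownian_traj <- function(D = 1e4, n = 200, dt = 0.05, sigma = 0,
                               seed = 1) {
  set.seed(seed)
  sd_step <- sqrt(2 * D * dt)
  data.frame(frame = 0:(n - 1), time_s = (0:(n - 1)) * dt,
             x_nm = cumsum(c(0, stats::rnorm(n - 1, 0, sd_step))) +
               stats::rnorm(n, 0, sigma),
             y_nm = cumsum(c(0, stats::rnorm(n - 1, 0, sd_step))) +
               stats::rnorm(n, 0, sigma))
}

# Two-piece constant-velocity 1-D track embedded in 2-D.
make_two_piece_track <- function(v1 = 600, v2 = 100, n_change = 60, n = 120,
                                 dt = 0.05, sigma = 9.8, seed = 1) {
  set.seed(seed)
  v <- ifelse(0:(n - 2) < n_change, v1, v2)
  d <- cumsum(c(0, v * dt))
  data.frame(frame = 0:(n - 1), time_s = (0:(n - 1)) * dt,
             x_nm = d + stats::rnorm(n, 0, sigma),
             y_nm = stats::rnorm(n, 0, sigma))
}

# Brute-force time-averaged MSD over one window: explicit double loop,
# independent of the cumulative-sum implementation in the package.
brute_force_msd <- function(x, y, lags_frames) {
  n <- length(x)
  out <- numeric(length(lags_frames))
  for (j in seq_along(lags_frames)) {
    k <- lags_frames[j]
    acc <- 0
    cnt <- 0L
    for (i in 1:(n - k)) {
      acc <- acc + (x[i + k] - x[i])^2 + (y[i + k] - y[i])^2
      cnt <- cnt + 1L
    }
    out[j] <- acc / cnt
  }
  out
}

# Direct-summation intensity-weighted centroid of a full frame (oracle for
# the ROI-based implementation; background assumed constant and known).
direct_centroid_px <- function(frame, background) {
  w <- pmax(frame - background, 0)
  xs <- 0:(ncol(frame) - 1)
  ys <- 0:(nrow(frame) - 1)
  c(x = sum(colSums(w) * xs) / sum(w), y = sum(rowSums(w) * ys) / sum(w))
}

# Simulate a cohort of labelled trajectories from one config (one RNG stream).
sim_cohort_one <- function(cfg, n) {
  set.seed(cfg$seed)
  lapply(seq_len(n), function(i) phagomotion:::simulate_trajectory_impl(cfg))
}
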