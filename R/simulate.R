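#' Simulate a labelled two-state cargo trajectory
#'
#' Draws one trajectory from the motor-switching model: exponential sojourns
#' in a directed state (constant per-run speed along a persistent direction;
#' a new run reverses direction with probability `p_reverse`) alternating
#' with a diffusive state (Gaussian increments of variance `2 * D_diff * dt`
#' per coordinate). State changes are applied at frame boundaries. Observed
#' positions are the true positions plus i.i.d. Gaussian localization noise
#' of standard deviation `sigma_loc` per coordinate.
#'
#' @param config A [sim_config()].
#' @return A `labeled_trajectory`: a data frame with columns `frame`
#'   (0-based), `time_s`, `x_nm`, `y_nm` (observed), `x_true_nm`,
#'   `y_true_nm`, and `state` (`"directed"` or `"diffusive"`), with the
#'   generating config in attribute `config` and the ground-truth sojourn
#'   table (columns `state`, `t_start`, `t_end`, `duration_s`, `speed_nm_s`,
#'   `direction_rad`) in attribute `sojourns`. Sojourn durations are the
#'   continuous exponential draws before discretization; the final sojourn
#'   is truncated by the recording and flagged `censored`.
#' @export
simulate_trajectory <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  simulate_trajectory_impl(config)
}

# Internal: assumes the RNG state is already positioned (used by
# simulate_cohort to draw many trajectories from one seed stream).
simulate_trajectory_impl <- function(config) {
  dt <- 1 / config$frame_rate
  n <- floor(config$duration * config$frame_rate) + 1L  # frames 0..n-1
  sj <- draw_sojourns(config, total_time = (n - 1L) * dt)

  # Per-interval state: interval i covers [t_i, t_{i+1}); a frame interval
  # takes the state of the sojourn covering its start time.
  t_starts <- (seq_len(n - 1L) - 1L) * dt
  idx <- findInterval(t_starts, sj$t_start)
  int_state <- sj$state[idx]
  int_speed <- sj$speed_nm_s[idx]
  int_dir <- sj$direction_rad[idx]

  dx <- numeric(n - 1L)
  dy <- numeric(n - 1L)
  dir_mask <- int_state == "directed"
  if (any(dir_mask)) {
    dx[dir_mask] <- int_speed[dir_mask] * cos(int_dir[dir_mask]) * dt
    dy[dir_mask] <- int_speed[dir_mask] * sin(int_dir[dir_mask]) * dt
    if (config$D_run > 0) {
      sd_run <- sqrt(2 * config$D_run * dt)
      nd <- sum(dir_mask)
      dx[dir_mask] <- dx[dir_mask] + stats::rnorm(nd, 0, sd_run)
      dy[dir_mask] <- dy[dir_mask] + stats::rnorm(nd, 0, sd_run)
    }
  }
  ndiff <- sum(!dir_mask)
  if (ndiff > 0L && config$D_diff > 0) {
    sd_step <- sqrt(2 * config$D_diff * dt)
    dx[!dir_mask] <- stats::rnorm(ndiff, 0, sd_step)
    dy[!dir_mask] <- stats::rnorm(ndiff, 0, sd_step)
  }
  x_true <- c(0, cumsum(dx))
  y_true <- c(0, cumsum(dy))
  if (config$sigma_loc > 0) {
    # sigma_loc is the measurement error as it enters the MSD model
    # (additive offset 2*sigma_loc^2 on the 2-D MSD), so each coordinate
    # carries sd sigma_loc/sqrt(2)
    sd_xy <- config$sigma_loc / sqrt(2)
    x <- x_true + stats::rnorm(n, 0, sd_xy)
    y <- y_true + stats::rnorm(n, 0, sd_xy)
  } else {
    x <- x_true
    y <- y_true
  }
  state <- c(int_state, int_state[n - 1L])  # last frame inherits last interval

  traj <- data.frame(frame = 0:(n - 1L),
                     time_s = (0:(n - 1L)) * dt,
                     x_nm = x, y_nm = y,
                     x_true_nm = x_true, y_true_nm = y_true,
                     state = state,
                     stringsAsFactors = FALSE)
  attr(traj, "config") <- config
  attr(traj, "sojourns") <- sj
  class(traj) <- c("labeled_trajectory", "data.frame")
  traj
}

# Alternating exponential sojourns covering [0, total_time]; continuous
# event times are recorded as ground truth, discretization happens in the
# caller at frame boundaries.
draw_sojourns <- function(config, total_time) {
  forced <- config$force_state
  state0 <- if (forced == "diffusive") "diffusive"
            else if (forced == "directed") "directed"
            else if (stats::runif(1) < config$k_on / (config$k_on + config$k_off))
              "directed" else "diffusive"
  states <- character(0); t0 <- numeric(0); t1 <- numeric(0)
  speeds <- numeric(0); dirs <- numeric(0)
  cur_dir <- stats::runif(1, 0, 2 * pi)
  t <- 0
  st <- state0
  first_run <- TRUE
  while (t < total_time) {
    if (forced != "none") {
      dur <- total_time - t
    } else {
      rate <- if (st == "directed") config$k_off else config$k_on
      dur <- stats::rexp(1, rate)
    }
    if (st == "directed") {
      if (!first_run && stats::runif(1) < config$p_reverse) cur_dir <- cur_dir + pi
      first_run <- FALSE
      sp <- draw_run_speed(config)
    } else {
      sp <- NA_real_
    }
    states <- c(states, st)
    t0 <- c(t0, t)
    t1 <- c(t1, min(t + dur, total_time))
    speeds <- c(speeds, sp)
    dirs <- c(dirs, if (st == "directed") cur_dir else NA_real_)
    t <- t + dur
    st <- if (st == "directed") "diffusive" else "directed"
  }
  data.frame(state = states, t_start = t0, t_end = t1,
             duration_s = t1 - t0,
             censored = c(rep(FALSE, length(t0) - 1L), TRUE),
             speed_nm_s = speeds, direction_rad = dirs,
             stringsAsFactors = FALSE)
}

# Truncated-normal per-run speed on [50, 1500] nm/s by inverse CDF.
draw_run_speed <- function(config) {
  if (config$v_sd == 0) return(config$v_mean)
  lo <- stats::pnorm(50, config$v_mean, config$v_sd)
  hi <- stats::pnorm(1500, config$v_mean, config$v_sd)
  u <- stats::runif(1, lo, hi)
  stats::qnorm(u, config$v_mean, config$v_sd)
}

#' Simulate a two-group cohort of labelled trajectories
#'
#' Generates `n_per_group` trajectories per condition and records the
#' ground-truth transport summary of each group (true percent time in the
#' directed state, mean run duration, speed and dissociation rate), so that
#' pipeline estimates can be checked against the generating process.
#'
#' @param config_control,config_treated [sim_config()] objects for the two
#'   conditions. The treated configuration typically has a higher `k_off`
#'   and/or lower `k_on` to emulate impaired motor engagement.
#' @param n_per_group Number of beads (trajectories) per group; the default
#'   matches the 63-bead early-phagosome cohorts the analysis targets.
#' @return A list with elements `control` and `treated`, each a list of
#'   `labeled_trajectory`, and `truth`, a data frame of per-group
#'   ground-truth summaries.
#' @export
simulate_cohort <- function(config_control, config_treated, n_per_group = 63) {
  if (!is.numeric(n_per_group) || length(n_per_group) != 1L || n_per_group < 1) {
    stop("`n_per_group` must be a single integer >= 1", call. = FALSE)
  }
  n_per_group <- as.integer(n_per_group)
  gen_group <- function(cfg) {
    validate_sim_config(cfg)
    set.seed(cfg$seed)
    lapply(seq_len(n_per_group), function(i) simulate_trajectory_impl(cfg))
  }
  ctrl <- gen_group(config_control)
  trt <- gen_group(config_treated)
  truth <- rbind(truth_summary(ctrl, "control"), truth_summary(trt, "treated"))
  list(control = ctrl, treated = trt, truth = truth)
}

truth_summary <- function(trajs, group) {
  pct_dir <- vapply(trajs, function(tr) 100 * mean(tr$state == "directed"),
                    numeric(1))
  runs <- do.call(rbind, lapply(trajs, function(tr) {
    sj <- attr(tr, "sojourns")
    sj[sj$state == "directed", , drop = FALSE]
  }))
  complete <- runs[!runs$censored, , drop = FALSE]
  data.frame(group = group,
             n_beads = length(trajs),
             pct_directed = mean(pct_dir),
             mean_run_duration_s = mean(complete$duration_s),
             mean_run_speed_nm_s = mean(runs$speed_nm_s),
             dissociation_rate_s = nrow(complete) / sum(runs$duration_s),
             stringsAsFactors = FALSE)
}

#' Render a trajectory as a synthetic image stack
#'
#' Produces one grayscale frame per trajectory time point with the particle
#' drawn as an isotropic Gaussian intensity profile centred at the true
#' position (converted to pixels at the configured pixel size), over a
#' constant background with additive Gaussian read noise. Default
#' intensity and noise give a high-contrast spot, as in DIC bead imaging,
#' whose centroid localization error stays within the 9.8 nm
#' measurement-noise floor of the trajectory model (rendered frames carry
#' no cellular background structure, so sub-pixel tracking on them is
#' cleaner than on in-cell data).
#'
#' @param traj A `labeled_trajectory` (or any trajectory data frame with
#'   `x_true_nm`/`y_true_nm` or `x_nm`/`y_nm` columns).
#' @param spot_sd Gaussian spot standard deviation, nm.
#' @param peak_intensity Peak spot intensity above background, counts.
#' @param background Constant background level, counts.
#' @param noise_sd Read-noise standard deviation, counts.
#' @param field_dim Optional `c(ny, nx)` field size in pixels; by default
#'   the field is sized to contain the trajectory with a margin.
#' @param margin_px Margin (pixels) required between the spot centre and
#'   the field edge; a spot closer than this to the border is an error.
#' @return A numeric array `ny x nx x n_frames` with attributes
#'   `pixel_size_nm`, `frame_rate`, and `origin_nm` (nm coordinates of the
#'   centre of pixel (1,1)).
#' @export
render_image_stack <- function(traj, spot_sd = 150, peak_intensity = 800,
                               background = 100, noise_sd = 12,
                               field_dim = NULL, margin_px = NULL) {
  cfg <- attr(traj, "config")
  px <- if (!is.null(cfg)) cfg$pixel_size else 27.6
  fr <- if (!is.null(cfg)) cfg$frame_rate else 20
  xs <- if ("x_true_nm" %in% names(traj)) traj$x_true_nm else traj$x_nm
  ys <- if ("y_true_nm" %in% names(traj)) traj$y_true_nm else traj$y_nm
  sd_px <- spot_sd / px
  if (is.null(margin_px)) margin_px <- ceiling(2 * sd_px)
  xpx <- xs / px
  ypx <- ys / px
  if (is.null(field_dim)) {
    # origin chosen so the trajectory sits comfortably inside the field
    pad <- margin_px + ceiling(2 * sd_px) + 4L
    ox <- floor(min(xpx)) - pad
    oy <- floor(min(ypx)) - pad
    nx <- ceiling(max(xpx)) - ox + pad + 1L
    ny <- ceiling(max(ypx)) - oy + pad + 1L
  } else {
    ny <- field_dim[1]; nx <- field_dim[2]
    ox <- 0; oy <- 0
  }
  cx <- xpx - ox  # 0-based pixel coordinates of the spot centre
  cy <- ypx - oy
  out <- vapply(seq_along(cx), function(i) {
    if (cx[i] < margin_px || cx[i] > nx - 1 - margin_px ||
        cy[i] < margin_px || cy[i] > ny - 1 - margin_px) {
      stop("spot leaves the field at frame ", traj$frame[i], call. = FALSE)
    }
    gx <- exp(-((0:(nx - 1L)) - cx[i])^2 / (2 * sd_px^2))
    gy <- exp(-((0:(ny - 1L)) - cy[i])^2 / (2 * sd_px^2))
    frame <- background + peak_intensity * outer(gy, gx)
    if (noise_sd > 0) frame <- frame + stats::rnorm(length(frame), 0, noise_sd)
    frame
  }, matrix(0, ny, nx))
  attr(out, "pixel_size_nm") <- px
  attr(out, "frame_rate") <- fr
  attr(out, "origin_nm") <- c(x = ox * px, y = oy * px)
  out
}
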