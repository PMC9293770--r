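#' Simulation configuration for two-state cargo trajectories
#'
#' Parameters of the stochastic motor-switching model used by
#' [simulate_trajectory()]. The cargo alternates between a motor-bound
#' (directed) state, in which it moves at a constant per-run speed along a
#' persistent direction, and a diffusive state with Brownian increments.
#' Sojourn times in each state are exponential with rates `k_off`
#' (leaving the directed state) and `k_on` (leaving the diffusive state).
#'
#' Defaults reflect the recording conditions the analysis is built for:
#' 20 frames/s, 150 s recordings, 27.6 nm/pixel, and a localization noise
#' floor of 9.8 nm per coordinate. Per-run speeds are drawn from a normal
#' distribution truncated to the 50--1500 nm/s range observed for
#' microtubule motor transport of phagosomes.
#'
#' @param frame_rate Frames per second.
#' @param duration Recording duration in seconds.
#' @param pixel_size Pixel size in nm (used only when rendering images).
#' @param sigma_loc Localization measurement error sigma, nm, defined as it
#'   enters the MSD model: the 2-D MSD of a stationary particle plateaus at
#'   `2 * sigma_loc^2`, i.e. each coordinate carries noise of standard
#'   deviation `sigma_loc / sqrt(2)`.
#' @param D_diff Diffusion constant in the diffusive state, nm^2/s.
#' @param D_run Diffusion constant of positional fluctuations superimposed
#'   on the constant-speed advance in the directed state, nm^2/s
#'   (tethered-cargo jitter: motor-bound cargo in cells is not rigidly
#'   ballistic). Set to 0 for strictly constant-velocity runs.
#' @param v_mean,v_sd Mean and SD of the per-run speed distribution, nm/s;
#'   the distribution is truncated to `[50, 1500]` nm/s. `v_sd = 0` gives a
#'   fixed speed `v_mean`.
#' @param k_off Rate of leaving the directed (motor-bound) state, 1/s.
#' @param k_on Rate of leaving the diffusive state, 1/s.
#' @param p_reverse Probability that a new run reverses direction.
#' @param force_state Either `"none"` (Markov switching), `"directed"` or
#'   `"diffusive"` to pin the trajectory to a single state throughout
#'   (used for calibration cohorts).
#' @param seed Integer seed; recorded in outputs so that trajectories are
#'   exactly reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(frame_rate = 20,
                       duration = 150,
                       pixel_size = 27.6,
                       sigma_loc = 9.8,
                       D_diff = 1e4,
                       D_run = 1000,
                       v_mean = 500,
                       v_sd = 200,
                       k_off = 1 / 6,
                       k_on = 1 / 6,
                       p_reverse = 0.5,
                       force_state = c("none", "directed", "diffusive"),
                       seed = 1L) {
  force_state <- match.arg(force_state)
  cfg <- list(frame_rate = frame_rate, duration = duration,
              pixel_size = pixel_size, sigma_loc = sigma_loc,
              D_diff = D_diff, D_run = D_run, v_mean = v_mean, v_sd = v_sd,
              k_off = k_off, k_on = k_on, p_reverse = p_reverse,
              force_state = force_state, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid `", field, "`: ", msg, call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(cfg$frame_rate) && cfg$frame_rate > 0, "frame_rate", "must be a positive number")
  chk(num1(cfg$duration) && cfg$duration > 0, "duration", "must be a positive number")
  chk(num1(cfg$pixel_size) && cfg$pixel_size > 0, "pixel_size", "must be a positive number")
  chk(num1(cfg$sigma_loc) && cfg$sigma_loc >= 0, "sigma_loc", "must be a non-negative number")
  chk(num1(cfg$D_diff) && cfg$D_diff >= 0, "D_diff", "must be a non-negative number")
  chk(num1(cfg$D_run) && cfg$D_run >= 0, "D_run", "must be a non-negative number")
  chk(num1(cfg$v_mean), "v_mean", "must be a finite number")
  chk(num1(cfg$v_sd) && cfg$v_sd >= 0, "v_sd", "must be a non-negative number")
  if (cfg$v_sd == 0) {
    chk(cfg$v_mean >= 50 && cfg$v_mean <= 1500, "v_mean",
        "fixed speed must lie in [50, 1500] nm/s")
  }
  chk(num1(cfg$k_off) && cfg$k_off > 0, "k_off", "must be a positive rate (1/s)")
  chk(num1(cfg$k_on) && cfg$k_on > 0, "k_on", "must be a positive rate (1/s)")
  chk(num1(cfg$p_reverse) && cfg$p_reverse >= 0 && cfg$p_reverse <= 1,
      "p_reverse", "must be a probability in [0, 1]")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L && is.finite(cfg$seed),
      "seed", "must be a single integer")
  invisible(cfg)
}

#' Analysis configuration
#'
#' Parameters of the motion-state classification and run-parsing pipeline.
#' Defaults implement a 2.0 s (40-frame at 20 frames/s) sliding window,
#' a fixed localization error of 9.8 nm in the MSD model, fit lags up to a
#' quarter of the window, and the run criteria of 200 nm length,
#' 50 nm/s speed and 0.25 s duration.
#'
#' @param window_frames Sliding-window length in frames.
#' @param stride_frames Window advance in frames.
#' @param sigma_loc_nm Fixed localization error sigma in the MSD model, nm.
#' @param max_lag_frames Largest lag (frames) used in each window fit;
#'   defaults to a quarter of the window.
#' @param alpha_bounds Allowed range of the scaling exponent in the fit.
#' @param min_segment_frames Motion segments shorter than this are absorbed
#'   into the longer neighbouring segment.
#' @param max_gap_frames Diffusive gaps up to this length (frames) are
#'   bridged when stitching consecutive directed segments.
#' @param min_run_length_nm,min_speed_nm_s,min_duration_s Run criteria:
#'   a parsed constant-velocity segment is a run when its net displacement
#'   exceeds `min_run_length_nm`, its speed exceeds `min_speed_nm_s` and its
#'   duration is at least `min_duration_s`. Segments slower than
#'   `min_speed_nm_s` are pauses.
#' @param cp_penalty_factor Multiplier of the `sigma^2 * log(n)` change-point
#'   penalty used by [parse_constant_velocity()].
#' @param cp_merge_z Pruning threshold for detected change points: adjacent
#'   pieces whose fitted velocities differ by less than this many combined
#'   standard errors are merged (0 or `Inf`-like values disable pruning).
#' @param n_validate Segments sampled per class by [validate_separation()].
#' @param seed Integer seed governing every random draw in the analysis.
#'
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(window_frames = 40,
                            stride_frames = 1,
                            sigma_loc_nm = 9.8,
                            max_lag_frames = floor(window_frames / 4),
                            alpha_bounds = c(0, 2.2),
                            min_segment_frames = 5,
                            max_gap_frames = 5,
                            min_run_length_nm = 200,
                            min_speed_nm_s = 50,
                            min_duration_s = 0.25,
                            cp_penalty_factor = 10,
                            cp_merge_z = 3,
                            n_validate = 1500,
                            seed = 1L) {
  cfg <- list(window_frames = as.integer(window_frames),
              stride_frames = as.integer(stride_frames),
              sigma_loc_nm = sigma_loc_nm,
              max_lag_frames = as.integer(max_lag_frames),
              alpha_bounds = alpha_bounds,
              min_segment_frames = as.integer(min_segment_frames),
              max_gap_frames = as.integer(max_gap_frames),
              min_run_length_nm = min_run_length_nm,
              min_speed_nm_s = min_speed_nm_s,
              min_duration_s = min_duration_s,
              cp_penalty_factor = cp_penalty_factor,
              cp_merge_z = cp_merge_z,
              n_validate = as.integer(n_validate),
              seed = as.integer(seed))
  class(cfg) <- "analysis_config"
  validate_analysis_config(cfg)
  cfg
}

validate_analysis_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid `", field, "`: ", msg, call. = FALSE)
  }
  chk(cfg$window_frames >= 8, "window_frames", "must be at least 8 frames")
  chk(cfg$stride_frames >= 1, "stride_frames", "must be at least 1")
  chk(is.finite(cfg$sigma_loc_nm) && cfg$sigma_loc_nm >= 0, "sigma_loc_nm",
      "must be non-negative")
  chk(cfg$max_lag_frames >= 4, "max_lag_frames",
      "at least 4 lags are needed for the MSD fit")
  chk(cfg$max_lag_frames <= cfg$window_frames - 1, "max_lag_frames",
      "cannot exceed window_frames - 1")
  chk(length(cfg$alpha_bounds) == 2L && cfg$alpha_bounds[1] >= 0 &&
        cfg$alpha_bounds[2] > cfg$alpha_bounds[1], "alpha_bounds",
      "must be an increasing pair with lower bound >= 0")
  chk(cfg$min_segment_frames >= 1, "min_segment_frames", "must be >= 1")
  chk(cfg$max_gap_frames >= 0, "max_gap_frames", "must be >= 0")
  chk(cfg$min_run_length_nm > 0, "min_run_length_nm", "must be positive")
  chk(cfg$min_speed_nm_s > 0, "min_speed_nm_s", "must be positive")
  chk(cfg$min_duration_s > 0, "min_duration_s", "must be positive")
  chk(cfg$cp_penalty_factor > 0, "cp_penalty_factor", "must be positive")
  chk(cfg$n_validate >= 1, "n_validate", "must be >= 1")
  invisible(cfg)
}

#' Read and write key-value configuration files
#'
#' Configurations are stored as plain `key = value` text. Numeric values,
#' numeric pairs (comma-separated) and bare strings round-trip without loss.
#'
#' @param cfg A `sim_config` or `analysis_config` object.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns the reconstructed configuration object.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, c("sim_config", "analysis_config")))
  kind <- class(cfg)[1]
  lines <- c(paste0("config_class = ", kind),
             vapply(names(cfg), function(k) {
               v <- cfg[[k]]
               paste0(k, " = ", paste(format(v, digits = 17, scientific = FALSE,
                                             trim = TRUE), collapse = ", "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*?)\\s*$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) {
    stop("malformed config line ", bad[1], " in ", path, ": ", lines[bad[1]],
         call. = FALSE)
  }
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  parse1 <- function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else v
  }
  obj <- stats::setNames(lapply(vals, parse1), keys)
  kind <- obj$config_class
  obj$config_class <- NULL
  if (identical(kind, "sim_config")) {
    do.call(sim_config, obj)
  } else if (identical(kind, "analysis_config")) {
    do.call(analysis_config, obj)
  } else {
    stop("config file ", path, " does not declare a known config_class",
         call. = FALSE)
  }
}
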