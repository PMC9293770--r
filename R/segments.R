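#' Label directed and diffusive motion segments
#'
#' Assigns every frame the scaling exponent of the window centred on it
#' (edge frames take the nearest window), thresholds at the mixture cutoff
#' (alpha >= cutoff is directed), merges maximal same-state intervals, and
#' absorbs segments shorter than `min_segment_frames` into the longer
#' neighbour to suppress single-window flicker.
#'
#' @param traj Trajectory data frame (columns `frame`, `time_s`, ...).
#' @param fits Window fits from [fit_windows()] (stride 1 expected for
#'   frame-centred attribution; other strides use the nearest window).
#' @param cutoff Scaling-exponent threshold, e.g. from
#'   [fit_alpha_distribution()].
#' @param min_segment_frames Minimum segment length in frames.
#' @return Data frame of motion segments: `start_frame`, `end_frame`
#'   (0-based, inclusive), `state`, `n_frames`, `mean_alpha`; the per-frame
#'   alpha vector is attached as attribute `frame_alpha`.
#' @export
label_segments <- function(traj, fits, cutoff, min_segment_frames = 5) {
  ok <- fits$fit_ok & is.finite(fits$alpha)
  if (!any(ok)) stop("no valid window fits to label from", call. = FALSE)
  fits <- fits[ok, , drop = FALSE]
  idx <- findInterval(traj$frame, fits$center_frame, all.inside = TRUE)
  # findInterval gives the left neighbour; take whichever centre is nearest
  right <- pmin(idx + 1L, nrow(fits))
  use_right <- (fits$center_frame[right] - traj$frame) <
    (traj$frame - fits$center_frame[idx])
  idx[use_right] <- right[use_right]
  frame_alpha <- fits$alpha[idx]
  lab <- ifelse(frame_alpha >= cutoff, "directed", "diffusive")
  lab <- absorb_short_segments(lab, min_segment_frames)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start_frame = traj$frame[starts],
                    end_frame = traj$frame[ends],
                    state = r$values,
                    n_frames = r$lengths,
                    mean_alpha = vapply(seq_along(starts), function(i) {
                      mean(frame_alpha[starts[i]:ends[i]])
                    }, numeric(1)),
                    stringsAsFactors = FALSE)
  attr(seg, "frame_alpha") <- frame_alpha
  attr(seg, "cutoff") <- cutoff
  seg
}

# Iteratively flip the shortest sub-threshold segment to the state of its
# longer neighbour until every segment meets the minimum length.
absorb_short_segments <- function(lab, min_len) {
  repeat {
    r <- rle(lab)
    if (length(r$lengths) <= 1L) return(lab)
    short <- which(r$lengths < min_len)
    if (!length(short)) return(lab)
    i <- short[which.min(r$lengths[short])]
    left_len <- if (i > 1L) r$lengths[i - 1L] else -1L
    right_len <- if (i < length(r$lengths)) r$lengths[i + 1L] else -1L
    take <- if (left_len >= right_len) r$values[i - 1L] else r$values[i + 1L]
    r$values[i] <- take
    lab <- inverse.rle(r)
  }
}

#' Check motion-state separation by class-averaged MSD fits
#'
#' Randomly samples segments of each class, averages their MSD curves, and
#' fits the fixed-sigma anomalous-diffusion model per class. Well-separated
#' classes give an average exponent near 1 for the diffusive class and
#' near 2 for the directed class.
#'
#' @param segments_list List of segment tables (one per bead) from
#'   [label_segments()].
#' @param trajs List of the matching trajectories.
#' @param config An [analysis_config()]; `n_validate` segments are sampled
#'   per class (without replacement when enough are available).
#' @param min_frames Minimum segment length (frames) for a segment to
#'   contribute an MSD curve.
#' @return List with per-class elements `diffusive` and `directed`, each a
#'   list of `n_segments`, `msd` (averaged curve), `fit` (from [fit_msd()])
#'   and `alpha`; plus `flag`, TRUE when a class had fewer than 100 usable
#'   segments.
#' @export
validate_separation <- function(segments_list, trajs, config = analysis_config(),
                                min_frames = 2 * config$max_lag_frames + 1) {
  stopifnot(length(segments_list) == length(trajs))
  pool <- do.call(rbind, lapply(seq_along(trajs), function(b) {
    seg <- segments_list[[b]]
    seg$bead <- b
    seg
  }))
  pool <- pool[pool$n_frames >= min_frames, , drop = FALSE]
  set.seed(config$seed)
  out <- list()
  flag <- FALSE
  for (cls in c("diffusive", "directed")) {
    rows <- pool[pool$state == cls, , drop = FALSE]
    if (nrow(rows) < 100L) flag <- TRUE
    take <- if (nrow(rows) > config$n_validate) {
      rows[sample.int(nrow(rows), config$n_validate), , drop = FALSE]
    } else rows
    if (nrow(take) == 0L) {
      out[[cls]] <- list(n_segments = 0L, msd = NULL, fit = NULL,
                         alpha = NA_real_)
      next
    }
    lags <- seq_len(config$max_lag_frames)
    acc <- matrix(0, nrow(take), length(lags))
    dt <- NA_real_
    for (i in seq_len(nrow(take))) {
      tr <- trajs[[take$bead[i]]]
      rows_i <- which(tr$frame >= take$start_frame[i] &
                        tr$frame <= take$end_frame[i])
      x <- tr$x_nm[rows_i]; y <- tr$y_nm[rows_i]
      dt <- stats::median(diff(tr$time_s[rows_i]))
      m <- length(x)
      for (j in seq_along(lags)) {
        k <- lags[j]
        acc[i, j] <- mean((x[(1 + k):m] - x[1:(m - k)])^2 +
                            (y[(1 + k):m] - y[1:(m - k)])^2)
      }
    }
    curve <- data.frame(lag_s = lags * dt, msd_nm2 = colMeans(acc))
    fit <- fit_msd(curve, sigma = config$sigma_loc_nm,
                   alpha_bounds = config$alpha_bounds)
    out[[cls]] <- list(n_segments = nrow(take), msd = curve, fit = fit,
                       alpha = fit$alpha)
  }
  out$flag <- flag
  out
}
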