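#' Read and write trajectory tables
#'
#' Trajectories are exchanged as tab-separated text with header columns
#' `frame`, `time_s`, `x_nm`, `y_nm` and optionally `state` (and the
#' ground-truth `x_true_nm`/`y_true_nm` when present). Units are nm and
#' seconds; frames are 0-based.
#'
#' @param traj Trajectory data frame.
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` the trajectory with attribute `source = "file"`.
#' @export
write_trajectory <- function(traj, path) {
  keep <- intersect(c("frame", "time_s", "x_nm", "y_nm",
                      "x_true_nm", "y_true_nm", "state"), names(traj))
  utils::write.table(traj[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tr <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("frame", "time_s", "x_nm", "y_nm")
  miss <- setdiff(need, names(tr))
  if (length(miss)) {
    stop("trajectory file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(tr$x_nm)) || any(!is.finite(tr$y_nm))) {
    stop("trajectory file ", path, " contains non-finite coordinates",
         call. = FALSE)
  }
  if (any(diff(tr$time_s) <= 0)) {
    stop("trajectory file ", path, " has non-increasing time stamps",
         call. = FALSE)
  }
  attr(tr, "source") <- "file"
  tr
}

#' Read and write multi-frame TIFF image stacks
#'
#' Frames are written as 32-bit float TIFF directories, rescaled into
#' [0, 1] for the writer. Pixel size, frame rate, the intensity rescaling
#' and the nm origin of the field travel in a plain-text sidecar file
#' `<path>.meta` so a stack round-trips with its calibration.
#'
#' @param stack Image array `ny x nx x n_frames` with `pixel_size_nm` and
#'   `frame_rate` attributes.
#' @param path File path.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` the
#'   array with metadata attributes restored.
#' @export
write_stack <- function(stack, path) {
  frames <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  mx <- max(vapply(frames, max, numeric(1)))
  mn <- min(vapply(frames, min, numeric(1)))
  rng <- if (mx > mn) mx - mn else 1
  frames <- lapply(frames, function(f) (f - mn) / rng)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, compression = "none")
  origin <- attr(stack, "origin_nm")
  if (is.null(origin)) origin <- c(x = 0, y = 0)
  writeLines(c(
    sprintf("pixel_size_nm = %.10g", attr(stack, "pixel_size_nm")),
    sprintf("frame_rate = %.10g", attr(stack, "frame_rate")),
    sprintf("offset = %.10g", mn),
    sprintf("scale = %.10g", rng),
    sprintf("origin_x_nm = %.10g", origin[["x"]]),
    sprintf("origin_y_nm = %.10g", origin[["y"]])
  ), paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  meta <- c(pixel_size_nm = NA_real_, frame_rate = NA_real_,
            offset = 0, scale = 1, origin_x_nm = 0, origin_y_nm = 0)
  meta_path <- paste0(path, ".meta")
  if (file.exists(meta_path)) {
    for (ln in readLines(meta_path)) {
      p <- trimws(strsplit(ln, "=", fixed = TRUE)[[1]])
      if (length(p) == 2L && p[1] %in% names(meta)) meta[p[1]] <- as.numeric(p[2])
    }
  } else {
    warning("no metadata sidecar ", meta_path, "; pixel size and frame rate unknown")
  }
  arr <- array(0, c(dim(frames[[1]])[1:2], length(frames)))
  for (i in seq_along(frames)) {
    arr[, , i] <- frames[[i]] * meta[["scale"]] + meta[["offset"]]
  }
  attr(arr, "pixel_size_nm") <- meta[["pixel_size_nm"]]
  attr(arr, "frame_rate") <- meta[["frame_rate"]]
  attr(arr, "origin_nm") <- c(x = meta[["origin_x_nm"]], y = meta[["origin_y_nm"]])
  arr
}
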