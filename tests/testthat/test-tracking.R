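# Static single-frame fixtures rendered at the default 27.6 nm pixel size.
render_static <- function(x_px, y_px, noise_sd = 0, field = c(41, 41),
                          seed = NULL, ...) {
  cfg <- sim_config(duration = 0.5, sigma_loc = 0, D_diff = 0,
                    force_state = "diffusive", seed = 1)
  tr <- data.frame(frame = 0, time_s = 0, x_true_nm = x_px * 27.6,
                   y_true_nm = y_px * 27.6)
  attr(tr, "config") <- cfg
  if (!is.null(seed)) set.seed(seed)
  render_image_stack(tr, noise_sd = noise_sd, field_dim = field, ...)
}

test_that("a spot on a pixel centre localizes exactly to that centre", {
  st <- render_static(20, 20)
  loc <- localize_centroid(st[, , 1], c(20, 20), tracking_config(), 27.6)
  expect_equal(loc[["x_px"]], 20, tolerance = 1e-9)
  expect_equal(loc[["y_px"]], 20, tolerance = 1e-9)
  expect_equal(loc[["x_nm"]], 20 * 27.6, tolerance = 1e-6)
})

test_that("sub-pixel offsets are recovered without bias on a grid", {
  tc <- tracking_config()
  for (off in list(c(0.30, -0.45), c(-0.25, 0.10), c(0.49, 0.49),
                   c(-0.40, -0.15))) {
    st <- render_static(20 + off[1], 20 + off[2])
    loc <- localize_centroid(st[, , 1], c(20, 20), tc, 27.6)
    expect_lt(abs(loc[["x_px"]] - (20 + off[1])), 0.01)
    expect_lt(abs(loc[["y_px"]] - (20 + off[2])), 0.01)
    # agreement with the direct-summation oracle on the full frame
    oracle <- direct_centroid_px(st[, , 1], background = 100)
    expect_equal(loc[["x_px"]], oracle[["x"]], tolerance = 5e-3)
    expect_equal(loc[["y_px"]], oracle[["y"]], tolerance = 5e-3)
  }
})

test_that("localization is equivariant under whole-pixel translation", {
  tc <- tracking_config()
  st1 <- render_static(20.3, 19.6, field = c(61, 61))
  st2 <- render_static(25.3, 27.6, field = c(61, 61))
  l1 <- localize_centroid(st1[, , 1], c(20, 20), tc, 27.6)
  l2 <- localize_centroid(st2[, , 1], c(25, 28), tc, 27.6)
  expect_equal(l2[["x_px"]] - l1[["x_px"]], 5, tolerance = 1e-6)
  expect_equal(l2[["y_px"]] - l1[["y_px"]], 8, tolerance = 1e-6)
})

test_that("border and empty ROIs raise errors naming the frame", {
  st <- render_static(20, 20)
  expect_error(localize_centroid(st[, , 1], c(3, 20), tracking_config(),
                                 27.6, frame_id = 7), "frame 7")
  flat <- matrix(5, 41, 41)
  expect_error(localize_centroid(flat, c(20, 20), tracking_config(), 27.6,
                                 frame_id = 2), "frame 2")
})

test_that("localization error at default render settings is within 9.8 nm", {
  tc <- tracking_config()
  set.seed(99)
  errs <- vapply(1:80, function(i) {
    off <- stats::runif(2, -0.5, 0.5)
    st <- render_static(20 + off[1], 20 + off[2], noise_sd = 12)
    loc <- localize_centroid(st[, , 1], c(20, 20), tc, 27.6)
    sqrt((loc[["x_px"]] - 20 - off[1])^2 + (loc[["y_px"]] - 20 - off[2])^2)
  }, numeric(1)) * 27.6
  expect_lt(stats::sd(errs), 9.8)
  expect_lt(sqrt(mean(errs^2)), 9.8)
})

test_that("a motionless noise-free stack tracks to a constant trajectory", {
  cfg <- sim_config(duration = 0.45, sigma_loc = 0, D_diff = 0,
                    force_state = "diffusive", seed = 1)
  tr <- simulate_trajectory(cfg)
  tr$x_true_nm <- tr$x_true_nm + 20 * 27.6
  tr$y_true_nm <- tr$y_true_nm + 20 * 27.6
  attr(tr, "config") <- cfg
  st <- render_image_stack(tr, noise_sd = 0, field_dim = c(41, 41))
  tk <- track_stack(st, c(20, 20), tracking_config())
  expect_equal(nrow(tk), nrow(tr))
  expect_lt(max(abs(tk$x_nm - 20 * 27.6)), 0.3)
  expect_lt(max(abs(tk$y_nm - 20 * 27.6)), 0.3)
  expect_equal(tk$time_s, tr$time_s)  # stamps reconstructed at 20 frames/s
})

test_that("tracking a rendered simulated trajectory stays within 15 nm RMS", {
  cfg <- sim_config(duration = 15, seed = 21)
  tr <- simulate_trajectory(cfg)
  set.seed(5)
  st <- render_image_stack(tr)
  origin <- attr(st, "origin_nm")
  start <- c((tr$x_true_nm[1] - origin[["x"]]) / 27.6,
             (tr$y_true_nm[1] - origin[["y"]]) / 27.6)
  tk <- track_stack(st, start, tracking_config())
  expect_equal(nrow(tk), nrow(tr))
  rms <- sqrt(mean((tk$x_nm - tr$x_true_nm)^2 + (tk$y_nm - tr$y_true_nm)^2))
  expect_lt(rms, 15)
})

test_that("association gating terminates the track instead of interpolating", {
  st1 <- render_static(26, 20, field = c(41, 61))
  st2 <- render_static(34, 20, field = c(41, 61))  # 8 px jump ~ 221 nm
  stack <- array(c(st1, st2), c(41, 61, 2))
  attr(stack, "pixel_size_nm") <- 27.6
  attr(stack, "frame_rate") <- 20
  expect_warning(tk <- track_stack(stack, c(26, 20),
                                   tracking_config(max_step = 100)),
                 "max_step")
  expect_equal(nrow(tk), 1L)
})

test_that("tracked and directly simulated positions classify alike", {
  cfg <- sim_config(duration = 40, seed = 23)
  tr <- simulate_trajectory(cfg)
  set.seed(9)
  st <- render_image_stack(tr)
  origin <- attr(st, "origin_nm")
  start <- c((tr$x_true_nm[1] - origin[["x"]]) / 27.6,
             (tr$y_true_nm[1] - origin[["y"]]) / 27.6)
  tk <- track_stack(st, start, tracking_config())
  ac <- analysis_config()
  cut <- 1.55
  seg_sim <- label_segments(tr, fit_windows(tr, ac), cut)
  seg_trk <- label_segments(tk, fit_windows(tk, ac), cut)
  lab_sim <- rep(seg_sim$state, seg_sim$n_frames)
  lab_trk <- rep(seg_trk$state, seg_trk$n_frames)
  expect_gte(mean(lab_sim == lab_trk), 0.95)
})
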