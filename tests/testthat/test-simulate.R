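test_that("degenerate motionless configuration stays at the origin", {
  cfg <- sim_config(force_state = "diffusive", D_diff = 0, sigma_loc = 0,
                    duration = 5, seed = 1)
  tr <- simulate_trajectory(cfg)
  expect_true(all(tr$x_nm == 0) && all(tr$y_nm == 0))
  expect_true(all(tr$state == "diffusive"))
})

test_that("pure ballistic motion covers speed x time exactly", {
  cfg <- sim_config(force_state = "directed", v_mean = 500, v_sd = 0,
                    D_run = 0, sigma_loc = 0, p_reverse = 0, duration = 10,
                    seed = 2)
  tr <- simulate_trajectory(cfg)
  disp <- sqrt((tr$x_nm - tr$x_nm[1])^2 + (tr$y_nm - tr$y_nm[1])^2)
  expect_equal(disp, 500 * tr$time_s, tolerance = 1e-12)
  expect_equal(nrow(tr), 10 * 20 + 1)
  expect_equal(diff(tr$time_s), rep(0.05, nrow(tr) - 1), tolerance = 1e-12)
})

test_that("ensemble MSD of forced diffusion matches 4 D t + 2 sigma^2", {
  D <- 1e4; sig <- 9.8; dt <- 0.05
  cfg <- sim_config(force_state = "diffusive", D_diff = D, sigma_loc = sig,
                    duration = 20, seed = 3)
  trs <- sim_cohort_one(cfg, 200)
  for (k in c(1L, 4L, 10L, 40L)) {  # lags 0.05 to 2 s
    per_traj <- vapply(trs, function(tr) {
      n <- nrow(tr)
      mean((tr$x_nm[(1 + k):n] - tr$x_nm[1:(n - k)])^2 +
             (tr$y_nm[(1 + k):n] - tr$y_nm[1:(n - k)])^2)
    }, numeric(1))
    theory <- 4 * D * k * dt + 2 * sig^2
    se <- stats::sd(per_traj) / sqrt(length(per_traj))
    expect_lt(abs(mean(per_traj) - theory), 3 * se)
  }
})

test_that("directed sojourn durations are exponential with mean 1/k_off", {
  cfg <- sim_config(k_off = 0.5, k_on = 2, seed = 4)
  trs <- sim_cohort_one(cfg, 250)
  dur <- unlist(lapply(trs, function(tr) {
    sj <- attr(tr, "sojourns")
    sj$duration_s[sj$state == "directed" & !sj$censored]
  }))
  expect_gt(length(dur), 1e4)
  ks <- suppressWarnings(stats::ks.test(dur, "pexp", rate = 0.5))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(dur), 2, tolerance = 0.05)
})

test_that("time in the directed state converges to k_on/(k_on+k_off)", {
  cfg <- sim_config(k_off = 1 / 9, k_on = 1 / 6, seed = 5)  # stationary 0.6
  trs <- sim_cohort_one(cfg, 60)
  frac <- vapply(trs, function(tr) mean(tr$state == "directed"), numeric(1))
  se <- stats::sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 0.6), 3 * se)
})

test_that("per-run speeds respect the truncated support", {
  cfg <- sim_config(v_mean = 200, v_sd = 400, seed = 6)
  trs <- sim_cohort_one(cfg, 30)
  sp <- unlist(lapply(trs, function(tr) {
    sj <- attr(tr, "sojourns")
    sj$speed_nm_s[sj$state == "directed"]
  }))
  expect_true(all(sp >= 50 & sp <= 1500))
})

test_that("the same seed reproduces trajectories bit for bit", {
  cfg <- sim_config(seed = 11)
  t1 <- simulate_trajectory(cfg)
  t2 <- simulate_trajectory(cfg)
  expect_identical(t1$x_nm, t2$x_nm)
  expect_identical(t1$y_nm, t2$y_nm)
  expect_identical(t1$state, t2$state)
})

test_that("cohorts record ground truth and are symmetric for equal configs", {
  cfg <- sim_config(duration = 60, seed = 8)
  co <- simulate_cohort(cfg, cfg, n_per_group = 5)
  expect_length(co$control, 5)
  expect_length(co$treated, 5)
  tr_truth <- co$truth
  expect_equal(tr_truth$pct_directed[1], tr_truth$pct_directed[2])
  expect_equal(tr_truth$mean_run_duration_s[1], tr_truth$mean_run_duration_s[2])
  expect_error(simulate_cohort(cfg, cfg, 0), "n_per_group")
  # default cohort size matches the early-phagosome tracking scale
  expect_identical(formals(simulate_cohort)$n_per_group, 63)
})

test_that("doubling k_off halves the true mean run duration", {
  cfg_c <- sim_config(k_off = 0.25, duration = 150, seed = 9)
  cfg_t <- sim_config(k_off = 0.5, duration = 150, seed = 10)
  co <- simulate_cohort(cfg_c, cfg_t, n_per_group = 40)
  ratio <- co$truth$mean_run_duration_s[co$truth$group == "treated"] /
    co$truth$mean_run_duration_s[co$truth$group == "control"]
  expect_equal(ratio, 0.5, tolerance = 0.12)
})

test_that("rendered stacks are Gaussian spots with correct timing metadata", {
  base <- sim_config(duration = 0.5, sigma_loc = 0, D_diff = 0,
                     force_state = "diffusive", seed = 1)
  # symmetric spot on a pixel grid point: frame symmetric about that pixel
  tr <- data.frame(frame = 0:1, time_s = c(0, 0.05),
                   x_true_nm = rep(20 * 27.6, 2), y_true_nm = rep(20 * 27.6, 2))
  attr(tr, "config") <- base
  st <- render_image_stack(tr, noise_sd = 0, field_dim = c(41, 41))
  fr <- st[, , 1]
  expect_equal(fr, fr[41:1, ], tolerance = 1e-12)      # mirror in y
  expect_equal(fr, fr[, 41:1], tolerance = 1e-12)      # mirror in x
  expect_equal(dim(st)[3], 2)
  expect_equal(attr(st, "frame_rate"), 20)             # 1/20 s frame interval
  expect_equal(attr(st, "pixel_size_nm"), 27.6)

  # known sub-pixel offset: intensity-weighted centroid of the frame
  tr2 <- tr
  tr2$x_true_nm <- (20 + 0.30) * 27.6
  tr2$y_true_nm <- (20 - 0.45) * 27.6
  attr(tr2, "config") <- base
  st2 <- render_image_stack(tr2, noise_sd = 0, field_dim = c(41, 41))
  cen <- direct_centroid_px(st2[, , 1], background = 100)
  expect_lt(abs(cen[["x"]] - 20.30), 0.01)
  expect_lt(abs(cen[["y"]] - 19.55), 0.01)

  # spot too close to the field border is an error naming the frame
  tr3 <- tr
  tr3$x_true_nm <- c(20, 2) * 27.6
  attr(tr3, "config") <- base
  expect_error(render_image_stack(tr3, noise_sd = 0, field_dim = c(41, 41)),
               "frame 1")
})
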