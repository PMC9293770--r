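test_that("directed segments are stitched across short diffusive gaps", {
  tr <- make_ballistic_traj(v = 300, n = 100)
  seg <- data.frame(start_frame = c(0L, 30L, 34L, 60L, 71L),
                    end_frame = c(29L, 33L, 59L, 70L, 99L),
                    state = c("directed", "diffusive", "directed",
                              "diffusive", "directed"),
                    n_frames = c(30L, 4L, 26L, 11L, 29L))
  tracks <- stitch_directed(seg, tr, max_gap_frames = 5)
  # 4-frame gap bridged, 11-frame gap splits
  expect_length(tracks, 2L)
  expect_equal(nrow(tracks[[1]]), 60L)  # 30 + 4 + 26 frames incl. gap
  expect_equal(nrow(tracks[[2]]), 29L)
  expect_false(attr(tracks[[1]], "ends_at_traj_end"))
  expect_true(attr(tracks[[2]], "ends_at_traj_end"))
  expect_length(stitch_directed(seg[seg$state == "diffusive", ], tr, 5), 0L)
})

test_that("a constant-velocity noisy track parses as a single run", {
  ac <- analysis_config()
  tr <- make_two_piece_track(v1 = 500, v2 = 500, n_change = 60, n = 120,
                             sigma = 9.8, seed = 4)
  p <- parse_constant_velocity(tr, ac)
  expect_equal(nrow(p), 1L)
  expect_length(attr(p, "changepoints"), 0L)
  expect_equal(p$speed_nm_s, 500, tolerance = 0.05)
  expect_equal(p$net_nm, p$speed_nm_s * p$duration_s, tolerance = 1e-9)
})

test_that("zero change points are reported on at least 95% of constant tracks", {
  ac <- analysis_config()
  zero <- vapply(1:60, function(s) {
    tr <- make_two_piece_track(v1 = 500, v2 = 500, n = 120, sigma = 9.8,
                               seed = 1000 + s)
    nrow(parse_constant_velocity(tr, ac)) == 1L
  }, logical(1))
  expect_gte(mean(zero), 0.95)
})

test_that("a two-piece track is cut within 3 frames of the true change", {
  ac <- analysis_config()
  hits <- vapply(1:40, function(s) {
    tr <- make_two_piece_track(v1 = 600, v2 = 100, n_change = 60, n = 120,
                               sigma = 9.8, seed = 2000 + s)
    p <- parse_constant_velocity(tr, ac)
    cps <- attr(p, "changepoints")
    length(cps) == 1L && abs(cps - 60L) <= 3L
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("parsing is invariant under rigid rotation of the trajectory", {
  ac <- analysis_config()
  tr <- make_two_piece_track(v1 = 600, v2 = 100, n_change = 60, n = 120,
                             sigma = 9.8, seed = 77)
  th <- 0.83
  tr_rot <- tr
  tr_rot$x_nm <- cos(th) * tr$x_nm - sin(th) * tr$y_nm
  tr_rot$y_nm <- sin(th) * tr$x_nm + cos(th) * tr$y_nm
  p1 <- parse_constant_velocity(tr, ac)
  p2 <- parse_constant_velocity(tr_rot, ac)
  expect_equal(attr(p1, "changepoints"), attr(p2, "changepoints"))
  expect_equal(p1$speed_nm_s, p2$speed_nm_s, tolerance = 1e-6)
})

test_that("parsed pieces partition the track and short tracks are flagged", {
  ac <- analysis_config()
  tr <- make_two_piece_track(v1 = 600, v2 = 100, n_change = 60, n = 120,
                             sigma = 9.8, seed = 5)
  p <- parse_constant_velocity(tr, ac)
  expect_equal(p$start_frame[1], 0L)
  expect_equal(p$end_frame[nrow(p)], 119L)
  if (nrow(p) > 1) expect_equal(p$start_frame[-1], p$end_frame[-nrow(p)] + 1L)
  short <- parse_constant_velocity(tr[1:6, ], ac)
  expect_equal(nrow(short), 0L)
  expect_true(attr(short, "too_short"))
})

test_that("run criteria classify the fixture parse table exactly", {
  fx <- read.delim(system.file("extdata", "run_criteria_fixture.tsv",
                               package = "phagomotion"))
  pieces <- data.frame(piece = fx$piece, start_frame = 0L, end_frame = 0L,
                       duration_s = fx$duration_s, net_nm = fx$net_nm,
                       speed_nm_s = fx$speed_nm_s,
                       velocity_sign = 1, kind = NA_character_)
  out <- classify_runs(pieces, analysis_config())
  expect_identical(out$kind, fx$expected_kind)
  expect_equal(as.vector(table(out$kind)[c("run", "pause", "subthreshold")]),
               c(2L, 2L, 2L))
})

test_that("recovered run speeds track the generating speed distribution", {
  cfg <- sim_config(seed = 41)
  trs <- sim_cohort_one(cfg, 15)
  res <- analyze_group(trs, analysis_config(), "speed")
  runs <- res$runs[res$runs$kind == "run", ]
  true_speed <- mean(unlist(lapply(trs, function(tr) {
    sj <- attr(tr, "sojourns")
    sj$speed_nm_s[sj$state == "directed"]
  })))
  expect_gt(nrow(runs), 300)
  expect_equal(mean(runs$speed_nm_s), true_speed, tolerance = 0.10)
})
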