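test_that("per-bead motion percentages sum to 100 and handle edge cases", {
  seg_full <- data.frame(start_frame = 0L, end_frame = 99L, state = "directed",
                         n_frames = 100L, mean_alpha = 1.9)
  seg_mixed <- data.frame(start_frame = c(0L, 60L), end_frame = c(59L, 99L),
                          state = c("directed", "diffusive"),
                          n_frames = c(60L, 40L), mean_alpha = c(1.9, 1.0))
  pct <- percent_motion(list(seg_full, seg_mixed))
  expect_equal(pct$pct_directed, c(100, 60))
  expect_equal(pct$pct_directed + pct$pct_diffusive, c(100, 100))
  empty <- seg_full[0, ]
  expect_warning(pct2 <- percent_motion(list(seg_full, empty)), "excluding")
  expect_equal(nrow(pct2), 1L)
})

test_that("run statistics use runs only, with hand-computed SEM", {
  runs <- data.frame(net_nm = c(400, 500, 600, 70),
                     speed_nm_s = c(500, 500, 500, 30),
                     duration_s = c(0.8, 1, 1.2, 2.3),
                     kind = c("run", "run", "run", "pause"))
  rl <- run_length_stats(runs)
  expect_equal(rl$mean, 500)
  expect_equal(rl$sem, 57.735, tolerance = 1e-4)  # sd(100)/sqrt(3)
  expect_equal(rl$n, 3L)
  # single run: mean defined, SEM flagged undefined
  one <- run_length_stats(runs[1, ])
  expect_equal(one$mean, 400)
  expect_false(one$sem_defined)
  # zero runs: flagged undefined, not zero
  zero <- velocity_stats(runs[runs$kind == "pause", ])
  expect_false(zero$defined)
  expect_true(is.na(zero$mean) || is.nan(zero$mean))
})

test_that("summary statistics are invariant to input order", {
  runs <- data.frame(net_nm = c(400, 500, 600, 250, 900),
                     speed_nm_s = c(500, 100, 700, 300, 250),
                     duration_s = 1, kind = "run")
  perm <- runs[c(3, 1, 5, 2, 4), ]
  expect_equal(run_length_stats(runs), run_length_stats(perm))
  expect_equal(velocity_stats(runs), velocity_stats(perm))
})

test_that("dissociation rate counts pause and diffusive-end terminations", {
  mk <- function(kinds, durs, ends_at_end) {
    tab <- data.frame(piece = seq_along(kinds), start_frame = 0L,
                      end_frame = 0L, duration_s = durs, net_nm = 300,
                      speed_nm_s = 400, velocity_sign = 1, kind = kinds)
    attr(tab, "ends_at_traj_end") <- ends_at_end
    tab
  }
  bead <- list(
    # run -> pause: one termination; 2 s in runs
    mk(c("run", "pause"), c(2, 0.5), FALSE),
    # run -> subthreshold -> pause: still one termination; 3 s in runs
    mk(c("run", "subthreshold", "pause"), c(3, 0.2, 0.6), FALSE),
    # run -> run (parser split): no pause termination, but the second run
    # ends with the track inside the recording: one termination; 5 s
    mk(c("run", "run"), c(2, 3), FALSE),
    # run at the recording end: censored, time still counted; 4 s
    mk(c("run"), 4, TRUE)
  )
  dis <- dissociation_rate(list(bead), min_terminations = 1L)
  expect_equal(dis$per_bead$n_terminations, 3L)
  expect_equal(dis$per_bead$time_in_runs_s, 14)
  expect_equal(dis$per_bead$rate, 3 / 14)
  expect_false(dis$flag)
  dis2 <- dissociation_rate(list(bead))
  expect_true(dis2$flag)  # fewer than 10 terminations
})

test_that("recovered dissociation rate matches the generating k_off", {
  cfg <- sim_config(k_off = 0.5, seed = 51)
  trs <- sim_cohort_one(cfg, 12)
  res <- analyze_group(trs, analysis_config(), "koff")
  expect_equal(res$dissociation$mean, 0.5, tolerance = 0.2)
})

test_that("Welch comparisons report t, p and the star convention", {
  x <- c(1.2, 1.4, 1.1, 1.3, 1.25)
  same <- welch_compare(x, x, "identical")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$stars, "ns")
  expect_true(welch_compare(x, c(1, 2), "tiny")$skipped ||
                is.finite(welch_compare(x, c(1, 2), "tiny")$p))
  skip <- welch_compare(x, 1.0, "one-obs")
  expect_true(skip$skipped)
  expect_identical(p_stars(0.03), "*")
  expect_identical(p_stars(0.004), "**")
  expect_identical(p_stars(2e-4), "***")
  expect_identical(p_stars(5e-5), "****")
  expect_identical(p_stars(0.2), "ns")
})

test_that("separated Normal groups are detected with high power", {
  reject <- vapply(1:500, function(s) {
    set.seed(s)
    a <- stats::rnorm(100, 600, 100)
    b <- stats::rnorm(100, 400, 100)
    welch_compare(a, b, "power")$p < 0.001
  }, logical(1))
  expect_gte(mean(reject), 0.99)
})
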