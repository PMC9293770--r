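#' Per-bead percent directed and diffusive motion
#'
#' Fraction of classified frames per bead spent in each motion state
#' (time-weighted). Beads with no classified frames are excluded with a
#' warning.
#'
#' @param segments_list List of segment tables (one per bead) from
#'   [label_segments()].
#' @return Data frame with one row per bead: `bead`, `pct_directed`,
#'   `pct_diffusive` (summing to 100 per bead), `n_frames`.
#' @export
percent_motion <- function(segments_list) {
  rows <- lapply(seq_along(segments_list), function(b) {
    seg <- segments_list[[b]]
    tot <- sum(seg$n_frames)
    if (is.null(seg) || nrow(seg) == 0L || tot == 0L) return(NULL)
    ndir <- sum(seg$n_frames[seg$state == "directed"])
    data.frame(bead = b, pct_directed = 100 * ndir / tot,
               pct_diffusive = 100 * (tot - ndir) / tot, n_frames = tot)
  })
  drop <- vapply(rows, is.null, logical(1))
  if (any(drop)) {
    warning("excluding ", sum(drop), " bead(s) with no classified frames")
  }
  do.call(rbind, rows[!drop])
}

mean_sem <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  list(mean = if (n) mean(x) else NA_real_,
       sem = if (n >= 2) stats::sd(x) / sqrt(n) else NA_real_,
       n = n,
       sem_defined = n >= 2)
}

#' Run-length and velocity statistics
#'
#' Mean and SEM over segments classified as runs (`kind == "run"` only).
#' With zero runs the statistics are flagged undefined rather than zero;
#' with a single run the mean is reported and the SEM flagged undefined.
#'
#' @param runs A parsed, classified segment table (or a row-bound set of
#'   them) from [classify_runs()].
#' @return For each: list with `mean`, `sem`, `n`, `sem_defined`,
#'   `defined`.
#' @export
run_length_stats <- function(runs) {
  v <- runs$net_nm[runs$kind == "run"]
  out <- mean_sem(v)
  out$defined <- out$n >= 1
  out
}

#' @rdname run_length_stats
#' @export
velocity_stats <- function(runs) {
  v <- runs$speed_nm_s[runs$kind == "run"]
  out <- mean_sem(v)
  out$defined <- out$n >= 1
  out
}

#' Dissociation rate from parsed run segments
#'
#' Estimates the rate of cargo leaving the motor-bound state as run
#' terminations per unit time spent in runs, computed per bead and then
#' summarised as mean and SEM across beads. This is the maximum-likelihood
#' rate for exponential motor-bound episodes with censoring. A run piece
#' terminates when it ends in a pause (speed below the run threshold:
#' motors disengaged) or when its directed track ends inside the recording
#' (the cargo went diffusive). A transition into another fast piece (a new
#' run or a subthreshold fragment) is not a termination: constant-velocity
#' parsing can split one motor-bound episode at internal velocity
#' fluctuations, and counting such splits would inflate the rate. A run
#' that ends exactly at the end of the recording is censored -- excluded
#' from the termination count while its duration stays in the denominator.
#'
#' @param pieces_per_bead List (one element per bead) of lists of parsed,
#'   classified piece tables (one table per stitched directed track, as
#'   returned by [parse_constant_velocity()] + [classify_runs()]).
#' @param min_terminations Below this group-total termination count the
#'   estimate is flagged unreliable.
#' @return List with `per_bead` (data frame: `bead`, `rate`,
#'   `n_terminations`, `time_in_runs_s`), `mean`, `sem`, `n`, and `flag`
#'   (TRUE when the group has fewer than `min_terminations` terminations).
#' @export
dissociation_rate <- function(pieces_per_bead, min_terminations = 10L) {
  per_bead <- do.call(rbind, lapply(seq_along(pieces_per_bead), function(b) {
    tracks <- pieces_per_bead[[b]]
    nterm <- 0L
    time_runs <- 0
    for (tab in tracks) {
      if (nrow(tab) == 0L) next
      run_rows <- which(tab$kind == "run")
      if (!length(run_rows)) next
      time_runs <- time_runs + sum(tab$duration_s[run_rows])
      censored_last <- isTRUE(attr(tab, "ends_at_traj_end"))
      for (r in run_rows) {
        # skip over short fast fragments: what does the run end in?
        nxt <- r + 1L
        while (nxt <= nrow(tab) && tab$kind[nxt] == "subthreshold") {
          nxt <- nxt + 1L
        }
        if (nxt <= nrow(tab)) {
          if (tab$kind[nxt] == "pause") nterm <- nterm + 1L
        } else if (!censored_last) {
          nterm <- nterm + 1L  # track ended mid-recording: went diffusive
        }
      }
    }
    data.frame(bead = b, rate = if (time_runs > 0) nterm / time_runs else NA_real_,
               n_terminations = nterm, time_in_runs_s = time_runs)
  }))
  ms <- mean_sem(per_bead$rate)
  list(per_bead = per_bead, mean = ms$mean, sem = ms$sem, n = ms$n,
       flag = sum(per_bead$n_terminations) < min_terminations)
}

#' Welch two-sample comparison with significance stars
#'
#' @param a,b Numeric vectors of per-unit values (beads or runs).
#' @param statistic Name of the compared statistic.
#' @return One-row data frame: `statistic`, `mean_a`, `mean_b`, `t`, `df`,
#'   `p`, `stars` (`ns`, `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#'   `****` p < 0.0001); the test is skipped (`NA`, flagged in `skipped`)
#'   when either group has fewer than two values.
#' @export
welch_compare <- function(a, b, statistic = "statistic") {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    return(data.frame(statistic = statistic, mean_a = mean(a), mean_b = mean(b),
                      t = NA_real_, df = NA_real_, p = NA_real_,
                      stars = NA_character_, skipped = TRUE,
                      stringsAsFactors = FALSE))
  }
  tst <- stats::t.test(a, b, var.equal = FALSE)
  data.frame(statistic = statistic, mean_a = mean(a), mean_b = mean(b),
             t = unname(tst$statistic), df = unname(tst$parameter),
             p = tst$p.value, stars = p_stars(tst$p.value), skipped = FALSE,
             stringsAsFactors = FALSE)
}

p_stars <- function(p) {
  if (!is.finite(p)) return(NA_character_)
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else "ns"
}

#' Transport summary for one analysed group
#'
#' Collects the headline transport statistics of a cohort: percent
#' directed/diffusive motion (mean +/- SEM across beads), run length and
#' velocity (mean +/- SEM across runs), and dissociation rate (mean +/- SEM
#' across beads).
#'
#' @param group Group label.
#' @param pct Per-bead percent table from [percent_motion()].
#' @param runs Row-bound classified run table of the group.
#' @param dis Result of [dissociation_rate()].
#' @return An object of class `transport_summary`.
#' @export
transport_summary <- function(group, pct, runs, dis) {
  out <- list(group = group,
              n_beads = nrow(pct),
              n_runs = sum(runs$kind == "run"),
              pct_directed = mean_sem(pct$pct_directed),
              pct_diffusive = mean_sem(pct$pct_diffusive),
              run_length = run_length_stats(runs),
              velocity = velocity_stats(runs),
              dissociation = list(mean = dis$mean, sem = dis$sem, n = dis$n,
                                  flag = dis$flag))
  class(out) <- "transport_summary"
  out
}

#' @export
print.transport_summary <- function(x, ...) {
  fmt <- function(s, unit) {
    if (is.null(s$mean) || !is.finite(s$mean)) return("undefined")
    sem <- if (isTRUE(is.finite(s$sem))) sprintf(" +/- %.3g", s$sem) else " (SEM undefined)"
    sprintf("%.4g%s %s", s$mean, sem, unit)
  }
  cat("Transport summary --", x$group, "\n")
  cat("  beads:", x$n_beads, "  runs:", x$n_runs, "\n")
  cat("  percent directed:  ", fmt(x$pct_directed, "%"), "\n")
  cat("  percent diffusive: ", fmt(x$pct_diffusive, "%"), "\n")
  cat("  run length:        ", fmt(x$run_length, "nm"), "\n")
  cat("  velocity:          ", fmt(x$velocity, "nm/s"), "\n")
  cat("  dissociation rate: ", fmt(x$dissociation, "1/s"), "\n")
  invisible(x)
}

#' Compare two analysed groups
#'
#' Welch two-sample t-tests on the per-unit values of each transport
#' statistic: beads for motion percentages and dissociation rate, runs for
#' run length and velocity.
#'
#' @param res_a,res_b Group analysis results from [analyze_group()].
#' @return Data frame of comparisons (one row per statistic).
#' @export
compare_groups <- function(res_a, res_b) {
  runs_a <- res_a$runs[res_a$runs$kind == "run", , drop = FALSE]
  runs_b <- res_b$runs[res_b$runs$kind == "run", , drop = FALSE]
  rbind(
    welch_compare(res_a$pct$pct_directed, res_b$pct$pct_directed, "pct_directed"),
    welch_compare(res_a$pct$pct_diffusive, res_b$pct$pct_diffusive, "pct_diffusive"),
    welch_compare(runs_a$net_nm, runs_b$net_nm, "run_length_nm"),
    welch_compare(runs_a$speed_nm_s, runs_b$speed_nm_s, "velocity_nm_s"),
    welch_compare(res_a$dissociation$per_bead$rate,
                  res_b$dissociation$per_bead$rate, "dissociation_rate_s")
  )
}
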