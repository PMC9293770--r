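#' Analyse a cohort of trajectories
#'
#' Runs the motion-state pipeline on a list of trajectories: sliding-window
#' MSD fits per bead, a pooled two-Gaussian mixture over the scaling
#' exponents to set the directed/diffusive cutoff (unless one is supplied),
#' segment labelling, directed-track stitching, constant-velocity parsing,
#' run classification and the transport summary.
#'
#' @param trajs List of trajectory data frames.
#' @param config An [analysis_config()].
#' @param group Group label carried into the summary.
#' @param cutoff Optional fixed scaling-exponent cutoff; when `NULL` the
#'   cutoff is taken from a mixture fitted to the cohort's pooled alphas.
#' @param fits Optional precomputed list of window fits (from
#'   [fit_windows()], one per trajectory) to avoid refitting.
#' @return An object of class `group_analysis`: list with `fits`, `alphas`,
#'   `mixture` (or `NULL` when a cutoff was supplied), `cutoff`,
#'   `segments` (per bead), `pieces` (per bead, per stitched track),
#'   `runs` (row-bound classified pieces), `pct`, `dissociation` and
#'   `summary`.
#' @export
analyze_group <- function(trajs, config = analysis_config(), group = "group",
                          cutoff = NULL, fits = NULL) {
  if (!length(trajs)) stop("no trajectories to analyse", call. = FALSE)
  if (is.null(fits)) fits <- lapply(trajs, fit_windows, config = config)
  alphas <- unlist(lapply(fits, function(f) f$alpha[f$fit_ok]))
  mixture <- NULL
  if (is.null(cutoff)) {
    mixture <- fit_alpha_distribution(alphas, seed = config$seed)
    cutoff <- mixture$cutoff
  }
  segments <- vector("list", length(trajs))
  pieces <- vector("list", length(trajs))
  for (b in seq_along(trajs)) {
    seg <- tryCatch(
      label_segments(trajs[[b]], fits[[b]], cutoff, config$min_segment_frames),
      error = function(e) {
        warning("bead ", b, " skipped: ", conditionMessage(e))
        NULL
      })
    segments[[b]] <- seg
    if (is.null(seg)) {
      pieces[[b]] <- list()
      next
    }
    tracks <- stitch_directed(seg, trajs[[b]], config$max_gap_frames)
    pieces[[b]] <- lapply(tracks, function(tk) {
      classify_runs(parse_constant_velocity(tk, config), config)
    })
  }
  keep <- !vapply(segments, is.null, logical(1))
  pct <- percent_motion(segments[keep])
  pct$bead <- which(keep)[pct$bead]
  runs <- do.call(rbind, c(list(data.frame()), unlist(pieces, recursive = FALSE)))
  dis <- dissociation_rate(pieces)
  out <- list(group = group, fits = fits, alphas = alphas, mixture = mixture,
              cutoff = cutoff, segments = segments, pieces = pieces,
              runs = runs, pct = pct, dissociation = dis,
              summary = transport_summary(group, pct, runs, dis),
              config = config)
  class(out) <- "group_analysis"
  out
}

#' Analyse and compare two cohorts with a shared cutoff
#'
#' Pools the sliding-window scaling exponents of both cohorts into a single
#' two-Gaussian mixture (one cutoff per condition pair, mirroring a single
#' cutoff per phagosome age), analyses each group against that cutoff and
#' compares the transport statistics by Welch t-tests.
#'
#' @param trajs_a,trajs_b Trajectory lists for the two groups.
#' @param config An [analysis_config()].
#' @param groups Character vector of the two group labels.
#' @return List with `mixture`, `cutoff`, per-group `group_analysis`
#'   objects (named after `groups`) and `comparisons`.
#' @export
analyze_two_groups <- function(trajs_a, trajs_b, config = analysis_config(),
                               groups = c("control", "treated")) {
  fits_a <- lapply(trajs_a, fit_windows, config = config)
  fits_b <- lapply(trajs_b, fit_windows, config = config)
  alphas <- c(unlist(lapply(fits_a, function(f) f$alpha[f$fit_ok])),
              unlist(lapply(fits_b, function(f) f$alpha[f$fit_ok])))
  mixture <- fit_alpha_distribution(alphas, seed = config$seed)
  res_a <- analyze_group(trajs_a, config, groups[1], cutoff = mixture$cutoff,
                         fits = fits_a)
  res_b <- analyze_group(trajs_b, config, groups[2], cutoff = mixture$cutoff,
                         fits = fits_b)
  out <- list(mixture = mixture, cutoff = mixture$cutoff,
              comparisons = compare_groups(res_a, res_b))
  out[[groups[1]]] <- res_a
  out[[groups[2]]] <- res_b
  out
}

#' Run the full file-based pipeline
#'
#' Reads trajectory files (tab-separated, see [read_trajectory()]) from one
#' or two group directories, runs the analysis, and writes a report bundle:
#' per-frame alpha tables, segment tables, run tables, the mixture report
#' and a JSON summary stamped with the configuration hash, seed and package
#' version. Identical inputs, configuration and seed give identical
#' reports.
#'
#' @param input Character vector of one or two directories of trajectory
#'   files (two directories are compared as control vs treated, in order).
#' @param config An [analysis_config()].
#' @param out_dir Output directory (created if needed).
#' @param groups Group labels (defaults to the directory base names).
#' @return Invisibly, the in-memory analysis result.
#' @export
run_pipeline <- function(input, config = analysis_config(),
                         out_dir = "pipeline_out", groups = NULL) {
  if (length(input) < 1L || length(input) > 2L) {
    stop("`input` must name one or two directories", call. = FALSE)
  }
  load_dir <- function(d) {
    files <- sort(list.files(d, pattern = "\\.(tsv|txt)$", full.names = TRUE))
    if (!length(files)) stop("no inputs: no trajectory files in ", d, call. = FALSE)
    trajs <- list()
    for (f in files) {
      tr <- tryCatch(read_trajectory(f), error = function(e) {
        warning("skipping ", f, ": ", conditionMessage(e))
        NULL
      })
      if (!is.null(tr)) trajs[[length(trajs) + 1L]] <- tr
    }
    if (!length(trajs)) stop("no inputs: no readable trajectory files in ", d,
                             call. = FALSE)
    trajs
  }
  if (is.null(groups)) groups <- basename(input)
  trajs <- lapply(input, load_dir)  # validate inputs before writing anything

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "analysis_config.txt")
  write_config(config, cfg_path)
  stamp <- list(config_hash = unname(tools::md5sum(cfg_path)),
                seed = config$seed,
                package_version = as.character(utils::packageVersion("phagomotion")))

  if (length(input) == 1L) {
    res <- analyze_group(trajs[[1]], config, groups[1])
    groups_res <- stats::setNames(list(res), groups[1])
    mixture <- res$mixture
    comparisons <- NULL
  } else {
    res2 <- analyze_two_groups(trajs[[1]], trajs[[2]], config, groups)
    groups_res <- res2[groups]
    mixture <- res2$mixture
    comparisons <- res2$comparisons
  }

  for (g in names(groups_res)) {
    res <- groups_res[[g]]
    utils::write.table(do.call(rbind, res$fits),
                       file.path(out_dir, paste0(g, "_window_alpha.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    seg_all <- do.call(rbind, lapply(seq_along(res$segments), function(b) {
      s <- res$segments[[b]]
      if (is.null(s)) return(NULL)
      cbind(bead = b, s)
    }))
    utils::write.table(seg_all, file.path(out_dir, paste0(g, "_segments.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$runs, file.path(out_dir, paste0(g, "_runs.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  sum_list <- lapply(groups_res, function(res) {
    s <- res$summary
    list(group = s$group, n_beads = s$n_beads, n_runs = s$n_runs,
         pct_directed = s$pct_directed[c("mean", "sem", "n")],
         pct_diffusive = s$pct_diffusive[c("mean", "sem", "n")],
         run_length_nm = s$run_length[c("mean", "sem", "n")],
         velocity_nm_s = s$velocity[c("mean", "sem", "n")],
         dissociation_rate_s = s$dissociation)
  })
  report <- c(stamp,
              list(cutoff = groups_res[[1]]$cutoff,
                   mixture = if (!is.null(mixture)) {
                     mixture[c("weights", "means", "sds", "cutoff", "n")]
                   },
                   groups = sum_list,
                   comparisons = comparisons))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(list(groups = groups_res, mixture = mixture,
                 comparisons = comparisons, report = report))
}
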