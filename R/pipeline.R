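# Orchestration: one config object carrying every tunable, and run_* stages
# that chain the modules over whole cohorts with seeded reproducibility.

#' Pipeline configuration
#'
#' Collects every tunable of the processing chain with the conventional
#' defaults: 5-s epochs, MVPA strictly above 100 mg, LPA 50--100 mg
#' inclusive, 10-min bouts at 80% occupancy, 16-h valid days, at least 6
#' valid days per subject with the first 6 retained, reliability target
#' > 0.70 over curves of K = 6 days, 60-min/15-min non-wear windows at
#' 13 mg SD / 50 mg range on 2 of 3 axes, 8 g clipping, and calibration
#' still-window settings.
#'
#' @param epoch_len Epoch length, s.
#' @param mvpa_threshold MVPA threshold, mg (exclusive).
#' @param lpa_low Lower LPA boundary, mg (inclusive).
#' @param bout_min Minimum bout length, min.
#' @param bout_fraction Minimum MVPA fraction in a bout.
#' @param min_wear_hours Valid-day wear criterion, h.
#' @param min_valid_days Analytical-sample criterion, days.
#' @param k_keep Valid days retained per subject.
#' @param reliability_target Target reliability (strictly exceeded when
#'   `strict_target`).
#' @param strict_target Strict inequality at the target.
#' @param K Maximum days on the reliability curve.
#' @param clip_g Dynamic-range clip, g.
#' @param negatives ENMO negative handling, `"truncate"` or `"absolute"`.
#' @param nonwear_window_min,nonwear_step_min,nonwear_sd_mg,nonwear_range_mg,nonwear_axes_required
#'   Non-wear detection settings (see [detect_nonwear()]).
#' @param calib_still_sd_mg,calib_window_s,calib_max_iter,calib_tol_mg
#'   Autocalibration settings (see [autocalibrate()]).
#' @param n_subjects,n_days Cohort size for the simulation stage.
#' @param seed Root RNG seed for the simulation stage.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(epoch_len = 5, mvpa_threshold = 100, lpa_low = 50,
                            bout_min = 10, bout_fraction = 0.8,
                            min_wear_hours = 16, min_valid_days = 6,
                            k_keep = 6, reliability_target = 0.70,
                            strict_target = TRUE, K = 6, clip_g = 8,
                            negatives = "truncate",
                            nonwear_window_min = 60, nonwear_step_min = 15,
                            nonwear_sd_mg = 13, nonwear_range_mg = 50,
                            nonwear_axes_required = 2,
                            calib_still_sd_mg = 13, calib_window_s = 10,
                            calib_max_iter = 50, calib_tol_mg = 0.1,
                            n_subjects = 100, n_days = 7, seed = 1L) {
  chk <- function(cond, field, msg) if (!cond) stop_config(field, msg)
  chk(is_number(epoch_len) && epoch_len > 0 && 86400 %% epoch_len == 0,
      "epoch_len", "must be > 0 and divide 86400 s")
  chk(is_number(lpa_low) && is_number(mvpa_threshold) &&
        0 < lpa_low && lpa_low < mvpa_threshold,
      "lpa_low", "need 0 < lpa_low < mvpa_threshold")
  chk(is_number(bout_min) && bout_min > 0, "bout_min", "must be > 0")
  chk(is_number(bout_fraction) && bout_fraction > 0 && bout_fraction <= 1,
      "bout_fraction", "must be in (0, 1]")
  chk(is_number(min_wear_hours) && min_wear_hours > 0 && min_wear_hours <= 24,
      "min_wear_hours", "must be in (0, 24]")
  chk(is_count(min_valid_days, 2), "min_valid_days", "must be an integer >= 2")
  chk(is_count(k_keep, 2) && k_keep <= min_valid_days,
      "k_keep", "must be an integer in 2..min_valid_days")
  chk(is_number(reliability_target) && reliability_target > 0 &&
        reliability_target < 1, "reliability_target", "must be in (0, 1)")
  chk(is_count(K, 1), "K", "must be a positive integer")
  chk(is_number(clip_g) && clip_g > 0, "clip_g", "must be > 0")
  chk(negatives %in% c("truncate", "absolute"),
      "negatives", "must be 'truncate' or 'absolute'")
  chk(is_count(nonwear_axes_required, 1) && nonwear_axes_required <= 3,
      "nonwear_axes_required", "must be 1, 2 or 3")
  for (f in c("nonwear_window_min", "nonwear_step_min", "nonwear_sd_mg",
              "nonwear_range_mg", "calib_still_sd_mg", "calib_window_s",
              "calib_tol_mg"))
    chk(is_number(get(f)) && get(f) > 0, f, "must be > 0")
  chk(is_count(calib_max_iter, 1), "calib_max_iter", "must be >= 1")
  chk(is_count(n_subjects, 2), "n_subjects", "must be an integer >= 2")
  chk(is_count(n_days, 2), "n_days", "must be an integer >= 2")
  chk(is_count(seed, 0), "seed", "must be a non-negative integer")
  structure(mget(names(formals(pipeline_config))), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds a flat mapping whose keys mirror the arguments of
#' [pipeline_config()]; unknown keys are rejected rather than ignored.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown))
    stop_config(unknown[1], "unknown configuration key")
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (f in names(x)) cat(sprintf("  %-24s %s\n", f, format(x[[f]])))
  invisible(x)
}

epoch_cfg_from <- function(cfg) {
  epoch_sim_config(n_subjects = cfg$n_subjects, n_days = cfg$n_days,
                   epoch_len = cfg$epoch_len, seed = cfg$seed)
}

#' Simulate a cohort (pipeline stage)
#'
#' Epoch fidelity (the default) generates per-subject [epoch_series()];
#' construct fidelity generates three balanced construct matrices directly
#' from the one-way variance-components model; raw fidelity generates full
#' tri-axial recordings (intended for small cohorts only).  A ground-truth
#' manifest accompanies the data; with `out_dir` the data and manifest are
#' written as CSV/JSON.
#'
#' @param cfg A [pipeline_config()].
#' @param fidelity `"epoch"`, `"construct"` or `"raw"`.
#' @param out_dir Optional output directory.
#' @param construct_params For construct fidelity: named list per construct
#'   of `mu`, `sigma_between`, `sigma_within`, `weekend_shift`.
#' @return A list with `fidelity`, `data` (list of series/recordings or of
#'   construct matrices) and `manifest`.
#' @export
run_simulate <- function(cfg = pipeline_config(), fidelity = c("epoch", "construct", "raw"),
                         out_dir = NULL,
                         construct_params = list(
                           overall = list(mu = 35, sigma_between = 8, sigma_within = 9, weekend_shift = -3),
                           lpa = list(mu = 150, sigma_between = 30, sigma_within = 45, weekend_shift = -10),
                           mvpa = list(mu = 20, sigma_between = 12, sigma_within = 20, weekend_shift = -4))) {
  fidelity <- match.arg(fidelity)
  stopifnot(inherits(cfg, "pipeline_config"))
  if (fidelity == "epoch") {
    ecfg <- epoch_cfg_from(cfg)
    data <- lapply(seq_len(cfg$n_subjects),
                   function(i) simulate_epoch_series(ecfg, i))
    manifest <- list(
      fidelity = "epoch", seed = cfg$seed,
      n_subjects = cfg$n_subjects, n_days = cfg$n_days,
      epoch_len = cfg$epoch_len,
      state_enmo_levels = as.list(ecfg$state_enmo_levels),
      weekend_activity_factor = ecfg$weekend_activity_factor,
      subject_multipliers = vapply(data, function(s) s$truth$mult_subject,
                                   numeric(1)))
  } else if (fidelity == "construct") {
    seeds <- child_seeds(cfg$seed, length(construct_params))
    data <- list(); truth <- list()
    for (i in seq_along(construct_params)) {
      cn <- names(construct_params)[i]
      p <- construct_params[[cn]]
      ccfg <- cohort_sim_config(
        n_subjects = cfg$n_subjects, n_days = cfg$n_days,
        mu_construct = p$mu, sigma_between = p$sigma_between,
        sigma_within = p$sigma_within,
        weekend_shift = p$weekend_shift %||% 0, seed = seeds[i])
      data[[cn]] <- simulate_construct_matrix(ccfg, construct = cn)
      truth[[cn]] <- list(icc_true = data[[cn]]$truth$icc_true,
                          icc_with_dow = data[[cn]]$truth$icc_with_dow,
                          min_days_true = min_days(data[[cn]]$truth$icc_true,
                                                   cfg$reliability_target,
                                                   cfg$strict_target))
    }
    manifest <- list(fidelity = "construct", seed = cfg$seed,
                     n_subjects = cfg$n_subjects, n_days = cfg$n_days,
                     params = construct_params, truth = truth)
  } else {
    seeds <- child_seeds(cfg$seed, cfg$n_subjects)
    data <- lapply(seq_len(cfg$n_subjects), function(i) {
      scfg <- signal_sim_config(days = cfg$n_days, epoch_len = cfg$epoch_len,
                                seed = seeds[i])
      simulate_raw_recording(scfg, subject_id = sprintf("S%04d", i))
    })
    manifest <- list(fidelity = "raw", seed = cfg$seed,
                     n_subjects = cfg$n_subjects, n_days = cfg$n_days)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (fidelity == "construct") {
      for (cn in names(data))
        write_construct_matrix_csv(data[[cn]],
                                   file.path(out_dir, paste0(cn, ".csv")))
    } else if (fidelity == "raw") {
      for (r in data)
        write_raw_csv(r, file.path(out_dir, paste0(r$subject_id, ".csv")))
    } else {
      for (s in data)
        write_epoch_csv(s, file.path(out_dir, paste0(s$subject_id, ".csv")))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(fidelity = fidelity, data = data, manifest = manifest)
}

#' Process recordings into day summaries (pipeline stage)
#'
#' Per subject: autocalibration, abnormal-value screening, ENMO epoching,
#' non-wear detection, intensity classification, bout detection and
#' calendar-day summaries.  Inputs may be a directory of CSV files (raw or
#' epoch layout, auto-detected from the header), or a list of
#' [raw_recording()] / [epoch_series()] objects; epoch-level inputs skip the
#' signal stage.  Subjects that fail (e.g. no complete calendar day) are
#' excluded with a logged reason, not fatal.
#'
#' @param x Input directory or list of recordings/series.
#' @param cfg A [pipeline_config()].
#' @return A list: `days` (stacked day-summary data.frame), `exclusions`
#'   (data.frame of subject_id, reason), `calibration` (per-subject models,
#'   raw inputs only).
#' @export
run_process <- function(x, cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.character(x)) {
    if (!dir.exists(x)) stop_input(sprintf("input directory not found: %s", x))
    files <- list.files(x, pattern = "\\.csv$", full.names = TRUE)
    files <- files[!grepl("manifest", files)]
    if (!length(files)) stop_input(sprintf("no CSV recordings in %s", x))
    x <- lapply(files, function(f) {
      hdr <- strsplit(readLines(f, n = 1), ",")[[1]]
      if ("x_g" %in% hdr) read_raw_csv(f) else read_epoch_csv(f)
    })
  }
  day_rows <- list(); excl <- list(); calibs <- list()
  for (obj in x) {
    sid <- obj$subject_id
    res <- tryCatch({
      if (inherits(obj, "raw_recording")) {
        calib <- tryCatch(
          autocalibrate(obj, still_sd_threshold = cfg$calib_still_sd_mg,
                        window_len = cfg$calib_window_s,
                        max_iter = cfg$calib_max_iter, tol = cfg$calib_tol_mg),
          error = function(e) identity_calibration())
        calibs[[sid]] <- calib
        rec <- screen_abnormal(obj, clip = cfg$clip_g)
        ep <- compute_enmo(rec, calib, epoch_len = cfg$epoch_len,
                           negatives = cfg$negatives)
        nw <- detect_nonwear(rec, epoch_len = cfg$epoch_len,
                             window_min = cfg$nonwear_window_min,
                             step_min = cfg$nonwear_step_min,
                             sd_threshold = cfg$nonwear_sd_mg,
                             range_threshold = cfg$nonwear_range_mg,
                             axes_required = cfg$nonwear_axes_required)
        ep <- flag_nonwear(ep, nw)
      } else if (inherits(obj, "epoch_series")) {
        ep <- obj
      } else stop_input("run_process: unsupported input object")
      labels <- classify_epochs(ep, lpa_low = cfg$lpa_low,
                                mvpa_threshold = cfg$mvpa_threshold)
      bouts <- detect_mvpa_bouts(labels, epoch_len = ep$epoch_len,
                                 min_bout = cfg$bout_min,
                                 min_fraction = cfg$bout_fraction)
      summarize_day(ep, labels, bouts, min_wear_hours = cfg$min_wear_hours)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1]] <- data.frame(subject_id = sid,
                                             reason = conditionMessage(res),
                                             stringsAsFactors = FALSE)
    } else {
      day_rows[[length(day_rows) + 1]] <- res
    }
  }
  if (!length(day_rows))
    stop_input("run_process: no subject produced a complete calendar day")
  list(days = do.call(rbind, day_rows),
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame(subject_id = character(0), reason = character(0)),
       calibration = calibs)
}

#' Reliability analysis (pipeline stage)
#'
#' @param days Day-summary data.frame (or path to its CSV).
#' @param cfg A [pipeline_config()].
#' @return A list: `report` (a [reliability_report()]), `n_included`,
#'   `n_excluded`.
#' @export
run_reliability <- function(days, cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.character(days)) days <- read_day_summary_csv(days)
  sel <- select_analytical_sample(days, min_valid_days = cfg$min_valid_days,
                                  k_keep = cfg$k_keep)
  rep <- reliability_report(sel$matrices, K = cfg$K,
                            target = cfg$reliability_target,
                            strict = cfg$strict_target)
  list(report = rep, n_included = sel$n_included, n_excluded = sel$n_excluded)
}

#' Day-of-week descriptives (pipeline stage)
#'
#' @param days Day-summary data.frame (or path to its CSV).
#' @param cfg A [pipeline_config()].
#' @param group Group label.
#' @return A list: `summaries` (per construct [dow_medians()] results),
#'   `table` (flat medians table), `tests` (weekday/weekend medians and
#'   p-values per construct).
#' @export
run_descriptives <- function(days, cfg = pipeline_config(), group = "all") {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.character(days)) days <- read_day_summary_csv(days)
  summaries <- lapply(c(overall = "overall", lpa = "lpa", mvpa = "mvpa"),
                      function(cn) dow_medians(days, cn, group = group))
  tests <- do.call(rbind, lapply(summaries, function(s) data.frame(
    group = s$group, construct = s$construct,
    weekday_median = s$weekday_median, weekend_median = s$weekend_median,
    p_dow = s$p_dow, p_wkend = s$p_wkend, stringsAsFactors = FALSE)))
  rownames(tests) <- NULL
  list(summaries = summaries, table = dow_table(summaries), tests = tests)
}

#' Run the full pipeline: simulate, process, reliability, descriptives
#'
#' Deterministic given (config, seed): re-running with the same settings
#' writes byte-identical reports.  Outputs in `out_dir`:
#' `day_summaries.csv`, per-construct matrix CSVs, `reliability_curves.csv`,
#' `reliability.json`, `descriptives_medians.csv`, `descriptives_tests.csv`,
#' `manifest.json`.
#'
#' @param out_dir Output directory (created if needed).
#' @param cfg A [pipeline_config()].
#' @param fidelity Simulation fidelity, see [run_simulate()].
#' @return Invisibly, a list with the stage outputs.
#' @export
run_all <- function(out_dir, cfg = pipeline_config(),
                    fidelity = c("epoch", "raw")) {
  fidelity <- match.arg(fidelity)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- run_simulate(cfg, fidelity = fidelity)
  proc <- run_process(sim$data, cfg)
  rel <- run_reliability(proc$days, cfg)
  desc <- run_descriptives(proc$days, cfg)

  write_day_summary_csv(proc$days, file.path(out_dir, "day_summaries.csv"))
  sel <- select_analytical_sample(proc$days, cfg$min_valid_days, cfg$k_keep)
  for (cn in names(sel$matrices))
    write_construct_matrix_csv(sel$matrices[[cn]],
                               file.path(out_dir, paste0("construct_", cn, ".csv")))
  curves <- rel$report$curves
  curves$reliability <- round(curves$reliability, 6)
  curves$reliability_2dp <- round(curves$reliability_2dp, 2)
  write.csv(curves, file.path(out_dir, "reliability_curves.csv"),
            row.names = FALSE, quote = FALSE)
  rel_json <- lapply(rel$report$results, function(r) {
    r$r_by_days <- as.list(round(r$r_by_days, 6))
    r$icc1 <- round(r$icc1, 6); r$msb <- round(r$msb, 6); r$msw <- round(r$msw, 6)
    r
  })
  jsonlite::write_json(
    list(target = rel$report$target, K = rel$report$K,
         n_included = rel$n_included, n_excluded = rel$n_excluded,
         results = rel_json),
    file.path(out_dir, "reliability.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  med <- desc$table; med$median <- round(med$median, 4)
  write.csv(med, file.path(out_dir, "descriptives_medians.csv"),
            row.names = FALSE, quote = FALSE)
  tst <- desc$tests
  for (cc in c("weekday_median", "weekend_median", "p_dow", "p_wkend"))
    tst[[cc]] <- signif(tst[[cc]], 6)
  write.csv(tst, file.path(out_dir, "descriptives_tests.csv"),
            row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sim$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sim = sim, process = proc, reliability = rel,
                 descriptives = desc, out_dir = out_dir))
}
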