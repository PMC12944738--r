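#' Run configuration for the analysis pipeline
#'
#' Aggregates every tunable of the detection-to-metrics pipeline with the
#' standard defaults: 50 fps, full bar length 2.20 m, SG(9, 3) smoothing,
#' 6 Hz zero-phase Butterworth, 0.5 m/s concentric threshold, 5-frame
#' minimum phase, 5-frame maximum interpolated gap. Serialises losslessly
#' to/from YAML ([load_run_config()] / [save_run_config()]).
#'
#' @param fps Frame rate, Hz.
#' @param bar_length Real bar length, metres.
#' @param mass Total load mass, kg.
#' @param g Gravitational acceleration, m/s^2.
#' @param sg_window,sg_order,butter_cutoff,butter_order See
#'   [filter_config()].
#' @param v_threshold,min_frames See [detect_concentric_phases()].
#' @param max_gap See [build_end_track()].
#' @param dialect Detection input dialect, see [read_obb_detections()].
#' @param image_width,image_height Image size, pixels.
#' @return An object of class `lp_run_config`.
#' @export
run_config <- function(fps = 50, bar_length = 2.20, mass = 25, g = 9.81,
                       sg_window = 9L, sg_order = 3L, butter_cutoff = 6,
                       butter_order = 4L, v_threshold = 0.5,
                       min_frames = 5L, max_gap = 5L,
                       dialect = c("yolo_obb_txt", "long_csv"),
                       image_width = 1920, image_height = 1080) {
  dialect <- match.arg(dialect)
  cfg <- list(fps = fps, bar_length = bar_length, mass = mass, g = g,
              sg_window = as.integer(sg_window), sg_order = as.integer(sg_order),
              butter_cutoff = butter_cutoff, butter_order = as.integer(butter_order),
              v_threshold = v_threshold, min_frames = as.integer(min_frames),
              max_gap = as.integer(max_gap), dialect = dialect,
              image_width = image_width, image_height = image_height)
  # validate the filter section eagerly so misconfiguration fails fast
  filter_config(fs = fps, sg_window = cfg$sg_window, sg_order = cfg$sg_order,
                butter_cutoff = butter_cutoff, butter_order = cfg$butter_order)
  if (mass <= 0 || bar_length <= 0) {
    abort("`mass` and `bar_length` must be positive.", class = "lp_config_error")
  }
  structure(cfg, class = "lp_run_config")
}

as_filter_config <- function(cfg) {
  filter_config(fs = cfg$fps, sg_window = cfg$sg_window,
                sg_order = cfg$sg_order, butter_cutoff = cfg$butter_cutoff,
                butter_order = cfg$butter_order)
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
load_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param cfg An `lp_run_config`.
#' @export
save_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "lp_run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Analyse a directory or CSV of detections into rep metrics
#'
#' End-to-end pipeline: read detections, build and calibrate the end-point
#' track, compute kinematics per contiguous block, segment concentric
#' phases and extract per-rep metrics. Writes a metrics CSV and a JSON
#' mirror embedding the effective configuration.
#'
#' @param detections_path Label directory (`yolo_obb_txt`) or CSV path
#'   (`long_csv`).
#' @param config An [run_config()].
#' @param out_csv,out_json Optional output paths.
#' @param trial_id Identifier written into the outputs.
#' @return The rep-metrics tibble (invisibly if `out_csv` is given), with
#'   a `trial_id` and `block` column.
#' @export
run_analyze <- function(detections_path, config = run_config(),
                        out_csv = NULL, out_json = NULL,
                        trial_id = "trial") {
  det <- read_obb_detections(detections_path, dialect = config$dialect,
                             image_width = config$image_width,
                             image_height = config$image_height)
  track <- build_end_track(det, fps = config$fps,
                           image_height = config$image_height,
                           max_gap = config$max_gap)
  traj <- calibrate(track, bar_length = config$bar_length)
  fcfg <- as_filter_config(config)
  traj_attrs <- attributes(traj)

  metrics <- purrr::map(sort(unique(traj$block)), function(b) {
    sub <- traj[traj$block == b, , drop = FALSE]
    for (at in c("scale_s", "L_pixel_mean", "L_real", "fps", "pivot_px")) {
      attr(sub, at) <- traj_attrs[[at]]
    }
    class(sub) <- c("lp_trajectory", class(tibble::tibble()))
    if (nrow(sub) <= 3 * config$butter_order) return(NULL)
    kin <- compute_kinematics(sub, mass = config$mass, cfg = fcfg,
                              g = config$g)
    phases <- detect_concentric_phases(kin$v, fps = config$fps,
                                       v_threshold = config$v_threshold,
                                       min_frames = config$min_frames)
    m <- rep_metrics(kin, phases, fcfg)
    if (nrow(m)) m$block <- b
    m
  }) |> purrr::compact() |> purrr::list_rbind()

  if (!nrow(metrics)) {
    abort("No concentric phase detected in the input.",
          class = "lp_no_phase")
  }
  metrics <- dplyr::mutate(metrics, trial_id = trial_id,
                           rep_index = dplyr::row_number()) |>
    dplyr::select("trial_id", "block", "rep_index", "ts", "te",
                  "duration_s", "peak_velocity", "mean_velocity",
                  "peak_power", "mean_power")
  if (!is.null(out_csv)) readr::write_csv(metrics, out_csv)
  if (!is.null(out_json)) {
    jsonlite::write_json(
      list(trial_id = trial_id, config = unclass(config),
           scale_m_per_px = attr(traj, "scale_s"),
           note = "force/power are model-based estimates (planar point-mass rotation)",
           metrics = metrics),
      out_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (is.null(out_csv)) metrics else invisible(metrics)
}

#' Compare two methods' per-trial metrics
#'
#' Reads a paired CSV (columns `trial_id`, optional grouping columns such
#' as `load` and `indicator`, and `method_a`, `method_b`) and produces the
#' full agreement battery, overall or per group.
#'
#' @param paired_path CSV of paired measurements.
#' @param group_by Character vector of grouping column names (optional).
#' @param out_json Optional JSON report path.
#' @param lambda,conf_level Passed to [agreement_report()].
#' @return Tibble of one-row agreement summaries (one per group).
#' @export
run_compare <- function(paired_path, group_by = NULL, out_json = NULL,
                        lambda = 1, conf_level = 0.95) {
  pairs <- readr::read_csv(paired_path, show_col_types = FALSE)
  need <- c("method_a", "method_b")
  missing_cols <- setdiff(c(need, group_by), names(pairs))
  if (length(missing_cols)) {
    abort(paste0("Paired CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "lp_parse_error")
  }
  if (anyNA(pairs$method_a) || anyNA(pairs$method_b)) {
    bad <- pairs$trial_id[is.na(pairs$method_a) | is.na(pairs$method_b)]
    abort(paste0("Unpaired trial(s): ", paste(unique(bad), collapse = ", ")),
          class = "lp_parse_error")
  }
  out <- if (length(group_by)) {
    agreement_by(pairs, .data$method_a, .data$method_b,
                 !!!rlang::syms(group_by), lambda = lambda,
                 conf_level = conf_level)
  } else {
    glance(agreement_report(pairs, .data$method_a, .data$method_b,
                            lambda = lambda, conf_level = conf_level))
  }
  if (!is.null(out_json)) {
    jsonlite::write_json(list(lambda = lambda, conf_level = conf_level,
                              groups = out),
                         out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  out
}

#' Write a synthetic trial to disk as regenerable fixtures
#'
#' Renders [simulate_press()] output as YOLO-OBB label files, a
#' ground-truth CSV and a JSON manifest carrying the full configuration
#' and seed, so the fixture set can be regenerated bit-exactly.
#'
#' @param cfg An [press_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the simulation object.
#' @export
run_simulate <- function(cfg, out_dir) {
  sim <- simulate_press(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_obb_labels(sim$detections, file.path(out_dir, "labels"),
                   image_width = cfg$image_width,
                   image_height = cfg$image_height)
  readr::write_csv(sim$truth, file.path(out_dir, "truth.csv"))
  readr::write_csv(sim$rep_windows, file.path(out_dir, "rep_windows.csv"))
  jsonlite::write_json(
    list(config = unclass(cfg), true_scale = sim$true_scale),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(sim)
}
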