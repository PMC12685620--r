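#' Session configuration
#'
#' Bundles everything needed for a full simulated tracking session: timing,
#' gantry arc, phantom configuration, scenarios and the tracking mode.
#'
#' @param duration_s Session length, s (default 70; 351 frames at 0.2 s).
#' @param frame_interval_s Frame interval, s (default 0.2).
#' @param training_s Length of the model-training window, s (default 20).
#' @param evaluation_s Length of the evaluation window, s (default 50);
#'   `training_s + evaluation_s` must equal `duration_s`.
#' @param arc A [session_arc()].
#' @param scenarios Subset of `c("S_no", "S_con", "S_var")`.
#' @param seed Session seed; overrides the respiratory config's seed so the
#'   whole session is a pure function of `(config, seed)`.
#' @param resp A [respiratory_config()].
#' @param anatomy An [anatomy_config()].
#' @param geom_args Named list of extra [view_geometry()] arguments.
#' @param tracking `"image"` (render frames, preprocess, NCC-match,
#'   triangulate) or `"truth"` (noise-free apex input; bypasses imaging).
#' @param frame_noise_sd Gaussian pixel-noise SD for rendered frames.
#' @param template_step_deg Template-bank grid spacing, degrees.
#' @param velocity_smooth Moving-average window for [estimate_velocity()]
#'   (samples; 1 = none).
#' @param seed_from_truth Seed first-frame matching from the projected true
#'   apex (default) instead of a wide-window search.
#' @param dome A [dome_params()] list.
#' @param out_dir Optional directory for CSV/JSON artifacts.
#' @return An object of class `session_config`.
#' @export
session_config <- function(duration_s = 70, frame_interval_s = 0.2,
                           training_s = 20, evaluation_s = 50,
                           arc = session_arc(),
                           scenarios = c("S_no", "S_con", "S_var"),
                           seed = 1L,
                           resp = respiratory_config(),
                           anatomy = anatomy_config(),
                           geom_args = list(),
                           tracking = c("image", "truth"),
                           frame_noise_sd = 0,
                           template_step_deg = 0.3,
                           velocity_smooth = 1L,
                           seed_from_truth = TRUE,
                           dome = dome_params(),
                           out_dir = NULL) {
  tracking <- match.arg(tracking)
  if (abs(training_s + evaluation_s - duration_s) > 1e-9)
    stop("BadConfig: training_s + evaluation_s must equal duration_s")
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  cfg <- list(duration_s = duration_s, frame_interval_s = frame_interval_s,
              training_s = training_s, evaluation_s = evaluation_s,
              arc = arc, scenarios = scenarios, seed = as.integer(seed),
              resp = resp, anatomy = anatomy, geom_args = geom_args,
              tracking = tracking, frame_noise_sd = frame_noise_sd,
              template_step_deg = template_step_deg,
              velocity_smooth = as.integer(velocity_smooth),
              seed_from_truth = seed_from_truth, dome = dome,
              out_dir = out_dir)
  class(cfg) <- "session_config"
  cfg
}

#' Pseudo-tumor trajectory from fiducial markers
#'
#' Ground-truth proxy for the tumor: each implanted marker is projected into
#' both views (or taken from supplied 2D detections), back-projected and
#' triangulated with the skew-ray midpoint rule; the per-frame centroid of
#' the reconstructed 3D marker positions is the pseudo-tumor.
#'
#' @param truth A `session_truth` (markers taken from the phantom ground
#'   truth and passed through the full 3D -> 2D -> 3D chain).
#' @param geom_fn Function `(frame_index, imager)` returning the frame's
#'   `view_geometry`.
#' @param detections Optional override: list with per-frame elements, each a
#'   list of per-marker lists of two `pixel_coord`s (views 1 and 2).
#' @return n x 3 matrix (columns x = LR, y = AP, z = SI), mm.
#' @export
pseudo_tumor_centroid <- function(truth, geom_fn, detections = NULL) {
  n <- nrow(truth)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_len(n)) {
    g1 <- geom_fn(i, 1L); g2 <- geom_fn(i, 2L)
    mk <- truth_markers(truth, i)
    pts <- lapply(seq_along(mk), function(k) {
      if (is.null(detections)) {
        q1 <- project_point(g1, mk[[k]])
        q2 <- project_point(g2, mk[[k]])
      } else {
        q1 <- detections[[i]][[k]][[1]]
        q2 <- detections[[i]][[k]][[2]]
      }
      unclass(triangulate(backproject_ray(g1, q1),
                          backproject_ray(g2, q2))$point)
    })
    out[i, ] <- colMeans(do.call(rbind, pts))
  }
  out
}

#' Run a full simulated tracking session
#'
#' Orchestrates the complete study pipeline on the synthetic phantom:
#' simulate the surrogate signal and anatomy; track the diaphragm apex
#' (rendered frames + NCC matching, or a noise-free truth pass-through);
#' reconstruct the pseudo-tumor from the fiducial markers; detect the
#' training-window breathing extrema; per scenario, build the offset model,
#' estimate training tumor positions, fit the 4D correlation model and
#' predict the evaluation window from the surrogate alone; summarize the
#' prediction errors. Fully reproducible from `(config, seed)`.
#'
#' @param cfg A [session_config()].
#' @return A list of class `session_result`: `signal`, `truth`, `apex`
#'   (per-frame estimated apex, with 2D detections when image tracking was
#'   used), `pseudo` (pseudo-tumor matrix), `extrema`, and per scenario
#'   `models` (`offset`, `fourdm`), `predictions`, `errors`
#'   ([error_series()]) and `summaries` ([error_summary()]).
#' @export
run_session <- function(cfg) {
  stopifnot(inherits(cfg, "session_config"))
  resp <- cfg$resp
  resp$seed <- cfg$seed
  sig <- simulate_respiration(resp, cfg$duration_s, cfg$frame_interval_s)
  if (cfg$velocity_smooth > 1)
    sig$p_dot <- estimate_velocity(sig$p_mm, cfg$frame_interval_s,
                                   cfg$velocity_smooth)
  truth <- simulate_anatomy(sig, cfg$anatomy, arc = cfg$arc)
  n <- nrow(truth)
  geom_fn <- function(i, k)
    do.call(view_geometry, c(list(gantry_angle = truth$angle1_deg[i],
                                  imager = as.integer(k)), cfg$geom_args))

  ## --- diaphragm apex ---------------------------------------------------
  if (cfg$tracking == "truth") {
    apex <- data.frame(time_s = truth$time_s,
                       apex_x_mm = truth$apex_x_mm,
                       apex_y_mm = truth$apex_y_mm,
                       apex_z_mm = truth$apex_z_mm,
                       residual_mm = 0)
  } else {
    banks <- lapply(1:2, function(k)
      render_templates(cfg$anatomy, arc = cfg$arc,
                       angle_step_deg = cfg$template_step_deg,
                       imager = k, geom_args = cfg$geom_args,
                       dome = cfg$dome))
    provider <- function(i, k) {
      g <- geom_fn(i, k)
      fr <- render_frame(g, truth_apex(truth, i), truth_markers(truth, i),
                         time_s = truth$time_s[i], polarity = "raw",
                         noise_sd = cfg$frame_noise_sd,
                         seed = cfg$seed + 8191L * i + as.integer(k),
                         dome = cfg$dome)
      preprocess(fr)
    }
    seeds <- if (isTRUE(cfg$seed_from_truth))
      lapply(1:2, function(k) project_point(geom_fn(1, k), truth_apex(truth, 1)))
    else list(NULL, NULL)
    apex <- track_session(provider, n, geom_fn, banks, seeds = seeds,
                          times = truth$time_s)
  }
  apex_mat <- cbind(apex$apex_x_mm, apex$apex_y_mm, apex$apex_z_mm)

  ## --- pseudo-tumor ground truth ---------------------------------------
  pseudo <- pseudo_tumor_centroid(truth, geom_fn)

  ## --- models and prediction per scenario -------------------------------
  extrema <- detect_extrema(sig, window = c(0, cfg$training_s))
  train_win <- c(0, cfg$training_s)
  eval_win <- c(cfg$training_s, cfg$duration_s)
  models <- predictions <- errors <- summaries <- list()
  for (sc in cfg$scenarios) {
    offset <- build_offset_model(sc, apex_mat, pseudo, sig, extrema)
    tumor_for_fit <- estimate_tumor(offset, apex_mat, sig$p_mm,
                                    tumor = pseudo)
    fourdm <- fit_4dm(sig, tumor_for_fit, window = train_win)
    pred <- predict_4dm(fourdm, sig$p_mm, sig$p_dot)
    err <- error_series(pred, pseudo, sig$time_s, window = eval_win)
    models[[sc]] <- list(offset = offset, fourdm = fourdm)
    predictions[[sc]] <- data.frame(time_s = sig$time_s,
                                    pred_x_mm = pred[, 1],
                                    pred_y_mm = pred[, 2],
                                    pred_z_mm = pred[, 3])
    errors[[sc]] <- err
    summaries[[sc]] <- error_summary(err, pseudo_si = pseudo[, "z"])
  }

  res <- list(config = cfg, signal = sig, truth = truth, apex = apex,
              pseudo = pseudo, extrema = extrema, models = models,
              predictions = predictions, errors = errors,
              summaries = summaries)
  class(res) <- "session_result"
  if (!is.null(cfg$out_dir)) write_session_artifacts(res, cfg$out_dir)
  res
}

#' Write session artifacts to a directory
#'
#' CSVs for the signal, ground truth, apex track, per-scenario predictions
#' and the error summary table, plus JSON model files.
#'
#' @param res A `session_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_artifacts <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_plain(as.data.frame(res$signal), file.path(dir, "signal.csv"))
  write_csv_plain(as.data.frame(res$truth), file.path(dir, "truth.csv"))
  write_csv_plain(as.data.frame(res$apex), file.path(dir, "apex.csv"))
  pseudo <- data.frame(time_s = res$signal$time_s,
                       pseudo_x_mm = res$pseudo[, 1],
                       pseudo_y_mm = res$pseudo[, 2],
                       pseudo_z_mm = res$pseudo[, 3])
  write_csv_plain(pseudo, file.path(dir, "pseudo_tumor.csv"))
  for (sc in names(res$predictions)) {
    write_csv_plain(res$predictions[[sc]],
                    file.path(dir, sprintf("predictions_%s.csv", sc)))
    write_csv_plain(as.data.frame(res$errors[[sc]]),
                    file.path(dir, sprintf("errors_%s.csv", sc)))
    write_models_json(res$models[[sc]]$offset, res$models[[sc]]$fourdm,
                      file.path(dir, sprintf("models_%s.json", sc)))
  }
  write_csv_plain(summary_table(res), file.path(dir, "summary.csv"))
  invisible(dir)
}

#' Tidy summary table of a session result
#'
#' @param res A `session_result`.
#' @return Data frame: one row per scenario x direction with mean, SD, E90,
#'   E95, plus the session SI amplitude `A` and reduction ratio `R`.
#' @export
summary_table <- function(res) {
  do.call(rbind, lapply(names(res$summaries), function(sc) {
    s <- res$summaries[[sc]]
    cbind(scenario = sc, s$by_direction, A_mm = s$A_mm, R = s$R)
  }))
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("Session: %d frames, %.1f s, scenarios: %s, tracking: %s\n",
              nrow(x$truth), x$config$duration_s,
              paste(names(x$summaries), collapse = ", "),
              x$config$tracking))
  print(summary_table(x), row.names = FALSE, digits = 4)
  invisible(x)
}
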