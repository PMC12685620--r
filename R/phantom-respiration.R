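#' Respiratory-signal configuration
#'
#' Parameters of the synthetic external surrogate: the averaged
#' anterior-posterior displacement of abdominal infrared markers, sampled
#' every 0.2 s. Positive values are posterior displacement; signal troughs
#' are end-expiration and peaks end-inspiration.
#'
#' The base breathing-depth waveform is `b(t) = sin^(2n)(pi t / T)` with `T`
#' the period and `n = lujan_exponent`. For `n > 1` the signal dwells near
#' its trough, reproducing the clinically typical long end-expiratory
#' plateau. On top of the scaled waveform sit a linear baseline drift, a
#' small cardiac-pulsation sinusoid, Gaussian sampling noise, and optional
#' irregularity events (temporary pauses, deep breaths, amplitude shifts).
#'
#' @param period_s Breathing period, s.
#' @param amplitude_mm Peak-to-trough breathing amplitude of the clean
#'   waveform, mm.
#' @param lujan_exponent Half the waveform exponent `2n`; positive integer.
#' @param drift_rate_mm_per_s Linear baseline drift, mm/s.
#' @param pulsation_amplitude_mm Amplitude of the cardiac pulsation term, mm.
#' @param pulsation_freq_hz Cardiac pulsation frequency, Hz.
#' @param noise_sd_mm SD of additive Gaussian sampling noise, mm.
#' @param irregularity_events List of events, each a list with fields
#'   `type` (one of `"pause"`, `"deep_breath"`, `"amplitude_shift"`),
#'   `start_s`, `duration_s` and (for the scaling events) `scale`.
#' @param seed Integer seed fixing all randomness of the signal.
#' @return An object of class `respiratory_config`.
#' @export
respiratory_config <- function(period_s = 4, amplitude_mm = 10,
                               lujan_exponent = 2,
                               drift_rate_mm_per_s = 0,
                               pulsation_amplitude_mm = 0,
                               pulsation_freq_hz = 1.2,
                               noise_sd_mm = 0,
                               irregularity_events = list(),
                               seed = 1L) {
  if (period_s <= 0) stop("BadConfig: period_s must be positive")
  if (amplitude_mm < 0) stop("BadConfig: amplitude_mm must be >= 0")
  if (lujan_exponent < 1 || lujan_exponent != round(lujan_exponent))
    stop("BadConfig: lujan_exponent must be a positive integer")
  cfg <- list(period_s = period_s, amplitude_mm = amplitude_mm,
              lujan_exponent = as.integer(lujan_exponent),
              drift_rate_mm_per_s = drift_rate_mm_per_s,
              pulsation_amplitude_mm = pulsation_amplitude_mm,
              pulsation_freq_hz = pulsation_freq_hz,
              noise_sd_mm = noise_sd_mm,
              irregularity_events = irregularity_events,
              seed = as.integer(seed))
  class(cfg) <- "respiratory_config"
  cfg
}

# Event-warped waveform time: pauses freeze the breathing clock, which then
# resumes without a jump.
warp_time <- function(t, events) {
  tau <- t
  for (ev in events) {
    if (!identical(ev$type, "pause")) next
    s <- ev$start_s; d <- ev$duration_s
    tau <- ifelse(t < s, tau, ifelse(t < s + d, tau - (t - s), tau - d))
  }
  tau
}

# Amplitude envelope: deep breaths and amplitude shifts scale the waveform
# inside a smoothly ramped window.
amplitude_envelope <- function(t, events) {
  env <- rep(1, length(t))
  for (ev in events) {
    if (identical(ev$type, "pause")) next
    ramp <- if (identical(ev$type, "deep_breath")) ev$duration_s / 4 else 0.5
    env <- env + (ev$scale - 1) * cos_window(t, ev$start_s, ev$duration_s, ramp)
  }
  env
}

#' Simulate an external respiratory surrogate signal
#'
#' @param cfg A [respiratory_config()].
#' @param duration_s Session length, s (default 70).
#' @param dt_s Sampling interval, s (default 0.2).
#' @return An object of class `respiratory_signal`: a data frame with columns
#'   `time_s`, `p_mm` (surrogate position), `p_dot` (velocity, mm/s, central
#'   differences) and `depth` (the clean, dimensionless breathing depth in
#'   `[0, 1]` nominally, that drives the anatomy).
#' @export
simulate_respiration <- function(cfg, duration_s = 70, dt_s = 0.2) {
  stopifnot(inherits(cfg, "respiratory_config"))
  if (duration_s <= 0 || dt_s <= 0)
    stop("BadConfig: duration_s and dt_s must be positive")
  t <- seq(0, duration_s, by = dt_s)
  tau <- warp_time(t, cfg$irregularity_events)
  b <- sin(pi * tau / cfg$period_s)^(2 * cfg$lujan_exponent)
  depth <- amplitude_envelope(t, cfg$irregularity_events) * b
  p <- cfg$drift_rate_mm_per_s * t + cfg$amplitude_mm * depth
  if (cfg$pulsation_amplitude_mm > 0)
    p <- p + cfg$pulsation_amplitude_mm * sin(2 * pi * cfg$pulsation_freq_hz * t)
  if (cfg$noise_sd_mm > 0)
    p <- p + with_seed(cfg$seed, stats::rnorm(length(t), 0, cfg$noise_sd_mm))
  sig <- data.frame(time_s = t, p_mm = p,
                    p_dot = estimate_velocity(p, dt_s), depth = depth)
  attr(sig, "dt_s") <- dt_s
  attr(sig, "config") <- cfg
  class(sig) <- c("respiratory_signal", "data.frame")
  sig
}

#' Anatomy configuration for the synthetic phantom
#'
#' Couples the diaphragm apex, the tumor, and the implanted fiducial markers
#' to the breathing depth. Two generation modes are provided:
#'
#' * `"hysteresis"` (default): the apex moves along SI proportionally to the
#'   breathing depth; the tumor follows the (lagged) depth through per-axis
#'   coupling coefficients, plus an SI asynchrony term that varies linearly
#'   with the surrogate `p` between its trough and peak — so a
#'   phase-dependent (variable) offset vector captures it exactly by
#'   construction, while a constant offset cannot.
#' * `"model_consistent"`: each tumor coordinate is an exact quadratic
#'   function of `(p, p_dot)` — the same functional class as the 4D
#'   correlation model — so a correct fit achieves zero prediction error on
#'   noiseless data.
#'
#' Default motion magnitudes follow typical thoracoabdominal values: ~15 mm
#' SI tumor excursion, a few mm LR/AP, and a 6.1 mm phase-dependent
#' apex-tumor asynchrony.
#'
#' @param apex_rest Diaphragm-apex rest (end-expiration) position,
#'   `room_point`.
#' @param apex_SI_excursion_mm Apex SI displacement per unit breathing depth,
#'   mm; negative = inferior at inspiration.
#' @param tumor_rest Tumor rest position, `room_point`.
#' @param coupling_mm Length-3 numeric (LR, AP, SI): tumor displacement per
#'   unit breathing depth, mm.
#' @param hysteresis_lag_s Tumor phase lag behind the diaphragm, s.
#' @param asynchrony_SI_amplitude_mm Magnitude of the phase-dependent SI
#'   apex-tumor offset between end-expiration and end-inspiration, mm.
#' @param n_markers Number of implanted fiducial markers (1-4).
#' @param marker_offsets_mm List of length-3 offsets (mm) of each marker from
#'   the tumor; defaults to a small fixed constellation.
#' @param mode `"hysteresis"` or `"model_consistent"`.
#' @param quad_coefs Optional 5 x 3 matrix (rows a, b, c, d, e; columns LR,
#'   AP, SI) used in `model_consistent` mode; a default is derived from
#'   `coupling_mm`.
#' @return An object of class `anatomy_config`.
#' @export
anatomy_config <- function(apex_rest = room_point(-40, 10, 0),
                           apex_SI_excursion_mm = -15,
                           tumor_rest = room_point(-30, 20, 40),
                           coupling_mm = c(-2, 4, -15),
                           hysteresis_lag_s = 0,
                           asynchrony_SI_amplitude_mm = 0,
                           n_markers = 3L,
                           marker_offsets_mm = NULL,
                           mode = c("hysteresis", "model_consistent"),
                           quad_coefs = NULL) {
  mode <- match.arg(mode)
  n_markers <- as.integer(n_markers)
  if (n_markers < 1L) stop("BadConfig: n_markers must be >= 1")
  if (is.null(marker_offsets_mm)) {
    bank <- list(c(8, 0, 2), c(-5, 6, -4), c(0, -7, 6), c(4, 4, -5))
    marker_offsets_mm <- bank[seq_len(n_markers)]
  }
  stopifnot(length(marker_offsets_mm) == n_markers)
  cfg <- list(apex_rest = as_room_point(apex_rest),
              apex_SI_excursion_mm = apex_SI_excursion_mm,
              tumor_rest = as_room_point(tumor_rest),
              coupling_mm = coupling_mm,
              hysteresis_lag_s = hysteresis_lag_s,
              asynchrony_SI_amplitude_mm = asynchrony_SI_amplitude_mm,
              n_markers = n_markers,
              marker_offsets_mm = lapply(marker_offsets_mm, as.numeric),
              mode = mode,
              quad_coefs = quad_coefs)
  class(cfg) <- "anatomy_config"
  cfg
}

default_quad_coefs <- function(cfg, amplitude_mm) {
  # Linear term maps the surrogate range onto the configured coupling; mild
  # curvature and velocity terms keep the design full-rank.
  lin <- cfg$coupling_mm / max(amplitude_mm, 1e-9)
  rbind(a = 0.02 * lin, b = lin, c = unclass(cfg$tumor_rest),
        d = 0.002 * lin, e = 0.05 * lin)
}

#' Simulate ground-truth anatomy trajectories for a session
#'
#' Produces the per-frame ground truth used to render frames and to score
#' tracking and prediction: surrogate value, gantry angles of both imagers,
#' apex, tumor, and fiducial marker positions.
#'
#' @param resp A `respiratory_signal` from [simulate_respiration()].
#' @param cfg An [anatomy_config()].
#' @param arc Gantry arc: list with `start_deg`, `end_deg` and `direction`
#'   (`"cw"` or `"ccw"`); traversed at constant angular velocity. Defaults to
#'   the clockwise 330-75 degree arc.
#' @param imager2_offset_deg Angular lead of imager 2 (default 90).
#' @return An object of class `session_truth`: a data frame with columns
#'   `time_s`, `angle1_deg`, `angle2_deg`, `p_mm`, `apex_x/y/z_mm`,
#'   `tumor_x/y/z_mm` and `marker<i>_x/y/z_mm`.
#' @export
simulate_anatomy <- function(resp, cfg, arc = session_arc(),
                             imager2_offset_deg = 90) {
  stopifnot(inherits(resp, "respiratory_signal"), inherits(cfg, "anatomy_config"))
  if (nrow(resp) == 0) stop("BadConfig: empty respiratory signal")
  t <- resp$time_s
  n <- length(t)
  dt <- attr(resp, "dt_s")
  depth <- resp$depth
  p <- resp$p_mm

  ang1 <- arc_angles(arc, n)
  ang2 <- (ang1 + imager2_offset_deg) %% 360

  apex <- matrix(rep(unclass(cfg$apex_rest), each = n), ncol = 3)
  colnames(apex) <- c("x", "y", "z")
  apex[, "z"] <- apex[, "z"] + cfg$apex_SI_excursion_mm * depth

  if (cfg$mode == "model_consistent") {
    qc <- cfg$quad_coefs %||%
      default_quad_coefs(cfg, attr(resp, "config")$amplitude_mm)
    X <- cbind(p^2, p, 1, resp$p_dot^2, resp$p_dot)
    tumor <- X %*% qc
    colnames(tumor) <- c("x", "y", "z")
  } else {
    # Lagged depth via linear interpolation of the clean waveform.
    lag <- cfg$hysteresis_lag_s
    depth_lag <- if (lag == 0) depth else
      stats::approx(t, depth, xout = pmax(t - lag, t[1]), rule = 2)$y
    tumor <- matrix(rep(unclass(cfg$tumor_rest), each = n), ncol = 3)
    colnames(tumor) <- c("x", "y", "z")
    tumor <- tumor + outer(depth_lag, cfg$coupling_mm)
    if (cfg$asynchrony_SI_amplitude_mm != 0) {
      rng <- range(p)
      if (diff(rng) < 1e-12) stop("BadConfig: flat surrogate with asynchrony")
      tumor[, "z"] <- tumor[, "z"] +
        cfg$asynchrony_SI_amplitude_mm * (p - rng[1]) / diff(rng)
    }
  }

  out <- data.frame(time_s = t, angle1_deg = ang1, angle2_deg = ang2,
                    p_mm = p,
                    apex_x_mm = apex[, "x"], apex_y_mm = apex[, "y"],
                    apex_z_mm = apex[, "z"],
                    tumor_x_mm = tumor[, "x"], tumor_y_mm = tumor[, "y"],
                    tumor_z_mm = tumor[, "z"])
  for (i in seq_len(cfg$n_markers)) {
    off <- cfg$marker_offsets_mm[[i]]
    out[[sprintf("marker%d_x_mm", i)]] <- tumor[, "x"] + off[1]
    out[[sprintf("marker%d_y_mm", i)]] <- tumor[, "y"] + off[2]
    out[[sprintf("marker%d_z_mm", i)]] <- tumor[, "z"] + off[3]
  }
  attr(out, "dt_s") <- dt
  attr(out, "anatomy") <- cfg
  attr(out, "arc") <- arc
  attr(out, "imager2_offset_deg") <- imager2_offset_deg
  class(out) <- c("session_truth", "data.frame")
  out
}

#' Gantry arc specification
#'
#' @param start_deg,end_deg Arc endpoints in degrees.
#' @param direction `"cw"` (angle increases, the positive-clockwise
#'   convention) or `"ccw"`.
#' @return A list of class `session_arc`.
#' @export
session_arc <- function(start_deg = 330, end_deg = 75, direction = "cw") {
  stopifnot(direction %in% c("cw", "ccw"))
  structure(list(start_deg = start_deg, end_deg = end_deg,
                 direction = direction),
            class = "session_arc")
}

#' Angles traversed along an arc at constant angular velocity
#'
#' @param arc A [session_arc()].
#' @param n Number of frames.
#' @return Numeric vector of `n` angles in `[0, 360)`.
#' @export
arc_angles <- function(arc, n) {
  span <- if (arc$direction == "cw") (arc$end_deg - arc$start_deg) %% 360
          else (arc$start_deg - arc$end_deg) %% 360
  sgn <- if (arc$direction == "cw") 1 else -1
  if (n == 1) return(arc$start_deg %% 360)
  (arc$start_deg + sgn * span * (seq_len(n) - 1) / (n - 1)) %% 360
}

# Extract marker positions of one frame as a list of room_points.
truth_markers <- function(truth, i) {
  cfg <- attr(truth, "anatomy")
  lapply(seq_len(cfg$n_markers), function(k)
    room_point(truth[[sprintf("marker%d_x_mm", k)]][i],
               truth[[sprintf("marker%d_y_mm", k)]][i],
               truth[[sprintf("marker%d_z_mm", k)]][i]))
}

truth_apex <- function(truth, i) {
  room_point(truth$apex_x_mm[i], truth$apex_y_mm[i], truth$apex_z_mm[i])
}
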