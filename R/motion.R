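#' Estimate surrogate velocity
#'
#' Finite-difference velocity of the respiratory signal: central differences
#' in the interior, one-sided at the ends, optionally preceded by a centred
#' moving average (symmetrically truncated at the edges, so linear signals
#' are preserved exactly).
#'
#' @param p Numeric vector of surrogate positions, mm.
#' @param dt Sampling interval, s.
#' @param smooth_window Odd moving-average window length in samples
#'   (1 = no smoothing). Default 1; the pipeline uses 3 when the signal
#'   carries pulsation or noise.
#' @return Numeric vector of velocities, mm/s.
#' @export
estimate_velocity <- function(p, dt, smooth_window = 1L) {
  n <- length(p)
  if (n < 3) stop("TooShort: need at least 3 samples")
  if (smooth_window > 1) {
    hw <- (smooth_window - 1) %/% 2
    p <- vapply(seq_len(n), function(i) {
      k <- min(hw, i - 1, n - i) # symmetric truncation near edges
      mean(p[(i - k):(i + k)])
    }, numeric(1))
  }
  v <- numeric(n)
  v[1] <- (p[2] - p[1]) / dt
  v[n] <- (p[n] - p[n - 1]) / dt
  v[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (2 * dt)
  v
}

#' Detect the final breathing extrema of a training window
#'
#' Finds local minima and maxima of the surrogate signal inside the window,
#' keeping only extrema whose prominence exceeds a fraction of the window's
#' peak-to-peak range (rejecting cardiac pulsation wiggles), and returns the
#' last trough (end-expiration) and last peak (end-inspiration).
#'
#' @param sig A `respiratory_signal` (or data frame with `time_s`, `p_mm`).
#' @param window Numeric length-2 time window in s, default `c(0, 20)`.
#' @param prominence_frac Prominence threshold as a fraction of the window
#'   peak-to-peak range (default 0.2).
#' @return A list of class `breathing_extrema`: `t_ex`, `t_in`, `p_ex`,
#'   `p_in`, `idx_ex`, `idx_in` (indices into `sig`).
#' @export
detect_extrema <- function(sig, window = c(0, 20), prominence_frac = 0.2) {
  sel <- which(sig$time_s >= window[1] & sig$time_s <= window[2])
  p <- sig$p_mm[sel]
  if (length(p) < 3) stop("NoCycle: window too short")
  thr <- prominence_frac * diff(range(p))
  pk <- local_extrema(p, thr)
  tr <- local_extrema(-p, thr)
  if (length(pk) == 0 || length(tr) == 0)
    stop("NoCycle: no qualifying trough/peak pair in the window")
  i_in <- sel[pk[length(pk)]]
  i_ex <- sel[tr[length(tr)]]
  ex <- list(t_ex = sig$time_s[i_ex], t_in = sig$time_s[i_in],
             p_ex = sig$p_mm[i_ex], p_in = sig$p_mm[i_in],
             idx_ex = i_ex, idx_in = i_in)
  if (ex$p_ex == ex$p_in)
    stop("NoCycle: degenerate extrema (p_ex == p_in)")
  class(ex) <- "breathing_extrema"
  ex
}

# Indices of local maxima of x with prominence >= thr. Prominence of a peak
# is its height above the higher of the two valley floors reached before a
# higher value (or the boundary) is met on each side.
local_extrema <- function(x, thr) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    lo_l <- x[i]; k <- i
    while (k > 1 && x[k - 1] <= x[i]) { k <- k - 1; lo_l <- min(lo_l, x[k]) }
    lo_r <- x[i]; k <- i
    while (k < n && x[k + 1] <= x[i]) { k <- k + 1; lo_r <- min(lo_r, x[k]) }
    keep[j] <- (x[i] - max(lo_l, lo_r)) >= thr
  }
  cand[keep]
}

#' Build an apex-to-tumor offset-vector model
#'
#' Three scenarios are supported:
#' * `S_no`: no offset model — the (pseudo-)tumor position is taken as
#'   directly observable and is passed through unchanged.
#' * `S_con`: a constant offset vector, the apex-to-tumor displacement at
#'   the end-expiratory phase, applied at every phase.
#' * `S_var`: a phase-dependent offset interpolated linearly in the
#'   surrogate `p` between its end-expiratory and end-inspiratory values.
#'
#' The SI offset endpoints use the apex position at the respective phase;
#' the LR/AP endpoints use the end-expiratory apex as a fixed starting
#' point, avoiding errors from respiratory lateral diaphragm shifts.
#'
#' @param scenario `"S_no"`, `"S_con"` or `"S_var"`.
#' @param apex_traj,tumor_traj n x 3 matrices (columns LR, AP, SI), mm,
#'   time-aligned with `sig`.
#' @param sig A `respiratory_signal`.
#' @param extrema A [detect_extrema()] result.
#' @param clamp Clamp `p` to the training extrema range when evaluating the
#'   variable offset (default `FALSE`: extrapolation allowed).
#' @return An object of class `offset_vector_model`.
#' @export
build_offset_model <- function(scenario, apex_traj = NULL, tumor_traj = NULL,
                               sig = NULL, extrema = NULL, clamp = FALSE) {
  scenario <- match.arg(scenario, c("S_no", "S_con", "S_var"))
  m <- list(scenario = scenario, clamp = clamp)
  if (scenario != "S_no") {
    stopifnot(!is.null(apex_traj), !is.null(tumor_traj), !is.null(extrema))
    apex_ex <- apex_traj[extrema$idx_ex, ]
    m$apex_ex <- as.numeric(apex_ex)
    m$s_ex <- as.numeric(tumor_traj[extrema$idx_ex, ] - apex_ex)
    if (scenario == "S_var") {
      if (extrema$p_ex == extrema$p_in)
        stop("DegenerateBreathingRange: p_ex == p_in")
      apex_in <- apex_traj[extrema$idx_in, ]
      # SI endpoint uses the same-phase apex; LR/AP use the fixed
      # end-expiratory apex.
      s_in <- as.numeric(tumor_traj[extrema$idx_in, ]) -
        c(apex_ex[1], apex_ex[2], apex_in[3])
      m$s_in <- s_in
      m$p_ex <- extrema$p_ex
      m$p_in <- extrema$p_in
    }
  }
  class(m) <- "offset_vector_model"
  m
}

#' Phase-dependent offset vector
#'
#' Evaluates the variable offset at surrogate value `p`:
#' `s(p) = s_in + (s_ex - s_in) * (p - p_in) / (p_ex - p_in)`, per
#' component. Exact at both endpoints and affine in `p`; extrapolation
#' beyond the training extrema is allowed unless the model clamps.
#'
#' @param m An `offset_vector_model` with `scenario = "S_var"`.
#' @param p Surrogate value(s), mm.
#' @return Offset 3-vector (or n x 3 matrix for vector `p`), mm.
#' @export
offset_at_phase <- function(m, p) {
  stopifnot(identical(m$scenario, "S_var"))
  if (m$p_ex == m$p_in) stop("DegenerateBreathingRange: p_ex == p_in")
  if (isTRUE(m$clamp))
    p <- pmin(pmax(p, min(m$p_in, m$p_ex)), max(m$p_in, m$p_ex))
  w <- (p - m$p_in) / (m$p_ex - m$p_in)
  if (length(p) == 1) m$s_in + (m$s_ex - m$s_in) * w
  else outer(w, m$s_ex - m$s_in) + matrix(m$s_in, length(p), 3, byrow = TRUE)
}

#' Estimate the tumor position from the tracked apex
#'
#' SI: per-frame apex SI plus the (phase-dependent or constant) SI offset.
#' LR/AP: the fixed end-expiratory apex plus the LR/AP offsets. `S_no`
#' passes the supplied tumor positions through unchanged.
#'
#' @param m An `offset_vector_model`.
#' @param apex_t n x 3 matrix of apex positions at the query times, mm.
#' @param p Surrogate values at the query times (length n).
#' @param apex_ex End-expiratory apex 3-vector; defaults to the one stored
#'   in the model.
#' @param tumor Optional n x 3 tumor positions, returned as-is for `S_no`.
#' @return n x 3 matrix of estimated tumor positions (columns LR, AP, SI).
#' @export
estimate_tumor <- function(m, apex_t, p, apex_ex = NULL, tumor = NULL) {
  if (identical(m$scenario, "S_no")) {
    if (is.null(tumor)) stop("S_no requires the observed tumor positions")
    return(as.matrix(tumor))
  }
  apex_t <- matrix(as.numeric(as.matrix(apex_t)), ncol = 3)
  apex_ex <- apex_ex %||% m$apex_ex
  n <- nrow(apex_t)
  s <- if (identical(m$scenario, "S_con"))
    matrix(m$s_ex, n, 3, byrow = TRUE)
  else {
    sv <- offset_at_phase(m, p)
    if (is.null(dim(sv))) matrix(sv, n, 3, byrow = TRUE) else sv
  }
  est <- matrix(NA_real_, n, 3)
  est[, 1] <- apex_ex[1] + s[, 1]
  est[, 2] <- apex_ex[2] + s[, 2]
  est[, 3] <- apex_t[, 3] + s[, 3]
  colnames(est) <- c("x", "y", "z")
  est
}

#' Fit the 4D correlation model
#'
#' Per anatomical direction, least-squares fit of the tumor coordinate on
#' the regressors `(p^2, p, 1, p_dot^2, p_dot)`. The model is linear in its
#' parameters, so the least-squares problem is solved in closed form via the
#' singular value decomposition (minimum-norm solution on rank deficiency,
#' which is flagged).
#'
#' @param sig A `respiratory_signal`.
#' @param tumor_traj n x 3 matrix of tumor positions, mm, aligned with
#'   `sig`.
#' @param window Training time window in s, default `c(0, 20)`.
#' @return An object of class `correlation_model`: `coef` (5 x 3 matrix,
#'   rows a, b, c, d, e; columns LR, AP, SI), `rank`, `rank_deficient`,
#'   `n_samples`.
#' @export
fit_4dm <- function(sig, tumor_traj, window = c(0, 20)) {
  sel <- which(sig$time_s >= window[1] & sig$time_s <= window[2])
  if (length(sel) < 5) stop("TooFewSamples: need >= 5 in-window samples")
  p <- sig$p_mm[sel]; pd <- sig$p_dot[sel]
  X <- cbind(p^2, p, 1, pd^2, pd)
  Y <- as.matrix(tumor_traj)[sel, , drop = FALSE]
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  rank <- sum(pos)
  dinv <- ifelse(pos, 1 / sv$d, 0)
  coef <- sv$v %*% (dinv * (t(sv$u) %*% Y))
  dimnames(coef) <- list(c("a", "b", "c", "d", "e"), c("x", "y", "z"))
  structure(list(coef = coef, rank = rank, rank_deficient = rank < 5L,
                 n_samples = length(sel)),
            class = "correlation_model")
}

#' Predict tumor position from the surrogate
#'
#' Evaluates the fitted quadratic correlation model
#' `F(p) = a p^2 + b p + c + d p_dot^2 + e p_dot` per direction. Only the
#' external surrogate enters the prediction.
#'
#' @param model A [fit_4dm()] result.
#' @param p,p_dot Surrogate positions (mm) and velocities (mm/s).
#' @return n x 3 matrix of predicted positions (columns LR, AP, SI), mm.
#' @export
predict_4dm <- function(model, p, p_dot) {
  X <- cbind(p^2, p, 1, p_dot^2, p_dot)
  out <- X %*% model$coef
  colnames(out) <- c("x", "y", "z")
  out
}

#' Serialize motion models to JSON
#'
#' @param offset An `offset_vector_model` (or `NULL`).
#' @param model A `correlation_model` (or `NULL`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_models_json <- function(offset, model, path) {
  payload <- list()
  if (!is.null(offset)) payload$offset <- unclass(offset)
  if (!is.null(model)) {
    payload$fourdm <- list(coef = as.data.frame(model$coef),
                           rank = model$rank,
                           rank_deficient = model$rank_deficient,
                           n_samples = model$n_samples)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
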