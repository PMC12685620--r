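#' Track the diaphragm apex through a dual-view session
#'
#' Frame-by-frame epipolar-constrained tracking. Per frame and per imager,
#' the imaging region is classified from the view angle; the non-lateral
#' view (or both, when neither is lateral) is matched first inside a window
#' around the previous frame's apex; when one view is lateral, the
#' non-lateral detection is back-projected and its epipolar line restricts
#' the lateral-view vertical search range. The two 2D detections are then
#' triangulated into a 3D apex with the skew-ray midpoint rule.
#'
#' Frames are produced lazily by `frame_provider(i, imager)` so that a full
#' 351-frame dual-view session never holds more than two frames in memory.
#'
#' @param frame_provider Function `(frame_index, imager)` returning a
#'   *preprocessed* [projection_image()] (inverted polarity).
#' @param n_frames Number of frames.
#' @param geoms Function `(frame_index, imager)` returning the frame's
#'   `view_geometry` (or a list of per-frame lists).
#' @param banks List of two `template_bank`s, one per imager.
#' @param seeds List of two `pixel_coord`s: first-frame apex seeds per
#'   imager; `NULL` entries trigger wide-window seeding via [seed_apex()].
#' @param times Frame times in s (for the output table).
#' @param gamma_floor Correlation floor; `gamma` below it for
#'   `lost_after` consecutive frames raises `LostTrack`.
#' @param lost_after Consecutive low-score frames tolerated.
#' @return A data frame of class `track_result` with per-frame columns
#'   `time_s`, `u1`, `v1`, `gamma1`, `region1`, `u2`, `v2`, `gamma2`,
#'   `region2`, `apex_x/y/z_mm`, `residual_mm`.
#' @export
track_session <- function(frame_provider, n_frames, geoms, banks,
                          seeds = list(NULL, NULL),
                          times = NULL, gamma_floor = 0.2, lost_after = 5L) {
  geom_of <- if (is.function(geoms)) geoms else
    function(i, k) geoms[[i]][[k]]
  if (is.null(times)) times <- seq_len(n_frames)
  out <- data.frame(time_s = times[seq_len(n_frames)],
                    u1 = NA_real_, v1 = NA_real_, gamma1 = NA_real_,
                    region1 = NA_character_,
                    u2 = NA_real_, v2 = NA_real_, gamma2 = NA_real_,
                    region2 = NA_character_,
                    apex_x_mm = NA_real_, apex_y_mm = NA_real_,
                    apex_z_mm = NA_real_, residual_mm = NA_real_)
  prev <- vector("list", 2)
  low_run <- 0L

  for (i in seq_len(n_frames)) {
    g <- list(geom_of(i, 1L), geom_of(i, 2L))
    regions <- vapply(g, function(x) classify_region(x$theta), character(1))
    if (all(regions == "lateral"))
      stop("track_session: both views lateral; invalid geometry")
    imgs <- list(frame_provider(i, 1L), frame_provider(i, 2L))
    tmpls <- list(select_template(banks[[1]], g[[1]]$theta),
                  select_template(banks[[2]], g[[2]]$theta))

    order_k <- order(regions == "lateral") # non-lateral first
    res <- vector("list", 2)
    for (k in order_k) {
      if (i == 1 && is.null(prev[[k]])) {
        if (!is.null(seeds[[k]])) prev[[k]] <- seeds[[k]]
        else prev[[k]] <- seed_apex(imgs[[k]], tmpls[[k]])$apex
      }
      epi <- NULL
      if (regions[k] == "lateral") {
        k_src <- 3L - k
        epi <- epipolar_segment(g[[k_src]], res[[k_src]]$apex, g[[k]])
      }
      win <- build_search_window(prev[[k]], regions[k], epi, g[[k]])
      m <- ncc_match(imgs[[k]], tmpls[[k]], win)
      m$region <- regions[k]
      res[[k]] <- m
      prev[[k]] <- m$apex
    }

    tri <- triangulate(backproject_ray(g[[1]], res[[1]]$apex),
                       backproject_ray(g[[2]], res[[2]]$apex))
    out$u1[i] <- res[[1]]$apex[["u"]]; out$v1[i] <- res[[1]]$apex[["v"]]
    out$gamma1[i] <- res[[1]]$score; out$region1[i] <- res[[1]]$region
    out$u2[i] <- res[[2]]$apex[["u"]]; out$v2[i] <- res[[2]]$apex[["v"]]
    out$gamma2[i] <- res[[2]]$score; out$region2[i] <- res[[2]]$region
    out$apex_x_mm[i] <- tri$point[["x"]]
    out$apex_y_mm[i] <- tri$point[["y"]]
    out$apex_z_mm[i] <- tri$point[["z"]]
    out$residual_mm[i] <- tri$residual_mm

    if (min(res[[1]]$score, res[[2]]$score) < gamma_floor) {
      low_run <- low_run + 1L
      if (low_run >= lost_after)
        stop(sprintf(
          "LostTrack: correlation below %.2f for %d consecutive frames (frame %d)",
          gamma_floor, low_run, i))
    } else low_run <- 0L
  }
  class(out) <- c("track_result", "data.frame")
  out
}
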