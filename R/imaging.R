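#' Inpaint fiducial-marker shadows
#'
#' Replaces each disc of radius 5 px around a known marker position with the
#' mean intensity of the surrounding 5-10 px annulus, so that the dark
#' fiducial shadows do not bias the diaphragm matching. Markers near the
#' border use the in-image part of the annulus. All other pixels are
#' untouched.
#'
#' @param img A [projection_image()] with `known_marker_pixels` set.
#' @param disc_radius,annulus_outer Disc and annulus radii in px.
#' @return The inpainted `projection_image`.
#' @export
inpaint_markers <- function(img, disc_radius = 5, annulus_outer = 10) {
  px <- img$pixels
  h <- nrow(px); w <- ncol(px)
  for (q in img$known_marker_pixels) {
    uc <- q[["u"]]; vc <- q[["v"]]
    u0 <- max(0, floor(uc - annulus_outer)); u1 <- min(w - 1, ceiling(uc + annulus_outer))
    v0 <- max(0, floor(vc - annulus_outer)); v1 <- min(h - 1, ceiling(vc + annulus_outer))
    if (u0 > u1 || v0 > v1) next
    uu <- u0:u1; vv <- v0:v1
    d <- sqrt(outer((vv - vc)^2, (uu - uc)^2, `+`))
    ann <- d > disc_radius & d <= annulus_outer
    disc <- d <= disc_radius
    if (!any(ann) || !any(disc)) next
    fill <- mean(px[vv + 1, uu + 1][ann])
    block <- px[vv + 1, uu + 1]
    block[disc] <- fill
    px[vv + 1, uu + 1] <- block
  }
  projection_image(px, img$geom, img$time_s, img$known_marker_pixels)
}

#' Logarithmic compression and density inversion
#'
#' Applies `log(1 + I)`, flips the polarity so that denser anatomy appears
#' brighter (`I' = max(log(1+I)) - log(1+I)`), and rescales the result back
#' to the input's dynamic range. Constant images pass through unchanged.
#'
#' @param img A [projection_image()].
#' @return The transformed `projection_image`.
#' @export
log_invert <- function(img) {
  px <- img$pixels
  lo <- min(px); hi <- max(px)
  if (hi - lo < .Machine$double.eps) return(img)
  j <- log1p(px)
  j <- max(j) - j
  out <- lo + (j - min(j)) / (max(j) - min(j)) * (hi - lo)
  projection_image(out, img$geom, img$time_s, img$known_marker_pixels)
}

# Block-average downsampling matrix mapping n_big samples onto n_small bins.
downsample_weights <- function(n_small, n_big) {
  bins <- floor((0:(n_big - 1)) * n_small / n_big)
  W <- matrix(0, n_small, n_big)
  for (b in 0:(n_small - 1)) {
    idx <- which(bins == b)
    W[b + 1, idx] <- 1 / length(idx)
  }
  W
}

# Bilinear interpolation weights (centre-aligned) for 1D resize.
bilinear_weights <- function(n_out, n_in) {
  x <- (0:(n_out - 1) + 0.5) * n_in / n_out - 0.5
  x <- pmin(pmax(x, 0), n_in - 1)
  i0 <- pmin(floor(x), n_in - 2)
  frac <- x - i0
  W <- matrix(0, n_out, n_in)
  W[cbind(1:n_out, i0 + 1)] <- 1 - frac
  W[cbind(1:n_out, i0 + 2)] <- W[cbind(1:n_out, i0 + 2)] + frac
  W
}

#' Resolution matching of kV frames
#'
#' Downsamples a 768 x 1024 frame to 75 px horizontally by 205 px vertically
#' (block averaging), approximating planning-CT voxel resolution, then
#' restores the original size by bilinear interpolation. The net effect is a
#' strong anisotropic low-pass that makes the kV frames resemble the
#' CT-derived templates.
#'
#' @param img A [projection_image()], 768 x 1024 px.
#' @param small_u,small_v Intermediate size (u, v), default 75 x 205.
#' @return The resolution-matched `projection_image` at the original size.
#' @export
resolution_match <- function(img, small_u = 75, small_v = 205) {
  px <- img$pixels
  if (nrow(px) != 1024 || ncol(px) != 768)
    stop("BadDims: resolution_match expects a 768 x 1024 frame")
  Dv <- downsample_weights(small_v, nrow(px))
  Du <- downsample_weights(small_u, ncol(px))
  small <- Dv %*% px %*% t(Du)
  Uv <- bilinear_weights(nrow(px), small_v)
  Uu <- bilinear_weights(ncol(px), small_u)
  out <- Uv %*% small %*% t(Uu)
  projection_image(out, img$geom, img$time_s, img$known_marker_pixels)
}

#' Full preprocessing chain
#'
#' Composition, in order: [inpaint_markers()], [log_invert()],
#' [resolution_match()]. Takes a raw-polarity kV frame to the inverted,
#' resolution-matched representation used for template matching.
#'
#' @param img A [projection_image()].
#' @return The preprocessed `projection_image`.
#' @export
preprocess <- function(img) {
  resolution_match(log_invert(inpaint_markers(img)))
}

#' Search window for apex matching
#'
#' In the non-lateral region the window spans +/-10 px horizontally around
#' the previous apex and +/-50 px vertically. In the lateral region the
#' vertical range is instead taken from the epipolar constraint: within
#' 15 px of the line's intersections with the left and right image edges
#' (the +/-10 px horizontal rule is reused). Windows are clipped to the
#' image bounds.
#'
#' @param prev `pixel_coord` of the previous-frame apex (`x_pre`, `y_pre`).
#' @param region `"lateral"` or `"non_lateral"`.
#' @param epi An `epipolar_segment` (required when lateral).
#' @param geom The view's `view_geometry` (for clipping).
#' @return A list of class `search_window` with integer `u_min`, `u_max`,
#'   `v_min`, `v_max`.
#' @export
build_search_window <- function(prev, region, epi = NULL, geom) {
  u0 <- round(prev[["u"]]) - 10
  u1 <- round(prev[["u"]]) + 10
  if (region == "non_lateral") {
    v0 <- round(prev[["v"]]) - 50
    v1 <- round(prev[["v"]]) + 50
  } else {
    if (is.null(epi))
      stop("MissingEpipolar: lateral-region window needs an epipolar segment")
    ve <- vapply(epi$edge_points, function(q) q[["v"]], numeric(1))
    v0 <- floor(min(ve)) - 15
    v1 <- ceiling(max(ve)) + 15
  }
  win <- list(u_min = max(0L, as.integer(u0)),
              u_max = min(geom$width - 1L, as.integer(u1)),
              v_min = max(0L, as.integer(v0)),
              v_max = min(geom$height - 1L, as.integer(v1)))
  class(win) <- "search_window"
  win
}

#' Normalized cross-correlation template match
#'
#' Exhaustive zero-mean normalized cross-correlation over all integer apex
#' placements inside the window (placements are restricted to positions
#' where the template lies fully inside the image). Returns the placement
#' maximizing the correlation `gamma`; exact ties break to the smallest `v`,
#' then smallest `u`.
#'
#' @param img A (preprocessed) [projection_image()].
#' @param tmpl A [diaphragm_template()].
#' @param window A `search_window` (apex coordinates).
#' @param return_gamma If `TRUE`, also return the full correlation matrix
#'   over the window (rows = v placements, cols = u placements).
#' @return A list of class `match_result`: `apex` (`pixel_coord`), `score`,
#'   `search_window`, `region` (filled by the tracker; `NA` here) and
#'   optionally `gamma_matrix`.
#' @export
ncc_match <- function(img, tmpl, window, return_gamma = FALSE) {
  px <- img$pixels
  tp <- tmpl$pixels
  au <- as.integer(round(tmpl$apex_offset[["u"]]))
  av <- as.integer(round(tmpl$apex_offset[["v"]]))
  h <- nrow(px); w <- ncol(px)
  th <- nrow(tp); tw <- ncol(tp)
  # clip to placements with the template fully inside the image
  u0 <- max(window$u_min, au)
  u1 <- min(window$u_max, w - 1L + au - (tw - 1L))
  v0 <- max(window$v_min, av)
  v1 <- min(window$v_max, h - 1L + av - (th - 1L))
  if (u0 > u1 || v0 > v1)
    stop("EmptyWindow: no valid template placement inside the window")
  if (stats::sd(tp) == 0)
    stop("ZeroVariance: template is constant, correlation undefined")
  res <- ncc_scan_cpp(px, tp, u0, u1, v0, v1, au, av, return_gamma)
  if (is.na(res$gamma))
    stop("ZeroVariance: every candidate patch is constant")
  out <- list(apex = pixel_coord(res$u, res$v),
              score = max(-1, min(1, res$gamma)),
              search_window = list(u_min = u0, u_max = u1,
                                   v_min = v0, v_max = v1),
              region = NA_character_)
  if (return_gamma) out$gamma_matrix <- res$gamma_matrix
  class(out) <- "match_result"
  out
}

#' Coarse-to-fine wide-window apex seeding
#'
#' First-frame seeding when no previous apex is available: a coarse grid
#' search (stride `stride` px) over all valid placements, refined by an
#' exhaustive match in a `+/-stride` neighbourhood of the coarse optimum.
#'
#' @param img A preprocessed [projection_image()].
#' @param tmpl A [diaphragm_template()].
#' @param stride Coarse stride in px.
#' @return A `match_result`.
#' @export
seed_apex <- function(img, tmpl, stride = 8L) {
  px <- img$pixels
  au <- as.integer(round(tmpl$apex_offset[["u"]]))
  av <- as.integer(round(tmpl$apex_offset[["v"]]))
  tw <- ncol(tmpl$pixels); th <- nrow(tmpl$pixels)
  u_lo <- au; u_hi <- ncol(px) - 1L + au - (tw - 1L)
  v_lo <- av; v_hi <- nrow(px) - 1L + av - (th - 1L)
  coarse <- ncc_scan_strided_cpp(px, tmpl$pixels, u_lo, u_hi, v_lo, v_hi,
                                 au, av, as.integer(stride))
  win <- list(u_min = max(u_lo, coarse$u - stride),
              u_max = min(u_hi, coarse$u + stride),
              v_min = max(v_lo, coarse$v - stride),
              v_max = min(v_hi, coarse$v + stride))
  class(win) <- "search_window"
  ncc_match(img, tmpl, win)
}
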