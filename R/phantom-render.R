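#' Dome rendering parameters
#'
#' The phantom renders the projected diaphragm as an analytic dome: a
#' half-ellipse boundary (apex at its most-superior point) separating a dark
#' lung field above from a bright abdomen below, with a smooth sigmoidal
#' edge. Radii are in detector pixels (0.2 mm at isocenter); defaults give a
#' ~57 mm half-width dome whose apparent width varies mildly with viewing
#' angle, and a gentle lateral shading term that makes the apex column
#' identifiable.
#'
#' @param ru_px Dome half-width at the reference (anterior) view, px.
#' @param rv_px Dome height (apex to shoulder), px.
#' @param edge_px Sigmoid edge width, px.
#' @param base,dome Intensities (arbitrary units in `[0, 1]`) of the lung
#'   field and of the abdomen just below the boundary.
#' @param shading Relative linear intensity fall-off across the dome width.
#' @param angle_mod Relative modulation of the dome width with viewing angle.
#' @param marker_radius_px Rendered fiducial-shadow radius, px.
#' @param marker_depth Fractional intensity drop inside a fiducial shadow.
#' @return A list of class `dome_params`.
#' @export
dome_params <- function(ru_px = 285, rv_px = 125, edge_px = 3,
                        base = 0.15, dome = 0.85, shading = 0.2,
                        angle_mod = 0.15, marker_radius_px = 3,
                        marker_depth = 0.9) {
  structure(list(ru_px = ru_px, rv_px = rv_px, edge_px = edge_px,
                 base = base, dome = dome, shading = shading,
                 angle_mod = angle_mod, marker_radius_px = marker_radius_px,
                 marker_depth = marker_depth),
            class = "dome_params")
}

#' Projection image
#'
#' Container for one kV frame: an intensity matrix with `height` rows (the
#' `v` axis, increasing inferior) and `width` columns (the `u` axis), the
#' acquisition time, the view geometry and the known 2D fiducial-marker
#' pixels used by the inpainting step.
#'
#' @param pixels Numeric matrix, `geom$height` x `geom$width`, nonnegative.
#' @param geom A `view_geometry`.
#' @param time_s Acquisition time, s.
#' @param known_marker_pixels List of `pixel_coord`s.
#' @return An object of class `projection_image`.
#' @export
projection_image <- function(pixels, geom, time_s = 0,
                             known_marker_pixels = list()) {
  stopifnot(is.matrix(pixels),
            nrow(pixels) == geom$height, ncol(pixels) == geom$width)
  if (any(pixels < 0)) stop("projection_image: intensities must be nonnegative")
  structure(list(pixels = pixels, geom = geom, time_s = time_s,
                 known_marker_pixels = known_marker_pixels),
            class = "projection_image")
}

# Analytic dome intensity evaluated on an arbitrary pixel grid.
# u, v: vectors of 0-based pixel coordinates; apex at (ua, va).
# Returns an length(v) x length(u) matrix in "inverted" polarity
# (dense anatomy bright), before any marker shadows.
dome_field <- function(u, v, ua, va, theta_deg, dp) {
  ru <- dp$ru_px * (1 - dp$angle_mod + dp$angle_mod * cos(theta_deg * pi / 180)^2)
  du <- (u - ua) / ru
  vb <- va + dp$rv_px * (1 - sqrt(pmax(0, 1 - pmin(abs(du), 1)^2)))
  below <- outer(v, vb, function(vv, vbb) 1 / (1 + exp(-(vv - vbb) / dp$edge_px)))
  amp <- (dp$dome - dp$base) * (1 - dp$shading * pmin(abs(du), 1)^2)
  dp$base + sweep(below, 2, amp, `*`)
}

# Multiplicative soft disc shadows at continuous pixel centres.
apply_marker_shadows <- function(img, centers, dp) {
  if (length(centers) == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  r <- dp$marker_radius_px
  for (q in centers) {
    uc <- q[["u"]]; vc <- q[["v"]]
    u0 <- max(0, floor(uc - r - 3)); u1 <- min(w - 1, ceiling(uc + r + 3))
    v0 <- max(0, floor(vc - r - 3)); v1 <- min(h - 1, ceiling(vc + r + 3))
    if (u0 > u1 || v0 > v1) next
    uu <- u0:u1; vv <- v0:v1
    d <- sqrt(outer((vv - vc)^2, (uu - uc)^2, `+`))
    mask <- 1 - dp$marker_depth / (1 + exp((d - r) / 0.7))
    img[vv + 1, uu + 1] <- img[vv + 1, uu + 1] * mask
  }
  img
}

#' Render one synthetic kV frame
#'
#' Renders the diaphragm dome so that its projected apex coincides with
#' `project_point(geom, apex)` (sub-pixel exact by construction), plus dark
#' circular fiducial shadows at the projected marker positions and optional
#' Gaussian pixel noise.
#'
#' `polarity = "inverted"` renders the post-inversion convention (denser
#' anatomy brighter), matching the template bank directly;
#' `polarity = "raw"` renders raw-kV polarity (denser anatomy darker), the
#' input expected by [preprocess()].
#'
#' @param geom A `view_geometry`.
#' @param apex Apex `room_point`.
#' @param markers List of marker `room_point`s (possibly empty).
#' @param time_s Frame time, s.
#' @param polarity `"inverted"` or `"raw"`.
#' @param noise_sd Gaussian pixel-noise SD (intensity units).
#' @param seed Optional integer seed for the noise.
#' @param dome A [dome_params()] list.
#' @return A [projection_image()] with `known_marker_pixels` filled in.
#' @export
render_frame <- function(geom, apex, markers = list(), time_s = 0,
                         polarity = c("inverted", "raw"),
                         noise_sd = 0, seed = NULL, dome = dome_params()) {
  polarity <- match.arg(polarity)
  qa <- project_point(geom, apex)
  if (qa[["u"]] < 0 || qa[["u"]] > geom$width - 1 ||
      qa[["v"]] < 0 || qa[["v"]] > geom$height - 1)
    stop("ApexOutsideImage: projected apex falls outside the frame")
  img <- dome_field(0:(geom$width - 1), 0:(geom$height - 1),
                    qa[["u"]], qa[["v"]], geom$theta, dome)
  if (polarity == "raw") img <- 1 - img
  mk <- lapply(markers, function(m) project_point(geom, m))
  img <- apply_marker_shadows(img, mk, dome)
  if (noise_sd > 0) {
    img <- img + with_seed(seed, matrix(stats::rnorm(length(img), 0, noise_sd),
                                        nrow = nrow(img)))
    img <- pmax(img, 0)
  }
  projection_image(img, geom, time_s = time_s, known_marker_pixels = mk)
}

#' Diaphragm template
#'
#' A 199 x 299 px intensity crop centred on the diaphragm apex, indexed by
#' the view angle it was rendered for.
#'
#' @param pixels 199 x 299 numeric matrix.
#' @param view_angle_deg Viewing angle (imager's own angle) in degrees.
#' @param apex_offset `pixel_coord` of the apex inside the template
#'   (defaults to the centre pixel, `(149, 99)` 0-based).
#' @return An object of class `diaphragm_template`.
#' @export
diaphragm_template <- function(pixels, view_angle_deg,
                               apex_offset = pixel_coord(149, 99)) {
  stopifnot(is.matrix(pixels), nrow(pixels) == 199, ncol(pixels) == 299)
  structure(list(pixels = pixels, view_angle_deg = view_angle_deg %% 360,
                 apex_offset = apex_offset),
            class = "diaphragm_template")
}

#' Render an angle-indexed diaphragm template bank
#'
#' One 299 x 199 px template per grid angle along the arc (0.3 degree grid
#' by default), rendered at the reference end-expiration breathing depth
#' with the apex at the template centre. The crop corresponds to
#' approximately 59.8 x 39.8 mm^2 at the isocenter.
#'
#' @param cfg An [anatomy_config()] (supplies the rest apex position).
#' @param arc A [session_arc()] covered by the bank.
#' @param angle_step_deg Grid spacing, degrees (default 0.3).
#' @param imager Which imager the bank serves (its own view angles are the
#'   arc angles plus the imager-2 offset when `imager = 2`).
#' @param geom_args Named list of extra arguments to [view_geometry()].
#' @param dome A [dome_params()] list.
#' @return An object of class `template_bank`: list of
#'   [diaphragm_template()]s with an `angles` attribute (grid view angles).
#' @export
render_templates <- function(cfg, arc = session_arc(), angle_step_deg = 0.3,
                             imager = 1L, geom_args = list(),
                             dome = dome_params()) {
  stopifnot(angle_step_deg > 0)
  span <- if (arc$direction == "cw") (arc$end_deg - arc$start_deg) %% 360
          else (arc$start_deg - arc$end_deg) %% 360
  sgn <- if (arc$direction == "cw") 1 else -1
  gantry <- arc$start_deg + sgn * seq(0, span, by = angle_step_deg)
  tmpl <- vector("list", length(gantry))
  apex <- cfg$apex_rest
  for (i in seq_along(gantry)) {
    geom <- do.call(view_geometry, c(list(gantry_angle = gantry[i],
                                          imager = as.integer(imager)),
                                     geom_args))
    qa <- project_point(geom, apex)
    # Template pixel grid positioned so the apex lands on the centre pixel.
    u <- qa[["u"]] + (0:298) - 149
    v <- qa[["v"]] + (0:198) - 99
    px <- dome_field(u, v, qa[["u"]], qa[["v"]], geom$theta, dome)
    tmpl[[i]] <- diaphragm_template(px, geom$theta)
  }
  structure(tmpl, angles = vapply(tmpl, function(x) x$view_angle_deg,
                                  numeric(1)),
            class = "template_bank")
}

#' Select the template nearest a view angle
#'
#' Nearest grid angle on the bank's 0.3 degree grid; ties go to the lower
#' angle. Angular distance is taken on the circle.
#'
#' @param bank A `template_bank`.
#' @param view_angle_deg The imager's view angle, degrees.
#' @return A `diaphragm_template`.
#' @export
select_template <- function(bank, view_angle_deg) {
  ang <- attr(bank, "angles")
  d <- abs((ang - view_angle_deg + 180) %% 360 - 180)
  # ties to the lower angle
  best <- which(d < min(d) + 1e-12)
  if (length(best) > 1) best <- best[which.min(ang[best])]
  bank[[best]]
}
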