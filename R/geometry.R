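#' Room-frame point
#'
#' A 3D position in the fixed, right-handed room frame with origin at the
#' treatment isocenter. Axes follow the radiotherapy convention:
#' `x` left-right (LR, + = patient left), `y` anterior-posterior
#' (AP, + = anterior), `z` superior-inferior (SI, + = superior).
#'
#' @param x,y,z Coordinates in mm (LR, AP, SI).
#' @return An object of class `room_point`: a named numeric 3-vector.
#' @export
room_point <- function(x, y, z) {
  p <- c(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (!all(is.finite(p))) stop("room_point: all components must be finite")
  class(p) <- "room_point"
  p
}

as_room_point <- function(p) {
  if (inherits(p, "room_point")) return(p)
  stopifnot(length(p) == 3)
  room_point(p[[1]], p[[2]], p[[3]])
}

#' Continuous pixel coordinate
#'
#' 0-based continuous detector pixel coordinate. `u` is horizontal
#' (perpendicular to the SI axis); `v` is vertical and increases toward
#' patient-inferior in the projection. Pixel centers sit at integer
#' coordinates with the origin at the top-left pixel.
#'
#' @param u,v Pixel coordinates (may be fractional).
#' @return An object of class `pixel_coord`.
#' @export
pixel_coord <- function(u, v) {
  q <- c(u = as.numeric(u), v = as.numeric(v))
  if (!all(is.finite(q))) stop("pixel_coord: coordinates must be finite")
  class(q) <- "pixel_coord"
  q
}

#' Stereo kV imager geometry
#'
#' Describes one kV imaging chain of an O-ring gantry carrying two orthogonal
#' source/detector pairs. The gantry rotates about the SI axis; at
#' `gantry_angle = 0` the source of imager 1 is anterior of the patient and
#' positive angles are clockwise in the front view. Imager 2 leads imager 1
#' by `imager2_offset_deg` (default +90).
#'
#' The detector pitch is derived from the isocenter pixel size:
#' `pitch = isocenter_pixel_size * SID / SAD`, so a 1 mm displacement
#' perpendicular to the beam axis at isocenter moves the projection by
#' `1 / isocenter_pixel_size` pixels (5 px at the 0.2 mm default).
#'
#' @param gantry_angle Gantry angle of imager 1 in degrees.
#' @param imager Imager index, 1 or 2.
#' @param sad Source-axis distance, mm.
#' @param sid Source-imager distance, mm.
#' @param isocenter_pixel_size Pixel size back-projected to isocenter, mm.
#' @param width,height Detector size in pixels (u, v).
#' @param principal_point `pixel_coord` where the source-isocenter axis
#'   pierces the detector; defaults to the image center.
#' @param imager2_offset_deg Angular lead of imager 2 over imager 1, degrees.
#' @return An object of class `view_geometry`.
#' @export
view_geometry <- function(gantry_angle, imager = 1L, sad = 1000, sid = 2000,
                          isocenter_pixel_size = 0.2,
                          width = 768L, height = 1024L,
                          principal_point = NULL,
                          imager2_offset_deg = 90) {
  stopifnot(imager %in% c(1L, 2L), sid > sad, sad > 0,
            isocenter_pixel_size > 0)
  if (is.null(principal_point))
    principal_point <- pixel_coord((width - 1) / 2, (height - 1) / 2)
  theta <- gantry_angle + if (imager == 2L) imager2_offset_deg else 0
  g <- list(
    gantry_angle = as.numeric(gantry_angle),
    imager = as.integer(imager),
    theta = as.numeric(theta),            # this imager's own viewing angle
    sad = as.numeric(sad),
    sid = as.numeric(sid),
    pitch = isocenter_pixel_size * sid / sad,
    isocenter_pixel_size = as.numeric(isocenter_pixel_size),
    width = as.integer(width),
    height = as.integer(height),
    principal_point = principal_point,
    imager2_offset_deg = as.numeric(imager2_offset_deg)
  )
  class(g) <- "view_geometry"
  g
}

# Orthonormal frame of a view: source position, beam axis (source -> iso),
# detector u axis (horizontal, in the transverse plane) and v axis
# (anti-parallel to SI so v grows toward patient-inferior).
view_frame <- function(geom) {
  th <- geom$theta * pi / 180
  src <- c(sin(th), cos(th), 0) * geom$sad
  axis <- c(-sin(th), -cos(th), 0)
  e_u <- c(cos(th), -sin(th), 0)
  e_v <- c(0, 0, -1)
  list(source = src, axis = axis, e_u = e_u, e_v = e_v)
}

#' Source position of a view
#'
#' @param geom A `view_geometry`.
#' @return A `room_point` at the kV source.
#' @export
source_position <- function(geom) {
  s <- view_frame(geom)$source
  room_point(s[1], s[2], s[3])
}

#' Project a room-frame point onto a detector
#'
#' Perspective projection through the kV source onto the detector plane
#' (perpendicular to the source-isocenter axis at distance `sid`), converted
#' to 0-based pixels.
#'
#' @param geom A `view_geometry`.
#' @param p A `room_point` (or numeric 3-vector).
#' @return A `pixel_coord`.
#' @export
project_point <- function(geom, p) {
  p <- as_room_point(p)
  fr <- view_frame(geom)
  w <- unclass(p) - fr$source
  if (sqrt(sum(w^2)) < 1e-12)
    stop("PointAtSource: point coincides with the kV source")
  t_ax <- sum(w * fr$axis)
  if (t_ax <= 0)
    stop("BehindSource: point does not project onto the detector")
  scale <- geom$sid / t_ax
  u_mm <- sum(w * fr$e_u) * scale
  v_mm <- sum(w * fr$e_v) * scale
  pixel_coord(geom$principal_point[["u"]] + u_mm / geom$pitch,
              geom$principal_point[["v"]] + v_mm / geom$pitch)
}

#' Back-project a detector pixel to a 3D ray
#'
#' Returns the ray from the kV source through the room-frame position of the
#' given detector pixel. `project_point()` of any point on the ray recovers
#' the pixel.
#'
#' @param geom A `view_geometry`.
#' @param q A `pixel_coord`.
#' @return A list of class `ray` with elements `origin` (`room_point`) and
#'   `direction` (unit 3-vector).
#' @export
backproject_ray <- function(geom, q) {
  fr <- view_frame(geom)
  du <- (q[["u"]] - geom$principal_point[["u"]]) * geom$pitch
  dv <- (q[["v"]] - geom$principal_point[["v"]]) * geom$pitch
  det_pt <- fr$source + geom$sid * fr$axis + du * fr$e_u + dv * fr$e_v
  d <- det_pt - fr$source
  d <- d / sqrt(sum(d^2))
  r <- list(origin = room_point(fr$source[1], fr$source[2], fr$source[3]),
            direction = d)
  class(r) <- "ray"
  r
}

#' Triangulate two rays (skew-ray midpoint rule)
#'
#' For rays that intersect exactly, returns the intersection. For skew rays —
#' the generic case once detection noise enters — returns the midpoint of the
#' shortest segment connecting the two infinite lines, with the segment
#' length as residual.
#'
#' @param r1,r2 Objects of class `ray`.
#' @return A list with `point` (`room_point`) and `residual_mm`.
#' @export
triangulate <- function(r1, r2) {
  o1 <- unclass(r1$origin); d1 <- r1$direction
  o2 <- unclass(r2$origin); d2 <- r2$direction
  cr <- c(d1[2] * d2[3] - d1[3] * d2[2],
          d1[3] * d2[1] - d1[1] * d2[3],
          d1[1] * d2[2] - d1[2] * d2[1])
  if (sqrt(sum(cr^2)) < 1e-12)
    stop("ParallelRays: rays are (anti-)parallel, no unique midpoint")
  # Closed form: minimize |o1 + t1 d1 - o2 - t2 d2|^2 over (t1, t2).
  w0 <- o1 - o2
  a <- sum(d1 * d1); b <- sum(d1 * d2); cc <- sum(d2 * d2)
  d <- sum(d1 * w0); e <- sum(d2 * w0)
  denom <- a * cc - b * b
  t1 <- (b * e - cc * d) / denom
  t2 <- (a * e - b * d) / denom
  p1 <- o1 + t1 * d1
  p2 <- o2 + t2 * d2
  mid <- (p1 + p2) / 2
  list(point = room_point(mid[1], mid[2], mid[3]),
       residual_mm = sqrt(sum((p1 - p2)^2)))
}

#' Epipolar segment of a pixel in the paired view
#'
#' Projects the back-projected ray of `q_src` (seen in `geom_src`) into
#' `geom_dst`, returning the epipolar line in normalized form
#' `a*u + b*v + c = 0` with `a^2 + b^2 = 1`, together with its intersections
#' with the left (`u = 0`) and right (`u = width - 1`) image edges.
#'
#' @param geom_src View in which the pixel was detected.
#' @param q_src `pixel_coord` of the detection.
#' @param geom_dst Paired view receiving the constraint.
#' @return A list of class `epipolar_segment` with `a`, `b`, `c` and
#'   `edge_points` (list of two `pixel_coord`s at the image edges).
#' @export
epipolar_segment <- function(geom_src, q_src, geom_dst) {
  ray <- backproject_ray(geom_src, q_src)
  o <- unclass(ray$origin)
  # Two distinct ray points: the source itself (the epipole) and the point at
  # isocenter depth. Both lie in front of the 90-degree-offset paired view.
  p_a <- o
  p_b <- o + geom_src$sad * ray$direction
  q_a <- project_point(geom_dst, room_point(p_a[1], p_a[2], p_a[3]))
  q_b <- project_point(geom_dst, room_point(p_b[1], p_b[2], p_b[3]))
  du <- q_b[["u"]] - q_a[["u"]]
  dv <- q_b[["v"]] - q_a[["v"]]
  nrm <- sqrt(du^2 + dv^2)
  if (nrm < 1e-9)
    stop("DegenerateEpipole: ray projects to a single point in the paired view")
  # Line through q_a with direction (du, dv): normal is (dv, -du).
  a <- dv / nrm; b <- -du / nrm
  cc <- -(a * q_a[["u"]] + b * q_a[["v"]])
  if (abs(b) < 1e-12)
    stop("DegenerateEpipole: epipolar line is vertical, no edge intersections")
  v_at <- function(u) -(cc + a * u) / b
  seg <- list(a = a, b = b, c = cc,
              edge_points = list(pixel_coord(0, v_at(0)),
                                 pixel_coord(geom_dst$width - 1,
                                             v_at(geom_dst$width - 1))))
  class(seg) <- "epipolar_segment"
  seg
}

#' Lateral / non-lateral imaging-region classification
#'
#' Gantry angles in 50-130 and 230-310 degrees view the patient from the
#' side, where the two hemidiaphragm shadows can overlap in projection;
#' matching there needs the epipolar constraint from the paired view.
#' Boundaries are inclusive.
#'
#' @param gantry_angle Angle in degrees (any real; normalized mod 360).
#' @return `"lateral"` or `"non_lateral"`.
#' @export
classify_region <- function(gantry_angle) {
  a <- gantry_angle %% 360
  if ((a >= 50 && a <= 130) || (a >= 230 && a <= 310)) "lateral"
  else "non_lateral"
}

#' Read/write a geometry configuration
#'
#' JSON round-trip of the scalar geometry parameters (mm / px / deg).
#'
#' @param path File path.
#' @return For `read_geometry_config`, a named list of parameters suitable
#'   for [view_geometry()] via `do.call`.
#' @export
read_geometry_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  keep <- intersect(names(cfg), c("sad", "sid", "isocenter_pixel_size",
                                  "width", "height", "imager2_offset_deg"))
  cfg[keep]
}

#' @rdname read_geometry_config
#' @param cfg Named list of geometry parameters.
#' @export
write_geometry_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pair of views at one frame
#'
#' Convenience constructor for the two orthogonal imagers at a common gantry
#' angle.
#'
#' @param gantry_angle Gantry angle of imager 1, degrees.
#' @param ... Passed to [view_geometry()].
#' @return List of two `view_geometry` objects.
#' @export
view_pair <- function(gantry_angle, ...) {
  list(view_geometry(gantry_angle, imager = 1L, ...),
       view_geometry(gantry_angle, imager = 2L, ...))
}
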