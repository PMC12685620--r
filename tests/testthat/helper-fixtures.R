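# Shared fixtures and independent oracles for the test suite.

# Random room points within +/- bound mm of the isocenter.
random_points <- function(n, bound = 150) {
  matrix(stats::runif(3 * n, -bound, bound), ncol = 3)
}

# Brute-force zero-mean NCC oracle: scans every placement of tmpl inside img
# (matrices, rows = v), returning argmax apex (0-based, apex offset au/av)
# and gamma. Iterates v outer / u inner with strict > so ties break to
# smallest v then smallest u, the package's documented convention.
ncc_oracle <- function(img, tmpl, au, av) {
  th <- nrow(tmpl); tw <- ncol(tmpl)
  tc <- tmpl - mean(tmpl)
  sst <- sum(tc^2)
  best <- -2; bu <- NA; bv <- NA
  for (r0 in 0:(nrow(img) - th)) {
    for (c0 in 0:(ncol(img) - tw)) {
      patch <- img[r0 + seq_len(th), c0 + seq_len(tw)]
      pc <- patch - mean(patch)
      den <- sqrt(sum(pc^2) * sst)
      if (den == 0) next
      g <- sum(pc * tc) / den
      if (g > best) { best <- g; bu <- c0 + au; bv <- r0 + av }
    }
  }
  list(u = bu, v = bv, gamma = best)
}

# Sub-pixel apex locator for rendered dome images: per column, the v of the
# largest |dI/dv| refined by a parabolic fit; the apex column minimizes the
# boundary v, again refined parabolically.
locate_apex_oracle <- function(px, polarity = c("inverted", "raw")) {
  polarity <- match.arg(polarity)
  if (polarity == "raw") px <- -px
  h <- nrow(px); w <- ncol(px)
  vb <- numeric(w)
  for (cc in seq_len(w)) {
    g <- diff(px[, cc])
    i <- which.max(g)
    if (i > 1 && i < length(g)) {
      y0 <- g[i - 1]; y1 <- g[i]; y2 <- g[i + 1]
      den <- y0 - 2 * y1 + y2
      off <- if (abs(den) > 1e-15) 0.5 * (y0 - y2) / den else 0
    } else off <- 0
    vb[cc] <- (i - 1) + 0.5 + off   # gradient between samples i-1 and i (0-based)
  }
  # the boundary is nearly flat in u near the apex, so locate the apex
  # column by a least-squares parabola over a wide window around the
  # (smoothed) minimum rather than by pointwise argmin
  sm <- stats::filter(vb, rep(1 / 9, 9), sides = 2)
  j0 <- which.min(ifelse(is.na(sm), Inf, sm))
  win <- max(1, j0 - 100):min(w, j0 + 100)
  uu <- win - 1
  fit <- stats::lm(vb[win] ~ uu + I(uu^2))
  cf <- stats::coef(fit)
  u_hat <- -cf[2] / (2 * cf[3])
  v_hat <- cf[1] + cf[2] * u_hat + cf[3] * u_hat^2
  c(u = unname(u_hat), v = unname(v_hat))
}

# Centroid-of-dark-disc oracle: intensity-weighted centroid of (max - I)
# inside a box around the expected position.
dark_disc_centroid <- function(px, u_about, v_about, half = 8) {
  uu <- max(0, round(u_about) - half):min(ncol(px) - 1, round(u_about) + half)
  vv <- max(0, round(v_about) - half):min(nrow(px) - 1, round(v_about) + half)
  blk <- px[vv + 1, uu + 1]
  wts <- max(blk) - blk
  c(u = sum(outer(rep(1, length(vv)), uu) * wts) / sum(wts),
    v = sum(outer(vv, rep(1, length(uu))) * wts) / sum(wts))
}

# Small, fast image-tracked session config shared by pipeline tests.
small_image_config <- function(seed = 11, scenarios = "S_var", ...) {
  session_config(duration_s = 12, training_s = 6, evaluation_s = 6,
                 scenarios = scenarios,
                 resp = respiratory_config(period_s = 4),
                 anatomy = anatomy_config(asynchrony_SI_amplitude_mm = 6.1),
                 tracking = "image", seed = seed, ...)
}

expect_room_near <- function(p, q, tol = 1e-9) {
  expect_lt(sqrt(sum((unclass(p) - unclass(q))^2)), tol)
}

# Small synthetic projection_image (dims free of the 768x1024 default so
# unit tests stay cheap).
tiny_image <- function(px, markers = list()) {
  g <- view_geometry(0, 1, width = ncol(px), height = nrow(px))
  projection_image(px, g, known_marker_pixels = markers)
}

# Small template constructor bypassing the 199x299 production dims, for
# cheap NCC unit tests.
diaphragm_template_small <- function(px, au, av) {
  structure(list(pixels = px, view_angle_deg = 0,
                 apex_offset = pixel_coord(au, av)),
            class = "diaphragm_template")
}
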