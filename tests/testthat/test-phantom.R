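test_that("clean respiratory signal is exactly periodic and deterministic", {
  cfg <- respiratory_config(period_s = 4, amplitude_mm = 10)
  sig <- simulate_respiration(cfg, duration_s = 20, dt_s = 0.2)
  per <- 4 / 0.2
  expect_lt(max(abs(sig$p_mm[1:(101 - per)] - sig$p_mm[(per + 1):101])), 1e-12)
  expect_true(all(sig$p_mm >= 0 & sig$p_mm <= 10 + 1e-12))
  # troughs (end-expiration) dwell longer than peaks for n > 1
  expect_gt(mean(sig$depth < 0.1), mean(sig$depth > 0.9))

  cfgn <- respiratory_config(noise_sd_mm = 0.3, seed = 7)
  s1 <- simulate_respiration(cfgn, 70, 0.2)
  s2 <- simulate_respiration(cfgn, 70, 0.2)
  expect_identical(s1$p_mm, s2$p_mm)
  s3 <- simulate_respiration(respiratory_config(noise_sd_mm = 0.3, seed = 8), 70, 0.2)
  expect_false(identical(s1$p_mm, s3$p_mm))
  expect_error(respiratory_config(period_s = 0), "BadConfig")
})

test_that("cardiac pulsation produces a spectral peak at its frequency", {
  cfg <- respiratory_config(period_s = 4, amplitude_mm = 10,
                            pulsation_amplitude_mm = 0.5,
                            pulsation_freq_hz = 1.2)
  sig <- simulate_respiration(cfg, 70, 0.2)
  n <- nrow(sig)
  sp <- Mod(stats::fft(sig$p_mm - mean(sig$p_mm)))[1:(n %/% 2)]
  freqs <- (seq_len(n %/% 2) - 1) / (n * 0.2)
  band <- which(freqs > 1.05 & freqs < 1.35)
  peak_f <- freqs[band[which.max(sp[band])]]
  expect_lt(abs(peak_f - 1.2), 0.05)
  # and that peak is a local maximum against the flanks outside the band
  flank <- which((freqs > 0.85 & freqs < 1.0) | (freqs > 1.4 & freqs < 1.6))
  expect_gt(max(sp[band]), 3 * max(sp[flank]))
})

test_that("irregularity events pause, deepen and rescale the waveform", {
  ev_pause <- list(list(type = "pause", start_s = 10, duration_s = 4))
  cfg <- respiratory_config(irregularity_events = ev_pause)
  sig <- simulate_respiration(cfg, 30, 0.2)
  sel <- sig$time_s >= 10 & sig$time_s <= 14
  expect_lt(diff(range(sig$depth[sel])), 1e-12)           # frozen
  ref <- simulate_respiration(respiratory_config(), 30, 0.2)
  expect_equal(sig$depth[sig$time_s < 10], ref$depth[ref$time_s < 10])

  ev_amp <- list(list(type = "amplitude_shift", start_s = 8, duration_s = 20,
                      scale = 0.5))
  siga <- simulate_respiration(respiratory_config(irregularity_events = ev_amp),
                               30, 0.2)
  expect_lt(max(siga$depth[siga$time_s > 10 & siga$time_s < 26]), 0.55)

  ev_deep <- list(list(type = "deep_breath", start_s = 8, duration_s = 4,
                       scale = 1.8))
  sigd <- simulate_respiration(respiratory_config(irregularity_events = ev_deep),
                               30, 0.2)
  expect_gt(max(sigd$depth), 1.5)
  expect_lt(max(sigd$depth[sigd$time_s > 16]), 1 + 1e-9)
})

test_that("synchronous anatomy keeps tumor and apex displacements proportional", {
  cfg <- anatomy_config(coupling_mm = c(0, 0, -7.5), apex_SI_excursion_mm = -15,
                        hysteresis_lag_s = 0, asynchrony_SI_amplitude_mm = 0)
  sig <- simulate_respiration(respiratory_config(), 20, 0.2)
  tr <- simulate_anatomy(sig, cfg)
  d_apex <- tr$apex_z_mm - tr$apex_z_mm[1]
  d_tum <- tr$tumor_z_mm - tr$tumor_z_mm[1]
  expect_equal(d_tum, 0.5 * d_apex, tolerance = 1e-12)
})

test_that("asynchrony amplitude is reproduced exactly between extreme phases", {
  cfg <- anatomy_config(coupling_mm = c(0, 0, -15), apex_SI_excursion_mm = -15,
                        asynchrony_SI_amplitude_mm = 6.1, hysteresis_lag_s = 0)
  sig <- simulate_respiration(respiratory_config(period_s = 4), 20, 0.2)
  tr <- simulate_anatomy(sig, cfg)
  i_ex <- which(tr$time_s == 0)        # depth 0
  i_in <- which(tr$time_s == 2)        # depth 1
  res <- asynchrony_residual(
    c(tr$apex_x_mm[i_ex], tr$apex_y_mm[i_ex], tr$apex_z_mm[i_ex]),
    c(tr$apex_x_mm[i_in], tr$apex_y_mm[i_in], tr$apex_z_mm[i_in]),
    c(tr$tumor_x_mm[i_ex], tr$tumor_y_mm[i_ex], tr$tumor_z_mm[i_ex]),
    c(tr$tumor_x_mm[i_in], tr$tumor_y_mm[i_in], tr$tumor_z_mm[i_in]))
  expect_equal(res, 6.1, tolerance = 1e-9)
})

test_that("marker constellation rides rigidly on the tumor", {
  cfg <- anatomy_config(n_markers = 3)
  sig <- simulate_respiration(respiratory_config(), 10, 0.2)
  tr <- simulate_anatomy(sig, cfg)
  offs <- do.call(rbind, cfg$marker_offsets_mm)
  for (i in c(1, 17, 51)) {
    mk <- do.call(rbind, lapply(seq_len(3), function(k)
      c(tr[[sprintf("marker%d_x_mm", k)]][i], tr[[sprintf("marker%d_y_mm", k)]][i],
        tr[[sprintf("marker%d_z_mm", k)]][i])))
    tum <- c(tr$tumor_x_mm[i], tr$tumor_y_mm[i], tr$tumor_z_mm[i])
    expect_equal(colMeans(mk), tum + colMeans(offs), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # single marker with zero offset collapses onto the tumor
  cfg1 <- anatomy_config(n_markers = 1, marker_offsets_mm = list(c(0, 0, 0)))
  tr1 <- simulate_anatomy(sig, cfg1)
  expect_equal(tr1$marker1_z_mm, tr1$tumor_z_mm)
})

test_that("model-consistent mode makes the tumor an exact quadratic in (p, p_dot)", {
  cfg <- anatomy_config(mode = "model_consistent")
  sig <- simulate_respiration(respiratory_config(noise_sd_mm = 0.1, seed = 3),
                              30, 0.2)
  tr <- simulate_anatomy(sig, cfg)
  qc <- apextrack:::default_quad_coefs(cfg, 10)
  X <- cbind(sig$p_mm^2, sig$p_mm, 1, sig$p_dot^2, sig$p_dot)
  expect_equal(tr$tumor_z_mm, as.numeric(X %*% qc[, 3]), tolerance = 1e-12)
})

test_that("gantry angle advances at constant angular velocity over the arcs", {
  a_cw <- arc_angles(session_arc(330, 75, "cw"), 351)
  steps <- diff(a_cw) %% 360
  expect_equal(unique(round(steps, 9)), 0.3)          # 105 deg / 350 frames
  expect_equal(a_cw[1], 330); expect_equal(a_cw[351], 75)
  a_ccw <- arc_angles(session_arc(30, 285, "ccw"), 351)
  expect_equal(a_ccw[1], 30); expect_equal(a_ccw[351], 285)
  expect_equal(unique(round(-diff(a_ccw) %% 360, 9)), 0.3)
})

test_that("rendered frames place the dome apex and markers at their projections", {
  g <- view_geometry(12, 1)
  apex <- room_point(-40, 10, -6)
  mk <- list(room_point(-30, 20, 40), room_point(-22, 14, 35))
  fr <- render_frame(g, apex, mk, polarity = "inverted")
  qa <- project_point(g, apex)
  hat <- locate_apex_oracle(fr$pixels)
  expect_lt(abs(hat["u"] - qa[["u"]]), 0.5)
  expect_lt(abs(hat["v"] - qa[["v"]]), 0.5)
  for (k in seq_along(mk)) {
    qm <- project_point(g, mk[[k]])
    cen <- dark_disc_centroid(fr$pixels, qm[["u"]], qm[["v"]])
    expect_lt(abs(cen["u"] - qm[["u"]]), 0.5)
    expect_lt(abs(cen["v"] - qm[["v"]]), 0.5)
  }
  expect_length(fr$known_marker_pixels, 2)
  # determinism with noise
  f1 <- render_frame(g, apex, mk, noise_sd = 0.02, seed = 5)
  f2 <- render_frame(g, apex, mk, noise_sd = 0.02, seed = 5)
  expect_identical(f1$pixels, f2$pixels)
  expect_error(render_frame(g, room_point(0, 0, -300)), "ApexOutsideImage")
})

test_that("template bank covers the arc at 0.3 deg with centred apexes", {
  cfg <- anatomy_config()
  bank <- render_templates(cfg, arc = session_arc(330, 75, "cw"),
                           angle_step_deg = 0.3, imager = 1)
  expect_length(bank, 351)
  tm <- bank[[100]]
  expect_identical(dim(tm$pixels), c(199L, 299L))
  expect_equal(unname(tm$apex_offset[["u"]]), 149)
  expect_equal(unname(tm$apex_offset[["v"]]), 99)
  hat <- locate_apex_oracle(tm$pixels)
  expect_lt(abs(hat["u"] - 149), 0.5)
  expect_lt(abs(hat["v"] - 99), 0.5)
  # adjacent-angle templates show < 2 px apparent apex shift
  h1 <- locate_apex_oracle(bank[[100]]$pixels)
  h2 <- locate_apex_oracle(bank[[101]]$pixels)
  expect_lt(sqrt(sum((h1 - h2)^2)), 2)
  # nearest-angle selection with ties to the lower angle
  expect_equal(select_template(bank, 0.05)$view_angle_deg, 0)
  expect_equal(select_template(bank, 0.15)$view_angle_deg, 0)
  expect_equal(select_template(bank, 0.2)$view_angle_deg, 0.3)
})
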