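test_that("velocity estimation is exact for linear signals and accurate for sinusoids", {
  t <- seq(0, 10, by = 0.2)
  expect_equal(estimate_velocity(4 * t, 0.2), rep(4, length(t)))
  expect_equal(estimate_velocity(4 * t, 0.2, smooth_window = 3), rep(4, length(t)))
  expect_equal(estimate_velocity(rep(2.5, 50), 0.2), rep(0, 50))

  p <- sin(2 * pi * t / 4)
  v <- estimate_velocity(p, 0.2)
  v_true <- (2 * pi / 4) * cos(2 * pi * t / 4)
  interior <- 2:(length(t) - 1)
  # second-order truncation error of the central difference is
  # (omega^2 h^2) / 6 ~ 1.65% of max|p'| at this period and sampling
  expect_lt(max(abs(v[interior] - v_true[interior])), 0.017 * max(abs(v_true)))
  expect_error(estimate_velocity(c(1, 2), 0.2), "TooShort")
})

test_that("extrema detection returns the final trough and peak of the window", {
  t <- seq(0, 25, by = 0.2)
  sig <- data.frame(time_s = t, p_mm = sin(2 * pi * t / 4))
  ex <- detect_extrema(sig, window = c(0, 20))
  expect_lt(abs(ex$t_in - 17), 0.1 + 1e-12)   # last peak at t = 17
  expect_lt(abs(ex$t_ex - 19), 0.1 + 1e-12)   # last trough at t = 19
  expect_equal(ex$p_in, max(sig$p_mm), tolerance = 1e-3)

  ramp <- data.frame(time_s = t, p_mm = 0.3 * t)
  expect_error(detect_extrema(ramp, c(0, 20)), "NoCycle")

  # small pulsation below the prominence threshold leaves extrema unchanged
  sig2 <- sig
  sig2$p_mm <- sig2$p_mm + 0.05 * sin(2 * pi * 1.2 * t)
  ex2 <- detect_extrema(sig2, window = c(0, 20))
  expect_lt(abs(ex2$t_in - ex$t_in), 0.21)
  expect_lt(abs(ex2$t_ex - ex$t_ex), 0.21)
})

test_that("offset models reproduce constant and variable apex-tumor offsets", {
  t <- seq(0, 20, by = 0.2)
  sig <- simulate_respiration(respiratory_config(period_s = 4), 20, 0.2)
  apex <- cbind(0 * t, 0 * t, -15 * sig$depth)
  ex <- detect_extrema(sig, c(0, 20))

  # tumor = apex + constant vector: S_con and S_var coincide at every p
  tum_c <- apex + matrix(c(3, -2, 10), length(t), 3, byrow = TRUE)
  m_con <- build_offset_model("S_con", apex, tum_c, sig, ex)
  m_var <- build_offset_model("S_var", apex, tum_c, sig, ex)
  est_c <- estimate_tumor(m_con, apex, sig$p_mm)
  est_v <- estimate_tumor(m_var, apex, sig$p_mm)
  expect_equal(est_c, est_v, tolerance = 1e-12)
  # SI follows the per-frame apex; LR/AP stay at the end-expiratory anchor
  expect_equal(est_c[, 3], apex[, 3] + 10, tolerance = 1e-12)
  expect_equal(unique(round(est_c[, 1], 12)), apex[ex$idx_ex, 1] + 3)

  # S_no passes the observed tumor through
  m_no <- build_offset_model("S_no")
  expect_identical(estimate_tumor(m_no, apex, sig$p_mm, tumor = tum_c), tum_c)

  # asynchronous phantom: |s_in - s_ex| in SI equals the built-in amplitude
  cfgA <- anatomy_config(coupling_mm = c(0, 0, -15), apex_SI_excursion_mm = -15,
                         asynchrony_SI_amplitude_mm = 6, hysteresis_lag_s = 0)
  tr <- simulate_anatomy(sig, cfgA)
  apexA <- cbind(tr$apex_x_mm, tr$apex_y_mm, tr$apex_z_mm)
  tumA <- cbind(tr$tumor_x_mm, tr$tumor_y_mm, tr$tumor_z_mm)
  mA <- build_offset_model("S_var", apexA, tumA, sig, ex)
  expect_equal(abs(mA$s_in[3] - mA$s_ex[3]), 6, tolerance = 1e-9)

  # S_var on the Eq.(1)-consistent phantom with noise-free apex: exact
  estA <- estimate_tumor(mA, apexA, sig$p_mm)
  expect_lt(max(abs(estA[, 3] - tumA[, 3])), 1e-9)

  # S_con on the asynchronous phantom at p = p_in: SI error = |s_in - s_ex|
  mAc <- build_offset_model("S_con", apexA, tumA, sig, ex)
  estAc <- estimate_tumor(mAc, apexA, sig$p_mm)
  expect_equal(unname(abs(estAc[ex$idx_in, 3] - tumA[ex$idx_in, 3])),
               abs(mA$s_in[3] - mA$s_ex[3]), tolerance = 1e-9)
})

test_that("the variable offset is affine in p with exact endpoints", {
  m <- structure(list(scenario = "S_var", clamp = FALSE,
                      s_ex = c(1, -2, 3), s_in = c(2, 0, -4),
                      p_ex = 0.5, p_in = 9.5, apex_ex = c(0, 0, 0)),
                 class = "offset_vector_model")
  expect_identical(offset_at_phase(m, m$p_in), m$s_in)
  expect_identical(offset_at_phase(m, m$p_ex), m$s_ex)
  expect_equal(offset_at_phase(m, (m$p_in + m$p_ex) / 2),
               (m$s_in + m$s_ex) / 2, tolerance = 1e-15)
  # affinity: second differences vanish
  s <- offset_at_phase(m, c(1, 2, 3))
  expect_equal(s[3, ] - s[2, ], s[2, ] - s[1, ], tolerance = 1e-12)
  m$p_in <- m$p_ex
  expect_error(offset_at_phase(m, 1), "DegenerateBreathingRange")
  # clamping caps extrapolation when enabled
  m2 <- structure(list(scenario = "S_var", clamp = TRUE,
                       s_ex = c(0, 0, 0), s_in = c(0, 0, 10),
                       p_ex = 0, p_in = 10, apex_ex = c(0, 0, 0)),
                  class = "offset_vector_model")
  expect_equal(offset_at_phase(m2, 15), c(0, 0, 10))
})

test_that("closed-form 4DM fit recovers known coefficients exactly", {
  set.seed(7)
  t <- seq(0, 19.8, by = 0.2)
  p <- 5 + 4 * sin(2 * pi * t / 3.7) + stats::runif(length(t), -0.5, 0.5)
  pd <- estimate_velocity(p, 0.2)
  sig <- data.frame(time_s = t, p_mm = p, p_dot = pd)
  truth_coef <- c(a = 0.5, b = -1.2, c = 3.0, d = 0.2, e = -0.4)
  y <- truth_coef["a"] * p^2 + truth_coef["b"] * p + truth_coef["c"] +
    truth_coef["d"] * pd^2 + truth_coef["e"] * pd
  fit <- fit_4dm(sig, cbind(y, y, y), window = c(0, 20))
  for (k in 1:3)
    expect_equal(unname(fit$coef[, k]), unname(truth_coef), tolerance = 1e-8)
  expect_false(fit$rank_deficient)

  # constant tumor coordinate -> (0, 0, c, 0, 0)
  fit_c <- fit_4dm(sig, cbind(rep(7, length(t)), 0 * t, 0 * t), c(0, 20))
  expect_equal(unname(fit_c$coef[, 1]), c(0, 0, 7, 0, 0), tolerance = 1e-8)

  # residual orthogonality to all five regressors (normal equations)
  yn <- y + stats::rnorm(length(t), 0, 0.5)
  fit_n <- fit_4dm(sig, cbind(yn, yn, yn), c(0, 20))
  X <- cbind(p^2, p, 1, pd^2, pd)
  r <- yn - as.numeric(X %*% fit_n$coef[, 1])
  expect_lt(max(abs(crossprod(X, r))) / max(abs(crossprod(X, yn))), 1e-8)

  expect_error(fit_4dm(sig[1:4, ], cbind(y, y, y)[1:4, ], c(0, 20)),
               "TooFewSamples")
})

test_that("rank-deficient designs are flagged and still reproduce in-sample", {
  t <- seq(0, 20, by = 0.2)
  p <- seq(1, 3, length.out = length(t))   # p_dot constant
  sig <- data.frame(time_s = t, p_mm = p,
                    p_dot = rep(0, length(t)))
  y <- 2 * p + 1
  fit <- fit_4dm(sig, cbind(y, y, y), c(0, 20))
  expect_true(fit$rank_deficient)
  pred <- predict_4dm(fit, sig$p_mm, sig$p_dot)
  expect_equal(unname(pred[, 1]), unname(y), tolerance = 1e-8)
})

test_that("4DM prediction evaluates the quadratic form", {
  m <- structure(list(coef = matrix(c(0, 0, 4.2, 0, 0), 5, 3,
                                    dimnames = list(c("a", "b", "c", "d", "e"),
                                                    c("x", "y", "z"))),
                      rank = 5L, rank_deficient = FALSE),
                 class = "correlation_model")
  expect_equal(unname(predict_4dm(m, c(0, 5, -3), c(1, 0, 2))[, 2]),
               rep(4.2, 3))
  # hand case: (1,2,3,4,5) at p = 2, p_dot = 1 -> 4 + 4 + 3 + 4 + 5 = 20
  m$coef[, 1] <- 1:5
  expect_equal(unname(predict_4dm(m, 2, 1)[1, 1]), 20)
})

test_that("models serialize to JSON and read back consistently", {
  t <- seq(0, 20, by = 0.2)
  sig <- simulate_respiration(respiratory_config(), 20, 0.2)
  apex <- cbind(0 * t, 0 * t, -15 * sig$depth)
  tum <- apex + matrix(c(1, 2, 3), length(t), 3, byrow = TRUE)
  ex <- detect_extrema(sig, c(0, 20))
  off <- build_offset_model("S_var", apex, tum, sig, ex)
  fit <- fit_4dm(sig, tum, c(0, 20))
  path <- tempfile(fileext = ".json")
  write_models_json(off, fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$offset$s_ex, off$s_ex)
  expect_equal(unname(as.matrix(back$fourdm$coef)), unname(fit$coef),
               tolerance = 1e-12)
})
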