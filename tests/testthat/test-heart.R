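test_that("the activation function has the printed shape and is continuous", {
  expect_equal(activation_sigma(0), 0)
  expect_equal(activation_sigma(0.4), 0) # diastole starts exactly at t_s
  expect_equal(activation_sigma(0.2), 2) # peak of 1 - cos at t_s/2
  expect_equal(activation_sigma(0.1), 1) # quarter systole
  expect_equal(activation_sigma(0.9), activation_sigma(0)) # periodic
  expect_equal(activation_sigma(0.2, half = TRUE), 1)
  # continuity at the systole/diastole transition
  eps <- 1e-8
  expect_lt(abs(activation_sigma(0.4 - eps) - activation_sigma(0.4 + eps)),
            1e-6)
})

test_that("ventricular pressure follows the elastance model in both phases", {
  vl <- ventricle_params("left")
  vol <- default_volume_model("left")
  t_dia <- 0.6
  expect_equal(ventricular_pressure(t_dia, vl, vol),
               vl$Ed * (vol$V(t_dia) - vl$V0))

  t <- seq(0, 0.9, length.out = 3000)[-3000]
  pl <- ventricular_pressure(t, vl, vol)
  expect_gt(max(pl), 100)
  expect_lt(max(pl), 140)

  vr <- ventricle_params("right")
  pr <- ventricular_pressure(t, vr, default_volume_model("right"))
  expect_lt(max(pr), max(pl))

  # systolic branch at mid systole: direct formula
  tm <- 0.2
  s <- activation_sigma(tm)
  expect_equal(ventricular_pressure(tm, vl, vol),
               vl$p0 * s + (vl$Ed + vl$Es * s) * (vol$V(tm) - vl$V0) +
                 vl$Rv * vol$dVdt(tm))
})

test_that("feedback pressure is linear with the configured ratios", {
  fp <- feedback_params()
  heart <- list(left = ventricle_params("left"),
                right = ventricle_params("right"))

  expect_equal(terminal_phi("LAD1", fp), 0.22) # septal bed
  expect_equal(terminal_phi("PLA", fp), 0.25)
  expect_equal(terminal_phi("MARG2", fp), 0.33)
  expect_error(terminal_phi("NOPE", fp), "unknown terminal")

  # phi = 0 reduces to the constant bed pressure
  fp0 <- feedback_params(phi_terminal = c(DIAG = 0))
  expect_equal(feedback_pressure(c(0.1, 0.5), "DIAG", fp0, heart),
               c(20, 20))

  # linear in p_v: phi * 100 + 20
  t0 <- 0.21
  pv <- ventricular_pressure(t0, heart$left)
  expect_equal(feedback_pressure(t0, "MARG2", fp, heart), 0.33 * pv + 20)
  expect_equal(0.33 * 100 + 20, 53)

  # linearity in p_s
  fp2 <- feedback_params(p_s = 35)
  expect_equal(feedback_pressure(t0, "MARG2", fp2, heart) -
                 feedback_pressure(t0, "MARG2", fp, heart), 15)
})

test_that("the lumped systemic model is physiological and valve flow is non-negative", {
  aw <- aortic_pressure_waveform(systemic_params())
  expect_true(all(aw$q_ao >= 0))
  CO <- attr(aw, "CO")
  expect_gt(CO, 4)
  expect_lt(CO, 7)
  expect_gt(mean(aw$p_a), 85)
  expect_lt(mean(aw$p_a), 110)
  expect_gt(min(aw$p_a), 60)
  expect_lt(max(aw$p_a), 140)
})

test_that("the inlet calibration hits the configured coronary fraction", {
  heart <- list(left = ventricle_params("left"),
                right = ventricle_params("right"))
  n <- 512
  t <- (0:(n - 1)) * 0.9 / n
  fake_dc <- list(
    L = list(R_eff = 2.5e4, P_eff = 25 + 10 * activation_sigma(t)),
    R = list(R_eff = 8e4, P_eff = 22 + 5 * activation_sigma(t))
  )
  for (mode in c("flow", "pressure")) {
    inl <- inlet_waveform(fake_dc, heart, n = n, coronary_fraction = 0.045,
                          mode = mode)
    expect_equal(inl$fraction, 0.045, tolerance = 0.001)
    expect_length(inl$q, 2)
  }

  # intramyocardial windkessel preserves the mean (DC) flow
  pa <- 95 + 15 * sin(2 * pi * t / 0.9)
  pb <- 30 + 20 * activation_sigma(t)
  q <- coronary_inflow_estimate(pa, pb, 3e4, 0.9)
  expect_equal(mean(q), mmHg_to_cgs(mean(pa) - mean(pb)) / 3e4,
               tolerance = 1e-10)
})
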