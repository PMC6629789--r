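wallw <- list(k1 = 2e7, k2 = -22.5, k3 = 8.65e5)

test_that("pulse wave velocity follows the tube law algebra", {
  r0 <- 0.15
  A0 <- pi * r0^2
  cp0 <- pulse_wave_velocity(A0, r0, wallw)
  Ehr <- wall_stiffness(r0, wallw)
  expect_equal(cp0, sqrt(2 * Ehr / (3 * 1.055 * 1)), tolerance = 1e-12)

  # doubling Eh scales c_p at A0 by sqrt(2)
  wall2 <- list(k1 = 2 * wallw$k1, k2 = wallw$k2, k3 = 2 * wallw$k3)
  expect_equal(pulse_wave_velocity(A0, r0, wall2) / cp0, sqrt(2),
               tolerance = 1e-12)

  # with this tube law c_p decreases with distension (A dp/dA ~ A^{-1/2})
  A <- seq(0.5, 2, length.out = 30) * A0
  cps <- pulse_wave_velocity(A, r0, wallw)
  expect_true(all(diff(cps) < 0))
  expect_equal(cps, cp0 * (A0 / A)^(1 / 4), tolerance = 1e-12)
})

test_that("the decomposition is exactly additive and sign-definite", {
  set.seed(42)
  n <- 300
  t <- seq(0, 0.9, length.out = n)
  p <- 95 + 12 * sin(2 * pi * t / 0.9) + 3 * sin(4 * pi * t / 0.9 + 1)
  u <- 12 + 6 * sin(2 * pi * t / 0.9 - 0.7)
  cp <- 900 + 50 * cos(2 * pi * t / 0.9)
  dec <- wia_decompose(p, u, cp, t)

  expect_equal(dec$dp_plus + dec$dp_minus, dec$dp, tolerance = 1e-12)
  expect_equal(dec$du_plus + dec$du_minus, dec$du, tolerance = 1e-12)
  expect_true(all(dec$wi_plus >= 0))
  expect_true(all(dec$wi_minus <= 0))
  expect_true(all(dec$wi_plus * dec$wi_minus <= 0))
  expect_equal(dec$wi_net, dec$wi_plus + dec$wi_minus, tolerance = 1e-12)

  # constant velocity: pressure splits evenly
  dec2 <- wia_decompose(p, rep(5, n), cp, t)
  expect_equal(dec2$dp_plus, dec2$dp / 2, tolerance = 1e-12)
  expect_equal(dec2$dp_minus, dec2$dp / 2, tolerance = 1e-12)

  expect_error(wia_decompose(p, u[-1], cp[-1], t[-1]), "equal length")
})

test_that("synthetic waveforms are recovered exactly", {
  fw <- make_synthetic_waveforms("forward_pulse", n = 256, seed = 3)
  dec <- wia_decompose(fw$p, fw$u, fw$c_p, fw$t, rho = fw$rho)
  expect_lt(max(abs(dec$dp_minus)), 1e-10 * max(abs(dec$dp_plus)))
  expect_lt(max(abs(dec$du_minus)), 1e-12 * max(abs(dec$du_plus)))

  bw <- make_synthetic_waveforms("backward_pulse", n = 256, seed = 4)
  decb <- wia_decompose(bw$p, bw$u, bw$c_p, bw$t, rho = bw$rho)
  expect_lt(max(abs(decb$dp_plus)), 1e-10 * max(abs(decb$dp_minus)))

  mx <- make_synthetic_waveforms("mixed", n = 512, seed = 5, mix = 0.7)
  decm <- wia_decompose(mx$p, mx$u, mx$c_p, mx$t, rho = mx$rho)
  expect_equal(decm$du_plus, diff(mx$u_fwd), tolerance = 1e-12)
  expect_equal(decm$du_minus, diff(mx$u_bwd), tolerance = 1e-12)

  # minimal length runs
  expect_silent(make_synthetic_waveforms("forward_pulse", n = 16))
  expect_error(make_synthetic_waveforms("mixed", n = 8), "n >= 16")
})

test_that("a single forward compression pulse segments as one FCW at 100%", {
  # a compression wavefront: monotone pressure/velocity rise carried
  # forward (the back of a symmetric pulse would itself be an FDW)
  n <- 512
  t <- seq(0, 0.9, length.out = n)
  u <- 10 * pnorm(t, mean = 0.2, sd = 0.03)
  p <- 80 + cgs_to_mmHg(1.055 * 1000 * u)
  dec <- wia_decompose(p, u, rep(1000, n), t)
  sw <- suppressWarnings(segment_six_waves(dec, t_s = 0.4))
  expect_equal(nrow(sw), 1)
  expect_equal(sw$type, "FCW")
  expect_equal(sw$percent, 100)
})

test_that("six-wave percentages are normalised and the table is deterministic", {
  sw <- baseline_scenario()$six_waves
  expect_equal(sum(sw$percent), 100, tolerance = 1e-9)
  expect_true(all(sw$type %in% c("FCW", "BCW", "FDW", "BDW")))
  # labels' direction matches their type letter
  expect_true(all(substr(sw$type, 1, 1) ==
                  ifelse(sw$wave %in% c("b", "d", "f"), "F", "B")))

  et <- energy_table(list(one = sw, two = sw))
  expect_equal(et$one_pct, et$two_pct)
  expect_true(all(c("davies_pct", "lee_pct") %in% names(et)))
  expect_equal(nrow(et), 6)
})
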