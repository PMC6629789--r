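# independent power-series evaluation of K = 1 - 2 J1(z)/(z J0(z)),
# z = i^{3/2} w0, valid for moderate w0
series_womersley_K <- function(omega, r0, vp) {
  w0 <- r0 * sqrt(omega * vp$rho / vp$mu)
  z <- w0 * exp(1i * 3 * pi / 4)
  J <- function(nu, z) {
    s <- 0 + 0i
    for (m in 0:80) {
      s <- s + (-1)^m * (z / 2)^(2 * m + nu) / (factorial(m) * gamma(m + nu + 1))
    }
    s
  }
  1 - 2 * J(1, z) / (z * J(0, z))
}

test_that("the Womersley factor matches an independent Bessel series and its limits", {
  vp <- small_vessel_params()
  K <- womersley_factor(2 * pi / 0.9, 0.05, vp)
  expect_lt(Mod(K - series_womersley_K(2 * pi / 0.9, 0.05, vp)), 1e-10)

  # several radii/frequencies in the continued-fraction regime
  for (r0 in c(0.002, 0.02, 0.1)) {
    for (k in c(1, 7, 40)) {
      om <- 2 * pi * k / 0.9
      expect_lt(Mod(womersley_factor(om, r0, vp) -
                    series_womersley_K(om, r0, vp)), 1e-10)
    }
  }

  # inviscid limit K -> 1; viscous limit K -> i w0^2 / 8
  Kbig <- womersley_factor(2 * pi * 5000 / 0.9, 0.15, vp)
  expect_lt(Mod(Kbig - 1), 0.01)
  w0 <- 1e-3
  Ksmall <- corowave:::cw_womersley_K(w0)
  expect_lt(Mod(Ksmall - 1i * w0^2 / 8) / Mod(1i * w0^2 / 8), 1e-4)
  expect_lt(Mod(corowave:::cw_womersley_K(39.99) -
                corowave:::cw_womersley_K(40.01)), 1e-3)

  expect_error(womersley_factor(-1, 0.05, vp), "non-negative")
})

test_that("small-vessel compliance follows the wall law", {
  vp <- small_vessel_params()
  Ehr <- wall_stiffness(0.05, vp)
  expect_equal(Ehr, 2e7 * exp(-22.5 * 0.05) + 8.65e5)
  expect_equal(Ehr, 7.36e6, tolerance = 1e-3)
  expect_equal(compliance(0.05, vp), 3 * pi * 0.05^3 / (2 * 0.05 * Ehr))

  # C scales as r0^3 / Eh: doubling all k's halves C
  vp2 <- small_vessel_params(k1 = 2 * vp$k1, k3 = 2 * vp$k3)
  expect_equal(compliance(0.05, vp2), compliance(0.05, vp) / 2)

  # large-radius limit of the stiffness law
  expect_equal(wall_stiffness(5, vp), vp$k3, tolerance = 1e-10)
})

test_that("the transmission line obeys its algebraic identities", {
  g <- 2e-6 + 3e-7i
  c <- 800 + 40i
  om <- 2 * pi / 0.9
  Zl <- 5e4 + 1e4i

  # short line transmits the load unchanged
  expect_lt(Mod(transmission_line_impedance(Zl, 1e-9, c, g, om) - Zl) / Mod(Zl),
            1e-9)
  # matched load is invariant for any length
  for (l in c(0.01, 0.5, 3)) {
    expect_lt(Mod(transmission_line_impedance(1 / g, l, c, g, om) - 1 / g) /
              Mod(1 / g), 1e-12)
  }
  # half-wavelength invariance (real wave speed)
  creal <- 700 + 0i
  l_half <- pi * Re(creal) / om
  expect_lt(Mod(transmission_line_impedance(Zl, l_half, creal, g, om) - Zl) /
            Mod(Zl), 1e-10)

  expect_error(transmission_line_impedance(Zl, -1, c, g, om), "positive")
})

test_that("a single leaf vessel has the Poiseuille DC impedance", {
  vp <- small_vessel_params()
  p <- structured_tree_params(r_min = 1e-3 * 0.999)
  sp <- root_impedance(1e-3, p, vp, n_harm = 4)
  expect_equal(Re(sp$Z[1]), 8 * vp$mu * (25 * 1e-3) / (pi * 1e-12),
               tolerance = 1e-12)
  expect_equal(Re(sp$Z[1]), 2.99e8, tolerance = 1e-2)
})

test_that("the memoised lattice recursion equals brute-force enumeration", {
  vp <- small_vessel_params()
  p <- structured_tree_params(r_min = 0.031)
  toy <- make_toy_tree(6, 0.05, 0.9, 0.6, 25, r_min = 0.031)
  expect_lte(max(toy$depth), 5)
  om <- 2 * pi * c(1, 3, 10) / 0.9
  Zb <- toy_tree_impedance(toy, vp, c(0, om))
  sp <- root_impedance(0.05, p, vp, n_harm = 10)
  expect_lt(abs(Re(sp$Z[1]) - Re(Zb[1])) / Re(Zb[1]), 1e-12)
  for (k in seq_along(om)) {
    expect_lt(Mod(sp$Z[1 + c(1, 3, 10)[k]] - Zb[1 + k]) / Mod(Zb[1 + k]), 1e-12)
  }
  # DC equivalence against direct series/parallel graph elimination
  expect_lt(abs(toy_tree_dc_resistance(toy, vp$mu) - Re(sp$Z[1])) /
            Re(sp$Z[1]), 1e-12)
})

test_that("a symmetric toy tree satisfies the parallel identity at DC", {
  vp <- small_vessel_params()
  toy <- make_toy_tree(1, 0.05, alpha = 0.7, beta = 0.7, l_rr = 25)
  Rp <- 8 * vp$mu * 25 * 0.05 / (pi * 0.05^4)
  Rd <- 8 * vp$mu * 25 * 0.035 / (pi * 0.035^4)
  expect_equal(toy_tree_dc_resistance(toy, vp$mu), Rp + Rd / 2,
               tolerance = 1e-12)
})

test_that("lowering the radius exponent increases every bed's DC impedance", {
  vp <- small_vessel_params()
  pa <- structured_tree_params(xi = 2.76, derive_from_xi = TRUE)
  pb <- structured_tree_params(xi = 2.4, derive_from_xi = TRUE)
  tree <- split_trifurcation(load_vessel_table(coronary_table1()))
  term <- tree$segments[tree$segments$terminal, ]
  for (r in term$r_dist) {
    expect_gt(root_impedance_dc(r, pb, vp), root_impedance_dc(r, pa, vp))
  }
})

test_that("impedance kernels are real, consistent and invertible", {
  vp <- small_vessel_params()
  p <- structured_tree_params()
  sp <- root_impedance(0.099, p, vp, n_harm = 64)
  kz <- impedance_to_kernel(sp, 128)

  # DC consistency: sum z dt = Z_0
  expect_equal(sum(kz) * attr(kz, "dt"), Re(sp$Z[1]), tolerance = 1e-10)
  # round trip recovers the spectrum (the Nyquist harmonic is stored as
  # its real part, as required for a real kernel)
  Z2 <- kernel_to_spectrum(kz)
  expect_lt(max(Mod(Z2[1:64] - sp$Z[1:64])) / max(Mod(sp$Z)), 1e-10)
  expect_equal(Re(Z2[65]), Re(sp$Z[65]), tolerance = 1e-10)
  expect_equal(Im(Z2[65]), 0)

  # a constant spectrum is a discrete delta (pure resistor)
  spR <- sp
  spR$Z <- rep(1234 + 0i, length(sp$Z))
  kR <- impedance_to_kernel(spR, 128)
  expect_equal(kR[1] * attr(kR, "dt"), 1234, tolerance = 1e-10)
  expect_lt(max(abs(kR[-1])) * attr(kR, "dt"), 1e-9)

  expect_error(impedance_to_kernel(sp, 256), "missing harmonics")
})

test_that("the outlet convolution has the resistor and no-flow limits", {
  kernel <- c(500, rep(0, 63))
  attr(kernel, "dt") <- 0.9 / 64
  q <- c(2, rnorm(63))
  expect_equal(outlet_pressure(q, kernel, p_f = 100),
               500 * 2 * 0.9 / 64 + 100)
  expect_equal(outlet_pressure(rep(0, 64), kernel, p_f = 77), 77)
  expect_error(outlet_pressure(1:3, kernel), "equal length")
})
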