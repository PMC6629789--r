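wall3 <- list(k1 = 2e7, k2 = -22.5, k3 = 8.65e5)

test_that("the tube law is anchored at the reference state and strictly monotone", {
  r0 <- 0.15
  A0 <- pi * r0^2
  tl <- tube_law_pressure(A0, A0, r0, wall3, p0 = 30)
  expect_equal(tl$p, 30)

  f_mmHg <- cgs_to_mmHg(4 / 3 * wall_stiffness(r0, wall3))
  expect_equal(tube_law_pressure(1e6 * A0, A0, r0, wall3, p0 = 30)$p,
               30 + f_mmHg, tolerance = 1e-2)

  A <- seq(0.3, 3, length.out = 400) * A0
  tl2 <- tube_law_pressure(A, A0, r0, wall3)
  expect_true(all(tl2$dp_dA > 0))
  expect_true(all(diff(tl2$p) > 0))
  # analytic derivative against central differences at interval midpoints
  fd <- diff(tl2$p) / diff(A)
  mid <- tube_law_pressure((A[-1] + A[-400]) / 2, A0, r0, wall3)$dp_dA
  expect_equal(fd, mid, tolerance = 1e-4)

  expect_error(tube_law_pressure(-1, A0, r0, wall3), "positive")
})

test_that("a uniform rest state is preserved to machine precision, with and without taper", {
  n <- 25
  # untapered, A = A0
  r0 <- rep(0.12, n)
  A <- pi * r0^2
  out <- lax_wendroff_step(A, rep(0, n), r0, wall3, dx = 0.1, dt = 2e-5,
                           n_steps = 50, p0 = 0)
  expect_equal(out$A, A, tolerance = 1e-14)
  expect_lt(max(abs(out$q)), 1e-10)

  # strongly tapered vessel at constant pressure (hydrostatic balance)
  r0t <- seq(0.15, 0.08, length.out = n)
  A0t <- pi * r0t^2
  f <- 4 / 3 * wall_stiffness(r0t, wall3)
  p_cgs <- mmHg_to_cgs(95 - 27)
  At <- A0t / (1 - p_cgs / f)^2
  outt <- lax_wendroff_step(At, rep(0, n), r0t, wall3, dx = 0.1, dt = 1e-5,
                            n_steps = 50, p0 = 27)
  expect_equal(outt$A, At, tolerance = 1e-13)
  expect_lt(max(abs(outt$q)), 1e-8)
})

test_that("the interior update conserves volume against its own fluxes", {
  n <- 41
  r0 <- rep(0.1, n)
  A0 <- pi * r0^2
  x <- seq(0, 4, length.out = n)
  A <- A0 * (1 + 0.03 * exp(-((x - 2) / 0.5)^2))
  q <- 0.5 * sin(pi * x / 4)
  dx <- x[2] - x[1]
  out <- lax_wendroff_step(A, q, r0, wall3, dx = dx, dt = 1e-5, n_steps = 1)
  lhs <- sum(out$A[2:(n - 1)] - A[2:(n - 1)]) * dx
  rhs <- -1e-5 * (out$qhalf[n - 1] - out$qhalf[1])
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("the junction solver splits symmetric daughters equally at tight residual", {
  # invariants chosen near a physiological state (p ~ 100 mmHg, u ~ 10 cm/s)
  parent <- list(W = 10 - 4 * 967, A0 = pi * 0.15^2,
                 f = 4 / 3 * wall_stiffness(0.15, wall3),
                 p0 = mmHg_to_cgs(28), A = pi * 0.15^2 * 1.05)
  d <- list(W = 1 + 4 * 1251, A0 = pi * 0.11^2,
            f = 4 / 3 * wall_stiffness(0.11, wall3),
            p0 = mmHg_to_cgs(28), A = pi * 0.11^2 * 1.05)
  sol <- junction_solve(parent, d, d)
  expect_lt(sol$residual, 1e-11)
  expect_equal(sol$q[2], sol$q[3], tolerance = 1e-12)
  expect_equal(sol$q[1], sol$q[2] + sol$q[3], tolerance = 1e-9)
  expect_equal(sol$p[1], sol$p[2], tolerance = 1e-6)
  expect_equal(sol$p[1], sol$p[3], tolerance = 1e-6)
})

test_that("a converged run reports tight junction residuals, mass balance and periodicity", {
  run <- baseline_scenario()$run
  gl <- glance(run)
  expect_true(gl$converged)
  expect_lte(gl$cycles, 20)
  expect_lt(gl$max_junction_residual, 1e-10)
  expect_lt(gl$final_dP_mmHg, 0.5)
  expect_lt(gl$cfl_max, 1)
  expect_equal(gl$coronary_fraction, 0.045, tolerance = 0.01)
  # vessel-end flux consistency of the characteristic boundary treatment
  expect_lt(gl$flux_consistency, 0.05)
})

test_that("an Ohmic terminal reproduces p = R q + p_f at the outlet", {
  # single-resistor kernel via the full network machinery: compare the
  # simulated outlet pressure with the algebraic boundary relation
  run <- baseline_scenario()$run
  nm <- "LCX3"
  s <- run_series(run, nm, "outlet")
  kz <- impedance_to_kernel(run$spectra[[nm]], length(run$t))
  pf <- feedback_pressure(run$t, nm, run$feedback, run$heart)
  # convolution of the recorded outlet flow with the kernel (periodic)
  n <- length(run$t)
  conv <- vapply(seq_len(n), function(i) {
    idx <- ((i - seq_len(n)) %% n) + 1
    sum(kz * s$q[idx]) * attr(kz, "dt")
  }, 0)
  expect_lt(max(abs(s$p - (cgs_to_mmHg(conv) + pf))) / diff(range(s$p)), 0.05)
})
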