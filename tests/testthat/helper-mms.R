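# Manufactured-solution machinery for the scheme-order study: smooth
# periodic fields with analytically derived residual forcing for the
# (A, q) system with the adopted tube law on a uniform vessel.
mms_fields <- function(x, t, par) {
  s <- sin(par$k * x); cx <- cos(par$k * x)
  co <- cos(par$w * t); si <- sin(par$w * t)
  A <- par$A0 * (1 + par$a * s * co)
  q <- par$Q * s * si
  list(
    A = A, q = q,
    A_t = -par$A0 * par$a * par$w * s * si,
    A_x = par$A0 * par$a * par$k * cx * co,
    q_t = par$Q * par$w * s * co,
    q_x = par$Q * par$k * cx * si
  )
}

mms_forcing <- function(x, t, par) {
  f <- mms_fields(x, t, par)
  A <- f$A; q <- f$q
  dpdA <- 0.5 * par$f * sqrt(par$A0) / A^1.5
  conv <- (2 * q * f$q_x * A - q^2 * f$A_x) / A^2
  visc <- -2 * pi * par$nu * sqrt(A / pi) * q / (par$delta * A)
  list(
    fA = f$A_t + f$q_x,
    fq = f$q_t + conv + (A / par$rho) * dpdA * f$A_x - visc
  )
}

mms_run <- function(n, par, t_end, cfl = 0.3) {
  dx <- par$L / (n - 1)
  x <- seq(0, par$L, length.out = n)
  c0 <- sqrt(par$f / (2 * par$rho))
  dt <- cfl * dx / (1.2 * c0)
  n_steps <- ceiling(t_end / dt)
  dt <- t_end / n_steps
  xh <- x[-n] + dx / 2

  f0 <- mms_fields(x, 0, par)
  tlev <- (0:n_steps) * dt
  bcA <- vapply(tlev, function(tt) mms_fields(c(0, par$L), tt, par)$A, numeric(2))
  bcq <- vapply(tlev, function(tt) mms_fields(c(0, par$L), tt, par)$q, numeric(2))
  bc <- cbind(bcA[1, ], bcq[1, ], bcA[2, ], bcq[2, ])

  fA_full <- matrix(0, n_steps, n); fq_full <- matrix(0, n_steps, n)
  fA_half <- matrix(0, n_steps, n - 1); fq_half <- matrix(0, n_steps, n - 1)
  for (st in seq_len(n_steps)) {
    tn <- (st - 1) * dt
    ff <- mms_forcing(x, tn, par)
    fA_full[st, ] <- ff$fA; fq_full[st, ] <- ff$fq
    fh <- mms_forcing(xh, tn + dt / 2, par)
    fA_half[st, ] <- fh$fA; fq_half[st, ] <- fh$fq
  }

  r0 <- sqrt(par$A0 / pi)
  out <- lax_wendroff_step(
    f0$A, f0$q, rep(r0, n), par$wall, dx = dx, dt = dt, n_steps = n_steps,
    rho = par$rho, mu = par$nu * par$rho, p0 = 0, delta = par$delta,
    bc = bc,
    forcing = list(fA_full = fA_full, fq_full = fq_full,
                   fA_half = fA_half, fq_half = fq_half))
  ex <- mms_fields(x, t_end, par)
  list(
    errA = sqrt(mean((out$A - ex$A)^2)) / par$A0,
    errq = sqrt(mean((out$q - ex$q)^2)) / max(abs(ex$q))
  )
}

mms_par <- function() {
  wall <- list(k1 = 2e7, k2 = -22.5, k3 = 8.65e5)
  r0 <- 0.1
  list(
    L = 4, k = 2 * pi / 4, w = 2 * pi / 0.05,
    A0 = pi * r0^2, a = 0.02, Q = 0.5,
    f = 4 / 3 * wall_stiffness(r0, wall), wall = wall,
    rho = 1.055, nu = 0.0047 / 1.055,
    delta = sqrt(0.0047 / 1.055 * 0.9 / (2 * pi))
  )
}
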