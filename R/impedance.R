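#' Small-vessel fluid and wall parameters
#'
#' Bundles the quantities the vascular-bed impedance computation needs:
#' blood density and viscosity, the wall-stiffness law coefficients
#' `Eh/r0 = k1 exp(k2 r0) + k3`, and the cardiac period.
#'
#' @param rho blood density, g cm^-3.
#' @param mu blood viscosity, g cm^-1 s^-1.
#' @param k1,k2,k3 wall-law coefficients (CGS: g s^-2 cm^-2, cm^-1,
#'   g s^-2 cm^-1).
#' @param period cardiac period, s.
#' @return object of class `small_vessel_params`.
#' @export
small_vessel_params <- function(rho = 1.055, mu = 0.0047,
                                k1 = 2e7, k2 = -22.5, k3 = 8.65e5,
                                period = 0.9) {
  stopifnot(rho > 0, mu > 0, k1 > 0, k3 > 0, period > 0)
  structure(list(rho = rho, mu = mu, k1 = k1, k2 = k2, k3 = k3,
                 period = period),
            class = "small_vessel_params")
}

#' Wall stiffness Eh/r0 as a function of radius
#'
#' @param r0 vessel radius (cm).
#' @param params a [small_vessel_params()] object (or any list with
#'   `k1`, `k2`, `k3`).
#' @return Eh/r0 in g s^-2 cm^-1 per cm, i.e. dyn cm^-2 scaled by h/r0.
#' @export
wall_stiffness <- function(r0, params) {
  params$k1 * exp(params$k2 * r0) + params$k3
}

#' Womersley viscous factor K
#'
#' Frequency-domain factor in the linearized momentum balance of pulsatile
#' flow in a small vessel: `K = 1 - F_J(w0)` with
#' `F_J = 2 J1(i^{3/2} w0) / (i^{3/2} w0 J0(i^{3/2} w0))` and Womersley
#' number `w0 = r0 sqrt(omega rho / mu)`. `K -> 1` in the inviscid
#' (high-frequency) limit and `K -> i w0^2/8 -> 0` in the viscous limit.
#' The zero-frequency (Poiseuille) branch is handled separately by
#' [root_impedance()], not here.
#'
#' @param omega angular frequency, rad s^-1 (vectorised, `omega > 0`; an
#'   `omega < 0` input is an error).
#' @param r0 vessel radius, cm.
#' @param params a [small_vessel_params()] object.
#' @return complex vector K.
#' @export
womersley_factor <- function(omega, r0, params) {
  if (any(omega < 0)) abort("omega must be non-negative")
  if (r0 <= 0) abort("r0 must be positive")
  w0 <- r0 * sqrt(omega * params$rho / params$mu)
  cw_womersley_K(w0)
}

#' Compliance of a small vessel
#'
#' `C = 3 A0 r0 / (2 E h)` with `A0 = pi r0^2` and `Eh/r0` from the wall
#' law, equivalently `C = 3 pi r0^2 / (2 (k1 exp(k2 r0) + k3))`. This is
#' the local area compliance `dA/dp` of the tube law at the reference state.
#'
#' @param r0 vessel radius, cm.
#' @param params a [small_vessel_params()] object.
#' @return compliance in cm^4 s^2 g^-1 (i.e. cm^2 per (g cm^-1 s^-2)).
#' @export
compliance <- function(r0, params) {
  if (any(r0 <= 0)) abort("r0 must be positive")
  3 * pi * r0^2 / (2 * (params$k1 * exp(params$k2 * r0) + params$k3))
}

#' Input impedance of a lossless transmission line
#'
#' Frequency-domain input impedance of a uniform small vessel of length `l`
#' with complex wave speed `c`, characteristic admittance `g`, loaded by
#' `Z_end` at its distal end:
#' `Z(0) = ((i/g) sin(theta) + Z_end cos(theta)) / (cos(theta) + i g Z_end sin(theta))`
#' with `theta = omega l / c`. A matched load `Z_end = 1/g` is transmitted
#' unchanged for any length.
#'
#' @param Z_end complex distal load impedance.
#' @param l vessel length, cm.
#' @param c complex wave speed, cm s^-1.
#' @param g complex characteristic admittance, cm^4 s g^-1.
#' @param omega angular frequency, rad s^-1.
#' @return complex input impedance.
#' @export
transmission_line_impedance <- function(Z_end, l, c, g, omega) {
  if (any(l <= 0)) abort("l must be positive")
  theta <- omega * l / c
  denom <- cos(theta) + 1i * g * Z_end * sin(theta)
  bad <- Mod(denom) < 1e-300
  if (any(bad)) {
    abort(sprintf("transmission-line resonance at omega = %g, l = %g",
                  omega[which(bad)[1]], l))
  }
  ((1i / g) * sin(theta) + Z_end * cos(theta)) / denom
}

#' Root impedance of a structured-tree vascular bed
#'
#' Computes the complex input impedance `Z(0, omega)` of the self-similar
#' binary tree attached to a terminal large artery, per harmonic of the
#' cardiac frequency. The recursion runs over the radius lattice
#' `(i, j) -> alpha^i beta^j r_root` (memoised: self-similarity makes the
#' lattice position the only state), combining daughters in parallel
#' (`1/Z_p = 1/Z_d1 + 1/Z_d2`) and propagating along each vessel with the
#' transmission-line relation. Vessels whose daughters fall below the
#' minimum radius carry the terminal load `Z_end` (default 0: a pressure
#' reservoir at the bed outlet). At zero frequency the transmission line is
#' replaced by its Poiseuille limit `Z_DC = 8 mu l / (pi r^4)` accumulated
#' through the same tree.
#'
#' @param r_root root radius, cm (distal radius of the terminal artery).
#' @param tree_params a [structured_tree_params()] object.
#' @param vessel_params a [small_vessel_params()] object.
#' @param n_harm number of positive harmonics to compute (frequencies
#'   `2 pi k / period`, k = 0..n_harm).
#' @param Z_terminal terminal load of the smallest vessels: its DC
#'   (Poiseuille-limit) resistance.
#' @param tau_cap time constant (s) of the terminal load: a value `> 0`
#'   models the capillary/venous bed behind each smallest arteriole as a
#'   single-pole windkessel `Z_t(omega) = R_t / (1 + i omega tau_cap)`;
#'   `0` keeps a purely resistive load.
#' @return object of class `impedance_spectrum`: list with `omega`
#'   (length `n_harm + 1`), `Z` (complex, same length, `Z[1]` the real DC
#'   impedance), `period`, `r_root`, and the lattice used.
#' @export
root_impedance <- function(r_root, tree_params, vessel_params,
                           n_harm = 512, Z_terminal = 0 + 0i,
                           tau_cap = 0) {
  if (r_root <= 0) abort("r_root must be positive")
  p <- tree_params
  vp <- vessel_params
  lattice <- structured_tree_radii(r_root, p)
  if (nrow(lattice) == 0) abort("r_root at or below r_min: empty vascular bed")
  omega <- 2 * pi * (1:n_harm) / vp$period

  # index map for (i, j) -> lattice row
  imax <- max(lattice$i); jmax <- max(lattice$j)
  idx <- matrix(NA_integer_, imax + 2, jmax + 2)
  idx[cbind(lattice$i + 1, lattice$j + 1)] <- seq_len(nrow(lattice))

  nL <- nrow(lattice)
  Zac <- matrix(NA_complex_, nL, n_harm)
  Zdc <- rep(NA_real_, nL)

  ord <- order(lattice$i + lattice$j, decreasing = TRUE)
  for (k in ord) {
    i <- lattice$i[k]; j <- lattice$j[k]
    r <- lattice$radius[k]; l <- lattice$length[k]
    c1 <- if (i + 2 <= nrow(idx)) idx[i + 2, j + 1] else NA_integer_
    c2 <- if (j + 2 <= ncol(idx)) idx[i + 1, j + 2] else NA_integer_
    kids <- c(c1, c2)
    kids <- kids[!is.na(kids)]
    if (length(kids) == 0) {
      ZL_ac <- Z_terminal / (1 + 1i * omega * tau_cap)
      ZL_dc <- Re(Z_terminal)
    } else if (length(kids) == 1) {
      ZL_ac <- Zac[kids, ]
      ZL_dc <- Zdc[kids]
    } else {
      ZL_ac <- 1 / (1 / Zac[kids[1], ] + 1 / Zac[kids[2], ])
      ZL_dc <- 1 / (1 / Zdc[kids[1]] + 1 / Zdc[kids[2]])
    }
    A0 <- pi * r^2
    K <- womersley_factor(omega, r, vp)
    Cc <- compliance(r, vp)
    cc <- sqrt(A0 * K / (vp$rho * Cc))
    g <- sqrt(Cc * A0 * K / vp$rho)
    Zac[k, ] <- transmission_line_impedance(ZL_ac, l, cc, g, omega)
    Zdc[k] <- 8 * vp$mu * l / (pi * r^4) + ZL_dc
  }
  root <- idx[1, 1]
  structure(
    list(omega = c(0, omega),
         Z = c(complex(real = Zdc[root], imaginary = 0), Zac[root, ]),
         period = vp$period, r_root = r_root, lattice = lattice,
         n_harm = n_harm),
    class = "impedance_spectrum"
  )
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf(
    "<impedance_spectrum> r_root=%.4g cm, %d harmonics, Z_DC=%.4g g cm^-4 s^-1\n",
    x$r_root, x$n_harm, Re(x$Z[1])))
  invisible(x)
}

#' Tidy an impedance spectrum
#' @param x an `impedance_spectrum`.
#' @param ... unused.
#' @return tibble with `harmonic`, `omega`, `Re_Z`, `Im_Z`, `mod_Z`.
#' @export
tidy.impedance_spectrum <- function(x, ...) {
  tibble(harmonic = seq_along(x$omega) - 1L, omega = x$omega,
         Re_Z = Re(x$Z), Im_Z = Im(x$Z), mod_Z = Mod(x$Z))
}

#' DC (Poiseuille) impedance of a structured-tree bed
#'
#' Zero-frequency branch of [root_impedance()] alone: the Poiseuille
#' resistance `8 mu l / (pi r^4)` of every vessel accumulated through the
#' radius lattice, with the terminal load at the leaves. Used for mean-flow
#' network reductions and terminal-load calibration, where the full
#' spectrum is not needed.
#'
#' @inheritParams root_impedance
#' @return DC input resistance (CGS, g cm^-4 s^-1).
#' @export
root_impedance_dc <- function(r_root, tree_params, vessel_params,
                              Z_terminal = 0) {
  if (r_root <= 0) abort("r_root must be positive")
  p <- tree_params
  lattice <- structured_tree_radii(r_root, p)
  if (nrow(lattice) == 0) abort("r_root at or below r_min: empty vascular bed")
  imax <- max(lattice$i); jmax <- max(lattice$j)
  idx <- matrix(NA_integer_, imax + 2, jmax + 2)
  idx[cbind(lattice$i + 1, lattice$j + 1)] <- seq_len(nrow(lattice))
  Zdc <- rep(NA_real_, nrow(lattice))
  ord <- order(lattice$i + lattice$j, decreasing = TRUE)
  mu <- vessel_params$mu
  for (k in ord) {
    i <- lattice$i[k]; j <- lattice$j[k]
    kids <- c(idx[i + 2, j + 1], idx[i + 1, j + 2])
    kids <- kids[!is.na(kids)]
    ZL <- if (length(kids) == 0) Re(Z_terminal)
          else if (length(kids) == 1) Zdc[kids]
          else 1 / (1 / Zdc[kids[1]] + 1 / Zdc[kids[2]])
    Zdc[k] <- 8 * mu * lattice$length[k] / (pi * lattice$radius[k]^4) + ZL
  }
  Zdc[idx[1, 1]]
}

#' Calibrate the terminal (capillary) load of the vascular beds
#'
#' The impedance of the smallest arterioles' downstream bed (capillaries
#' and venules) is not resolved by the structured tree; it enters as a
#' constant terminal load on every leaf. This routine finds the single
#' load value for which the DC reduction of the whole coronary network,
#' driven by the mean aortic pressure against the mean feedback pressures,
#' carries the target fraction of cardiac output. Calibrated once on the
#' baseline configuration and then held fixed across scenarios.
#'
#' @param tree binary `coronary_tree`.
#' @param tree_params [structured_tree_params()].
#' @param vessel_params [small_vessel_params()].
#' @param pf_mean named vector: mean feedback pressure per terminal, mmHg.
#' @param p_a_mean mean aortic pressure, mmHg.
#' @param q_target target mean coronary flow, ml s^-1.
#' @param mu blood viscosity.
#' @return terminal load (CGS), possibly 0 if the uncalibrated network is
#'   already too resistive.
#' @export
calibrate_terminal_load <- function(tree, tree_params, vessel_params,
                                    pf_mean, p_a_mean, q_target, mu) {
  terminals <- tree$segments$name[tree$segments$terminal]
  flow_at <- function(Zt) {
    bed <- vapply(terminals, function(nm) {
      r <- tree$segments$r_dist[tree$segments$name == nm]
      root_impedance_dc(r, tree_params, vessel_params, Z_terminal = Zt)
    }, 0)
    dc <- tree_dc_reduction(tree, bed, function(nm, t) pf_mean[[nm]],
                            t = 0, mu = mu)
    sum(vapply(dc, function(d) {
      (mmHg_to_cgs(p_a_mean) - mmHg_to_cgs(d$P_eff)) / d$R_eff
    }, 0))
  }
  if (flow_at(0) <= q_target) return(0)
  f <- function(logZ) flow_at(exp(logZ)) - q_target
  r <- uniroot(f, lower = log(1e4), upper = log(1e14), tol = 1e-10)
  exp(r$root)
}

#' Time-domain kernel of an impedance spectrum
#'
#' Inverse discrete Fourier transform of the (Hermitian-extended) impedance
#' spectrum, normalised so that the outflow boundary condition reads
#' `p(L, t_n) = sum_m z(t_m) q(L, t_n - t_m) dt`. The DC consistency
#' `sum(z) * dt = Z_0` holds exactly.
#'
#' @param spectrum an `impedance_spectrum` (harmonics 0..`n_samples`/2
#'   required).
#' @param n_samples number of time samples per period (even).
#' @return numeric kernel of length `n_samples` with attributes `dt` and
#'   `period`.
#' @export
impedance_to_kernel <- function(spectrum, n_samples) {
  if (n_samples %% 2 != 0) abort("n_samples must be even")
  need <- n_samples / 2
  if (length(spectrum$Z) < need + 1) {
    abort(sprintf("missing harmonics: need 0..%d, have 0..%d",
                  need, length(spectrum$Z) - 1))
  }
  Zh <- spectrum$Z[1:(need + 1)]
  Zh[need + 1] <- complex(real = Re(Zh[need + 1]), imaginary = 0)
  full <- c(Zh, Conj(rev(Zh[2:need])))
  z <- fft(full, inverse = TRUE) / spectrum$period
  if (max(abs(Im(z))) > 1e-9 * max(abs(Re(z)), 1e-300)) {
    warn("kernel has non-negligible imaginary part after symmetrisation")
  }
  out <- Re(z)
  attr(out, "dt") <- spectrum$period / n_samples
  attr(out, "period") <- spectrum$period
  out
}

#' Kernel-to-spectrum round trip
#'
#' Discrete Fourier transform of a time-domain kernel back to impedance
#' harmonics; inverse of [impedance_to_kernel()].
#'
#' @param kernel real kernel with `dt` attribute (or supply `period`).
#' @param period cardiac period, s.
#' @return complex vector of harmonics 0..n/2.
#' @export
kernel_to_spectrum <- function(kernel, period = attr(kernel, "period")) {
  n <- length(kernel)
  Z <- fft(kernel) * period / n
  Z[1:(n / 2 + 1)]
}

#' Distal pressure from the impedance convolution
#'
#' The outflow boundary condition of a terminal vessel:
#' `p(L, t) = sum_m z(t_m) q(L, t - t_m) dt + p_f(t)`, with `q_history`
#' ordered from the current sample backwards (`q_history[1] = q(L, t)`).
#'
#' @param q_history flow history over one period, most recent first
#'   (cm^3 s^-1).
#' @param kernel impedance kernel from [impedance_to_kernel()].
#' @param p_f feedback pressure at this instant (CGS).
#' @param dt kernel sampling interval, s.
#' @return distal pressure (CGS units).
#' @export
outlet_pressure <- function(q_history, kernel, p_f = 0, dt = attr(kernel, "dt")) {
  if (length(q_history) != length(kernel)) {
    abort("q_history and kernel must have equal length")
  }
  sum(kernel * q_history) * dt + p_f
}

#' Export an impedance spectrum or kernel to delimited text
#'
#' @param x an `impedance_spectrum`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_impedance <- function(x, path) {
  readr::write_csv(tidy.impedance_spectrum(x), path)
  invisible(path)
}
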