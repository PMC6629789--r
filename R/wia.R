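#' Pulse wave velocity from the simulated area series
#'
#' `c_p = sqrt(A / rho * dp/dA)` evaluated sample-by-sample on the
#' simulated area at the probe station, with the local wall stiffness.
#' With the adopted tube law `c_p^2 = (2/3)(Eh/(rho r0)) sqrt(A0/A)`, so
#' `c_p` at `A = A0` is `sqrt(2 Eh / (3 rho r0))`.
#'
#' @param A area series, cm^2.
#' @param r0 reference radius at the probe, cm.
#' @param wall list with `k1`, `k2`, `k3`.
#' @param rho blood density, g cm^-3.
#' @return pulse wave velocity series, cm s^-1.
#' @export
pulse_wave_velocity <- function(A, r0, wall, rho = 1.055) {
  if (any(A <= 0)) abort("A must be positive")
  f <- 4 / 3 * wall_stiffness(r0, wall)
  A0 <- pi * r0^2
  sqrt(0.5 * f / rho * sqrt(A0 / A))
}

#' Forward/backward wavefront decomposition
#'
#' Splits sampled pressure and velocity increments into forward (+) and
#' backward (-) travelling components with the water-hammer relations
#' `dp± = (dp ± rho c_p du) / 2`, `du± = (du ± dp / (rho c_p)) / 2`, using
#' the local (time-varying) pulse wave velocity, and forms the wave
#' intensities `WI± = (dp±/dt)(du±/dt)`. The decomposition is exactly
#' additive (`dp+ + dp- = dp`, `du+ + du- = du`) and sign-definite
#' (`WI+ >= 0 >= WI-`).
#'
#' @param p pressure series, mmHg.
#' @param u velocity series, cm s^-1.
#' @param c_p pulse wave velocity series (same length), cm s^-1.
#' @param t sample times, s (uniform).
#' @param rho blood density, g cm^-3.
#' @return object of class `wave_decomposition`: tibble with columns `t`,
#'   `dp`, `du`, `dp_plus`, `dp_minus` (mmHg), `du_plus`, `du_minus`
#'   (cm s^-1), `wi_plus`, `wi_minus`, `wi_net` (CGS intensity units,
#'   g cm^-1 s^-4); attributes `rho`, `dt`.
#' @export
wia_decompose <- function(p, u, c_p, t, rho = 1.055) {
  n <- length(p)
  if (length(u) != n || length(c_p) != n || length(t) != n) {
    abort("p, u, c_p, t must have equal length")
  }
  dt <- t[2] - t[1]
  dp <- diff(mmHg_to_cgs(p))
  du <- diff(u)
  rc <- rho * c_p[-n]
  dp_plus <- 0.5 * (dp + rc * du)
  dp_minus <- 0.5 * (dp - rc * du)
  du_plus <- 0.5 * (du + dp / rc)
  du_minus <- 0.5 * (du - dp / rc)
  wi_plus <- (dp_plus / dt) * (du_plus / dt)
  wi_minus <- (dp_minus / dt) * (du_minus / dt)
  out <- tibble(
    t = t[-n],
    dp = cgs_to_mmHg(dp), du = du,
    dp_plus = cgs_to_mmHg(dp_plus), dp_minus = cgs_to_mmHg(dp_minus),
    du_plus = du_plus, du_minus = du_minus,
    wi_plus = wi_plus, wi_minus = wi_minus, wi_net = wi_plus + wi_minus
  )
  attr(out, "rho") <- rho
  attr(out, "dt") <- dt
  class(out) <- c("wave_decomposition", class(out))
  out
}

#' Wave decomposition at a probe of a run
#'
#' Convenience wrapper: extracts the midpoint series of a vessel from a
#' `coro_run`, computes the local pulse wave velocity and decomposes.
#'
#' @param run a `coro_run`.
#' @param vessel segment name.
#' @param station probe station (see [run_series()]).
#' @return a `wave_decomposition`.
#' @export
run_wia <- function(run, vessel, station = "mid") {
  s <- run_series(run, vessel, station)
  g <- run$grids[[vessel]]
  j <- which.min(abs(g$x - s$x[1]))
  cp <- sqrt(s$A / run$config$blood$rho *
             (0.5 * g$f[j] * sqrt(g$A0[j]) / s$A^1.5))
  wia_decompose(s$p, s$u, cp, s$t, rho = run$config$blood$rho)
}

# Contiguous lobes of one signed intensity channel above a threshold.
# A run is further split where the pressure-wavefront channel changes sign
# (a compression turning into a decompression is two waves even if |WI|
# never drops below threshold between them); sign changes shorter than 2%
# of the cycle are treated as jitter and not split on.
find_lobes <- function(t, wi, dp_channel, thr, direction) {
  above <- abs(wi) > thr
  if (!any(above)) return(NULL)
  dt <- t[2] - t[1]
  min_run <- max(2L, as.integer(0.02 * length(t)))
  sg <- sign(dp_channel)
  sg[sg == 0] <- 1
  rs <- rle(sg)
  short <- rs$lengths < min_run
  if (any(short) && !all(short)) { # absorb jitter into the previous run
    vals <- rs$values
    for (k in which(short)) vals[k] <- if (k > 1) vals[k - 1] else vals[which(!short)[1]]
    sg <- inverse.rle(structure(list(lengths = rs$lengths, values = vals),
                                class = "rle"))
    sg <- inverse.rle(rle(sg)) # renormalise
  }
  grp <- cumsum(c(TRUE, diff(above) != 0 | diff(sg) != 0))
  idx <- split(seq_along(t), grp)
  purrr::map_dfr(idx, function(ii) {
    if (!above[ii[1]]) return(NULL)
    e <- sum(abs(wi[ii])) * dt
    net_dp <- sum(dp_channel[ii])
    peak <- ii[which.max(abs(wi[ii]))]
    tibble(
      direction = direction,
      sign = if (net_dp >= 0) "compression" else "decompression",
      t_start = t[ii[1]], t_end = t[ii[length(ii)]], t_peak = t[peak],
      energy = e
    )
  })
}

#' Segment the six coronary waves
#'
#' Detects contiguous lobes of forward and backward wave intensity
#' (threshold: a fraction of the global peak |WI|), classifies each lobe by
#' direction and by the net sign of its pressure wavefront (compression vs
#' decompression), and aligns the chronologically ordered lobes to the
#' canonical six-phase coronary template
#' a:BCW, b:FCW, c:BCW, d:FDW, e:BDW, f:FCW (order-preserving alignment
#' maximising matched energy). Energies are time integrals of |WI| per
#' lobe; percentages are relative to the total energy of the labelled
#' lobes.
#'
#' @param dec a `wave_decomposition` over one converged cycle.
#' @param t_s end of systole, s (annotation only).
#' @param threshold lobe detection threshold as a fraction of peak |WI|.
#' @return object of class `six_wave_table`: tibble with columns `wave`
#'   (a..f), `type` (BCW/FCW/FDW/BDW), `t_start`, `t_end`, `t_peak`,
#'   `energy`, `percent`. Fewer than six rows (with a warning) if a phase
#'   is not detected.
#' @export
segment_six_waves <- function(dec, t_s = 0.4, threshold = 0.01) {
  thr <- threshold * max(abs(c(dec$wi_plus, dec$wi_minus)))
  fwd <- find_lobes(dec$t, dec$wi_plus, dec$dp_plus, thr, "forward")
  bwd <- find_lobes(dec$t, dec$wi_minus, dec$dp_minus, thr, "backward")
  lobes <- dplyr::bind_rows(fwd, bwd)
  if (is.null(lobes) || nrow(lobes) == 0) {
    warn("no wave lobes above threshold")
    return(structure(tibble(), class = c("six_wave_table", class(tibble()))))
  }
  lobes$type <- with(lobes, paste0(
    ifelse(direction == "forward", "F", "B"),
    ifelse(sign == "compression", "C", "D"), "W"))
  lobes <- lobes[order(lobes$t_peak), ]

  template <- c(a = "BCW", b = "FCW", c = "BCW", d = "FDW", e = "BDW", f = "FCW")
  # canonical timing of the six phases (fractions of the cycle, systole
  # ending at t_s): used as a soft prior so that, e.g., an early-systolic
  # backward compression lobe is labelled (a) rather than (c)
  t_c <- max(dec$t) + (dec$t[2] - dec$t[1])
  win <- rbind(
    a = c(0, 0.5 * t_s), b = c(0, t_s),
    c = c(0.3 * t_s, 1.5 * t_s), d = c(0.4 * t_s, t_c),
    e = c(0.4 * t_s, t_c), f = c(t_s, t_c)
  )
  weight <- function(i, k) {
    inside <- lobes$t_peak[i] >= win[k, 1] & lobes$t_peak[i] <= win[k, 2]
    lobes$energy[i] * if (inside) 1 else 0.1
  }
  nL <- nrow(lobes); nT <- length(template)
  # DP alignment: best[i, k] = max matched (windowed) energy using lobes
  # 1..i and template slots 1..k, order preserving.
  best <- matrix(0, nL + 1, nT + 1)
  take <- matrix(FALSE, nL + 1, nT + 1)
  for (i in seq_len(nL)) {
    for (k in seq_len(nT)) {
      skip <- max(best[i, k + 1], best[i + 1, k])
      m <- -Inf
      if (lobes$type[i] == template[k]) m <- best[i, k] + weight(i, k)
      if (m >= skip) {
        best[i + 1, k + 1] <- m
        take[i + 1, k + 1] <- TRUE
      } else {
        best[i + 1, k + 1] <- skip
      }
    }
  }
  # traceback
  assign_idx <- rep(NA_integer_, nT)
  i <- nL; k <- nT
  while (i > 0 && k > 0) {
    if (take[i + 1, k + 1]) {
      assign_idx[k] <- i
      i <- i - 1; k <- k - 1
    } else if (best[i, k + 1] >= best[i + 1, k]) {
      i <- i - 1
    } else {
      k <- k - 1
    }
  }
  matched <- !is.na(assign_idx)
  if (!all(matched)) {
    warn(sprintf("only %d of 6 wave phases detected", sum(matched)))
  }
  out <- lobes[assign_idx[matched], ]
  out$wave <- names(template)[matched]
  total <- sum(out$energy)
  out$percent <- 100 * out$energy / total
  out <- out[, c("wave", "type", "t_start", "t_end", "t_peak",
                 "energy", "percent")]
  attr(out, "t_s") <- t_s
  attr(out, "threshold") <- threshold
  attr(out, "unmatched_energy") <- sum(lobes$energy) - total
  class(out) <- c("six_wave_table", class(out))
  out
}

#' Published reference wave-energy fractions
#'
#' Cumulative proportional wave-intensity energies (percent) reported by
#' two experimental studies of human coronary wave intensity, included as
#' static comparison columns for [energy_table()].
#'
#' @return tibble with `wave`, `type`, `davies_pct`, `lee_pct`.
#' @export
reference_wave_energies <- function() {
  tibble(
    wave = letters[1:6],
    type = c("BCW", "FCW", "BCW", "FDW", "BDW", "FCW"),
    davies_pct = c(1.9, 22.3, 20.5, 18.9, 30.0, 6.1),
    lee_pct = c(5.1, 27.4, 2.8, 13.4, 37.3, 14.1)
  )
}

#' Side-by-side wave-energy comparison table
#'
#' @param tables named list of `six_wave_table`s (one per scenario).
#' @param reference include the published experimental reference columns.
#' @return tibble with one row per wave and one percent column per
#'   scenario.
#' @export
energy_table <- function(tables, reference = TRUE) {
  if (length(tables) == 0) abort("need at least one six-wave table")
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("run", seq_along(tables))
  }
  out <- reference_wave_energies()[, c("wave", "type")]
  if (reference) out <- reference_wave_energies()
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    out[[paste0(nm, "_pct")]] <-
      tb$percent[match(out$wave, tb$wave)]
  }
  out
}

#' Write a wave decomposition to delimited text
#' @param dec a `wave_decomposition`.
#' @param path output file (CSV).
#' @return `path`, invisibly.
#' @export
write_wia <- function(dec, path) {
  readr::write_csv(as_tibble(dec), path)
  invisible(path)
}
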