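#' Ventricular elastance parameters
#'
#' Parameters of the time-varying elastance pressure model for one
#' ventricle: during systole
#' `p_v = p0 sigma(t) + (Ed + Es sigma(t)) (V - V0) + Rv dV/dt`,
#' during diastole `p_v = Ed (V - V0)`, with activation
#' `sigma(t) = 1 - cos(2 pi t / t_s)` (peak 2, as conventionally printed
#' without the 1/2 factor; set `sigma_half = TRUE` in the configuration to
#' halve it).
#'
#' @param side `"left"` or `"right"`; selects published defaults.
#' @param p0 peak isovolumetric pressure, mmHg.
#' @param Es systolic elastance, mmHg ml^-1.
#' @param Ed diastolic elastance, mmHg ml^-1.
#' @param V0 unstressed volume, ml.
#' @param Rv myocardial resistance, mmHg s ml^-1.
#' @param t_s end of systole, s.
#' @param t_c cardiac period, s.
#' @return object of class `ventricle_params`.
#' @export
ventricle_params <- function(side = c("left", "right"),
                             p0 = NULL, Es = NULL, Ed = NULL, V0 = NULL,
                             Rv = NULL, t_s = 0.4, t_c = 0.9) {
  side <- match.arg(side)
  def <- if (side == "left") {
    list(p0 = 50, Es = 1.375, Ed = 0.1, V0 = 11.29, Rv = 0.08)
  } else {
    list(p0 = 24, Es = 0.3288, Ed = 0.03, V0 = 3.33, Rv = 0.0175)
  }
  out <- list(side = side,
              p0 = p0 %||% def$p0, Es = Es %||% def$Es, Ed = Ed %||% def$Ed,
              V0 = V0 %||% def$V0, Rv = Rv %||% def$Rv,
              t_s = t_s, t_c = t_c)
  if (!(out$t_s > 0 && out$t_s < out$t_c)) abort("need 0 < t_s < t_c")
  if (!(out$Es > out$Ed && out$Ed > 0)) abort("need Es > Ed > 0")
  structure(out, class = "ventricle_params")
}

#' Activation function of the cardiac cycle
#'
#' `sigma(t) = 1 - cos(2 pi t / t_s)` for `0 <= t < t_s` (systole) and 0
#' in diastole, extended periodically with period `t_c`. Continuous
#' everywhere; peak value 2 at `t = t_s / 2` (or 1 with `half = TRUE`).
#'
#' @param t time, s (vectorised).
#' @param t_s end of systole, s.
#' @param t_c cardiac period, s.
#' @param half divide by two (conventional normalisation to peak 1).
#' @return dimensionless activation.
#' @export
activation_sigma <- function(t, t_s = 0.4, t_c = 0.9, half = FALSE) {
  tm <- t %% t_c
  s <- ifelse(tm < t_s, 1 - cos(2 * pi * tm / t_s), 0)
  if (half) s / 2 else s
}

#' Prescribed ventricular volume profile
#'
#' The elastance pressure model needs `V(t) - V0` and `dV/dt` but the
#' circulation that would determine them dynamically is deliberately kept
#' out of the model, so a smooth stroke profile is prescribed:
#' `V(t) = V_ed - SV * s(t)` with `s` a C1 cosine ejection ramp over
#' systole (`s(0) = 0`, `s(t_s) = 1`, zero slope at both ends) and a
#' constant-rate refill in diastole. Defaults are chosen so the left
#' ventricular pressure peaks near 120 mmHg with the published elastances.
#'
#' @param V_ed end-diastolic volume, ml.
#' @param SV stroke volume of the profile, ml.
#' @param t_s,t_c systole end and period, s.
#' @return object of class `volume_model` with functions `V(t)` and
#'   `dVdt(t)` (both vectorised and `t_c`-periodic).
#' @export
volume_model <- function(V_ed, SV, t_s = 0.4, t_c = 0.9) {
  stopifnot(V_ed > 0, SV > 0, SV < V_ed)
  force(V_ed); force(SV); force(t_s); force(t_c)
  sfun <- function(t) {
    tm <- t %% t_c
    ifelse(tm < t_s, (1 - cos(pi * tm / t_s)) / 2, 1 - (tm - t_s) / (t_c - t_s))
  }
  dsfun <- function(t) {
    tm <- t %% t_c
    ifelse(tm < t_s, pi / (2 * t_s) * sin(pi * tm / t_s), -1 / (t_c - t_s))
  }
  structure(list(
    V = function(t) V_ed - SV * sfun(t),
    dVdt = function(t) -SV * dsfun(t),
    V_ed = V_ed, SV = SV, t_s = t_s, t_c = t_c
  ), class = "volume_model")
}

#' Default volume profiles for left and right ventricles
#' @param side `"left"` or `"right"`.
#' @param t_s,t_c systole end and period, s.
#' @return a [volume_model()].
#' @export
default_volume_model <- function(side = c("left", "right"),
                                 t_s = 0.4, t_c = 0.9) {
  side <- match.arg(side)
  if (side == "left") volume_model(V_ed = 26.3, SV = 12, t_s = t_s, t_c = t_c)
  else volume_model(V_ed = 11.3, SV = 6, t_s = t_s, t_c = t_c)
}

#' Ventricular pressure from the elastance model
#'
#' @param t time, s (vectorised).
#' @param vp a [ventricle_params()] object.
#' @param vol a [volume_model()]; default derived from `vp$side`.
#' @param sigma_half use the peak-1 activation normalisation.
#' @return pressure in mmHg.
#' @export
ventricular_pressure <- function(t, vp, vol = NULL, sigma_half = FALSE) {
  vol <- vol %||% default_volume_model(vp$side, vp$t_s, vp$t_c)
  tm <- t %% vp$t_c
  s <- activation_sigma(tm, vp$t_s, vp$t_c, half = sigma_half)
  V <- vol$V(tm)
  dV <- vol$dVdt(tm)
  systole <- tm < vp$t_s
  ifelse(systole,
         vp$p0 * s + (vp$Ed + vp$Es * s) * (V - vp$V0) + vp$Rv * dV,
         vp$Ed * (V - vp$V0))
}

#' Feedback-pressure parameters
#'
#' Myocardial contraction squeezes the vascular beds; this is modelled by
#' adding `p_f(t) = phi * p_v(t) + p_s` to the distal boundary condition of
#' every terminal artery, where `p_v` is the ventricular pressure of the
#' territory the bed lies in and `p_s` is the coronary bed pressure.
#'
#' @param phi named vector of feedback ratios per supply location
#'   (defaults: left ventricle 33%, right ventricle 25%, septum 22%).
#' @param phi_terminal optional named vector of per-terminal overrides
#'   (terminal name -> phi).
#' @param p_s coronary bed pressure, mmHg.
#' @return object of class `feedback_params`.
#' @export
feedback_params <- function(phi = c(left_ventricle = 0.33,
                                    right_ventricle = 0.25,
                                    septum = 0.22),
                            phi_terminal = NULL, p_s = 20) {
  if (any(phi < 0 | phi > 1)) abort("phi must lie in [0, 1]")
  if (!is.null(phi_terminal) && any(phi_terminal < 0 | phi_terminal > 1)) {
    abort("phi overrides must lie in [0, 1]")
  }
  if (p_s < 0) abort("p_s must be non-negative")
  structure(list(phi = phi, phi_terminal = phi_terminal, p_s = p_s),
            class = "feedback_params")
}

#' Feedback ratio of a terminal vessel
#' @param terminal terminal segment name.
#' @param fp a [feedback_params()] object.
#' @param supply named supply map (default [coronary_supply_map()]).
#' @return phi (dimensionless).
#' @export
terminal_phi <- function(terminal, fp, supply = coronary_supply_map()) {
  if (!is.null(fp$phi_terminal) && terminal %in% names(fp$phi_terminal)) {
    return(unname(fp$phi_terminal[[terminal]]))
  }
  loc <- supply[terminal]
  if (is.na(loc)) abort(paste0("unknown terminal vessel: ", terminal))
  unname(fp$phi[[loc]])
}

#' Feedback pressure at a terminal vascular bed
#'
#' `p_f(t) = phi * p_v(t) + p_s`; `p_v` is the left ventricular pressure
#' for left-ventricle and septal beds and the right ventricular pressure
#' for right-ventricle beds. Linear in both `p_v` and `p_s`.
#'
#' @param t time, s (vectorised).
#' @param terminal terminal segment name.
#' @param fp a [feedback_params()] object.
#' @param heart list with `left`, `right` ([ventricle_params()]),
#'   optional `vol_left`, `vol_right` and `sigma_half`.
#' @param supply named supply map.
#' @return feedback pressure in mmHg.
#' @export
feedback_pressure <- function(t, terminal, fp, heart,
                              supply = coronary_supply_map()) {
  phi <- terminal_phi(terminal, fp, supply)
  loc <- supply[terminal]
  vp <- if (identical(unname(loc), "right_ventricle")) heart$right else heart$left
  vol <- if (identical(unname(loc), "right_ventricle")) heart$vol_right else heart$vol_left
  pv <- ventricular_pressure(t, vp, vol,
                             sigma_half = isTRUE(heart$sigma_half))
  phi * pv + fp$p_s
}

#' Systemic lumped-parameter inlet model
#'
#' A minimal elastance-ventricle / aortic-valve / three-element windkessel
#' model producing a periodic aortic-root pressure. Ejection is a smooth
#' half-sine of stroke volume `SV` over systole (non-negative: the valve is
#' a diode); the windkessel (characteristic impedance `Zc`, peripheral
#' resistance `Rp`, compliance `C`, venous pressure `p_ven`) is solved
#' exactly in the frequency domain.
#'
#' @param SV systemic stroke volume, ml.
#' @param Zc characteristic impedance, mmHg s ml^-1.
#' @param Rp peripheral resistance, mmHg s ml^-1.
#' @param C arterial compliance, ml mmHg^-1.
#' @param p_ven venous pressure, mmHg.
#' @return object of class `systemic_params`.
#' @export
systemic_params <- function(SV = 75, Zc = 0.04, Rp = 1.10, C = 1.7,
                            p_ven = 5) {
  stopifnot(SV > 0, Zc >= 0, Rp > 0, C > 0)
  structure(list(SV = SV, Zc = Zc, Rp = Rp, C = C, p_ven = p_ven),
            class = "systemic_params")
}

#' Lumped coronary inflow estimate with intramyocardial compression
#'
#' Classic three-element intramyocardial model of one coronary tree: the
#' epicardial share `R1 = fr_prox * R` feeds an intramyocardial
#' compartment of compliance `C = tau_im / R2` whose back pressure is the
#' bed feedback pressure; the microvascular share `R2` drains it. Systolic
#' compression charges the compartment and throttles inflow (the
#' early-systolic dip), and its diastolic discharge produces the
#' diastolic-dominant inflow typical of the left coronary circulation.
#' Solved exactly per harmonic; the mean flow equals `(mean p_a - mean
#' p_back)/R`, so DC calibration is unchanged.
#'
#' @param p_a aortic pressure over one period, mmHg (uniform sampling).
#' @param p_back effective bed back pressure over the same grid, mmHg.
#' @param R total tree DC resistance, CGS.
#' @param period cardiac period, s.
#' @param fr_prox proximal resistance fraction.
#' @param tau_im distal time constant `R2 * C`, s.
#' @return inflow over the period, ml s^-1.
#' @export
coronary_inflow_estimate <- function(p_a, p_back, R, period,
                                     fr_prox = 0.3, tau_im = 0.3) {
  n <- length(p_a)
  if (length(p_back) == 1) p_back <- rep(p_back, n)
  R1 <- fr_prox * R
  R2 <- (1 - fr_prox) * R
  C <- tau_im / R2
  Pa <- fft(mmHg_to_cgs(p_a)) / n
  Pb <- fft(mmHg_to_cgs(p_back)) / n
  k <- c(0:(n / 2), -(n / 2 - 1):-1)
  w <- 2 * pi * k / period
  Pc <- (Pa / R1 + Pb / R2) / (1i * w * C + 1 / R1 + 1 / R2)
  Q <- (Pa - Pc) / R1
  Re(fft(Q, inverse = TRUE))
}

#' Aortic-root pressure waveform from the lumped model
#'
#' @param sys a [systemic_params()] object.
#' @param t_s,t_c systole end and period, s.
#' @param n samples per period.
#' @return tibble with `t` (s), `q_ao` (ml s^-1, aortic valve flow, always
#'   `>= 0`) and `p_a` (mmHg, aortic pressure); attribute `CO` in L min^-1.
#' @export
aortic_pressure_waveform <- function(sys, t_s = 0.4, t_c = 0.9, n = 1024) {
  t <- (0:(n - 1)) * t_c / n
  q_ao <- ifelse(t < t_s, sys$SV * pi / (2 * t_s) * sin(pi * t / t_s), 0)
  q_ao <- pmax(q_ao, 0)
  # periodic 3-element windkessel solved per harmonic
  Q <- fft(q_ao) / n
  k <- c(0:(n / 2), -(n / 2 - 1):-1)
  w <- 2 * pi * k / t_c
  H <- sys$Rp / (1 + 1i * w * sys$Rp * sys$C)
  Pc <- Q * H
  p_c <- Re(fft(Pc, inverse = TRUE))
  p_a <- sys$Zc * q_ao + p_c + sys$p_ven
  out <- tibble(t = t, q_ao = q_ao, p_a = p_a)
  attr(out, "CO") <- mean(q_ao) * 60 / 1000 * (1)
  out
}

#' Inlet waveforms for the coronary roots
#'
#' Combines the lumped systemic model with a DC (Poiseuille) reduction of
#' the coronary network to produce the inlet forcing for the 1D solver.
#' In the default `"flow"` mode the inflow of each root is estimated as
#' `q(t) = (p_a(t) - P_eff(t)) / R_eff` from the tree's Thevenin-equivalent
#' resistance and (time-varying) effective back pressure, and then scaled
#' by a single inlet scale factor so that the total mean coronary inflow is
#' `coronary_fraction` of cardiac output. In `"pressure"` mode the aortic
#' pressure is rescaled about the effective bed pressure to achieve the
#' same mean-flow calibration.
#'
#' @param tree_dc per-root list of `R_eff` (CGS) and `P_eff(t)` (mmHg,
#'   sampled on the same grid), from [tree_dc_reduction()].
#' @param heart heart configuration (for `t_s`, `t_c`).
#' @param sys a [systemic_params()] object.
#' @param coronary_fraction target mean coronary flow as a fraction of
#'   cardiac output.
#' @param n samples per period.
#' @param mode `"flow"` or `"pressure"`.
#' @param fr_prox proximal (epicardial) fraction of the tree resistance in
#'   the intramyocardial windkessel of the inflow estimate.
#' @param tau_im intramyocardial time constant `R_distal * C_im`, s.
#' @return object of class `coronary_inlet`: list with `t`, `p_a` (mmHg),
#'   per-root flows `q` (ml s^-1, flow mode), `p_in` (mmHg, pressure mode),
#'   `CO` (L min^-1), `scale`, `fraction` (achieved, DC estimate).
#' @export
inlet_waveform <- function(tree_dc, heart, sys = systemic_params(),
                           coronary_fraction = 0.045, n = 1024,
                           mode = c("flow", "pressure"),
                           fr_prox = 0.3, tau_im = 0.3) {
  mode <- match.arg(mode)
  t_s <- heart$left$t_s; t_c <- heart$left$t_c
  aw <- aortic_pressure_waveform(sys, t_s, t_c, n)
  CO_mls <- mean(aw$q_ao) # ml s^-1
  CO <- CO_mls * 60 / 1000 # L min^-1
  target <- coronary_fraction * CO_mls

  q_raw <- lapply(tree_dc, function(d) {
    coronary_inflow_estimate(aw$p_a, d$P_comp %||% d$P_eff, d$R_eff, t_c,
                             fr_prox = fr_prox, tau_im = tau_im)
  })
  mean_raw <- sum(vapply(q_raw, mean, 0))
  if (mode == "flow") {
    if (abs(mean_raw) < 1e-12) abort("inlet calibration failed: zero raw coronary flow")
    s <- target / mean_raw
    q <- lapply(q_raw, function(x) s * x)
    fraction <- sum(vapply(q, mean, 0)) / CO_mls
    out <- list(t = aw$t, p_a = aw$p_a, q = q, p_in = NULL, CO = CO,
                scale = s, fraction = fraction, mode = mode)
  } else {
    # p_in = P_ref + s (p_a - P_ref); mean flow affine in s
    G <- vapply(tree_dc, function(d) 1 / d$R_eff, 0)
    P_ref <- sum(G * vapply(tree_dc, function(d) mean(d$P_eff), 0)) / sum(G)
    base <- sum(vapply(tree_dc, function(d) {
      (mmHg_to_cgs(P_ref) - mean(mmHg_to_cgs(d$P_eff))) / d$R_eff
    }, 0))
    slope <- sum(G) * (mean(mmHg_to_cgs(aw$p_a)) - mmHg_to_cgs(P_ref))
    if (abs(slope) < 1e-12) abort("inlet calibration failed: degenerate pressure slope")
    s <- (target - base) / slope
    p_in <- P_ref + s * (aw$p_a - P_ref)
    flows <- lapply(tree_dc, function(d) {
      (mmHg_to_cgs(p_in) - mmHg_to_cgs(d$P_eff)) / d$R_eff
    })
    fraction <- sum(vapply(flows, mean, 0)) / CO_mls
    out <- list(t = aw$t, p_a = aw$p_a, q = flows, p_in = p_in, CO = CO,
                scale = s, fraction = fraction, mode = mode)
  }
  structure(out, class = "coronary_inlet")
}
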