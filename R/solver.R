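#' Tube-law pressure and its area derivative
#'
#' Pressure-area relation of the large-vessel wall:
#' `p = p0 + (4/3)(Eh/r0)(1 - sqrt(A0/A))`, a strictly increasing function
#' of `A` with asymptote `p0 + (4/3)(Eh/r0)` as `A -> Inf`. A literal
#' linear variant `(1 - A/A0)`-free form is available for sensitivity
#' (`form = "linear"`: `p = p0 + (4/3)(Eh/r0)(A/A0 - 1)`).
#'
#' @param A cross-sectional area, cm^2 (vectorised).
#' @param A0 reference area, cm^2.
#' @param r0 reference radius, cm.
#' @param wall list with `k1`, `k2`, `k3`.
#' @param p0 reference pressure, mmHg.
#' @param form `"sqrt"` (default) or `"linear"`.
#' @return list with `p` (mmHg) and `dp_dA` (mmHg cm^-2).
#' @export
tube_law_pressure <- function(A, A0, r0, wall, p0 = 0, form = c("sqrt", "linear")) {
  form <- match.arg(form)
  if (any(A <= 0)) abort("A must be positive")
  f <- 4 / 3 * wall_stiffness(r0, wall) # CGS
  if (form == "sqrt") {
    p <- f * (1 - sqrt(A0 / A))
    dp <- 0.5 * f * sqrt(A0) / A^1.5
  } else {
    p <- f * (A / A0 - 1)
    dp <- rep(f / A0, length(A))
  }
  list(p = p0 + cgs_to_mmHg(p), dp_dA = cgs_to_mmHg(dp))
}

#' Advance a single vessel by Lax-Wendroff steps
#'
#' Thin wrapper over the compiled two-step (Richtmyer) scheme for one
#' vessel with Dirichlet boundary values (held at their initial state
#' unless `bc` is supplied). Intended for scheme-level verification:
#' constant-state preservation, discrete mass conservation, manufactured
#' solutions and pulse-propagation tests.
#'
#' @param A,q initial state (length-n vectors, CGS).
#' @param r0 reference radius per node, cm (or scalar).
#' @param wall list with `k1`, `k2`, `k3`.
#' @param dx grid spacing, cm.
#' @param dt time step, s.
#' @param n_steps number of steps.
#' @param rho,mu blood density and viscosity.
#' @param p0 reference pressure, mmHg.
#' @param delta boundary-layer thickness, cm.
#' @param bc optional `(n_steps + 1) x 4` matrix of boundary values
#'   `[A_left, q_left, A_right, q_right]` per time level.
#' @param forcing optional list with matrices `fA_full`, `fq_full`
#'   (`n_steps x n`) and `fA_half`, `fq_half` (`n_steps x (n-1)`)
#'   (manufactured-solution source terms).
#' @return list with final `A`, `q` and the last step's half-node fluxes
#'   `qhalf`.
#' @export
lax_wendroff_step <- function(A, q, r0, wall, dx, dt, n_steps = 1,
                              rho = 1.055, mu = 0.0047, p0 = 0,
                              delta = sqrt(mu / rho * 0.9 / (2 * pi)),
                              bc = NULL, forcing = NULL) {
  n <- length(A)
  if (length(r0) == 1) r0 <- rep(r0, n)
  A0 <- pi * r0^2
  f <- 4 / 3 * wall_stiffness(r0, wall)
  drdx <- c(diff(r0), 0) / dx
  drdx[n] <- drdx[n - 1]
  dfdx <- 4 / 3 * wall$k1 * wall$k2 * exp(wall$k2 * r0) * drdx
  dA0dx <- 2 * pi * r0 * drdx
  if (is.null(bc)) {
    bc <- matrix(rep(c(A[1], q[1], A[n], q[n]), each = n_steps + 1),
                 n_steps + 1, 4)
  }
  empty <- matrix(0, 0, 0)
  fr <- forcing %||% list(fA_full = empty, fq_full = empty,
                          fA_half = empty, fq_half = empty)
  cw_run_single(n, dx, A0, f, dA0dx, dfdx, mmHg_to_cgs(p0), rho, mu / rho,
                delta, dt, as.integer(n_steps), A, q, bc,
                fr$fA_full, fr$fq_full, fr$fA_half, fr$fq_half)
}

#' Solve the junction matching conditions
#'
#' Damped Newton solution of the three conditions at a bifurcation node -
#' flow conservation `q_p = q_d1 + q_d2` and static-pressure continuity
#' `p_p = p_d1 = p_d2` - combined with the outgoing characteristic
#' invariant of each vessel (`u -/+ 4c` carried to the boundary from the
#' interior). Mirrors the solver core's junction treatment; exposed for
#' verification.
#'
#' @param parent,d1,d2 lists with fields `W` (characteristic invariant
#'   value, forward for the parent, backward for the daughters), `A0`, `f`
#'   (CGS), `p0` (CGS), and starting `A`.
#' @param rho blood density.
#' @param tol residual tolerance (scaled).
#' @param maxit Newton iteration cap.
#' @return list with `A`, `q`, `p` (CGS) per vessel and `residual`.
#' @export
junction_solve <- function(parent, d1, d2, rho = 1.055, tol = 1e-11,
                           maxit = 60) {
  cspd <- function(A, v) sqrt(0.5 * v$f / rho * sqrt(v$A0 / A))
  pres <- function(A, v) v$p0 + v$f * (1 - sqrt(v$A0 / A))
  dpdA <- function(A, v) 0.5 * v$f * sqrt(v$A0) / A^1.5
  x <- c(parent$A, d1$A, d2$A)
  ps <- max(parent$f, d1$f, d2$f)
  for (it in seq_len(maxit)) {
    cp <- cspd(x[1], parent); c1 <- cspd(x[2], d1); c2 <- cspd(x[3], d2)
    up <- parent$W + 4 * cp
    u1 <- d1$W - 4 * c1
    u2 <- d2$W - 4 * c2
    R <- c(x[1] * up - x[2] * u1 - x[3] * u2,
           pres(x[1], parent) - pres(x[2], d1),
           pres(x[1], parent) - pres(x[3], d2))
    qs <- max(1, abs(x[1] * up))
    res <- max(abs(R[1]) / qs, abs(R[2]) / ps, abs(R[3]) / ps)
    if (res < tol) break
    J <- rbind(
      c(up - cp, -(u1 + c1), -(u2 + c2)),
      c(dpdA(x[1], parent), -dpdA(x[2], d1), 0),
      c(dpdA(x[1], parent), 0, -dpdA(x[3], d2))
    )
    dxs <- solve(J, -R)
    lim <- min(1, 0.2 * x / abs(dxs))
    x <- x + lim * dxs
  }
  cp <- cspd(x[1], parent); c1 <- cspd(x[2], d1); c2 <- cspd(x[3], d2)
  list(
    A = x,
    q = c(x[1] * (parent$W + 4 * cp), x[2] * (d1$W - 4 * c1),
          x[3] * (d2$W - 4 * c2)),
    p = c(pres(x[1], parent), pres(x[2], d1), pres(x[3], d2)),
    residual = res
  )
}

# Poiseuille resistance of a linearly tapered segment: (8 mu / pi) int dx/r^4
taper_resistance <- function(length, r_prox, r_dist, mu) {
  if (abs(r_prox - r_dist) < 1e-12) {
    8 * mu * length / (pi * r_prox^4)
  } else {
    8 * mu / pi * length / (3 * (r_prox - r_dist)) * (r_dist^-3 - r_prox^-3)
  }
}

#' Thevenin (DC) reduction of a coronary tree
#'
#' Reduces each root's large-vessel tree plus terminal-bed DC impedances to
#' an equivalent resistance `R_eff` and effective back pressure `P_eff(t)`
#' (conductance-weighted combination of the terminal feedback pressures).
#' Used by the lumped inlet model and for mean-flow calibration.
#'
#' @param tree a binary `coronary_tree` (after [split_trifurcation()]).
#' @param bed_dc named vector of terminal-bed DC impedances (CGS).
#' @param pf_fun function(terminal, t) -> feedback pressure (mmHg).
#' @param t time grid, s.
#' @param mu blood viscosity.
#' @param pf_fun_comp optional second pressure function (e.g. the full
#'   intramyocardial compression pressure used by the lumped inflow
#'   estimate), reduced with the same conductance weights.
#' @return named list per root: `R_eff` (CGS), `P_eff` (mmHg over `t`),
#'   and `P_comp` when `pf_fun_comp` is given.
#' @export
tree_dc_reduction <- function(tree, bed_dc, pf_fun, t, mu,
                              pf_fun_comp = NULL) {
  seg <- tree$segments
  reduce <- function(nm) {
    row <- seg[seg$name == nm, ]
    Rseg <- taper_resistance(row$length, row$r_prox, row$r_dist, mu)
    kids <- row$daughters[[1]]
    if (length(kids) == 0) {
      list(R = Rseg + bed_dc[[nm]], P = pf_fun(nm, t),
           Pc = if (!is.null(pf_fun_comp)) pf_fun_comp(nm, t))
    } else {
      subs <- lapply(kids, reduce)
      G <- vapply(subs, function(s) 1 / s$R, 0)
      Pw <- Reduce(`+`, Map(function(s, g) s$P * g, subs, as.list(G)))
      Pc <- if (!is.null(pf_fun_comp)) {
        Reduce(`+`, Map(function(s, g) s$Pc * g, subs, as.list(G))) / sum(G)
      }
      list(R = Rseg + 1 / sum(G), P = Pw / sum(G), Pc = Pc)
    }
  }
  out <- lapply(tree$roots, reduce)
  names(out) <- tree$roots
  lapply(out, function(x) {
    c(list(R_eff = x$R, P_eff = x$P),
      if (!is.null(x$Pc)) list(P_comp = x$Pc))
  })
}

# Build the discretised network: grids, wall fields, topology indices.
build_network <- function(tree, cfg) {
  seg <- tree$segments
  nv <- nrow(seg)
  dx_target <- cfg$solver$dx
  min_nodes <- cfg$solver$min_nodes
  grids <- vector("list", nv)
  off <- 0L
  for (v in seq_len(nv)) {
    L <- seg$length[v]
    n <- max(min_nodes, ceiling(L / dx_target) + 1)
    dx <- L / (n - 1)
    x <- seq(0, L, length.out = n)
    r0 <- seg$r_prox[v] + (seg$r_dist[v] - seg$r_prox[v]) * x / L
    drdx <- (seg$r_dist[v] - seg$r_prox[v]) / L
    Ehr <- cfg$wall$k1 * exp(cfg$wall$k2 * r0) + cfg$wall$k3
    f <- 4 / 3 * Ehr
    dfdx <- 4 / 3 * cfg$wall$k1 * cfg$wall$k2 * exp(cfg$wall$k2 * r0) * drdx
    A0 <- pi * r0^2
    dA0dx <- 2 * pi * r0 * drdx
    grids[[v]] <- list(off = off, n = as.integer(n), dx = dx, x = x,
                       r0 = r0, A0 = A0, f = f, dfdx = dfdx, dA0dx = dA0dx)
    off <- off + as.integer(n)
  }
  names(grids) <- seg$name
  list(grids = grids, n_nodes = off)
}

# Which root tree does each segment belong to?
segment_root <- function(tree) {
  seg <- tree$segments
  parent <- setNames(seg$parent, seg$name)
  vapply(seg$name, function(nm) {
    while (!is.na(parent[[nm]])) nm <- parent[[nm]]
    nm
  }, "")
}

#' Run the coronary model to a periodic state
#'
#' Builds the full model from a configuration (geometry, structured-tree
#' impedances, heart waveforms, inlet calibration), integrates the 1D
#' equations with the two-step Lax-Wendroff scheme over repeated cardiac
#' cycles, and returns the first cycle for which the maximum pressure
#' change against the previous cycle (over every node) falls below the
#' tolerance.
#'
#' @param config a [coronary_config()].
#' @param tree optionally a prebuilt binary `coronary_tree` (default:
#'   loaded from `config$geometry$path` and trifurcation-split).
#' @param quiet suppress per-cycle convergence messages.
#' @return object of class `coro_run`: config, tree, grids, time grid `t`
#'   (one period, `n_kernel` samples), matrices `A`, `q`, `p` (samples x
#'   nodes, CGS), inlet object, impedance spectra, and diagnostics.
#' @export
run_to_periodic <- function(config = coronary_config(), tree = NULL,
                            quiet = TRUE) {
  cfg <- config
  if (is.null(tree)) {
    tree <- load_vessel_table(cfg$geometry$path)
    sc <- cfg$geometry$scale
    if (!identical(sc, 1.0) || isTRUE(cfg$geometry$scale_lcx_only)) {
      tree <- scale_tree(tree, sc, cfg$geometry$scale_lcx_only)
    }
    d2sc <- if (isTRUE(cfg$geometry$scale_lcx_only)) 1.0 else sc
    lm <- tree$segments$name[
      vapply(tree$segments$daughters, length, 0L) == 3]
    if (length(lm) == 1) {
      tree <- split_trifurcation(tree, cfg$geometry$d2_radius * d2sc,
                                 cfg$geometry$d2_length * d2sc, lmca = lm)
    }
  }
  seg <- tree$segments
  net <- build_network(tree, cfg)
  grids <- net$grids
  nv <- nrow(seg)

  # structured-tree parameters (alpha, beta re-derived when xi overridden)
  tp <- structured_tree_params(
    alpha = cfg$tree$alpha, beta = cfg$tree$beta, xi = cfg$tree$xi,
    gamma = cfg$tree$gamma, eta = cfg$tree$eta, r_min = cfg$tree$r_min,
    l_rr = cfg$tree$l_rr, derive_from_xi = cfg$tree$derive_from_xi
  )
  vp <- small_vessel_params(rho = cfg$blood$rho, mu = cfg$blood$mu,
                            k1 = cfg$wall$k1, k2 = cfg$wall$k2,
                            k3 = cfg$wall$k3, period = cfg$heart$t_c)

  # heart waveforms
  hl <- cfg$heart$left; hr <- cfg$heart$right
  vpl <- ventricle_params("left", p0 = hl$p0, Es = hl$Es, Ed = hl$Ed,
                          V0 = hl$V0, Rv = hl$Rv,
                          t_s = cfg$heart$t_s, t_c = cfg$heart$t_c)
  vpr <- ventricle_params("right", p0 = hr$p0, Es = hr$Es, Ed = hr$Ed,
                          V0 = hr$V0, Rv = hr$Rv,
                          t_s = cfg$heart$t_s, t_c = cfg$heart$t_c)
  voll <- volume_model(hl$V_ed, hl$SV, cfg$heart$t_s, cfg$heart$t_c)
  volr <- volume_model(hr$V_ed, hr$SV, cfg$heart$t_s, cfg$heart$t_c)
  heart <- list(left = vpl, right = vpr, vol_left = voll, vol_right = volr,
                sigma_half = cfg$heart$sigma_half)
  fp <- feedback_params(phi = cfg$feedback$phi,
                        phi_terminal = cfg$feedback$phi_terminal,
                        p_s = cfg$feedback$p_s)
  supply <- coronary_supply_map()

  t_c <- cfg$heart$t_c
  n_k <- cfg$solver$n_kernel
  t_grid <- (0:(n_k - 1)) * t_c / n_k

  # reference pressure per tree side: time-average ventricular pressure
  pv_left <- ventricular_pressure(t_grid, vpl, voll, cfg$heart$sigma_half)
  pv_right <- ventricular_pressure(t_grid, vpr, volr, cfg$heart$sigma_half)
  p0_side <- c(left = mean(pv_left), right = mean(pv_right)) # mmHg
  roots <- segment_root(tree)
  is_right <- roots[seg$name] == "RCA"
  p0_seg <- ifelse(is_right, p0_side["right"], p0_side["left"]) # mmHg

  terminals <- seg$name[seg$terminal]
  pf_fun <- function(nm, t) feedback_pressure(t, nm, fp, heart, supply)

  # reference (baseline) physiology: terminal-load calibration and the
  # lumped inlet model are computed on the reference configuration and
  # held fixed across scenario overrides
  ref <- reference_config(cfg)
  ref_tree <- load_vessel_table(ref$geometry$path)
  lm <- ref_tree$segments$name[
    vapply(ref_tree$segments$daughters, length, 0L) == 3]
  if (length(lm) == 1) {
    ref_tree <- split_trifurcation(ref_tree, ref$geometry$d2_radius,
                                   ref$geometry$d2_length, lmca = lm)
  }
  ref_tp <- structured_tree_params(
    alpha = ref$tree$alpha, beta = ref$tree$beta, xi = ref$tree$xi,
    gamma = ref$tree$gamma, eta = ref$tree$eta, r_min = ref$tree$r_min,
    l_rr = ref$tree$l_rr, derive_from_xi = ref$tree$derive_from_xi
  )
  ref_fp <- feedback_params(phi = ref$feedback$phi,
                            phi_terminal = ref$feedback$phi_terminal,
                            p_s = ref$feedback$p_s)
  ref_pf_fun <- function(nm, t) feedback_pressure(t, nm, ref_fp, heart, supply)
  sysp <- do.call(systemic_params, cfg$inlet$systemic)
  aw <- aortic_pressure_waveform(sysp, cfg$heart$t_s, t_c, n_k)
  ref_terminals <- ref_tree$segments$name[ref_tree$segments$terminal]
  Zt <- cfg$impedance$Z_terminal
  if (identical(Zt, "auto")) {
    pf_mean <- vapply(ref_terminals,
                      function(nm) mean(ref_pf_fun(nm, t_grid)), 0)
    q_target <- cfg$inlet$coronary_fraction * mean(aw$q_ao)
    Zt <- calibrate_terminal_load(ref_tree, ref_tp, vp, pf_mean,
                                  mean(aw$p_a), q_target, cfg$blood$mu)
  }

  # terminal impedances and kernels (run configuration, calibrated load)
  spectra <- lapply(terminals, function(nm) {
    r_root <- seg$r_dist[seg$name == nm]
    root_impedance(r_root, tp, vp, n_harm = n_k / 2, Z_terminal = Zt + 0i,
                   tau_cap = cfg$impedance$tau_cap)
  })
  names(spectra) <- terminals
  kernels <- vapply(spectra, function(s) impedance_to_kernel(s, n_k),
                    numeric(n_k))

  # inlet estimated from the reference DC network
  ref_bed_dc <- vapply(ref_terminals, function(nm) {
    r <- ref_tree$segments$r_dist[ref_tree$segments$name == nm]
    root_impedance_dc(r, ref_tp, vp, Z_terminal = Zt)
  }, 0)
  comp_fp <- feedback_params(phi = c(left_ventricle = cfg$inlet$phi_comp,
                                     right_ventricle = cfg$inlet$phi_comp,
                                     septum = cfg$inlet$phi_comp),
                             p_s = ref$feedback$p_s)
  comp_fun <- function(nm, t) feedback_pressure(t, nm, comp_fp, heart, supply)
  ref_dc <- tree_dc_reduction(ref_tree, ref_bed_dc, ref_pf_fun, t_grid,
                              cfg$blood$mu, pf_fun_comp = comp_fun)
  inlet <- inlet_waveform(ref_dc, heart, sys = sysp,
                          coronary_fraction = cfg$inlet$coronary_fraction,
                          n = n_k, mode = cfg$inlet$mode,
                          fr_prox = cfg$inlet$fr_prox,
                          tau_im = cfg$inlet$tau_im)
  inlet$Z_terminal <- Zt

  # time step from a CFL estimate at the reference state
  c_ref <- unlist(lapply(grids, function(g) {
    sqrt(g$f / (2 * cfg$blood$rho))
  }))
  dx_min <- min(vapply(grids, function(g) g$dx, 0))
  c_max <- 1.3 * max(c_ref) + 150
  dt_max <- cfg$solver$cfl * dx_min / c_max
  n_steps <- as.integer(n_k * ceiling(t_c / (n_k * dt_max)))
  dt <- t_c / n_steps

  # per-step inlet and feedback waveforms
  step_t <- (0:(n_steps - 1)) * dt
  interp_per <- function(y) {
    approx(x = c(t_grid, t_c), y = c(y, y[1]), xout = step_t)$y
  }
  root_names <- tree$roots
  inlet_mode <- if (inlet$mode == "pressure") 1L else 0L
  inlet_wave <- vapply(root_names, function(nm) {
    if (inlet_mode == 1L) mmHg_to_cgs(interp_per(inlet$p_in))
    else interp_per(inlet$q[[nm]])
  }, numeric(n_steps))

  pf_steps <- vapply(terminals, function(nm) {
    mmHg_to_cgs(pf_fun(nm, step_t))
  }, numeric(n_steps))

  # flatten node fields
  node_A0 <- unlist(lapply(grids, `[[`, "A0"), use.names = FALSE)
  node_f <- unlist(lapply(grids, `[[`, "f"), use.names = FALSE)
  node_dA0 <- unlist(lapply(grids, `[[`, "dA0dx"), use.names = FALSE)
  node_df <- unlist(lapply(grids, `[[`, "dfdx"), use.names = FALSE)
  node_p0 <- unlist(lapply(seq_len(nv), function(v) {
    rep(mmHg_to_cgs(p0_seg[v]), grids[[v]]$n)
  }), use.names = FALSE)

  vtab <- lapply(grids, function(g) list(off = g$off, n = g$n, dx = g$dx))
  vidx <- setNames(seq_len(nv) - 1L, seg$name)
  internal <- seg$name[!seg$terminal]
  junc <- t(vapply(internal, function(nm) {
    kids <- seg$daughters[[which(seg$name == nm)]]
    c(vidx[nm], vidx[kids[1]], vidx[kids[2]])
  }, integer(3)))
  if (length(internal) == 0) junc <- matrix(integer(0), 0, 3)

  delta <- sqrt(cfg$blood$mu / cfg$blood$rho * t_c / (2 * pi))

  res <- cw_run_network(
    vessels = unname(vtab),
    node_A0 = node_A0, node_f = node_f, node_dA0dx = node_dA0,
    node_dfdx = node_df, node_p0 = node_p0,
    rho = cfg$blood$rho, nu = cfg$blood$mu / cfg$blood$rho,
    delta = delta, dt = dt, n_steps = n_steps, n_rec = n_k,
    junctions = junc,
    inlet_vessel = unname(vidx[root_names]), inlet_mode = inlet_mode,
    inlet_wave = inlet_wave,
    outlet_vessel = unname(vidx[terminals]), outlet_kernel = kernels,
    outlet_pf = pf_steps,
    max_cycles = cfg$solver$max_cycles,
    tol = mmHg_to_cgs(cfg$solver$tol_mmHg),
    newton_tol = cfg$solver$newton_tol,
    newton_maxit = cfg$solver$newton_maxit
  )
  if (!quiet) {
    message(sprintf("converged=%s after %d cycles (dP %.3g mmHg)",
                    res$converged, res$cycles,
                    cgs_to_mmHg(tail(res$conv_history, 1))))
  }

  structure(list(
    config = cfg, tree = tree, grids = grids, t = t_grid,
    A = res$A, q = res$q, p = res$p,
    inlet = inlet, spectra = spectra, heart = heart, feedback = fp,
    p0_side = p0_side, dt_solver = dt, n_steps = n_steps,
    diagnostics = list(
      cycles = res$cycles, converged = res$converged,
      conv_history = cgs_to_mmHg(res$conv_history),
      max_junction_residual = res$max_junction_residual,
      cfl_max = res$cfl_max,
      mass_net = setNames(as.numeric(res$mass_net), seg$name),
      mass_throughput = setNames(as.numeric(res$mass_throughput), seg$name),
      flux_imbalance = setNames(as.numeric(res$flux_imbalance), seg$name),
      zero_padded_first_cycle = res$zero_padded_first_cycle
    )
  ), class = "coro_run")
}

# Uniformly scale lengths and radii (whole tree or LCX subtree only).
scale_tree <- function(tree, scale, lcx_only = FALSE) {
  seg <- tree$segments
  if (lcx_only) {
    inlcx <- rep(FALSE, nrow(seg))
    roots <- segment_root(tree)
    in_subtree <- function(nm) {
      while (!is.na(nm)) {
        if (nm == "LCX") return(TRUE)
        nm <- seg$parent[seg$name == nm]
      }
      FALSE
    }
    inlcx <- vapply(seg$name, in_subtree, TRUE)
    seg$length[inlcx] <- seg$length[inlcx] * scale
    seg$r_prox[inlcx] <- seg$r_prox[inlcx] * scale
    seg$r_dist[inlcx] <- seg$r_dist[inlcx] * scale
  } else {
    seg$length <- seg$length * scale
    seg$r_prox <- seg$r_prox * scale
    seg$r_dist <- seg$r_dist * scale
  }
  new_coronary_tree(seg[, c("name", "length", "r_prox", "r_dist", "parent")])
}

#' Extract a time series at a probe station
#'
#' @param run a `coro_run`.
#' @param vessel segment name.
#' @param station `"mid"`, `"inlet"`, `"outlet"`, or a position in cm.
#' @return tibble with `t` (s), `x` (cm), `A` (cm^2), `q` (ml s^-1),
#'   `u` (cm s^-1), `p` (mmHg).
#' @export
run_series <- function(run, vessel, station = "mid") {
  g <- run$grids[[vessel]]
  if (is.null(g)) abort(paste0("unknown vessel: ", vessel))
  j <- if (identical(station, "mid")) {
    as.integer(round((g$n + 1) / 2))
  } else if (identical(station, "inlet")) 1L
  else if (identical(station, "outlet")) g$n
  else which.min(abs(g$x - station))
  col <- g$off + j
  A <- run$A[, col]; q <- run$q[, col]; p <- run$p[, col]
  tibble(t = run$t, x = g$x[j], A = A, q = q, u = q / A, p = cgs_to_mmHg(p))
}

#' Per-vessel cycle summary of a run
#'
#' @param x a `coro_run`.
#' @param ... unused.
#' @return tibble with one row per vessel: peak/mean pressure (mmHg), peak
#'   and mean flow (ml s^-1), peak velocity (cm s^-1), time of peak flow.
#' @export
tidy.coro_run <- function(x, ...) {
  purrr::map_dfr(names(x$grids), function(nm) {
    s <- run_series(x, nm, "mid")
    tibble(
      vessel = nm,
      p_peak = max(s$p), p_min = min(s$p), p_mean = mean(s$p),
      q_peak = max(s$q), q_mean = mean(s$q),
      u_peak = max(s$u), u_mean = mean(s$u),
      t_q_peak = s$t[which.max(s$q)]
    )
  })
}

#' One-line diagnostics of a run
#'
#' @param x a `coro_run`.
#' @param ... unused.
#' @return tibble with convergence and balance diagnostics; `fraction` is
#'   the achieved mean coronary inflow over cardiac output.
#' @export
glance.coro_run <- function(x, ...) {
  qin <- sum(vapply(x$tree$roots, function(r) {
    mean(run_series(x, r, "inlet")$q)
  }, 0))
  CO_mls <- x$inlet$CO * 1000 / 60
  d <- x$diagnostics
  mass <- max(abs(d$mass_net) / pmax(d$mass_throughput, 1e-12))
  flux <- max(abs(d$flux_imbalance) / pmax(d$mass_throughput, 1e-12))
  tibble(
    cycles = d$cycles, converged = d$converged,
    final_dP_mmHg = tail(d$conv_history, 1),
    max_junction_residual = d$max_junction_residual,
    cfl_max = d$cfl_max,
    mass_error = mass,
    flux_consistency = flux,
    CO_L_min = x$inlet$CO,
    coronary_fraction = qin / CO_mls
  )
}

#' @export
print.coro_run <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<coro_run> %d vessels, %d samples/period, %s after %d cycles\n",
              length(x$grids), length(x$t),
              if (d$converged) "converged" else "NOT converged", d$cycles))
  invisible(x)
}

#' Write per-vessel midpoint time series to delimited text
#'
#' @param run a `coro_run`.
#' @param path output file (CSV).
#' @param vessels vessels to include (default all).
#' @param station probe station, as in [run_series()].
#' @return `path`, invisibly.
#' @export
write_run_series <- function(run, path, vessels = names(run$grids),
                             station = "mid") {
  out <- purrr::map_dfr(vessels, function(nm) {
    dplyr::mutate(run_series(run, nm, station), vessel = nm, .before = 1)
  })
  readr::write_csv(out, path)
  invisible(path)
}
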