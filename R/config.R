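#' Full model configuration
#'
#' Assembles all parameter groups with their published defaults. Any entry
#' can be overridden with [config_set()] using a dotted path, e.g.
#' `config_set(cfg, "wall.k3", 2 * 8.65e5)`.
#'
#' @param ... named overrides applied with [config_set()] (dotted paths).
#' @return nested list of class `coronary_config`.
#' @export
coronary_config <- function(...) {
  cfg <- list(
    geometry = list(
      path = coronary_table1(),
      d2_radius = 0.185, d2_length = 0.25,
      scale = 1.0, scale_lcx_only = FALSE
    ),
    tree = list(
      alpha = 0.9, beta = 0.6, xi = 2.76, gamma = 0.41, eta = 1.16,
      r_min = 1e-3, l_rr = 25, derive_from_xi = FALSE
    ),
    blood = list(rho = 1.055, mu = 0.0047),
    wall = list(k1 = 2e7, k2 = -22.5, k3 = 8.65e5),
    heart = list(
      t_s = 0.4, t_c = 0.9, sigma_half = FALSE,
      left = list(p0 = 50, Es = 1.375, Ed = 0.1, V0 = 11.29, Rv = 0.08,
                  V_ed = 26.3, SV = 12),
      right = list(p0 = 24, Es = 0.3288, Ed = 0.03, V0 = 3.33, Rv = 0.0175,
                   V_ed = 11.3, SV = 6)
    ),
    feedback = list(
      phi = c(left_ventricle = 0.33, right_ventricle = 0.25, septum = 0.22),
      phi_terminal = NULL, p_s = 20
    ),
    inlet = list(
      mode = "flow", coronary_fraction = 0.045,
      fr_prox = 0.3, tau_im = 0.1, phi_comp = 0.85,
      systemic = list(SV = 75, Zc = 0.04, Rp = 1.10, C = 1.7, p_ven = 5)
    ),
    impedance = list(Z_terminal = "auto", tau_cap = 0.2),
    solver = list(
      dx = 0.1, min_nodes = 8, cfl = 0.5, n_kernel = 4096,
      tol_mmHg = 0.5, max_cycles = 20, newton_tol = 1e-11, newton_maxit = 60
    )
  )
  cfg <- structure(cfg, class = "coronary_config")
  dots <- list(...)
  for (nm in names(dots)) cfg <- config_set(cfg, nm, dots[[nm]])
  cfg
}

#' Set a configuration entry by dotted path
#'
#' @param cfg a `coronary_config`.
#' @param path dotted path, e.g. `"tree.xi"`.
#' @param value new value.
#' @return modified configuration.
#' @export
config_set <- function(cfg, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  ref <- cfg
  for (k in keys[-length(keys)]) {
    if (is.null(ref[[k]])) abort(paste0("unknown config path: ", path))
    ref <- ref[[k]]
  }
  last <- keys[length(keys)]
  if (!(last %in% names(ref))) abort(paste0("unknown config path: ", path))
  cfg[[keys]] <- value
  cfg
}

#' Get a configuration entry by dotted path
#' @param cfg a `coronary_config`.
#' @param path dotted path.
#' @return the value.
#' @export
config_get <- function(cfg, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  out <- cfg
  for (k in keys) out <- out[[k]]
  out
}

#' Reference (baseline) configuration of a run
#'
#' The lumped inlet model and the terminal-load calibration are properties
#' of the baseline physiology: they are computed from the configuration
#' with the scenario overrides on geometry scaling, structured-tree
#' parameters, wall stiffness and per-terminal feedback reverted to their
#' defaults, and are then held fixed while the scenario changes the 1D
#' network. This mirrors a fixed upstream circulation: a diseased coronary
#' bed does not change the aorta.
#'
#' @param cfg a `coronary_config`.
#' @return the reference `coronary_config`.
#' @export
reference_config <- function(cfg) {
  def <- coronary_config()
  ref <- cfg
  ref$tree <- def$tree
  ref$wall <- def$wall
  ref$geometry$scale <- 1.0
  ref$geometry$scale_lcx_only <- FALSE
  ref$geometry$d2_radius <- def$geometry$d2_radius
  ref$geometry$d2_length <- def$geometry$d2_length
  ref$feedback$phi_terminal <- NULL
  ref
}

#' Coarse-resolution configuration preset
#'
#' Reduced discretisation (dx 0.2 cm, 1024 kernel samples per period,
#' 5-node minimum) for rapid iteration and continuous-integration runs;
#' results agree with the default resolution to within a few percent.
#'
#' @param ... further overrides, as in [coronary_config()].
#' @return a `coronary_config`.
#' @export
coronary_config_coarse <- function(...) {
  coronary_config(
    "solver.dx" = 0.2, "solver.n_kernel" = 1024, "solver.min_nodes" = 5,
    "solver.tol_mmHg" = 0.5, ...
  )
}

#' @export
print.coronary_config <- function(x, ...) {
  cat("<coronary_config>\n")
  str(x, max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' @importFrom utils str
NULL
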