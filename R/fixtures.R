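#' Explicit toy structured tree
#'
#' Enumerates a small self-similar binary tree vessel-by-vessel (no radius
#' lattice, no memoisation), for use as a brute-force oracle against the
#' lattice-based impedance recursion. Daughter radii are `alpha r` and
#' `beta r`; branching stops below `r_min` or at the generation cap.
#' Optionally the radii are perturbed with a seeded multiplicative jitter
#' (which breaks self-similarity, so the lattice representation no longer
#' applies and the tree must be enumerated).
#'
#' @param generations maximum depth (root = generation 0; keep `<= 6` for
#'   brute-force use).
#' @param r_root root radius, cm.
#' @param alpha,beta daughter radius ratios.
#' @param l_rr length-to-radius ratio.
#' @param r_min minimum radius, cm (0: depth-limited only).
#' @param jitter sd of multiplicative log-normal radius perturbation.
#' @param seed RNG seed for the perturbation.
#' @return tibble with `id`, `parent` (0 for the root's parent), `depth`,
#'   `radius`, `length`, `n_alpha`, `n_beta`.
#' @export
make_toy_tree <- function(generations, r_root, alpha = 0.9, beta = 0.6,
                          l_rr = 25, r_min = 0, jitter = 0, seed = 1L) {
  if (generations > 6) abort("keep generations <= 6 for brute-force oracles")
  if (jitter > 0) set.seed(seed)
  rows <- list()
  nid <- 0L
  grow <- function(parent, depth, radius, ia, ib) {
    nid <<- nid + 1L
    id <- nid
    r <- radius
    if (jitter > 0) r <- r * exp(stats::rnorm(1, 0, jitter))
    rows[[id]] <<- tibble(id = id, parent = parent, depth = depth,
                          radius = r, length = l_rr * r,
                          n_alpha = ia, n_beta = ib)
    if (depth < generations) {
      if (alpha * radius >= r_min * (1 - 1e-12)) {
        grow(id, depth + 1L, alpha * radius, ia + 1L, ib)
      }
      if (beta * radius >= r_min * (1 - 1e-12)) {
        grow(id, depth + 1L, beta * radius, ia, ib + 1L)
      }
    }
  }
  grow(0L, 0L, r_root, 0L, 0L)
  dplyr::bind_rows(rows)
}

#' Brute-force impedance of an explicit toy tree
#'
#' Vessel-by-vessel recursion (parallel daughters, transmission line per
#' vessel, Poiseuille limit at omega = 0) without any lattice memoisation;
#' independent oracle for [root_impedance()].
#'
#' @param toy tibble from [make_toy_tree()].
#' @param vessel_params a [small_vessel_params()] object.
#' @param omega angular frequencies, rad s^-1 (0 allowed).
#' @param Z_terminal terminal load.
#' @return complex matrix, rows = frequencies.
#' @export
toy_tree_impedance <- function(toy, vessel_params, omega,
                               Z_terminal = 0 + 0i) {
  vp <- vessel_params
  zin <- function(id, w) {
    row <- toy[toy$id == id, ]
    kids <- toy$id[toy$parent == id]
    ZL <- if (length(kids) == 0) {
      Z_terminal
    } else if (length(kids) == 1) {
      zin(kids, w)
    } else {
      1 / (1 / zin(kids[1], w) + 1 / zin(kids[2], w))
    }
    if (w == 0) {
      8 * vp$mu * row$length / (pi * row$radius^4) + ZL
    } else {
      A0 <- pi * row$radius^2
      K <- womersley_factor(w, row$radius, vp)
      Cc <- compliance(row$radius, vp)
      cc <- sqrt(A0 * K / (vp$rho * Cc))
      g <- sqrt(Cc * A0 * K / vp$rho)
      transmission_line_impedance(ZL, row$length, cc, g, w)
    }
  }
  root <- toy$id[toy$parent == 0]
  vapply(omega, function(w) zin(root, w), complex(1))
}

#' Brute-force Poiseuille network reduction of a toy tree
#'
#' Direct series/parallel graph elimination of the DC resistance network;
#' oracle for the DC branch of [root_impedance()].
#'
#' @param toy tibble from [make_toy_tree()].
#' @param mu blood viscosity.
#' @return DC resistance (CGS).
#' @export
toy_tree_dc_resistance <- function(toy, mu) {
  rdc <- function(id) {
    row <- toy[toy$id == id, ]
    R <- 8 * mu * row$length / (pi * row$radius^4)
    kids <- toy$id[toy$parent == id]
    if (length(kids) == 0) return(R)
    if (length(kids) == 1) return(R + rdc(kids))
    R + 1 / (1 / rdc(kids[1]) + 1 / rdc(kids[2]))
  }
  rdc(toy$id[toy$parent == 0])
}

#' Synthetic pressure/velocity waveforms with known decomposition
#'
#' Constructs sampled (p, u) series whose forward/backward split is known
#' analytically through the water-hammer relations `dp = +/- rho c du`:
#' a pure forward pulse, a pure backward pulse, or a mixture with a known
#' energy split.
#'
#' @param kind `"forward_pulse"`, `"backward_pulse"` or `"mixed"`.
#' @param n samples (`>= 16`).
#' @param seed RNG seed (pulse placement jitter).
#' @param rho density, g cm^-3.
#' @param c wave speed, cm s^-1 (constant).
#' @param mix forward fraction of the velocity amplitude for `"mixed"`.
#' @return list with `t` (s), `p` (mmHg), `u` (cm s^-1), `c_p` (constant
#'   series), `rho`, and the constructed forward/backward components
#'   `u_fwd`, `u_bwd`.
#' @export
make_synthetic_waveforms <- function(kind = c("forward_pulse",
                                              "backward_pulse", "mixed"),
                                     n = 256, seed = 1L, rho = 1.055,
                                     c = 1000, mix = 0.7) {
  kind <- match.arg(kind)
  if (n < 16) abort("need n >= 16")
  set.seed(seed)
  t <- seq(0, 1, length.out = n)
  centre <- stats::runif(1, 0.3, 0.5)
  pulse <- function(t0, w) exp(-((t - t0) / w)^2)
  u_f <- u_b <- numeric(n)
  if (kind == "forward_pulse") {
    u_f <- 10 * pulse(centre, 0.05)
  } else if (kind == "backward_pulse") {
    u_b <- -8 * pulse(centre, 0.05)
  } else {
    u_f <- 10 * mix * pulse(centre, 0.05)
    u_b <- -10 * (1 - mix) * pulse(centre + 0.25, 0.04)
  }
  u <- u_f + u_b
  p_cgs <- rho * c * (u_f - u_b) # dp = +rho c du_f, dp = -rho c du_b
  list(t = t, p = cgs_to_mmHg(p_cgs + mmHg_to_cgs(80)), u = u,
       c_p = rep(c, n), rho = rho, u_fwd = u_f, u_bwd = u_b)
}

#' Write a toy tree's root segment table in the loader dialect
#'
#' Emits a geometry file readable by [load_vessel_table()], so synthetic
#' trees can round-trip through the same I/O path as measured ones.
#'
#' @param toy tibble from [make_toy_tree()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_toy_tree <- function(toy, path) {
  out <- tibble(
    name = paste0("V", toy$id),
    length_mm = toy$length * 10,
    r_prox_mm = toy$radius * 10,
    r_dist_mm = toy$radius * 10,
    parent = ifelse(toy$parent == 0, "", paste0("V", toy$parent))
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}
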