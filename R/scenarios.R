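#' Run a named scenario
#'
#' A scenario is a pure function of the base configuration and a set of
#' dotted-path overrides: rerunning with the same inputs reproduces the
#' outputs bit-for-bit (the model has no stochastic component). The
#' resolved configuration is embedded in the result for provenance.
#'
#' @param config base [coronary_config()].
#' @param overrides named list of dotted-path overrides.
#' @param name scenario label.
#' @param probe vessel probed for the summary metrics and six-wave table.
#' @param quiet suppress solver messages.
#' @return object of class `coro_scenario`: list with `name`, `run`
#'   (`coro_run`), `probe`, `metrics` (tibble), `six_waves`
#'   (`six_wave_table`), `config`.
#' @export
run_scenario <- function(config = coronary_config(), overrides = list(),
                         name = "scenario", probe = "LCX", quiet = TRUE) {
  cfg <- config
  for (nm in names(overrides)) cfg <- config_set(cfg, nm, overrides[[nm]])
  run <- run_to_periodic(cfg, quiet = quiet)
  s <- run_series(run, probe, "mid")
  dec <- run_wia(run, probe, "mid")
  sw <- segment_six_waves(dec, t_s = cfg$heart$t_s)
  metrics <- tibble(
    scenario = name, probe = probe,
    p_peak = max(s$p), p_min = min(s$p),
    u_peak = max(s$u), q_peak = max(s$q), q_mean = mean(s$q),
    wi_peak = max(abs(c(dec$wi_plus, dec$wi_minus))),
    fdw_peak = fdw_peak(dec, sw),
    t_q_peak = s$t[which.max(s$q)]
  )
  structure(list(name = name, run = run, probe = probe, metrics = metrics,
                 six_waves = sw, decomposition = dec, config = cfg),
            class = "coro_scenario")
}

# Peak forward-decompression intensity within the labelled FDW window
# (falls back to the global peak of the decompression part of WI+).
fdw_peak <- function(dec, sw) {
  row <- sw[sw$type == "FDW", ]
  if (nrow(row) >= 1) {
    w <- dec$t >= row$t_start[1] & dec$t <= row$t_end[1]
    return(max(abs(dec$wi_plus[w])))
  }
  neg <- dec$dp_plus < 0
  if (!any(neg)) return(0)
  max(abs(dec$wi_plus[neg]))
}

#' @export
print.coro_scenario <- function(x, ...) {
  cat(sprintf("<coro_scenario> %s (probe %s)\n", x$name, x$probe))
  print(x$metrics)
  invisible(x)
}

#' Case A: stiffened large arteries
#'
#' Doubles the constant wall-stiffness coefficient `k3` everywhere
#' (`Eh/r0 = k1 exp(k2 r0) + k3`), modelling arterial stiffening, and
#' reports the probe metrics and six-wave table.
#'
#' @param config base configuration.
#' @param probe probed vessel.
#' @param quiet suppress messages.
#' @return a `coro_scenario`.
#' @export
run_case_A <- function(config = coronary_config(), probe = "LCX",
                       quiet = TRUE) {
  run_scenario(config,
               overrides = list("wall.k3" = 2 * config$wall$k3),
               name = "case_A_stiffening", probe = probe, quiet = quiet)
}

#' Case B: vascular rarefaction
#'
#' Reduces the structured-tree radius exponent from its baseline to
#' `xi = 2.4` (loss of small vessels in the beds). The daughter ratios
#' `alpha`, `beta` are re-derived from `(gamma, xi)` so the exponent
#' actually propagates into the tree; only the bed impedances change.
#'
#' @param config base configuration.
#' @param xi reduced radius exponent.
#' @param probe probed vessel.
#' @param quiet suppress messages.
#' @return a `coro_scenario`.
#' @export
run_case_B <- function(config = coronary_config(), xi = 2.4, probe = "LCX",
                       quiet = TRUE) {
  run_scenario(config,
               overrides = list("tree.xi" = xi, "tree.derive_from_xi" = TRUE),
               name = "case_B_rarefaction", probe = probe, quiet = quiet)
}

#' Case C: feedback-pressure sweep
#'
#' Varies the ventricular-pressure feedback ratio phi of one terminal
#' vessel's bed and reports systolic and diastolic mean flow at the probe.
#'
#' @param config base configuration.
#' @param phi_values feedback ratios to sweep.
#' @param terminal terminal vessel whose phi is varied.
#' @param probe probed vessel (default: the varied terminal).
#' @param quiet suppress messages.
#' @return list with `sweep` (tibble: phi, systolic/diastolic mean flow,
#'   peaks) and `runs` (list of `coro_run`).
#' @export
run_case_C <- function(config = coronary_config(),
                       phi_values = c(0, 0.22, 0.33, 0.6),
                       terminal = "LAD1", probe = terminal, quiet = TRUE) {
  t_s <- config$heart$t_s
  runs <- lapply(phi_values, function(phi) {
    cfg <- config_set(config, "feedback.phi_terminal",
                      setNames(phi, terminal))
    run_to_periodic(cfg, quiet = quiet)
  })
  sweep <- purrr::map2_dfr(runs, phi_values, function(r, phi) {
    s <- run_series(r, probe, "mid")
    sys <- s$t < t_s
    tibble(phi = phi,
           q_sys = mean(s$q[sys]), q_dia = mean(s$q[!sys]),
           q_peak = max(s$q), p_peak = max(s$p))
  })
  list(sweep = sweep, runs = runs, terminal = terminal, probe = probe)
}

#' Case D: geometric scaling of the coronary tree
#'
#' Scales all lengths and radii of the tree (default: the whole tree, per
#' the reported systemic effect sizes; set
#' `config_set(config, "geometry.scale_lcx_only", TRUE)` to scale the LCX
#' subtree only) and reports peak flow velocity, pressure, wave intensity
#' and forward-decompression-wave intensity at the probe as percentages of
#' the baseline values.
#'
#' @param config base configuration.
#' @param scales size factors.
#' @param probe probed vessel.
#' @param baseline optional precomputed baseline `coro_scenario` to reuse.
#' @param quiet suppress messages.
#' @return list with `table` (tibble: scale_pct, flow_peak_pct,
#'   pressure_peak_pct, wi_peak_pct, fdw_peak_pct), `scenarios`,
#'   `baseline`.
#' @export
run_case_D <- function(config = coronary_config(),
                       scales = c(0.90, 0.95, 1.05, 1.10),
                       probe = "LCX", baseline = NULL, quiet = TRUE) {
  if (is.null(baseline)) {
    baseline <- run_scenario(config, name = "baseline", probe = probe,
                             quiet = quiet)
  }
  scen <- lapply(scales, function(sc) {
    run_scenario(config, overrides = list("geometry.scale" = sc),
                 name = sprintf("case_D_scale_%g", sc), probe = probe,
                 quiet = quiet)
  })
  b <- baseline$metrics
  table <- purrr::map2_dfr(scen, scales, function(s, sc) {
    m <- s$metrics
    tibble(
      scale_pct = 100 * sc,
      flow_peak_pct = 100 * m$u_peak / b$u_peak,
      pressure_peak_pct = 100 * m$p_peak / b$p_peak,
      wi_peak_pct = 100 * m$wi_peak / b$wi_peak,
      fdw_peak_pct = 100 * m$fdw_peak / b$fdw_peak
    )
  })
  list(table = table, scenarios = scen, baseline = baseline)
}
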