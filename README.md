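# corowave

One-dimensional pulse-wave simulation of the human coronary arterial
tree, for physiologists and modellers who want coronary pressure, flow and
wave-intensity waveforms at arbitrary network locations under healthy and
diseased conditions.

The model solves the cross-sectionally averaged continuity and momentum
equations on a measured 17-segment coronary network (left main and right
coronary trees, with the left-main trifurcation modelled as two adjacent
bifurcations),

```
A_t + q_x = 0
q_t + (q²/A)_x + (A/ρ) p_x = −2πνr q / (δA),     p = p0 + (4/3)(Eh/r0)(1 − √(A0/A))
```

with a two-step Lax–Wendroff scheme. Every terminal artery drains into a
structured-tree vascular bed — a self-similar binary tree (radius ratios
α = 0.9, β = 0.6, minimum radius 10 µm) whose complex root impedance
Z(0, ω) is computed by a Womersley/transmission-line recursion over the
radius lattice and applied in the time domain as a convolution. Myocardial
contraction feeds back on the beds as p_f(t) = φ·p_v(t) + p_s, with
ventricular pressures from a time-varying elastance model. Wave-intensity
analysis splits the simulated waveforms into forward/backward
compression/decompression waves and segments the six canonical coronary
wave phases (a–f).

See `vignettes/corowave-methods.Rmd` for the model, its closures and the
numerical choices.

## Worked example

```r
library(corowave)

cfg  <- coronary_config_coarse()   # fast profile; coronary_config() for full resolution
base <- run_scenario(cfg, name = "baseline", probe = "LCX")

glance(base$run)
#>   cycles converged final_dP_mmHg max_junction_residual cfl_max mass_error
#> 1      4 TRUE              0.418             1.000e-11   0.190   0.000589
#>   flux_consistency CO_L_min coronary_fraction
#> 1           0.0363     5.00             0.045
```

The run reached a periodic state in 4 cardiac cycles (cycle-to-cycle
pressure change 0.42 mmHg), with junction residuals at 1e−11, a net
volume change per cycle of 0.06% of throughput, and the mean coronary
inflow calibrated to 4.5% of a 5.0 L/min cardiac output.

```r
dplyr::filter(tidy(base$run), vessel %in% c("LMCA", "LAD", "LCX", "RCA"))
#>   vessel p_peak p_min p_mean q_peak q_mean u_peak u_mean t_q_peak
#> 1 RCA      116.  97.7  106.    1.14  0.932   14.5   11.7    0.456
#> 2 LMCA     117.  79.8   98.0   3.95  2.82    33.8   23.7    0.454
#> 3 LAD      118.  79.4   97.9   1.75  1.23    23.6   16.4    0.454
#> 4 LCX      118.  79.5   97.9   1.58  1.15    21.4   15.5    0.446
```

Pressures are ~118/80 mmHg; peak flow in the left vessels occurs at
t ≈ 0.45 s — after end-systole (t_s = 0.4 s), the diastolic-dominant
pattern characteristic of the left coronary circulation, while the RCA is
less diastolic-dominant.

```r
base$six_waves
#>   wave type  t_start t_end t_peak   energy percent
#> 1 a    BCW    0.0176 0.159 0.0809 2816420.   23.9
#> 2 d    FDW    0.142  0.332 0.234  1803531.   15.3
#> 3 e    BDW    0.173  0.373 0.272  6479447.   55.0
#> 4 f    FCW    0.379  0.586 0.410   670771.    5.70
```

The backward decompression wave (e), generated by myocardial relaxation
decompressing the intramural beds, carries the largest energy share —
the hallmark of coronary wave intensity. `autoplot(base$run)`,
`autoplot(base$decomposition)` and `autoplot(base$six_waves)` plot the
waveforms, the wave-intensity channels and the energy table.

Scenario runners reproduce the pathological experiments:
`run_case_A()` (arterial stiffening, k3 doubled), `run_case_B()`
(vascular rarefaction, radius exponent 2.76 → 2.4), `run_case_C()`
(feedback-ratio sweep) and `run_case_D()` (geometric scaling ±5/±10%).
A thin command-line wrapper is installed at `inst/cli/corowave`.

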