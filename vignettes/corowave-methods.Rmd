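---
title: "Modelling coronary pulse waves with corowave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling coronary pulse waves with corowave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

`corowave` simulates pulsatile blood flow in the large human coronary
arteries with a nonlinear one-dimensional model. A measured network of 17
tapered segments (two roots: the left main coronary artery and the right
coronary artery) carries cross-sectionally averaged continuity and momentum
equations for area $A(x,t)$ and flow $q(x,t)$:

$$\partial_t A + \partial_x q = 0, \qquad
  \partial_t q + \partial_x\!\left(\frac{q^2}{A}\right)
  + \frac{A}{\rho}\,\partial_x p = -\frac{2\pi \nu r}{\delta}\frac{q}{A},$$

closed by the tube law
$p = p_0 + \tfrac{4}{3}\frac{Eh}{r_0}\bigl(1 - \sqrt{A_0/A}\bigr)$ with the
radius-dependent stiffness $Eh/r_0 = k_1 e^{k_2 r_0} + k_3$. The viscous
drag uses a boundary-layer thickness $\delta = \sqrt{\nu t_c / 2\pi}$. All
internal computation is in CGS units (g, cm, s); pressures cross the user
interface in mmHg.

The printed momentum equation of the source model carries the friction
term without the $1/\rho$ factor that the divided-by-density form requires;
we use the dimensionally consistent $-2\pi\nu r q/(\delta A)$. The tube law
is the square-root (pressure-bounded) state equation that underlies the
published $k_1,k_2,k_3$ coefficients; a literal linear variant is available
via `tube_law_pressure(form = "linear")` for sensitivity.

Three boundary types close the network:

* **Inlet.** The aortic side is a minimal lumped model: a half-sine
  ejection of configurable stroke volume through a diode valve into a
  three-element windkessel, solved exactly per harmonic
  (`aortic_pressure_waveform()`). The coronary inflow of each root is then
  estimated from that aortic pressure through an intramyocardial
  windkessel (`coronary_inflow_estimate()`): the proximal (epicardial)
  share of the tree resistance feeds a compliant intramyocardial
  compartment whose back pressure is the myocardial compression pressure,
  and the microvascular share drains it. Systole charges the compartment
  and throttles inflow — the classic early-systolic dip — and its
  diastolic discharge makes left coronary inflow diastolic-dominant.
  The inflow is scaled by a single factor so the mean coronary flow is a
  configured fraction of cardiac output (default 4.5%). A pure
  pressure-imposed inlet is available (`inlet.mode = "pressure"`).
* **Junctions.** Flow conservation and static-pressure continuity,
  combined with the outgoing characteristic of each vessel, solved by a
  damped Newton iteration to a scaled residual below $10^{-11}$ each step.
  The measured left-main trifurcation is first split into two adjacent
  bifurcations through a short untapered intermediate segment
  (`split_trifurcation()`, radius 0.185 cm, length 0.25 cm); the solver
  itself only ever sees binary junctions.
* **Outlets.** Each terminal artery feeds a structured-tree vascular bed:
  a self-similar binary tree with daughter radii $\alpha r$ and
  $\beta r$ ($\alpha = 0.9$, $\beta = 0.6$), pruned at a minimum radius of
  10 µm, vessel length 25 radii. Womersley-profile linearised flow gives
  each small vessel a complex wave speed and admittance, and the root
  impedance $Z(0,\omega)$ follows from a transmission-line recursion with
  parallel combination at bifurcations. The recursion runs over the radius
  lattice $(i,j) \mapsto \alpha^i\beta^j r_{\rm root}$ — self-similarity
  makes the lattice position the only state, so beds with millions of
  nominal vessels cost a few hundred lattice nodes. In the time domain the
  boundary condition is the convolution
  $p(L,t) = \sum_m z(t_m)\, q(L, t - t_m)\, \Delta t + p_f(t)$.

## Myocardial feedback

Contraction squeezes the intramural beds. Each terminal bed receives a
feedback pressure $p_f = \varphi\, p_v(t) + p_s$ added to its boundary
condition, with $p_s = 20$ mmHg and $\varphi$ by territory (left ventricle
33%, right ventricle 25%, septum 22%). Ventricular pressures come from a
time-varying elastance model,
$p_v = p_0\sigma + (E_d + E_s \sigma)(V - V_0) + R_v \dot V$ in systole and
$E_d (V - V_0)$ in diastole, with activation
$\sigma = 1 - \cos(2\pi t/t_s)$ as conventionally printed (peak 2; a
`sigma_half` switch halves it for sensitivity). The ventricular volume is
not resolved by a closed-loop circulation; a smooth prescribed stroke
profile stands in (`volume_model()`), with defaults chosen once so the left
ventricular pressure peaks near 120 mmHg with the published elastances
(the published unstressed volumes are small, so the profile's stroke
volume is a pressure-shaping device; the cardiac output used for the
coronary-fraction calibration comes from the systemic lumped model's
stroke volume, default 75 ml at 0.9 s period, i.e. 5 L/min). The tube-law
reference pressure $p_0$ of each tree is the time-averaged ventricular
pressure of its side, recomputed every run.

## Closure calibration (and why it exists)

With zero terminal load, the structured trees built from the published
parameters are far too conductive: ten beds in parallel would carry an
order of magnitude more than the stated 4–5% of cardiac output at
physiological aortic pressure. The under-specified closure is the load
behind the smallest arterioles. `corowave` therefore terminates every leaf
with a capillary/venous windkessel $Z_t(\omega) = R_t/(1 + i\omega\tau)$,
with $\tau = 0.2$ s, and calibrates the single resistance $R_t$ so that
the DC reduction of the whole network carries the configured coronary
fraction at the mean aortic pressure (`calibrate_terminal_load()`). The
compliance part matters as much as the resistance: a purely resistive
load would present a bed impedance an order of magnitude above the vessel
characteristic impedance at every frequency, so the feedback pressure
could not transmit into the arteries and neither diastolic-dominant flow
nor the backward waves would appear.

Two quantities are deliberately **properties of the baseline
configuration** and are held fixed under scenario overrides: the
calibrated terminal load and the lumped inflow estimate
(`reference_config()`). A diseased coronary bed does not change the aorta;
re-calibrating per scenario would cancel the very effect under study.

Remaining inlet-estimate constants, chosen once against the published
baseline physiology and then frozen: compression pressure at
`phi_comp = 0.85` of the territory ventricular pressure (lumped coronary
models use the full ventricular pressure as intramyocardial pressure;
0.85 is a transmural average), intramyocardial time constant
`tau_im = 0.1` s, proximal resistance fraction `fr_prox = 0.3`.

## Numerics

* Two-step (Richtmyer) Lax–Wendroff, second order on smooth solutions
  (verified by a manufactured-solution convergence study in the test
  suite). The momentum equation is integrated in the pressure-gradient
  form $-(A/\rho)\partial_x p$ with a half-node pressure built from the
  average nodal pressure plus the nonlinear half-state increment: constant
  pressure with zero flow is then an exact discrete steady state on
  tapered, stiffness-graded vessels. Continuity stays in conservation
  form.
* Boundary nodes are advanced along characteristics with the source terms
  (viscous drag and the explicit tapering/stiffness gradients of the tube
  law) integrated along the path, and quadratic foot interpolation.
  Omitting these source corrections biases tapered-vessel boundaries and
  excites a standing odd–even mode. A residual vessel-end flux
  inconsistency of order 1% remains (reported as `flux_consistency` in
  `glance()`); the true net volume change per converged cycle
  (`mass_error`) is below 0.1%.
* Discretisation defaults: $\Delta x \le 0.1$ cm (minimum 8 nodes per
  vessel), CFL number 0.5 against a stiffness-based wave-speed estimate,
  4096 samples per period for the outlet convolution, and cycle-to-cycle
  convergence when the $L_\infty$ pressure change falls below 0.5 mmHg
  (usually 4–6 cycles from rest; the first cycle uses a zero-padded
  convolution history and is flagged). A coarse profile
  (`coronary_config_coarse()`: $\Delta x$ 0.2 cm, 1024 samples, 5-node
  minimum) is used by the test suite and agrees with the default
  resolution to within about a percent in peak pressures and velocities.
* $\omega = 0$ is a removable singularity of the transmission line; the
  recursion uses the Poiseuille limit $8\mu l/(\pi r^4)$ there. The
  Womersley factor uses a Lentz continued fraction for the Bessel ratio up
  to $w_0 = 40$ and a three-term Hankel asymptotic ratio above (interface
  mismatch below $10^{-3}$, series-verified to $10^{-10}$ in the
  continued-fraction regime).

## Wave-intensity analysis

Sampled increments of pressure and velocity are split with the
water-hammer relations
$\delta p^\pm = \tfrac12(\delta p \pm \rho c_p\, \delta u)$ using the
local, time-varying pulse wave velocity
$c_p = \sqrt{(A/\rho)\,\partial p/\partial A}$ evaluated on the simulated
area. The decomposition is exactly additive and the intensities
$WI^\pm = (\delta p^\pm/\delta t)(\delta u^\pm/\delta t)$ are
sign-definite by construction. Note that with the adopted tube law $c_p$
*decreases* with distension ($A\,\partial p/\partial A \propto A^{-1/2}$);
claims that it should increase hold only for strain-stiffening wall laws.

Six-wave segmentation is our algorithm (the six phases are usually
described narratively): contiguous lobes of $|WI^\pm|$ above 1% of the
global peak, additionally split where the wavefront-pressure channel
changes sign, are labelled a–f by aligning the chronologically ordered
lobes to the canonical template (BCW, FCW, BCW, FDW, BDW, FCW) with an
order-preserving dynamic program that maximises matched energy, weighted
by soft timing windows tied to $t_s$. Energies are time integrals of
$|WI|$ per lobe; percentages are shares of the labelled lobes' total.

In this model the backward decompression wave (e) dominates (≈55% at the
LCX midpoint) and the early backward compression wave (a) is prominent,
as in human measurements. Two systolic waves are structurally weak here:
the systolic forward compression wave (b) is largely absorbed into the
prescribed inflow waveform (a pressure-imposed inlet restores it but
loses the diastolic dominance of flow at these feedback ratios), and the
late-systolic backward compression wave (c) merges into (a) because the
printed activation relaxes from mid-systole, leaving no separate
late-systolic compression.

## Scenarios

* **Case A — stiffening:** `wall.k3` doubled everywhere. Peak velocity and
  the forward decompression wave's absolute energy increase; its
  *normalised* share can dip slightly because other waves grow too.
* **Case B — rarefaction:** radius exponent $\xi: 2.76 \to 2.4$. Because
  the printed $\alpha, \beta$ are fixed numbers, $\xi$ only enters the
  tree through the branching relations, so $\alpha, \beta$ are re-derived
  from $(\gamma, \xi)$ when $\xi$ is overridden
  ($\alpha = (1+\gamma^{\xi/2})^{-1/\xi}$, $\beta = \alpha\sqrt\gamma$; at
  baseline the derived 0.911/0.583 are close to the printed 0.9/0.6).
  This prunes roughly four-fifths of the nominal vessels, and with the
  calibrated per-leaf terminal load every bed's impedance rises about
  five-fold; under the fixed inflow the peak LCX pressure rises to
  ≈360 mmHg. The published account of the same experiment reports a rise
  to 150 mmHg alongside a "20% reduction in small vessels" — numbers we
  could not reconcile with any fixed terminal-load semantics; the model
  reports its own converged value.
* **Case C — feedback sweep:** $\varphi$ of one terminal bed (default
  LAD1) varied 0–60%. Systolic flow decreases strictly with $\varphi$;
  the diastolic margin $q_{\rm dia} - q_{\rm sys}$ increases. Absolute
  diastolic flow is nearly $\varphi$-independent because diastolic
  ventricular pressure is a few mmHg.
* **Case D — size scaling:** all lengths and radii scaled by 90–110%
  (whole tree by default; `geometry.scale_lcx_only` restricts it). With
  the inflow fixed at the reference calibration, peak velocity scales
  close to the inverse square of size and peak pressure follows the bed
  impedance — both within a few percentage points of the published
  percentages. The forward-decompression peak is monotone in size but far
  less extreme than the published 340–16% span.

Every scenario is a pure function of (configuration, overrides); results
embed the resolved configuration.

## What the toy fixtures do and do not show

The brute-force fixtures (`make_toy_tree()`, `toy_tree_impedance()`,
`make_synthetic_waveforms()`) verify the impedance recursion against
vessel-by-vessel enumeration and the wave decomposition against
constructed ground truth to near machine precision. They exercise clean,
noise-free, uniformly sampled signals and small trees; they say nothing
about measurement noise, ensemble averaging, or patient-to-patient
geometric variation, none of which this package models.

## Known limitations

* The bed impedances are static over the cycle: myocardial compression
  enters only as the additive feedback pressure, not as a time-varying
  impedance inside the trees.
* The right coronary peak velocity is low (~15 vs ~22 cm/s reported)
  under the homogeneous per-leaf terminal load; territory-specific
  capillary densities would be needed to redistribute flow toward the
  right tree.
* The characteristic boundary treatment leaves an O(1%) flux-reporting
  inconsistency at vessel ends at the coarse resolution.
* No venous circulation, no valve dynamics beyond a diode, no
  viscoelastic wall, no curvature or gravity.
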