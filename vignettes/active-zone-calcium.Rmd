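---
title: "Modelling calcium microdomains at the Drosophila NMJ active zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling calcium microdomains at the Drosophila NMJ active zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Some active zones (AZs) of the Drosophila larval neuromuscular junction
carry a T-bar: an electron-dense, table-shaped structure (a ~30 nm
pedestal topped by a ~140 nm platform) around which voltage-gated
calcium channels (VGCCs) cluster. Because vesicle release probability
depends super-linearly on the local calcium concentration, an obstacle
that slows the dispersal of incoming calcium could directly increase
synaptic strength. `azsim` quantifies that idea: it simulates
action-potential-driven calcium influx, diffusion, buffering and
extrusion in a small cytosolic volume over the AZ membrane and compares
three anatomies that differ only in geometry:

* `tbar_clustered` — T-bar present, channels clustered in an annulus
  (outer diameter 70 nm) around the pedestal;
* `no_tbar_clustered` — same annular channel zone, no obstacle;
* `no_tbar_dispersed` — no obstacle, the same six channels spread over
  a 140 nm disk.

All inputs are generated by the package; there is no external data.

## Model

Two concentrations are tracked on a cytosolic box whose floor is the
presynaptic membrane: free calcium and free mobile buffer (calbindin-like),

$$\partial_t [\mathrm{Ca}] = D_{Ca}\Delta[\mathrm{Ca}] - R, \qquad
  \partial_t [B] = D_B\Delta[B] - R,$$

with mass-action buffering
$R = k_{on}[B][\mathrm{Ca}] - k_{off}([B]_{tot}-[B])$. The side and top
walls hold both species at their resting values (the surrounding bouton
is treated as a large reservoir); the floor is impermeable except on the
channel zone $C$, which carries the composite membrane flux

$$I_M = \rho_{VGCC}\,I_{VGCC} + \rho_{PMCA}\,I_{PMCA} +
        \rho_{NCX}\,I_{NCX} + \rho_{leak}\,I_{leak}.$$

The VGCC current is a Goldman–Hodgkin–Katz open-channel flux gated by
Borg-Graham-style Hodgkin–Huxley variables, $I = m^2 h \cdot F(V)$, with
$m$ a fast activation pair and $h$ a slow inactivation gate (the slow
gate reproduces the mild peak depression seen under 100 Hz trains). PMCA
and NCX extrusion are Hill functions of intracellular calcium (orders 2
and 1). The leak is a constant flux density fixed by calibration so that
the net membrane flux vanishes exactly at rest; together with the exact
buffer equilibrium used for the initial condition, the unstimulated
system is a steady state to machine precision.

### Parameters and units

Lengths are in µm, time in s, concentrations in µM, and amounts in
µM·µm³ (1 mol = 10²¹ µM·µm³). The kinetic defaults are the literature
values used throughout: $D_{Ca} = 200$, $D_B = 30$ µm²/s,
$k_{on} = 44$ /(µM s), $k_{off} = 36$ /s, $[B]_{tot} = 40$ µM, resting
calcium 50 nM, external calcium 1.5 mM, PMCA/NCX turnovers
$8\times10^{-24}$ and $2.5\times10^{-21}$ mol/s with half-saturations
60 nM and 1.8 µM, and maximal densities 75 000 and 2 500 µm⁻².

Two parameter groups have no single standard literature value and are
therefore package presets, chosen once:

* **Gating constants.** The N-type preset uses literature-plausible
  values ($m$: $V_{1/2} = -21$ mV, gating charge 3.4, $\tau_0 = 2$ ms;
  $h$: $V_{1/2} = -40$ mV, charge $-2$, $\tau_0 = 75$ ms). The scenario
  comparisons are ratios at matched peaks and are insensitive to the
  influx scale and shape; the gating choice mainly sets the timing.
* **Action-potential template and permeability.** The spike is a
  difference of exponentials (rise 1.0 ms, decay 2.5 ms, support 8 ms,
  $-70 \to +20$ mV) with a linear taper so it starts and ends exactly at
  rest. Together with the gating preset this places the first calcium
  peak ≈ 4.2 ms after spike onset, the reference timing for this
  synapse; the default permeability $p_x = 0.1$ µm³/s puts near-membrane
  peak microdomains in the tens of µM, the physiologically reported
  range. Both are configurable (`ap_train()`, `channel_params()`).

### Channel density

Each scenario carries exactly `n_channels` (default 6) channels spread
uniformly over its zone. The density is *derived* as
`n_channels / area(C)` on the actual grid, so the channel count is exact
at any resolution; the rounded literature densities (2297.1 µm⁻²
clustered, 395.8 µm⁻² dispersed) are available as presets
(`use_literature_density = TRUE`) and are used for grid-convergence studies,
where a level-independent density is the right control.

## Discretization

The box is a uniform cell-centered voxel grid. The T-bar is realized by
a staircase: a cell is an obstacle cell exactly when its center lies in
the analytic solid (pedestal cylinder plus roof disk). The grid must
resolve the roof (`h` ≤ roof thickness, one cell layer at the default
h = 10 nm). Boundary faces are classified into the channel zone C (an
annulus or disk of floor faces), the remaining floor B, the Dirichlet
walls W, and the fluid–obstacle interface T; B and T are zero-flux.

Each time step splits into four verifiable stages:

1. **Gating** — exact exponential relaxation at frozen voltage.
2. **Membrane flux** — evaluated per channel face from the adjacent
   cell's calcium. The pump feedback is stiff on the resting time step,
   so the face source uses a linearized exponential update (the exact
   solution of the locally linearized source ODE), which is
   unconditionally stable and reduces to the plain explicit source for
   small slopes.
3. **Implicit diffusion** — backward Euler, solved by dimension-split
   tridiagonal sweeps with the Douglas stabilizing correction (default
   `method = "adi"`). The correction makes the splitting error act on
   the step increment rather than the field, so quasi-steady microdomain
   profiles are essentially independent of the step size; the plain
   sequential sweep (`"lie"`, strictly monotone) and an unsplit
   sparse-Cholesky solve (`"direct"`) are kept as references and used in
   the tests as independent cross-checks.
4. **Reaction** — the local buffering pair is advanced *exactly*:
   during pure reaction Ca − B is conserved, reducing the update to a
   scalar Riccati equation with a closed-form solution. This preserves
   positivity, B ≤ B_total, and fixes chemical equilibrium exactly.

The step policy is 2 µs inside a 6 ms window after each spike onset
(resolving the ms-scale waveform and gating by ~3 orders of magnitude)
and 20 µs between spikes. A step that would produce a negative
concentration is retried as two half steps; clipping is never used, so
sealed-box mass balance holds to solver precision.

## Evaluation

Concentrations are read out as circle averages: `n_phi_max` (64) points
on a circle of radius R at height H over the (virtual) pedestal center,
trilinearly interpolated from cell centers and averaged. Stencils that
touch the obstacle renormalize over their fluid corners and flag the
probe (this matters only at H = 0.04 µm directly under the roof).
Peaks are detected per action-potential period; scenario ratios are
computed at *matched peaks* (each scenario's own peak time), with a
fixed-time read-out also available. The under-roof subdomain U (the
fluid below the virtual roof) provides a volume-averaged alternative
read-out with the same ordering.

## Problem sizes and study design

The default acceptance-scale configuration is the reduced
0.6 × 0.6 × 0.3 µm box at h = 10 nm (108 000 cells); the full-size
1.2 × 1.2 × 0.6 µm box is a switch (`box_mode = "full"`), and a
0.24 × 0.24 × 0.12 µm mini box supports cheap parameter sweeps. The
far-field walls sit far outside the sub-50-nm microdomain in all modes,
and the box-size insensitivity of the scenario ratios is itself asserted
in the test suite. Comparison runs simulate one 40 Hz period past the
first peak (6 ms), the 20 Hz later-peak comparison runs through the
second spike (56 ms), and the 100 Hz comparison through the fifth spike
(46 ms). These sizes keep a full scenario comparison within minutes on
one CPU.

```{r example}
library(azsim)
tb <- run_scenario(make_preset("tbar_clustered", t_end = 0.006))
cl <- run_scenario(make_preset("no_tbar_clustered", t_end = 0.006))
dp <- run_scenario(make_preset("no_tbar_dispersed", t_end = 0.006))
scenario_ratios(tb, cl, dp, R = 0.03, H = 0.01, peak_index = 1)
```

## Numerical choices, verification, and known limitations

* **Oracles.** The gating and reaction sub-steps are checked against
  adaptive ODE integrations to 10⁻⁸ relative error; the diffusion
  operator against the hemispherical steady-state Green's function of a
  point source on a reflecting plane (radial differences within 5%);
  the split solver against the unsplit backward-Euler solve; sealed-box
  total calcium (free + bound) is conserved over thousands of steps.
* **Grid convergence.** `convergence_study()` reruns a configuration on
  nested levels (spacing halved, time steps scaled with h² so the
  splitting error is level-independent) and reports successive relative
  differences of probe values. These decrease monotonically (~2–3× per
  level). Because the staircase re-shapes the discrete geometry at every
  level, the spatial error is first order (≈ 0.5% between the 5 nm and
  2.5 nm levels near the membrane); reaching the sub-per-mill regime
  that boundary-fitted meshes attain would need sub-nm spacings. This is
  the known cost of the voxel discretization and the reason the
  per-mill convergence expectation in the acceptance suite is strict.
* **Degenerate inputs.** Grids that do not tile the box, spacings that
  cannot resolve the roof, channel zones smaller than one face, probe
  circles inside the pedestal or outside the box, and empty subdomains
  are all rejected with explicit errors.
* **What the generator does not emulate.** Channels are a continuum
  density, not discrete stochastic channels; the T-bar is an idealized
  cylinder-plus-disk rather than a reconstructed shape; the AP template
  is imposed, not computed from membrane excitability; vesicle release
  probability is not modelled. Passing tests therefore support the
  geometric comparison of anatomies under identical kinetics — not
  absolute calcium predictions for a particular synapse.
* **Buffer saturation.** At high channel counts the local buffer
  saturates more in the clustered geometries, so the dispersed-case
  fold grows mildly with channel number even though the near-membrane
  excess stays within a few percent — visible in `sweep_vgcc()`.
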