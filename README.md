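# azsim

Voxel-based simulation of calcium microdomains at presynaptic active
zones of the Drosophila larval neuromuscular junction (NMJ).

## The problem

Some NMJ active zones carry a **T-bar** — a table-shaped electron-dense
structure (a ~30 nm pedestal with a ~140 nm roof) around which
voltage-gated calcium channels (VGCCs) cluster. Vesicle release
probability rises super-linearly with the local calcium concentration,
so an obstacle that slows the dispersal of incoming calcium can directly
strengthen the synapse. `azsim` is for computational neuroscientists who
want to quantify that geometric effect: it simulates
action-potential-driven calcium influx, diffusion, buffering and
extrusion in a 3D cytosolic volume over the active-zone membrane and
compares three anatomies that differ only in geometry — T-bar with
clustered channels, no T-bar with the same clustered channels, and no
T-bar with the same six channels dispersed over a wider zone.

## The model

Two species on a voxelized box (floor = presynaptic membrane):

- **Reaction–diffusion**: ∂ₜ[Ca] = D_Ca Δ[Ca] − R, ∂ₜ[B] = D_B Δ[B] − R,
  with mass-action buffering R = k_on·[B]·[Ca] − k_off·([B]_tot − [B]);
  resting values held at the far-field walls (Dirichlet), zero flux
  through the floor and the obstacle surface.
- **Membrane flux on the channel zone**:
  I_M = ρ_VGCC·I_VGCC + ρ_PMCA·I_PMCA + ρ_NCX·I_NCX + ρ_leak·I_leak,
  with a Goldman–Hodgkin–Katz open-channel flux gated Borg-Graham style
  (I_VGCC = m²h·F(V)), Hill-type PMCA/NCX extrusion, and a leak
  calibrated so the resting state is an exact steady state.
- **Numerics**: operator splitting with exact exponential gating, a
  linearized-exponential membrane source, implicit (backward-Euler)
  diffusion via dimension-split tridiagonal sweeps with the Douglas
  stabilizing correction, and a closed-form exact update of the local
  buffering reaction. Unsplit sparse solves and analytic Green's-function
  solutions serve as cross-checks in the test suite.

All inputs are generated by the package (parametric anatomy, kinetic
parameter presets, action-potential trains); there is no external data.

## Worked example

Compare the three canonical anatomies through the first 40 Hz calcium
peak on the desk-scale grid (0.6 × 0.6 × 0.3 µm box, 10 nm voxels;
about half a minute per scenario):

```r
library(azsim)
tb <- run_scenario(make_preset("tbar_clustered",    t_end = 0.006))
cl <- run_scenario(make_preset("no_tbar_clustered", t_end = 0.006))
dp <- run_scenario(make_preset("no_tbar_dispersed", t_end = 0.006))

r1 <- scenario_ratios(tb, cl, dp, R = 0.03, H = 0.01, peak_index = 1)
r4 <- scenario_ratios(tb, cl, dp, R = 0.03, H = 0.04, peak_index = 1)
cols <- c("R", "H", "tbar", "no_tbar_clustered", "no_tbar_dispersed",
          "excess_pct", "fold_clustered", "fold_dispersed", "t_peak_tbar")
print(rbind(r1[, cols], r4[, cols]), row.names = FALSE)
```

```
    R    H     tbar no_tbar_clustered no_tbar_dispersed excess_pct
 0.03 0.01 26.14589          19.88962         11.764234   31.45495
 0.03 0.04 19.12658          10.06755          7.264155   89.98235
 fold_clustered fold_dispersed t_peak_tbar
       1.314550       2.222490    0.004128
       1.899824       2.633008    0.004132
```

Reading: at the first calcium peak (≈ 4.1 ms after spike onset) the
circle-averaged concentration 30 nm from the (virtual) pedestal center
and 10 nm above the membrane is ≈ 26 µM with the T-bar versus ≈ 20 µM
without it — a ≈ 31% enhancement from the diffusion obstacle alone.
Just under the roof (H = 0.04 µm) the obstacle nearly doubles the local
calcium (fold ≈ 1.9), which is where docked vesicles would sense the
difference. The dispersed-channel scenario stays another ≈ 2× lower at
matched probes (`fold_dispersed`). `summary()`, `plot()` and
`write_result()` give peak tables, probe traces and CSV/JSON/VTK
exports; `sweep_vgcc()`, `sweep_buffer_pumps()`, `run_comparison()` and
`convergence_study()` reproduce the sensitivity analyses.

A thin command-line front end is installed under
`inst/scripts/azsim` (`azsim compare --presets ... --freq 40`, etc.).

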