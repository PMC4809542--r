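# uteromag

Multiscale forward electromagnetic modeling of uterine contractions during
pregnancy, for researchers working on magnetomyography (MMG) and
electrohysterography: given a myocyte model, a fibered uterine surface, and
a sensor geometry, the package computes the abdominal magnetic field a
151-channel SQUID gradiometer array would record during a contraction.

The model has three scales:

- **Cell.** A generalized FitzHugh–Nagumo myocyte
  `dv_m/dt = [k(v_m−v1)(v2−v_m)(v_m−v3) − w + ν h(t)]/(ε1 c_m)`,
  `dw/dt = ε2(β v_m − γ w + δ)`, whose response to a constant stimulus ν is
  classified by bifurcation analysis: a unique equilibrium exists for all ν
  when Δ1 < 0, and a window of ν (computed in closed form from Δ2) makes it
  unstable with a surrounding limit cycle, producing spike trains. Periodic
  gating of ν between the two regimes produces the bursting action
  potentials of uterine contractions.
- **Tissue.** Random fiber orientations on 25 contiguous surface regions,
  cylindrically anisotropic conductivity tensors
  `G = (σl−σt) a3 a3ᵀ + σt I`, and a closed-form traveling-wave speed
  `c = |ṽ1 − 2ṽ2 + ṽ3|/c_m · sqrt(k σel ζ / (2 ε1 a_m (ζ+1)))` from the
  roots of the front cubic.
- **Organ.** An anisotropic monodomain reaction–diffusion solve on the
  (spherical or pear-shaped) uterine mid-wall surface with a localized
  pacemaker, source current dipoles `J_s = −ζ Ge′ ∇v_m`, quasi-static
  Biot–Savart fields, and a SARA-style gradiometer array (151 channels,
  8 cm baseline) on the abdominal surface. An optional coarse voxel Poisson
  solver supplies volume (return) currents.

## Worked example

```r
library(uteromag)

p <- fhn_params()          # published myocyte constants
limit_cycle_range(p)
#> [1] 0.01177297 0.20669000          # spiking window for constant nu
resting_potential(p)
#> [1] -0.05565152                    # volts: -55.7 mV

# bursting at the contraction rhythm: 1 min on, 7 min period
tr <- simulate_cell(p, stimulus("periodic_heaviside", amplitude = 0.11,
                                period = 420, duration = 60),
                    duration = 1800, dt = 0.01)
burst_intervals(tr)$intervals
#> [1] 420 420 420 420

wavespeed_analytic(p, tissue_params())
#> traveling-wave speed: 0.0428 m/s (three_real_roots)
#>   roots used: -0.05565, -0.05369, -0.01566
#>   diffusion coefficient: 4.029e-05 m^2/s  v_mr: -0.0557 V
```

The window endpoints (0.012–0.207), the −55.7 mV resting potential, the
420 s burst period, and the 0.043 m/s fiber-direction conduction speed are
the quantities a myometrial physiologist would check first; all four match
published measurements from term-pregnancy preparations.

An end-to-end scenario — spherical uterus, fixed-angle fibers, fundus
pacemaker, field maps at chosen instants:

```r
cfg <- scenario_config(subdiv = 6, duration = 11, snapshot_times = 10)
res <- run_scenario(cfg, out_dir = "scenario_out")
range(res$maps)   # tesla; tens of picotesla, the MMG scale
```

`preprocess_mmg()` applies the acquisition pipeline used with the real
device (32 Hz, 0.1–1 Hz band-pass, 0.25–0.35 Hz breathing notch). A thin
command-line front end over these functions is installed at
`inst/cli/uteromag.R`.

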