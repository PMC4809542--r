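---
title: "Methods: a multiscale forward model of uterine magnetomyograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multiscale forward model of uterine magnetomyograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uteromag)
```

`uteromag` computes the abdominal magnetic field produced by electrical
activity of the pregnant uterus, from the single myocyte up to a 151-channel
SQUID gradiometer array. This vignette explains the model at each scale, the
numerical choices behind the implementation, and what the bundled synthetic
test conditions do and do not establish about real recordings.

## The myocyte model and its stimulus window

Each myocyte is a two-variable generalized FitzHugh--Nagumo system,

$$\frac{dv_m}{dt} = \frac{k(v_m-v_1)(v_2-v_m)(v_m-v_3) - w + \nu h(t)}
  {\varepsilon_1 c_m}, \qquad
  \frac{dw}{dt} = \varepsilon_2(\beta v_m - \gamma w + \delta),$$

with $v_m$ the transmembrane potential (V), $w$ a recovery variable, and
$\nu h(t)$ the pacemaker drive. The default constants (`fhn_params()`) are
the published set for a term-pregnancy myocyte: $c_m = 0.01$ F/m$^2$,
$\varepsilon_1 = 10\ \Omega$m$^2$, $\varepsilon_2 = 10$ S$^{-1}$,
$(v_1, v_2, v_3) = (-0.02, -0.04, -0.065)$ V, $k = 7000$ V$^{-2}$,
$\beta = 1$, $\gamma = 0.1$, $\delta = 0.052$ V.

Because the nullcline equation is cubic in $v_m$, the stimulus is expressed
as a function of the equilibrium instead of the reverse:
$\nu(v_m^*) = -k(v_m^*-v_1)(v_2-v_m^*)(v_m^*-v_3) +
(\beta v_m^* + \delta)/\gamma$. Two discriminants organize the behavior
(`discriminants()`): $\Delta_1 < 0$ guarantees a unique equilibrium for
every $\nu$, and $\Delta_2 > 0$ opens a band of equilibria
$v_m^* \in \big((v_1{+}v_2{+}v_3 \mp \sqrt{\Delta_2})/3\big)$ that are
unstable and surrounded by a limit cycle. Mapping those bounds through
$\nu(v_m^*)$ gives the window of constant stimulus amplitudes that sustain
spiking — `limit_cycle_range()` returns $(0.0118, 0.2067)$ for the defaults.
A constant $\nu$ inside the window produces spike trains; a periodic gate
that alternates the cell between the stable and the spiking regime produces
bursting. With a 1-minute-on / 7-minute-period heaviside drive of amplitude
0.11 the model rests at $-55.7$ mV between bursts and bursts recur every
420 s, the interval of spontaneous term contractions.

Near the window boundary the linearization has a complex eigenvalue pair
whose imaginary part (`hopf_frequency()`) scales as
$\sqrt{\varepsilon_2 / (\varepsilon_1 c_m)}$: spiking can be made faster by
lowering $\varepsilon_1$ or raising $\varepsilon_2$. Away from the boundary
the dynamics are relaxational and the eigenvalues are real, so the function
deliberately refuses to report a frequency there; measured spike rates
(`spike_frequency()`) are the meaningful quantity in that regime.

**Spike and burst counting.** No counting convention is published with the
spike-rate table, so the package fixes one: upward crossings of
$v_m = -0.035$ V (midway between rest and spike peak) with a 0.2 s
refractory lockout, counted over the final 80% of the trace and divided by
that window's length. Burst onsets are the first spikes after quiescent gaps
longer than 60 s. Under this convention the simulated rates land within
about 4% of the published table corners (0.160 vs 0.164 spikes/s at
$\varepsilon_1 = \varepsilon_2 = 1$; 0.986 vs 1.020 at
$\varepsilon_1 = \varepsilon_2 = 10$), consistent with a
counting-convention difference of one spike per window.

**Integration.** `simulate_cell()` uses `deSolve::lsoda` (rtol $10^{-8}$,
atol $10^{-10}$), which switches automatically between explicit and implicit
methods; the system becomes stiff for small $\varepsilon_1$, and lsoda's
automatic switching covers exactly that case. Equilibria are located through
the cubic's companion-matrix roots (`polyroot`), keeping the root with
$|\mathrm{Im}| < 10^{-9}$.

## Fibers, conductivity, and the analytic front speed

Myometrial fibers lack a global architecture, so the surface is divided into
25 contiguous regions by rejection-sampling seed elements with pairwise
separations of at least 4 cm (`partition_regions()`; the distance is
Euclidean, which on these gently curved surfaces differs negligibly from the
geodesic at 4 cm scales) and assigning each element to its nearest seed.
Each region draws one fiber angle from Normal$(0, \pi/4)$; angle 0 is the
vertical (fundus-to-cervix) direction.

At a point with outward unit normal $n = (n_x, n_y, n_z)$ and
$s = \sqrt{n_x^2 + n_z^2}$, the tangent basis is
$t_1 = (n_x n_y, -s^2, n_z n_y)/s$ (steepest vertical descent) and
$t_2 = (-n_z, 0, n_x)/s$ (horizontal), and the fiber runs
$a_3 = \cos\alpha\, t_1 + \sin\alpha\, t_2$. This orthonormal construction
is the unique reading of the fiber-angle definition that keeps $a_3$
unit-length and tangent for every normal; the sign of $t_2$ fixes
"counterclockwise seen from $+y$" as the positive-angle convention. Where
the normal is parallel to the vertical axis the construction is singular and
a fixed fallback pair $t_1 = (1,0,0)$, $t_2 = (0,0,1)$ is used — any fixed
tangent pair preserves the invariants there.

Conductivity tensors are cylindrically symmetric about the fiber:
$G = (\sigma_l - \sigma_t) a_3 a_3^T + \sigma_t I$. The published tissue
constants are $\sigma_{el} = 0.68$ S/m and the anisotropy ratio
$\zeta$ ($G_i' = \zeta G_e'$, the equal-anisotropy-ratio assumption that
makes the monodomain reduction exact); $\zeta = 0.518$ for the speed
analysis and 0.818 for the validation conductivity set — both are carried in
configuration (`tissue_params()`, `compartment defaults`). The transverse
conductivity is not printed; the package defaults to
$\sigma_{et} = \sigma_{el}/5$, a mid-range smooth-muscle anisotropy,
configurable through `t_ratio`.

On the leading front of a propagating wave the slow variable sits at its
resting value $w = (\beta v_{mr} + \delta)/\gamma$, which reduces the
monodomain equation along the fiber to a scalar bistable
reaction--diffusion equation. Its front speed is
$$c = \frac{|\tilde v_1 - 2\tilde v_2 + \tilde v_3|}{c_m}
  \sqrt{\frac{k\,\sigma_{el}\,\zeta}{2\,\varepsilon_1 a_m (\zeta+1)}},$$
with $\tilde v_i$ the ascending roots of
$f(v) = (v-v_1)(v_2-v)(v-v_3) - (\beta v_{mr}+\delta)/(k\gamma)$ and
$a_m = 575870$ m$^{-1}$ the membrane surface-to-volume ratio.

**A near-tangency worth knowing about.** For the default constants the
cubic $f$ sits extremely close to a double root, and the root structure
flips with the fourth decimal of $v_{mr}$. With the rounded printed value
$v_{mr} = -0.056$ V the cubic has one real root and a complex pair; taking
real parts (`path = "real_part_fallback"`) gives $c = 0.0469$ m/s. With the
model's own resting potential $-0.05565$ V — which rounds to the printed
$-0.056$ — all three roots are real and $c = 0.0428$ m/s, matching the
published 0.0429 to 0.1%. `wavespeed_analytic()` therefore defaults
$v_{mr}$ to `resting_potential(params)`, reports which root path was taken,
and exposes both readings. An independent 1-D cable simulation of the full
two-variable system propagates at a speed within 10% of the three-real-root
value, supporting that reading.

## The monodomain surface solver

The myometrium is geometrically thin (1 cm wall on a 16 cm organ), so the
package solves the monodomain equation on the mid-wall surface — a 2-D
curved manifold — rather than a 3-D shell; the wall thickness re-enters as a
volumetric factor in the source strength. `assemble_diffusion_operator()`
builds a linear (P1) finite-element stiffness matrix for
$\nabla\!\cdot\!\frac{\zeta}{\zeta+1} G_e' \nabla v_m$: basis-function
gradients are tangential to each triangle, so contracting them with the full
3×3 tensor is algebraically identical to projecting the tensor onto the
tangent plane first. The mass matrix is lumped (vertex areas). The surface
is closed, so the zero-flux boundary condition holds identically and the
operator annihilates constants and conserves the surface integral — both
asserted in the test suite, along with the analytic Laplace--Beltrami
eigenvalue $\ell(\ell+1) D / r^2$ on the sphere.

Time stepping is operator splitting: the reaction term advances with four
explicit sub-steps per diffusion step (a compiled kernel, with per-vertex
parameters so region-specific ionic configurations are just vectors),
followed by one backward-Euler diffusion solve using a sparse Cholesky
factor computed once. The default $\Delta t = 1$ ms resolves the ~5 ms
upstroke; halving it changes the measured front speed by under 1%.
Non-finite states abort with the failing step reported.

**Pacemakers and regional ionics.** `pacemaker_spec()` applies
$V_{stim} = 0.11$ V for $T_{stim} = 5$ s within a 5 cm radius, with a
0.05 Hz cosine carrier $\cos(2\pi \cdot 0.05 (t - T_{stim}))$ as used in
the validation runs (a plain gate is also available, since it is not stated
which was used for the sensitivity maps). `region_ionic()` reproduces
limited propagation: vertices within 10 cm of the pacemaker get the
limit-cycle-capable parameter set, all others a stable-equilibrium set
($\varepsilon_1 = 200$, $\varepsilon_2 = 0.09$, $k = 10000$), which confines
activation to the inside region.

**Front width and mesh resolution.** The bistable front is only
$\sim 0.9$ mm wide ($\sqrt{2D/A}/(\tilde v_3 - \tilde v_1)$ with
$D = 4.03\times10^{-5}$ m$^2$/s), far below any desk-scale mesh spacing.
Icosphere subdivision 7 (163,842 vertices, $\approx$1.3 mm edges) is the
finest level used; there the measured fundus-to-equator speed is
0.0374 m/s, 11% below the published organ-scale 0.0421 m/s, and the error
shrinks monotonically with refinement (subdivision 6 gives 0.0335 m/s).
Full grid-independence (under 3% change per level) would need at least one
more subdivision — 650k vertices — which is beyond the intended desk-scale
envelope; the refinement trend is asserted instead. Below subdivision 6 the
front fails to propagate at all (discrete pinning), which is why scenario
runs default to subdivision 6 and property tests that only need a
propagating wave use a thicker-front regime (smaller $a_m$).

**Speed measurement convention.** The fundus-to-equator speed is measured
from the first threshold crossings ($v_m = -0.035$ V, the spike threshold)
at a fundus-adjacent vertex just *outside* the stimulated patch and at an
equatorial vertex, divided into the great-circle arc between them. Points
inside the stimulated patch activate nearly simultaneously and would
inflate the estimate. Arc length (not chord) is used as the surface
distance.

## The magnetic forward model

Each activated element contributes a source current density
$J_s = -\zeta G_e' \nabla v_m$ and hence a current dipole
$Q = J_s \times \text{area} \times \text{thickness}$. The default forward
path is the quasi-static primary-current approximation: Biot--Savart
superposition of those dipoles in an infinite homogeneous medium
($\mu_0 = 4\pi\times10^{-7}$ T·m/A), evaluated by a compiled kernel with a
singular-evaluation guard. The four-compartment return-current problem
(abdomen 0.2 S/m, amniotic fluid 1.74 S/m, fetus 0.5 S/m, air
$5\times10^{-15}$ S/m) is available as an optional coarse voxel
finite-difference Poisson solver (`solve_volume_potential()`, harmonic-mean
face conductivities, insulating outer boundary, dipoles deposited as charge
pairs); its secondary currents can be added to the Biot--Savart sum. Tests
verify the classical property that volume currents in a spherically
symmetric conductor contribute nothing to the radial field outside, and
that the interior potential matches the infinite-medium dipole form. The
fetal boundary scaling factor $\lambda$ is never assigned a value in the
source material; the solver's conductivity-function interface leaves the
fetus compartment fully configurable, with continuity ($\lambda = 1$) as
the default reading.

The sensor model (`sara_array()`) places 151 inner coils on the anterior
cap of the abdominal surface in concentric rings (counts proportional to
ring circumference, alternate rings rotated half a slot), oriented along
the outward surface normal, with the second coil of each hardware
gradiometer 8 cm further out; the recorded channel is the difference of the
normal field components at the two coils, which rejects spatially uniform
fields. The true device's coil coordinates are not public, so this
deterministic lattice is a stand-in with the correct channel count,
baseline, and concave-cap geometry; arrays are serializable to CSV so
experiments are reproducible. The concave cap itself is modeled as the
anterior polar cap of the abdominal sphere (21 cm radius, front face 2 cm
anterior of the uterus), so in sphere and cap modes the sensors sample the
same surface — consistent with the finding that abdomen shape barely
affects the maps under a primary-current forward model.

## Scenarios, preprocessing, and the synthetic test bed

`run_scenario()` composes geometry → fibers → propagation → forward field →
sensors from a single declarative `scenario_config()` and emits a manifest
(JSON) with every parameter and seed, so a run is exactly repeatable. The
six published configuration-matrix rows (sphere/anatomical uterus,
sphere/cap abdomen, fixed/random fibers, fundus/lateral pacemaker,
normal-component/gradiometer sensing) are pure configuration. "Fundus" is
the $+y$ pole, "lateral" the $+x$ equator point, "back" the posterior site
$(0, 13, -7.5)$ cm. In the packaged sensitivity analysis each
configuration's map is sampled on its own array with channels index-matched
across configurations, and compared by Pearson correlation against the
baseline map; fiber-orientation and pacemaker-location changes decorrelate
the maps far more than either shape change, and that ordering (not any
specific correlation value) is the asserted result.

The anatomical-like uterus (`make_pear_uterus()`) is a *synthetic*
stand-in: an icosphere with radial modulation
$\rho = r(1 + 0.08u - 0.05u^2)$, $u$ the unit-sphere height, giving a
fundus-heavy, lower-segment-tapered closed surface whose volume stays
within a few percent of the sphere's. The mild modulation is deliberate: a
near-term uterus differs from a sphere in shape, not in overall scale, and
a strongly shrunken stand-in would change the wave's transit phase at a
fixed snapshot instant — a size effect that would masquerade as a shape
effect in the sensitivity comparison. The surface is not derived from
imaging and stands in only for the role "a smooth non-spherical uterus of
comparable size".

`preprocess_mmg()` mirrors the published acquisition pipeline: downsample
to 32 Hz (anti-aliased, skipped when the input is already slower), then
zero-phase 0.1--1 Hz band-pass and 0.25--0.35 Hz band-stop (maternal
breathing sits near 0.33 Hz). Only band edges are published; the package
uses 4th-order Butterworth designs applied forward--backward, recorded in
the manifest. The realized responses at probe frequencies: under 1 dB loss
at 0.15 and 0.5 Hz, better than 40 dB rejection at DC, better than 20 dB at
0.3 Hz and 2 Hz.

**What the synthetic conditions do not show.** The test bed exercises the
published study conditions: identical myocytes everywhere (up to the
two-region configuration), noise-free fields, a rigid geometry, no maternal
cardiac or breathing interference in the simulated records (the notch
filter is exercised on synthetic probes), and desk-scale meshes two orders
of magnitude coarser than the cluster-scale finite-element solves they
emulate. Passing tests therefore establish internal correctness and
reproduction of the published analytic and cellular-level numbers at full
precision, and of organ-scale propagation at 10--15% desk-scale accuracy —
not agreement with any real patient recording, which the source analysis
itself attempted only qualitatively.

## Problem sizes used by the packaged checks

Cellular-level checks integrate up to 30 simulated minutes (exact burst
timing) and 3 minutes (spike rates). The organ-level front-speed check runs
icosphere subdivisions 6 and 7 (40,962 and 163,842 vertices) for 8 s of
simulated time at $\Delta t = 2$ ms; the configuration-sensitivity check
runs six subdivision-6 scenarios for 11 s each. These sizes were chosen as
the smallest at which the respective quantities are mesh-stable in the
sense described above.
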