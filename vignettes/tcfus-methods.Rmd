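---
title: "Models and numerical methods in tcfus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in tcfus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tcfus)
```

`tcfus` simulates transcranial focused ultrasound (tcFUS): full-wave
acoustic propagation through water, soft tissue and bone on 3D rectilinear
grids, phase/amplitude steering of a hemispherical phased array, and the
temperature rise the deposited acoustic energy induces. This vignette
documents the governing models, the numerical choices behind them, and the
assumptions a user should know before trusting a result.

## Acoustic models

### Linear pressure wave equation (LAPWE)

The linear solver advances

$$\rho \nabla\!\cdot\!\Big(\frac{1}{\rho}\nabla p\Big)
  - \frac{1}{c^2}\frac{\partial^2 p}{\partial t^2}
  - \frac{\tilde a}{c^2}\frac{\partial p}{\partial t} = 0,$$

where the density-variation term $\rho\nabla(1/\rho)\nabla p$ (rather than
a plain Laplacian) is what makes reflection and transmission at
tissue-bone and tissue-air interfaces come out right, and

$$\tilde a = 2a\sqrt{\frac{a^2c^4}{4\pi^2 f^2} + c^2}$$

converts the spatial attenuation coefficient $a$ (Np/m, linear in
frequency: $a = (a/f)\cdot f[\mathrm{MHz}]$) into a temporal damping rate.
For the weak attenuation of water and soft tissue $\tilde a \approx 2ac$,
which makes a plane wave decay as $e^{-ax}$; the solver's measured decay
rate matches the nominal $\alpha$ to better than 1% (see the nonlinear
cross-check test).

### Westervelt-Lighthill equation (WLE)

The nonlinear solver adds thermoviscous and convective nonlinearity terms,

$$\rho \nabla\!\cdot\!\Big(\frac{1}{\rho}\nabla p\Big)
  - \frac{1}{c^2} p_{tt}
  + \frac{\delta}{c^4} p_{ttt}
  + \frac{\beta}{\rho c^4} (p^2)_{tt} = 0,
  \qquad \beta = 1 + \tfrac{B}{2A},
  \qquad \delta = \frac{2\alpha c^3}{4\pi^2 f^2}.$$

A word on the $\beta$ coefficient's normalization: with
$\beta = 1 + B/2A$ the standard Westervelt equation carries the nonlinear
term as $\beta/(\rho c^4)$. Some published restatements insert an extra
factor $1/2$; that variant produces exactly half the correct
second-harmonic growth. The package uses the standard form, which we
verify against the Fubini perturbation series: the simulated second
harmonic of a 2 MPa, 1 MHz plane wave tracks
$p_2(\sigma) = p_0 J_2(2\sigma)/\sigma$ ($\sigma = z/z_{shock}$) to within
a few percent over $\sigma \in [0.07, 0.52]$, and a 1 kPa wave keeps its
second harmonic below $-77$ dB.

Time stepping uses four stored pressure levels; the third time derivative
and $(p^2)_{tt}$ are evaluated with backward differences, the classical
explicit treatment for this equation. No shock-capturing is attempted:
runs that steepen into shocks on an under-resolved grid will ring, which
the solver reports as an instability rather than silently smearing.

### Discretization

The spatial operator is a flux form: face fluxes
$G = \overline{(1/\rho)}\,\partial p/\partial n$ with the face average
$\overline{(1/\rho)} = 2/(\rho_i + \rho_j)$ (the harmonic mean of the two
adjacent $1/\rho$ values). This preserves continuity of normal particle
velocity across material interfaces, which is precisely what the
plane-wave R/T validation exercises. Grids are rectilinear and may be
nonuniform per axis; stencils use the local spacings (three-point,
second order).

Two accuracy modes exist:

* `order = 2` (default): the flux scheme everywhere. Robust for
  heterogeneous media; numerical dispersion at 10 points per wavelength is
  about 1% in phase speed.
* `order = 4`: in regions that are homogeneous, uniformly gridded, and
  outside the PML, the Laplacian switches to 4th-order stencils and the
  time step gains a Lax-Wendroff $(c\,\Delta t)^2/12\,\nabla^4 p$
  correction, with automatic fallback to the flux scheme near interfaces
  and boundaries. This matters for near-field diffraction patterns: the
  deep interference nulls of a piston field are filled in by 2nd-order
  dispersion (on-axis deviation ~8% from the analytic reference at
  $\lambda/10$) but survive the 4th-order path (~1%). The CFL bound is
  $\Delta/(2c)$ for order 4 versus $\Delta/(\sqrt3\,c)$ for order 2,
  both with a 0.95 safety factor; the step is then rounded down so a
  period is an integer number of steps.

### Absorbing boundaries

Domains are truncated by a convolutional PML: the recursive-convolution
(memory-variable) realization of complex coordinate stretching, applied to
both spatial-derivative stages of the second-order equation. The profile
is polynomial of order 3 with a theoretical normal-incidence reflection
target of $10^{-4}$ and 16 layers by default; faces can also be left as
rigid (zero-flux) walls, which double as symmetry planes for thin-slab
("2D") runs. Measured normal-incidence reflection of the 16-layer PML is
around $10^{-3}$ of the incident amplitude or less.

Air: at tissue-scale time steps the ~1000-fold density contrast of air
dominates its behavior, so air-labelled voxels are by default clamped to
$p = 0$ (pressure release), reproducing near-total reflection with a phase
flip ($R \to -1$, which the suite checks). A `"full"` mode keeps air as a
propagating medium at its own cost in CFL.

### Sources, receivers, phasors

Three source types serve different jobs:

* **soft** (additive) point/voxel sources: transparent to returning waves;
  used for all time-reversal work, where a hard source would re-scatter
  the returning field;
* **hard** (Dirichlet) sources, optionally limited to a Tukey-windowed
  tone burst per source: used for plane-wave validation runs, where the
  burst must be launched cleanly and the source must then get out of the
  way (each source column stops being enforced when its burst ends);
* **normal-velocity (baffle) sources** on the lower-z rigid wall: these
  impose the surface velocity through the boundary face flux and make the
  FDTD piston the exact discrete analogue of a uniformly vibrating piston
  in an infinite rigid baffle, i.e. of the Rayleigh-integral reference
  with $p_0 = \rho c u_0$. Edge voxels carry 4x4-supersampled coverage
  weights so the discrete aperture area matches the nominal one; the
  radiating plane is the wall itself, half a voxel below the first cell
  centers, and on-axis comparisons measure axial distance from the wall.

Inverse (time-reversal recording) runs place a continuously driven soft
point source at the target and record phasors at the voxel nearest each
element center. Because that voxel can sit up to half a voxel away from
the true center, each captured phasor is phase-referenced back to the
element center using the water wavenumber and the known source position
(`snap_correction`); without it, rasterization alone injects up to
~0.4 rad of spurious per-element phase at 230 kHz and $\lambda/8$.

Steady state is reached by running a fixed number of periods (default 60,
after which extending to 90 changes the field by well under 0.1%), and
complex amplitude/phase fields ("phasors") are extracted by single-frequency
discrete Fourier projection over the final two periods — an integer number
of periods with a half-open sample window, so the projection of a pure tone
is exact. Harmonic phasors (e.g. at $2f$) can be extracted in the same run.

## Validation phantoms

The package generates all of its own inputs; no external data is read.

* **Interface slabs**: one-voxel-thick (thin-slab) domains with a
  grid-aligned planar interface, a phase-ramped, laterally tapered
  hard-source line launching an oblique tone burst, and probes above and
  below the interface. Oblique incidence is realized by per-column source
  delays, never by rotating the grid, so the interface stays exactly
  grid-aligned. Incident, reflected and transmitted bursts are separated
  by time gating; complex amplitudes are demodulated in 6-period windows,
  and the sign of R is decided by the residual phase after removing the
  known propagation delay (a residual beyond $\pi/2$ means a phase flip).
  The transmitted probe sits 2 wavelengths below the interface: far enough
  to be outside the interface's near field, close enough that the
  edge-diffraction ripple of the finite tapered beam (a few percent at
  8 wavelengths depth) has not yet accumulated.
* **Pistons**: circular (r = 10 mm), rectangular (20 x 20 mm) and planar
  ring (7.5/10 mm) apertures at 500 kHz in water (c = 1500 m/s,
  rho = 1000 kg/m3), lossless or with alpha = 5.756 Np/m, on a rigid
  baffle, compared on axis against the attenuated closed-form annulus
  solution (circular/ring) or a numerically integrated attenuated
  Rayleigh-Sommerfeld surface integral (rectangular). The two references
  cross-check each other to 0.5%.
* **Spherical-shell skull**: water exterior, bone shell, brain interior,
  with table properties for each. The shell thickness can be perturbed
  over direction by a seeded combination of first/second-order spherical
  harmonics normalized so that `perturb_frac` is the relative RMS
  thickness variation (clamped to $[0.25, 1.75]\,t_0$). All generators are
  pure functions of their parameters and seed.

What the shell phantom does *not* emulate: anatomical skull geometry
(tables, diploe, sutures), per-voxel bone property variation from CT
porosity, shear-wave conversion in bone, and the surrounding scalp/skin
layers. Passing the refocusing tests therefore demonstrates the
correction machinery and its expected qualitative ordering, not clinical
performance on a human head.

## Transducer model and steering

The clinical-scale array is idealized as 1024 flat, 1 cm2 circular
elements tangent to a 30 cm-diameter sphere, laid out by a golden-angle
spiral over the lower hemisphere (with a pole-repelling offset that
improves the worst-pair spacing); the elements of the real device tile the
cap at ~72% fill, so center spacings are compared against the
equivalent-square pitch $\sqrt{A}$ rather than a disc diameter. Scaled
arrays (fewer, smaller elements on a smaller cap) follow the same
construction. Element faces are rasterized to a one-voxel-thick band of
grid voxels (which makes the rasterized count area-exact regardless of
tilt), with conflicts resolved to the nearest element.

Element drive amplitude for a total acoustic power $P$ is
$p_{el} = \sqrt{P Z_w / (N A)}$ with $Z_w = 1.4823\times10^6$ kg/m2/s
(1482.3 m/s x 1000 kg/m3); 1000 W over 1024 one-cm2 elements gives
120.31 kPa.

The four aberration-correction strategies:

* **DPC** — phases $2\pi f d_i/c_w$ from element-target distances in pure
  water; fixed amplitudes.
* **RTPC** — straight-ray bone thickness $b_i$ from voxel marching along
  each element-target segment (no refraction), phases
  $2\pi f[(d_i-b_i)/c_w + b_i/c_b]$; fixed amplitudes.
* **SPC** — phase conjugation of the phasors captured at the element
  centers during an inverse run driven by a point source at the target;
  fixed amplitudes.
* **SPAC** — as SPC, with captured amplitudes retained and scaled by
  $f = \sqrt{N p_{el}^2 / \sum_i p_{cap,i}^2}$, so
  $\sum_i A_i^2 = N p_{el}^2$ exactly.

Sign convention (fixed once, used everywhere): the drive phase is the
*negative* of the propagation phase, so a wave driven with phase $+kd$
arrives at distance $d$ with zero phase; SPC's $-\arg p_{cap}$ realizes
the same convention automatically. Elements whose captured amplitude falls
below $10^{-6}$ of the maximum carry no usable phase (no line of sight)
and are deactivated.

The ray model earns its keep only where the aberration is
thickness-dominated and incidence is near-normal — e.g. a target near the
center of the shell. For strongly oblique crossings, refraction through
the curved shell (which straight rays cannot see) dominates the true
aberration, and RTPC degenerates to DPC-like performance; this matches
the expectation that simulation-based corrections are the robust option
away from the geometric focus.

## Thermal model

The Pennes bioheat equation

$$\rho C \frac{\partial T}{\partial t} = \nabla\!\cdot\!(k \nabla T)
  + \rho Q + \rho S - \rho_b c_b \rho \omega (T - T_b)$$

is advanced by explicit finite differences with harmonic-mean face
conductivities and an adaptive stability-bounded step
$\Delta t \le \rho C \Delta^2 / (6k)$.

Units, stated explicitly because the literature is inconsistent:

* $\omega$ is entered in ml/min/kg (clinical convention) and converted
  internally to m3 of blood per kg of tissue per second
  ($\times 10^{-6}/60$), which is what the sink form
  $\rho_b c_b \rho \omega (T-T_b)$ requires for W/m3.
* The acoustic heat source is stored per unit mass, $S$ in W/kg, with
  $S = a p^2 / (\rho^2 c)$, so that $\rho S = a p^2/(\rho c) = 2\alpha I$
  is the classical plane-wave relaxation-absorption heating. (Writing the
  deposition formula directly as a per-volume rate while also multiplying
  by $\rho$ in the bioheat equation would double-count the density; the
  per-mass form keeps the steady-state balance
  $\Delta T = S/(\rho_b c_b \omega)$ exact, which the suite verifies to
  1%.)

Boundary handling is label-based: a label can be declared *Dirichlet*
(voxels pinned at a temperature, e.g. a 16 degC water bolus surface),
or an *ambient* medium imposing the mixed condition
$k\,\partial T/\partial n + h(T - T_{out}) = F$ on every interface with
tissue ($h = 0$ gives a pure imposed flux). The standard head-treatment
configuration uses water at 16 degC with $h = 70$ W/m2/K and air at
25 degC with $h = 6$ W/m2/K. Vascular shutdown multiplies the perfusion
term by 1 below 50 degC, linearly down to 0 at 51 degC, and 0 above —
exactly, not smoothly, since the thresholds themselves are the model.

The treatment protocol runs 30 min of equilibration without acoustic
source (cooling equilibrium is typically reached after about 10 min),
then 20 s of sonication; both end states are returned, and temperature
rise is reported as $\Delta T$ over the equilibrium state. Whether
"ablation" means $T = 50$ degC or $\Delta T = 50$ K for a 37 degC
baseline is ambiguous in parts of the literature; the package reports
both absolute and rise fields and asserts neither as a lesion criterion.

## Focal-region analysis

`focal_metrics()` reproduces the standard lesion/focus bookkeeping:
smooth with a 3-voxel box filter (width configurable; the filter protects
maxima detection from voxel noise), find local maxima over 26-voxel
neighborhoods, select the maximum *nearest the intended target* (not the
global one — a mislocated beam should be reported as mislocated, not
silently re-centred), threshold at 50% of that peak, and take the
26-connected component containing it. Reported: distance of the component
centroid and of the peak voxel to the target, per-axis FWHM as the
component's bounding extent, shape factor (max/min extent), and volume as
the sum of voxel volumes. Connectivity 26 and filter width 3 are choices;
both are parameters.

## Study conditions and problem sizes

The validation scenarios run at sizes chosen so the whole suite completes
on a laptop-class single core:

* Interface cases: 1 MHz, $\lambda/20$ in the incident medium, thin-slab
  domains a few cm across; nine (medium, angle) cases in ~30 s total.
  Measured R/T agree with the analytic coefficients to ~0.005 and with
  the reference coefficient table to better than 0.02.
* Piston cases: $\lambda/10$, 36 x 36 x 24-30 mm domains, 60 periods,
  order-4 interior scheme; ~90 s per case. Maximum on-axis NSD over the
  six cases is ~2.3% (bound 3.5%).
* Refocusing: 230 kHz, $\lambda/10$ = 0.64 mm, shell outer radius 18 mm,
  mean thickness 6 mm, RMS thickness perturbation 0.3 (a skull-realistic
  several-mm variation), 64 elements of 9 mm2 on a 64 mm-diameter cap,
  target at the geometric focus, 16-period inverse and forward runs.
  Under these conditions the target-pressure ordering
  DPC < RTPC < SPC < SPAC is strict across seeds, with RTPC ~10% above
  DPC and SPAC 30-40% above, and SPC/SPAC peaks land within one voxel of
  the target.
* Thermal identities run on millimetre-scale blocks in seconds.

## Known limitations

* No shear waves: bone supports mode conversion that a fluid model cannot
  capture; near-skull secondary hot-spots are therefore not predicted
  reliably.
* Homogeneous per-tissue properties; no CT-derived per-voxel bone maps.
* The ray tracer ignores refraction by construction.
* Explicit time stepping throughout: very long thermal equilibrations at
  fine resolution are affordable only because the stability-bound step is
  recomputed per phase.
* Soft-tissue densities and thermal constants are database conventions,
  not measurements tied to this package; only the water constants enter
  quantitative validation results.
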