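# tcfus

Full-wave acoustic and bioheat simulation for transcranial focused
ultrasound (tcFUS), in R with compiled (Rcpp) stepping kernels.

Therapeutic ultrasound delivered through the intact skull is aberrated by
bone: its roughly doubled sound speed and density and order-of-magnitude
higher absorption shift and smear the focus and sap focal gain.
Phased-array applicators compensate by driving each element with its own
phase and amplitude. `tcfus` is for modellers who want to simulate that
whole chain on synthetic phantoms: propagate the wave, compute the
per-element corrections, check where the focus actually lands, and
estimate the induced heating.

## What is inside

* **Acoustic FDTD solvers** for the linear acoustic pressure wave equation
  extended with a density-variation term,
  `rho div((1/rho) grad p) - p_tt/c^2 - (atilde/c^2) p_t = 0`,
  and for the nonlinear Westervelt–Lighthill equation (thermoviscous
  `delta/c^4 p_ttt` and nonlinearity `beta/(rho c^4) (p^2)_tt` terms,
  `beta = 1 + B/2A`), on 3D rectilinear (optionally nonuniform) grids with
  convolutional-PML absorbing boundaries, soft/hard/velocity-baffle
  sources, and steady-state phasor extraction by Fourier projection.
* **Transducers**: an idealized hemispherical array (1024 x 1 cm^2
  elements on a 30 cm sphere by default, scalable), element drive from
  acoustic power via `p_el = sqrt(P Z_w / (N A))`, and voxel rasterization
  of element faces.
* **Aberration correction**: the four standard strategies — distance-based
  (DPC), ray-traced through the skull (RTPC), and time-reversal phase
  (SPC) / phase+amplitude (SPAC) corrections from an inverse run driven by
  a virtual point source at the target, with power normalization
  `sum A_i^2 = N p_el^2`.
* **Thermal solver**: Pennes bioheat equation with the relaxation
  absorption source `rho S = a p^2/(rho c)`, label-based
  Dirichlet/Neumann/convective boundaries, linear vascular shutdown
  between 50 and 51 degC, and the equilibrate-then-sonicate treatment
  protocol.
* **Phantoms and references**: plane-wave interface slabs, baffled pistons
  (circular/rectangular/ring), seeded spherical-shell skull phantoms;
  analytic R/T coefficients and Snell angles, closed-form and
  Rayleigh-integral piston references, the normalized-standard-deviation
  (NSD) field comparison, and FWHM/volume/shape connected-component focal
  metrics.

## Worked example

Reflection and transmission of a 1 MHz plane wave hitting a water-like /
(c = 2000 m/s, rho = 1900 kg/m^3) interface at normal incidence, measured
from a time-gated FDTD run and compared with the impedance formulas:

```r
library(tcfus)
setup <- make_interface_setup(cA = 1500, rhoA = 1000,
                              cB = 2000, rhoB = 1900,
                              theta_i = 0, f = 1e6)
m <- measure_interface(setup)
c(T_measured = m$measured$T, R_measured = m$measured$R,
  T_analytic = m$analytic$T, R_analytic = m$analytic$R)
#> T_measured R_measured T_analytic R_analytic
#>  1.4273     0.4364     1.4340     0.4340
```

The measured transmission (1.427) and reflection (0.436) coefficients sit
within 0.007 of the analytic values — the wave gains amplitude crossing
into the stiffer medium (T > 1) while 43% of the incident amplitude is
reflected. The element drive level for a clinical-scale array:

```r
element_surface_pressure(P_total = 1000, N_elements = 1024,
                         A_element = 1e-4)
#> [1] 120314.1     # Pa, i.e. ~120.31 kPa per element at 1000 W
```

A complete focusing run through a perturbed spherical-shell skull phantom
(inverse propagation, all four strategies, focal metrics) is wrapped by
`run_scenario()`; see `?run_scenario` and the methods vignette
(`vignettes/tcfus-methods.Rmd`) for the models and the choices behind
them. A thin command-line wrapper is installed at `inst/cli/tcfus.R`.

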