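---
title: "An idealized finite-element model of the human middle ear and its vibrometry-style validation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An idealized finite-element model of the human middle ear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otomech)
```

## The problem

The middle ear transforms sound pressure in the ear canal into motion
of the cochlear fluid. Its standard dynamic descriptor is the umbo
displacement transfer function (UDTF): the displacement magnitude of
the umbo — the apex of the conical tympanic membrane, where the malleus
handle attaches — per unit sound pressure, versus frequency. Intact
human ears show a characteristic pattern: a nearly flat UDTF below
about 1 kHz, a first resonance near 1 kHz, and a roll-off above it.
Because the response is linear over moderate stimulus levels
(60–80 dB SPL), measurements taken at different levels collapse onto
one UDTF, which is what makes the transfer-function framing useful.

`otomech` implements both sides of a model-validation workflow: a
harmonic structural finite-element model of an idealized middle ear,
and the measurement-style statistics (one-third-octave pure-tone
schedules, log-normal population summaries, synthetic subjects,
model-vs-measurement comparison) needed to exercise the full pipeline
without access to subjects or instrumentation.

## The structural model

The discrete problem solved at each frequency $f$ (with
$\omega = 2\pi f$) is

$$\left[\,K \circ (1 + i\,\eta) \;+\; i\omega C \;-\; \omega^2 M\,\right]\,u = f_p,$$

where $K$ and $M$ are assembled from shell, solid and connector
elements, $\eta$ is a per-region structural (hysteretic) loss factor
applied element-wise into a complex stiffness, and $C$ collects the
discrete viscous dampers of the cochlear load. Hysteretic damping was
chosen over proportional (Rayleigh) damping: it damps every mode of a
region equally instead of tying damping to two global coefficients,
which is the conventional way to tame unrealistically peaky responses
in middle-ear models. The complex system is solved by direct sparse LU
factorization of the equivalent real $2n \times 2n$ augmented form, one
factorization per frequency — no modal truncation, so no truncation
choices to defend. Symmetric diagonal equilibration is applied first:
the model mixes mineralized dofs (stiffness $\sim 10^7$ N/m) with
near-massless drilling rotations, a spread that otherwise defeats
sparse LU pivoting.

Element technology:

* **Shells** (tympanic membrane, annular-ligament ring, manubrium
  strip): flat triangular facets combining a constant-strain membrane,
  discrete-Kirchhoff (DKT) bending, and a weak drilling-rotation
  stabilization of the Zienkiewicz form ($10^{-6} E t A$, null on
  rigid rotations). The drilling dofs carry $10^{-4}\times$ the bending
  rotary inertia: with matching inertia the stabilization's soft global
  modes land inside the audio band (observed at 2.3 kHz on a plate
  fixture); with reduced inertia they sit far above 100 kHz while $M$
  stays positive definite. An isotropic resting tension $T$ (N/m) adds
  the membrane geometric stiffness
  $T \int \nabla N_i \cdot \nabla N_j \, dA$ on transverse deflections.
* **Solids** (ossicles, incudomalleolar and incudostapedial joints):
  linear tetrahedra with consistent mass; they pass the uniform-strain
  patch test to machine precision.
* **Connectors**: grounded springs ($k\,dd^\top$ on a node's
  translations), spring–dampers, and bars whose axial stiffness is
  $EA/L$ with $E$ taken from the material registry — so the shipped
  material presets act on the ligaments too.

Verification is by closed forms: single-dof static and resonant
amplitudes to $10^{-10}$, the clamped circular plate fundamental
($\lambda^2 = 10.2158$) to better than 2 % at mesh size $a/12$, a
clamped beam strip against Euler–Bernoulli, dense complex solves as
oracles for the sparse path, and exact linearity/reciprocity checks.

## The idealized geometry and its calibration

No geometry is published for this model family's subject-specific
meshes, so the package generates a parametric stand-in
(`ear_params()`, `build_ear_mesh()`): a conical membrane (radius
4.5 mm, cone depth 1.5 mm, pars tensa thickness 0.074 mm) on a
structured polar grid, split into pars tensa, a rim-adjacent pars
flaccida patch, a peripheral annular-ligament ring, and a stiff
manubrium strip along one meridian; an ossicular chain of stacked
solid blocks (malleus handle/neck/head, incudomalleolar joint, incus
body/short/long process, incudostapedial joint, stapes) whose
densities are the published per-part values and whose volumes are
sized so each ossicle lands at a literature-typical mass (stapes
≈ 3 mg, malleus ≈ 27 mg, incus ≈ 29 mg); and the connector set — 42
vertical cochlear spring–dampers summing to 70 N/m and 0.054 N·s/m,
the 9 N/m stapedial annular ligament shared over the footplate rim,
lateral footplate springs, and four grounded ligament/tendon bars.

The surrogate cannot claim geometric equivalence to any real ear, only
topological fidelity (membrane → manubrium → malleus → incudomalleolar
joint → incus → incudostapedial joint → stapes → footplate, which the
tests assert for arbitrary valid parameters). Its free parameters were
therefore calibrated **once**, against the canonical response traits of
the intact middle ear (flat UDTF below ~800 Hz, first resonance near
1 kHz), using modal and strain-energy diagnostics rather than curve
fitting:

* A bare idealized cone with the published membrane modulus and
  thickness is about an order of magnitude too compliant — its drum
  modes fall at 250–500 Hz. The real membrane's anatomical curvature
  and radial fiber structure are what stiffen it. The surrogate
  emulates this with a resting tension of 150 N/m on the taut regions,
  which moves the membrane's own modes above 2 kHz while leaving the
  statics membrane-dominated.
* A straight, pencil-like ossicular chain hanging from the umbo
  see-saws about its soft joints at low frequency. The chain is
  therefore compact (cross-section 6.4 mm², segment lengths halved,
  masses unchanged), and the footplate's lateral constraint springs
  default to 5000 N/m each — representing the transverse grip of the
  oval-window annular seal, for which no published constant exists
  (only the 9 N/m piston-direction total is published). With the
  published suggestion of lateral stiffness equal to the per-spring
  vertical value (70/42 N/m), the chain's rigid-body rocking modes
  fall below 100 Hz, which no intact ear shows.
* Structural loss factors are not published for this property set.
  Defaults are 0.05 for mineralized regions, 0.7 for soft tissue, 1.2
  for the annular-ligament ring, and 0.7 for the annular-seal springs
  — high values consistent with the heavily damped response of the
  physiological system, and required for the flat-then-resonant shape
  rather than a sequence of sharp peaks. All are config-exposed.

With these defaults frozen, the default model (≈ 2300 free dofs at
mesh size 0.6 mm) produces a UDTF flat to 2.8 dB over 200–800 Hz with
its first resonance at ≈ 1.03 kHz and a high-frequency roll-off
steeper than 20 dB/decade — the trait set the calibration targeted,
now asserted by the test suite.

## The measurement pipeline

`third_octave_centers()` produces the base-10 nominal one-third-octave
series; 200 Hz–10 kHz contains exactly 18 bands. `spl_to_pressure()`
uses the universal 20 µPa RMS reference. Vibrometer velocity readings
convert to displacement by the steady-state relation $d = v/(2\pi f)$.
`to_udtf()` divides displacement magnitudes by the excitation pressure
— the linearity assumption — so 60 dB and 80 dB runs of a linear system
give identical UDTF samples.

`aggregate_lognormal()` implements the log-normal population summary:
per frequency, the arithmetic mean and $n-1$ standard deviation of
$\log_{10}$ magnitudes across subjects (within-subject samples are
averaged on the log scale first), with 10th/90th percentile bands from
the fitted normal quantiles ($z = \pm 1.2816$) by default and an
empirical-quantile mode for large samples. Base-10 logs are the
default for dB compatibility; a natural-log mode exists.

## The synthetic-subject generator

`population_model()` + `generate_population()` emulate a vibrometry
study population so every downstream stage is testable without data:
a template UDTF (generalized second-order resonator: flat compliance,
resonance at $f_0$ with quality factor $q$, asymptotic roll-off of
`slope` dB/decade), a per-subject level shift and resonance shift
drawn once on the $\log_{10}$ scale, and per-tone multiplicative noise
whose SD shrinks as $1/\sqrt{n}$ under repetition averaging (a
raw-repeat mode generates every repetition instead). Defaults: $f_0$
= 1 kHz, compliance 3e-5 mm/Pa (a literature-typical umbo compliance),
slope −30 dB/decade (between the ideal mass line and the shallower
measured roll-offs), $q = 1.4$, subject level SD 0.2 log10 units
(≈ 4 dB, "large variations between subjects"), resonance SD 0.05,
noise SD 0.05 before averaging, 20 averages per tone, 2 levels
(60/80 dB), 5 subjects as the study-scale default. Seeds derive per
subject from one master seed by a fixed integer sequence, so datasets
are reproducible and subjects independent.

What the generator does *not* emulate: physiological disturbances
(heartbeat, breathing), probe-microphone calibration error, ear-canal
standing waves, or any frequency dependence of the inter-subject
spread. Passing parameter-recovery and linearity tests against it
therefore validates the statistical pipeline's algebra, not the
realism of any particular ear.

## Model-vs-measurement comparison

`compare_udtf()` resamples the model spectrum onto the measurement
centers by linear interpolation in (log f, log magnitude) — exact for
power laws, < 0.2 dB error at 60 points/decade on resonator curves —
and reports per-center deviations $20\log_{10}$(model / measured
geometric mean). The divergence band is the lowest center from which
the absolute deviation exceeds the threshold at *every* higher center;
this persistence rule ignores isolated spikes and matches the notion
of a model that "deviates more and more" with frequency. The threshold
defaults to 6 dB and is a free parameter — no published criterion
exists for "describes the response well".

## Numerical choices and limitations

* Frequencies are swept on a logarithmic grid (60 points/decade by
  default) and resampled to measurement centers for comparison.
* The umbo response averages $|u_z|$ over the umbo-region nodes
  (magnitude first, then mean) — conservative against phase
  cancellation; the complex-mean alternative is an option. The region
  is all membrane nodes within 0.3 mm of the apex.
* Degenerate inputs are rejected at build time (zero-area facets,
  inverted tetrahedra, meshes too coarse to resolve the flaccida
  sector); the harmonic solver reports a condition estimate when asked
  to solve an exactly resonant undamped system.
* Modal extraction uses a shifted-and-inverted dense eigensolve with
  diagonal scaling; it is intended for verification fixtures
  (thousands of dofs), not production-scale models.
* Test and acceptance runs use the default 0.6 mm mesh (≈ 2300 free
  dofs) and 12–60 frequency points per decade; these sizes resolve the
  traits being asserted while keeping a full pipeline run in minutes.
* The model is linear: no prestress states beyond the constant-tension
  term, no viscoelastic or frequency-dependent moduli, no ear-canal
  acoustics (pressure is uniform on the membrane by construction), and
  no claim of anatomical realism. Conclusions about real ears require
  real geometry; the package's claims are about the method pipeline
  and the idealized surrogate's qualitative behavior.
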