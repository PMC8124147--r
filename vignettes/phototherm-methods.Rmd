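---
title: "Multiscale thermal dosimetry for nanoparticle photothermal therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale thermal dosimetry for nanoparticle photothermal therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phototherm)
```

## The model

`phototherm` computes steady-state temperature fields around laser-heated
plasmonic nanoparticles at three nested scales, all built from one
primitive: the conduction Green's function of a point heat source in an
infinite homogeneous medium, clamped at the physical radius of the heated
object,

$$\Delta T(\mathbf{r}) \;=\; \frac{P}{4\pi\kappa\,\max(|\mathbf{r}|, R)},$$

where $P$ is the absorbed power, $\kappa$ the thermal conductivity, and
$R$ the object radius (the rise is constant inside the object). The three
scales differ only in what plays the role of the source:

* **Nanoscale** — a single gold nanosphere absorbs $P = \sigma_{abs} I$;
  arrays of particles superpose linearly (`single_particle_dT()`,
  `superpose()`).
* **Micron scale** — a cell holds a cubic lattice of $N_{np}$ particles;
  the exact field sums every particle (`cell_field_exact()`), while the
  coarse form treats the whole cell as one source of strength
  $N_{np}\sigma_{abs} I$ clamped at the cell radius
  (`cell_field_coarse()`). The two agree outside cells; inside, the coarse
  form is lower because the near-particle peaks are averaged away — for
  the default loaded cell the difference at the centre is on the order of
  0.1 K, three orders of magnitude above the sub-mK mismatch outside. The
  test suite checks exactly this contrast.
* **Millimetre scale** — the tumor is a cylinder of cells on a cubic
  lattice; each lit cell is a coarse source whose strength is attenuated
  by Beer–Lambert's law at the cell's own depth and gated laterally by
  the beam footprint (`tissue_field()`).

The absolute temperature is `baseline + rise` with a default baseline of
37 °C (body temperature).

### Assumptions worth knowing about

* **Steady state in an infinite medium.** No boundary conditions, no
  surface cooling, no blood perfusion, no transients. Fields therefore
  overestimate temperatures far from the sources compared to a perfused
  tissue, and say nothing about heating or cooling dynamics.
* **Collimated top-hat beams.** A cell is lit iff its lateral position is
  inside the footprint; light does not spread sideways, and the intensity
  profile is uniform inside the footprint. This keeps the tissue field a
  pure superposition with per-source Beer attenuation, consistent with
  using a one-dimensional attenuation law.
* **Absorption-dominated optics.** Scattered-light interference and
  diffuse fluence build-up are ignored; for the default tumor optics
  ($\mu_a \approx 39.4\,\mathrm{cm^{-1}}$ vs
  $\mu_s' \approx 1.9\,\mathrm{cm^{-1}}$) absorption dominates attenuation
  by a factor of twenty, so this is a mild approximation.
* **Heat sources only inside the tumor.** Healthy tissue holds no
  nanoparticles; it heats purely by conduction.

## Particle optics

`mie_efficiencies()` evaluates the Mie series for a homogeneous sphere
with the standard logarithmic-derivative downward recurrence and the
Bohren–Huffman truncation $n_{stop} = x + 4x^{1/3} + 2$; energy partition
$Q_{ext} = Q_{sca} + Q_{abs}$ is exact to $10^{-8}$ over the tested range,
and the small-sphere limit agrees with the closed-form Rayleigh absorption
to better than 1% for $x \le 0.05$. The reduced scattering efficiency is
$Q_s' = Q_{sca}(1-g)$.

**Optical constants.** The vendored default is the Johnson & Christy
(1972) gold table, linearly interpolated in $n$ and $k$; it is the
de-facto standard for gold plasmonics. No size-dependent mean-free-path
correction is applied. Any three-column table can be swapped in via
`read_optical_constants()`.

**Medium refractive index.** The host medium index defaults to
`n_medium = 1.40`, a standard soft-tissue value. This was a genuinely open
choice: water (1.33) is common in nanoparticle optics, but the medium
here is tumor tissue, and 1.40 simultaneously reproduces the full set of
worked-example optical values this package targets — plasmon peak near
532 nm, $Q_a \approx 3.3$ vs 3.4, $Q_s' \approx 0.267$ vs 0.27, and
$\sigma_{abs} \approx 4100$ vs $4293\,\mathrm{nm^2}$ (all within ~5%) —
where water leaves the cross-section ~20% low. The index is configurable
everywhere it appears.

## Loading, attenuation and geometry

Nanoparticle loading enters twice, and the geometry module keeps the two
views consistent:

* **Bulk optics:** $\mu_{a,n} = 0.75 f_v Q_a / R_{NP}$ and
  $\mu_{s,n}' = 0.75 f_v Q_s' / R_{NP}$ add to the medium coefficients
  (`nanoparticle_attenuation()`, `composite_coefficients()`).
* **Discrete sources:** `particles_per_cell()` allocates
  $N_{np} = \mathrm{round}(f_v a^3 / \tfrac43\pi R_{NP}^3)$ particles to
  each cell-lattice box of side $a$, so the discrete model realizes the
  same volume fraction that drives the attenuation (default scenario:
  20 889 particles per cell at $f_v = 5.6\times10^{-6}$, $a = 50$ µm,
  $R_{NP} = 20$ nm).

Both lattices (particles in a cell, cells in the tumor) are deterministic
cubic lattices — the model's reading of "uniformly distributed" — with a
seeded random-placement alternative (`random_positions_in_sphere()`) for
robustness checks only. The cell radius (10 µm) and the intra-cell spacing
(derived from the particle budget, ~585 nm by default) are configurable;
cell size is only stated as "tens of microns" in the source material, so
a mid-range mammalian-cell radius was fixed once. The cell lattice places
depth levels at half-integer multiples of the spacing so that every cell
centre lies strictly inside the tumor; "distance between cells" is read
as centre-to-centre.

These generated lattices are the package's synthetic data. They emulate
idealized uniform nanoparticle uptake; they do not emulate aggregation,
endosomal clustering, heterogeneous cell loading, irregular cell packing,
or perfusion-shaped temperature plateaus. Passing tests therefore
establish the correctness of the model's own arithmetic and its internal
approximations — not that real tumors heat this way.

## Beam shapes

`beam_spec()` supports full-coverage, centred-spot, ring and spot-array
footprints. The spot array places `n_inner` disk centres at angles
$2\pi k/n$ on radius $P_1$ and `n_outer` on $P_2$ offset by half the outer
angular spacing — the relative phase is not fixed by the source material,
and staggering maximizes azimuthal coverage; it is configurable. Boundary
points count as lit (closed footprints), which makes lattice points that
fall exactly on a circle deterministic. `lit_area()` is analytic except
for overlapping spot arrays, where exact 1-D interval unions are
integrated over a fine set of chords (cross-checked against seeded Monte
Carlo in the tests). Comparisons across shapes keep the surface intensity
per shape fixed — the convention of the worked examples (15, 30 and
90 W/cm² for full, ring and array) — so delivered power
$I_0 \times$ area varies with the footprint and is reported alongside.

## Numerics

* **Direct sum** (`superpose()`): exact $O(N_{src} N_{nodes})$ compiled
  summation, source-outer loops for cache locality. This is the oracle
  path; ~200 000 cells × 33³ nodes runs in tens of seconds.
* **Particle-mesh fast path** (`fast_field()`): cloud-in-cell deposition,
  zero-padded FFT convolution with the clamped kernel sampled at grid
  offsets, plus an exact near-field correction within 8 grid cells of
  every source (the mesh's trilinear image charges are subtracted and the
  true kernel added). Trilinear deposition preserves monopole and dipole
  moments, so the residual quadrupole error decays as $(h/r)^2$ beyond
  the correction window; the documented contract — ≤ 0.5% maximum
  relative error with ≥ 2 nodes per clamp radius — is enforced by test.
  Grids that cannot support the mesh (an axis with < 4 nodes, irregular
  spacing, or spacing coarser than the clamp radius) fall back to the
  direct sum with a warning.
* **Grids.** `tumor_grid()` spans twice the tumor in each direction with
  presets of 33/49/81 nodes per axis; `tumor_plane_grid()` gives a
  101×81 axial plane. Planar figures and trend tests use the plane grid;
  volumetric overheating summaries use the coarse 3D preset, a deliberate
  accuracy/size trade-off for routine runs.
* **Interpolation and contours.** Reference points use trilinear
  interpolation; isotherms use marching squares
  (`grDevices::contourLines`) on an axial slice. The deepest axial
  crossing of an isotherm is found by linear interpolation along the
  axis profile.
* **Degenerate inputs.** Empty source sets give a zero field; `fv = 0`
  gives zero sources, a zero field and a zero overheating volume; scan
  ties in `plasmon_peak()` break toward the shorter wavelength; equality
  at footprint boundaries counts as lit.

## Damage metrics

Thermal damage uses the Arrhenius integral
$\Omega(t) = A e^{-E_a/RT} t$ with damage at $\Omega \ge 1$ and minimum
damage time $t_{min} = 1/(A e^{-E_a/RT})$, evaluated in the log domain so
the huge frequency factors cannot overflow. The default coefficients
($A = 3.1\times10^{98}\,\mathrm{s^{-1}}$,
$E_a = 6.28\times10^5\,\mathrm{J/mol}$) are the classical
Henriques–Moritz soft-tissue values from the thermal-damage literature —
they are *not* fitted to this package's scenario and should be replaced
when a tissue-specific pair is known.

Therapy quality is summarized by `therapy_report()`: temperatures at three
reference points, tumor uniformity $(\max-\min)/\mathrm{mean}$, the
healthy-tissue volume above an overheating threshold (default 52 °C,
configurable), minimum damage times at the reference points, and
delivered power. The reference points default to **B** on the tumor side
at mid-depth, **C** at the bottom centre and **D** at the top side edge.
Their coordinates were an open choice; placing B at mid-depth (rather
than at the bottom corner) is what makes the model reproduce the expected
clinical orderings — side hotter than bottom centre for deep tumors under
full coverage, the reverse for shallow tumors — because a bottom-corner B
sits diagonally far from the heated top disc and always reads colder than
the bottom centre. All three points are configurable.

## Scenario pipeline

`run_scenario()` wires the whole chain — Mie optics (or explicit
overrides), composite attenuation, lattices, beam gating, field, report —
from a validated YAML configuration with unit-suffixed keys (unknown keys
are rejected, every offending key listed). Identical configuration and
seed produce byte-identical report JSON. `compare_shapes()` runs several
beam configurations against a shared tumor and tabulates the metrics.
A thin command-line front end with `optics`, `field`, `compare` and
`report` subcommands ships in `inst/cli/phototherm.R`. Fields export to
flat CSV (long `x,y,z,value` format) plus the JSON report; both are
plain text.

## Known limitations

* No perfusion, boundaries or transients (see assumptions): absolute
  temperatures far from sources are upper bounds.
* The Beer–Lambert model has no diffuse fluence: at depths of several
  attenuation lengths real fluence exceeds the collimated estimate.
* Mie optics assume isolated spheres; dense intracellular clusters
  couple plasmonically and shift the resonance.
* The Arrhenius defaults are generic soft-tissue coefficients; absolute
  damage times carry their (large) literature uncertainty, so they are
  best used comparatively.
* The printed worked-example cross-section depends on the (unstated)
  optical-constants source of the original calculation; with the vendored
  Johnson & Christy table the package reproduces it to ~5%, not to all
  printed digits.
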