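---
title: "Whole-body dose equivalent for image-guided radiotherapy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body dose equivalent for image-guided radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periDose)
```

## Overview

`periDose` computes the whole-body 3D dose-equivalent distribution of an
image-guided radiotherapy (IGRT) treatment by combining four pieces, each
per treatment session: the in-field dose grid of a treatment planning
system (TPS), an analytical out-of-field photon stray dose, an analytical
peripheral photoneutron dose equivalent for high-energy (15 MV) beams, and
the imaging dose of a daily cone-beam CT (CBCT).  The per-session grids
are summed voxelwise and multiplied by the number of sessions.  Dose
equivalent is additive here because photons enter with a radiation
weighting factor of 1 and the neutron model outputs dose equivalent
directly.

All spatial quantities live on a regular voxel lattice with physical
spacing and origin in room coordinates (cm): x lateral, y anterior, z
longitudinal (towards the head), isocenter at the origin.  The gantry
angle follows the IEC convention; at angle g the X-ray target sits at
`(sad*sin g, sad*cos g, 0)` with a source-axis distance of 100 cm
(TrueBeam standard; configurable).  The clinical working resolution is
0.2 x 0.2 x 0.5 cm^3 voxels; every simulation shipped with the package
(tests and the acceptance script) uses 0.8 x 0.8 x 1.0 cm^3 (and parts of
the unit-test suite 1.6 x 1.6 x 2 cm^3) so that a full six-plan pipeline
runs in seconds — the models themselves are resolution-independent.

## Radiological depth

Both the photon depth attenuation and the neutron model need the
soft-tissue-equivalent (radiological) depth from the X-ray target to a
point: the line integral of the relative density along the straight
connecting line, from the body entry surface to the point.  Lung voxels
carry 0.25 of the soft-tissue density, so 4 cm of lung contributes 1 cm
of depth.  The implementation is an exact voxel-traversal (Siddon-style)
parametric algorithm in C++; an independent fine-step (0.005–0.01 cm)
numerical integrator in pure R serves as the test oracle only.  The two
agree to well under 1% on the synthetic anthropomorphic phantom.

## The stray-dose model

The out-of-field photon dose is the sum of patient scatter (`ps`),
collimator scatter (`cs`) and head leakage (`hl`).  Per field and per
session:

* `ps = Dfx * w_f * A_ps * (A/100)^0.7 * L_ps(d_edge) * exp(-t/20)`
* `cs = MU_f * A_cs * L_cs(d_edge) * exp(-t/16)`
* `hl = MU_f * A_hl * exp(-r_iso/150) * exp(-t/32)`

with `Dfx` the fraction dose, `w_f` the field's MU share, `A` the field
area (cm^2), `d_edge` the 3D distance from the field edge (the 50%
aperture rectangle diverging from the source), `t` the radiological
depth, `r_iso` the distance from the isocenter, and lateral falloffs
`L(x) = exp(-x/a) + b*(x0/(x+x0))^2` — an exponential near-field term
plus an inverse-square-like far tail, the generic shape of measured
peripheral-dose profiles.  Patient scatter is exactly linear in the
fraction dose, collimator scatter and head leakage exactly linear in MU;
these homogeneity properties are enforced by tests.

### Calibration

The model's six amplitudes (three per nominal energy) are the only tuned
constants.  The shipped defaults are produced by `calibrateStrayModel()`
under the constraints the underlying measurement campaign reports:

1. patient scatter per target Gy at 6 MV is 2.0 times the 15 MV value;
2. collimator scatter per MU at 15 MV is 1.5 times the 6 MV value;
3. the population mean photon energy (below) over the out-of-field probe
   sites of the synthetic study is 0.40 MeV for the 6 MV plans and
   0.47 MeV for the 15 MV plans.

Constraints 1–2 are imposed exactly (the 15 MV amplitudes anchor the
6 MV ones); constraint 3 fixes the remaining two degrees of freedom — a
joint rescaling of the `cs` and the `hl` amplitudes of both energies —
by a deterministic Nelder–Mead fit on the synthetic phantom.  The
reference condition for the ratios is a single 10 x 10 cm^2 field on a
30 cm soft-tissue slab, evaluated on the central axis 15 cm beyond the
field edge (`referenceComponents()`).  A consequence worth noting: the
fitted effective leakage amplitude is larger than a bare leakage-only
value, because in this model head leakage also absorbs the
neutron-capture gamma contribution that ionization-chamber-adjusted
leakage calibrations include.

With the shipped configuration, patient scatter dominates near the field
edge (strongest for 6 MV), while deep in the body beyond ~50 cm from the
isocenter head leakage dominates — the spatial pattern whole-body TLD
measurements show.

### Known limitations

No electron contamination and no surface-buildup correction: the model
is expected to underestimate skin dose (by up to a factor of two in the
underlying measurements).  Capture gammas are not modelled separately
(folded into leakage).  Non-coplanar beams, wedges and
flattening-filter-free beams are out of scope.

## Photoneutron dose equivalent

For 15 MV beams, neutrons from the treatment head are modelled as a point
source at the X-ray target:
`H = MU * S / r^2 * exp(-t / lambda_n)` per field, with `S` the source
strength (Sv cm^2/MU) and `lambda_n` = 8 cm the tissue attenuation
length.  6 MV plans produce no photoneutrons (below threshold), and
voxels inside any field aperture are masked to zero — inside the primary
beam, neutron dose is negligible relative to photon dose and the model is
peripheral only.  The defaults `S` = 0.012 Sv cm^2/MU and `lambda_n` =
8 cm are order-of-magnitude values flagged `calibrated = FALSE`; every
shipped analysis uses ratio or shape properties that do not depend on
them: linearity in MU, the closed-form depth ratio
`H1 r1^2 / (H2 r2^2) = exp((t2-t1)/lambda_n)` (checked against the
brute-force depth integral within 1%), and the location of the MPAX
maximum at the minimum radiological depth — the "neck peak" of an
anthropomorphic body, which the synthetic phantom reproduces.  The
depth variable is density-scaled (lungs at 0.25), with the caveat that
this choice is exactly what makes analytical neutron models overestimate
lung dose; a configuration switch is deliberately not offered because
the whole depth machinery is shared with the photon model.

The paired-TLD conversion (`tld600ToDoseEquiv()`) mirrors the
measurement chain: subtract the photon-equivalent signal (photon dose
times the chip's relative energy response), clamp negative residuals to
zero with a flag, and multiply by a depth-dependent conversion factor
(linear interpolation in a configurable two-column table).

## CBCT imaging dose

A full-trajectory pelvis CBCT contributes a per-scan grid built from
per-slice mean doses: linear interpolation between sampled slice
positions along the medial patient axis, the same value for every voxel
of a transversal slice (a good first approximation for full-rotation
scans), and an exponential tail (default decay length 6 cm) beyond the
sampled range.  The default profile is a flat 20 mGy plateau over the
+/- 8.75 cm field of view — a realistic order of magnitude for a pelvis
protocol; measured per-slice values are a required input for absolute
work.  Daily imaging means one scan per session.

## Fusion and DEVH comparison

The TPS grid is reliable close to the target but degrades quickly
outside; the stray model is built for the far field.  The hand-over is a
hard switch at a longitudinal plane 4 cm from the treatment volume
(about 3 cm from the field edge).  `fuseGrids()` reports the relative
step across the seam; on the synthetic study it is 13–20%, consistent
with the overlap-region agreement that justifies a plane fusion (no
blending).

DEVHs are cumulative histograms ("fraction of the volume receiving at
least D") over 200 log-spaced bins from 1e-4 Sv to the grid maximum.
Technique comparisons use `bandRatio()`: a dose band (default the
out-of-field band from 0.05% to 5% of the prescribed dose) is mapped to
the volume-fraction interval it occupies in the reference histogram, and
the ratio of the doses at the midpoint volume fraction is returned.
This operationalizes "factor of k" statements as a vertical DEVH shift
and returns exactly k for uniformly scaled grids.  A minimum-dose ratio
is available through `devhQuantile()` near volume fraction 1.  On the
synthetic six-plan study at 15 MV the band ratios come out near the MU
ratios of the plans (IMRT/3DCRT ~3.1–3.7, VMAT/3DCRT ~1.8–2.0), diluted
slightly by the technique-independent CBCT floor — the mechanism behind
the observation that intensity-modulated techniques with more beam-on
time pay for it in out-of-field dose.

## Mean photon energy and detector response

At every out-of-field point the mean photon energy is the dose-weighted
mean of the three component energies,
`E = (ps*E_ps + cs*E_cs + hl*E_hl) / (ps+cs+hl)`, with the measured
component energies (MeV):

```{r}
componentEnergies()
```

The collimator-scatter energy is the 35 cm value because that is where
collimator scatter is largest relative to the other contributions.  The
result is convex (always inside the component-energy hull) and invariant
to uniform rescaling of the dose triple.  Correction factors for a
detector are the reciprocal relative response at the local mean energy;
response curves are editable tables with linear interpolation, and the
shipped curves are analytic synthetic stand-ins
(`syntheticResponseCurve()`), not measured data.

## The synthetic study

`syntheticSpec()` defines an Alderson-like body of stacked elliptical
sections (pelvis, trunk with two 0.25-density lung ellipsoids, neck,
head; ~102 cm tall), a pelvic target ellipsoid at the isocenter, 189
TLD-like probe sites (151 beyond the fusion boundary, all at least
~1 cm deep, seeded and reproducible), and 10% multiplicative lognormal
measurement noise — the agreement level of careful whole-body TLD
dosimetry.  The six benchmark plans carry the published fractionation
and MU totals (3DCRT 2.0 Gy x 26, 7326/5846 MU; IMRT 2.2 Gy x 23,
22989/21661 MU; VMAT 2.2 Gy x 23, 13409/11847 MU for 6/15 MV), with
equal per-field MU splits and default gantry geometry (four-field box at
0/90/180/270 degrees, five equally spaced IMRT fields, one VMAT arc
grouped into six fields) — only MU totals enter the MU-scaling
components, so the split is a convention, not a fitted quantity.  The
synthetic in-field grid is the prescription inside the target, an
exponential penumbra (1.2 cm) outside it, floored at 0.9 times the
stray-model dose so the two calculations meet consistently at the
boundary; the 0.9 emulates the mild out-of-field underestimation of
planning systems.

What passing tests on this phantom do **not** show: performance on real
anatomy (curved medial axes, heterogeneous bone/air, organ-specific
geometry), absolute neutron dose (uncalibrated constants), skin dose, or
TPS behaviour — the in-field grid is generated, not planned.

## Numerical choices

* Voxel centers on the lattice, half-open voxel extents, trilinear
  interpolation for off-lattice sampling.
* Arc grouping bins are closed-open and anchored at the arc start angle;
  MU is conserved exactly by construction.
* MU/Gy is rounded half-up to match published plan tables.
* The MPAX is a straight longitudinal line through the isocenter's
  transverse position (body curvature is not followed; flagged in the
  spec object).
* Degenerate inputs fail loudly: mismatched lattices, points outside the
  grid, empty masks, zero prescribed dose and out-of-range energies or
  depths are errors, not silent zeros; the single deliberate clamp (the
  negative neutron residual) carries a flag.
* Grid files use a plain-text self-describing format with `%.17g`
  values, which round-trips doubles bit-exactly.
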