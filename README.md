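# periDose

Whole-body dose-equivalent modelling for image-guided external-beam
radiotherapy (IGRT).

## The problem

A radiotherapy treatment planning system calculates dose accurately around
the target volume, but the rest of the body still receives an unwanted
low dose from stray radiation — and that out-of-field dose is what drives
second-cancer risk estimates and fetal-dose assessments.  `periDose`
assembles a whole-body 3D dose-equivalent distribution for an IGRT
treatment from analytical models:

* **Out-of-field photon stray dose** as the sum of three components, per
  treatment session:

  `D(x) = D_ps(x) + D_cs(x) + D_hl(x)`

  where patient scatter (`ps`) scales with the target dose per session,
  and collimator scatter (`cs`) and head leakage (`hl`) scale with the
  delivered monitor units (MU).  Each component is
  `amplitude x lateral falloff(d_edge) x exp(-t / lambda)`, with `d_edge`
  the distance from the field edge and `t` the radiological depth from
  the X-ray target, computed by exact Siddon ray tracing through the
  voxel phantom (lung at 0.25 of the soft-tissue density).
* **Peripheral photoneutron dose equivalent** (15 MV beams) from a point
  source at the X-ray target:
  `H(x) = MU x S / r^2 x exp(-t / lambda_n)`, zero inside the primary
  beam.
* **CBCT imaging dose**: per-slice mean doses interpolated along the
  medial patient axis (constant within each transversal slice), with an
  exponential tail beyond the field of view, one scan per session.
* **Fusion**: the in-field (planning-system) grid hands over to the stray
  model at a longitudinal plane 4 cm from the treatment volume; the total
  per-treatment dose equivalent is `(photon + neutron + CBCT) x sessions`.
* **Mean photon energy** at every out-of-field point, as the dose-weighted
  mean of the measured component energies,
  `E(x) = sum_i D_i(x) E_i / sum_i D_i(x)`, used to derive detector
  energy-response correction factors (TLD dosimetry).
* **DEVHs** (dose-equivalent volume histograms) and band-ratio /
  deviation statistics for comparing techniques (3DCRT, IMRT, VMAT) and
  beam energies (6 vs 15 MV).

A synthetic-data module generates every input end to end: an Alderson-like
voxel phantom, the six benchmark pelvic plans with their published MU
totals, a synthetic in-field dose grid, TLD-like probe locations, and
pseudo-measurements with 10% multiplicative noise.

## Worked example

```r
library(periDose)

spec    <- syntheticSpec(spacing = c(0.8, 0.8, 1.0))
phantom <- buildPhantom(spec)
plans   <- planFixtures()

muPerGy(plans[["IMRT_15MV"]])
#> [1] 428

pl  <- plans[["IMRT_15MV"]]
sg  <- strayDoseGrid(pl, phantom)                     # Gy / session
ng  <- neutronDoseGrid(pl, phantom)                   # Sv / session
cb  <- cbctDoseGrid(defaultCbctProfile(), phantom)    # Gy / scan
tps <- syntheticTpsGrid(pl, phantom, spec, strayGrid = sg)
fu  <- fuseGrids(tps, sg, FusionSpec(targetMask(phantom, spec), 4),
                 bodyMask(phantom))
fu$seam$meanRelStep                  # relative step across the 4 cm plane
#> [1] 0.1305311
tot <- totalDoseEquivalent(fu$grid, ng, cb, pl@nFractions)
tot
#> DoseGrid [Sv]: 46 x 31 x 105 voxels, spacing 0.8 x 0.8 x 1 cm
#>   origin (-18, -12, -19) cm; value range [0, 51.06]

pr     <- probeLocations(phantom, spec, seed = 1)
probes <- as.matrix(pr[pr$outOfField, c("x", "y", "z")])
cd     <- componentDoses(pl, phantom, probes)
mean(meanEnergy(cd, energy = "15MV"))
#> [1] 0.4756573
```

The seam step says the synthetic in-field grid and the stray model agree
to ~13% where they meet; the ~0.47 MeV population mean is the
energy entering the TLD response correction for 15 MV treatments.

## Scope

Electron contamination, surface buildup (skin dose), Monte Carlo
transport, organ-weighted effective dose and second-cancer risk models
are out of scope; the neutron constants are order-of-magnitude defaults
flagged uncalibrated until machine-commissioned values are supplied.  See
the methods vignette (`vignettes/whole-body-dose.Rmd`) for the model
assumptions, calibration and limitations.
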