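#' Measured mean energies of the stray components
#'
#' Mean photon energies (MeV) of patient scatter, collimator scatter and
#' head leakage per nominal beam energy, from field measurements in a 30 cm
#' slab phantom.  The collimator-scatter value is the one determined 35 cm
#' from the field edge, where collimator scatter is largest relative to the
#' other contributions, and is used at every location.
#'
#' @return data.frame with columns `energy`, `ps`, `cs`, `hl` (MeV).
#' @export
componentEnergies <- function() {
  data.frame(energy = c("6MV", "15MV"),
             ps = c(0.28, 0.29),
             cs = c(0.62, 0.53),
             hl = c(0.35, 0.45),
             stringsAsFactors = FALSE)
}

.energyRow <- function(energies, energy) {
  row <- energies[energies$energy == energy, , drop = FALSE]
  if (nrow(row) != 1L)
    stop(sprintf("no component energies for %s", energy))
  row
}

#' Dose-weighted mean photon energy
#'
#' The out-of-field mean photon energy at a location is the mean of the
#' three component energies weighted by the calculated component doses:
#' `(ps*E_ps + cs*E_cs + hl*E_hl) / (ps + cs + hl)`.  The result always
#' lies within the hull of the component energies and is invariant to a
#' uniform rescaling of the three doses.
#'
#' @param components data.frame with columns `ps`, `cs`, `hl` (one row per
#'   location), e.g. from [componentDoses()].
#' @param energies a [componentEnergies()] table.
#' @param energy `"6MV"` or `"15MV"`.
#' @return numeric vector of mean energies (MeV).
#' @examples
#' meanEnergy(data.frame(ps = 1, cs = 0, hl = 0))        # 0.28
#' meanEnergy(data.frame(ps = 1, cs = 1, hl = 1), energy = "15MV")
#' @export
meanEnergy <- function(components, energies = componentEnergies(),
                       energy = "6MV") {
  row <- .energyRow(energies, energy)
  tot <- components$ps + components$cs + components$hl
  if (any(tot <= 0))
    stop("mean energy undefined where all component doses are zero")
  (components$ps * row$ps + components$cs * row$cs +
     components$hl * row$hl) / tot
}

#' Detector energy-response correction factor
#'
#' The correction factor is the reciprocal of the detector's relative
#' response at the local mean photon energy; the corrected dose is the
#' detected dose times this factor.
#'
#' @param meanEnergyMeV mean photon energy (MeV), within the curve's range.
#' @param curve a [ResponseCurve-class].
#' @return numeric vector of dimensionless factors.
#' @export
correctionFactor <- function(meanEnergyMeV, curve) {
  rng <- range(curve@energyMeV)
  if (any(meanEnergyMeV < rng[1] | meanEnergyMeV > rng[2]))
    stop(sprintf("mean energy outside the tabulated range [%g, %g] MeV",
                 rng[1], rng[2]))
  r <- approx(curve@energyMeV, curve@response, xout = meanEnergyMeV)$y
  1 / r
}

#' Construct a ResponseCurve
#'
#' @param detector detector label.
#' @param energyMeV ascending tabulated energies (MeV).
#' @param response relative response at each energy; renormalized so the
#'   response at `calibrationEnergy` is exactly 1.
#' @param calibrationEnergy calibration energy (MeV).
#' @return a [ResponseCurve-class].
#' @export
ResponseCurve <- function(detector, energyMeV, response, calibrationEnergy) {
  r0 <- approx(energyMeV, response, xout = calibrationEnergy, rule = 1)$y
  if (is.na(r0) || r0 <= 0)
    stop("calibrationEnergy must lie inside the tabulated range")
  new("ResponseCurve", detector = detector, energyMeV = as.numeric(energyMeV),
      response = as.numeric(response) / r0,
      calibrationEnergy = as.numeric(calibrationEnergy))
}

#' Synthetic detector response curve
#'
#' An analytic stand-in for a LiF-chip energy-response curve: relative
#' response `1 + a * exp(-E / e0)`, normalized at the calibration energy.
#' `a > 0` gives an over-response toward lower photon energies (TLD100-like),
#' `a < 0` an under-response (TLD100H-like).  Synthetic: shipped for tests
#' and examples, not a measured curve.
#'
#' @param detector label.
#' @param a amplitude of the low-energy deviation.
#' @param e0 energy scale of the deviation (MeV).
#' @param calibrationEnergy calibration energy (MeV); 1.25 MeV is a typical
#'   effective calibration-beam energy.
#' @return a [ResponseCurve-class].
#' @export
syntheticResponseCurve <- function(detector = "TLD100-synthetic", a = 0.3,
                                   e0 = 0.5, calibrationEnergy = 1.25) {
  e <- seq(0.05, 3, by = 0.05)
  ResponseCurve(detector, e, 1 + a * exp(-e / e0), calibrationEnergy)
}

#' Read / write a response curve as CSV
#'
#' Two columns `energy_MeV`, `response`; the calibration energy is stored
#' in a comment-free extra column on the first row.
#'
#' @param curve a [ResponseCurve-class].
#' @param path file path.
#' @export
writeResponseCurve <- function(curve, path) {
  df <- data.frame(energy_MeV = curve@energyMeV, response = curve@response,
                   detector = curve@detector,
                   calibration_MeV = curve@calibrationEnergy)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResponseCurve
#' @export
readResponseCurve <- function(path) {
  df <- read.csv(path)
  ResponseCurve(df$detector[1], df$energy_MeV, df$response,
                df$calibration_MeV[1])
}

#' Voxelwise mean photon energy grid
#'
#' Applies the dose-weighted mean energy voxel by voxel to the three stray
#' component grids; voxels with zero total component dose are set to `NA`.
#'
#' @param componentGrids list with [DoseGrid-class] elements `ps`, `cs`,
#'   `hl` on one lattice (e.g. from `strayDoseGrid(..., components = TRUE)`).
#' @param energies a [componentEnergies()] table.
#' @param energy `"6MV"` or `"15MV"`.
#' @return a [DoseGrid-class] with unit `"MeV"`.
#' @export
meanEnergyGrid <- function(componentGrids, energies = componentEnergies(),
                           energy = "6MV") {
  ps <- componentGrids$ps; cs <- componentGrids$cs; hl <- componentGrids$hl
  .stopIfLatticeMismatch(ps, cs)
  .stopIfLatticeMismatch(ps, hl)
  row <- .energyRow(energies, energy)
  tot <- ps@values + cs@values + hl@values
  e <- (ps@values * row$ps + cs@values * row$cs + hl@values * row$hl) / tot
  e[tot <= 0] <- NA_real_
  DoseGrid(e, ps@spacing, ps@origin, "MeV")
}

#' Mean photon energy summary over probe locations
#'
#' Samples the component grids at TLD-like probe sites, applies the
#' dose-weighted mean energy at each site, and reports the population mean
#' and sample standard deviation.
#'
#' @inheritParams meanEnergyGrid
#' @param probes n x 3 matrix of probe locations (cm).
#' @return list with `mean`, `sd`, `n` and the per-site energies `perSite`.
#' @export
probeEnergySummary <- function(componentGrids, probes,
                               energies = componentEnergies(),
                               energy = "6MV") {
  probes <- .asPointMatrix(probes)
  comp <- data.frame(ps = sampleGrid(componentGrids$ps, probes),
                     cs = sampleGrid(componentGrids$cs, probes),
                     hl = sampleGrid(componentGrids$hl, probes))
  e <- meanEnergy(comp, energies, energy)
  list(mean = mean(e), sd = if (length(e) > 1) sd(e) else 0,
       n = length(e), perSite = e)
}
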