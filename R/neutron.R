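#' Default photoneutron model configuration
#'
#' Order-of-magnitude defaults for a 15 MV TrueBeam-class machine, flagged
#' uncalibrated: the source strength and attenuation length should be
#' replaced by machine-commissioned constants for absolute work.  All
#' shipped analyses rely only on ratio and shape properties of the model,
#' which are independent of these two constants.
#'
#' @param sourceStrength Sv cm^2 per MU (default 0.012).
#' @param lambda soft-tissue attenuation length in cm (default 8).
#' @return a [NeutronModelConfig-class].
#' @export
defaultNeutronConfig <- function(sourceStrength = 0.012, lambda = 8) {
  depth <- seq(0, 40, by = 5)
  # synthetic depth-to-dose-equivalent conversion for the residual TLD600
  # signal: decreasing with depth as the spectrum thermalizes
  factor <- 2.0 * exp(-depth / 25) + 0.3
  new("NeutronModelConfig", sourceStrength = sourceStrength, lambda = lambda,
      fluenceToDoseEquiv = 1,
      depthConversion = data.frame(depth_cm = depth, factor = factor),
      calibrated = FALSE)
}

#' Peripheral neutron dose equivalent at points (per session)
#'
#' Point source of neutrons at the X-ray producing target: for each field,
#' `H = MU_session * S * fluenceToDoseEquiv / r^2 * exp(-depth / lambda)`,
#' with `r` the source-to-point distance and `depth` the radiological depth
#' (lungs scaled by their 0.25 relative density).  Summed over fields; for
#' a VMAT plan the six grouped fields provide the per-field source
#' positions.  6 MV plans return 0 (no photoneutron production below
#' threshold); points inside any field aperture return 0 with the
#' `inField` flag set, since the model is peripheral only.
#'
#' @param plan a [TreatmentPlan-class].
#' @param phantom a [VoxelPhantom-class].
#' @param points n x 3 matrix of room coordinates (cm) inside the phantom
#'   grid.
#' @param config a [NeutronModelConfig-class].
#' @param isocenter isocenter room coordinates (cm).
#' @param sad source-axis distance (cm).
#' @return data.frame with columns `H` (Sv per session) and `inField`.
#' @export
neutronDoseEquivalent <- function(plan, phantom, points,
                                  config = defaultNeutronConfig(),
                                  isocenter = c(0, 0, 0), sad = 100) {
  points <- .asPointMatrix(points)
  n <- nrow(points)
  H <- numeric(n)
  anyIn <- logical(n)
  if (plan@nominalEnergy == "6MV")
    return(data.frame(H = H, inField = anyIn))
  for (f in plan@fields) {
    geo <- .fieldGeometry(f, points, sad, isocenter)
    depth <- radiologicalDepth(phantom, geo$source, points)
    muSession <- f@mu / plan@nFractions
    H <- H + muSession * config@sourceStrength * config@fluenceToDoseEquiv /
      geo$rSource^2 * exp(-depth / config@lambda)
    anyIn <- anyIn | geo$inField
  }
  H[anyIn] <- 0
  data.frame(H = H, inField = anyIn)
}

#' Whole-body neutron dose-equivalent grid (per session)
#'
#' [neutronDoseEquivalent()] evaluated at every body voxel center; zero for
#' 6 MV plans and inside the in-field mask.
#'
#' @inheritParams neutronDoseEquivalent
#' @return a [DoseGrid-class] with unit `"Sv"`.
#' @export
neutronDoseGrid <- function(plan, phantom, config = defaultNeutronConfig(),
                            isocenter = c(0, 0, 0), sad = 100) {
  d <- dim(phantom@density)
  a <- array(0, d)
  idx <- which(phantom@bodyMask)
  if (length(idx) && plan@nominalEnergy != "6MV") {
    cc <- voxelCenters(phantom)
    ai <- arrayInd(idx, d)
    pts <- cbind(cc$x[ai[, 1]], cc$y[ai[, 2]], cc$z[ai[, 3]])
    a[idx] <- neutronDoseEquivalent(plan, phantom, pts, config,
                                    isocenter, sad)$H
  }
  DoseGrid(a, phantom@spacing, phantom@origin, "Sv")
}

#' Convert a paired-TLD neutron signal to dose equivalent
#'
#' The raw TLD600 signal (registering photons and neutrons, in
#' photon-dose-calibrated units) is corrected for the photon contamination
#' measured by the companion photon-only chip: the photon-equivalent signal
#' is the photon dose times the chip's relative response at the local mean
#' photon energy.  The residual neutron signal is transformed to neutron
#' dose equivalent with a depth-dependent conversion factor (linear
#' interpolation in the configured table).  Negative residuals clamp to
#' zero and set the `clamped` flag.
#'
#' @param rawSignal TLD600 signal(s) in photon-dose-equivalent units (>= 0).
#' @param photonDose photon dose at the location (Gy).
#' @param meanEnergyMeV local mean photon energy (MeV).
#' @param depth radiological depth of the location (cm), within the
#'   conversion-table range.
#' @param config a [NeutronModelConfig-class].
#' @param responseCurve photon energy-response curve of the TLD600-type chip.
#' @return data.frame with columns `H` (Sv) and `clamped`.
#' @export
tld600ToDoseEquiv <- function(rawSignal, photonDose, meanEnergyMeV, depth,
                              config = defaultNeutronConfig(),
                              responseCurve = syntheticResponseCurve()) {
  dc <- config@depthConversion
  if (any(depth < min(dc$depth_cm) | depth > max(dc$depth_cm)))
    stop("depth outside the conversion-table range")
  resp <- approx(responseCurve@energyMeV, responseCurve@response,
                 xout = meanEnergyMeV)$y
  residual <- rawSignal - photonDose * resp
  clamped <- residual < 0
  if (any(clamped))
    warning("negative neutron residual clamped to 0 at some locations")
  residual[clamped] <- 0
  f <- approx(dc$depth_cm, dc$factor, xout = depth)$y
  data.frame(H = residual * f, clamped = clamped)
}
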