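#' @import methods
#' @importFrom stats approx median optim quantile rlnorm runif sd lm coef setNames
#' @importFrom utils read.csv write.csv
#' @useDynLib periDose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.DOSE_UNITS <- c("Gy", "Sv", "MeV")

#' DoseGrid: a scalar field on a regular voxel lattice
#'
#' A 3D scalar field (absorbed dose in Gy, dose equivalent in Sv, or a mean
#' photon energy in MeV) sampled at voxel centers of a regular lattice with
#' physical spacing and origin in room coordinates (cm).  Two grids are
#' combinable only if their lattices (shape, spacing, origin) match exactly.
#'
#' @slot values numeric 3D array, one value per voxel.
#' @slot spacing numeric length-3, voxel spacing (dx, dy, dz) in cm.
#' @slot origin numeric length-3, room coordinates of the center of voxel
#'   (1,1,1) in cm.
#' @slot unit one of `"Gy"`, `"Sv"`, `"MeV"`.
#'
#' @exportClass DoseGrid
setClass("DoseGrid",
  representation(values = "array", spacing = "numeric",
                 origin = "numeric", unit = "character"))

setValidity("DoseGrid", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) return("spacing must be 3 positive numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite numbers")
  if (length(object@unit) != 1L || !object@unit %in% .DOSE_UNITS)
    return(sprintf("unit must be one of %s", paste(.DOSE_UNITS, collapse = ", ")))
  if (object@unit %in% c("Gy", "Sv")) {
    if (any(!is.finite(v))) return("dose values must be finite")
    if (any(v < 0)) return("dose values must be >= 0")
  } else {
    if (any(is.infinite(v))) return("energy values must be finite or NA")
  }
  TRUE
})

#' VoxelPhantom: voxelized body model
#'
#' Density (relative to soft tissue, whose mass density is taken as
#' 1.0 g/cm^3), a boolean body mask, per-voxel material labels and the medial
#' patient axis (MPAX), all on one regular lattice.  Lung voxels carry a
#' density of 0.25 times soft tissue.
#'
#' @slot density numeric 3D array, g/cm^3 (equal to relative density here).
#' @slot bodyMask logical 3D array.
#' @slot material integer 3D array: 0 = air, 1 = soft tissue, 2 = lung.
#' @slot mpax numeric matrix (n x 3) of ordered points (inferior to superior)
#'   along the medial patient axis, room coordinates in cm.
#' @slot spacing,origin lattice geometry as for [DoseGrid-class].
#'
#' @exportClass VoxelPhantom
setClass("VoxelPhantom",
  representation(density = "array", bodyMask = "array", material = "array",
                 mpax = "matrix", spacing = "numeric", origin = "numeric"))

setValidity("VoxelPhantom", function(object) {
  d <- dim(object@density)
  if (length(d) != 3L) return("density must be a 3D array")
  if (!identical(d, dim(object@bodyMask)) || !identical(d, dim(object@material)))
    return("density, bodyMask and material must share one lattice")
  if (any(object@density[!object@bodyMask] != 0))
    return("density must be 0 outside the body mask")
  lung <- object@material == 2L
  if (any(abs(object@density[lung] - 0.25) > 1e-9))
    return("lung voxels must have density 0.25 x soft tissue")
  soft <- object@material == 1L
  if (any(abs(object@density[soft] - 1.0) > 1e-9))
    return("soft-tissue voxels must have density 1.0")
  if (ncol(object@mpax) != 3L && nrow(object@mpax) > 0L)
    return("mpax must be an n x 3 matrix")
  TRUE
})

#' BeamField: one static treatment field
#'
#' @slot gantryAngle gantry angle in degrees, [0, 360).
#' @slot aperture equivalent rectangular field (x width, y width) in cm,
#'   defined at the isocenter plane.
#' @slot mu monitor units delivered by this field (>= 0).
#' @slot collimatorAngle collimator rotation in degrees (default 0).
#'
#' @exportClass BeamField
setClass("BeamField",
  representation(gantryAngle = "numeric", aperture = "numeric",
                 mu = "numeric", collimatorAngle = "numeric"),
  prototype(collimatorAngle = 0))

setValidity("BeamField", function(object) {
  if (object@gantryAngle < 0 || object@gantryAngle >= 360)
    return("gantryAngle must lie in [0, 360)")
  if (length(object@aperture) != 2L || any(object@aperture <= 0))
    return("aperture must be two positive widths (cm)")
  if (object@mu < 0) return("mu must be >= 0")
  TRUE
})

#' TreatmentPlan: nominal energy, fields and fractionation
#'
#' @slot nominalEnergy `"6MV"` or `"15MV"`.
#' @slot technique `"3DCRT"`, `"IMRT"` or `"VMAT"`.
#' @slot fields list of [BeamField-class] objects.
#' @slot fractionDose prescribed dose per fraction in Gy.
#' @slot nFractions number of treatment sessions.
#'
#' @exportClass TreatmentPlan
setClass("TreatmentPlan",
  representation(nominalEnergy = "character", technique = "character",
                 fields = "list", fractionDose = "numeric",
                 nFractions = "integer"))

setValidity("TreatmentPlan", function(object) {
  if (!object@nominalEnergy %in% c("6MV", "15MV"))
    return("nominalEnergy must be '6MV' or '15MV'")
  if (!object@technique %in% c("3DCRT", "IMRT", "VMAT"))
    return("technique must be 3DCRT, IMRT or VMAT")
  if (!all(vapply(object@fields, is, TRUE, class2 = "BeamField")))
    return("fields must be BeamField objects")
  if (object@fractionDose < 0) return("fractionDose must be >= 0")
  if (object@nFractions < 1L) return("nFractions must be >= 1")
  TRUE
})

#' StrayModelConfig: parameters of the out-of-field photon stray model
#'
#' Houses, per nominal energy, the amplitudes and falloff constants of the
#' three stray components (patient scatter `ps`, collimator scatter `cs`,
#' head leakage `hl`).  Each component dose is
#' amplitude x lateral falloff x exponential in-phantom attenuation, where
#' the lateral falloff in the distance from the field edge is an
#' exponential-plus-inverse-square mixture.  `ps` scales with the delivered
#' target dose per session, `cs` and `hl` with monitor units.
#'
#' @slot params named list with entries `"6MV"` and `"15MV"`, each holding
#'   lists `ps`, `cs`, `hl` of numeric parameters (see [defaultStrayConfig()]).
#' @slot sad source-axis distance in cm (default 100).
#'
#' @exportClass StrayModelConfig
setClass("StrayModelConfig",
  representation(params = "list", sad = "numeric"),
  prototype(sad = 100))

setValidity("StrayModelConfig", function(object) {
  for (en in c("6MV", "15MV")) {
    p <- object@params[[en]]
    if (is.null(p)) return(sprintf("missing parameters for %s", en))
    for (comp in c("ps", "cs", "hl")) {
      q <- p[[comp]]
      if (is.null(q)) return(sprintf("missing %s parameters for %s", comp, en))
      if (q[["amp"]] < 0) return("amplitudes must be >= 0")
      if (q[["lambda"]] <= 0) return("attenuation lengths must be > 0")
    }
  }
  if (object@sad <= 0) return("sad must be > 0")
  TRUE
})

#' NeutronModelConfig: parameters of the peripheral photoneutron model
#'
#' Point source of neutrons at the X-ray target; fluence falls off with the
#' inverse square of the source distance and attenuates exponentially with
#' the radiological (soft-tissue-equivalent) depth; a fluence-to-dose-
#' equivalent conversion folds the spectrum weighting into one factor.
#' A depth-dependent conversion table maps a residual TLD600 signal to
#' neutron dose equivalent.
#'
#' @slot sourceStrength Sv cm^2 per MU (point-source amplitude at 1 cm).
#' @slot lambda soft-tissue attenuation length in cm.
#' @slot fluenceToDoseEquiv dimensionless multiplier applied on top of
#'   `sourceStrength` (kept separate so a tabulated conversion can replace it).
#' @slot depthConversion data.frame with columns `depth_cm`, `factor`
#'   (Sv per unit residual signal), covering the phantom depth range.
#' @slot calibrated logical; shipped defaults are order-of-magnitude values
#'   flagged `FALSE` until machine-specific constants are supplied.
#'
#' @exportClass NeutronModelConfig
setClass("NeutronModelConfig",
  representation(sourceStrength = "numeric", lambda = "numeric",
                 fluenceToDoseEquiv = "numeric", depthConversion = "data.frame",
                 calibrated = "logical"),
  prototype(fluenceToDoseEquiv = 1, calibrated = FALSE))

setValidity("NeutronModelConfig", function(object) {
  if (object@sourceStrength <= 0) return("sourceStrength must be > 0")
  if (object@lambda <= 0) return("lambda must be > 0")
  if (object@fluenceToDoseEquiv <= 0) return("fluenceToDoseEquiv must be > 0")
  dc <- object@depthConversion
  if (!all(c("depth_cm", "factor") %in% names(dc)))
    return("depthConversion needs columns depth_cm, factor")
  if (any(dc$factor <= 0)) return("conversion factors must be > 0")
  if (is.unsorted(dc$depth_cm, strictly = TRUE))
    return("depthConversion depths must be strictly increasing")
  TRUE
})

#' CbctProfile: per-slice mean dose of one CBCT scan
#'
#' @slot slicePositions longitudinal sample positions (cm), ascending.
#' @slot sliceMeanDose mean absorbed dose per scan in each sampled
#'   transversal slice (Gy).
#' @slot fovLongitudinal half-length of the field of view from the isocenter
#'   (cm).
#' @slot fovDiameter transversal field-of-view diameter (cm).
#' @slot tailDecayLength exponential falloff length outside the sampled
#'   range (cm).
#'
#' @exportClass CbctProfile
setClass("CbctProfile",
  representation(slicePositions = "numeric", sliceMeanDose = "numeric",
                 fovLongitudinal = "numeric", fovDiameter = "numeric",
                 tailDecayLength = "numeric"))

setValidity("CbctProfile", function(object) {
  if (length(object@slicePositions) != length(object@sliceMeanDose))
    return("slicePositions and sliceMeanDose must have equal length")
  if (is.unsorted(object@slicePositions, strictly = TRUE))
    return("slicePositions must be strictly increasing")
  if (any(object@sliceMeanDose < 0)) return("sliceMeanDose must be >= 0")
  if (object@fovLongitudinal <= 0) return("fovLongitudinal must be > 0")
  if (object@tailDecayLength <= 0) return("tailDecayLength must be > 0")
  TRUE
})

#' ResponseCurve: relative energy response of a detector
#'
#' Relative response versus mean photon energy, normalized to 1 at the
#' calibration energy.  Linear interpolation between tabulated points.
#'
#' @slot detector detector label (e.g. `"TLD100H"`).
#' @slot energyMeV tabulated mean photon energies (MeV), ascending.
#' @slot response relative response (> 0) at each energy.
#' @slot calibrationEnergy energy at which the response is 1 (MeV).
#'
#' @exportClass ResponseCurve
setClass("ResponseCurve",
  representation(detector = "character", energyMeV = "numeric",
                 response = "numeric", calibrationEnergy = "numeric"))

setValidity("ResponseCurve", function(object) {
  if (length(object@energyMeV) != length(object@response))
    return("energyMeV and response must have equal length")
  if (is.unsorted(object@energyMeV, strictly = TRUE))
    return("energyMeV must be strictly increasing")
  if (any(object@response <= 0)) return("response must be > 0")
  r1 <- approx(object@energyMeV, object@response,
               xout = object@calibrationEnergy, rule = 1)$y
  if (is.na(r1) || abs(r1 - 1) > 1e-6)
    return("response must be 1 at the calibration energy")
  TRUE
})

#' DEVH: cumulative dose-equivalent volume histogram
#'
#' For each dose edge, the fraction of the masked volume receiving at least
#' that dose.  The first edge is 0, where the fraction is 1 by construction.
#'
#' @slot dose ascending dose bin edges (unit as tagged).
#' @slot fraction volume fraction receiving >= each edge, non-increasing.
#' @slot nVoxels number of voxels in the mask.
#' @slot unit dose unit of the edges.
#'
#' @exportClass DEVH
setClass("DEVH",
  representation(dose = "numeric", fraction = "numeric",
                 nVoxels = "integer", unit = "character"))

setValidity("DEVH", function(object) {
  if (length(object@dose) != length(object@fraction))
    return("dose and fraction must have equal length")
  if (is.unsorted(object@dose)) return("dose edges must be ascending")
  if (any(diff(object@fraction) > 1e-12))
    return("fraction must be non-increasing in dose")
  if (object@dose[1] != 0 || abs(object@fraction[1] - 1) > 1e-12)
    return("histogram must start at fraction 1 for dose 0")
  if (object@nVoxels < 1L) return("mask must be non-empty")
  TRUE
})

#' FusionSpec: where the in-field grid hands over to the stray model
#'
#' @slot targetMask logical 3D array flagging the treatment volume.
#' @slot boundaryDistance longitudinal distance (cm) from the treatment
#'   volume at which the in-field grid is replaced by the stray model
#'   (default 4).
#'
#' @exportClass FusionSpec
setClass("FusionSpec",
  representation(targetMask = "array", boundaryDistance = "numeric"),
  prototype(boundaryDistance = 4))

setValidity("FusionSpec", function(object) {
  if (!is.logical(object@targetMask)) return("targetMask must be logical")
  if (object@boundaryDistance <= 0) return("boundaryDistance must be > 0")
  TRUE
})

#' SyntheticSpec: geometry and noise of the synthetic study
#'
#' Describes the Alderson-like stacked-ellipse body (pelvis, abdomen/thorax
#' with lungs, neck, head), the pelvic target ellipsoid, the number of
#' TLD-like probe locations and the multiplicative measurement noise.
#'
#' @slot sections data.frame of body sections: `name`, `zMin`, `zMax`,
#'   `halfX`, `halfY` (cm).
#' @slot lungCenters numeric matrix (2 x 3), centers of the two lung
#'   ellipsoids (cm).
#' @slot lungHalfAxes numeric length-3 half axes of each lung (cm).
#' @slot targetCenter,targetHalfAxes pelvic target ellipsoid (cm); the
#'   isocenter sits at the target center.
#' @slot nProbes total number of probe locations (default 189).
#' @slot nProbesOutOfField probes placed beyond the fusion boundary
#'   (default 151).
#' @slot noiseSD multiplicative lognormal noise SD of pseudo-measurements
#'   (default 0.10).
#' @slot spacing voxel spacing of generated phantoms/grids (cm).
#'
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(sections = "data.frame", lungCenters = "matrix",
                 lungHalfAxes = "numeric", targetCenter = "numeric",
                 targetHalfAxes = "numeric", nProbes = "integer",
                 nProbesOutOfField = "integer", noiseSD = "numeric",
                 spacing = "numeric"))

setValidity("SyntheticSpec", function(object) {
  s <- object@sections
  if (!all(c("name", "zMin", "zMax", "halfX", "halfY") %in% names(s)))
    return("sections needs columns name, zMin, zMax, halfX, halfY")
  if (any(s$zMax <= s$zMin) || any(s$halfX <= 0) || any(s$halfY <= 0))
    return("degenerate body section dimensions")
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  if (object@nProbesOutOfField > object@nProbes)
    return("nProbesOutOfField cannot exceed nProbes")
  if (any(object@spacing <= 0)) return("spacing must be positive")
  TRUE
})
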