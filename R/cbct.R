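#' Default CBCT per-slice dose profile
#'
#' A full-trajectory pelvis CBCT: flat in-FOV plateau of 20 mGy per scan
#' over a +/- 8.75 cm longitudinal field of view, 46.5 cm transversal
#' field-of-view diameter, and an exponential falloff with a 6 cm decay
#' length outside the sampled range.  The plateau level is a realistic
#' order of magnitude for a pelvis protocol; per-slice values measured for
#' a specific scanner should replace it for absolute work.
#'
#' @param plateauDose in-FOV mean dose per scan (Gy).
#' @param fov longitudinal half-length of the field of view (cm).
#' @param tailDecayLength exponential decay length outside the FOV (cm).
#' @return a [CbctProfile-class].
#' @export
defaultCbctProfile <- function(plateauDose = 0.020, fov = 8.75,
                               tailDecayLength = 6) {
  pos <- seq(-fov, fov, by = 2.5)
  new("CbctProfile", slicePositions = pos,
      sliceMeanDose = rep(plateauDose, length(pos)),
      fovLongitudinal = fov, fovDiameter = 46.5,
      tailDecayLength = tailDecayLength)
}

#' Construct a CbctProfile
#'
#' @param slicePositions ascending longitudinal sample positions (cm).
#' @param sliceMeanDose mean dose per scan in each slice (Gy).
#' @param fovLongitudinal longitudinal FOV half-length (cm).
#' @param fovDiameter transversal FOV diameter (cm).
#' @param tailDecayLength exponential falloff length outside the samples
#'   (cm).
#' @return a [CbctProfile-class].
#' @export
CbctProfile <- function(slicePositions, sliceMeanDose, fovLongitudinal = 8.75,
                        fovDiameter = 46.5, tailDecayLength = 6) {
  if (is.unsorted(slicePositions, strictly = TRUE))
    stop("slicePositions must be sorted strictly ascending")
  new("CbctProfile", slicePositions = as.numeric(slicePositions),
      sliceMeanDose = as.numeric(sliceMeanDose),
      fovLongitudinal = fovLongitudinal, fovDiameter = fovDiameter,
      tailDecayLength = tailDecayLength)
}

#' Read / write a CBCT profile as CSV
#'
#' Columns `position_cm`, `mean_dose_Gy`; FOV and tail parameters on the
#' first row.
#'
#' @param profile a [CbctProfile-class].
#' @param path file path.
#' @export
writeCbctProfile <- function(profile, path) {
  df <- data.frame(position_cm = profile@slicePositions,
                   mean_dose_Gy = profile@sliceMeanDose,
                   fov_longitudinal_cm = profile@fovLongitudinal,
                   fov_diameter_cm = profile@fovDiameter,
                   tail_decay_cm = profile@tailDecayLength)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCbctProfile
#' @export
readCbctProfile <- function(path) {
  df <- read.csv(path)
  CbctProfile(df$position_cm, df$mean_dose_Gy, df$fov_longitudinal_cm[1],
              df$fov_diameter_cm[1], df$tail_decay_cm[1])
}

#' Whole-body CBCT dose grid for one scan
#'
#' The per-scan dose of a full-rotation CBCT is, to first approximation,
#' homogeneous within a transversal slice; the grid is built by linear
#' interpolation of the per-slice mean dose along the medial patient axis,
#' so every voxel of a transversal slice carries the same value.  Beyond
#' the outermost sampled slice the dose falls off exponentially with the
#' configured tail decay length.  Voxels outside the body mask are zero.
#'
#' @param profile a [CbctProfile-class].
#' @param phantom a [VoxelPhantom-class].
#' @return a [DoseGrid-class] (Gy per scan).
#' @export
cbctDoseGrid <- function(profile, phantom) {
  cc <- voxelCenters(phantom)
  z <- cc$z
  pos <- profile@slicePositions
  dose <- profile@sliceMeanDose
  perSlice <- approx(pos, dose, xout = z, rule = 1)$y
  below <- z < pos[1]
  above <- z > pos[length(pos)]
  perSlice[below] <- dose[1] * exp(-(pos[1] - z[below]) / profile@tailDecayLength)
  perSlice[above] <- dose[length(dose)] *
    exp(-(z[above] - pos[length(pos)]) / profile@tailDecayLength)
  d <- dim(phantom@density)
  a <- array(rep(perSlice, each = d[1] * d[2]), d)
  a[!phantom@bodyMask] <- 0
  DoseGrid(a, phantom@spacing, phantom@origin, "Gy")
}

#' Scale a per-scan grid by the number of sessions
#'
#' Daily image guidance: one scan per session, so the per-treatment imaging
#' dose is the per-scan grid times the number of sessions.
#'
#' @param grid a [DoseGrid-class] (per scan).
#' @param nSessions number of sessions (>= 0).
#' @return a [DoseGrid-class].
#' @export
scaleBySessions <- function(grid, nSessions) {
  if (nSessions < 0) stop("nSessions must be >= 0")
  grid * nSessions
}
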