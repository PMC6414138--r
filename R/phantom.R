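#' Construct a VoxelPhantom
#'
#' @param density numeric 3D array of densities relative to soft tissue
#'   (soft tissue 1.0, lung 0.25, air 0).
#' @param bodyMask logical 3D array; density must be 0 outside it.
#' @param material integer 3D array (0 air, 1 soft tissue, 2 lung).  If
#'   missing, derived from the density values.
#' @param mpax n x 3 matrix of medial-patient-axis points, ordered inferior
#'   to superior.
#' @param spacing,origin lattice geometry in cm.
#' @return a [VoxelPhantom-class].
#' @export
VoxelPhantom <- function(density, bodyMask, material = NULL, mpax,
                         spacing, origin) {
  storage.mode(density) <- "double"
  if (is.null(material)) {
    material <- array(0L, dim(density))
    material[abs(density - 1.0) < 1e-9] <- 1L
    material[abs(density - 0.25) < 1e-9] <- 2L
  }
  storage.mode(material) <- "integer"
  new("VoxelPhantom", density = density, bodyMask = bodyMask,
      material = material, mpax = as.matrix(mpax),
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' @rdname VoxelPhantom-class
#' @export
setMethod("bodyMask", "VoxelPhantom", function(object) object@bodyMask)

#' @rdname VoxelPhantom-class
#' @export
setMethod("phantomDensity", "VoxelPhantom", function(object) object@density)

#' @rdname VoxelPhantom-class
#' @export
setMethod("mpaxPoints", "VoxelPhantom", function(object) object@mpax)

#' @rdname VoxelPhantom-class
#' @export
setMethod("gridSpacing", "VoxelPhantom", function(object) object@spacing)

#' @rdname VoxelPhantom-class
#' @export
setMethod("gridOrigin", "VoxelPhantom", function(object) object@origin)

setMethod("show", "VoxelPhantom", function(object) {
  d <- dim(object@density)
  cat(sprintf("VoxelPhantom: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g cm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  body voxels: %d (%.1f%%), lung voxels: %d, MPAX points: %d\n",
              sum(object@bodyMask),
              100 * mean(object@bodyMask),
              sum(object@material == 2L), nrow(object@mpax)))
})

#' Source position for a gantry angle
#'
#' Room coordinate convention: x lateral, y anterior (+y towards the gantry
#' at angle 0 for a head-first supine patient), z longitudinal (+z towards
#' the head); the isocenter is the origin.  The X-ray producing target sits
#' at the source-axis distance from the isocenter, in the transversal plane
#' z = 0: at gantry angle g (IEC, degrees) the source is at
#' (sad sin g, sad cos g, 0).
#'
#' @param gantryAngle gantry angle in degrees.
#' @param sad source-axis distance in cm (default 100, TrueBeam standard).
#' @param isocenter room coordinates of the isocenter (cm).
#' @return numeric length-3 source position (cm).
#' @export
sourcePosition <- function(gantryAngle, sad = 100, isocenter = c(0, 0, 0)) {
  g <- gantryAngle * pi / 180
  isocenter + c(sad * sin(g), sad * cos(g), 0)
}

#' Radiological depth along source-to-point rays
#'
#' Soft-tissue-equivalent path length: the line integral of the relative
#' density along the straight line connecting the source (the X-ray
#' producing target) and each point, from the phantom entry surface to the
#' point.  Lung voxels contribute 0.25 x their geometric length; air
#' contributes nothing, so a segment that never crosses the body yields 0.
#' Uses an exact voxel-traversal (Siddon-style) algorithm.
#'
#' @param phantom a [VoxelPhantom-class].
#' @param source numeric length-3 source position (cm); may lie outside the
#'   grid.
#' @param points n x 3 matrix of evaluation points (cm); must lie inside the
#'   grid bounds.
#' @return numeric vector of depths (cm).
#' @examples
#' ph <- waterPhantom(30, spacing = c(2, 2, 2))
#' radiologicalDepth(ph, c(0, 100, 0), c(0, 5, 0))  # 10 cm into the cube
#' @export
radiologicalDepth <- function(phantom, source, points) {
  points <- .asPointMatrix(points)
  if (!all(.insideGridBounds(phantom, points)))
    stop("all points must lie inside the phantom grid bounds")
  .siddonDepth(as.vector(phantom@density), dim(phantom@density),
               phantom@spacing, phantom@origin, as.numeric(source), points)
}

# Independent fine-step numerical line integral (test oracle only):
# nearest-voxel density sampled every `step` cm along the segment.
.radiologicalDepthNumeric <- function(phantom, source, point, step = 0.01) {
  d <- as.numeric(point) - as.numeric(source)
  L <- sqrt(sum(d^2))
  if (L == 0) return(0)
  n <- max(2L, ceiling(L / step))
  t <- (seq_len(n) - 0.5) / n
  pos <- outer(t, d) + matrix(as.numeric(source), n, 3, byrow = TRUE)
  dims <- dim(phantom@density)
  idx <- matrix(0L, n, 3)
  ok <- rep(TRUE, n)
  for (a in 1:3) {
    i <- as.integer(round((pos[, a] - phantom@origin[a]) / phantom@spacing[a])) + 1L
    ok <- ok & i >= 1L & i <= dims[a]
    idx[, a] <- pmin(pmax(i, 1L), dims[a])
  }
  dens <- phantom@density[idx]
  dens[!ok] <- 0
  sum(dens) * (L / n)
}

#' Profile of a grid along the medial patient axis
#'
#' Samples a grid by trilinear interpolation at every MPAX point, ordered
#' inferior to superior.
#'
#' @param grid a [DoseGrid-class] on the phantom's lattice.
#' @param phantom a [VoxelPhantom-class].
#' @return data.frame with columns `z` (longitudinal position, cm) and
#'   `value`.
#' @export
mpaxProfile <- function(grid, phantom) {
  .stopIfLatticeMismatch(grid, phantom)
  mp <- phantom@mpax
  if (nrow(mp) == 0L)
    return(data.frame(z = numeric(0), value = numeric(0)))
  data.frame(z = mp[, 3], value = sampleGrid(grid, mp))
}

#' Homogeneous water cube phantom
#'
#' A side x side x side cm soft-tissue cube centered on the isocenter; used
#' as the reference geometry for stray-model calibration (the field
#' measurements behind the component energies were made in a 30 cm slab
#' phantom) and in tests.
#'
#' @param side cube side length in cm.
#' @param spacing voxel spacing in cm.
#' @param center cube center (cm).
#' @return a [VoxelPhantom-class].
#' @export
waterPhantom <- function(side = 30, spacing = c(1, 1, 1),
                         center = c(0, 0, 0)) {
  n <- pmax(2L, as.integer(round(side / spacing)))
  origin <- center - (n - 1) / 2 * spacing
  dens <- array(1.0, n)
  mask <- array(TRUE, n)
  z <- origin[3] + (seq_len(n[3]) - 1) * spacing[3]
  mpax <- cbind(center[1], center[2], z)
  VoxelPhantom(dens, mask, mpax = mpax, spacing = spacing, origin = origin)
}
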