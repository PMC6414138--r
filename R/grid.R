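#' Construct a DoseGrid
#'
#' @param values numeric 3D array of voxel values.
#' @param spacing voxel spacing (dx, dy, dz) in cm.
#' @param origin room coordinates (cm) of the center of voxel (1,1,1).
#' @param unit `"Gy"`, `"Sv"` or `"MeV"`.
#' @return a [DoseGrid-class] object.
#' @examples
#' g <- DoseGrid(array(1, c(4, 4, 4)), spacing = c(1, 1, 1),
#'               origin = c(0, 0, 0))
#' doseUnit(g)
#' @export
DoseGrid <- function(values, spacing, origin, unit = "Gy") {
  storage.mode(values) <- "double"
  new("DoseGrid", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), unit = unit)
}

#' @rdname DoseGrid-class
#' @export
setMethod("doseValues", "DoseGrid", function(object) object@values)

#' @rdname DoseGrid-class
#' @export
setMethod("gridSpacing", "DoseGrid", function(object) object@spacing)

#' @rdname DoseGrid-class
#' @export
setMethod("gridOrigin", "DoseGrid", function(object) object@origin)

#' @rdname DoseGrid-class
#' @export
setMethod("doseUnit", "DoseGrid", function(object) object@unit)

setMethod("show", "DoseGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("DoseGrid [%s]: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g cm\n",
              object@unit, d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  rng <- range(object@values, na.rm = TRUE)
  cat(sprintf("  origin (%.3g, %.3g, %.3g) cm; value range [%.4g, %.4g]\n",
              object@origin[1], object@origin[2], object@origin[3],
              rng[1], rng[2]))
})

#' Lattice identity of two grids
#'
#' Two grids (or a grid and a phantom) are combinable only when shape,
#' spacing and origin match exactly.
#'
#' @param a,b `DoseGrid` or `VoxelPhantom` objects.
#' @return `TRUE` or `FALSE`.
#' @export
sameLattice <- function(a, b) {
  dimA <- if (is(a, "VoxelPhantom")) dim(a@density) else dim(a@values)
  dimB <- if (is(b, "VoxelPhantom")) dim(b@density) else dim(b@values)
  identical(dimA, dimB) &&
    isTRUE(all(a@spacing == b@spacing)) &&
    isTRUE(all(a@origin == b@origin))
}

.stopIfLatticeMismatch <- function(a, b) {
  if (!sameLattice(a, b))
    stop("grids are not on the same lattice (shape, spacing, origin must match)")
  invisible(TRUE)
}

#' Voxel-center coordinates of a lattice
#'
#' @param object a `DoseGrid` or `VoxelPhantom`.
#' @return list with numeric vectors `x`, `y`, `z` of voxel-center
#'   coordinates (cm).
#' @export
voxelCenters <- function(object) {
  d <- if (is(object, "VoxelPhantom")) dim(object@density) else dim(object@values)
  list(x = object@origin[1] + (seq_len(d[1]) - 1) * object@spacing[1],
       y = object@origin[2] + (seq_len(d[2]) - 1) * object@spacing[2],
       z = object@origin[3] + (seq_len(d[3]) - 1) * object@spacing[3])
}

#' Trilinear sampling of a grid at arbitrary points
#'
#' Values are interpolated trilinearly between voxel centers; points outside
#' the voxel-center hull are clamped to the nearest face (the phantom
#' builders keep probe points interior, so clamping only guards rounding).
#'
#' @param grid a `DoseGrid`.
#' @param points numeric matrix (n x 3) of room coordinates in cm.
#' @return numeric vector of sampled values.
#' @export
sampleGrid <- function(grid, points) {
  points <- .asPointMatrix(points)
  v <- grid@values
  d <- dim(v)
  out <- numeric(nrow(points))
  fidx <- matrix(0, nrow(points), 3)
  frac <- matrix(0, nrow(points), 3)
  for (a in 1:3) {
    t <- (points[, a] - grid@origin[a]) / grid@spacing[a]
    t <- pmin(pmax(t, 0), d[a] - 1)
    i0 <- pmin(floor(t), d[a] - 2)
    i0 <- pmax(i0, 0)
    fidx[, a] <- i0
    frac[, a] <- t - i0
  }
  acc <- numeric(nrow(points))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- ((if (cx == 1) frac[, 1] else 1 - frac[, 1]) *
          (if (cy == 1) frac[, 2] else 1 - frac[, 2]) *
          (if (cz == 1) frac[, 3] else 1 - frac[, 3]))
    idx <- cbind(fidx[, 1] + cx + 1, fidx[, 2] + cy + 1, fidx[, 3] + cz + 1)
    acc <- acc + w * v[idx]
  }
  acc
}

.asPointMatrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be n x 3 (x, y, z in cm)")
  storage.mode(points) <- "double"
  points
}

.insideGridBounds <- function(object, points) {
  d <- if (is(object, "VoxelPhantom")) dim(object@density) else dim(object@values)
  ok <- rep(TRUE, nrow(points))
  for (a in 1:3) {
    lo <- object@origin[a] - 0.5 * object@spacing[a]
    hi <- object@origin[a] + (d[a] - 0.5) * object@spacing[a]
    ok <- ok & points[, a] >= lo & points[, a] <= hi
  }
  ok
}

#' Voxelwise arithmetic on matching lattices
#'
#' Addition requires identical lattices and compatible units (Gy and Sv are
#' added as dose equivalent with a photon radiation weighting factor of 1;
#' the result is tagged Sv when units differ).
#'
#' @param e1,e2 `DoseGrid` objects, or a grid and a scalar.
#' @export
setMethod("+", signature("DoseGrid", "DoseGrid"), function(e1, e2) {
  .stopIfLatticeMismatch(e1, e2)
  if ("MeV" %in% c(e1@unit, e2@unit))
    stop("cannot add energy grids")
  unit <- if (e1@unit == e2@unit) e1@unit else "Sv"
  DoseGrid(e1@values + e2@values, e1@spacing, e1@origin, unit)
})

#' @rdname plus-DoseGrid-DoseGrid-method
#' @export
setMethod("*", signature("DoseGrid", "numeric"), function(e1, e2) {
  DoseGrid(e1@values * e2, e1@spacing, e1@origin, e1@unit)
})

#' @rdname plus-DoseGrid-DoseGrid-method
#' @export
setMethod("*", signature("numeric", "DoseGrid"), function(e1, e2) e2 * e1)

#' Write / read a grid in the package's self-describing text format
#'
#' One file per grid: a small `key: value` header (dimensions, spacing,
#' origin, unit, optional tag) followed by one value per line in C `%.17g`
#' format, x fastest.  The round trip is bit-exact for doubles.
#'
#' @param grid a `DoseGrid`.
#' @param path file path.
#' @param tag optional free-text tag (e.g. a component name).
#' @return `readDoseGrid` returns a [DoseGrid-class]; the tag, if present,
#'   is attached as attribute `"tag"`.
#' @export
writeDoseGrid <- function(grid, path, tag = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- dim(grid@values)
  writeLines(c("format: periDose-grid-1",
               sprintf("dim: %d %d %d", d[1], d[2], d[3]),
               sprintf("spacing: %s", paste(sprintf("%.17g", grid@spacing), collapse = " ")),
               sprintf("origin: %s", paste(sprintf("%.17g", grid@origin), collapse = " ")),
               sprintf("unit: %s", grid@unit),
               if (!is.null(tag)) sprintf("tag: %s", tag),
               "data:"), con)
  writeLines(sprintf("%.17g", as.vector(grid@values)), con)
  invisible(path)
}

#' @rdname writeDoseGrid
#' @export
readDoseGrid <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "format: periDose-grid-1")
    stop("not a periDose grid file")
  hEnd <- match("data:", lines)
  hdr <- lines[2:(hEnd - 1)]
  getField <- function(key) {
    hit <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^", key, ": "), "", hit[1])
  }
  d <- as.integer(strsplit(getField("dim"), " ")[[1]])
  vals <- as.numeric(lines[(hEnd + 1):(hEnd + prod(d))])
  g <- DoseGrid(array(vals, d),
                spacing = as.numeric(strsplit(getField("spacing"), " ")[[1]]),
                origin = as.numeric(strsplit(getField("origin"), " ")[[1]]),
                unit = getField("unit"))
  tag <- getField("tag")
  if (!is.null(tag)) attr(g, "tag") <- tag
  g
}
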