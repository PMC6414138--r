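#' Construct a FusionSpec
#'
#' @param targetMask logical 3D array flagging the treatment volume on the
#'   working lattice.
#' @param boundaryDistance longitudinal hand-over distance from the
#'   treatment volume in cm (default 4, roughly 3 cm from the field edge:
#'   closer in, planning-system dose is reliable; further out it degrades
#'   quickly and the stray model takes over).
#' @return a [FusionSpec-class].
#' @export
FusionSpec <- function(targetMask, boundaryDistance = 4) {
  new("FusionSpec", targetMask = targetMask,
      boundaryDistance = as.numeric(boundaryDistance))
}

# longitudinal (z) distance of every voxel from the target volume
.longitudinalTargetDistance <- function(grid, spec) {
  d <- dim(grid@values)
  if (!any(spec@targetMask)) stop("target mask is empty")
  kTarget <- range(which(apply(spec@targetMask, 3, any)))
  z <- grid@origin[3] + (seq_len(d[3]) - 1) * grid@spacing[3]
  zLo <- z[kTarget[1]]; zHi <- z[kTarget[2]]
  dz <- pmax(0, pmax(zLo - z, z - zHi))
  array(rep(dz, each = d[1] * d[2]), d)
}

#' Fuse the in-field dose grid with the stray-model grid
#'
#' Hard-switch fusion at a longitudinal plane: voxels closer than the
#' boundary distance to the treatment volume take the planning-system
#' value, all others the stray-model value.  A seam report quantifies the
#' relative step between the two calculations in the one-voxel-thick shells
#' on either side of the boundary.
#'
#' @param tpsGrid in-field [DoseGrid-class] (valid within the boundary).
#' @param strayGrid stray-model [DoseGrid-class] (valid beyond it).
#' @param spec a [FusionSpec-class].
#' @param bodyMask optional logical array restricting the seam report to
#'   body voxels.
#' @return list with `grid` (the fused [DoseGrid-class]) and `seam`
#'   (list: `meanRelStep`, `maxRelStep`, `n` seam voxels).
#' @export
fuseGrids <- function(tpsGrid, strayGrid, spec, bodyMask = NULL) {
  .stopIfLatticeMismatch(tpsGrid, strayGrid)
  dz <- .longitudinalTargetDistance(tpsGrid, spec)
  inside <- dz < spec@boundaryDistance
  fused <- strayGrid@values
  fused[inside] <- tpsGrid@values[inside]
  seamBand <- abs(dz - spec@boundaryDistance) <= tpsGrid@spacing[3]
  if (!is.null(bodyMask)) seamBand <- seamBand & bodyMask
  tv <- tpsGrid@values[seamBand]; sv <- strayGrid@values[seamBand]
  ok <- (tv + sv) > 0
  rel <- abs(tv[ok] - sv[ok]) / ((tv[ok] + sv[ok]) / 2)
  list(grid = DoseGrid(fused, tpsGrid@spacing, tpsGrid@origin, tpsGrid@unit),
       seam = list(meanRelStep = if (length(rel)) mean(rel) else NA_real_,
                   maxRelStep = if (length(rel)) max(rel) else NA_real_,
                   n = sum(seamBand)))
}

#' Per-treatment whole-body dose equivalent
#'
#' Adds the fused photon dose, the neutron dose equivalent and the daily
#' imaging dose per session, and multiplies by the number of sessions.
#' Photon Gy enters the dose equivalent with a radiation weighting factor
#' of 1; neutron grids are dose equivalent already.
#'
#' @param photonFused fused photon [DoseGrid-class] (Gy per session).
#' @param neutron neutron [DoseGrid-class] (Sv per session); optional.
#' @param cbct imaging [DoseGrid-class] (Gy per scan, one scan per
#'   session); optional.
#' @param nFractions number of sessions.
#' @return a [DoseGrid-class] with unit `"Sv"` per whole treatment.
#' @export
totalDoseEquivalent <- function(photonFused, neutron = NULL, cbct = NULL,
                                nFractions = 1L) {
  acc <- photonFused@values
  for (g in list(neutron, cbct)) {
    if (is.null(g)) next
    .stopIfLatticeMismatch(photonFused, g)
    acc <- acc + g@values
  }
  DoseGrid(acc * nFractions, photonFused@spacing, photonFused@origin, "Sv")
}

#' Cumulative dose-equivalent volume histogram
#'
#' For logarithmically spaced dose edges spanning the positive range of the
#' masked values (prepended with edge 0), the fraction of the masked volume
#' receiving at least that dose.
#'
#' @param grid a [DoseGrid-class].
#' @param mask logical array selecting the volume (e.g. the body mask, or
#'   the body mask restricted to the out-of-field region).
#' @param nBins number of logarithmic bins (default 200).
#' @param minDose lower edge of the logarithmic range (default 1e-4, in the
#'   grid's unit).
#' @return a [DEVH-class].
#' @export
devh <- function(grid, mask, nBins = 200L, minDose = 1e-4) {
  if (!any(mask)) stop("mask is empty")
  v <- grid@values[mask]
  vmax <- max(v)
  edges <- if (vmax > minDose) {
    c(0, exp(seq(log(minDose), log(vmax), length.out = nBins)))
  } else c(0, minDose)
  vs <- sort(v)
  # fraction of voxels with value >= edge
  frac <- 1 - (findInterval(edges, vs, left.open = TRUE) / length(vs))
  new("DEVH", dose = edges, fraction = frac, nVoxels = length(vs),
      unit = grid@unit)
}

setMethod("show", "DEVH", function(object) {
  cat(sprintf("DEVH [%s]: %d voxels, %d dose edges up to %.4g\n",
              object@unit, object@nVoxels, length(object@dose),
              max(object@dose)))
})

#' @describeIn devh volume fraction receiving at least `dose` (linear
#'   interpolation between edges).
#' @param x a [DEVH-class].
#' @param dose dose value(s).
#' @export
devhFractionAt <- function(x, dose) {
  f <- approx(x@dose, x@fraction, xout = dose, rule = 1)$y
  f[dose <= 0] <- 1
  f[dose > max(x@dose)] <- 0  # nothing receives more than the grid maximum
  f
}

#' @describeIn devh inverse lookup: the dose received by at least the given
#'   volume fraction.
#' @param fraction volume fraction(s) in (0, 1].
#' @export
devhQuantile <- function(x, fraction) {
  f <- x@fraction
  d <- x@dose
  vapply(fraction, function(ff) {
    i <- which(f <= ff)[1]
    if (is.na(i)) return(d[length(d)])
    if (i == 1L) return(d[1])
    # linear interpolation on the (fraction, dose) curve
    if (f[i - 1] == f[i]) return(d[i])
    d[i - 1] + (d[i] - d[i - 1]) * (f[i - 1] - ff) / (f[i - 1] - f[i])
  }, 0)
}

#' Plot a set of DEVHs
#'
#' @param x a [DEVH-class] or list of them.
#' @param y ignored.
#' @param ... further arguments passed to [graphics::matplot()].
#' @importFrom graphics matplot legend
#' @export
setMethod("plot", signature("DEVH", "missing"), function(x, y, ...) {
  matplot(x@dose, x@fraction, type = "l", log = "x",
          xlab = sprintf("dose equivalent [%s]", x@unit),
          ylab = "volume fraction receiving >= dose", ...)
})

#' Band ratio of two DEVHs
#'
#' Operationalizes "factor" comparisons between techniques: the dose band
#' (in the reference histogram `devhB`) is mapped to the volume-fraction
#' interval it occupies; the ratio of the doses received by the midpoint
#' volume fraction in the two histograms is returned.  For a grid scaled
#' uniformly by k relative to the reference this yields exactly k.
#'
#' @param devhA,devhB [DEVH-class] objects on one body mask (`devhB` is
#'   the reference/denominator).
#' @param band numeric length-2 `(lo, hi)` dose band in the histogram unit.
#' @return dimensionless ratio.
#' @export
bandRatio <- function(devhA, devhB, band) {
  if (band[1] >= band[2]) stop("band must satisfy lo < hi")
  fHi <- devhFractionAt(devhB, band[2])
  fLo <- devhFractionAt(devhB, band[1])
  if (fLo <= fHi) stop("no volume falls inside the dose band")
  fMid <- (fLo + fHi) / 2
  devhQuantile(devhA, fMid) / devhQuantile(devhB, fMid)
}

#' Calculated-vs-measured deviation statistics
#'
#' Per-location percent deviation `100 * (calculated - measured) /
#' measured`, summarized as mean and sample standard deviation.
#'
#' @param calculated,measured numeric vectors of equal length (measured
#'   values must be > 0).
#' @return list with `meanPct`, `sdPct`, `n`, and the per-location
#'   deviations `pct`.
#' @export
deviationStats <- function(calculated, measured) {
  if (length(calculated) != length(measured) || length(calculated) < 1L)
    stop("calculated and measured must have equal length >= 1")
  if (any(measured <= 0)) stop("measured values must be > 0")
  pct <- 100 * (calculated - measured) / measured
  list(meanPct = mean(pct), sdPct = if (length(pct) > 1) sd(pct) else 0,
       n = length(pct), pct = pct)
}

#' Export a DEVH as CSV
#'
#' @param x a [DEVH-class].
#' @param path file path.
#' @export
writeDevh <- function(x, path) {
  write.csv(data.frame(dose = x@dose, volume_fraction = x@fraction),
            path, row.names = FALSE)
  invisible(path)
}
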