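#' Default synthetic study specification
#'
#' An Alderson-like body built from stacked elliptical sections (pelvis,
#' abdomen/thorax with two low-density lungs, neck, head), about 102 cm
#' from the inferior pelvis to the top of the head, with a pelvic target
#' ellipsoid (a prostate rhabdomyosarcoma surrogate) centered on the
#' isocenter.  Probe counts and the 10% multiplicative measurement noise
#' mirror the whole-body TLD study the package emulates: 189 locations, of
#' which 151 are out-of-field.
#'
#' @param spacing voxel spacing in cm (default 0.8 x 0.8 x 1.0; the
#'   clinical grid of 0.2 x 0.2 x 0.5 is configurable but slow for
#'   simulation studies).
#' @param nProbes,nProbesOutOfField probe counts.
#' @param noiseSD multiplicative lognormal noise SD.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(spacing = c(0.8, 0.8, 1.0), nProbes = 189L,
                          nProbesOutOfField = 151L, noiseSD = 0.10) {
  sections <- data.frame(
    name = c("pelvis", "trunk", "neck", "head"),
    zMin = c(-18, 8, 52, 61),
    zMax = c(8, 52, 61, 84),
    halfX = c(17, 16, 5.5, 8),
    halfY = c(11, 10.5, 5.5, 10),
    stringsAsFactors = FALSE)
  new("SyntheticSpec", sections = sections,
      lungCenters = rbind(c(-5.5, 0, 39), c(5.5, 0, 39)),
      lungHalfAxes = c(4.5, 6.5, 11),
      targetCenter = c(0, 0, 0), targetHalfAxes = c(3.5, 3, 4),
      nProbes = as.integer(nProbes),
      nProbesOutOfField = as.integer(nProbesOutOfField),
      noiseSD = noiseSD, spacing = as.numeric(spacing))
}

#' Build the synthetic voxel phantom
#'
#' Soft tissue (relative density 1.0) inside the stacked elliptical body
#' sections, 0.25 inside the lung ellipsoids, 0 outside the body.  The
#' medial patient axis is a straight longitudinal line through the
#' isocenter's transverse position.  Deterministic: no random numbers.
#'
#' @param spec a [SyntheticSpec-class].
#' @return a [VoxelPhantom-class].
#' @export
buildPhantom <- function(spec = syntheticSpec()) {
  s <- spec@sections
  sp <- spec@spacing
  xmax <- max(s$halfX) + sp[1]
  ymax <- max(s$halfY) + sp[2]
  zlo <- min(s$zMin) - sp[3]; zhi <- max(s$zMax) + sp[3]
  nx <- as.integer(ceiling(2 * xmax / sp[1])) + 1L
  ny <- as.integer(ceiling(2 * ymax / sp[2])) + 1L
  nz <- as.integer(ceiling((zhi - zlo) / sp[3])) + 1L
  origin <- c(-(nx - 1) / 2 * sp[1], -(ny - 1) / 2 * sp[2], zlo)
  x <- origin[1] + (seq_len(nx) - 1) * sp[1]
  y <- origin[2] + (seq_len(ny) - 1) * sp[2]
  z <- origin[3] + (seq_len(nz) - 1) * sp[3]
  mask <- array(FALSE, c(nx, ny, nz))
  xy2 <- function(hx, hy) outer((x / hx)^2, (y / hy)^2, "+") <= 1
  for (r in seq_len(nrow(s))) {
    kSel <- which(z >= s$zMin[r] & z < s$zMax[r])
    if (!length(kSel)) next
    slice <- xy2(s$halfX[r], s$halfY[r])
    mask[, , kSel] <- mask[, , kSel] | array(slice, c(nx, ny, length(kSel)))
  }
  dens <- array(0, c(nx, ny, nz))
  dens[mask] <- 1.0
  material <- array(0L, c(nx, ny, nz))
  material[mask] <- 1L
  ha <- spec@lungHalfAxes
  for (l in seq_len(nrow(spec@lungCenters))) {
    cen <- spec@lungCenters[l, ]
    kSel <- which(abs(z - cen[3]) <= ha[3])
    for (k in kSel) {
      rz2 <- ((z[k] - cen[3]) / ha[3])^2
      inl <- outer(((x - cen[1]) / ha[1])^2, ((y - cen[2]) / ha[2])^2, "+") +
        rz2 <= 1
      inl <- inl & mask[, , k]
      dk <- dens[, , k]; mk <- material[, , k]
      dk[inl] <- 0.25; mk[inl] <- 2L
      dens[, , k] <- dk; material[, , k] <- mk
    }
  }
  zBody <- z[z >= min(s$zMin) + sp[3] / 2 & z <= max(s$zMax) - sp[3] / 2]
  mpax <- cbind(spec@targetCenter[1], spec@targetCenter[2], zBody)
  VoxelPhantom(dens, mask, material, mpax, sp, origin)
}

#' Target-volume mask on the phantom lattice
#'
#' @param phantom a [VoxelPhantom-class].
#' @param spec a [SyntheticSpec-class].
#' @return logical 3D array.
#' @export
targetMask <- function(phantom, spec = syntheticSpec()) {
  cc <- voxelCenters(phantom)
  d <- dim(phantom@density)
  cen <- spec@targetCenter; ha <- spec@targetHalfAxes
  m2 <- array(0, d)
  gx <- ((cc$x - cen[1]) / ha[1])^2
  gy <- ((cc$y - cen[2]) / ha[2])^2
  gz <- ((cc$z - cen[3]) / ha[3])^2
  m2 <- outer(outer(gx, gy, "+"), gz, "+")
  m2 <= 1 & phantom@bodyMask
}

#' Synthetic in-field dose grid (per session)
#'
#' A stand-in for a treatment-planning-system calculation: the fraction
#' dose uniformly inside the target ellipsoid, a smooth exponential
#' penumbra (default decay length 1.2 cm) outside it, floored at
#' `tpsStrayFactor` times the stray-model dose so that the in-field grid
#' decays to the stray level near the fusion boundary (the slight deficit
#' emulates the mild out-of-field underestimation typical of planning
#' systems).  Deterministic.
#'
#' @param plan a [TreatmentPlan-class].
#' @param phantom a [VoxelPhantom-class].
#' @param spec a [SyntheticSpec-class].
#' @param strayGrid optional precomputed per-session stray
#'   [DoseGrid-class] for the same plan (computed if missing).
#' @param config a [StrayModelConfig-class].
#' @param penumbra penumbra decay length in cm.
#' @param tpsStrayFactor multiplier on the stray-model floor.
#' @return a [DoseGrid-class] (Gy per session).
#' @export
syntheticTpsGrid <- function(plan, phantom, spec = syntheticSpec(),
                             strayGrid = NULL,
                             config = defaultStrayConfig(),
                             penumbra = 1.2, tpsStrayFactor = 0.9) {
  if (is.null(strayGrid))
    strayGrid <- strayDoseGrid(plan, phantom, config,
                               isocenter = spec@targetCenter)
  cc <- voxelCenters(phantom)
  d <- dim(phantom@density)
  cen <- spec@targetCenter; ha <- spec@targetHalfAxes
  gx <- ((cc$x - cen[1]) / ha[1])^2
  gy <- ((cc$y - cen[2]) / ha[2])^2
  gz <- ((cc$z - cen[3]) / ha[3])^2
  m <- sqrt(outer(outer(gx, gy, "+"), gz, "+"))
  rx <- outer(outer((cc$x - cen[1])^2, (cc$y - cen[2])^2, "+"),
              (cc$z - cen[3])^2, "+")
  dist <- sqrt(rx) * pmax(m - 1, 0) / pmax(m, 1e-9)  # distance to surface
  v <- plan@fractionDose * exp(-dist / penumbra)
  v[m <= 1] <- plan@fractionDose
  v <- pmax(v, tpsStrayFactor * strayGrid@values)
  v[!phantom@bodyMask] <- 0
  DoseGrid(v, phantom@spacing, phantom@origin, "Gy")
}

#' TLD-like probe locations
#'
#' Samples interior probe sites at least about 1 cm deep (all six 1 cm
#' axis-offset neighbours must stay inside the body), spread over the
#' whole body: `nProbesOutOfField` sites beyond the fusion boundary and
#' the remainder within it.  Reproducible for a fixed seed.
#'
#' @param phantom a [VoxelPhantom-class].
#' @param spec a [SyntheticSpec-class].
#' @param seed RNG seed.
#' @param boundaryDistance the fusion boundary (cm) separating in-field
#'   from out-of-field sites.
#' @return data.frame with columns `id`, `x`, `y`, `z`, `outOfField`.
#' @export
probeLocations <- function(phantom, spec = syntheticSpec(), seed = 1L,
                           boundaryDistance = 4) {
  s <- spec@sections
  insideBody <- function(pts) {
    ok <- .insideGridBounds(phantom, pts)
    idx <- matrix(1L, nrow(pts), 3)
    for (a in 1:3) {
      i <- as.integer(round((pts[, a] - phantom@origin[a]) /
                              phantom@spacing[a])) + 1L
      idx[, a] <- pmin(pmax(i, 1L), dim(phantom@density)[a])
    }
    ok & phantom@bodyMask[idx]
  }
  deepEnough <- function(pts) {
    ok <- insideBody(pts)
    for (a in 1:3) for (sgn in c(-1, 1)) {
      off <- pts
      off[, a] <- off[, a] + sgn * 1.0
      ok <- ok & insideBody(off)
    }
    ok
  }
  zTgt <- spec@targetCenter[3]
  azT <- spec@targetHalfAxes[3]
  drawSites <- function(n, outOf) {
    pts <- matrix(0, 0, 3)
    while (nrow(pts) < n) {
      m <- 4L * (n - nrow(pts)) + 20L
      z <- runif(m, min(s$zMin) + 1, max(s$zMax) - 1)
      row <- findInterval(z, c(s$zMin, max(s$zMax)))
      x <- runif(m, -1, 1) * s$halfX[row] * 0.9
      y <- runif(m, -1, 1) * s$halfY[row] * 0.9
      cand <- cbind(x, y, z)
      dz <- pmax(0, pmax((zTgt - azT) - z, z - (zTgt + azT)))
      okSide <- if (outOf) dz >= boundaryDistance else dz < boundaryDistance
      cand <- cand[okSide & deepEnough(cand), , drop = FALSE]
      pts <- rbind(pts, cand)
    }
    pts[seq_len(n), , drop = FALSE]
  }
  set.seed(seed)
  nOut <- spec@nProbesOutOfField
  nIn <- spec@nProbes - nOut
  out <- drawSites(nOut, TRUE)
  inn <- if (nIn > 0) drawSites(nIn, FALSE) else matrix(0, 0, 3)
  pts <- rbind(out, inn)
  data.frame(id = seq_len(nrow(pts)), x = pts[, 1], y = pts[, 2],
             z = pts[, 3],
             outOfField = rep(c(TRUE, FALSE), c(nOut, nIn)))
}

#' Pseudo-measurements from model truth
#'
#' Multiplies the model-predicted truth at each probe by independent
#' lognormal noise (meanlog 0, sdlog `noiseSD`), emulating the roughly 10%
#' calculated-vs-measured agreement of whole-body TLD dosimetry.
#'
#' @param truth numeric vector of model predictions at the probes.
#' @param probes data.frame from [probeLocations()] (optional; positions
#'   are copied into the table when given).
#' @param noiseSD multiplicative noise SD (0 reproduces the truth).
#' @param seed RNG seed.
#' @param detector detector label for the table.
#' @return data.frame with columns `id`, `x`, `y`, `z`, `dose`, `detector`.
#' @export
pseudoMeasurements <- function(truth, probes = NULL, noiseSD = 0.10,
                               seed = 1L, detector = "TLD700H") {
  set.seed(seed)
  n <- length(truth)
  dose <- truth * rlnorm(n, meanlog = 0, sdlog = noiseSD)
  data.frame(id = seq_len(n),
             x = if (is.null(probes)) NA_real_ else probes$x,
             y = if (is.null(probes)) NA_real_ else probes$y,
             z = if (is.null(probes)) NA_real_ else probes$z,
             dose = dose, detector = detector)
}

#' Refit stray-model amplitudes from measurements
#'
#' The stray model is linear in its three amplitudes, so given measured
#' total doses at probe sites the amplitudes are recovered by least
#' squares on the per-component shape factors (the component doses
#' evaluated with unit amplitudes).
#'
#' @param plan a [TreatmentPlan-class] (or list of plans sharing one
#'   nominal energy, measurements stacked in the same order).
#' @param phantom a [VoxelPhantom-class].
#' @param probes n x 3 matrix or `probeLocations()` data.frame.
#' @param measured measured total stray dose per session at each probe
#'   (stacked over plans if several).
#' @param config a [StrayModelConfig-class] supplying the shape constants.
#' @return named numeric vector `c(ps, cs, hl)` of fitted amplitudes.
#' @export
refitStrayAmplitudes <- function(plan, phantom, probes, measured,
                                 config = defaultStrayConfig()) {
  plans <- if (is(plan, "TreatmentPlan")) list(plan) else plan
  en <- plans[[1]]@nominalEnergy
  if (is.data.frame(probes)) probes <- as.matrix(probes[, c("x", "y", "z")])
  unitCfg <- config
  for (comp in c("ps", "cs", "hl"))
    unitCfg@params[[en]][[comp]]$amp <- 1
  shapes <- do.call(rbind, lapply(plans, function(pl)
    componentDoses(pl, phantom, probes, unitCfg)[, c("ps", "cs", "hl")]))
  fit <- lm(measured ~ 0 + ps + cs + hl, data = cbind(shapes, measured = measured))
  setNames(coef(fit), c("ps", "cs", "hl"))
}
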