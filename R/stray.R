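#' Default out-of-field stray model configuration
#'
#' Parameters of the three-component stray model for 6 and 15 MV.  Each
#' component dose at a point is
#' `amplitude * lateral(dEdge) * exp(-depth / lambda)`, with
#' `lateral(x) = exp(-x / latExp) + latInvFrac * (latInvX0 / (x + latInvX0))^2`
#' in the distance `x` (cm) from the field edge, and `depth` the
#' radiological depth from the X-ray target to the point.  Patient scatter
#' additionally scales with the target dose per session and with the field
#' area through `(A / 100 cm^2)^areaExp`; collimator scatter and head
#' leakage scale with monitor units, head leakage varying only slowly in
#' space (`exp(-distance to isocenter / spatialLength)`).
#'
#' The shipped amplitudes are the output of [calibrateStrayModel()] run on
#' the default synthetic phantom and benchmark plans with the documented
#' cross-energy and population mean-energy constraints (6 MV patient scatter
#' twice the 15 MV value per Gy, 15 MV collimator scatter 1.5 times the 6 MV
#' value per MU, population mean photon energies 0.40 / 0.47 MeV); the
#' falloff constants are fixed shape choices on the scale of published
#' peripheral-dose measurements.
#'
#' @return a [StrayModelConfig-class].
#' @export
defaultStrayConfig <- function() {
  shapePs <- list(latExp = 7, latInvFrac = 0.03, latInvX0 = 10,
                  lambda = 20, areaExp = 0.7)
  shapeCs <- list(latExp = 11, latInvFrac = 0.07, latInvX0 = 25, lambda = 16)
  shapeHl <- list(spatialLength = 150, lambda = 32)
  amp <- .DEFAULT_STRAY_AMPLITUDES
  params <- list(
    "6MV" = list(ps = c(list(amp = amp[["ps6"]]), shapePs),
                 cs = c(list(amp = amp[["cs6"]]), shapeCs),
                 hl = c(list(amp = amp[["hl6"]]), shapeHl)),
    "15MV" = list(ps = c(list(amp = amp[["ps15"]]), shapePs),
                  cs = c(list(amp = amp[["cs15"]]), shapeCs),
                  hl = c(list(amp = amp[["hl15"]]), shapeHl)))
  new("StrayModelConfig", params = params, sad = 100)
}

# Amplitudes frozen from the shipped calibration run (see the methods
# vignette); ps in Gy per target Gy, cs/hl in Gy per MU.
.DEFAULT_STRAY_AMPLITUDES <- c(
  ps6 = 0.030, ps15 = 0.015,
  cs6 = 1.1750397405e-04, cs15 = 1.7625596107e-04,
  hl6 = 3.8129642417e-05, hl15 = 2.3301448144e-05)

.lateral <- function(x, p) {
  exp(-x / p$latExp) + p$latInvFrac * (p$latInvX0 / (x + p$latInvX0))^2
}

# Per-field beam-frame geometry at a set of points: distance from the field
# edge (cm), in-field flag, distances to source and isocenter.
.fieldGeometry <- function(field, points, sad = 100, isocenter = c(0, 0, 0)) {
  src <- sourcePosition(field@gantryAngle, sad, isocenter)
  u <- sweep(points, 2, src)
  axis <- (isocenter - src) / sad
  l <- u %*% axis
  w <- u - outer(as.vector(l), axis)
  # transverse in-plane unit vectors: x-jaw horizontal, y-jaw longitudinal
  tx <- c(axis[2], -axis[1], 0)
  tx <- tx / sqrt(sum(tx^2))
  px <- abs(w %*% tx)
  py <- abs(w[, 3])
  lEff <- pmax(as.vector(l), 1e-6)
  hx <- 0.5 * field@aperture[1] * lEff / sad
  hy <- 0.5 * field@aperture[2] * lEff / sad
  dEdge <- sqrt(pmax(px - hx, 0)^2 + pmax(py - hy, 0)^2)
  inField <- as.vector(px <= hx & py <= hy & l > 0)
  rSource <- sqrt(rowSums(u^2))
  rIso <- sqrt(rowSums(sweep(points, 2, isocenter)^2))
  list(source = src, dEdge = as.vector(dEdge), inField = inField,
       rSource = rSource, rIso = rIso)
}

#' Stray-component doses at points (per session)
#'
#' Patient scatter (`ps`), collimator scatter (`cs`) and head leakage
#' (`hl`), summed over the plan's fields, in Gy per treatment session.
#' `ps` is proportional to the fraction dose, `cs` and `hl` to the monitor
#' units delivered per session; all components attenuate exponentially with
#' the radiological depth along the source-to-point line and fall off with
#' the distance from the field edge.
#'
#' @param plan a [TreatmentPlan-class].
#' @param phantom a [VoxelPhantom-class].
#' @param points n x 3 matrix of room coordinates (cm) outside the region
#'   covered by the in-field grid.
#' @param config a [StrayModelConfig-class].
#' @param isocenter room coordinates of the isocenter (cm).
#' @return data.frame with columns `ps`, `cs`, `hl`, `total` (Gy per
#'   session) and `inField` (logical: inside any field aperture).
#' @export
componentDoses <- function(plan, phantom, points, config = defaultStrayConfig(),
                           isocenter = c(0, 0, 0)) {
  points <- .asPointMatrix(points)
  pars <- config@params[[plan@nominalEnergy]]
  if (is.null(pars))
    stop(sprintf("no stray parameters for energy %s", plan@nominalEnergy))
  n <- nrow(points)
  ps <- cs <- hl <- numeric(n)
  anyIn <- logical(n)
  tm <- totalMu(plan)
  for (f in plan@fields) {
    geo <- .fieldGeometry(f, points, config@sad, isocenter)
    depth <- radiologicalDepth(phantom, geo$source, points)
    muW <- if (tm > 0) f@mu / tm else 1 / length(plan@fields)
    muSession <- f@mu / plan@nFractions
    area <- prod(f@aperture)
    ps <- ps + plan@fractionDose * muW * pars$ps$amp *
      (area / 100)^pars$ps$areaExp * .lateral(geo$dEdge, pars$ps) *
      exp(-depth / pars$ps$lambda)
    cs <- cs + muSession * pars$cs$amp * .lateral(geo$dEdge, pars$cs) *
      exp(-depth / pars$cs$lambda)
    hl <- hl + muSession * pars$hl$amp *
      exp(-geo$rIso / pars$hl$spatialLength) * exp(-depth / pars$hl$lambda)
    anyIn <- anyIn | geo$inField
  }
  data.frame(ps = ps, cs = cs, hl = hl, total = ps + cs + hl,
             inField = anyIn)
}

#' Whole-body stray dose grid (per session)
#'
#' Evaluates [componentDoses()] at every body voxel center.  Values inside
#' the in-field region are replaced by the in-field grid at fusion time and
#' carry no meaning on their own.
#'
#' @inheritParams componentDoses
#' @param components if `TRUE`, return the three component grids alongside
#'   the total.
#' @return a [DoseGrid-class] (Gy per session), or, with
#'   `components = TRUE`, a list with elements `ps`, `cs`, `hl`, `total`.
#' @export
strayDoseGrid <- function(plan, phantom, config = defaultStrayConfig(),
                          components = FALSE, isocenter = c(0, 0, 0)) {
  d <- dim(phantom@density)
  idx <- which(phantom@bodyMask)
  cc <- voxelCenters(phantom)
  ai <- arrayInd(idx, d)
  pts <- cbind(cc$x[ai[, 1]], cc$y[ai[, 2]], cc$z[ai[, 3]])
  comp <- if (length(idx)) {
    componentDoses(plan, phantom, pts, config, isocenter)
  } else {
    data.frame(ps = numeric(0), cs = numeric(0), hl = numeric(0),
               total = numeric(0))
  }
  mk <- function(col) {
    a <- array(0, d)
    a[idx] <- comp[[col]]
    DoseGrid(a, phantom@spacing, phantom@origin, "Gy")
  }
  if (!components) return(mk("total"))
  list(ps = mk("ps"), cs = mk("cs"), hl = mk("hl"), total = mk("total"))
}

#' Stray components at the reference condition
#'
#' The calibration reference: a single 10 x 10 cm2 field at gantry 0 on a
#' 30 x 30 x 80 cm soft-tissue slab centered at the isocenter, evaluated on
#' the slab midline 15 cm beyond the field edge.  Delivered with 1 MU and a
#' fraction dose of 1 Gy, so `ps` is per target Gy and `cs`/`hl` are per
#' MU.
#'
#' @param config a [StrayModelConfig-class].
#' @param energy `"6MV"` or `"15MV"`.
#' @return named numeric vector `c(ps, cs, hl)`.
#' @export
referenceComponents <- function(config = defaultStrayConfig(),
                                energy = "6MV") {
  ph <- .referencePhantom()
  plan <- TreatmentPlan(energy, "3DCRT",
                        list(BeamField(0, c(10, 10), mu = 1)),
                        fractionDose = 1, nFractions = 1L)
  pt <- matrix(c(0, 0, 20), 1)  # 15 cm beyond the 5 cm field edge
  cd <- componentDoses(plan, ph, pt, config)
  c(ps = cd$ps, cs = cd$cs, hl = cd$hl)
}

.referencePhantom <- function() {
  n <- c(15L, 15L, 40L)
  spacing <- c(2, 2, 2)
  origin <- -(n - 1) / 2 * spacing
  dens <- array(1.0, n)
  z <- origin[3] + (seq_len(n[3]) - 1) * spacing[3]
  VoxelPhantom(dens, array(TRUE, n), mpax = cbind(0, 0, z),
               spacing = spacing, origin = origin)
}

#' Calibrate the stray model to its cross-energy and energy constraints
#'
#' Enforces the cross-energy amplitude ratios exactly (patient scatter per
#' Gy at 6 MV = `psRatio` times the 15 MV value; collimator scatter per MU
#' at 15 MV = `csRatio` times the 6 MV value), keeping the 15 MV amplitudes
#' as anchors.  If population mean-energy targets and a phantom/plan/probe
#' context are supplied, the collimator-scatter and head-leakage amplitudes
#' of both energies are additionally rescaled jointly (preserving the
#' ratios) so that the dose-weighted mean photon energy averaged over the
#' out-of-field probe sites matches the targets.  Deterministic; no random
#' numbers are used.
#'
#' @param config starting [StrayModelConfig-class].
#' @param psRatio,csRatio cross-energy amplitude ratios (defaults 2.0 and
#'   1.5).
#' @param meanEnergyTargets optional named vector, e.g.
#'   `c("6MV" = 0.40, "15MV" = 0.47)` (MeV).
#' @param phantom,plans,probes context for the mean-energy constraint: a
#'   phantom, a named list of plans covering both energies, and an n x 3
#'   matrix of out-of-field probe points.
#' @param energies a [componentEnergies()] table.
#' @param tol maximum acceptable residual (MeV) on each mean-energy target.
#' @return a calibrated [StrayModelConfig-class].
#' @export
calibrateStrayModel <- function(config = defaultStrayConfig(),
                                psRatio = 2.0, csRatio = 1.5,
                                meanEnergyTargets = NULL,
                                phantom = NULL, plans = NULL, probes = NULL,
                                energies = componentEnergies(),
                                tol = 0.01) {
  p <- config@params
  p[["6MV"]]$ps$amp <- psRatio * p[["15MV"]]$ps$amp
  p[["6MV"]]$cs$amp <- p[["15MV"]]$cs$amp / csRatio
  config@params <- p

  if (is.null(meanEnergyTargets)) {
    validObject(config)
    return(config)
  }
  if (is.null(phantom) || is.null(plans) || is.null(probes))
    stop("mean-energy calibration needs phantom, plans and probes")

  applyScale <- function(cfg, s) {
    q <- cfg@params
    for (en in c("6MV", "15MV")) {
      q[[en]]$cs$amp <- q[[en]]$cs$amp * exp(s[1])
      q[[en]]$hl$amp <- q[[en]]$hl$amp * exp(s[2])
    }
    cfg@params <- q
    cfg
  }
  residuals <- function(cfg) {
    vapply(names(meanEnergyTargets), function(en) {
      sel <- vapply(plans, function(pl) pl@nominalEnergy == en, TRUE)
      es <- unlist(lapply(plans[sel], function(pl) {
        cd <- componentDoses(pl, phantom, probes, cfg)
        meanEnergy(cd, energies, energy = en)
      }))
      mean(es) - meanEnergyTargets[[en]]
    }, 0)
  }
  obj <- function(s) sum(residuals(applyScale(config, s))^2)
  fit <- optim(c(0, 0), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-10, maxit = 400))
  out <- applyScale(config, fit$par)
  res <- residuals(out)
  if (any(abs(res) > tol))
    stop(sprintf(
      "stray calibration infeasible: mean-energy residuals %s MeV exceed tol %.3g",
      paste(sprintf("%s=%+.3f", names(res), res), collapse = ", "), tol))
  validObject(out)
  out
}
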