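#' Construct a BeamField
#'
#' @param gantryAngle gantry angle in degrees, [0, 360).
#' @param aperture equivalent rectangular field (x width, y width) in cm at
#'   the isocenter plane.
#' @param mu monitor units (>= 0).
#' @param collimatorAngle collimator rotation in degrees.
#' @return a [BeamField-class].
#' @export
BeamField <- function(gantryAngle, aperture, mu, collimatorAngle = 0) {
  new("BeamField", gantryAngle = as.numeric(gantryAngle),
      aperture = as.numeric(aperture), mu = as.numeric(mu),
      collimatorAngle = as.numeric(collimatorAngle))
}

#' Construct a TreatmentPlan
#'
#' @param nominalEnergy `"6MV"` or `"15MV"`.
#' @param technique `"3DCRT"`, `"IMRT"` or `"VMAT"`.
#' @param fields list of [BeamField-class] objects.
#' @param fractionDose dose per fraction in Gy.
#' @param nFractions number of sessions.
#' @return a [TreatmentPlan-class].
#' @export
TreatmentPlan <- function(nominalEnergy, technique, fields, fractionDose,
                          nFractions) {
  new("TreatmentPlan", nominalEnergy = nominalEnergy, technique = technique,
      fields = fields, fractionDose = as.numeric(fractionDose),
      nFractions = as.integer(nFractions))
}

#' @rdname TreatmentPlan-class
#' @export
setMethod("totalMu", "TreatmentPlan", function(object)
  sum(vapply(object@fields, function(f) f@mu, 0)))

#' @rdname TreatmentPlan-class
#' @export
setMethod("prescribedDose", "TreatmentPlan", function(object)
  object@fractionDose * object@nFractions)

setMethod("show", "TreatmentPlan", function(object) {
  cat(sprintf("TreatmentPlan: %s %s, %g Gy x %d = %g Gy, %d fields, %.0f MU total\n",
              object@technique, object@nominalEnergy, object@fractionDose,
              object@nFractions, prescribedDose(object),
              length(object@fields), totalMu(object)))
})

#' Monitor units per treatment Gy
#'
#' Total monitor units divided by the prescribed dose, rounded half-up to an
#' integer (the convention of published plan summaries).
#'
#' @param plan a [TreatmentPlan-class].
#' @return integer MU/Gy.
#' @examples
#' plans <- planFixtures()
#' muPerGy(plans[["3DCRT_6MV"]])  # 141
#' @export
muPerGy <- function(plan) {
  pd <- prescribedDose(plan)
  if (pd <= 0) stop("prescribed dose must be > 0")
  as.integer(floor(totalMu(plan) / pd + 0.5))
}

#' Group arc control points into discrete fields
#'
#' Approximates a VMAT arc by a small number of static fields: the delivered
#' gantry range is partitioned into `nGroups` equal angular bins (closed on
#' the left, anchored at the arc start angle); each bin becomes one field
#' carrying the MU sum of its control points, the MU-weighted mean gantry
#' angle and the MU-weighted mean aperture.  Total MU is conserved exactly.
#'
#' @param controlPoints data.frame with columns `gantryAngle` (deg), `mu`,
#'   `apertureX`, `apertureY` (cm).
#' @param nGroups number of output fields (default 6).
#' @return list of [BeamField-class] objects.
#' @export
discretizeArc <- function(controlPoints, nGroups = 6L) {
  if (nrow(controlPoints) == 0L) stop("at least one control point is required")
  if (nGroups < 1L) stop("nGroups must be >= 1")
  ang <- controlPoints$gantryAngle
  lo <- min(ang); hi <- max(ang)
  width <- if (hi > lo) (hi - lo) / nGroups else 1
  bin <- pmin(floor((ang - lo) / width), nGroups - 1) + 1L
  fields <- vector("list", nGroups)
  keep <- logical(nGroups)
  for (b in seq_len(nGroups)) {
    sel <- bin == b
    if (!any(sel)) next
    mu <- controlPoints$mu[sel]
    w <- if (sum(mu) > 0) mu / sum(mu) else rep(1 / sum(sel), sum(sel))
    fields[[b]] <- BeamField(
      gantryAngle = sum(w * ang[sel]) %% 360,
      aperture = c(sum(w * controlPoints$apertureX[sel]),
                   sum(w * controlPoints$apertureY[sel])),
      mu = sum(mu))
    keep[b] <- TRUE
  }
  fields[keep]
}

# MU totals, fractionation and default geometry of the six benchmark plans
# (pelvic target).  Gantry angles for the four-field box and the
# intensity-modulated techniques are clinical defaults: 0/90/180/270 for
# 3DCRT, five equally spaced fields for IMRT, one full arc for VMAT.
.PLAN_TABLE <- data.frame(
  technique = rep(c("3DCRT", "IMRT", "VMAT"), each = 2),
  energy = rep(c("6MV", "15MV"), 3),
  fractionDose = c(2.0, 2.0, 2.2, 2.2, 2.2, 2.2),
  nFractions = c(26L, 26L, 23L, 23L, 23L, 23L),
  totalMu = c(7326, 5846, 22989, 21661, 13409, 11847),
  stringsAsFactors = FALSE)

#' The six benchmark treatment plans
#'
#' Six pelvic plans (3DCRT, IMRT, VMAT at 6 and 15 MV) with the published
#' fractionation and total monitor units: 3DCRT 2.0 Gy x 26 with a
#' four-field box (average opening about 9 x 10 cm2), IMRT 2.2 Gy x 23 with
#' five dynamic fields (about 3 x 10 cm2), VMAT 2.2 Gy x 23 with one full
#' arc grouped into six fields.  Per-field MU are split equally (only MU
#' totals drive the MU-scaling dose components).
#'
#' @param arcControlPoints number of control points used to represent the
#'   VMAT arc before grouping (default 72).
#' @return named list of six [TreatmentPlan-class] objects, names like
#'   `"IMRT_15MV"`.
#' @examples
#' muPerGy(planFixtures()[["VMAT_6MV"]])  # 265
#' @export
planFixtures <- function(arcControlPoints = 72L) {
  out <- list()
  for (r in seq_len(nrow(.PLAN_TABLE))) {
    row <- .PLAN_TABLE[r, ]
    fields <- switch(row$technique,
      "3DCRT" = {
        angles <- c(0, 90, 180, 270)
        lapply(angles, function(g)
          BeamField(g, aperture = c(9, 10), mu = row$totalMu / 4))
      },
      "IMRT" = {
        angles <- seq(0, 288, by = 72)
        lapply(angles, function(g)
          BeamField(g, aperture = c(3, 10), mu = row$totalMu / 5))
      },
      "VMAT" = {
        n <- arcControlPoints
        cp <- data.frame(
          gantryAngle = seq(0, 360 - 360 / n, length.out = n),
          mu = rep(row$totalMu / n, n),
          apertureX = 3, apertureY = 10)
        discretizeArc(cp, nGroups = 6L)
      })
    plan <- TreatmentPlan(row$energy, row$technique, fields,
                          row$fractionDose, row$nFractions)
    out[[paste(row$technique, row$energy, sep = "_")]] <- plan
  }
  out
}

#' Write / read a treatment plan as structured text (YAML)
#'
#' @param plan a [TreatmentPlan-class].
#' @param path file path.
#' @return `readPlan` returns a [TreatmentPlan-class].
#' @export
writePlan <- function(plan, path) {
  yaml::write_yaml(list(
    nominalEnergy = plan@nominalEnergy,
    technique = plan@technique,
    fractionDose = plan@fractionDose,
    nFractions = plan@nFractions,
    fields = lapply(plan@fields, function(f) list(
      gantryAngle = f@gantryAngle, mu = f@mu,
      apertureX = f@aperture[1], apertureY = f@aperture[2],
      collimatorAngle = f@collimatorAngle))), path)
  invisible(path)
}

#' @rdname writePlan
#' @export
readPlan <- function(path) {
  x <- yaml::read_yaml(path)
  fields <- lapply(x$fields, function(f)
    BeamField(f$gantryAngle, c(f$apertureX, f$apertureY), f$mu,
              if (is.null(f$collimatorAngle)) 0 else f$collimatorAngle))
  TreatmentPlan(x$nominalEnergy, x$technique, fields, x$fractionDose,
                x$nFractions)
}
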