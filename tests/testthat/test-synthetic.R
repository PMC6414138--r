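test_that("the synthetic phantom obeys its material rules and is deterministic", {
  spec <- testSpec()
  ph <- testPhantom()
  dens <- phantomDensity(ph)
  expect_true(all(dens[ph@material == 2L] == 0.25))
  expect_true(all(dens[ph@material == 1L] == 1.0))
  expect_true(all(dens[!bodyMask(ph)] == 0))
  expect_gt(sum(ph@material == 2L), 0)
  # MPAX points lie inside the body
  mp <- mpaxPoints(ph)
  expect_true(all(periDose:::.insideGridBounds(ph, mp)))
  # rebuilding gives a byte-identical phantom (no hidden randomness)
  ph2 <- buildPhantom(spec)
  expect_identical(phantomDensity(ph2), dens)
  # zero lung extent -> uniform soft-tissue body
  spec0 <- spec
  spec0@lungHalfAxes <- c(1e-9, 1e-9, 1e-9)
  ph0 <- buildPhantom(spec0)
  expect_equal(sum(ph0@material == 2L), 0)
  expect_true(all(phantomDensity(ph0)[bodyMask(ph0)] == 1.0))
})

test_that("probe locations are interior, reproducible and correctly split", {
  spec <- testSpec()
  ph <- testPhantom()
  pr <- probeLocations(ph, spec, seed = 4L)
  expect_equal(nrow(pr), spec@nProbes)
  expect_equal(sum(pr$outOfField), spec@nProbesOutOfField)
  pr2 <- probeLocations(ph, spec, seed = 4L)
  expect_identical(pr, pr2)
  pr3 <- probeLocations(ph, spec, seed = 5L)
  expect_false(identical(pr$x, pr3$x))
  # all sites are at least ~1 cm inside the body
  pts <- as.matrix(pr[, c("x", "y", "z")])
  for (a in 1:3) for (sgn in c(-1, 1)) {
    off <- pts; off[, a] <- off[, a] + sgn
    idx <- matrix(1L, nrow(off), 3)
    for (b in 1:3) {
      i <- as.integer(round((off[, b] - gridOrigin(ph)[b]) /
                              gridSpacing(ph)[b])) + 1L
      idx[, b] <- pmin(pmax(i, 1L), dim(phantomDensity(ph))[b])
    }
    expect_true(all(bodyMask(ph)[idx]))
  }
})

test_that("pseudo-measurements apply seeded multiplicative noise", {
  truth <- rep(2, 50)
  m0 <- pseudoMeasurements(truth, noiseSD = 0, seed = 8L)
  expect_equal(m0$dose, truth)
  m1 <- pseudoMeasurements(truth, noiseSD = 0.1, seed = 8L)
  m2 <- pseudoMeasurements(truth, noiseSD = 0.1, seed = 8L)
  expect_identical(m1$dose, m2$dose)
  expect_false(identical(m1$dose, truth))
  # at large n the percent-deviation SD approaches the injected 10%
  big <- pseudoMeasurements(rep(1, 1e4), noiseSD = 0.10, seed = 9L)
  stats <- deviationStats(big$dose, rep(1, 1e4))
  expect_equal(stats$sdPct, 10, tolerance = 0.05)
})

test_that("the synthetic in-field grid matches the prescription and the seam", {
  spec <- testSpec()
  ph <- testPhantom()
  plan <- testPlans()[["IMRT_15MV"]]
  sg <- strayDoseGrid(plan, ph)
  tps <- syntheticTpsGrid(plan, ph, spec, strayGrid = sg)
  tm <- targetMask(ph, spec)
  # target voxels carry the fraction dose per session
  expect_equal(unique(doseValues(tps)[tm]), plan@fractionDose)
  # at the boundary plane the in-field grid sits within 20% of the stray model
  fu <- fuseGrids(tps, sg, FusionSpec(tm, 4), bodyMask(ph))
  expect_lt(fu$seam$meanRelStep, 0.20)
  # a zero-dose plan produces a zero grid
  p0 <- TreatmentPlan("15MV", "IMRT", list(BeamField(0, c(3, 10), 0)),
                      fractionDose = 0, nFractions = 1L)
  g0 <- syntheticTpsGrid(p0, ph, spec)
  expect_equal(max(doseValues(g0)), 0)
})

test_that("stray amplitudes are recovered from noisy pseudo-measurements", {
  spec <- testSpec()
  ph <- testPhantom()
  plans <- testPlans()[c("3DCRT_15MV", "IMRT_15MV")]
  probes <- testProbes()
  cfg <- defaultStrayConfig()
  truth <- unlist(lapply(plans, function(pl)
    componentDoses(pl, ph, probes, cfg)$total))
  meas <- pseudoMeasurements(truth, noiseSD = 0.10, seed = 12L)$dose
  fit <- refitStrayAmplitudes(plans, ph, probes, meas, cfg)
  want <- c(ps = cfg@params[["15MV"]]$ps$amp,
            cs = cfg@params[["15MV"]]$cs$amp,
            hl = cfg@params[["15MV"]]$hl$amp)
  expect_true(all(abs(fit / want - 1) < 0.20))
})

test_that("calculated-vs-pseudo-measured agreement mirrors the injected noise", {
  ph <- testPhantom()
  plan <- testPlans()[["VMAT_15MV"]]
  probes <- testProbes()
  truth <- componentDoses(plan, ph, probes)$total
  meas <- pseudoMeasurements(truth, noiseSD = 0.10, seed = 13L)$dose
  stats <- deviationStats(truth, meas)
  expect_lt(abs(stats$meanPct), 5)
  expect_gt(stats$sdPct, 5)
  expect_lt(stats$sdPct, 15)
})
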