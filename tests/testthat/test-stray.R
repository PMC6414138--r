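test_that("a zero plan deposits no stray dose", {
  ph <- testPhantom()
  p0 <- TreatmentPlan("6MV", "3DCRT", list(BeamField(0, c(10, 10), 0)),
                      fractionDose = 0, nFractions = 1L)
  cd <- componentDoses(p0, ph, testProbes()[1:5, ])
  expect_equal(cd$ps, rep(0, 5))
  expect_equal(cd$cs, rep(0, 5))
  expect_equal(cd$hl, rep(0, 5))
})

test_that("collimator scatter and head leakage are exactly linear in MU, patient scatter in fraction dose", {
  ph <- testPhantom()
  pts <- testProbes()[1:25, ]
  set.seed(21)
  for (en in c("6MV", "15MV")) {
    mus <- runif(3, 50, 400)
    p1 <- TreatmentPlan(en, "3DCRT",
                        list(BeamField(20, c(8, 10), mus[1]),
                             BeamField(140, c(6, 9), mus[2]),
                             BeamField(260, c(9, 11), mus[3])),
                        fractionDose = 2, nFractions = 5L)
    p2 <- p1
    p2@fields <- lapply(p1@fields, function(f) { f@mu <- 2 * f@mu; f })
    cd1 <- componentDoses(p1, ph, pts)
    cd2 <- componentDoses(p2, ph, pts)
    expect_equal(cd2$cs, 2 * cd1$cs, tolerance = 1e-12)
    expect_equal(cd2$hl, 2 * cd1$hl, tolerance = 1e-12)
    expect_equal(cd2$ps, cd1$ps, tolerance = 1e-12)  # same geometry and Gy
    p3 <- p1
    p3@fractionDose <- 2 * p1@fractionDose
    cd3 <- componentDoses(p3, ph, pts)
    expect_equal(cd3$ps, 2 * cd1$ps, tolerance = 1e-12)
    expect_equal(cd3$cs, cd1$cs, tolerance = 1e-12)
  }
})

test_that("cross-energy amplitude ratios hold at the reference condition", {
  r6 <- referenceComponents(defaultStrayConfig(), "6MV")
  r15 <- referenceComponents(defaultStrayConfig(), "15MV")
  # 6 MV patient scatter per Gy is twice the 15 MV value
  expect_equal(unname(r6["ps"] / r15["ps"]), 2.0, tolerance = 1e-9)
  # 15 MV collimator scatter per MU is 1.5 times the 6 MV value
  expect_equal(unname(r15["cs"] / r6["cs"]), 1.5, tolerance = 1e-9)
})

test_that("component dominance matches the expected spatial pattern", {
  ph <- testPhantom()
  plans <- testPlans()
  # near the field edge, patient scatter dominates the 6 MV stray dose
  near <- matrix(c(0, 0, 9), 1)
  cdNear <- componentDoses(plans[["3DCRT_6MV"]], ph, near)
  expect_gt(cdNear$ps, cdNear$cs)
  expect_gt(cdNear$ps, cdNear$hl)
  # far from the field and deep in the body, head leakage dominates
  far <- matrix(c(0, 0, 58), 1)  # > 50 cm from the isocenter, on the MPAX
  for (nm in c("3DCRT_6MV", "IMRT_15MV")) {
    cdFar <- componentDoses(plans[[nm]], ph, far)
    expect_gt(cdFar$hl, cdFar$ps)
    expect_gt(cdFar$hl, cdFar$cs)
  }
})

test_that("components decrease monotonically along the body axis on a uniform phantom", {
  # constant-cross-section soft-tissue column: no anatomy-driven depth dips
  ph <- slabPhantom(side = c(30, 30, 120), spacing = c(2, 2, 2))
  plan <- TreatmentPlan("6MV", "3DCRT", list(BeamField(0, c(10, 10), 200)),
                        fractionDose = 2, nFractions = 1L)
  z <- seq(10, 56, by = 2)
  pts <- cbind(0, 0, z)
  cd <- componentDoses(plan, ph, pts)
  for (comp in c("ps", "cs", "hl"))
    expect_true(all(diff(cd[[comp]]) <= 1e-12), info = comp)
  expect_true(all(cd$total >= 0))
})

test_that("the stray grid agrees with point evaluation at voxel centers", {
  ph <- testPhantom()
  plan <- testPlans()[["VMAT_6MV"]]
  grids <- strayDoseGrid(plan, ph, components = TRUE)
  d <- dim(phantomDensity(ph))
  idx <- which(bodyMask(ph))[c(10, 500, 2000)]
  ai <- arrayInd(idx, d)
  cc <- voxelCenters(ph)
  pts <- cbind(cc$x[ai[, 1]], cc$y[ai[, 2]], cc$z[ai[, 3]])
  cd <- componentDoses(plan, ph, pts)
  expect_equal(doseValues(grids$total)[idx], cd$total, tolerance = 1e-12)
  expect_equal(doseValues(grids$ps)[idx], cd$ps, tolerance = 1e-12)
  # an all-zero plan yields a zero grid
  p0 <- TreatmentPlan("6MV", "3DCRT", list(BeamField(0, c(10, 10), 0)),
                      fractionDose = 0, nFractions = 1L)
  g0 <- strayDoseGrid(p0, ph)
  expect_equal(max(doseValues(g0)), 0)
})

test_that("recalibration restores the cross-energy constraints after a perturbation", {
  cfg <- defaultStrayConfig()
  cfg@params[["6MV"]]$cs$amp <- cfg@params[["6MV"]]$cs$amp * 1.1
  cfg@params[["6MV"]]$ps$amp <- cfg@params[["6MV"]]$ps$amp * 0.9
  cfg2 <- calibrateStrayModel(cfg)
  r6 <- referenceComponents(cfg2, "6MV")
  r15 <- referenceComponents(cfg2, "15MV")
  expect_equal(unname(r6["ps"] / r15["ps"]), 2.0, tolerance = 1e-9)
  expect_equal(unname(r15["cs"] / r6["cs"]), 1.5, tolerance = 1e-9)
})

test_that("unknown beam energies are a configuration error", {
  ph <- testPhantom()
  plan <- testPlans()[["3DCRT_6MV"]]
  cfg <- defaultStrayConfig()
  cfg@params[["6MV"]] <- NULL
  expect_error(componentDoses(plan, ph, testProbes()[1, , drop = FALSE], cfg),
               "no stray parameters")
})
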