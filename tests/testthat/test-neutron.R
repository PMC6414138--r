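test_that("6 MV plans produce no photoneutrons", {
  ph <- testPhantom()
  cd <- neutronDoseEquivalent(testPlans()[["IMRT_6MV"]], ph,
                              testProbes()[1:10, ])
  expect_equal(cd$H, rep(0, 10))
})

test_that("neutron dose equivalent is exactly linear in MU", {
  ph <- testPhantom()
  pts <- testProbes()[1:20, ]
  set.seed(31)
  p1 <- TreatmentPlan("15MV", "IMRT",
                      lapply(runif(4, 0, 359), function(g)
                        BeamField(g, c(4, 10), runif(1, 100, 800))),
                      fractionDose = 2.2, nFractions = 23L)
  p2 <- p1
  p2@fields <- lapply(p1@fields, function(f) { f@mu <- 2 * f@mu; f })
  expect_equal(neutronDoseEquivalent(p2, ph, pts)$H,
               2 * neutronDoseEquivalent(p1, ph, pts)$H, tolerance = 1e-12)
})

test_that("depth dependence follows the closed-form attenuation within 1% of brute force", {
  # uniform column, beam along -z: points on the central ray have known
  # depth; correcting for inverse square isolates exp(-depth / lambda)
  ph <- slabPhantom(side = c(30, 30, 60), spacing = c(1, 1, 1))
  cfg <- defaultNeutronConfig()
  plan <- TreatmentPlan("15MV", "3DCRT", list(BeamField(90, c(5, 5), 100)),
                        fractionDose = 2, nFractions = 1L)
  src <- sourcePosition(90)
  # three points on one off-axis ray (outside the aperture), at increasing
  # depth behind the +x entry face
  xs <- c(10, 0, -8)
  pts <- cbind(xs, (100 - xs) * 0.1, 0)
  H <- neutronDoseEquivalent(plan, ph, pts, cfg)$H
  r <- sqrt(rowSums(sweep(pts, 2, src)^2))
  dBrute <- vapply(1:3, function(i)
    periDose:::.radiologicalDepthNumeric(ph, src, pts[i, ], step = 0.005), 0)
  for (i in 2:3) {
    ratio <- (H[1] * r[1]^2) / (H[i] * r[i]^2)
    expect_equal(ratio, exp((dBrute[i] - dBrute[1]) / cfg@lambda),
                 tolerance = 0.01)
  }
  # H decreases strictly with depth at comparable source distance
  expect_true(all(diff(H) < 0))
})

test_that("the MPAX maximum of H sits at the minimum radiological depth", {
  ph <- testPhantom()
  cfg <- defaultNeutronConfig()
  plan <- TreatmentPlan("15MV", "3DCRT", list(BeamField(0, c(9, 10), 100)),
                        fractionDose = 2, nFractions = 1L)
  mp <- mpaxPoints(ph)
  oof <- mp[, 3] >= 8  # beyond the target region
  H <- neutronDoseEquivalent(plan, ph, mp, cfg)$H
  dep <- radiologicalDepth(ph, sourcePosition(0), mp)
  zMax <- mp[oof, 3][which.max(H[oof])]
  zMin <- mp[oof, 3][which.min(dep[oof])]
  expect_lte(abs(zMax - zMin), 2 * gridSpacing(ph)[3])
})

test_that("H per MU along the MPAX is close to technique-independent", {
  ph <- testPhantom()
  plans <- testPlans()
  cfg <- defaultNeutronConfig()
  mp <- mpaxPoints(ph)
  oof <- mp[, 3] >= 8
  perMu <- sapply(c("3DCRT_15MV", "IMRT_15MV", "VMAT_15MV"), function(nm) {
    pl <- plans[[nm]]
    neutronDoseEquivalent(pl, ph, mp, cfg)$H / (totalMu(pl) / pl@nFractions)
  })
  spread <- apply(perMu[oof, ], 1, function(r) (max(r) - min(r)) / mean(r))
  expect_lt(mean(spread), 0.15)
})

test_that("in-field voxels are masked to zero", {
  ph <- testPhantom()
  plan <- testPlans()[["IMRT_15MV"]]
  inside <- matrix(c(0, 0, 0), 1)  # isocenter, inside every aperture
  cd <- neutronDoseEquivalent(plan, ph, inside)
  expect_true(cd$inField)
  expect_equal(cd$H, 0)
  g <- neutronDoseGrid(testPlans()[["3DCRT_6MV"]], ph)
  expect_equal(max(doseValues(g)), 0)  # 6 MV grid is identically zero
})

test_that("paired-TLD conversion subtracts photon contamination and applies the depth factor", {
  cfg <- defaultNeutronConfig()
  curve <- syntheticResponseCurve(a = -0.2)  # under-responding chip
  resp <- approx(curve@energyMeV, curve@response, xout = 0.4)$y
  # raw signal equal to the photon-equivalent signal -> 0 Sv
  r0 <- tld600ToDoseEquiv(0.05 * resp, 0.05, 0.4, depth = 10, cfg, curve)
  expect_equal(r0$H, 0)
  # unit residual at a depth with factor f -> f Sv; linear in the residual
  f10 <- approx(cfg@depthConversion$depth_cm, cfg@depthConversion$factor,
                xout = 10)$y
  r1 <- tld600ToDoseEquiv(1, 0, 0.4, 10, cfg, curve)
  expect_equal(r1$H, f10, tolerance = 1e-12)
  r2 <- tld600ToDoseEquiv(2, 0, 0.4, 10, cfg, curve)
  expect_equal(r2$H, 2 * r1$H, tolerance = 1e-12)
  # negative residuals clamp to zero with a warning flag
  expect_warning(rc <- tld600ToDoseEquiv(0.01, 1, 0.4, 10, cfg, curve),
                 "clamped")
  expect_equal(rc$H, 0)
  expect_true(rc$clamped)
  expect_error(tld600ToDoseEquiv(1, 0, 0.4, 99, cfg, curve), "depth")
})
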