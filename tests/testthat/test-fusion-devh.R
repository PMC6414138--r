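.mkGrid <- function(ph, v) {
  DoseGrid(array(v, dim(phantomDensity(ph))), gridSpacing(ph), gridOrigin(ph))
}

test_that("fusion switches at the longitudinal boundary plane", {
  ph <- testPhantom()
  tm <- targetMask(ph, testSpec())
  spec <- FusionSpec(tm, 4)
  tps <- .mkGrid(ph, 2)
  stray <- .mkGrid(ph, 1)
  fu <- fuseGrids(tps, stray, spec)
  cc <- voxelCenters(ph)
  d <- dim(phantomDensity(ph))
  # target spans z in [-4, 4]; boundary at longitudinal distance 4
  kIn <- which.min(abs(cc$z - 7))   # 3 cm from the target volume -> TPS
  kOut <- which.min(abs(cc$z - 9))  # 5 cm -> stray model
  expect_equal(unique(as.vector(doseValues(fu$grid)[, , kIn])), 2)
  expect_equal(unique(as.vector(doseValues(fu$grid)[, , kOut])), 1)
  # identical grids fuse to themselves with zero seam step
  fu2 <- fuseGrids(tps, tps, spec)
  expect_equal(doseValues(fu2$grid), doseValues(tps))
  expect_equal(fu2$seam$meanRelStep, 0)
  # zero stray grid -> zero beyond the boundary
  fu3 <- fuseGrids(tps, .mkGrid(ph, 0), spec)
  expect_equal(max(doseValues(fu3$grid)[, , kOut]), 0)
  expect_error(fuseGrids(tps, DoseGrid(array(1, d), gridSpacing(ph),
                                       gridOrigin(ph) + 1), spec), "lattice")
})

test_that("the per-treatment total stacks components and multiplies by sessions", {
  ph <- testPhantom()
  photon <- .mkGrid(ph, 1)
  tot <- totalDoseEquivalent(photon, nFractions = 23L)
  expect_equal(unique(as.vector(doseValues(tot))), 23)
  expect_identical(doseUnit(tot), "Sv")
  z <- totalDoseEquivalent(.mkGrid(ph, 0), .mkGrid(ph, 0), .mkGrid(ph, 0), 5L)
  expect_equal(max(doseValues(z)), 0)
  # the DEVH of a sum dominates the DEVH of each addend at every dose
  n <- .mkGrid(ph, 0.5)
  tot2 <- totalDoseEquivalent(photon, n, nFractions = 1L)
  mask <- bodyMask(ph)
  dTot <- devh(tot2, mask)
  dPhoton <- devh(photon, mask)
  expect_true(all(devhFractionAt(dTot, dPhoton@dose) >= dPhoton@fraction - 1e-12))
})

test_that("DEVHs are correct cumulative histograms", {
  ph <- testPhantom()
  mask <- bodyMask(ph)
  u <- devh(.mkGrid(ph, 1), mask)
  expect_equal(devhFractionAt(u, c(0, 0.5, 1)), c(1, 1, 1))
  expect_lt(devhFractionAt(u, 1.01), 1e-9)
  # half the voxels at 2, half at 0 -> fraction 0.5 at dose 1
  v <- array(0, dim(mask))
  idx <- which(mask)
  v[idx[seq_len(floor(length(idx) / 2))]] <- 2
  h <- devh(DoseGrid(v, gridSpacing(ph), gridOrigin(ph)), mask)
  expect_equal(devhFractionAt(h, 1), floor(length(idx) / 2) / length(idx),
               tolerance = 1e-9)
  # non-increasing everywhere
  expect_true(all(diff(h@fraction) <= 1e-12))
  expect_error(devh(.mkGrid(ph, 1), array(FALSE, dim(mask))), "empty")
})

test_that("scaling a grid shifts its DEVH by exactly that factor", {
  ph <- testPhantom()
  set.seed(41)
  v <- array(0, dim(phantomDensity(ph)))
  v[bodyMask(ph)] <- rexp(sum(bodyMask(ph)))
  g <- DoseGrid(v, gridSpacing(ph), gridOrigin(ph))
  h1 <- devh(g, bodyMask(ph))
  h3 <- devh(g * 3, bodyMask(ph))
  f <- c(0.9, 0.5, 0.1, 0.01)
  expect_equal(devhQuantile(h3, f), 3 * devhQuantile(h1, f), tolerance = 0.02)
})

test_that("band ratios recover uniform scale factors", {
  ph <- testPhantom()
  set.seed(43)
  v <- array(0, dim(phantomDensity(ph)))
  v[bodyMask(ph)] <- rlnorm(sum(bodyMask(ph)), -3, 1.2)
  a <- DoseGrid(2 * v, gridSpacing(ph), gridOrigin(ph))
  b <- DoseGrid(v, gridSpacing(ph), gridOrigin(ph))
  ha <- devh(a, bodyMask(ph)); hb <- devh(b, bodyMask(ph))
  expect_equal(bandRatio(hb, hb, c(0.01, 0.5)), 1.0, tolerance = 1e-9)
  expect_equal(bandRatio(ha, hb, c(0.01, 0.5)), 2.0, tolerance = 0.02)
  expect_error(bandRatio(ha, hb, c(0.5, 0.1)), "lo < hi")
  expect_error(bandRatio(ha, hb, c(1e6, 2e6)), "band")
})

test_that("deviation statistics report mean and sample SD in percent", {
  m <- c(1, 2, 3, 4)
  s0 <- deviationStats(m, m)
  expect_equal(s0$meanPct, 0); expect_equal(s0$sdPct, 0)
  s10 <- deviationStats(1.1 * m, m)
  expect_equal(s10$meanPct, 10, tolerance = 1e-9)
  expect_equal(s10$sdPct, 0, tolerance = 1e-9)
  s2 <- deviationStats(c(1.1, 0.9), c(1, 1))
  expect_equal(s2$meanPct, 0, tolerance = 1e-12)
  expect_equal(s2$sdPct, sd(c(10, -10)), tolerance = 1e-9)  # 14.142...
  expect_error(deviationStats(1, 0), "> 0")
  expect_error(deviationStats(c(1, 2), 1), "equal length")
})
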