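test_that("radiological depth through uniform soft tissue equals the geometric path", {
  ph <- waterPhantom(30, spacing = c(1, 1, 1))
  # beam from +y; 10 cm beyond the entry surface at y = 15
  expect_equal(radiologicalDepth(ph, c(0, 100, 0), c(0, 5, 0)), 10,
               tolerance = 1e-9)
  # point on the entry surface: zero-length in-body path
  expect_equal(radiologicalDepth(ph, c(0, 100, 0), c(0, 15, 0)), 0,
               tolerance = 1e-9)
})

test_that("lung tissue contributes 0.25 of its geometric length", {
  # 20 cm box, lung layer z in [0, 4), soft tissue elsewhere; beam along -z
  ph <- slabPhantom(side = c(20, 20, 20), lungZ = c(0, 4))
  # from z = +10 surface to z = -6: 6 cm soft + 4 cm lung + 6 cm soft
  d <- radiologicalDepth(ph, c(0, 0, 100), c(0, 0, -6))
  expect_equal(d, 6 + 0.25 * 4 + 6, tolerance = 1e-9)
  # stopping inside the lung: 6 soft + 2 lung
  d2 <- radiologicalDepth(ph, c(0, 0, 100), c(0, 0, 2))
  expect_equal(d2, 6 + 0.25 * 2, tolerance = 1e-9)
})

test_that("depth is monotone along a ray and linear in density", {
  ph <- testPhantom()
  src <- sourcePosition(63)
  tgt <- c(1.2, -0.8, 30.5)
  t <- seq(0.55, 1, length.out = 40)
  pts <- outer(t, tgt - src) + matrix(src, 40, 3, byrow = TRUE)
  pts <- pts[periDose:::.insideGridBounds(ph, pts), , drop = FALSE]
  d <- radiologicalDepth(ph, src, pts)
  expect_true(all(diff(d) >= -1e-9))
  # scaling the density array by k scales the line integral by exactly k
  d2 <- periDose:::.siddonDepth(as.vector(phantomDensity(ph)) * 1.7,
                                dim(phantomDensity(ph)), gridSpacing(ph),
                                gridOrigin(ph), src, pts)
  expect_equal(d2, 1.7 * d, tolerance = 1e-12)
})

test_that("Siddon traversal agrees with a fine-step numerical integral", {
  ph <- testPhantom()
  set.seed(5)
  pr <- testProbes()
  idx <- sample(nrow(pr), 12)
  for (g in c(0, 110, 245)) {
    src <- sourcePosition(g)
    d <- radiologicalDepth(ph, src, pr[idx, ])
    dNum <- vapply(idx, function(i)
      periDose:::.radiologicalDepthNumeric(ph, src, pr[i, ], step = 0.005), 0)
    expect_equal(d, dNum, tolerance = 0.01)
  }
})

test_that("points outside the grid bounds are a domain error", {
  ph <- waterPhantom(20, spacing = c(2, 2, 2))
  expect_error(radiologicalDepth(ph, c(0, 100, 0), c(0, 0, 300)), "bounds")
})

test_that("MPAX profiles sample the grid along the medial axis", {
  ph <- testPhantom()
  ones <- DoseGrid(array(1, dim(phantomDensity(ph))), gridSpacing(ph),
                   gridOrigin(ph))
  pr <- mpaxProfile(ones, ph)
  expect_equal(pr$value, rep(1, nrow(mpaxPoints(ph))))
  expect_true(all(diff(pr$z) > 0))
  # a field linear in z is reproduced at the sample points
  d <- dim(phantomDensity(ph))
  z <- gridOrigin(ph)[3] + (seq_len(d[3]) - 1) * gridSpacing(ph)[3]
  lin <- DoseGrid(array(rep(pmax(z, 0), each = d[1] * d[2]), d),
                  gridSpacing(ph), gridOrigin(ph))
  pr2 <- mpaxProfile(lin, ph)
  expect_equal(pr2$value, pmax(pr2$z, 0), tolerance = 1e-9)
  # empty MPAX -> empty profile
  ph2 <- ph
  ph2@mpax <- matrix(numeric(0), 0, 3)
  expect_equal(nrow(mpaxProfile(ones, ph2)), 0)
  # lattice mismatch is an incompatibility error
  shifted <- DoseGrid(array(1, d), gridSpacing(ph), gridOrigin(ph) + 0.1)
  expect_error(mpaxProfile(shifted, ph), "lattice")
})
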