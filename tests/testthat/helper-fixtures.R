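# Shared fixtures, built once per test run.  The coarse spacing keeps the
# unit-test phantoms small; the acceptance tests build their own phantom at
# the documented simulation resolution.

.fixtures <- new.env(parent = emptyenv())

testSpec <- function() {
  if (is.null(.fixtures$spec))
    .fixtures$spec <- syntheticSpec(spacing = c(1.6, 1.6, 2))
  .fixtures$spec
}

testPhantom <- function() {
  if (is.null(.fixtures$phantom))
    .fixtures$phantom <- buildPhantom(testSpec())
  .fixtures$phantom
}

testPlans <- function() {
  if (is.null(.fixtures$plans))
    .fixtures$plans <- planFixtures()
  .fixtures$plans
}

testProbes <- function(outOfFieldOnly = TRUE) {
  if (is.null(.fixtures$probes))
    .fixtures$probes <- probeLocations(testPhantom(), testSpec(), seed = 11L)
  pr <- .fixtures$probes
  if (outOfFieldOnly) pr <- pr[pr$outOfField, ]
  as.matrix(pr[, c("x", "y", "z")])
}

# layered slab phantom: a box of soft tissue with an optional lung layer
# spanning [lungZMin, lungZMax) in z, used for closed-form depth checks
slabPhantom <- function(side = c(20, 20, 20), spacing = c(1, 1, 1),
                        lungZ = NULL) {
  n <- as.integer(round(side / spacing))
  origin <- -(n - 1) / 2 * spacing
  dens <- array(1.0, n)
  z <- origin[3] + (seq_len(n[3]) - 1) * spacing[3]
  if (!is.null(lungZ)) {
    sel <- which(z >= lungZ[1] & z < lungZ[2])
    dens[, , sel] <- 0.25
  }
  VoxelPhantom(dens, array(TRUE, n), mpax = cbind(0, 0, z),
               spacing = spacing, origin = origin)
}
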