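#' @rdname DoseGrid-class
#' @param object a `DoseGrid` or `VoxelPhantom`.
#' @export
setGeneric("doseValues", function(object) standardGeneric("doseValues"))

#' @rdname DoseGrid-class
#' @export
setGeneric("gridSpacing", function(object) standardGeneric("gridSpacing"))

#' @rdname DoseGrid-class
#' @export
setGeneric("gridOrigin", function(object) standardGeneric("gridOrigin"))

#' @rdname DoseGrid-class
#' @export
setGeneric("doseUnit", function(object) standardGeneric("doseUnit"))

#' @rdname VoxelPhantom-class
#' @param object a `VoxelPhantom`.
#' @export
setGeneric("bodyMask", function(object) standardGeneric("bodyMask"))

#' @rdname VoxelPhantom-class
#' @export
setGeneric("phantomDensity", function(object) standardGeneric("phantomDensity"))

#' @rdname VoxelPhantom-class
#' @export
setGeneric("mpaxPoints", function(object) standardGeneric("mpaxPoints"))

#' @rdname TreatmentPlan-class
#' @param object a `TreatmentPlan`.
#' @export
setGeneric("totalMu", function(object) standardGeneric("totalMu"))

#' @rdname TreatmentPlan-class
#' @export
setGeneric("prescribedDose", function(object) standardGeneric("prescribedDose"))
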