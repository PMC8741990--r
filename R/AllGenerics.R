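#' @rdname TumorMask-class
#' @param object,x a package object.
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname TumorMask-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname TumorMask-class
#' @export
setGeneric("maskOrigin", function(x) standardGeneric("maskOrigin"))

#' @rdname TumorMask-class
#' @export
setGeneric("nOccupied", function(x) standardGeneric("nOccupied"))

#' Tumor volume of a mask in cm^3
#'
#' The volume is exactly the occupied voxel count times the physical
#' voxel volume; 1 cm^3 is identically 1 ml.
#'
#' @param x a [TumorMask-class] (or an object carrying one).
#' @return volume in cm^3.
#' @examples
#' maskVolume(makeSphereMask(4))
#' @export
setGeneric("maskVolume", function(x) standardGeneric("maskVolume"))

#' @rdname ConcentrationField-class
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' @rdname ConcentrationField-class
#' @export
setGeneric("fieldMask", function(x) standardGeneric("fieldMask"))

#' @rdname InjectionPlan-class
#' @param x an [InjectionPlan-class].
#' @export
setGeneric("planSites", function(x) standardGeneric("planSites"))

#' @rdname InjectionPlan-class
#' @export
setGeneric("planDoses", function(x) standardGeneric("planDoses"))

#' @rdname InjectionPlan-class
#' @export
setGeneric("totalDose", function(x) standardGeneric("totalDose"))
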