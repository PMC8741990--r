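# small masks and plans built in code for the unit tests

# straight line of n voxels along x, useful for controlled distances
lineMask <- function(n, spacing_mm = 1) {
  tumorMask(array(TRUE, c(n, 1, 1)), spacing_mm = spacing_mm)
}

# single-voxel tumor
pointMask <- function(spacing_mm = 1) {
  tumorMask(array(TRUE, c(1, 1, 1)), spacing_mm = spacing_mm)
}

# plan at given occupied-voxel row indices of voxelCenters(mask)
planAt <- function(mask, rows, doses) {
  new("InjectionPlan", sites = voxelCenters(mask)[rows, , drop = FALSE],
      doses = doses)
}

# wrap explicit values as a field on a mask
fieldOn <- function(mask, values) {
  new("ConcentrationField", values = values, mask = mask)
}

defaultParams <- modelParams()
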