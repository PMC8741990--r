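#' Construct a TumorMask
#'
#' Low-level constructor; most users will call [makeSphereMask()] or
#' [readMaskNifti()] instead.
#'
#' @param occupancy 3-D logical array.
#' @param spacing_mm voxel edge lengths in mm (scalar or length 3).
#' @param origin_mm physical offset of the grid corner in mm (length 3).
#' @return a [TumorMask-class].
#' @export
tumorMask <- function(occupancy, spacing_mm = 1, origin_mm = c(0, 0, 0)) {
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  new("TumorMask", occupancy = occupancy, spacing = as.numeric(spacing_mm),
      origin = as.numeric(origin_mm))
}

#' Synthetic sphere mask of a prescribed volume
#'
#' Generates a centered digital sphere whose continuous radius is
#' `(3 V / 4 pi)^(1/3)`. A voxel is occupied when its center lies inside
#' the continuous sphere (no partial-volume weighting), which keeps the
#' discretized volume within 2% of the request for volumes
#' representable at the given spacing. Sphere surrogates stand in for
#' tumors known only by their volume.
#'
#' @param volume_cm3 target volume in cm^3 (> 0).
#' @param spacing_mm isotropic voxel edge in mm (default 1, CT-typical).
#' @return a [TumorMask-class] centered at the physical origin.
#' @examples
#' m <- makeSphereMask(1)         # ~1000 voxels at 1 mm spacing
#' maskVolume(m)
#' @export
makeSphereMask <- function(volume_cm3, spacing_mm = 1) {
  stopifnot(is.numeric(volume_cm3), length(volume_cm3) == 1L,
            is.finite(volume_cm3), volume_cm3 > 0,
            is.numeric(spacing_mm), length(spacing_mm) == 1L,
            spacing_mm > 0)
  r_mm <- (3 * volume_cm3 * 1000 / (4 * pi))^(1 / 3)  # continuous radius, mm
  if (2 * r_mm / spacing_mm < 3) {
    v_min <- 4 / 3 * pi * (1.5 * spacing_mm)^3 / 1000
    stop(sprintf(paste0("volume %.4g cm^3 is too small for %.3g mm voxels: ",
                        "the sphere diameter must span at least 3 voxels ",
                        "(minimum representable volume %.4g cm^3)"),
                 volume_cm3, spacing_mm, v_min))
  }
  # Candidate grid alignments: per axis the sphere center sits either on a
  # voxel center or on a voxel corner. The voxel-center-inside rule leaves a
  # surface-term discretization error whose sign depends on this sub-voxel
  # alignment; the combination whose count best matches the target volume is
  # chosen (deterministic preference order on ties).
  K <- as.integer(ceiling(r_mm / spacing_mm) + 1L)
  coords <- list(center = (-K:K) * spacing_mm,
                 corner = (seq(-K, K - 1L) + 0.5) * spacing_mm)
  combos <- expand.grid(x = c("center", "corner"), y = c("center", "corner"),
                        z = c("center", "corner"), stringsAsFactors = FALSE)
  target <- volume_cm3 * 1000 / spacing_mm^3          # target voxel count
  counts <- vapply(seq_len(nrow(combos)), function(i) {
    sum(outer(outer(coords[[combos$x[i]]]^2, coords[[combos$y[i]]]^2, `+`),
              coords[[combos$z[i]]]^2, `+`) <= r_mm^2)
  }, numeric(1))
  best <- which.min(abs(counts - target))             # first index on ties
  cx <- coords[[combos$x[best]]]
  cy <- coords[[combos$y[best]]]
  cz <- coords[[combos$z[best]]]
  occ <- array(outer(outer(cx^2, cy^2, `+`), cz^2, `+`) <= r_mm^2,
               c(length(cx), length(cy), length(cz)))
  tumorMask(occ, spacing_mm,
            origin_mm = c(cx[1], cy[1], cz[1]) - spacing_mm / 2)
}

#' @rdname TumorMask-class
#' @export
setMethod("occupancy", "TumorMask", function(x) x@occupancy)

#' @rdname TumorMask-class
#' @export
setMethod("voxelSpacing", "TumorMask", function(x) x@spacing)

#' @rdname TumorMask-class
#' @export
setMethod("maskOrigin", "TumorMask", function(x) x@origin)

#' @rdname TumorMask-class
#' @export
setMethod("nOccupied", "TumorMask", function(x) sum(x@occupancy))

#' @rdname maskVolume
#' @export
setMethod("maskVolume", "TumorMask", function(x)
  sum(x@occupancy) * prod(x@spacing) / 1000)

setMethod("show", "TumorMask", function(object) {
  d <- dim(object@occupancy)
  cat(sprintf("TumorMask: %d x %d x %d grid, %d occupied voxels\n",
              d[1], d[2], d[3], sum(object@occupancy)))
  cat(sprintf("  spacing  %s mm\n  volume   %.4g cm^3\n",
              paste(signif(object@spacing, 4), collapse = " x "),
              maskVolume(object)))
})

#' Physical centers of the occupied voxels
#'
#' @param mask a [TumorMask-class].
#' @return numeric matrix, one row per occupied voxel (column-major
#'   order), positions in cm.
#' @export
voxelCenters <- function(mask) {
  d <- dim(mask@occupancy)
  idx <- which(mask@occupancy)
  ijk <- arrayInd(idx, d)
  # mm -> cm at the boundary; voxel-center convention
  sweep(sweep(ijk - 0.5, 2L, mask@spacing, `*`), 2L, mask@origin, `+`) / 10
}

#' Extend the bounding box of a mask by a margin
#'
#' Crops the grid to the tight bounding box of the occupied voxels and
#' extends it by `pad_mm` on every face, preserving occupancy and the
#' physical positions of all voxels. The transient solver requires a
#' padded domain so its zero-concentration boundary approximates free
#' space.
#'
#' @param mask a [TumorMask-class].
#' @param pad_mm margin in mm (>= 0).
#' @return a [TumorMask-class] on the padded grid.
#' @export
padDomain <- function(mask, pad_mm) {
  stopifnot(is.numeric(pad_mm), length(pad_mm) == 1L, pad_mm >= 0)
  occ <- mask@occupancy
  d <- dim(occ)
  ijk <- arrayInd(which(occ), d)
  lo <- apply(ijk, 2L, min)
  hi <- apply(ijk, 2L, max)
  pad_vox <- as.integer(ceiling(pad_mm / mask@spacing))
  nd <- hi - lo + 1L + 2L * pad_vox
  out <- array(FALSE, nd)
  shift <- pad_vox - lo + 1L
  out[cbind(ijk[, 1] + shift[1], ijk[, 2] + shift[2], ijk[, 3] + shift[3])] <- TRUE
  tumorMask(out, mask@spacing,
            origin_mm = mask@origin + (lo - 1L - pad_vox) * mask@spacing)
}

#' Read and write tumor masks as NIfTI volumes
#'
#' Masks are exchanged as NIfTI (`.nii`/`.nii.gz`) binary volumes. Any
#' nonzero voxel counts as occupied; the voxel spacing is taken from the
#' header.
#'
#' @param path file path.
#' @return `readMaskNifti` returns a [TumorMask-class];
#'   `writeMaskNifti` invisibly returns `path`.
#' @export
readMaskNifti <- function(path) {
  img <- RNifti::readNifti(path)
  occ <- array(as.array(img) != 0, dim(img))
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(pd[1:3] <= 0))
    stop("NIfTI header of '", path, "' has no usable voxel spacing")
  tumorMask(occ, spacing_mm = pd[1:3])
}

#' @rdname readMaskNifti
#' @param mask a [TumorMask-class].
#' @export
writeMaskNifti <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask@occupancy),
                               dim(mask@occupancy)))
  RNifti::pixdim(img) <- mask@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# map physical positions (cm) to 1-based voxel indices of a mask grid
.positionToIndex <- function(mask, pos_cm) {
  pos_mm <- pos_cm * 10
  ijk <- sweep(sweep(matrix(pos_mm, ncol = 3L), 2L, mask@origin, `-`),
               2L, mask@spacing, `/`)
  ceiling(ijk - 1e-9)
}
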