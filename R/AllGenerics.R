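#' @include AllClasses.R
NULL

#' Accessors for ImageVolume
#'
#' `imageData` returns the raw 3D array, `voxelSpacing` the voxel size in mm,
#' `imageOrigin` the world coordinate of the first voxel centre, and
#' `acqMeta` the acquisition metadata list (optionally a single field).
#'
#' @param object an [ImageVolume-class].
#' @param field optional name of a single metadata entry.
#' @return array, numeric(3), or list/value respectively.
#' @aliases imageData voxelSpacing imageOrigin acqMeta
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))

#' @rdname imageData
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))

#' @rdname imageData
#' @export
setGeneric("imageOrigin", function(object) standardGeneric("imageOrigin"))

#' @rdname imageData
#' @export
setGeneric("acqMeta", function(object, field = NULL) standardGeneric("acqMeta"))

#' Accessors for PhantomLayout
#'
#' `fiducials` returns the fiducial-sphere table, `parameterArray` one of the
#' three MR parameter arrays, `resolutionInset` one of the two hole sets, and
#' `wedgeSpec` the slice-profile wedge description.
#'
#' @param object a [PhantomLayout-class].
#' @param kind for `parameterArray` one of "NiCl2", "MnCl2", "PD"; for
#'   `resolutionInset` one of "coarse", "fine".
#' @return a data.frame (or list for `wedgeSpec`).
#' @aliases fiducials parameterArray resolutionInset wedgeSpec
#' @export
setGeneric("fiducials", function(object) standardGeneric("fiducials"))

#' @rdname fiducials
#' @export
setGeneric("parameterArray", function(object, kind) standardGeneric("parameterArray"))

#' @rdname fiducials
#' @export
setGeneric("resolutionInset", function(object, kind) standardGeneric("resolutionInset"))

#' @rdname fiducials
#' @export
setGeneric("wedgeSpec", function(object) standardGeneric("wedgeSpec"))

setMethod("imageData", "ImageVolume", function(object) object@data)
setMethod("voxelSpacing", "ImageVolume", function(object) object@spacing)
setMethod("imageOrigin", "ImageVolume", function(object) object@origin)
setMethod("acqMeta", "ImageVolume", function(object, field = NULL) {
  if (is.null(field)) object@meta else object@meta[[field]]
})

setMethod("fiducials", "PhantomLayout", function(object) object@fiducials)

setMethod("parameterArray", "PhantomLayout", function(object, kind) {
  kind <- match.arg(kind, c("NiCl2", "MnCl2", "PD"))
  object@arrays[object@arrays$array == kind, , drop = FALSE]
})

setMethod("resolutionInset", "PhantomLayout", function(object, kind) {
  kind <- match.arg(kind, c("coarse", "fine"))
  object@insets[[kind]]
})

setMethod("wedgeSpec", "PhantomLayout", function(object) object@wedges)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat("ImageVolume:", paste(d, collapse = " x "), "voxels,",
      paste(format(object@spacing, digits = 4), collapse = " x "), "mm\n")
  m <- object@meta
  if (!is.null(m$sequence)) cat("  sequence:", m$sequence, "\n")
  tags <- c(TR_ms = "TR", TE_ms = "TE", TI_ms = "TI", flip_deg = "flip")
  for (nm in names(tags))
    if (!is.null(m[[nm]]))
      cat("  ", tags[[nm]], ": ", paste(m[[nm]], collapse = ", "), "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "PhantomLayout", function(object) {
  cat("PhantomLayout (", object@units, ", ", object@convention, ")\n", sep = "")
  cat("  fiducial spheres :", nrow(object@fiducials), "\n")
  for (k in unique(object@arrays$array))
    cat("  ", k, " array        : ", sum(object@arrays$array == k),
        " spheres\n", sep = "")
  for (k in names(object@insets))
    cat("  ", k, " inset : ", nrow(object@insets[[k]]), " holes\n", sep = "")
  invisible(NULL)
})

setMethod("show", "SimilarityTransform", function(object) {
  ang <- rotationAngle(object@rotation)
  cat("SimilarityTransform: scale =", format(object@scale, digits = 6),
      "| rotation =", format(ang, digits = 4), "deg",
      "| translation =", paste(format(object@translation, digits = 4),
                               collapse = ", "), "mm\n")
  invisible(NULL)
})

setMethod("show", "SimulationConfig", function(object) {
  acq <- object@acquisition
  cat("SimulationConfig:", acq$sequence, "\n")
  cat("  matrix:", paste(acq$matrix, collapse = " x "),
      " voxel:", paste(acq$voxel_mm, collapse = " x "), "mm\n")
  cat("  noise:", object@noise$kind, "sigma =", object@noise$sigma,
      "seed =", object@noise$seed, "\n")
  invisible(NULL)
})
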