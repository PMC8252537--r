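#' @import methods
NULL

#' ImageVolume: a 3D scalar image with geometry and acquisition metadata
#'
#' Container for one reconstructed magnitude image: a 3D voxel array plus
#' voxel spacing (mm), world-space origin of the first voxel centre (mm),
#' direction cosines, and an acquisition metadata list (TR, TE, TI, flip
#' angle, series description). World coordinates follow the phantom
#' convention: +X left, +Y posterior (down), +Z superior.
#'
#' @slot data 3D numeric array of voxel intensities.
#' @slot spacing numeric(3), voxel edge lengths in mm.
#' @slot origin numeric(3), world coordinate (mm) of the centre of voxel
#'   (1,1,1).
#' @slot orientation 3x3 orthonormal matrix of direction cosines mapping
#'   voxel axes to world axes (identity for simulator output).
#' @slot meta named list of acquisition metadata (TR_ms, TE_ms, TI_ms,
#'   flip_deg, sequence, series, rep, ...). Unused entries may be absent.
#'
#' @seealso [imageVolume()], [voxelToWorld()], [worldToVoxel()]
#' @export
setClass("ImageVolume",
  representation(
    data = "array",
    spacing = "numeric",
    origin = "numeric",
    orientation = "matrix",
    meta = "list"
  )
)

setValidity("ImageVolume", function(object) {
  msg <- NULL
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values (mm)")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must be length 3 (mm)")
  if (!all(dim(object@orientation) == c(3L, 3L)) ||
      max(abs(crossprod(object@orientation) - diag(3))) > 1e-6)
    msg <- c(msg, "orientation must be a 3x3 orthonormal matrix")
  if (is.null(msg)) TRUE else msg
})

#' PhantomLayout: positions and sizes of all phantom structures
#'
#' Queryable model of the system phantom in phantom coordinates (mm, origin
#' at the centre of the central fiducial sphere): the 57-sphere fiducial
#' lattice, the three 14-sphere MR parameter arrays, the two resolution
#' insets, and the slice-profile wedge pair.
#'
#' @slot fiducials data.frame with one row per fiducial sphere: id, x, y, z
#'   (mm), inner_diameter (mm), group.
#' @slot arrays data.frame with one row per parameter-array sphere: array
#'   (NiCl2/MnCl2/PD), element (1-14), x, y, z, inner_diameter, ring
#'   (outer/inner).
#' @slot insets named list of two HoleSet data.frames (coarse, fine); each
#'   has columns size_mm, hole (index within size), u, v (in-plate mm,
#'   relative to inset origin), diameter_mm, group_angle_deg (0 or 10),
#'   shared (logical).
#' @slot wedges list describing the slice-profile wedge pair: wedge_angle_deg
#'   (10), height_mm (10), roi_mm (c(4, 50)), orientations (c(+1, -1)),
#'   centers (2x3 matrix, phantom mm).
#' @slot units character, always "mm".
#' @slot convention character description of the coordinate convention.
#'
#' @seealso [phantomLayout()], [fiducials()], [parameterArray()]
#' @export
setClass("PhantomLayout",
  representation(
    fiducials = "data.frame",
    arrays = "data.frame",
    insets = "list",
    wedges = "list",
    units = "character",
    convention = "character"
  )
)

setValidity("PhantomLayout", function(object) {
  msg <- NULL
  f <- object@fiducials
  need <- c("id", "x", "y", "z", "inner_diameter", "group")
  if (!all(need %in% names(f)))
    msg <- c(msg, "fiducials must have columns id,x,y,z,inner_diameter,group")
  else {
    r <- sqrt(f$x^2 + f$y^2 + f$z^2) + f$inner_diameter / 2
    if (any(r >= 100))
      msg <- c(msg, "all fiducial spheres must lie strictly inside the 200 mm shell")
  }
  a <- object@arrays
  if (nrow(a) && !all(c("array", "element", "x", "y", "z") %in% names(a)))
    msg <- c(msg, "arrays must have columns array,element,x,y,z")
  if (is.null(msg)) TRUE else msg
})

#' SimilarityTransform: rotation + translation + isotropic scale
#'
#' The map from phantom (prescribed) to scanner (apparent) coordinates fitted
#' by the generalized Procrustes alignment of the fiducial lattice:
#' p -> scale * rotation %*% p + translation. Reflections are disallowed.
#'
#' @slot rotation 3x3 proper orthogonal matrix (det = +1).
#' @slot translation numeric(3), mm.
#' @slot scale positive scalar.
#' @seealso [fitSimilarity()], [applyTransform()]
#' @export
setClass("SimilarityTransform",
  representation(rotation = "matrix", translation = "numeric",
                 scale = "numeric")
)

setValidity("SimilarityTransform", function(object) {
  msg <- NULL
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L)) || max(abs(crossprod(R) - diag(3))) > 1e-6)
    msg <- c(msg, "rotation must be 3x3 orthogonal")
  else if (det(R) < 0)
    msg <- c(msg, "rotation must be proper (det = +1); reflections disallowed")
  if (length(object@translation) != 3L)
    msg <- c(msg, "translation must be length 3")
  if (length(object@scale) != 1L || object@scale <= 0)
    msg <- c(msg, "scale must be a positive scalar")
  if (is.null(msg)) TRUE else msg
})

#' SimulationConfig: full specification of a digital-reference-object render
#'
#' Everything needed to render a synthetic phantom image series: the layout,
#' per-region (PD, T1, T2) properties, the acquisition (sequence, timings,
#' voxel grid), a geometric distortion field, a multiplicative receive-bias
#' field, and the noise model. A config plus its seed fully determines the
#' output.
#'
#' @slot layout a [PhantomLayout-class].
#' @slot regions data.frame keyed by region (fiducial sphere id or array
#'   element) with PD (0-1), T1_ms, T2_ms.
#' @slot acquisition list: sequence ("IR_SE","SE","SPGR_VFA","GRE3D"),
#'   TR_ms, TE_ms, TI_ms (vector, IR), flip_deg (vector, VFA), voxel_mm
#'   (numeric 3), matrix (integer 3), origin_mm (numeric 3),
#'   slice_thickness_mm.
#' @slot distortion list: scale, rotation (3x3), translation_mm,
#'   poly (optional data.frame of monomial displacement terms).
#' @slot bias list: kind ("uniform","linear","radial"), coefficients.
#' @slot noise list: sigma (absolute signal units), kind
#'   ("rician","gaussian","none"), seed (integer).
#' @slot options list: supersample (default 3), background_signal,
#'   background_T1_ms, shell_radius_mm, inversion_efficiency.
#' @seealso [simulationConfig()], [renderVolume()], [renderSeries()]
#' @export
setClass("SimulationConfig",
  representation(
    layout = "PhantomLayout",
    regions = "data.frame",
    acquisition = "list",
    distortion = "list",
    bias = "list",
    noise = "list",
    options = "list"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  acq <- object@acquisition
  if (is.null(acq$voxel_mm) || any(acq$voxel_mm <= 0))
    msg <- c(msg, "acquisition$voxel_mm must be positive")
  if (!is.null(acq$TR_ms) && any(acq$TR_ms <= 0))
    msg <- c(msg, "TR must be positive")
  if (!is.null(acq$flip_deg) &&
      (any(acq$flip_deg <= 0) || any(acq$flip_deg > 180)))
    msg <- c(msg, "flip angles must lie in (0, 180] degrees")
  if (!is.null(object@noise$sigma) && object@noise$sigma < 0)
    msg <- c(msg, "noise sigma must be >= 0")
  if (is.null(msg)) TRUE else msg
})
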