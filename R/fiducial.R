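#' @include AllClasses.R utils.R simulate.R
NULL

#' Render a sphere correlation kernel on a voxel grid
#'
#' Noiseless partial-volume rasterization of a sphere of the given diameter
#' at the image's voxel spacing, mean-subtracted so that correlation with a
#' constant background is zero.
#'
#' @param diameter_mm sphere inner diameter (default 10 mm).
#' @param spacing_mm numeric(3) voxel size.
#' @param ss supersampling factor for partial volume.
#' @return 3D array (odd dimensions), zero mean.
#' @export
sphereKernel <- function(diameter_mm = 10, spacing_mm = c(1, 1, 1), ss = 3L) {
  r <- diameter_mm / 2
  n <- 2 * ceiling(r / spacing_mm + 1) + 1
  axes <- lapply(1:3, function(d) (seq_len(n[d]) - (n[d] + 1) / 2) * spacing_mm[d])
  k <- paintSphere(array(0, n), axes, c(0, 0, 0), r, 1, ss = ss)
  k - mean(k)
}

# Design pseudo-inverse for the 3x3x3 quadratic peak refinement.
.quadDesign <- local({
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  X <- cbind(1, g, g^2, g[, 1] * g[, 2], g[, 1] * g[, 3], g[, 2] * g[, 3])
  solve(crossprod(X), t(X))
})

# Sub-voxel peak offset from the 3x3x3 neighbourhood of a correlation peak:
# fit a full 3D quadratic and solve grad = 0; offsets are clamped to one
# voxel so a degenerate fit cannot escape the neighbourhood.
quadraticPeakOffset <- function(nbhd) {
  b <- .quadDesign %*% as.vector(nbhd)
  g <- b[2:4]
  H <- matrix(c(2 * b[5], b[8], b[9],
                b[8], 2 * b[6], b[10],
                b[9], b[10], 2 * b[7]), 3, 3)
  off <- tryCatch(-solve(H, g), error = function(e) c(0, 0, 0))
  pmin(pmax(as.numeric(off), -1), 1)
}

#' Locate fiducial spheres by cross-correlation
#'
#' Correlates the image with a rendered sphere kernel (FFT-based, whole
#' volume), then for each layout sphere finds the correlation maximum within
#' a search window about its nominal position and refines it to sub-voxel
#' precision with a 3D quadratic fit to the 3 x 3 x 3 peak neighbourhood.
#' The integrated intensity over a spherical ROI at the found centre is
#' recorded for the uniformity analysis. Spheres whose peak lies on the
#' window edge, whose correlation is below `corr_frac` of the median peak,
#' or whose integrated intensity deviates more than `intensity_frac` from
#' the group median are flagged (air bubbles and defects present this way)
#' and excluded downstream.
#'
#' @param volume an [ImageVolume-class] (voxel size <= 2 mm).
#' @param layout a [PhantomLayout-class], or a data.frame with columns
#'   id, x, y, z, inner_diameter, group.
#' @param transform optional [SimilarityTransform-class] giving the initial
#'   phantom-to-scanner guess (default identity).
#' @param search_mm half-width of the search window about the nominal
#'   position (default 10; at most half the 40 mm lattice spacing to prevent
#'   neighbour capture).
#' @param kernel optional kernel array from [sphereKernel()].
#' @param roi_diameter_mm ROI diameter for the integrated intensity.
#' @param corr_frac,intensity_frac flagging thresholds.
#' @return data.frame (class "LocalizationResult") with one row per sphere:
#'   id, group, prescribed x/y/z, apparent xa/ya/za, corr_peak,
#'   integrated_intensity, flag ("" if usable).
#' @export
locateSpheres <- function(volume, layout, transform = NULL, search_mm = 10,
                          kernel = NULL, roi_diameter_mm = 10,
                          corr_frac = 0.6, intensity_frac = 0.4) {
  f <- if (is(layout, "PhantomLayout")) fiducials(layout) else layout
  sp <- voxelSpacing(volume)
  if (max(sp) > 2)
    stop("voxel size must be <= 2 mm for sphere localization")
  if (search_mm > 20) search_mm <- 20
  if (is.null(kernel))
    kernel <- sphereKernel(stats::median(f$inner_diameter), sp)
  img <- imageData(volume)
  dims <- dim(img)
  if (any(dim(kernel) > dims))
    stop("kernel larger than image")
  # circular cross-correlation, kernel centre at voxel (1,1,1)
  kpad <- array(0, dims)
  kd <- dim(kernel)
  kc <- (kd + 1) / 2
  idx <- lapply(1:3, function(d) ((seq_len(kd[d]) - kc[d]) %% dims[d]) + 1)
  kpad[idx[[1]], idx[[2]], idx[[3]]] <- kernel
  corr <- Re(stats::fft(stats::fft(img) * Conj(stats::fft(kpad)),
                        inverse = TRUE)) / prod(dims)

  nominal <- as.matrix(f[, c("x", "y", "z")])
  if (!is.null(transform)) nominal <- applyTransform(transform, nominal)
  guess <- worldToVoxel(volume, nominal)
  win <- pmax(1, round(search_mm / sp))
  n <- nrow(f)
  apparent <- matrix(NA_real_, n, 3)
  peak <- rep(NA_real_, n)
  intens <- rep(NA_real_, n)
  flag <- character(n)
  roi_r <- roi_diameter_mm / 2
  for (k in seq_len(n)) {
    ctr <- round(guess[k, ])
    lo <- ctr - win; hi <- ctr + win
    if (any(lo < 1) || any(hi > dims)) {
      flag[k] <- "outside_volume"
      next
    }
    w <- corr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    m <- arrayInd(which.max(w), dim(w))
    peak[k] <- w[m]
    if (any(m == 1) || any(m == dim(w))) {
      flag[k] <- "edge_of_window"
      next
    }
    nb <- corr[(lo[1] + m[1] - 2):(lo[1] + m[1]),
               (lo[2] + m[2] - 2):(lo[2] + m[2]),
               (lo[3] + m[3] - 2):(lo[3] + m[3])]
    off <- quadraticPeakOffset(nb)
    pk <- lo + m - 1 + off
    apparent[k, ] <- voxelToWorld(volume, pk)
    # integrated intensity over the ROI at the found centre
    rr <- ceiling(roi_r / sp)
    il <- pmax(1, round(pk) - rr); ih <- pmin(dims, round(pk) + rr)
    sub <- img[il[1]:ih[1], il[2]:ih[2], il[3]:ih[3], drop = FALSE]
    dx <- imageOrigin(volume)[1] + (il[1]:ih[1] - 1) * sp[1] - apparent[k, 1]
    dy <- imageOrigin(volume)[2] + (il[2]:ih[2] - 1) * sp[2] - apparent[k, 2]
    dz <- imageOrigin(volume)[3] + (il[3]:ih[3] - 1) * sp[3] - apparent[k, 3]
    d2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
    intens[k] <- sum(sub[d2 <= roi_r^2]) * prod(sp)
  }
  ok <- flag == "" & !is.na(peak)
  if (any(ok)) {
    medpk <- stats::median(peak[ok])
    low <- ok & peak < corr_frac * medpk
    flag[low] <- "low_correlation"
    ok <- flag == ""
    for (g in unique(f$group)) {
      sel <- ok & f$group == g
      if (sum(sel) >= 3) {
        medi <- stats::median(intens[sel])
        out <- sel & abs(intens - medi) > intensity_frac * abs(medi)
        flag[out] <- "intensity_outlier"
      }
    }
  }
  res <- data.frame(id = f$id, group = f$group,
                    x = f$x, y = f$y, z = f$z,
                    xa = apparent[, 1], ya = apparent[, 2], za = apparent[, 3],
                    corr_peak = peak, integrated_intensity = intens,
                    flag = flag, stringsAsFactors = FALSE)
  class(res) <- c("LocalizationResult", "data.frame")
  res
}

#' Fit a similarity transform between point sets (generalized Procrustes)
#'
#' Closed-form weighted orthogonal Procrustes solution with isotropic scale
#' (SVD of the weighted cross-covariance), minimizing
#' sum w_i || apparent_i - (s R prescribed_i + t) ||^2 over proper rotations
#' (reflections disallowed).
#'
#' @param prescribed,apparent n x 3 matrices of corresponding points (mm).
#' @param weights optional non-negative weights.
#' @return a [SimilarityTransform-class].
#' @export
fitSimilarity <- function(prescribed, apparent, weights = NULL) {
  P <- as.matrix(prescribed); A <- as.matrix(apparent)
  keep <- stats::complete.cases(P) & stats::complete.cases(A)
  if (!is.null(weights)) keep <- keep & weights > 0
  P <- P[keep, , drop = FALSE]; A <- A[keep, , drop = FALSE]
  w <- if (is.null(weights)) rep(1, nrow(P)) else weights[keep]
  if (nrow(P) < 4) stop("need at least 4 point correspondences")
  w <- w / sum(w)
  muP <- colSums(P * w); muA <- colSums(A * w)
  Pc <- sweep(P, 2, muP); Ac <- sweep(A, 2, muA)
  C <- crossprod(Ac * w, Pc)            # weighted cross-covariance
  sv <- svd(C)
  if (sv$d[3] < 1e-10 * sv$d[1])
    stop("degenerate point configuration (coplanar or collinear)")
  S <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))
  R <- sv$u %*% S %*% t(sv$v)
  varP <- sum(w * rowSums(Pc^2))
  s <- sum(diag(S) * sv$d) / varP
  t <- muA - s * as.numeric(R %*% muP)
  new("SimilarityTransform", rotation = R, translation = t, scale = s)
}

#' Apply a similarity transform to points
#'
#' @param transform a [SimilarityTransform-class].
#' @param pts n x 3 matrix (mm).
#' @return n x 3 matrix.
#' @export
applyTransform <- function(transform, pts) {
  pts <- rbind(pts)
  sweep(transform@scale * t(transform@rotation %*% t(pts)), 2,
        transform@translation, "+")
}

#' Geometric distortion report
#'
#' Residual displacement of each located sphere after the fitted similarity
#' transform accounts for rotation, translation and overall scale:
#' deltaR = R_apparent - (s R R_prescribed + t). Components follow the
#' phantom axes (x left, y posterior, z superior), grouped by the seven
#' fiducial groups.
#'
#' @param localization result of [locateSpheres()].
#' @param transform a [SimilarityTransform-class] from [fitSimilarity()].
#' @param layout optional [PhantomLayout-class] (for sphere metadata).
#' @return list of class "DistortionReport": per_sphere data.frame (id,
#'   group, prescribed, apparent, dx, dy, dz, dr, flag), scale, rotation,
#'   translation, group_summary (rms per group), rms_mm (overall, unflagged).
#' @export
computeDistortion <- function(localization, transform, layout = NULL) {
  loc <- localization
  pres <- as.matrix(loc[, c("x", "y", "z")])
  app <- as.matrix(loc[, c("xa", "ya", "za")])
  fitted <- applyTransform(transform, pres)
  d <- app - fitted
  dr <- sqrt(rowSums(d^2))
  per <- data.frame(id = loc$id, group = loc$group,
                    x = loc$x, y = loc$y, z = loc$z,
                    xa = loc$xa, ya = loc$ya, za = loc$za,
                    dx = d[, 1], dy = d[, 2], dz = d[, 3], dr = dr,
                    flag = loc$flag, stringsAsFactors = FALSE)
  ok <- loc$flag == "" & !is.na(dr)
  gs <- do.call(rbind, lapply(split(per[ok, ], per$group[ok]), function(g)
    data.frame(group = g$group[1], n = nrow(g),
               rms_mm = sqrt(mean(g$dr^2)), max_mm = max(g$dr))))
  rownames(gs) <- NULL
  structure(list(per_sphere = per, scale = transform@scale,
                 rotation = transform@rotation,
                 translation = transform@translation,
                 group_summary = gs,
                 rms_mm = sqrt(mean(dr[ok]^2))),
            class = "DistortionReport")
}

#' Image-uniformity report from fiducial intensities
#'
#' Integrated ROI intensities of the (identically filled) fiducial spheres,
#' normalized to the maximum unflagged sphere; departures from 1 map the
#' receive-coil sensitivity profile.
#'
#' @param localization result of [locateSpheres()].
#' @return data.frame (class "UniformityReport"): id, group, x, y, z,
#'   integrated_intensity, normalized (NA for flagged spheres), flag.
#' @export
computeUniformity <- function(localization) {
  loc <- localization
  ok <- loc$flag == "" & !is.na(loc$integrated_intensity)
  ref <- max(loc$integrated_intensity[ok])
  norm <- ifelse(ok, loc$integrated_intensity / ref, NA_real_)
  out <- data.frame(id = loc$id, group = loc$group,
                    x = loc$x, y = loc$y, z = loc$z,
                    integrated_intensity = loc$integrated_intensity,
                    normalized = norm, flag = loc$flag,
                    stringsAsFactors = FALSE)
  class(out) <- c("UniformityReport", "data.frame")
  out
}

#' Local volume distortion from intensity support
#'
#' Ratio of each sphere's apparent volume (voxels above half maximum of the
#' background-subtracted local intensity) to its nominal volume. A locally
#' scaled image region scales this ratio by the cube of the scale factor.
#'
#' @param volume the [ImageVolume-class] used for localization.
#' @param localization result of [locateSpheres()].
#' @param nominal_diameter_mm sphere inner diameter (default 10).
#' @return data.frame: id, volume_mm3, volume_ratio (NA for flagged).
#' @export
volumeDistortion <- function(volume, localization, nominal_diameter_mm = 10) {
  loc <- localization
  img <- imageData(volume)
  sp <- voxelSpacing(volume)
  dims <- dim(img)
  r <- nominal_diameter_mm / 2
  out <- data.frame(id = loc$id, volume_mm3 = NA_real_,
                    volume_ratio = NA_real_)
  for (k in seq_len(nrow(loc))) {
    if (loc$flag[k] != "" || is.na(loc$xa[k])) next
    ctr <- c(loc$xa[k], loc$ya[k], loc$za[k])
    ext <- ceiling((r + 5) / sp)
    cv <- round(worldToVoxel(volume, rbind(ctr)))[1, ]
    lo <- pmax(1, cv - ext); hi <- pmin(dims, cv + ext)
    sub <- img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    dx <- imageOrigin(volume)[1] + (lo[1]:hi[1] - 1) * sp[1] - ctr[1]
    dy <- imageOrigin(volume)[2] + (lo[2]:hi[2] - 1) * sp[2] - ctr[2]
    dz <- imageOrigin(volume)[3] + (lo[3]:hi[3] - 1) * sp[3] - ctr[3]
    d2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
    shell <- sub[d2 >= (r + 2)^2 & d2 <= (r + 5)^2]
    core <- sub[d2 <= (r / 2)^2]
    if (!length(shell) || !length(core)) next
    bg <- stats::median(shell)
    amp <- stats::median(core)
    thr <- bg + 0.5 * (amp - bg)
    # above-half-maximum support counted on a 3x interpolated sub-grid, so
    # the support boundary is placed at sub-voxel precision
    fs <- sp / 3
    gx <- seq(ctr[1] - (r + 3), ctr[1] + (r + 3), by = fs[1])
    gy <- seq(ctr[2] - (r + 3), ctr[2] + (r + 3), by = fs[2])
    gz <- seq(ctr[3] - (r + 3), ctr[3] + (r + 3), by = fs[3])
    pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    vals <- interp3(img, worldToVoxel(volume, pts), outside = bg)
    vol <- sum(vals > thr) * prod(fs)
    out$volume_mm3[k] <- vol
    out$volume_ratio[k] <- vol / (4 / 3 * pi * r^3)
  }
  out
}

#' Full fiducial analysis: locate, align, report
#'
#' Runs [locateSpheres()], fits the similarity transform on unflagged
#' spheres (refitting if flagging changes the point set — the "generalized"
#' iteration), and assembles distortion and uniformity reports.
#'
#' @param volume an [ImageVolume-class].
#' @param layout a [PhantomLayout-class].
#' @param ... passed to [locateSpheres()].
#' @return list: localization, transform, distortion (DistortionReport),
#'   uniformity (UniformityReport).
#' @export
fiducialAnalysis <- function(volume, layout, ...) {
  loc <- locateSpheres(volume, layout, ...)
  ok <- loc$flag == "" & !is.na(loc$xa)
  if (sum(ok) < 4) stop("fewer than 4 usable fiducial spheres")
  tr <- fitSimilarity(as.matrix(loc[ok, c("x", "y", "z")]),
                      as.matrix(loc[ok, c("xa", "ya", "za")]))
  list(localization = loc,
       transform = tr,
       distortion = computeDistortion(loc, tr),
       uniformity = computeUniformity(loc))
}
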