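#' @include AllClasses.R utils.R relaxometry.R
NULL

# Voxel values whose centres fall inside a sphere of radius r about a world
# point; returns numeric(0) if the ROI misses the volume.
.roiVox <- function(volume, centre, r) {
  sp <- voxelSpacing(volume)
  dims <- dim(imageData(volume))
  cv <- round(worldToVoxel(volume, rbind(centre)))[1, ]
  ext <- ceiling(r / sp)
  lo <- pmax(1, cv - ext); hi <- pmin(dims, cv + ext)
  if (any(lo > hi)) return(numeric(0))
  sub <- imageData(volume)[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dx <- imageOrigin(volume)[1] + (lo[1]:hi[1] - 1) * sp[1] - centre[1]
  dy <- imageOrigin(volume)[2] + (lo[2]:hi[2] - 1) * sp[2] - centre[2]
  dz <- imageOrigin(volume)[3] + (lo[3]:hi[3] - 1) * sp[3] - centre[3]
  d2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
  sub[d2 <= r^2]
}

#' Measure proton density with local background normalization
#'
#' For each sphere of the PD array: the 10 mm ROI mean is divided by the
#' local background (the mean of four small spherical samples taken 3 mm
#' outside the sphere wall, at +/-x and +/-z in the plate plane), which
#' cancels the receive-bias profile because the background fill is water
#' everywhere; the ratios are then scaled so the 100 % water sphere reads
#' 100. Background samples that land inside another structure are re-taken
#' at 45-degree rotated offsets and the sphere is flagged.
#'
#' @param volume a PD-weighted (short-TE spin echo) [ImageVolume-class].
#' @param layout a [PhantomLayout-class].
#' @param transform optional [SimilarityTransform-class] mapping phantom to
#'   scanner coordinates.
#' @param reference reference table giving prescribed PD per element.
#' @param roi_diameter_mm ROI diameter (default 10).
#' @param bg_offset_mm clearance outside the sphere wall (default 3).
#' @param bg_sample_radius_vox radius of each background sample in voxels.
#' @param outer_radius_mm sphere outer radius (wall included), default 10.
#' @return data.frame (class "PDResult"): element, raw_mean, background,
#'   ratio, measured_PD_pct, prescribed_PD_pct, error_pp, flag.
#' @export
measurePD <- function(volume, layout, transform = NULL,
                      reference = referenceTable(), roi_diameter_mm = 10,
                      bg_offset_mm = 3, bg_sample_radius_vox = 3,
                      outer_radius_mm = 10) {
  arr <- parameterArray(layout, "PD")
  ctrs <- as.matrix(arr[, c("x", "y", "z")])
  if (!is.null(transform)) ctrs <- applyTransform(transform, ctrs)
  ref <- reference[reference$array == "PD", ]
  sp <- voxelSpacing(volume)
  samp_r <- bg_sample_radius_vox * min(sp)
  off_d <- outer_radius_mm + bg_offset_mm + samp_r
  # in-plate sample quad (+/-x, +/-z in the phantom frame): a point-symmetric
  # quad cancels the curvature of a smooth bias field to second order, so
  # collision fallbacks rotate the whole quad rather than dropping points
  quad <- function(phi_deg) {
    c_ <- cos(phi_deg * pi / 180); s_ <- sin(phi_deg * pi / 180)
    d <- rbind(c(c_, 0, s_), c(-c_, 0, -s_), c(-s_, 0, c_), c(s_, 0, -c_))
    if (!is.null(transform)) d <- t(transform@rotation %*% t(d))
    d
  }
  all_ctrs <- ctrs
  clearOf <- function(p) {
    # background sample must not intersect any PD sphere
    d <- sqrt(rowSums(sweep(all_ctrs, 2, p, "-")^2))
    all(d > outer_radius_mm + samp_r)
  }
  n <- nrow(arr)
  raw <- bg <- rep(NA_real_, n)
  flag <- character(n)
  for (i in seq_len(n)) {
    raw[i] <- mean(.roiVox(volume, ctrs[i, ], roi_diameter_mm / 2))
    pts <- NULL
    for (phi in seq(0, 75, by = 15)) {
      cand <- sweep(off_d * quad(phi), 2, ctrs[i, ], "+")
      if (all(apply(cand, 1, clearOf))) {
        pts <- cand
        if (phi > 0) flag[i] <- "background_resampled"
        break
      }
    }
    if (is.null(pts)) {
      # no fully clear quad: fall back to the clear subset at 0 degrees
      cand <- sweep(off_d * quad(0), 2, ctrs[i, ], "+")
      pts <- cand[apply(cand, 1, clearOf), , drop = FALSE]
      flag[i] <- "background_partial"
    }
    vals <- unlist(lapply(seq_len(nrow(pts)), function(j)
      mean(.roiVox(volume, pts[j, ], samp_r))))
    bg[i] <- mean(vals, na.rm = TRUE)
  }
  ratio <- raw / bg
  ref_pd <- ref$PD[match(arr$element, ref$element)] * 100
  i100 <- which.max(ref_pd)
  measured <- ratio / ratio[i100] * 100
  out <- data.frame(element = arr$element, raw_mean = raw, background = bg,
                    ratio = ratio, measured_PD_pct = measured,
                    prescribed_PD_pct = ref_pd,
                    error_pp = measured - ref_pd, flag = flag,
                    stringsAsFactors = FALSE)
  class(out) <- c("PDResult", "data.frame")
  out
}

#' SNR by the two-acquisition difference method
#'
#' Noise in each ROI is estimated from the difference of two identical
#' scans: N = SD(S2 - S1) / sqrt(2); the signal is the two-scan average
#' S_av = (S1_av + S2_av) / 2 and SNR = S_av / N. Temporal drift between
#' replicates is assumed negligible. The within-ROI mean/SD ("spatial")
#' ratio is also reported; it mixes noise with any true nonuniformity.
#'
#' @param volume1,volume2 co-registered replicate [ImageVolume-class]s.
#' @param centres_mm n x 3 matrix of ROI centres (world mm).
#' @param roi_diameter_mm ROI diameter (default 10).
#' @return data.frame (class "SNRResult"): roi, S_av, noise, SNR (NA and
#'   flagged when the difference is identically zero), spatial_ratio,
#'   n_voxels, flag.
#' @export
estimateSNR <- function(volume1, volume2, centres_mm, roi_diameter_mm = 10) {
  if (!all(dim(imageData(volume1)) == dim(imageData(volume2))))
    stop("replicate volumes must have identical geometry")
  centres_mm <- rbind(centres_mm)
  r <- roi_diameter_mm / 2
  rows <- lapply(seq_len(nrow(centres_mm)), function(i) {
    v1 <- .roiVox(volume1, centres_mm[i, ], r)
    v2 <- .roiVox(volume2, centres_mm[i, ], r)
    dS <- v2 - v1
    N <- stats::sd(dS) / sqrt(2)
    S_av <- (mean(v1) + mean(v2)) / 2
    flag <- ""
    snr <- S_av / N
    if (!is.finite(N) || N == 0) {
      snr <- NA_real_
      flag <- "zero_noise"
    }
    data.frame(roi = i, S_av = S_av, noise = N, SNR = snr,
               spatial_ratio = mean(v1) / stats::sd(v1),
               n_voxels = length(v1), flag = flag)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("SNRResult", "data.frame")
  out
}
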