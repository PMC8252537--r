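#' @include AllClasses.R geometry.R utils.R
NULL

# ---------------------------------------------------------------------------
# Signal models
# ---------------------------------------------------------------------------

#' Inversion-recovery magnitude signal
#'
#' Magnitude inversion-recovery model S(TI) = |A (1 - (1 + delta)
#' exp(-TI/T1))|, with A proportional to proton density and delta the
#' inversion efficiency (1 for a perfect 180-degree pulse). Only magnitude
#' is modelled because phase is typically unavailable on scanner exports.
#'
#' @param PD proton density, fraction of the water signal (0-1).
#' @param T1_ms longitudinal relaxation time, ms (> 0).
#' @param TI_ms inversion time(s), ms (>= 0).
#' @param delta inversion efficiency in [0, 1.2].
#' @param A_scale amplitude of a PD = 1 region at full recovery.
#' @return magnitude signal, same length as `TI_ms`.
#' @export
signalIR <- function(PD, T1_ms, TI_ms, delta = 1, A_scale = 1) {
  if (any(T1_ms <= 0)) stop("T1 must be positive")
  if (any(TI_ms < 0)) stop("TI must be non-negative")
  A <- A_scale * PD
  abs(A * (1 - (1 + delta) * exp(-TI_ms / T1_ms)))
}

#' Spoiled gradient-echo (variable flip angle) signal
#'
#' Steady-state spoiled GRE amplitude S(alpha) = S90 sin(alpha) (1 - E) /
#' (1 - E cos(alpha)) with E = exp(-TR/T1); S90 (the fully relaxed
#' 90-degree signal) is proportional to proton density. The signal is
#' maximal at the Ernst angle cos(alpha_E) = E.
#'
#' @param PD proton density fraction.
#' @param T1_ms T1 in ms (> 0).
#' @param TR_ms repetition time in ms (> 0).
#' @param alpha_deg flip angle(s) in degrees, (0, 180].
#' @param S90_scale amplitude of a PD = 1 region at alpha = 90, long TR.
#' @return signal, same length as `alpha_deg`.
#' @export
signalVFA <- function(PD, T1_ms, TR_ms, alpha_deg, S90_scale = 1) {
  if (any(T1_ms <= 0)) stop("T1 must be positive")
  if (any(TR_ms <= 0)) stop("TR must be positive")
  E <- exp(-TR_ms / T1_ms)
  a <- alpha_deg * pi / 180
  S90_scale * PD * sin(a) * (1 - E) / (1 - E * cos(a))
}

#' Spin-echo signal
#'
#' Monoexponential transverse decay S(TE) = S0 exp(-TE/T2), S0 proportional
#' to proton density (long-TR regime).
#'
#' @param PD proton density fraction.
#' @param T2_ms transverse relaxation time, ms (> 0).
#' @param TE_ms echo time(s), ms (>= 0).
#' @param S0_scale amplitude of a PD = 1 region at TE = 0.
#' @return signal, same length as `TE_ms`.
#' @export
signalSE <- function(PD, T2_ms, TE_ms, S0_scale = 1) {
  if (any(T2_ms <= 0)) stop("T2 must be positive")
  if (any(TE_ms < 0)) stop("TE must be non-negative")
  S0_scale * PD * exp(-TE_ms / T2_ms)
}

#' Ernst angle
#'
#' Flip angle maximizing the spoiled-GRE signal: acos(exp(-TR/T1)).
#'
#' @param TR_ms repetition time, ms.
#' @param T1_ms T1, ms.
#' @return angle in degrees.
#' @export
ernstAngle <- function(TR_ms, T1_ms) acos(exp(-TR_ms / T1_ms)) * 180 / pi

# ---------------------------------------------------------------------------
# Distortion and bias fields
# ---------------------------------------------------------------------------

#' Construct a geometric distortion field
#'
#' A similarity part (isotropic scale, rotation, translation) composed with
#' a smooth nonlinear displacement given by low-order 3D polynomial terms.
#' The apparent position of a phantom point p is
#' scale * R p + t + u(p), where u is the polynomial displacement evaluated
#' in coordinates normalized by 100 mm. The zero field is the identity.
#'
#' @param scale isotropic scale factor.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation_mm numeric(3).
#' @param poly optional data.frame with columns axis (1-3, displacement
#'   component), px, py, pz (monomial exponents), coef_mm (displacement in
#'   mm when the monomial equals 1, i.e. at 100 mm).
#' @return a list of class "distortionField".
#' @export
distortionField <- function(scale = 1, rotation = diag(3),
                            translation_mm = c(0, 0, 0), poly = NULL) {
  structure(list(scale = scale, rotation = rotation,
                 translation_mm = translation_mm, poly = poly),
            class = "distortionField")
}

#' Apply a distortion field to points
#'
#' @param field a [distortionField()].
#' @param pts n x 3 matrix of phantom coordinates (mm).
#' @return n x 3 matrix of apparent coordinates (mm).
#' @export
applyDistortion <- function(field, pts) {
  pts <- rbind(pts)
  out <- field$scale * t(field$rotation %*% t(pts))
  out <- sweep(out, 2, field$translation_mm, "+")
  if (!is.null(field$poly) && nrow(field$poly)) {
    q <- pts / 100
    for (r in seq_len(nrow(field$poly))) {
      term <- field$poly[r, ]
      out[, term$axis] <- out[, term$axis] +
        term$coef_mm * q[, 1]^term$px * q[, 2]^term$py * q[, 3]^term$pz
    }
  }
  out
}

# Nonlinear displacement alone, evaluated at phantom points (mm).
polyDisplacement <- function(field, pts) {
  pts <- rbind(pts)
  out <- matrix(0, nrow(pts), 3)
  if (!is.null(field$poly) && nrow(field$poly)) {
    q <- pts / 100
    for (r in seq_len(nrow(field$poly))) {
      term <- field$poly[r, ]
      out[, term$axis] <- out[, term$axis] +
        term$coef_mm * q[, 1]^term$px * q[, 2]^term$py * q[, 3]^term$pz
    }
  }
  out
}

#' Construct a multiplicative receive-bias field
#'
#' Smooth scalar gain applied to all intensities. Kinds: "uniform" (constant
#' `gain`), "linear" (gain = 1 + slope_per_100mm * (p . axis)/100), and
#' "radial" (gain = centre + (edge - centre) * (r/100)^2, mimicking receive
#' coil falloff).
#'
#' @param kind "uniform", "linear" or "radial".
#' @param gain constant gain (uniform).
#' @param axis numeric(3) direction (linear).
#' @param slope_per_100mm relative gain change per 100 mm (linear).
#' @param centre,edge gains at r = 0 and r = 100 mm (radial).
#' @param origin_mm centre of the radial field.
#' @return a list of class "biasField".
#' @export
biasField <- function(kind = c("uniform", "linear", "radial"), gain = 1,
                      axis = c(0, 1, 0), slope_per_100mm = 0,
                      centre = 1, edge = 1, origin_mm = c(0, 0, 0)) {
  kind <- match.arg(kind)
  structure(list(kind = kind, gain = gain, axis = axis,
                 slope_per_100mm = slope_per_100mm, centre = centre,
                 edge = edge, origin_mm = origin_mm),
            class = "biasField")
}

#' Evaluate a bias field at points
#'
#' @param bias a [biasField()].
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return numeric vector of gains.
#' @export
biasAt <- function(bias, pts) {
  pts <- rbind(pts)
  switch(bias$kind,
    uniform = rep(bias$gain, nrow(pts)),
    linear = {
      u <- bias$axis / sqrt(sum(bias$axis^2))
      1 + bias$slope_per_100mm * (pts %*% u) / 100
    }[, 1],
    radial = {
      r2 <- rowSums(sweep(pts, 2, bias$origin_mm, "-")^2)
      bias$centre + (bias$edge - bias$centre) * r2 / 100^2
    }
  )
}

# ---------------------------------------------------------------------------
# Region properties and acquisition presets
# ---------------------------------------------------------------------------

#' Read the shipped (synthetic) reference relaxation tables
#'
#' Reference (PD, T1, T2) per array element at 3 T, 20 C. The shipped tables
#' are synthetic stand-ins anchored to published single-element values and
#' the stated square-root-of-two progressions; replace with the calibration
#' certificate for a real phantom via `path`.
#'
#' @param path CSV with columns array, element, PD, T1_ms, T2_ms
#'   (default: the packaged synthetic tables).
#' @return data.frame.
#' @export
referenceTable <- function(path = system.file("extdata",
                                              "reference_synthetic_3T.csv",
                                              package = "sysphantom")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Default region properties for the simulator
#'
#' One row per distinct signal region: every fiducial sphere (shared CuSO4
#' fill: T1 = 407 ms, T2 = 347 ms, PD = 1), every parameter-array element
#' (from the reference table), and the background fill (long-T1 deionized
#' water).
#'
#' @param layout a [PhantomLayout-class].
#' @param reference data.frame from [referenceTable()].
#' @return data.frame with columns region ("fiducial", "array",
#'   "background"), array, element, PD, T1_ms, T2_ms.
#' @export
defaultRegionProperties <- function(layout = phantomLayout(),
                                    reference = referenceTable()) {
  fid <- data.frame(region = "fiducial", array = NA_character_,
                    element = fiducials(layout)$id,
                    PD = 1, T1_ms = 407, T2_ms = 347)
  arr <- data.frame(region = "array", array = reference$array,
                    element = reference$element, PD = reference$PD,
                    T1_ms = reference$T1_ms, T2_ms = reference$T2_ms)
  bg <- data.frame(region = "background", array = NA_character_,
                   element = NA_integer_, PD = 1, T1_ms = 3100, T2_ms = 1800)
  rbind(fid, arr, bg)
}

#' Acquisition presets
#'
#' Named presets mirroring the recommended protocol series: "isotropic3D"
#' (short-TE 3D GRE, 1 mm isotropic, whole phantom — fiducial analysis),
#' "t1_ir" (IR spin echo, 10 TIs from 50 to 3000 ms, TR 4500 ms), "t1_vfa"
#' (3D GRE, flips 2-30 degrees, TR 5.37 ms), "t2_se" (spin echo, TE 10-320
#' by 10 ms, TR 5000 ms), "pd_snr" (spin echo, TR 5000 / TE 10 ms, two
#' identical repeats).
#'
#' @param name preset name.
#' @param voxel_mm voxel size override, numeric(3) or scalar.
#' @param fov_mm field of view (mm), numeric(3) or scalar.
#' @param centre_mm FOV centre in phantom coordinates.
#' @return acquisition list for [simulationConfig()].
#' @export
acquisitionPreset <- function(name = c("isotropic3D", "t1_ir", "t1_vfa",
                                       "t2_se", "pd_snr"),
                              voxel_mm = NULL, fov_mm = NULL,
                              centre_mm = NULL) {
  name <- match.arg(name)
  acq <- switch(name,
    isotropic3D = list(sequence = "GRE3D", TR_ms = 6.3, TE_ms = 1.89,
                       flip_deg = 10, voxel_mm = c(1, 1, 1),
                       fov_mm = c(220, 220, 220), centre_mm = c(0, 0, 0)),
    t1_ir = list(sequence = "IR_SE", TR_ms = 4500, TE_ms = 10,
                 TI_ms = c(50, 100, 200, 350, 500, 750, 1000, 1500, 2000, 3000),
                 voxel_mm = c(1, 1, 2),
                 fov_mm = c(140, 24, 140), centre_mm = c(0, -66, 0)),
    t1_vfa = list(sequence = "SPGR_VFA", TR_ms = 5.37, TE_ms = 1.49,
                  flip_deg = c(2, 4, 6, 8, 10, 14, 18, 22, 26, 30),
                  voxel_mm = c(1, 1, 2),
                  fov_mm = c(140, 24, 140), centre_mm = c(0, -66, 0)),
    t2_se = list(sequence = "SE", TR_ms = 5000, TE_ms = seq(10, 320, by = 10),
                 voxel_mm = c(1, 1, 2),
                 fov_mm = c(140, 24, 140), centre_mm = c(0, -26, 0)),
    pd_snr = list(sequence = "SE", TR_ms = 5000, TE_ms = 10, repeats = 2L,
                  voxel_mm = c(1, 1, 2),
                  fov_mm = c(140, 24, 140), centre_mm = c(0, 14, 0))
  )
  if (!is.null(voxel_mm)) acq$voxel_mm <- rep(voxel_mm, length.out = 3)
  if (!is.null(fov_mm)) acq$fov_mm <- rep(fov_mm, length.out = 3)
  if (!is.null(centre_mm)) acq$centre_mm <- centre_mm
  acq$matrix <- pmax(2L, as.integer(round(acq$fov_mm / acq$voxel_mm)))
  acq$origin_mm <- acq$centre_mm - (acq$matrix - 1) / 2 * acq$voxel_mm
  acq
}

#' Construct a simulation configuration
#'
#' @param layout a [PhantomLayout-class].
#' @param regions region-property table ([defaultRegionProperties()]).
#' @param acquisition acquisition list ([acquisitionPreset()]).
#' @param distortion a [distortionField()] (default: identity).
#' @param bias a [biasField()] (default: uniform gain 1).
#' @param noise list(sigma, kind, seed); kind one of "rician", "gaussian",
#'   "none".
#' @param options list overriding defaults: supersample (3), shell_radius_mm
#'   (100), inversion_efficiency (1), amplitude (signal of a PD = 1 region,
#'   500), render_background (TRUE).
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(layout = phantomLayout(),
                             regions = defaultRegionProperties(layout),
                             acquisition = acquisitionPreset("isotropic3D"),
                             distortion = distortionField(),
                             bias = biasField("uniform"),
                             noise = list(sigma = 0, kind = "none", seed = 1L),
                             options = list()) {
  opt <- list(supersample = 3L, shell_radius_mm = 100,
              inversion_efficiency = 1, amplitude = 500,
              render_background = TRUE)
  opt[names(options)] <- options
  noise_def <- list(sigma = 0, kind = "none", seed = 1L)
  noise_def[names(noise)] <- noise
  new("SimulationConfig", layout = layout, regions = regions,
      acquisition = acquisition, distortion = unclass(distortion),
      bias = unclass(bias), noise = noise_def, options = opt)
}

# Signal value for one region at series element i of the acquisition.
regionSignal <- function(props, acq, i, opt) {
  A <- opt$amplitude
  switch(acq$sequence,
    IR_SE = signalIR(props$PD, props$T1_ms, acq$TI_ms[i],
                     delta = opt$inversion_efficiency, A_scale = A),
    SPGR_VFA = signalVFA(props$PD, props$T1_ms, acq$TR_ms,
                         acq$flip_deg[i], S90_scale = A),
    SE = signalSE(props$PD, props$T2_ms,
                  acq$TE_ms[min(i, length(acq$TE_ms))], S0_scale = A),
    GRE3D = signalVFA(props$PD, props$T1_ms, acq$TR_ms, acq$flip_deg[1],
                      S90_scale = A),
    stop("unknown sequence: ", acq$sequence)
  )
}

# ---------------------------------------------------------------------------
# Rasterization
# ---------------------------------------------------------------------------

# Paint a sphere into `arr` (modified in place by the caller via return
# value). axes = list of voxel-centre coordinates per dim. Partial volume by
# ss^3 supersampling of boundary voxels only; interior painted at full
# fraction. Painted fraction composites over existing content.
paintSphere <- function(arr, axes, centre, radius, value, ss = 3L) {
  rng <- lapply(1:3, function(d) {
    which(abs(axes[[d]] - centre[d]) <= radius + 1.5 * .axstep(axes[[d]]))
  })
  if (any(lengths(rng) == 0)) return(arr)
  dx <- axes[[1]][rng[[1]]] - centre[1]
  dy <- axes[[2]][rng[[2]]] - centre[2]
  dz <- axes[[3]][rng[[3]]] - centre[3]
  nx <- length(dx); ny <- length(dy); nz <- length(dz)
  d2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
  dist <- sqrt(d2)
  vox <- c(.axstep(axes[[1]]), .axstep(axes[[2]]), .axstep(axes[[3]]))
  h <- sqrt(sum(vox^2)) / 2
  frac <- array(0, dim(d2))
  frac[dist <= radius - h] <- 1
  bnd <- which(dist > radius - h & dist < radius + h)
  if (length(bnd)) {
    ii <- arrayInd(bnd, dim(d2))
    bx <- dx[ii[, 1]]; by <- dy[ii[, 2]]; bz <- dz[ii[, 3]]
    offs <- (seq_len(ss) - (ss + 1) / 2) / ss
    # each subcell contributes a linearly ramped indicator over its own
    # width, which suppresses the alignment-dependent quantization bias of
    # a hard threshold
    a <- mean(vox) / ss
    inside <- numeric(length(bnd))
    for (ox in offs) for (oy in offs) for (oz in offs) {
      d <- sqrt((bx + ox * vox[1])^2 + (by + oy * vox[2])^2 +
                  (bz + oz * vox[3])^2)
      inside <- inside + pmin(pmax((radius - d) / a + 0.5, 0), 1)
    }
    frac[bnd] <- inside / ss^3
  }
  sub <- arr[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  arr[rng[[1]], rng[[2]], rng[[3]]] <- sub * (1 - frac) + value * frac
  arr
}

.axstep <- function(ax) if (length(ax) > 1) ax[2] - ax[1] else 1

# Rician / Gaussian noise applied to a signal array, given pre-seeded RNG.
applyNoise <- function(arr, sigma, kind) {
  if (sigma <= 0 || kind == "none") return(arr)
  n <- length(arr)
  if (kind == "gaussian") return(arr + array(stats::rnorm(n, 0, sigma), dim(arr)))
  re <- arr + array(stats::rnorm(n, 0, sigma), dim(arr))
  im <- array(stats::rnorm(n, 0, sigma), dim(arr))
  sqrt(re^2 + im^2)
}

#' Render one synthetic phantom volume
#'
#' Rasterizes the phantom at the configured acquisition settings: each
#' sphere is painted with its signal-model value at series element `index`,
#' sphere centres are displaced by the distortion field, intensities are
#' multiplied by the bias field, and noise (Rician by default) is applied
#' last. Deterministic for a given config and index.
#'
#' @param config a [SimulationConfig-class].
#' @param index series element (which TI / TE / flip), 1-based.
#' @param rep_index replicate number (changes only the noise draw).
#' @return an [ImageVolume-class].
#' @export
renderVolume <- function(config, index = 1L, rep_index = 1L) {
  acq <- config@acquisition
  opt <- config@options
  vox <- acq$voxel_mm
  lay <- config@layout
  min_id <- min(c(fiducials(lay)$inner_diameter, lay@arrays$inner_diameter))
  if (max(vox) >= min_id)
    stop("voxel size (", max(vox), " mm) must be smaller than the smallest ",
         "sphere diameter (", min_id, " mm): geometry unresolvable")
  dims <- acq$matrix
  axes <- lapply(1:3, function(d) acq$origin_mm[d] + (seq_len(dims[d]) - 1) * vox[d])
  arr <- array(0, dims)
  dist <- config@distortion
  regions <- config@regions

  if (isTRUE(opt$render_background)) {
    bgp <- regions[regions$region == "background", ][1, ]
    if (!is.na(bgp$PD)) {
      sbg <- regionSignal(bgp, acq, index, opt)
      ctr <- applyDistortion(dist, rbind(c(0, 0, 0)))[1, ]
      arr <- paintSphere(arr, axes, ctr, dist$scale * opt$shell_radius_mm,
                         sbg, ss = opt$supersample)
    }
  }

  fid <- fiducials(lay)
  fprops <- regions[regions$region == "fiducial", ]
  if (nrow(fid) && nrow(fprops)) {
    sfid <- regionSignal(fprops[1, ], acq, index, opt)
    ctrs <- applyDistortion(dist, as.matrix(fid[, c("x", "y", "z")]))
    for (k in seq_len(nrow(fid)))
      arr <- paintSphere(arr, axes, ctrs[k, ], fid$inner_diameter[k] / 2,
                         sfid, ss = opt$supersample)
  }

  arrs <- lay@arrays
  aprops <- regions[regions$region == "array", ]
  if (nrow(arrs) && nrow(aprops)) {
    ctrs <- applyDistortion(dist, as.matrix(arrs[, c("x", "y", "z")]))
    for (k in seq_len(nrow(arrs))) {
      p <- aprops[aprops$array == arrs$array[k] &
                    aprops$element == arrs$element[k], ]
      if (!nrow(p)) next
      s <- regionSignal(p[1, ], acq, index, opt)
      arr <- paintSphere(arr, axes, ctrs[k, ], arrs$inner_diameter[k] / 2,
                         s, ss = opt$supersample)
    }
  }

  if (config@bias$kind != "uniform" || config@bias$gain != 1) {
    gx <- expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]])
    gain <- biasAt(config@bias, as.matrix(gx))
    arr <- arr * array(gain, dims)
  }

  noise <- config@noise
  if (noise$sigma > 0 && noise$kind != "none") {
    old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(as.integer(noise$seed) + 1000L * (index - 1L) +
               100000L * (rep_index - 1L))
    arr <- applyNoise(arr, noise$sigma, noise$kind)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  }

  meta <- list(sequence = acq$sequence, TR_ms = acq$TR_ms, TE_ms = acq$TE_ms,
               series = acq$sequence, rep = rep_index)
  if (acq$sequence == "IR_SE") meta$TI_ms <- acq$TI_ms[index]
  if (acq$sequence == "SPGR_VFA") meta$flip_deg <- acq$flip_deg[index]
  if (acq$sequence == "SE") meta$TE_ms <- acq$TE_ms[min(index, length(acq$TE_ms))]
  if (acq$sequence == "GRE3D") meta$flip_deg <- acq$flip_deg[1]
  imageVolume(arr, vox, acq$origin_mm, meta = meta)
}

#' Render a full synthetic series
#'
#' One volume per TI (IR), TE (SE), or flip angle (VFA); for single-contrast
#' acquisitions with `repeats` set (the SNR protocol), that many replicate
#' volumes differing only in their noise draws.
#'
#' @param config a [SimulationConfig-class].
#' @return list of [ImageVolume-class] objects, series-sorted.
#' @export
renderSeries <- function(config) {
  acq <- config@acquisition
  n <- switch(acq$sequence,
    IR_SE = length(acq$TI_ms),
    SE = length(acq$TE_ms),
    SPGR_VFA = length(acq$flip_deg),
    GRE3D = 1L
  )
  if (is.null(n) || n == 0) stop("empty acquisition series")
  reps <- if (!is.null(acq$repeats) && n == 1L) acq$repeats else 1L
  if (reps > 1L) {
    lapply(seq_len(reps), function(r) renderVolume(config, 1L, rep_index = r))
  } else {
    lapply(seq_len(n), function(i) renderVolume(config, i))
  }
}

# ---------------------------------------------------------------------------
# Wedge (slice-profile) image rendering
# ---------------------------------------------------------------------------

#' Render the paired wedge images for slice-profile analysis
#'
#' Simulates the 2D image of the two 10-degree wedges for a slice of given
#' thickness: the in-plane signal at position x is the fraction of the
#' through-plane slice-sensitivity profile intersecting the wedge ramp
#' z = (x - x0) tan(10 deg +/- theta). A plane misalignment theta tilts one
#' ramp steeper and the other shallower. The slice profile is boxcar by
#' default or Gaussian (sigma = thickness / 2.355, i.e. matched FWHM).
#'
#' @param thickness_mm prescribed slice thickness (< wedge height 10 mm).
#' @param theta_deg misalignment of the slice plane to the wedge base.
#' @param spacing_mm in-plane pixel size.
#' @param length_mm profile length (ROI long axis, default 50 mm).
#' @param width_mm ROI short axis (averaged over, default 4 mm).
#' @param profile "boxcar" or "gaussian" slice-sensitivity profile.
#' @param noise_sigma additive Gaussian noise (relative to unit plateau).
#' @param seed RNG seed for the noise draw.
#' @return list with elements `pos` and `neg`, each a list(position_mm,
#'   image) where image is length(position) x width pixels; plus spacing_mm
#'   and the ground-truth thickness and theta.
#' @export
renderWedgeImages <- function(thickness_mm, theta_deg = 0, spacing_mm = 0.25,
                              length_mm = 50, width_mm = 4,
                              profile = c("boxcar", "gaussian"),
                              noise_sigma = 0, seed = 1L) {
  profile <- match.arg(profile)
  if (thickness_mm > 10)
    stop("slice thickness exceeds the 10 mm wedge height")
  nx <- round(length_mm / spacing_mm)
  nw <- max(1L, round(width_mm / spacing_mm))
  x <- (seq_len(nx) - 0.5) * spacing_mm - length_mm / 2
  oneWedge <- function(sgn) {
    alpha <- (10 + sgn * theta_deg) * pi / 180
    # slice centred mid-wedge-height; ramp origin placed so the edge
    # transition is centred in the ROI
    z0 <- 5
    x0 <- -z0 / tan(alpha)
    if (profile == "boxcar") {
      lo <- z0 - thickness_mm / 2
      # supersample x across the pixel for partial-volume realism
      val <- rowMeans(vapply(((1:5) - 3) / 5 * spacing_mm, function(o) {
        hh <- pmin(pmax((x + o - x0) * tan(alpha), 0), 10)
        pmin(pmax(hh - lo, 0), thickness_mm) / thickness_mm
      }, numeric(nx)))
    } else {
      sg <- thickness_mm / (2 * sqrt(2 * log(2)))
      val <- rowMeans(vapply(((1:5) - 3) / 5 * spacing_mm, function(o) {
        hh <- pmin(pmax((x + o - x0) * tan(alpha), 0), 10)
        stats::pnorm((hh - z0) / sg)
      }, numeric(nx)))
    }
    img <- matrix(rep(val, nw), nx, nw)
    if (noise_sigma > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sigma), nx, nw)
    list(position_mm = x, image = img)
  }
  if (noise_sigma > 0) set.seed(seed)
  list(pos = oneWedge(+1), neg = oneWedge(-1), spacing_mm = spacing_mm,
       truth = list(thickness_mm = thickness_mm, theta_deg = theta_deg))
}
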