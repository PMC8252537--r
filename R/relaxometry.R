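#' @include AllClasses.R utils.R
NULL

#' Extract an ROI signal series from an image series
#'
#' Pools the voxels whose centres lie within a circular/spherical ROI of
#' the given diameter about `centre_mm`, across a sorted image series, and
#' returns both the ROI-mean signal curve and the per-voxel curves. The
#' series x-variable (TI, TE or flip angle) is taken from volume metadata.
#'
#' @param volumes list of [ImageVolume-class] with consistent geometry.
#' @param centre_mm numeric(3) ROI centre in world coordinates.
#' @param roi_diameter_mm ROI diameter (default 10 mm).
#' @param recentre if TRUE, re-centre the ROI on the local intensity
#'   centroid of the first volume (parameter-array spheres carry extra
#'   positional uncertainty).
#' @return list of class "ROISeries": x, x_kind ("TI_ms","TE_ms",
#'   "flip_deg"), mean_signal, voxel_signals (voxels x series),
#'   centre_mm, roi_diameter_mm, n_voxels.
#' @export
roiSeries <- function(volumes, centre_mm, roi_diameter_mm = 10,
                      recentre = FALSE) {
  stopifnot(length(volumes) >= 1)
  v1 <- volumes[[1]]
  kind <- if (!is.null(acqMeta(v1, "TI_ms"))) "TI_ms"
          else if (!is.null(acqMeta(v1, "flip_deg"))) "flip_deg"
          else "TE_ms"
  x <- vapply(volumes, function(v) as.numeric(acqMeta(v, kind)[1]), 0)
  r <- roi_diameter_mm / 2
  sp <- voxelSpacing(v1)
  dims <- dim(imageData(v1))
  if (recentre) {
    cv <- worldToVoxel(v1, rbind(centre_mm))[1, ]
    ext <- ceiling(r / sp) + 1
    lo <- pmax(1, round(cv) - ext); hi <- pmin(dims, round(cv) + ext)
    sub <- imageData(v1)[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    w <- pmax(sub - stats::median(sub), 0)
    if (sum(w) > 0) {
      gi <- arrayInd(seq_along(w), dim(w))
      cw <- colSums(gi * as.vector(w)) / sum(w) + lo - 1
      centre_mm <- voxelToWorld(v1, rbind(cw))[1, ]
    }
  }
  cv <- worldToVoxel(v1, rbind(centre_mm))[1, ]
  ext <- ceiling(r / sp)
  lo <- pmax(1, round(cv) - ext); hi <- pmin(dims, round(cv) + ext)
  dx <- imageOrigin(v1)[1] + (lo[1]:hi[1] - 1) * sp[1] - centre_mm[1]
  dy <- imageOrigin(v1)[2] + (lo[2]:hi[2] - 1) * sp[2] - centre_mm[2]
  dz <- imageOrigin(v1)[3] + (lo[3]:hi[3] - 1) * sp[3] - centre_mm[3]
  d2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
  sel <- d2 <= r^2
  vox <- vapply(volumes, function(v) {
    sub <- imageData(v)[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    sub[sel]
  }, numeric(sum(sel)))
  ord <- order(x)
  structure(list(x = x[ord], x_kind = kind,
                 mean_signal = colMeans(vox)[ord],
                 voxel_signals = vox[, ord, drop = FALSE],
                 centre_mm = centre_mm, roi_diameter_mm = roi_diameter_mm,
                 n_voxels = sum(sel)),
            class = "ROISeries")
}

# Variable-projection coarse grid for the magnitude IR model: for each
# (T1, delta) the amplitude A enters linearly through |1-(1+d)e^(-TI/T1)|.
.irGrid <- function(ti, y, t1_grid, d_grid) {
  best <- list(sse = Inf)
  for (d in d_grid) for (t1 in t1_grid) {
    g <- abs(1 - (1 + d) * exp(-ti / t1))
    A <- sum(y * g) / sum(g^2)
    sse <- sum((y - A * g)^2)
    if (sse < best$sse) best <- list(sse = sse, T1 = t1, delta = d, A = A)
  }
  best
}

#' Fit the magnitude inversion-recovery T1 model
#'
#' Nonlinear least squares of S(TI) = |A (1 - (1 + delta) exp(-TI/T1))| to
#' magnitude ROI data (no polarity restoration; phase is assumed
#' unavailable). The optimizer is seeded from a variable-projection grid of
#' log-spaced T1 values and several inversion efficiencies to escape the
#' non-smooth signal null. Standard errors come from the Jacobian-based
#' covariance of the converged fit.
#'
#' @param TI_ms inversion times (ms), at least 4.
#' @param signal magnitude ROI signal at each TI.
#' @param TR_ms optional repetition time; a fitted T1 close to or above TR
#'   triggers a warning (model assumes TR >> T1).
#' @param delta_max upper bound on the inversion efficiency (default 1.2).
#' @return list of class "T1IRFit": T1_ms, A, delta, se (named vector),
#'   deviation of each point, converged, n_points.
#' @export
fitT1IR <- function(TI_ms, signal, TR_ms = NULL, delta_max = 1.2) {
  if (inherits(TI_ms, "ROISeries")) {
    signal <- TI_ms$mean_signal
    TI_ms <- TI_ms$x
  }
  stopifnot(length(TI_ms) == length(signal))
  if (length(TI_ms) < 4) stop("need at least 4 TI points")
  t1_grid <- exp(seq(log(10), log(5000), length.out = 40))
  d_grid <- c(0.7, 0.85, 1, 1.1)
  g0 <- .irGrid(TI_ms, signal, t1_grid, d_grid)
  dat <- data.frame(TI = TI_ms, y = signal)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ abs(A * (1 - (1 + d) * exp(-TI / T1))), data = dat,
                      start = list(A = g0$A, d = g0$delta, T1 = g0$T1),
                      lower = c(A = 0, d = 0, T1 = 1e-3),
                      upper = c(A = Inf, d = delta_max, T1 = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(T1_ms = g0$T1, A = g0$A, delta = g0$delta,
                se = c(A = NA_real_, delta = NA_real_, T1_ms = NA_real_),
                converged = FALSE, n_points = length(TI_ms))
  } else {
    cf <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, 3))
    out <- list(T1_ms = unname(cf["T1"]), A = unname(cf["A"]),
                delta = unname(cf["d"]),
                se = c(A = unname(se["A"]), delta = unname(se["d"]),
                       T1_ms = unname(se["T1"])),
                converged = TRUE, n_points = length(TI_ms))
  }
  if (!is.null(TR_ms) && out$T1_ms > TR_ms / 3)
    warning("fitted T1 (", round(out$T1_ms), " ms) is not << TR (", TR_ms,
            " ms); IR model assumes full recovery between repetitions")
  class(out) <- "T1IRFit"
  out
}

#' Voxel-wise T1 map over an ROI, then average
#'
#' Fits the magnitude IR model independently to every voxel of an ROI
#' series, forms the T1 map, and averages the T1 values (not the signals).
#'
#' @param series an "ROISeries" from [roiSeries()].
#' @param ... passed to [fitT1IR()].
#' @return list: T1_ms (mean of voxel T1s), sd_ms, voxel_T1_ms, n_voxels.
#' @export
fitT1IRVoxelMap <- function(series, ...) {
  vm <- series$voxel_signals
  t1 <- apply(vm, 1, function(y) {
    f <- suppressWarnings(fitT1IR(series$x, y, ...))
    if (f$converged) f$T1_ms else NA_real_
  })
  list(T1_ms = mean(t1, na.rm = TRUE), sd_ms = stats::sd(t1, na.rm = TRUE),
       voxel_T1_ms = t1, n_voxels = length(t1))
}

#' Fit the variable-flip-angle (spoiled GRE) T1 model
#'
#' Nonlinear least squares of S(alpha) = S90 sin(a)(1 - E)/(1 - E cos(a)),
#' E = exp(-TR/T1), initialized from the standard linearization
#' S/sin(a) = E * S/tan(a) + S90 (1 - E).
#'
#' @param flip_deg flip angles in degrees (>= 2 distinct).
#' @param signal ROI signal at each flip angle.
#' @param TR_ms repetition time (ms), required.
#' @return list of class "VFAFit": T1_ms, S90, se, converged, ernst_deg.
#' @export
fitT1VFA <- function(flip_deg, signal, TR_ms) {
  if (inherits(flip_deg, "ROISeries")) {
    signal <- flip_deg$mean_signal
    flip_deg <- flip_deg$x
  }
  if (length(unique(flip_deg)) < 2) stop("need at least 2 distinct flip angles")
  if (missing(TR_ms) || TR_ms <= 0) stop("TR must be known and positive")
  a <- flip_deg * pi / 180
  yl <- signal / sin(a); xl <- signal / tan(a)
  lf <- stats::lm(yl ~ xl)
  E0 <- min(max(stats::coef(lf)[2], 1e-6), 1 - 1e-6)
  T10 <- -TR_ms / log(E0)
  S900 <- max(stats::coef(lf)[1] / (1 - E0), max(signal))
  dat <- data.frame(a = a, y = signal)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ S90 * sin(a) * (1 - exp(-TR_ms / T1)) /
        (1 - exp(-TR_ms / T1) * cos(a)),
      data = dat, start = list(S90 = S900, T1 = T10),
      lower = c(S90 = 0, T1 = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(T1_ms = T10, S90 = S900,
                se = c(S90 = NA_real_, T1_ms = NA_real_), converged = FALSE)
  } else {
    cf <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, 2))
    out <- list(T1_ms = unname(cf["T1"]), S90 = unname(cf["S90"]),
                se = c(S90 = unname(se["S90"]), T1_ms = unname(se["T1"])),
                converged = TRUE)
  }
  out$ernst_deg <- ernstAngle(TR_ms, out$T1_ms)
  if (all(flip_deg < out$ernst_deg) || all(flip_deg > out$ernst_deg))
    warning("all flip angles lie on one side of the Ernst angle (",
            round(out$ernst_deg, 1), " deg): T1 is ill-conditioned")
  class(out) <- "VFAFit"
  out
}

#' Fit the spin-echo T2 decay with noise-floor exclusion
#'
#' Nonlinear least squares of S(TE) = S0 exp(-TE/T2). Points at or below
#' the noise floor are excluded (long-TE magnitude data are Rician-biased
#' toward the floor), and the first echo can optionally be dropped (it is
#' frequently anomalous on spin-echo protocols). Exclusions are recorded
#' with their reason.
#'
#' @param TE_ms echo times (ms).
#' @param signal ROI signal at each TE.
#' @param floor noise-floor level in signal units (see [noiseFloor()]), or
#'   NULL for no floor exclusion.
#' @param drop_first drop the first (shortest-TE) point.
#' @return list of class "T2Fit": T2_ms, S0, se, n_points_used,
#'   excluded (data.frame TE_ms, reason), converged.
#' @export
fitT2SE <- function(TE_ms, signal, floor = NULL, drop_first = FALSE) {
  if (inherits(TE_ms, "ROISeries")) {
    signal <- TE_ms$mean_signal
    TE_ms <- TE_ms$x
  }
  excl <- data.frame(TE_ms = numeric(0), reason = character(0))
  keep <- rep(TRUE, length(TE_ms))
  if (drop_first) {
    i <- which.min(TE_ms)
    keep[i] <- FALSE
    excl <- rbind(excl, data.frame(TE_ms = TE_ms[i], reason = "first_echo"))
  }
  if (!is.null(floor)) {
    below <- keep & signal <= floor
    if (any(below)) {
      excl <- rbind(excl, data.frame(TE_ms = TE_ms[below],
                                     reason = "below_noise_floor"))
      keep[below] <- FALSE
    }
  }
  if (sum(keep) < 3) stop("fewer than 3 usable echo points after exclusions")
  te <- TE_ms[keep]; y <- signal[keep]
  pos <- y > 0
  lf <- stats::lm(log(y[pos]) ~ te[pos])
  T20 <- max(-1 / stats::coef(lf)[2], 1)
  S00 <- unname(exp(stats::coef(lf)[1]))
  dat <- data.frame(te = te, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ S0 * exp(-te / T2), data = dat,
                      start = list(S0 = S00, T2 = T20),
                      lower = c(S0 = 0, T2 = 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(T2_ms = T20, S0 = S00,
                se = c(S0 = NA_real_, T2_ms = NA_real_), converged = FALSE)
  } else {
    cf <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, 2))
    out <- list(T2_ms = unname(cf["T2"]), S0 = unname(cf["S0"]),
                se = c(S0 = unname(se["S0"]), T2_ms = unname(se["T2"])),
                converged = TRUE)
  }
  out$n_points_used <- sum(keep)
  out$excluded <- excl
  class(out) <- "T2Fit"
  out
}

#' Noise-floor estimate from a signal-free background region
#'
#' mean + `multiplier` x SD of the background sample; points below this
#' level are excluded from T2 fits.
#'
#' @param background numeric vector of background voxel values.
#' @param multiplier SD multiplier (default 2).
#' @return scalar floor level.
#' @export
noiseFloor <- function(background, multiplier = 2) {
  mean(background) + multiplier * stats::sd(background)
}

#' Percent deviation of a measured value from its reference
#'
#' 100 * (measured - reference) / reference, signed.
#'
#' @param measured,reference numeric (reference > 0, non-missing).
#' @return signed percent deviation.
#' @export
deviation <- function(measured, reference) {
  if (any(is.na(reference)) || any(reference <= 0))
    stop("reference value missing or non-positive")
  100 * (measured - reference) / reference
}

#' Fit a relaxivity line through rate-versus-concentration data
#'
#' Relaxation rates (1000/T, 1/s) are modelled as linear in the
#' paramagnetic salt concentration: R(C) = r * C + R_water, with the
#' zero-concentration intercept fixed to the measured high-purity-water
#' rate (default) or left free.
#'
#' @param concentration_mM salt concentrations (>= 0).
#' @param times_ms measured relaxation times (ms).
#' @param water_rate_s water rate (1/s) for the fixed intercept, or NULL to
#'   fit the intercept freely.
#' @return list of class "RelaxivityFit": r_per_mM_s, r_se, intercept_s,
#'   residuals_s, fixed_intercept.
#' @export
fitRelaxivity <- function(concentration_mM, times_ms, water_rate_s = NULL) {
  if (any(concentration_mM < 0)) stop("concentrations must be non-negative")
  if (length(concentration_mM) < 2) stop("need at least 2 concentrations")
  rate <- 1000 / times_ms
  if (is.null(water_rate_s)) {
    f <- stats::lm(rate ~ concentration_mM)
    out <- list(r_per_mM_s = unname(stats::coef(f)[2]),
                r_se = suppressWarnings(summary(f)$coefficients[2, 2]),
                intercept_s = unname(stats::coef(f)[1]),
                residuals_s = unname(stats::residuals(f)),
                df_residual = f$df.residual,
                fixed_intercept = FALSE)
  } else {
    y <- rate - water_rate_s
    f <- stats::lm(y ~ 0 + concentration_mM)
    out <- list(r_per_mM_s = unname(stats::coef(f)[1]),
                r_se = suppressWarnings(summary(f)$coefficients[1, 2]),
                intercept_s = water_rate_s,
                residuals_s = unname(stats::residuals(f)),
                df_residual = f$df.residual,
                fixed_intercept = TRUE)
  }
  class(out) <- "RelaxivityFit"
  out
}

#' Relaxometry analysis of a parameter array
#'
#' Extracts the 14 ROI series of one MR parameter array (nominal centres
#' mapped through the fiducial similarity transform, optionally re-centred
#' on the local centroid), fits the requested model per element, and
#' reports values, standard errors, and percent deviation from reference.
#'
#' @param volumes sorted image series (list of [ImageVolume-class]).
#' @param layout a [PhantomLayout-class].
#' @param kind which array: "NiCl2", "MnCl2", "PD".
#' @param model "t1_ir", "t1_vfa", or "t2_se".
#' @param transform optional [SimilarityTransform-class] (default identity).
#' @param reference reference table from [referenceTable()].
#' @param mode "roi_mean" or "voxel_map" (IR only).
#' @param TR_ms repetition time (VFA).
#' @param ... further arguments to the fit function (e.g. `floor`,
#'   `drop_first` for T2).
#' @return data.frame: element, value_ms, se_ms, extra (delta or S0),
#'   reference_ms, deviation_pct, n_points.
#' @export
relaxometryAnalysis <- function(volumes, layout, kind, model,
                                transform = NULL, reference = referenceTable(),
                                mode = c("roi_mean", "voxel_map"),
                                TR_ms = NULL, ...) {
  mode <- match.arg(mode)
  arr <- parameterArray(layout, kind)
  ctrs <- as.matrix(arr[, c("x", "y", "z")])
  if (!is.null(transform)) ctrs <- applyTransform(transform, ctrs)
  ref <- reference[reference$array == kind, ]
  rows <- lapply(seq_len(nrow(arr)), function(i) {
    el <- arr$element[i]
    na_row <- data.frame(element = el, value_ms = NA_real_, se_ms = NA_real_,
                         extra = NA_real_, reference_ms = NA_real_,
                         deviation_pct = NA_real_, n_points = 0L)
    ser <- tryCatch(roiSeries(volumes, ctrs[i, ],
                              recentre = !is.null(transform)),
                    error = function(e) NULL)
    # elements outside the imaged FOV are reported as missing, not errors
    if (is.null(ser) || ser$n_voxels == 0 ||
        !all(is.finite(ser$mean_signal))) return(na_row)
    refv <- switch(model,
      t1_ir = , t1_vfa = ref$T1_ms[match(el, ref$element)],
      t2_se = ref$T2_ms[match(el, ref$element)])
    tryCatch({
    if (model == "t1_ir" && mode == "voxel_map") {
      f <- fitT1IRVoxelMap(ser)
      val <- f$T1_ms; se <- f$sd_ms / sqrt(f$n_voxels); extra <- NA; np <- length(ser$x)
    } else if (model == "t1_ir") {
      f <- fitT1IR(ser$x, ser$mean_signal, ...)
      val <- f$T1_ms; se <- f$se["T1_ms"]; extra <- f$delta; np <- f$n_points
    } else if (model == "t1_vfa") {
      f <- fitT1VFA(ser$x, ser$mean_signal, TR_ms = TR_ms)
      val <- f$T1_ms; se <- f$se["T1_ms"]; extra <- f$S90; np <- length(ser$x)
    } else if (model == "t2_se") {
      f <- fitT2SE(ser$x, ser$mean_signal, ...)
      val <- f$T2_ms; se <- f$se["T2_ms"]; extra <- f$S0; np <- f$n_points_used
    } else stop("unknown model: ", model)
    data.frame(element = el, value_ms = val, se_ms = unname(se),
               extra = unname(extra), reference_ms = refv,
               deviation_pct = if (!is.na(refv)) deviation(val, refv) else NA,
               n_points = np)
    }, error = function(e) na_row)
  })
  do.call(rbind, rows)
}
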