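#' @include AllClasses.R utils.R
NULL

#' Edge response function of a wedge ROI
#'
#' Averages the 4 mm x 50 mm rectangular wedge ROI across its short axis to
#' a 1D edge response function (ERF), and differentiates it with respect to
#' image position (central differences, optional 3-point smoothing). The
#' derivative, after angle correction, is the slice profile. The derivative
#' is invariant to additive image offsets.
#'
#' @param image matrix (positions along the ROI long axis x width pixels),
#'   or a wedge element from [renderWedgeImages()] (list with position_mm
#'   and image).
#' @param position_mm positions of the rows of `image` (mm); taken from the
#'   list input if omitted.
#' @param smooth apply 3-point box smoothing to the derivative (reported,
#'   because smoothing biases the FWHM).
#' @return list of class "EdgeResponse": position_mm, erf, deriv, smoothed.
#' @export
edgeResponse <- function(image, position_mm = NULL, smooth = FALSE) {
  if (is.list(image) && !is.null(image$image)) {
    position_mm <- image$position_mm
    image <- image$image
  }
  if (is.null(position_mm)) stop("position_mm required")
  erf <- rowMeans(image)
  n <- length(erf)
  if (n < 5) stop("ROI too short")
  d <- numeric(n)
  d[2:(n - 1)] <- (erf[3:n] - erf[1:(n - 2)]) /
    (position_mm[3:n] - position_mm[1:(n - 2)])
  d[1] <- d[2]; d[n] <- d[n - 1]
  if (smooth)
    d <- stats::filter(d, rep(1 / 3, 3), sides = 2) |> as.numeric() |>
      (\(x) { x[is.na(x)] <- d[is.na(x)]; x })()
  structure(list(position_mm = position_mm, erf = erf, deriv = d,
                 smoothed = smooth),
            class = "EdgeResponse")
}

# Plane-misalignment angle from the two projected widths (degrees).
# w1 is from the positive-inclination wedge, w2 from the negative.
wedgeTheta <- function(w1, w2, wedge_angle_deg = 10) {
  0.5 * asin((w2 - w1) * sin(2 * wedge_angle_deg * pi / 180) / (w2 + w1)) *
    180 / pi
}

#' Slice thickness by the NEMA wedge method
#'
#' The projected widths w1, w2 of the two opposed 10-degree wedges are the
#' FWHMs of the differentiated edge responses. The slice-plane misalignment
#' is theta = 1/2 asin[(w2 - w1) sin(2 * 10 deg) / (w2 + w1)]; each wedge's
#' corrected angle is alpha = 10 deg +/- theta, and multiplying image
#' position by tan(alpha) converts the derivative into the slice profile,
#' whose FWHM is the slice thickness (averaged over both wedges).
#'
#' @param profile_pos,profile_neg "EdgeResponse" objects for the positive
#'   and negative inclination wedges.
#' @param wedge_angle_deg nominal wedge angle (10).
#' @param max_thickness_mm wedge height bound; computed thicknesses above
#'   it are rejected (default 10 mm).
#' @return list of class "SliceProfileResult": t_sl_mm, theta_deg, w1_mm,
#'   w2_mm, profile (position mm -> relative excitation, angle-corrected),
#'   method = "nema".
#' @export
nemaThickness <- function(profile_pos, profile_neg, wedge_angle_deg = 10,
                          max_thickness_mm = 10) {
  w1 <- fwhmLinear(profile_pos$position_mm, profile_pos$deriv)
  w2 <- fwhmLinear(profile_neg$position_mm, profile_neg$deriv)
  if (is.na(w1) || is.na(w2))
    stop("edge-response derivative does not cross half maximum on both sides")
  th <- wedgeTheta(w1, w2, wedge_angle_deg)
  a1 <- (wedge_angle_deg + th) * pi / 180
  a2 <- (wedge_angle_deg - th) * pi / 180
  t1 <- fwhmLinear(profile_pos$position_mm * tan(a1), profile_pos$deriv)
  t2 <- fwhmLinear(profile_neg$position_mm * tan(a2), profile_neg$deriv)
  t_sl <- (t1 + t2) / 2
  if (t_sl > max_thickness_mm)
    stop("measured thickness ", round(t_sl, 2),
         " mm exceeds the 10 mm wedge height")
  prof <- data.frame(
    position_mm = profile_pos$position_mm * tan(a1),
    excitation = profile_pos$deriv / max(profile_pos$deriv))
  structure(list(t_sl_mm = t_sl, theta_deg = th, w1_mm = w1, w2_mm = w2,
                 profile = prof, method = "nema"),
            class = "SliceProfileResult")
}

# Continuous flat-ramp-flat model; linear in (lo, hi) given breakpoints.
.rampFit <- function(x, y, b1, b2) {
  r <- pmin(pmax((x - b1) / (b2 - b1), 0), 1)
  f <- stats::lm.fit(cbind(1 - r, r), y)
  list(sse = sum(f$residuals^2), lo = f$coefficients[1],
       hi = f$coefficients[2])
}

# Fit one ERF with a flat-ramp-flat piecewise linear model. Breakpoints by
# coarse grid (from the 10/90 % crossings) then Nelder-Mead refinement.
# Returns w = b2 - b1 with a covariance-based uncertainty.
fitRamp <- function(position_mm, erf, min_ramp_samples = 3) {
  x <- position_mm; y <- erf
  lo0 <- stats::quantile(y, 0.02); hi0 <- stats::quantile(y, 0.98)
  lev <- function(p) lo0 + p * (hi0 - lo0)
  up <- y[length(y)] > y[1]
  cross <- function(level) {
    s <- if (up) y else -y
    l <- if (up) level else -level
    i <- which(s >= l)[1]
    if (is.na(i) || i == 1) return(x[1])
    x[i - 1] + (l - s[i - 1]) / (s[i] - s[i - 1]) * (x[i] - x[i - 1])
  }
  b1g <- cross(lev(0.1)); b2g <- cross(lev(0.9))
  if (b2g <= b1g) { b1g <- x[2]; b2g <- x[length(x) - 1] }
  span <- b2g - b1g
  obj <- function(p) {
    if (p[2] - p[1] < 1e-3) return(1e12)
    .rampFit(x, y, p[1], p[2])$sse
  }
  # coarse grid around the crossing-based guess
  cand <- expand.grid(b1 = b1g + seq(-0.5, 0.5, length.out = 7) * span * 0.5,
                      b2 = b2g + seq(-0.5, 0.5, length.out = 7) * span * 0.5)
  sse <- apply(cand, 1, obj)
  p0 <- as.numeric(cand[which.min(sse), ])
  opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  b1 <- opt$par[1]; b2 <- opt$par[2]
  dx <- mean(diff(x))
  if ((b2 - b1) / dx < min_ramp_samples)
    stop("ramp shorter than ", min_ramp_samples, " samples")
  fit <- .rampFit(x, y, b1, b2)
  n <- length(y)
  sigma2 <- opt$value / max(1, n - 4)
  # numerical Hessian of the SSE in (b1, b2); cov = 2 sigma^2 H^-1
  h <- max(dx / 4, 1e-3)
  H <- matrix(0, 2, 2)
  f0 <- obj(c(b1, b2))
  for (i in 1:2) for (j in 1:2) {
    ei <- c(0, 0); ei[i] <- h
    ej <- c(0, 0); ej[j] <- h
    H[i, j] <- (obj(c(b1, b2) + ei + ej) - obj(c(b1, b2) + ei) -
                  obj(c(b1, b2) + ej) + f0) / h^2
  }
  covb <- tryCatch(2 * sigma2 * solve(H), error = function(e)
    matrix(NA_real_, 2, 2))
  w_se <- sqrt(max(0, covb[1, 1] + covb[2, 2] - 2 * covb[1, 2]))
  list(w = b2 - b1, w_se = w_se, b1 = b1, b2 = b2,
       lo = fit$lo, hi = fit$hi, sse = opt$value)
}

#' Slice thickness by the automated piecewise-linear method
#'
#' Fits each wedge's edge response with a continuous flat-ramp-flat
#' piecewise-linear function (breakpoints free, plateau levels profiled
#' out), takes the projected widths w = ramp length, and converts to slice
#' thickness t = (w1 + w2)/2 * tan(10 deg). Averaging the two opposed
#' wedges cancels the first-order misalignment error; theta is reported
#' from the same width pair. The uncertainty comes from the breakpoint
#' covariance of the fits.
#'
#' @param erf_pos,erf_neg "EdgeResponse" objects (positive / negative
#'   inclination wedge).
#' @param wedge_angle_deg nominal wedge angle (10).
#' @param max_thickness_mm wedge height bound (10 mm); larger results are
#'   rejected.
#' @return list of class "SliceProfileResult": t_sl_mm (the first-order
#'   formula above), t_corrected_mm (per-wedge angle-corrected thickness
#'   (w1 tan(10 + theta) + w2 tan(10 - theta))/2, exact in theta), t_se_mm,
#'   theta_deg, w1_mm, w2_mm, method = "automated".
#' @export
automatedThickness <- function(erf_pos, erf_neg, wedge_angle_deg = 10,
                               max_thickness_mm = 10) {
  f1 <- fitRamp(erf_pos$position_mm, erf_pos$erf)
  f2 <- fitRamp(erf_neg$position_mm, erf_neg$erf)
  w1 <- f1$w; w2 <- f2$w
  tn <- tan(wedge_angle_deg * pi / 180)
  t_sl <- (w1 + w2) / 2 * tn
  if (t_sl > max_thickness_mm)
    stop("measured thickness ", round(t_sl, 2),
         " mm exceeds the 10 mm wedge height")
  t_se <- tn / 2 * sqrt(sum(c(f1$w_se, f2$w_se)^2, na.rm = TRUE))
  th <- wedgeTheta(w1, w2, wedge_angle_deg)
  t_corr <- (w1 * tan((wedge_angle_deg + th) * pi / 180) +
               w2 * tan((wedge_angle_deg - th) * pi / 180)) / 2
  structure(list(t_sl_mm = t_sl, t_corrected_mm = t_corr, t_se_mm = t_se,
                 theta_deg = th, w1_mm = w1, w2_mm = w2,
                 method = "automated"),
            class = "SliceProfileResult")
}

#' Full slice-profile analysis of a wedge image pair
#'
#' Computes both the NEMA derivative-FWHM thickness and the automated
#' piecewise-linear thickness from a rendered or measured wedge image pair.
#'
#' @param wedges list with `pos` and `neg` wedge images (as produced by
#'   [renderWedgeImages()]).
#' @param smooth smoothing flag passed to [edgeResponse()].
#' @return list: nema and automated "SliceProfileResult"s.
#' @export
sliceProfileAnalysis <- function(wedges, smooth = FALSE) {
  ep <- edgeResponse(wedges$pos, smooth = smooth)
  en <- edgeResponse(wedges$neg, smooth = smooth)
  list(nema = nemaThickness(ep, en), automated = automatedThickness(ep, en))
}
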