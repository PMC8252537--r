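test_that("edge response of an ideal step has an impulse derivative and offset invariance", {
  x <- seq(-10, 10, by = 0.5)
  img <- matrix(rep(as.numeric(x >= 0), 3), length(x), 3)
  er <- edgeResponse(img, x)
  expect_equal(sum(er$deriv > 1e-9), 2L)  # central difference spreads one bin each side
  er2 <- edgeResponse(img + 7, x)
  expect_equal(er2$deriv, er$deriv)
})

test_that("a boxcar slice through a 10-degree wedge gives a ramp of projected width t/tan(10)", {
  w <- renderWedgeImages(3, theta_deg = 0, spacing_mm = 0.1)
  er <- edgeResponse(w$pos)
  width <- fwhmLinear(er$position_mm, er$deriv)
  expect_equal(width, 3 / tan(10 * pi / 180), tolerance = 0.01)
})

test_that("theta formula: symmetric widths give zero, swapping wedges flips the sign", {
  w <- renderWedgeImages(3, theta_deg = 0.7, spacing_mm = 0.1)
  ep <- edgeResponse(w$pos); en <- edgeResponse(w$neg)
  r1 <- nemaThickness(ep, en)
  r2 <- nemaThickness(en, ep)
  expect_equal(r2$theta_deg, -r1$theta_deg, tolerance = 1e-6)
  expect_equal(r2$t_sl_mm, r1$t_sl_mm, tolerance = 1e-3)
  w0 <- renderWedgeImages(3, theta_deg = 0, spacing_mm = 0.1)
  r0 <- nemaThickness(edgeResponse(w0$pos), edgeResponse(w0$neg))
  expect_equal(r0$theta_deg, 0, tolerance = 1e-6)
})

test_that("simulated boxcar slices are recovered within 2% (t) and 0.05 deg (theta)", {
  for (t in c(3, 5)) for (th in c(0.7, 2)) {
    w <- renderWedgeImages(t, theta_deg = th, spacing_mm = 0.1)
    res <- sliceProfileAnalysis(w)
    expect_lt(abs(res$nema$t_sl_mm / t - 1), 0.02)
    expect_lt(abs(res$nema$theta_deg - th), 0.05)
    expect_lt(abs(res$automated$t_corrected_mm / t - 1), 0.02)
    expect_lt(abs(res$automated$theta_deg - th), 0.05)
    # the first-order formula carries its theta^2/sin^2(10 deg) bias
    bias <- (th * pi / 180)^2 / sin(10 * pi / 180)^2
    expect_lt(abs(res$automated$t_sl_mm / t - 1), bias + 0.02)
  }
  # at small misalignment the two methods agree within the automated
  # method's uncertainty
  w <- renderWedgeImages(3, theta_deg = 0.7, spacing_mm = 0.1)
  res <- sliceProfileAnalysis(w)
  expect_lt(abs(res$automated$t_sl_mm - res$nema$t_sl_mm),
            3 * res$automated$t_se_mm + 0.02 * 3)
})

test_that("the printed-width formula evaluates the symmetric and asymmetric instances", {
  # symmetric: w1 = w2 = 17.0 mm -> t = 17 tan(10) = 3.00 mm, theta = 0
  x <- seq(-25, 25, by = 0.1)
  ramp <- function(w) pmin(pmax((x + w / 2) / w, 0), 1)
  mk <- function(w) structure(list(position_mm = x, erf = ramp(w),
                                   deriv = c(0, diff(ramp(w))) / 0.1),
                              class = "EdgeResponse")
  r <- automatedThickness(mk(17), mk(17))
  expect_equal(round(r$t_sl_mm, 2), 3.00)
  expect_equal(r$theta_deg, 0, tolerance = 1e-6)
  # asymmetric: w1 = 16.6, w2 = 19.2 -> t = (35.8/2) tan(10) = 3.16 mm
  r2 <- automatedThickness(mk(16.6), mk(19.2))
  expect_equal(round(r2$t_sl_mm, 2), 3.16)
})

test_that("averaging both wedges cancels misalignment to first order (error is O(theta^2))", {
  err_at <- function(th) {
    w <- renderWedgeImages(3, theta_deg = th, spacing_mm = 0.05)
    abs(sliceProfileAnalysis(w)$automated$t_sl_mm - 3)
  }
  e1 <- err_at(1); e2 <- err_at(2)
  expect_lt(e2, 4.5 * pmax(e1, 1e-4))
})

test_that("thicknesses beyond the 10 mm wedge height are rejected", {
  expect_error(renderWedgeImages(12, 0), "wedge height")
  x <- seq(-40, 40, by = 0.2)
  big <- function(w) {
    r <- pmin(pmax((x + w / 2) / w, 0), 1)
    structure(list(position_mm = x, erf = r, deriv = c(0, diff(r)) / 0.2),
              class = "EdgeResponse")
  }
  expect_error(automatedThickness(big(65), big(65)), "wedge height")
  expect_error(nemaThickness(big(65), big(65)), "wedge height")
})
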