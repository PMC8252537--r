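fine <- buildResolutionInset("fine")

test_that("inset synthesis preserves the DC term and psf = 0 is the pure finite-k image", {
  syn0 <- synthesizeInsetImage(fine, 0.35, psf_2sigma = 0, magnitude = FALSE)
  # image integral equals the total hole area, independent of the PSF
  area <- sum(pi * (fine$diameter_mm / 2)^2)
  expect_equal(sum(syn0$image) * syn0$grid$dx^2, area, tolerance = 1e-8)
  synb <- synthesizeInsetImage(fine, 0.35, psf_2sigma = 0.2, magnitude = FALSE)
  expect_equal(sum(synb$image) * synb$grid$dx^2, area, tolerance = 1e-8)
  # psf = 0 equals the unblurred rendering exactly
  syn00 <- synthesizeInsetImage(fine, 0.35, magnitude = FALSE)
  expect_identical(syn0$image, syn00$image)
  expect_error(synthesizeInsetImage(fine, 0.35, psf_2sigma = -0.1))
})

test_that("analytic synthesis matches the independent rasterize-and-truncate oracle within 2%", {
  h8 <- fine[fine$size_mm == 0.8, ]
  syn <- synthesizeInsetImage(h8, 0.35, 0, magnitude = TRUE)
  oracle <- abs(rasterTruncationOracle(h8, syn$grid, os = 9))
  rel <- sqrt(sum((syn$image - oracle)^2) / sum(oracle^2))
  expect_lt(rel, 0.02)
})

test_that("PSF width is recovered within one grid step for widths around the machine scale", {
  widths <- seq(0, 0.2, by = 0.005)
  for (w in c(0.05, 0.075, 0.1)) {
    meas <- synthesizeInsetImage(fine, 0.35, psf_2sigma = w)$image
    est <- estimatePSF(meas, fine, 0.35, widths = widths)
    expect_lte(abs(est$psf_width_2sigma - w), 0.005)
    # residual curve has a single interior minimum
    r <- est$match_residual$residual
    dr <- diff(r)
    expect_equal(sum(diff(sign(dr)) != 0), 1L)
    expect_false(est$boundary_warning)
  }
  # self-match at psf = 0 recovers zero width
  meas0 <- synthesizeInsetImage(fine, 0.35, 0)$image
  expect_equal(estimatePSF(meas0, fine, 0.35, widths = widths)$psf_width_2sigma, 0)
})

test_that("estimated PSF width is monotone in the applied blur", {
  widths <- seq(0, 0.3, by = 0.005)
  est <- vapply(c(0.03, 0.08, 0.15, 0.25), function(w) {
    meas <- synthesizeInsetImage(fine, 0.35, psf_2sigma = w)$image
    estimatePSF(meas, fine, 0.35, widths = widths)$psf_width_2sigma
  }, 0)
  expect_true(all(diff(est) > 0))
})

test_that("resolvability follows the sampling limit: 0.5 mm resolved, 0.4 mm not, at 0.35 mm voxels", {
  syn <- synthesizeInsetImage(fine, 0.35, psf_2sigma = 0)
  acr <- acrResolvability(syn$image, fine, syn$grid)
  expect_equal(acr$acr_resolution_mm, 0.5)
  expect_false(acr$per_size$resolved[acr$per_size$size_mm == 0.4])
  expect_true(all(acr$per_size$resolved[acr$per_size$size_mm >= 0.5]))
})

test_that("heavy blur leaves no fine-inset group resolved; zero margin is monotone in hole size", {
  syn <- synthesizeInsetImage(fine, 0.35, psf_2sigma = 1.5)
  acr <- acrResolvability(syn$image, fine, syn$grid)
  expect_true(is.na(acr$acr_resolution_mm))
  # margin = 0 on a clean image: resolvability non-decreasing with size
  syn0 <- synthesizeInsetImage(fine, 0.35, psf_2sigma = 0)
  acr0 <- acrResolvability(syn0$image, fine, syn0$grid, margin = 0)
  r <- acr0$per_size$resolved[order(acr0$per_size$size_mm)]
  expect_true(all(diff(as.integer(r)) >= 0))
})

test_that("the full report separates sampling-limited and Gaussian components", {
  meas <- synthesizeInsetImage(fine, 0.35, psf_2sigma = 0.075)$image
  rep_ <- resolutionReport(meas, fine, 0.35, widths = seq(0, 0.15, 0.005))
  expect_equal(rep_$kspace_limited_resolution_mm, 0.35)
  expect_equal(rep_$psf_width_2sigma, 0.075)
  expect_equal(rep_$acr_resolution_mm, 0.5)
})
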