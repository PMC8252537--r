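test_that("inversion-recovery signal model has the correct limits and null", {
  expect_equal(signalIR(1, 407, 1e9, delta = 0.85, A_scale = 500), 500)
  # delta = 1: null at TI = T1 ln 2, and magnitude A at TI = 0
  expect_equal(signalIR(1, 300, 300 * log(2), delta = 1), 0)
  expect_equal(signalIR(0.7, 300, 0, delta = 1, A_scale = 500), 350)
  expect_error(signalIR(1, -5, 100))
})

test_that("spoiled-GRE signal saturates at S90 and peaks at the Ernst angle", {
  expect_equal(signalVFA(1, 407, 1e7, 90, S90_scale = 500), 500,
               tolerance = 1e-8)
  a <- seq(0.5, 60, by = 0.01)
  s <- signalVFA(1, 407, 5.37, a)
  expect_equal(a[which.max(s)], ernstAngle(5.37, 407), tolerance = 1e-3)
  # closed form evaluated independently: acos(exp(-5.37/407)) = 9.3 deg (2 s.f.)
  expect_equal(round(ernstAngle(5.37, 407), 1), 9.3)
  expect_error(signalVFA(1, 407, -1, 10))
})

test_that("spin-echo decay obeys the exponential identities", {
  expect_equal(signalSE(1, 100, 0, 500), 500)
  expect_equal(signalSE(1, 100, 100, 500), 500 / exp(1))
  # halving T2 squares the attenuation ratio at fixed TE
  r1 <- signalSE(1, 80, 60) / signalSE(1, 80, 0)
  r2 <- signalSE(1, 40, 60) / signalSE(1, 40, 0)
  expect_equal(r2, r1^2)
  expect_error(signalSE(1, 0, 10))
})

test_that("rasterization paints sphere volumes to within 1% at 1 mm voxels", {
  lay <- phantomLayout()
  acq <- acquisitionPreset("isotropic3D", fov_mm = 30)
  cfg <- simulationConfig(layout = lay, acquisition = acq,
                          options = list(render_background = FALSE))
  v <- renderVolume(cfg)
  s <- signalVFA(1, 407, 6.3, 10, 500)
  vol <- sum(imageData(v)) / s * prod(voxelSpacing(v))
  expect_lt(abs(vol / (4 / 3 * pi * 5^3) - 1), 0.01)
})

test_that("doubling the bias field doubles every ROI mean exactly (noise off)", {
  lay <- phantomLayout()
  acq <- acquisitionPreset("isotropic3D", fov_mm = 30)
  cfg1 <- simulationConfig(layout = lay, acquisition = acq,
                           bias = biasField("uniform", gain = 1))
  cfg2 <- simulationConfig(layout = lay, acquisition = acq,
                           bias = biasField("uniform", gain = 2))
  expect_equal(imageData(renderVolume(cfg2)), 2 * imageData(renderVolume(cfg1)))
})

test_that("Rician background mean matches the Rayleigh closed form", {
  lay <- phantomLayout()
  acq <- acquisitionPreset("isotropic3D", fov_mm = 30, centre_mm = c(110, 110, 110))
  # FOV entirely outside the shell: signal-free region
  cfg <- simulationConfig(layout = lay, acquisition = acq,
                          noise = list(sigma = 4, kind = "rician", seed = 5),
                          options = list(render_background = FALSE))
  v <- renderVolume(cfg)
  vals <- as.vector(imageData(v))
  expect_gte(length(vals), 1e4)
  expect_lt(abs(mean(vals) / (4 * sqrt(pi / 2)) - 1), 0.02)
})

test_that("renders are deterministic: identical config and seed give identical voxels", {
  lay <- phantomLayout()
  acq <- acquisitionPreset("isotropic3D", fov_mm = 24)
  cfg <- simulationConfig(layout = lay, acquisition = acq,
                          noise = list(sigma = 3, kind = "rician", seed = 42))
  expect_identical(imageData(renderVolume(cfg)), imageData(renderVolume(cfg)))
})

test_that("series rendering yields one volume per TI/TE with metadata, and repeats differ only in noise", {
  lay <- phantomLayout()
  small <- function(name) {
    a <- acquisitionPreset(name)
    a$fov_mm <- c(24, 24, 24); a$centre_mm <- c(0, -66, 0)
    a$matrix <- pmax(2L, as.integer(round(a$fov_mm / a$voxel_mm)))
    a$origin_mm <- a$centre_mm - (a$matrix - 1) / 2 * a$voxel_mm
    a
  }
  ir <- renderSeries(simulationConfig(layout = lay, acquisition = small("t1_ir")))
  expect_length(ir, 10L)
  tis <- vapply(ir, function(v) acqMeta(v, "TI_ms"), 0)
  expect_equal(tis[c(1, 10)], c(50, 3000))
  expect_equal(tis, sort(tis))
  se <- acquisitionPreset("t2_se")
  expect_equal(se$TE_ms, seq(10, 320, by = 10))
  # SNR protocol: two replicates, same signal, different noise draws
  ps <- small("pd_snr")
  reps <- renderSeries(simulationConfig(
    layout = lay, acquisition = ps,
    noise = list(sigma = 2, kind = "rician", seed = 9)))
  expect_length(reps, 2L)
  expect_false(identical(imageData(reps[[1]]), imageData(reps[[2]])))
  # noiseless replicates are identical by construction
  reps0 <- renderSeries(simulationConfig(layout = lay, acquisition = ps))
  expect_identical(imageData(reps0[[1]]), imageData(reps0[[2]]))
})

test_that("unresolvable geometry (voxel >= sphere diameter) is refused", {
  lay <- phantomLayout()
  acq <- acquisitionPreset("isotropic3D", voxel_mm = 16, fov_mm = 64)
  cfg <- simulationConfig(layout = lay, acquisition = acq)
  expect_error(renderVolume(cfg), "unresolvable")
})

test_that("distortion fields compose similarity and polynomial parts; zero field is the identity", {
  pts <- matrix(c(10, -20, 30, 0, 0, 0, 50, 50, -50), 3, 3, byrow = TRUE)
  expect_equal(applyDistortion(distortionField(), pts), pts)
  poly <- data.frame(axis = 1, px = 2, py = 0, pz = 0, coef_mm = 2)
  fld <- distortionField(scale = 1.01, translation_mm = c(1, 0, 0), poly = poly)
  out <- applyDistortion(fld, pts)
  expect_equal(out[, 1], 1.01 * pts[, 1] + 1 + 2 * (pts[, 1] / 100)^2)
  expect_equal(out[, 2], 1.01 * pts[, 2])
})
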