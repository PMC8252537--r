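test_that("an image identical to the kernel at a lattice point localizes with zero offset", {
  kern <- sphereKernel(10, c(1, 1, 1))
  img <- array(0, c(41, 41, 41))
  kd <- dim(kern)
  ctr <- c(21, 21, 21)
  lo <- ctr - (kd - 1) / 2
  img[lo[1]:(lo[1] + kd[1] - 1), lo[2]:(lo[2] + kd[2] - 1),
      lo[3]:(lo[3] + kd[3] - 1)] <- kern - min(kern)
  v <- imageVolume(img, c(1, 1, 1), origin = -c(20, 20, 20))
  loc <- locateSpheres(v, oneSphere(c(0, 0, 0)), search_mm = 8)
  expect_equal(c(loc$xa, loc$ya, loc$za), c(0, 0, 0), tolerance = 1e-8)
})

test_that("a noiseless sub-voxel offset is recovered within 0.05 mm", {
  lay <- phantomLayout()
  acq <- acquisitionPreset("isotropic3D", fov_mm = 30)
  offs <- list(c(0.41, 0.44, -0.21), c(-0.33, 0.05, 0.49))
  for (off in offs) {
    cfg <- simulationConfig(layout = lay, acquisition = acq,
                            distortion = distortionField(translation_mm = off),
                            options = list(render_background = FALSE))
    v <- renderVolume(cfg)
    loc <- locateSpheres(v, oneSphere(c(0, 0, 0)), search_mm = 6)
    err <- sqrt(sum((c(loc$xa, loc$ya, loc$za) - off)^2))
    expect_lt(err, 0.05)
  }
})

test_that("similarity fit solves the trivial and constructed instances exactly", {
  set.seed(11)
  P <- matrix(rnorm(30, sd = 50), 10, 3)
  # identity
  tr <- fitSimilarity(P, P)
  expect_equal(tr@rotation, diag(3), tolerance = 1e-12)
  expect_equal(tr@translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(tr@scale, 1, tolerance = 1e-12)
  # pure shift
  tr <- fitSimilarity(P, sweep(P, 2, c(3, -2, 1), "+"))
  expect_equal(tr@translation, c(3, -2, 1), tolerance = 1e-10)
  expect_equal(tr@scale, 1, tolerance = 1e-12)
  # scaled rotation: s = 1.01, random proper rotation, recovered to machine precision
  R0 <- rotationMatrix(c(1, 2, 3), 25)
  A <- 1.01 * t(R0 %*% t(P))
  tr <- fitSimilarity(P, A)
  expect_equal(tr@scale, 1.01, tolerance = 1e-12)
  expect_equal(tr@rotation, R0, tolerance = 1e-12)
  # contract errors
  expect_error(fitSimilarity(P[1:3, ], P[1:3, ]), "4 point")
  Pplane <- cbind(P[, 1:2], 0)
  expect_error(fitSimilarity(Pplane, Pplane), "degenerate")
})

test_that("closed-form Procrustes equals the brute-force least-squares oracle on random instances", {
  set.seed(7)
  for (rep in 1:10) {
    P <- matrix(rnorm(30, sd = 40), 10, 3)
    R0 <- rotationMatrix(rnorm(3), runif(1, -20, 20))
    s0 <- runif(1, 0.95, 1.05)
    A <- s0 * t(R0 %*% t(P)) +
      matrix(rnorm(3, sd = 5), 10, 3, byrow = TRUE) +
      matrix(rnorm(30, sd = 0.1), 10, 3)  # noise so the optimum is non-trivial
    cf <- fitSimilarity(P, A)
    bf <- bruteForceSimilarity(P, A)
    sse_cf <- sum((A - applyTransform(cf, P))^2)
    expect_lt(abs(sse_cf - bf$sse) / bf$sse, 1e-8)
    expect_equal(cf@scale, bf$scale, tolerance = 1e-4)
  }
})

test_that("distortion report carries the sign convention and absorbs the mean displacement", {
  # synthetic localization table: exact apparent = prescribed, one sphere
  # pushed +1 mm in x beyond the global fit
  f <- buildFiducialLattice()
  loc <- data.frame(id = f$id, group = f$group, x = f$x, y = f$y, z = f$z,
                    xa = f$x, ya = f$y, za = f$z,
                    corr_peak = 1, integrated_intensity = 1, flag = "")
  loc$xa[loc$id == 1] <- loc$x[loc$id == 1] + 1
  tr <- fitSimilarity(as.matrix(loc[, c("x", "y", "z")]),
                      as.matrix(loc[, c("xa", "ya", "za")]))
  rep_ <- computeDistortion(loc, tr)
  d <- rep_$per_sphere
  expect_gt(d$dx[d$id == 1], 0.9)    # positive x displacement keeps its sign
  expect_lt(abs(mean(d$dx)), 1e-6)   # translation absorbed by the fit
  expect_lt(abs(mean(d$dy)), 1e-6)
})

test_that("uniformity normalizes to the maximum unflagged sphere and excludes flagged ones", {
  loc <- data.frame(id = 1:5, group = "g", x = 0, y = 0, z = 1:5,
                    xa = 0, ya = 0, za = 1:5, corr_peak = 1,
                    integrated_intensity = c(10, 8, 6, 4, 100),
                    flag = c("", "", "", "", "bubble"))
  u <- computeUniformity(loc)
  expect_equal(max(u$normalized, na.rm = TRUE), 1)
  expect_equal(u$normalized[1], 1)           # max unflagged is the reference
  expect_true(is.na(u$normalized[5]))        # flagged excluded
})

test_that("a linear bias field produces monotone uniformity ordering along its axis", {
  lay <- phantomLayout()
  f <- buildFiducialLattice()
  sub <- f[f$x == 0 & f$z == 0, ]            # five spheres along y
  lay2 <- lay; lay2@fiducials <- sub; lay2@arrays <- lay@arrays[0, ]
  acq <- acquisitionPreset("isotropic3D", fov_mm = c(30, 190, 30))
  cfg <- simulationConfig(layout = lay2, acquisition = acq,
                          bias = biasField("linear", axis = c(0, 1, 0),
                                           slope_per_100mm = 0.4),
                          options = list(render_background = FALSE))
  v <- renderVolume(cfg)
  loc <- locateSpheres(v, sub, search_mm = 6)
  u <- computeUniformity(loc)
  ord <- order(u$y)
  expect_equal(u$normalized[ord], sort(u$normalized))
})

test_that("volume distortion ratio is 1 for an undistorted render and scales as the cube", {
  lay <- phantomLayout()
  acq <- acquisitionPreset("isotropic3D", fov_mm = 34)
  cfg <- simulationConfig(layout = lay, acquisition = acq,
                          options = list(render_background = FALSE))
  v <- renderVolume(cfg)
  loc <- locateSpheres(v, oneSphere(c(0, 0, 0)), search_mm = 6)
  vd <- volumeDistortion(v, loc)
  expect_equal(vd$volume_ratio[1], 1, tolerance = 0.05)
  # locally scaled render: sphere radius 1.1x -> ratio 1.331
  lay11 <- oneSphere(c(0, 0, 0)); lay11$inner_diameter <- 11
  lay2 <- lay; lay2@fiducials <- lay11; lay2@arrays <- lay@arrays[0, ]
  v2 <- renderVolume(simulationConfig(layout = lay2, acquisition = acq,
                                      options = list(render_background = FALSE)))
  loc2 <- locateSpheres(v2, oneSphere(c(0, 0, 0)), search_mm = 6)
  vd2 <- volumeDistortion(v2, loc2)
  expect_equal(vd2$volume_ratio[1], 1.1^3, tolerance = 0.07)
  # flagged sphere reports a missing ratio
  loc2$flag[1] <- "bubble"
  expect_true(is.na(volumeDistortion(v2, loc2)$volume_ratio[1]))
})
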