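ti10 <- c(50, 100, 200, 350, 500, 750, 1000, 1500, 2000, 3000)

test_that("magnitude IR fit recovers T1, A and delta exactly from noiseless model data", {
  for (t1 in c(20, 50, 200, 407, 1000, 2000)) {
    y <- signalIR(1, t1, ti10, delta = 0.85, A_scale = 500)
    f <- fitT1IR(ti10, y)
    expect_lt(abs(f$T1_ms / t1 - 1), 1e-3)
    expect_equal(f$delta, 0.85, tolerance = 1e-3)
    expect_equal(f$A, 500, tolerance = 0.5)
  }
  # delta = 1 identity
  y <- abs(1 - 2 * exp(-ti10 / 300))
  f <- fitT1IR(ti10, y)
  expect_equal(f$delta, 1, tolerance = 1e-4)
  # scaling invariance: A absorbs an overall factor, T1 unchanged
  y <- signalIR(1, 407, ti10, delta = 0.9)
  f1 <- fitT1IR(ti10, y)
  f2 <- fitT1IR(ti10, 1000 * y)
  expect_equal(f2$T1_ms, f1$T1_ms, tolerance = 1e-8)
  expect_error(fitT1IR(ti10[1:3], y[1:3]), "4 TI")
})

test_that("a short-T1 series with few informative points carries an enlarged stderr", {
  set.seed(21)
  sig <- 5
  se_short <- replicate(20, {
    y <- ricianObs(500 * (1 - 1.85 * exp(-ti10 / 20)), sig)
    f <- suppressWarnings(fitT1IR(ti10, y))
    f$se["T1_ms"] / f$T1_ms
  })
  se_mid <- replicate(20, {
    y <- ricianObs(500 * (1 - 1.85 * exp(-ti10 / 400)), sig)
    f <- suppressWarnings(fitT1IR(ti10, y))
    f$se["T1_ms"] / f$T1_ms
  })
  expect_gt(median(se_short), 5 * median(se_mid))
})

test_that("VFA fit recovers T1 and matches the two-point closed form on noiseless data", {
  fl <- c(2, 4, 6, 8, 10, 14, 18, 22, 26, 30)
  for (t1 in c(100, 407, 1500)) {
    y <- signalVFA(1, t1, 5.37, fl, S90_scale = 500)
    f <- fitT1VFA(fl, y, 5.37)
    expect_lt(abs(f$T1_ms / t1 - 1), 1e-3)
    expect_equal(f$S90, 500, tolerance = 0.5)
  }
  # two-point exact solution agrees with the nonlinear fit
  y2 <- signalVFA(1, 407, 5.37, c(4, 20), S90_scale = 500)
  tp <- twoPointVFA(c(4, 20), y2, 5.37)
  fn <- suppressWarnings(fitT1VFA(c(4, 20), y2, 5.37))
  expect_equal(fn$T1_ms, tp$T1_ms, tolerance = 1e-6)
  # rendered signal maximum sits at the flip nearest the Ernst angle
  fl_dense <- 1:30
  s <- signalVFA(1, 407, 5.37, fl_dense)
  expect_equal(fl_dense[which.max(s)],
               fl_dense[which.min(abs(fl_dense - ernstAngle(5.37, 407)))])
  # one-sided flip angles trigger the ill-conditioning warning
  yos <- signalVFA(1, 1500, 5.37, c(10, 15, 20, 25))
  expect_warning(fitT1VFA(c(10, 15, 20, 25), yos, 5.37), "Ernst")
})

test_that("T2 fit is exact on noiseless decays and records exclusions", {
  te <- seq(10, 320, by = 10)
  y <- signalSE(1, 100, te, 500)
  f <- fitT2SE(te, y)
  expect_equal(f$T2_ms, 100, tolerance = 1e-6)
  expect_equal(f$S0, 500, tolerance = 1e-4)
  # first-echo drop removes TE = 10 ms and records the reason
  f2 <- fitT2SE(te, y, drop_first = TRUE)
  expect_equal(f2$excluded$TE_ms, 10)
  expect_equal(f2$excluded$reason, "first_echo")
  expect_equal(f2$n_points_used, 31L)
  expect_error(fitT2SE(te[1:4], y[1:4], floor = max(y)), "3 usable")
})

test_that("noise-floor exclusion reduces the Rician bias of long-TE T2 fits", {
  set.seed(31)
  te <- seq(10, 320, by = 10)
  S <- signalSE(1, 60, te, 500)
  sig <- 10
  flr <- noiseFloor(ricianObs(numeric(2000), sig))
  res <- t(replicate(60, {
    y <- ricianObs(S, sig)
    c(with_floor = fitT2SE(te, y, floor = flr)$T2_ms,
      no_floor = fitT2SE(te, y)$T2_ms)
  }))
  bias_floor <- abs(mean(res[, 1]) - 60)
  bias_none <- abs(mean(res[, 2]) - 60)
  expect_lt(bias_floor, bias_none)
})

test_that("deviation is the signed percent difference; archival Ni-12 values give +0.3%", {
  expect_equal(deviation(100, 100), 0)
  expect_equal(deviation(110, 100), 10)
  expect_equal(round(deviation(44.67, 44.53), 1), 0.3)
  expect_equal(round(deviation(31.97, 31.86), 1), 0.3)
  expect_error(deviation(10, NA))
})

test_that("relaxivity fits recover the slope with fixed and free intercepts", {
  C <- c(0.1, 0.4, 0.8, 1.6)
  rate <- 80 * C + 0.5
  f <- fitRelaxivity(C, 1000 / rate, water_rate_s = 0.5)
  expect_equal(f$r_per_mM_s, 80, tolerance = 1e-9)
  expect_equal(f$intercept_s, 0.5)
  # zero concentration reproduces the water rate by construction
  expect_equal(0.5 + f$r_per_mM_s * 0, f$intercept_s)
  ffree <- fitRelaxivity(C, 1000 / rate)
  expect_equal(ffree$r_per_mM_s, 80, tolerance = 1e-6)
  expect_equal(ffree$intercept_s, 0.5, tolerance = 1e-6)
  expect_error(fitRelaxivity(-C, 1000 / rate), "non-negative")
  # coverage: noisy rates recover the slope within stderr at the nominal rate
  set.seed(41)
  hit <- replicate(200, {
    noisy <- 80 * C + 0.5 + rnorm(4, 0, 0.3)
    f <- fitRelaxivity(C, 1000 / noisy, water_rate_s = 0.5)
    abs(f$r_per_mM_s - 80) <= qt(0.975, f$df_residual) * f$r_se
  })
  expect_gte(mean(hit), 0.90)
})

test_that("ROI-mean and voxel-map T1 estimates agree within combined errors on a rendered series", {
  lay <- phantomLayout()
  acq <- acquisitionPreset("t1_ir", fov_mm = c(24, 16, 24),
                           centre_mm = c(0, -66, 50))  # NiCl2 element 1
  cfg <- simulationConfig(layout = lay, acquisition = acq,
                          noise = list(sigma = 2, kind = "rician", seed = 13))
  vols <- renderSeries(cfg)
  ctr <- as.matrix(parameterArray(lay, "NiCl2")[1, c("x", "y", "z")])[1, ]
  ser <- roiSeries(vols, ctr, roi_diameter_mm = 8)
  f_roi <- fitT1IR(ser$x, ser$mean_signal)
  f_map <- fitT1IRVoxelMap(ser)
  comb <- sqrt(f_roi$se["T1_ms"]^2 + (f_map$sd_ms / sqrt(f_map$n_voxels))^2)
  expect_lt(abs(f_roi$T1_ms - f_map$T1_ms), 3 * comb + 0.02 * f_roi$T1_ms)
  # both close to the configured truth
  truth <- referenceTable()$T1_ms[1]
  expect_lt(abs(f_roi$T1_ms / truth - 1), 0.03)
})

test_that("parameter recovery holds across the shipped T1 range at SNR 100", {
  set.seed(51)
  A <- 500; sig <- 5
  t1s <- c(50, 100, 500, 2000)
  cover <- c(); biases <- c()
  for (t1 in t1s) {
    S <- A * (1 - 1.85 * exp(-ti10 / t1))
    res <- t(replicate(100, {
      f <- suppressWarnings(fitT1IR(ti10, ricianObs(S, sig)))
      c(f$T1_ms, f$se["T1_ms"])
    }))
    biases <- c(biases, abs(mean(res[, 1]) / t1 - 1))
    cover <- c(cover, abs(res[, 1] - t1) <= 1.96 * res[, 2])
  }
  expect_true(all(biases < 0.01))
  expect_gte(mean(cover), 0.90)
})
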