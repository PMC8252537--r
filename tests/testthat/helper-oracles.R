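# Shared oracles and small fixtures, independent of the implementation
# paths they check.

# Brute-force similarity fit: direct nonlinear least squares over
# (rotation vector, translation, log scale) with numerical optimization.
bruteForceSimilarity <- function(P, A) {
  rotvec <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    u <- v / th
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  # scale and translation are linear given the rotation, so profile them
  # out exactly and optimize only the 3 rotation parameters
  profiled <- function(R) {
    RP <- t(R %*% t(P))
    X <- cbind(as.vector(RP)) # s column; translation via per-axis means
    n <- nrow(P)
    D <- cbind(X, kronecker(diag(3), rep(1, n)))
    f <- stats::lm.fit(D, as.vector(A))
    list(sse = sum(f$residuals^2), s = unname(f$coefficients[1]),
         t = unname(f$coefficients[2:4]))
  }
  obj <- function(p) profiled(rotvec(p))$sse
  best <- NULL
  for (init in list(c(0, 0, 0), c(0.2, -0.2, 0.2), c(-0.3, 0.1, 0.4))) {
    o <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
    o <- stats::optim(o$par, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
    if (is.null(best) || o$value < best$value) best <- o
  }
  pr <- profiled(rotvec(best$par))
  list(rotation = rotvec(best$par), translation = pr$t,
       scale = pr$s, sse = pr$sse)
}

# Closed-form two-flip-angle VFA solution: S_i = b sin(a_i) + E S_i cos(a_i)
# is linear in (b, E) with b = S90 (1 - E).
twoPointVFA <- function(flip_deg, S, TR_ms) {
  a <- flip_deg * pi / 180
  M <- cbind(sin(a), S * cos(a))
  sol <- solve(M, S)
  E <- sol[2]
  list(T1_ms = -TR_ms / log(E), S90 = sol[1] / (1 - E))
}

# A minimal one-sphere fiducial table at a given centre.
oneSphere <- function(centre, id = 1L) {
  data.frame(id = id, x = centre[1], y = centre[2], z = centre[3],
             inner_diameter = 10, group = "fiducial_internal")
}

# Independent finite-k-space oracle for the inset synthesis: rasterize the
# disks at os-fold resolution on the same FOV, FFT, keep exactly the
# frequency support of the coarse grid, inverse transform.
rasterTruncationOracle <- function(holes, grid, os = 9) {
  ux <- grid$x0 + (seq_len(grid$nx * os) - 1) * grid$dx / os
  vy <- grid$y0 + (seq_len(grid$ny * os) - 1) * grid$dx / os
  hi <- matrix(0, length(ux), length(vy))
  for (k in seq_len(nrow(holes))) {
    d2 <- outer((ux - holes$u[k])^2, (vy - holes$v[k])^2, "+")
    hi <- hi + (d2 <= (holes$diameter_mm[k] / 2)^2)
  }
  H <- stats::fft(hi)
  pick <- function(n, N) c(1:ceiling((n + 1) / 2),
                           (N - floor((n - 1) / 2) + 1):N)
  Hs <- H[pick(grid$nx, nrow(hi)), pick(grid$ny, ncol(hi))]
  Re(stats::fft(Hs, inverse = TRUE)) / (nrow(hi) * ncol(hi))
}

# Magnitude (Rician) observation of a signed signal vector.
ricianObs <- function(S, sigma) {
  sqrt((S + stats::rnorm(length(S), 0, sigma))^2 +
         stats::rnorm(length(S), 0, sigma)^2)
}
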