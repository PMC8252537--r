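# Small shared numerical helpers.

#' Rotation matrix from axis and angle
#'
#' @param axis numeric(3), need not be normalized.
#' @param angle_deg rotation angle in degrees (right-handed).
#' @return 3x3 proper orthogonal matrix.
#' @export
rotationMatrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Net rotation angle (degrees) of a 3x3 rotation matrix.
rotationAngle <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c_))) * 180 / pi
}

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 1-based; the world coordinate of voxel (1,1,1) is the
#' volume origin. `worldToVoxel` returns fractional (continuous) indices.
#'
#' @param volume an [ImageVolume-class].
#' @param idx n x 3 matrix of (possibly fractional) 1-based voxel indices.
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix.
#' @export
voxelToWorld <- function(volume, idx) {
  idx <- rbind(idx)
  sweep(t(volume@orientation %*% t(sweep(idx - 1, 2, volume@spacing, "*"))),
        2, volume@origin, "+")
}

#' @rdname voxelToWorld
#' @export
worldToVoxel <- function(volume, xyz) {
  xyz <- rbind(xyz)
  rel <- t(t(volume@orientation) %*% t(sweep(xyz, 2, volume@origin, "-")))
  sweep(rel, 2, volume@spacing, "/") + 1
}

# Trilinear interpolation of a 3D array at fractional 1-based indices.
# Points outside the grid return `outside`.
interp3 <- function(arr, idx, outside = NA_real_) {
  idx <- rbind(idx)
  d <- dim(arr)
  i0 <- pmin(pmax(floor(idx[, 1]), 1L), d[1] - 1L)
  j0 <- pmin(pmax(floor(idx[, 2]), 1L), d[2] - 1L)
  k0 <- pmin(pmax(floor(idx[, 3]), 1L), d[3] - 1L)
  fx <- idx[, 1] - i0; fy <- idx[, 2] - j0; fz <- idx[, 3] - k0
  v <- function(a, b, c) arr[cbind(a, b, c)]
  out <- (1 - fx) * (1 - fy) * (1 - fz) * v(i0, j0, k0) +
    fx * (1 - fy) * (1 - fz) * v(i0 + 1L, j0, k0) +
    (1 - fx) * fy * (1 - fz) * v(i0, j0 + 1L, k0) +
    (1 - fx) * (1 - fy) * fz * v(i0, j0, k0 + 1L) +
    fx * fy * (1 - fz) * v(i0 + 1L, j0 + 1L, k0) +
    fx * (1 - fy) * fz * v(i0 + 1L, j0, k0 + 1L) +
    (1 - fx) * fy * fz * v(i0, j0 + 1L, k0 + 1L) +
    fx * fy * fz * v(i0 + 1L, j0 + 1L, k0 + 1L)
  bad <- idx[, 1] < 1 | idx[, 1] > d[1] | idx[, 2] < 1 | idx[, 2] > d[2] |
    idx[, 3] < 1 | idx[, 3] > d[3]
  out[bad] <- outside
  out
}

# Bilinear interpolation of a 2D matrix at fractional 1-based (i, j).
interp2 <- function(mat, ij, outside = NA_real_) {
  ij <- rbind(ij)
  d <- dim(mat)
  i0 <- pmin(pmax(floor(ij[, 1]), 1L), d[1] - 1L)
  j0 <- pmin(pmax(floor(ij[, 2]), 1L), d[2] - 1L)
  fx <- ij[, 1] - i0; fy <- ij[, 2] - j0
  out <- (1 - fx) * (1 - fy) * mat[cbind(i0, j0)] +
    fx * (1 - fy) * mat[cbind(i0 + 1L, j0)] +
    (1 - fx) * fy * mat[cbind(i0, j0 + 1L)] +
    fx * fy * mat[cbind(i0 + 1L, j0 + 1L)]
  bad <- ij[, 1] < 1 | ij[, 1] > d[1] | ij[, 2] < 1 | ij[, 2] > d[2]
  out[bad] <- outside
  out
}

# Linear-interpolated full width at half maximum of a sampled profile.
# x must be increasing; returns NA if the half level is never crossed on
# both sides of the maximum.
fwhmLinear <- function(x, y) {
  imax <- which.max(y)
  half <- y[imax] / 2
  left <- NA_real_; right <- NA_real_
  if (imax > 1) {
    below <- which(y[seq_len(imax - 1)] < half)
    if (length(below)) {
      i <- max(below)
      left <- x[i] + (half - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i])
    }
  }
  if (imax < length(y)) {
    below <- which(y[seq(imax + 1, length(y))] < half) + imax
    if (length(below)) {
      i <- min(below)
      right <- x[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
    }
  }
  right - left
}

#' Construct an ImageVolume
#'
#' @param data 3D numeric array.
#' @param spacing numeric(3), voxel size in mm.
#' @param origin numeric(3), world position (mm) of the first voxel centre.
#' @param orientation 3x3 direction-cosine matrix (default identity).
#' @param meta named list of acquisition metadata.
#' @return an [ImageVolume-class].
#' @export
imageVolume <- function(data, spacing, origin = c(0, 0, 0),
                        orientation = diag(3), meta = list()) {
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = orientation, meta = meta)
}
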