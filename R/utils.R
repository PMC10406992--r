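# Internal geometry and interpolation helpers shared across modules.

# Map 0-based voxel indices (n x 3) to world mm through a 4x4 affine.
index_to_world <- function(affine, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  t(affine[1:3, 1:3] %*% t(ijk) + affine[1:3, 4])
}

# Inverse map: world mm (n x 3) to continuous 0-based voxel indices.
world_to_index <- function(affine, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(xyz) + inv[1:3, 4])
}

# All voxel-center world coordinates of a 3D grid, x fastest (column-major).
grid_world_coords <- function(dim3, affine) {
  ijk <- as.matrix(expand.grid(
    i = 0:(dim3[1] - 1), j = 0:(dim3[2] - 1), k = 0:(dim3[3] - 1)
  ))
  index_to_world(affine, ijk)
}

voxel_size_from_affine <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# World coordinates of the geometric center of the voxel grid.
volume_center_world <- function(dim3, affine) {
  drop(index_to_world(affine, matrix((dim3 - 1) / 2, 1)))
}

#' @keywords internal
#' @noRd
# Trilinear interpolation of a 3D volume at continuous 0-based voxel
# coordinates (n x 3). Values outside the grid are NA.
trilinear_sample <- function(vol, idx) {
  d <- dim(vol)
  idx <- matrix(idx, ncol = 3)
  x <- idx[, 1]; y <- idx[, 2]; z <- idx[, 3]
  out <- rep(NA_real_, nrow(idx))
  ok <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 & z >= 0 & z <= d[3] - 1
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), d[1] - 2L); x0 <- pmax(x0, 0L)
  y0 <- pmin(floor(y), d[2] - 2L); y0 <- pmax(y0, 0L)
  z0 <- pmin(floor(z), d[3] - 2L); z0 <- pmax(z0, 0L)
  if (d[1] == 1L) x0 <- rep(0L, length(x))
  if (d[2] == 1L) y0 <- rep(0L, length(y))
  if (d[3] == 1L) z0 <- rep(0L, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1); z1 <- pmin(z0 + 1, d[3] - 1)
  # linear indices (1-based) of the 8 cell corners
  lin <- function(i, j, k) 1 + i + d[1] * (j + d[2] * k)
  v000 <- vol[lin(x0, y0, z0)]; v100 <- vol[lin(x1, y0, z0)]
  v010 <- vol[lin(x0, y1, z0)]; v110 <- vol[lin(x1, y1, z0)]
  v001 <- vol[lin(x0, y0, z1)]; v101 <- vol[lin(x1, y0, z1)]
  v011 <- vol[lin(x0, y1, z1)]; v111 <- vol[lin(x1, y1, z1)]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}

# Nearest-neighbour lookup at continuous 0-based voxel coordinates.
nearest_sample <- function(vol, idx) {
  d <- dim(vol)
  idx <- matrix(idx, ncol = 3)
  i <- round(idx[, 1]); j <- round(idx[, 2]); k <- round(idx[, 3])
  out <- rep(NA_real_, nrow(idx))
  ok <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 & k >= 0 & k <= d[3] - 1
  ok[is.na(ok)] <- FALSE
  out[ok] <- vol[1 + i[ok] + d[1] * (j[ok] + d[2] * k[ok])]
  out
}

# 1D Gaussian smoothing with reflected edges; sigma in samples.
gauss_smooth_1d <- function(v, sigma) {
  if (sigma <= 0) return(v)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(v)
  pad <- c(v[pmin(r:1, n)], v, v[pmax(n - (1:r) + 1, 1)])
  stats::filter(pad, k, sides = 2)[(r + 1):(r + n)]
}

# Linear interpolation with zero extrapolation before t=0 through (0,0).
interp_curve <- function(t, v, tout) {
  if (t[1] > 0) { t <- c(0, t); v <- c(0, v) }
  stats::approx(t, v, xout = tout, rule = 2)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
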