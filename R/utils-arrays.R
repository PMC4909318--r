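# Low-level array helpers shared by the filtering, projection and spot
# detection code. Matrices are indexed [y, x]; 3D arrays [z, y, x].

# out[i, j] = m[i + dy, j + dx], `fill` outside the image.
shift_mat <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- seq(1 + max(0, dy), nr + min(0, dy))
  ci <- seq(1 + max(0, dx), nc + min(0, dx))
  if (length(ri) < 1 || length(ci) < 1) return(out)
  out[ri - dy, ci - dx] <- m[ri, ci]
  out
}

# out[k, i, j] = a[k + dz, i + dy, j + dx], `fill` outside the volume.
shift_arr3 <- function(a, dz, dy, dx, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  zi <- seq(1 + max(0, dz), d[1] + min(0, dz))
  yi <- seq(1 + max(0, dy), d[2] + min(0, dy))
  xi <- seq(1 + max(0, dx), d[3] + min(0, dx))
  if (length(zi) < 1 || length(yi) < 1 || length(xi) < 1) return(out)
  out[zi - dz, yi - dy, xi - dx] <- a[zi, yi, xi]
  out
}

# Integer offsets (dy, dx) covering the disk of radius r (pixels).
disk_offsets <- function(r) {
  s <- seq(-floor(r), floor(r))
  g <- expand.grid(dy = s, dx = s)
  g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(seq(-r, r), sd = sigma)
  w / sum(w)
}

# 1D convolution along one axis with replicated (clamped) edges.
conv_axis_mat <- function(m, w, axis) {
  if (length(w) == 1) return(m)
  n <- dim(m)[axis]
  r <- (length(w) - 1) / 2
  out <- matrix(0, nrow(m), ncol(m))
  for (s in seq_along(w)) {
    off <- s - r - 1
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + w[s] * (if (axis == 1) m[idx, , drop = FALSE] else m[, idx, drop = FALSE])
  }
  out
}

conv_axis_arr3 <- function(a, w, axis) {
  if (length(w) == 1) return(a)
  n <- dim(a)[axis]
  r <- (length(w) - 1) / 2
  out <- array(0, dim(a))
  for (s in seq_along(w)) {
    off <- s - r - 1
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + w[s] * switch(axis,
      a[idx, , , drop = FALSE],
      a[, idx, , drop = FALSE],
      a[, , idx, drop = FALSE])
  }
  out
}

gauss_blur_mat <- function(m, sigma_px) {
  k <- gauss_kernel(sigma_px)
  conv_axis_mat(conv_axis_mat(m, k, 1), k, 2)
}

# Anisotropic separable Gaussian; sigmas in voxel units per axis (z, y, x).
gauss_blur_arr3 <- function(a, sigma_z, sigma_y, sigma_x) {
  a <- conv_axis_arr3(a, gauss_kernel(sigma_z), 1)
  a <- conv_axis_arr3(a, gauss_kernel(sigma_y), 2)
  conv_axis_arr3(a, gauss_kernel(sigma_x), 3)
}

# Second difference along one axis, replicated edges, physical spacing.
second_diff_mat <- function(m, axis, spacing) {
  n <- dim(m)[axis]
  up <- pmin(seq_len(n) + 1L, n)
  dn <- pmax(seq_len(n) - 1L, 1L)
  if (axis == 1) (m[up, , drop = FALSE] - 2 * m + m[dn, , drop = FALSE]) / spacing^2
  else (m[, up, drop = FALSE] - 2 * m + m[, dn, drop = FALSE]) / spacing^2
}

second_diff_arr3 <- function(a, axis, spacing) {
  n <- dim(a)[axis]
  up <- pmin(seq_len(n) + 1L, n)
  dn <- pmax(seq_len(n) - 1L, 1L)
  d <- switch(axis,
    a[up, , , drop = FALSE] - 2 * a + a[dn, , , drop = FALSE],
    a[, up, , drop = FALSE] - 2 * a + a[, dn, , drop = FALSE],
    a[, , up, drop = FALSE] - 2 * a + a[, , dn, drop = FALSE])
  d / spacing^2
}

laplacian_mat <- function(m, spacing_um) {
  second_diff_mat(m, 1, spacing_um) + second_diff_mat(m, 2, spacing_um)
}

laplacian_arr3 <- function(a, z_step, pixel_size_xy) {
  second_diff_arr3(a, 1, z_step) +
    second_diff_arr3(a, 2, pixel_size_xy) +
    second_diff_arr3(a, 3, pixel_size_xy)
}

# Strict local minima, 8-connectivity. Returns logical matrix.
local_minima_mat <- function(m) {
  nb <- matrix(Inf, nrow(m), ncol(m))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pmin(nb, shift_mat(m, dy, dx, fill = Inf))
  }
  m < nb
}

# Strict local minima, 26-connectivity. Returns logical array.
local_minima_arr3 <- function(a) {
  nb <- array(Inf, dim(a))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    nb <- pmin(nb, shift_arr3(a, dz, dy, dx, fill = Inf))
  }
  a < nb
}
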