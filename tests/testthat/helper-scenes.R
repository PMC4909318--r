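# Shared fixtures: brute-force oracles and standard synthetic scenes.
# Everything is generated in code at test time; no stored data.

# exhaustive per-pixel max/argmax over z
mip_oracle <- function(a) {
  d <- dim(a)
  mip <- matrix(0, d[2], d[3])
  height <- matrix(0L, d[2], d[3])
  for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    mip[y, x] <- max(a[, y, x])
    height[y, x] <- which.max(a[, y, x])
  }
  list(mip = mip, height = height)
}

# naive double-loop disk max - min
range_oracle <- function(h, r) {
  out <- matrix(0, nrow(h), ncol(h))
  for (y in seq_len(nrow(h))) for (x in seq_len(ncol(h))) {
    vals <- c()
    for (dy in -r:r) for (dx in -r:r) {
      if (dy^2 + dx^2 > r^2) next
      yy <- y + dy; xx <- x + dx
      if (yy >= 1 && yy <= nrow(h) && xx >= 1 && xx <= ncol(h))
        vals <- c(vals, h[yy, xx])
    }
    out[y, x] <- max(vals) - min(vals)
  }
  out
}

# one centered sphere; background-corrected acquisition
sphere_scene <- function(radius = 50, mu = 0, seed = 7, z_step = 10,
                         nz = 24, xy = 96, zc = 110, ...) {
  generate_scene(scene_spec(
    volume_shape = c(nz, xy, xy), z_step = z_step, mu = mu,
    background_level = 10, noise_sd = 5, seed = seed,
    centers = matrix(c(60, 60, zc), 1), radii = radius, ...))
}

# a half-visible spheroid under the corrected-counting study conditions
half_scene <- function(seed) {
  generate_scene(scene_spec(
    volume_shape = c(40, 96, 96), z_step = 5, mu = 0.012,
    positive_fraction = 0.06, min_spot_spacing = 18,
    background_level = 10, noise_sd = 5, spot_intensity = 2700,
    seed = seed,
    centers = matrix(c(60, 60, 60 + (seed %% 10) / 2), 1), radii = 50))
}

# isolated-nuclei stack: n points with pairwise LATERAL spacing >=
# `spacing` (which implies the same 3D spacing, and means every nucleus
# wins the MIP in its own neighborhood -- no lateral occlusion)
spaced_nuclei <- function(n, spacing, shape = c(16, 200, 200),
                          pixel_size_xy = 1.3, z_step = 10, seed = 123,
                          intensity = 400, background = 100) {
  set.seed(seed)
  ext <- c((shape[1] - 1) * z_step, (shape[2] - 1) * pixel_size_xy,
           (shape[3] - 1) * pixel_size_xy)
  pts <- matrix(numeric(0), 0, 3)
  while (nrow(pts) < n) {
    cand <- c(runif(1, 10, ext[3] - 10), runif(1, 10, ext[2] - 10),
              runif(1, 20, ext[1] - 20))
    if (nrow(pts)) {
      d2 <- (pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2
      if (min(d2) < spacing^2) next
    }
    pts <- rbind(pts, cand)
  }
  list(centers = pts,
       stack = render_nuclei_stack(shape, pts, pixel_size_xy, z_step,
                                   nucleus_sigma = 3, intensity = intensity,
                                   background_level = background,
                                   noise_sd = 5, seed = seed + 1))
}

# greedy one-to-one matching of detected spots to true points (3D um)
match_spots <- function(spots, truth, radius) {
  used <- rep(FALSE, nrow(spots))
  tp <- 0L
  for (i in seq_len(nrow(truth))) {
    d2 <- (spots$x_um - truth[i, 1])^2 + (spots$y_um - truth[i, 2])^2 +
      (spots$z_um - truth[i, 3])^2
    j <- which(!used & d2 < radius^2)
    if (length(j)) {
      used[j[which.min(d2[j])]] <- TRUE
      tp <- tp + 1L
    }
  }
  list(recall = tp / nrow(truth), precision = tp / nrow(spots), tp = tp)
}

# grid of well-separated Gaussian blobs / disks for scale selection
blob_image <- function(s, dim = 260, amp = 500, noise = 3, seed = 5) {
  set.seed(seed)
  g <- expand.grid(x = seq(40, dim - 40, by = 8 * s + 10),
                   y = seq(40, dim - 40, by = 8 * s + 10))
  g <- g[seq_len(min(9, nrow(g))), ]
  m <- matrix(0, dim, dim)
  gx <- row(m); gy <- col(m)
  for (i in seq_len(nrow(g)))
    m <- m + amp * exp(-((gx - g$x[i])^2 + (gy - g$y[i])^2) / (2 * s^2))
  m + matrix(rnorm(dim^2, 100, noise), dim)
}

disk_image <- function(r, dim = 260, noise = 3, seed = 5) {
  set.seed(seed)
  g <- expand.grid(x = seq(40, dim - 40, by = 8 * r + 10),
                   y = seq(40, dim - 40, by = 8 * r + 10))
  g <- g[seq_len(min(9, nrow(g))), ]
  m <- matrix(100, dim, dim)
  gx <- row(m); gy <- col(m)
  for (i in seq_len(nrow(g)))
    m[(gx - g$x[i])^2 + (gy - g$y[i])^2 <= r^2] <- 600
  m + matrix(rnorm(dim^2, 0, noise), dim)
}

log_scale_grid <- function(max_spot_radius = 8, n = 20) {
  exp(seq(log(max_spot_radius / 10), log(max_spot_radius), length.out = n))
}
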