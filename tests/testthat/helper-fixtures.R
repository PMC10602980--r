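# shared fixture builders; everything is generated in code at test time

# solid sphere mask of radius r_mm on an isotropic grid
fx_sphere_mask <- function(r_mm = 10, spacing = 0.5, margin = 1.5) {
  n <- 2L * ceiling((r_mm + margin) / spacing) + 1L
  g <- voxel_grid(rep(n, 3), rep(spacing, 3), rep(-(n - 1) / 2 * spacing, 3))
  P <- as.matrix(expand.grid(x = grid_axis(g, 1), y = grid_axis(g, 2),
                             z = grid_axis(g, 3)))
  binary_mask(array(sqrt(rowSums(P^2)) <= r_mm, dim = g$shape), g)
}

# axis-aligned solid tube (along z) mask
fx_tube_mask <- function(radius = 5, length = 40, spacing = 1) {
  nxy <- 2L * ceiling((radius + 3) / spacing) + 1L
  nz <- ceiling(length / spacing) + 1L
  g <- voxel_grid(c(nxy, nxy, nz), rep(spacing, 3),
                  c(-(nxy - 1) / 2 * spacing, -(nxy - 1) / 2 * spacing, 0))
  P <- as.matrix(expand.grid(x = grid_axis(g, 1), y = grid_axis(g, 2),
                             z = grid_axis(g, 3)))
  binary_mask(array(sqrt(P[, 1]^2 + P[, 2]^2) <= radius, dim = g$shape), g)
}

# independent flood-fill component counter (6/26-neighbour), R implementation
fx_flood_count <- function(voxels) {
  d <- dim(voxels)
  seen <- array(FALSE, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  count <- 0L
  idx_all <- which(voxels & !seen)
  while (length(idx_all)) {
    count <- count + 1L
    queue <- idx_all[1]
    seen[queue] <- TRUE
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ai <- arrayInd(v, d)
      for (r in seq_len(nrow(offs))) {
        p <- ai + offs[r, ]
        if (any(p < 1) || any(p > d)) next
        li <- p[1] + d[1] * (p[2] - 1 + d[2] * (p[3] - 1))
        if (voxels[li] && !seen[li]) {
          seen[li] <- TRUE
          queue <- c(queue, li)
        }
      }
    }
    idx_all <- which(voxels & !seen)
  }
  count
}

# tiny synthetic 4D flow dataset with a single-peak pulsatile tube flow
fx_flow_dataset <- function(n_frames = 20, peak_frame = 6, radius = 5,
                            length = 60, spacing = 2, peak_U = 0.6,
                            venc = 1.5) {
  nxy <- 2L * ceiling((radius + 4) / spacing) + 1L
  nz <- ceiling(length / spacing) + 1L
  g <- voxel_grid(c(nxy, nxy, nz), rep(spacing, 3),
                  c(-(nxy - 1) / 2 * spacing, -(nxy - 1) / 2 * spacing, 0))
  P <- as.matrix(expand.grid(x = grid_axis(g, 1), y = grid_axis(g, 2),
                             z = grid_axis(g, 3)))
  r <- sqrt(P[, 1]^2 + P[, 2]^2)
  prof <- ifelse(r <= radius, 1 - (r / radius)^2, 0)
  ft <- (seq_len(n_frames) - 1) / n_frames
  U <- 0.05 + (peak_U - 0.05) *
    exp(-0.5 * ((seq_len(n_frames) - peak_frame) / 1.5)^2)
  dims <- c(g$shape, n_frames)
  vz <- array(0, dims)
  for (f in seq_len(n_frames)) vz[, , , f] <- 2 * U[f] * prof
  zero <- array(0, dims)
  mag <- array(50, dims)
  flow4d_dataset(g, ft, 1.0, mag, zero, zero, vz, venc = venc)
}

expect_watertight <- function(surface) {
  expect_true(isTRUE(as.logical(is_watertight(surface))))
}

# shared end-to-end pipeline: phantom -> CPC-MRA -> segment -> mask/surface
fx_pipeline_mask <- function(spec, ithresh = 0.1, slice_gap = 1.0) {
  ph <- make_phantom(spec)
  cpc <- build_cpc(ph$dataset, cpc_config(background_mode = "suppress"),
                   slice_gap = slice_gap)
  mask <- largest_component(threshold_segment(cpc, ithresh))
  list(phantom = ph, cpc = cpc, mask = mask)
}

# tiny independent erosion used only by the closing test
erode_oracle <- function(a) {
  d <- dim(a)
  out <- a
  for (off in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                   c(0,0,1), c(0,0,-1))) {
    sh <- array(FALSE, d)
    xs <- max(1, 1 + off[1]):min(d[1], d[1] + off[1])
    ys <- max(1, 1 + off[2]):min(d[2], d[2] + off[2])
    zs <- max(1, 1 + off[3]):min(d[3], d[3] + off[3])
    sh[xs, ys, zs] <- a[xs - off[1], ys - off[2], zs - off[3]]
    out <- out & sh
  }
  out
}

# literal 2^n sign-enumeration oracle for the signed-rank test
wilcoxon_enum_oracle <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wplus <- sum(r[d > 0])
  wp <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    sgn <- as.integer(intToBits(m))[1:n]
    wp[m + 1] <- sum(r[sgn == 1])
  }
  lower <- mean(wp <= wplus + 1e-9)
  upper <- mean(wp >= wplus - 1e-9)
  min(1, 2 * min(lower, upper))
}

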