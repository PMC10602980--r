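#' Voxel grid geometry
#'
#' A `VoxelGrid` describes a regular 3D sampling lattice in a right-handed,
#' patient-based LPS frame: voxel centers sit at `origin + (index - 1) *
#' spacing` (1-based indices), all coordinates in millimetres.  Volumes on a
#' grid are plain 3D arrays indexed `[x, y, z]`.
#'
#' @param shape integer triple `(nx, ny, nz)`, each >= 1.
#' @param spacing numeric triple `(dx, dy, dz)` in mm, each > 0.
#' @param origin numeric triple, mm coordinate of the first voxel center.
#' @return an object of class `VoxelGrid`.
#' @export
voxel_grid <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(shape < 1L)) stop("VoxelGrid: all shape components must be >= 1")
  if (any(spacing <= 0)) stop("VoxelGrid: all spacings must be > 0")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "VoxelGrid")
}

#' @export
print.VoxelGrid <- function(x, ...) {
  cat(sprintf("VoxelGrid %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Voxel center coordinates along one axis
#' @param grid a `VoxelGrid`
#' @param axis 1, 2 or 3
#' @return numeric vector of mm coordinates
#' @export
grid_axis <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

#' Bounding box of a grid (voxel centers)
#' @param grid a `VoxelGrid`
#' @return 2x3 matrix, rows = min/max mm coordinates
#' @export
grid_bbox <- function(grid) {
  lo <- grid$origin
  hi <- grid$origin + (grid$shape - 1) * grid$spacing
  rbind(min = lo, max = hi)
}

#' Trilinear sampling of a volume at arbitrary points
#'
#' Samples outside the grid evaluate to 0 (the volume is taken to vanish
#' beyond the outermost voxel centers).
#'
#' @param vol 3D array on `grid`
#' @param grid a `VoxelGrid`
#' @param pts n x 3 matrix of mm coordinates
#' @return numeric vector of n sampled values
#' @export
sample_volume <- function(vol, grid, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  n <- nrow(pts)
  # continuous 0-based index coordinates
  u <- sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$spacing, "/")
  i0 <- floor(u)
  fr <- u - i0
  out <- numeric(n)
  sh <- grid$shape
  inb <- u[, 1] >= 0 & u[, 1] <= sh[1] - 1 &
    u[, 2] >= 0 & u[, 2] <= sh[2] - 1 &
    u[, 3] >= 0 & u[, 3] <= sh[3] - 1
  if (!any(inb)) return(out)
  i0 <- i0[inb, , drop = FALSE]
  fr <- fr[inb, , drop = FALSE]
  # clamp the upper corner for points exactly on the far face
  i1 <- pmin(i0 + 1, matrix(rep(sh - 1, each = nrow(i0)), ncol = 3))
  i0 <- pmin(i0, matrix(rep(sh - 1, each = nrow(i0)), ncol = 3))
  lin <- function(ix, iy, iz) {
    vol[1 + ix + sh[1] * (iy + sh[2] * iz)]
  }
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  v000 <- lin(i0[, 1], i0[, 2], i0[, 3]); v100 <- lin(i1[, 1], i0[, 2], i0[, 3])
  v010 <- lin(i0[, 1], i1[, 2], i0[, 3]); v110 <- lin(i1[, 1], i1[, 2], i0[, 3])
  v001 <- lin(i0[, 1], i0[, 2], i1[, 3]); v101 <- lin(i1[, 1], i0[, 2], i1[, 3])
  v011 <- lin(i0[, 1], i1[, 2], i1[, 3]); v111 <- lin(i1[, 1], i1[, 2], i1[, 3])
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inb] <- c0 * (1 - fz) + c1 * fz
  out
}

#' Euclidean distance transform of a boolean volume
#'
#' Distance (mm) from each foreground voxel center to the nearest background
#' voxel center, honouring anisotropic spacing.  Background voxels map to 0.
#'
#' @param voxels logical 3D array
#' @param grid the `VoxelGrid` the array lives on
#' @return numeric 3D array of distances, mm
#' @export
distance_transform <- function(voxels, grid) {
  d <- cpp_edt3d(as.logical(voxels), grid$shape, grid$spacing)
  array(d, dim = grid$shape)
}
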