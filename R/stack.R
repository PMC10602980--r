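#' Image stack in one anatomical plane
#'
#' An ordered set of 2D grayscale slices with uniform slice gap, the working
#' representation of both the per-phase velocity-mapped stacks and the final
#' composite angiogram.  The LPS axis convention fixes the in-plane axes:
#' transverse slices (fixed z) are indexed `[x, y]`, coronal (fixed y)
#' `[x, z]`, sagittal (fixed x) `[y, z]`.
#'
#' @param pixels 3D array `[in-plane 1, in-plane 2, slice]`, intensities in
#'   `[0, I_max]`
#' @param plane `"transverse"`, `"coronal"` or `"sagittal"`
#' @param slice_gap mm between consecutive slice planes (> 0)
#' @param in_plane_spacing mm pair for the two in-plane axes
#' @param origin mm coordinate (3-vector) of the first pixel center of the
#'   first slice
#' @param I_max intensity ceiling (default 4095, 12-bit)
#' @return an object of class `ImageStack`
#' @export
image_stack <- function(pixels, plane, slice_gap, in_plane_spacing,
                        origin = c(0, 0, 0), I_max = 4095) {
  plane <- match.arg(plane, c("transverse", "coronal", "sagittal"))
  if (length(dim(pixels)) != 3)
    stop("ImageStack: pixels must be a 3D array [i, j, slice]")
  n_slices <- dim(pixels)[3]
  if (n_slices < 1) stop("ImageStack: n_slices must be >= 1")
  if (slice_gap <= 0) stop("ImageStack: slice_gap must be > 0")
  if (any(pixels < 0) || any(pixels > I_max))
    stop("ImageStack: intensities must lie in [0, I_max]")
  structure(list(pixels = pixels, plane = plane, n_slices = n_slices,
                 slice_gap = as.numeric(slice_gap),
                 in_plane_spacing = as.numeric(in_plane_spacing),
                 origin = as.numeric(origin), I_max = as.numeric(I_max)),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  cat(sprintf("ImageStack (%s): %d slices of %d x %d, gap %.3g mm\n",
              x$plane, x$n_slices, dim(x$pixels)[1], dim(x$pixels)[2],
              x$slice_gap))
  invisible(x)
}

# axis bookkeeping: world axis indices (x=1,y=2,z=3) for each plane label
plane_axes <- function(plane) {
  switch(plane,
         transverse = list(normal = 3L, inplane = c(1L, 2L)),
         coronal    = list(normal = 2L, inplane = c(1L, 3L)),
         sagittal   = list(normal = 1L, inplane = c(2L, 3L)),
         stop(sprintf("unknown plane label '%s'", plane)))
}

#' Reslice a volume into an image stack
#'
#' Slice `i` (1-based) is sampled on the plane at offset `(i - 1) *
#' slice_gap` along the plane normal from the volume origin, by trilinear
#' interpolation; in-plane sampling is at the native voxel spacing.  A
#' requested extent beyond the volume bounding box is clamped with a
#' warning.
#'
#' @param vol 3D array on `grid`
#' @param grid a [voxel_grid()]
#' @param plane `"transverse"`, `"coronal"` or `"sagittal"`
#' @param n_slices number of slices (>= 1)
#' @param slice_gap mm between slices (> 0)
#' @param I_max intensity ceiling recorded on the stack (values are not
#'   rescaled; sampled values are clipped into `[0, I_max]`)
#' @return an [image_stack()]
#' @export
reslice <- function(vol, grid, plane, n_slices, slice_gap, I_max = NULL) {
  ax <- plane_axes(plane)
  if (n_slices < 1) stop("reslice: n_slices must be >= 1")
  if (slice_gap <= 0) stop("reslice: slice_gap must be > 0")
  bb <- grid_bbox(grid)
  extent <- bb[2, ax$normal] - bb[1, ax$normal]
  if ((n_slices - 1) * slice_gap > extent + 1e-9) {
    n_fit <- max(1L, 1L + floor(extent / slice_gap))
    warning(sprintf(
      "reslice: %d slices at gap %.3g mm exceed the volume extent %.3g mm; clamped to %d slices",
      n_slices, slice_gap, extent, n_fit))
    n_slices <- n_fit
  }
  a1 <- grid_axis(grid, ax$inplane[1])
  a2 <- grid_axis(grid, ax$inplane[2])
  offs <- grid$origin[ax$normal] + (seq_len(n_slices) - 1) * slice_gap
  n1 <- length(a1); n2 <- length(a2)
  pix <- array(0, dim = c(n1, n2, n_slices))
  pts <- matrix(0, nrow = n1 * n2, ncol = 3)
  pts[, ax$inplane[1]] <- rep(a1, times = n2)
  pts[, ax$inplane[2]] <- rep(a2, each = n1)
  for (s in seq_len(n_slices)) {
    pts[, ax$normal] <- offs[s]
    pix[, , s] <- sample_volume(vol, grid, pts)
  }
  if (is.null(I_max)) I_max <- max(pix, 1e-12)
  pix <- pmin(pmax(pix, 0), I_max)
  org <- grid$origin
  image_stack(pix, plane, slice_gap,
              in_plane_spacing = grid$spacing[ax$inplane],
              origin = org, I_max = I_max)
}

#' Reassemble an image stack into a volume on its own grid
#'
#' The stack's sampling lattice is itself a regular grid (in-plane native
#' spacing, slice gap along the normal); this returns that volume plus its
#' `VoxelGrid`, with array axes permuted back to world (x, y, z) order.
#'
#' @param stack an `ImageStack`
#' @return list with elements `vol` (3D array) and `grid`
#' @export
stack_to_volume <- function(stack) {
  ax <- plane_axes(stack$plane)
  perm <- integer(3)
  perm[ax$inplane[1]] <- 1L
  perm[ax$inplane[2]] <- 2L
  perm[ax$normal] <- 3L
  vol <- aperm(stack$pixels, perm)
  spacing <- numeric(3)
  spacing[ax$inplane] <- stack$in_plane_spacing
  spacing[ax$normal] <- stack$slice_gap
  grid <- voxel_grid(dim(vol), spacing, stack$origin)
  list(vol = vol, grid = grid)
}
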