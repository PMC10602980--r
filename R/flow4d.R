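#' Time-resolved 4D flow dataset
#'
#' Container for one cardiac cycle of velocity-encoded MRI: a magnitude
#' volume and three signed velocity-component volumes per frame, plus grid
#' and timing metadata.  Velocities are stored in m/s; components are
#' clipped to `[-venc, venc]` on construction (the encodable range).
#'
#' @param grid a [voxel_grid()]
#' @param frame_times numeric, seconds, strictly increasing, within
#'   `[0, period_T)`
#' @param period_T cardiac period, seconds
#' @param magnitude 4D array `[nx, ny, nz, n_frames]`, arbitrary units >= 0
#' @param vx,vy,vz 4D arrays of signed velocity components, m/s
#' @param venc velocity-encoding limit, m/s (default 1.5, i.e. 150 cm/s)
#' @return an object of class `Flow4DDataset`
#' @export
flow4d_dataset <- function(grid, frame_times, period_T, magnitude,
                           vx, vy, vz, venc = 1.5) {
  stopifnot(inherits(grid, "VoxelGrid"))
  n_frames <- length(frame_times)
  if (n_frames < 1) stop("Flow4DDataset: need at least one frame")
  if (any(diff(frame_times) <= 0))
    stop("Flow4DDataset: frame_times must be strictly increasing")
  if (any(frame_times < 0) || any(frame_times >= period_T))
    stop("Flow4DDataset: frame_times must lie in [0, period_T)")
  if (venc <= 0) stop("Flow4DDataset: venc must be > 0")
  want <- c(grid$shape, n_frames)
  for (nm in c("magnitude", "vx", "vy", "vz")) {
    a <- get(nm)
    if (!identical(as.integer(dim(a)), as.integer(want)))
      stop(sprintf("grid mismatch: %s has dim (%s), expected (%s)", nm,
                   paste(dim(a), collapse = ","),
                   paste(want, collapse = ",")))
  }
  if (any(magnitude < 0)) stop("Flow4DDataset: magnitude must be >= 0")
  clip <- function(a) pmin(pmax(a, -venc), venc)
  structure(list(grid = grid, n_frames = n_frames,
                 frame_times = as.numeric(frame_times),
                 period_T = as.numeric(period_T),
                 magnitude = magnitude,
                 velocity = list(vx = clip(vx), vy = clip(vy), vz = clip(vz)),
                 venc = as.numeric(venc)),
            class = "Flow4DDataset")
}

#' @export
print.Flow4DDataset <- function(x, ...) {
  cat(sprintf(
    "Flow4DDataset: %d frames over T = %.3g s, VENC %.3g m/s\n",
    x$n_frames, x$period_T, x$venc))
  print(x$grid)
  invisible(x)
}

check_frame <- function(dataset, frame) {
  if (length(frame) != 1 || frame < 1 || frame > dataset$n_frames)
    stop(sprintf("frame index %s out of range 1..%d",
                 paste(frame, collapse = ","), dataset$n_frames))
  as.integer(frame)
}

#' Per-voxel velocity magnitude of one frame
#'
#' @param dataset a `Flow4DDataset`
#' @param frame frame index (1-based)
#' @return 3D array of speeds, m/s (bounded by `sqrt(3) * venc`)
#' @export
velocity_magnitude <- function(dataset, frame) {
  frame <- check_frame(dataset, frame)
  v <- dataset$velocity
  sqrt(v$vx[, , , frame]^2 + v$vy[, , , frame]^2 + v$vz[, , , frame]^2)
}

#' Spatial-mean speed per frame over the above-threshold mask
#'
#' Mean velocity magnitude of voxels moving faster than `v_threshold`, per
#' frame; 0 for frames with no above-threshold voxel.  This is the waveform
#' surrogate used to locate the systolic phases.
#'
#' @param dataset a `Flow4DDataset`
#' @param v_threshold m/s
#' @return numeric vector of length `n_frames`
#' @export
mean_speed_series <- function(dataset, v_threshold = 0.25) {
  vapply(seq_len(dataset$n_frames), function(f) {
    m <- velocity_magnitude(dataset, f)
    sel <- m >= v_threshold
    if (!any(sel)) 0 else mean(m[sel])
  }, numeric(1))
}
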