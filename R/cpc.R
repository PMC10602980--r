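#' Configuration for CPC-MRA synthesis
#'
#' Parameters of the composite phase-contrast angiogram.  The velocity
#' threshold defaults to 0.25 m/s (25 cm/s), the value at which lumen
#' contrast is good with low noise; 0.25-0.40 m/s is the useful range
#' (lower admits noise, higher risks underestimating the lumen).  The
#' intensity map is affine in speed up to `v_ceiling` (defaults to VENC, the
#' encodable maximum).
#'
#' @param v_threshold m/s; speeds below it map to background
#' @param v_ceiling m/s; speeds at or above it map to `I_max`.  `NULL`
#'   means "use the dataset VENC" (resolved when the config meets data).
#' @param phases integer frame indices to composite, or `NULL` for the
#'   automatic SA/PS/SD selection
#' @param blend_mode `"alpha-mean"` (equal-weight mean, default) or
#'   `"pixel-max"`
#' @param background_mode `"retain-magnitude"` (scaled anatomical image
#'   under the lumen signal) or `"suppress"` (zero background)
#' @param stretch_saturation fraction of pixels saturated at each tail by
#'   the final contrast stretch (default 0.01)
#' @param I_max intensity ceiling of the synthesized stacks (default 4095)
#' @return an object of class `CPCConfig`
#' @export
cpc_config <- function(v_threshold = 0.25, v_ceiling = NULL, phases = NULL,
                       blend_mode = c("alpha-mean", "pixel-max"),
                       background_mode = c("retain-magnitude", "suppress"),
                       stretch_saturation = 0.01, I_max = 4095) {
  blend_mode <- match.arg(blend_mode)
  background_mode <- match.arg(background_mode)
  if (v_threshold < 0) stop("CPCConfig: v_threshold must be >= 0")
  if (!is.null(v_ceiling) && v_threshold >= v_ceiling)
    stop("CPCConfig: need 0 <= v_threshold < v_ceiling")
  if (stretch_saturation < 0 || stretch_saturation >= 0.5)
    stop("CPCConfig: stretch_saturation must lie in [0, 0.5)")
  if (!is.null(phases) && length(phases) == 0)
    stop("CPCConfig: phases must be non-empty or NULL")
  structure(list(v_threshold = v_threshold, v_ceiling = v_ceiling,
                 phases = if (is.null(phases)) NULL else as.integer(phases),
                 blend_mode = blend_mode, background_mode = background_mode,
                 stretch_saturation = stretch_saturation, I_max = I_max),
            class = "CPCConfig")
}

resolve_ceiling <- function(config, dataset) {
  if (is.null(config$v_ceiling)) dataset$venc else config$v_ceiling
}

#' Automatic selection of the systolic phases (SA, PS, SD)
#'
#' Locates the three frames merged into the composite: peak systole (PS) is
#' the frame maximizing the spatial-mean speed over the above-threshold
#' mask; systolic acceleration (SA) is the frame before PS, among those with
#' mean >= 50% of the PS mean, with the steepest rising mean; systolic
#' deceleration (SD) the symmetric choice after PS (steepest falling).  The
#' search is circular in the cardiac cycle.  This automates the manual
#' choice of frames near 0.21 T / 0.26 T / 0.36 T; explicit indices in
#' [cpc_config()] override it.
#'
#' @param dataset a [flow4d_dataset()]
#' @param v_threshold m/s mask threshold for the mean-speed series
#' @return integer vector `c(SA, PS, SD)` of frame indices
#' @export
select_systolic_phases <- function(dataset, v_threshold = 0.25) {
  n <- dataset$n_frames
  if (n < 3) stop("select_systolic_phases: need at least 3 frames")
  m <- mean_speed_series(dataset, v_threshold)
  if (all(m == 0) || diff(range(m)) < 1e-12 && max(m) == 0)
    stop("no systolic phase detectable: zero-flow dataset")
  ps <- which.max(m)
  if (diff(range(m)) < 1e-9) {
    warning("select_systolic_phases: constant flow; returning adjacent frames")
    ps2 <- max(2L, min(ps, n - 1L))
    return(c(ps2 - 1L, ps2, ps2 + 1L))
  }
  cidx <- function(i) ((i - 1L) %% n) + 1L
  grad <- m[cidx(seq_len(n) + 1L)] - m  # forward circular gradient
  half <- 0.5 * m[ps]
  # candidates strictly before PS (circularly, within half a cycle)
  before <- cidx(ps - seq_len(floor(n / 2)))
  before <- before[m[before] >= half]
  sa <- if (length(before)) before[which.max(grad[before])] else cidx(ps - 1L)
  after <- cidx(ps + seq_len(floor(n / 2)))
  after <- after[m[after] >= half]
  sd_ <- if (length(after)) after[which.min(grad[cidx(after - 1L)])] else cidx(ps + 1L)
  if (sa == ps) sa <- cidx(ps - 1L)
  if (sd_ == ps) sd_ <- cidx(ps + 1L)
  c(SA = sa, PS = ps, SD = sd_)
}

#' Velocity-proportional image stack at one cardiac phase
#'
#' Reslices the frame's velocity magnitude into the requested plane and maps
#' it to intensity: pixels with speed `v >= v_threshold` get `I_max *
#' min(v, v_ceiling) / v_ceiling`; sub-threshold pixels show the background,
#' either 0 (`"suppress"`) or the resliced anatomical magnitude image
#' rescaled so its maximum is 25% of `I_max` (`"retain-magnitude"`), so the
#' lumen always dominates.  The set of above-threshold pixels is attached as
#' attribute `vmask` for downstream provenance.
#'
#' @param dataset a [flow4d_dataset()]
#' @param frame frame index
#' @param config a [cpc_config()]
#' @param plane,n_slices,slice_gap reslicing geometry (see [reslice()])
#' @return an [image_stack()]
#' @export
phase_stack <- function(dataset, frame, config, plane = "transverse",
                        n_slices, slice_gap = 0.35) {
  stopifnot(inherits(config, "CPCConfig"))
  frame <- check_frame(dataset, frame)
  vceil <- resolve_ceiling(config, dataset)
  vmag <- velocity_magnitude(dataset, frame)
  vs <- reslice(vmag, dataset$grid, plane, n_slices, slice_gap,
                I_max = sqrt(3) * dataset$venc)
  v <- vs$pixels
  above <- v >= config$v_threshold
  pix <- array(0, dim = dim(v))
  pix[above] <- config$I_max * pmin(v[above], vceil) / vceil
  if (config$background_mode == "retain-magnitude") {
    ms <- reslice(dataset$magnitude[, , , frame], dataset$grid, plane,
                  dim(v)[3], slice_gap, I_max = NULL)
    bg <- ms$pixels
    if (max(bg) > 0) bg <- bg / max(bg) * 0.25 * config$I_max
    pix[!above] <- bg[!above]
  }
  out <- image_stack(pix, plane, slice_gap, vs$in_plane_spacing, vs$origin,
                     I_max = config$I_max)
  attr(out, "vmask") <- above
  out
}

#' Contrast stretch to the full intensity range
#'
#' Linear remap sending the `saturation` quantile to 0 and the
#' `1 - saturation` quantile to `I_max`, clipping outside; a constant image
#' is returned unchanged (degenerate rule).  With `saturation = 0.01` about
#' 1% of pixels saturate at each tail, filling the available range.
#'
#' @param stack an [image_stack()]
#' @param saturation fraction per tail in `[0, 0.5)`
#' @return an [image_stack()]
#' @export
contrast_stretch <- function(stack, saturation = 0.01) {
  stopifnot(inherits(stack, "ImageStack"))
  if (saturation < 0 || saturation >= 0.5)
    stop("contrast_stretch: saturation must lie in [0, 0.5)")
  px <- stack$pixels
  q <- stats::quantile(px, c(saturation, 1 - saturation), names = FALSE,
                       type = 7)
  if (q[2] <= q[1]) return(stack)  # constant (or degenerate) image
  out <- (px - q[1]) / (q[2] - q[1]) * stack$I_max
  out <- pmin(pmax(out, 0), stack$I_max)
  res <- image_stack(out, stack$plane, stack$slice_gap,
                     stack$in_plane_spacing, stack$origin, stack$I_max)
  attr(res, "vmask") <- attr(stack, "vmask")
  res
}

stack_geometry_key <- function(s) {
  list(plane = s$plane, dim = dim(s$pixels), gap = s$slice_gap,
       sp = s$in_plane_spacing)
}

#' Composite CPC-MRA stack from per-phase stacks
#'
#' Merges velocity-mapped stacks from several cardiac phases slice by slice.
#' The slice-wise "sum" of phases is realized as equal-weight alpha
#' blending (per-pixel mean) so intensity stays uniform where phases
#' overlap; `"pixel-max"` keeps each region at its brightest phase.  The
#' blend is followed by a contrast stretch to `[0, I_max]`.  Per-pixel
#' provenance (which phases exceeded the velocity threshold) is kept in
#' `$phase_provenance` as a logical array `[i, j, slice, phase]`.
#'
#' @param stacks list of [image_stack()]s from [phase_stack()] (matching
#'   geometry)
#' @param config a [cpc_config()]
#' @return a `CPCStack` (an `ImageStack` with `config` and
#'   `phase_provenance` fields)
#' @export
composite <- function(stacks, config) {
  stopifnot(inherits(config, "CPCConfig"), length(stacks) >= 1)
  g1 <- stack_geometry_key(stacks[[1]])
  for (s in stacks[-1])
    if (!identical(stack_geometry_key(s), g1))
      stop("stack mismatch: composited stacks must share plane, shape, spacing and gap")
  arrs <- lapply(stacks, function(s) s$pixels)
  blended <- if (config$blend_mode == "alpha-mean") {
    Reduce(`+`, arrs) / length(arrs)
  } else {
    Reduce(pmax, arrs)
  }
  prov <- vapply(stacks, function(s) {
    vm <- attr(s, "vmask")
    if (is.null(vm)) {
      # stacks built outside phase_stack: anything above the background
      # ceiling (25% of I_max) is taken as lumen signal
      vm <- if (config$background_mode == "suppress") s$pixels > 0
            else s$pixels > 0.25 * config$I_max
    }
    vm
  }, FUN.VALUE = array(TRUE, dim = dim(arrs[[1]])))
  prov <- array(prov, dim = c(dim(arrs[[1]]), length(stacks)))
  base <- stacks[[1]]
  out <- image_stack(blended, base$plane, base$slice_gap,
                     base$in_plane_spacing, base$origin, base$I_max)
  attr(out, "vmask") <- apply(prov, 1:3, any)
  out <- contrast_stretch(out, config$stretch_saturation)
  out$config <- config
  out$phase_provenance <- prov
  class(out) <- c("CPCStack", "ImageStack")
  out
}

#' @export
print.CPCStack <- function(x, ...) {
  cat("CPC-MRA composite ")
  NextMethod()
}

#' One-call CPC-MRA build
#'
#' Runs phase selection (unless `config$phases` is set), per-phase stack
#' synthesis and compositing.
#'
#' @inheritParams phase_stack
#' @return a `CPCStack`
#' @export
build_cpc <- function(dataset, config = cpc_config(), plane = "transverse",
                      n_slices = NULL, slice_gap = 0.35) {
  phases <- config$phases
  if (is.null(phases))
    phases <- select_systolic_phases(dataset, config$v_threshold)
  if (is.null(n_slices)) {
    ax <- plane_axes(plane)
    extent <- diff(grid_bbox(dataset$grid)[, ax$normal])
    n_slices <- max(1L, 1L + floor(extent / slice_gap))
  }
  stacks <- lapply(phases, function(f)
    phase_stack(dataset, f, config, plane, n_slices, slice_gap))
  out <- composite(stacks, config)
  out$phases <- phases
  out
}

#' False-color overlay of the SA/PS/SD stacks
#'
#' Renders where the three systolic phases agree: pixels above threshold in
#' all three phases are white; a pixel bright only at peak systole shows in
#' magenta, only at systolic deceleration in green, only at systolic
#' acceleration in blue.  Channel values are the per-phase normalized
#' intensities.
#'
#' @param sa,ps,sd_ the three [phase_stack()] outputs (matching geometry)
#' @param v_threshold m/s (used only if stacks lack their `vmask`
#'   attribute)
#' @param I_max output channel ceiling (default 1: RGB in `[0, 1]`)
#' @return 4D array `[i, j, slice, rgb]`
#' @export
false_color_overlay <- function(sa, ps, sd_, v_threshold = 0.25, I_max = 1) {
  g1 <- stack_geometry_key(sa)
  if (!identical(stack_geometry_key(ps), g1) ||
      !identical(stack_geometry_key(sd_), g1))
    stop("stack mismatch: overlay stacks must share geometry")
  norm <- function(s) s$pixels / s$I_max
  msk <- function(s) {
    vm <- attr(s, "vmask")
    if (is.null(vm)) vm <- s$pixels > 0
    vm
  }
  a <- norm(sa); p <- norm(ps); d <- norm(sd_)
  ma <- msk(sa); mp <- msk(ps); md <- msk(sd_)
  # magenta = R + B for PS, green for SD, blue for SA; white where all agree
  r <- p * mp
  g <- d * md
  b <- pmax(p * mp, a * ma)
  allm <- ma & mp & md
  lum <- pmax(a, p, d)
  r[allm] <- lum[allm]; g[allm] <- lum[allm]; b[allm] <- lum[allm]
  out <- array(0, dim = c(dim(a), 3))
  out[, , , 1] <- r; out[, , , 2] <- g; out[, , , 3] <- b
  out * I_max
}

#' Above-threshold mask of a stack or composite
#'
#' @param stack an `ImageStack` or `CPCStack`
#' @return logical array matching the stack pixels
#' @export
stack_vmask <- function(stack) {
  vm <- attr(stack, "vmask")
  if (is.null(vm)) stop("stack carries no velocity-threshold provenance")
  vm
}
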