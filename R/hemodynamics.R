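#' Blood (fluid) properties
#'
#' Defaults are the standard Newtonian blood assumption: density 1060
#' kg/m^3, dynamic viscosity 0.004 Pa s.
#'
#' @param density kg/m^3
#' @param dynamic_viscosity Pa s
#' @return an object of class `FluidProperties`
#' @export
fluid_properties <- function(density = 1060, dynamic_viscosity = 0.004) {
  if (density <= 0 || dynamic_viscosity <= 0)
    stop("FluidProperties: density and viscosity must be > 0")
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "FluidProperties")
}

#' Wall-shear-stress field over one cardiac cycle
#'
#' Per-surface-element WSS vector time series.  `tau` is an `n_elements x
#' n_times x 3` array (Pa).  Times must be strictly increasing within
#' `[0, period_T]`; the cycle integrals close periodically (the last sample
#' wraps to `t = T` using the first) when the endpoint is not duplicated.
#'
#' @param element_ids identifiers (length n)
#' @param element_areas mm^2, > 0
#' @param times seconds, strictly increasing, length m >= 2
#' @param tau n x m x 3 array, Pa
#' @param period_T cardiac period, seconds
#' @return an object of class `WSSField`
#' @export
wss_field <- function(element_ids, element_areas, times, tau, period_T) {
  n <- length(element_ids)
  m <- length(times)
  if (m < 2) stop("WSSField: need at least 2 time samples")
  if (any(diff(times) <= 0)) stop("WSSField: times must be strictly increasing")
  if (times[1] < 0 || times[m] > period_T + 1e-12)
    stop("WSSField: times must lie within [0, period_T]")
  if (any(element_areas <= 0)) stop("WSSField: areas must be > 0")
  if (!identical(as.integer(dim(tau)), as.integer(c(n, m, 3))))
    stop("WSSField: tau must be an n_elements x n_times x 3 array")
  structure(list(element_ids = element_ids,
                 element_areas = as.numeric(element_areas),
                 times = as.numeric(times), tau = tau,
                 period_T = as.numeric(period_T)),
            class = "WSSField")
}

#' @export
print.WSSField <- function(x, ...) {
  cat(sprintf("WSSField: %d elements x %d times over T = %.3g s\n",
              length(x$element_ids), length(x$times), x$period_T))
  invisible(x)
}

# close the cycle: append t = T with the first sample unless already there
closed_cycle <- function(field) {
  t <- field$times
  tau <- field$tau
  if (abs(t[length(t)] - field$period_T) > 1e-12) {
    t <- c(t, field$period_T)
    first <- field$tau[, 1, , drop = FALSE]
    tau <- array(0, dim = c(dim(field$tau)[1], length(t), 3))
    tau[, seq_along(field$times), ] <- field$tau
    tau[, length(t), ] <- first[, 1, ]
  }
  list(times = t, tau = tau)
}

trapz_rows <- function(times, M) {
  # row-wise trapezoid integral of an n x m matrix sampled at `times`
  dt <- diff(times)
  w <- c(dt / 2, 0) + c(0, dt / 2)
  as.numeric(M %*% w)
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' `TAWSS = (1/T) integral_0^T |tau(t)| dt` per element, by trapezoidal
#' quadrature with periodic closure of the cycle.
#'
#' @param field a [wss_field()]
#' @return numeric vector, Pa, one value per element
#' @export
tawss <- function(field) {
  stopifnot(inherits(field, "WSSField"))
  cc <- closed_cycle(field)
  mag <- sqrt(cc$tau[, , 1]^2 + cc$tau[, , 2]^2 + cc$tau[, , 3]^2)
  mag <- matrix(mag, nrow = dim(cc$tau)[1])
  trapz_rows(cc$times, mag) / field$period_T
}

#' Oscillatory shear index (OSI)
#'
#' `OSI = 0.5 * (1 - |integral tau dt| / integral |tau| dt)` per element;
#' 0 for unidirectional shear, 0.5 for fully reversing shear with zero
#' mean.  Elements with zero total shear get OSI 0 (degenerate rule).
#'
#' @param field a [wss_field()]
#' @return numeric vector in `[0, 0.5]`
#' @export
osi <- function(field) {
  stopifnot(inherits(field, "WSSField"))
  cc <- closed_cycle(field)
  n <- dim(cc$tau)[1]
  ix <- trapz_rows(cc$times, matrix(cc$tau[, , 1], nrow = n))
  iy <- trapz_rows(cc$times, matrix(cc$tau[, , 2], nrow = n))
  iz <- trapz_rows(cc$times, matrix(cc$tau[, , 3], nrow = n))
  mag <- sqrt(cc$tau[, , 1]^2 + cc$tau[, , 2]^2 + cc$tau[, , 3]^2)
  imag <- trapz_rows(cc$times, matrix(mag, nrow = n))
  out <- numeric(n)
  nz <- imag > 0
  ratio <- sqrt(ix[nz]^2 + iy[nz]^2 + iz[nz]^2) / imag[nz]
  out[nz] <- 0.5 * (1 - pmin(ratio, 1))
  out
}

#' Upper and lower extreme-value element subsets
#'
#' The upper subset holds elements with values at or above the
#' `1 - fraction` quantile, the lower those at or below the `fraction`
#' quantile (quantiles over element counts, linear interpolation); ties at
#' the cut are included, so a subset may exceed `fraction * n` elements.
#'
#' @param values per-element values
#' @param fraction tail fraction in (0, 0.5), default 0.05
#' @return list with integer index vectors `upper` and `lower`
#' @export
extreme_regions <- function(values, fraction = 0.05) {
  if (fraction <= 0 || fraction >= 0.5)
    stop("extreme_regions: fraction must lie in (0, 0.5)")
  if (diff(range(values)) == 0) {
    warning("extreme_regions: all values equal; both subsets are all elements")
    return(list(upper = seq_along(values), lower = seq_along(values)))
  }
  qs <- stats::quantile(values, c(fraction, 1 - fraction), names = FALSE,
                        type = 7)
  list(upper = which(values >= qs[2]), lower = which(values <= qs[1]))
}

#' Cross-sectional flow waveform from a 4D flow dataset
#'
#' For each cardiac frame and each of the analysis planes (transverse
#' planes at the given z positions), the flow rate is the sum of
#' through-plane velocity times pixel area over lumen pixels on the
#' dataset's nearest native slice.  The per-frame mean and SD across the
#' planes form the raw waveform, which is interpolated with a natural cubic
#' spline to a dense series at `dt` (default 1 ms).
#'
#' @param dataset a [flow4d_dataset()]
#' @param plane_z z positions of the analysis planes, mm (default: 5
#'   equally spaced planes through the lumen extent)
#' @param lumen_mask a [binary_mask()] on the dataset grid
#' @param dt interpolation step, seconds
#' @return an object of class `FlowWaveform`: `times`, `q_mean`, `q_sd`
#'   (m^3/s), `interpolated` (data.frame `t`, `q`)
#' @export
flow_waveform <- function(dataset, plane_z = NULL, lumen_mask, dt = 0.001) {
  stopifnot(inherits(dataset, "Flow4DDataset"),
            inherits(lumen_mask, "BinaryMask"))
  g <- dataset$grid
  if (!identical(g$shape, lumen_mask$grid$shape))
    stop("flow_waveform: mask grid does not match the dataset grid")
  zax <- grid_axis(g, 3)
  if (is.null(plane_z)) {
    zn <- range(zax[apply(lumen_mask$voxels, 3, any)])
    plane_z <- seq(zn[1], zn[2], length.out = 7)[2:6]
  }
  ks <- vapply(plane_z, function(z) which.min(abs(zax - z)), integer(1))
  for (i in seq_along(ks))
    if (!any(lumen_mask$voxels[, , ks[i]]))
      stop(sprintf("flow_waveform: plane %d (z = %.1f mm) misses the lumen",
                   i, plane_z[i]))
  pix_area_m2 <- prod(g$spacing[1:2]) * 1e-6
  Q <- matrix(0, nrow = dataset$n_frames, ncol = length(ks))
  for (f in seq_len(dataset$n_frames)) {
    vz <- dataset$velocity$vz[, , , f]
    for (i in seq_along(ks)) {
      k <- ks[i]
      sel <- lumen_mask$voxels[, , k]
      Q[f, i] <- sum(vz[, , k][sel]) * pix_area_m2
    }
  }
  q_mean <- rowMeans(Q)
  q_sd <- apply(Q, 1, stats::sd)
  tt <- seq(0, dataset$period_T, by = dt)
  sp <- stats::spline(dataset$frame_times, q_mean, xout = tt,
                      method = "natural")
  structure(list(times = dataset$frame_times, q_mean = q_mean, q_sd = q_sd,
                 per_plane = Q,
                 interpolated = data.frame(t = sp$x, q = sp$y)),
            class = "FlowWaveform")
}

#' @export
print.FlowWaveform <- function(x, ...) {
  cat(sprintf("FlowWaveform: %d raw frames, peak %.3g m^3/s, dense dt = %.3g s\n",
              length(x$times), max(x$q_mean),
              diff(x$interpolated$t[1:2])))
  invisible(x)
}

#' Parabolic (Poiseuille) velocity profile for a given flow rate
#'
#' `u(r) = 2 (q / (pi R^2)) (1 - (r/R)^2)`: no-slip at the wall, centerline
#' velocity twice the spatial mean `q / (pi R^2)`.  Radii beyond `R`
#' return 0.
#'
#' @param q flow rate, m^3/s
#' @param radius tube radius R, m
#' @param points radial positions, m
#' @return velocity samples, m/s
#' @export
parabolic_profile <- function(q, radius, points) {
  if (radius <= 0) stop("parabolic_profile: radius must be > 0")
  u <- 2 * (q / (pi * radius^2)) * (1 - (points / radius)^2)
  u[points > radius] <- 0
  u
}

#' Reynolds number
#'
#' `Re = rho U D / mu`.
#'
#' @param fluid a [fluid_properties()]
#' @param U characteristic velocity, m/s (> 0)
#' @param D characteristic diameter, m (> 0)
#' @return dimensionless Reynolds number
#' @export
reynolds <- function(fluid, U, D) {
  stopifnot(inherits(fluid, "FluidProperties"))
  if (U <= 0 || D <= 0) stop("reynolds: U and D must be > 0")
  fluid$density * U * D / fluid$dynamic_viscosity
}

#' Read / write WSS fields as long-format CSV
#'
#' Columns: `element_id, area_mm2, t_s, taux_Pa, tauy_Pa, tauz_Pa`.
#'
#' @param field a [wss_field()]
#' @param path CSV file
#' @param period_T cardiac period for the reader (defaults to the largest
#'   time in the file)
#' @return `path` invisibly / a `WSSField`
#' @export
write_wss_csv <- function(field, path) {
  n <- length(field$element_ids)
  m <- length(field$times)
  df <- data.frame(element_id = rep(field$element_ids, times = m),
                   area_mm2 = rep(field$element_areas, times = m),
                   t_s = rep(field$times, each = n),
                   taux_Pa = as.numeric(field$tau[, , 1]),
                   tauy_Pa = as.numeric(field$tau[, , 2]),
                   tauz_Pa = as.numeric(field$tau[, , 3]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wss_csv
#' @export
read_wss_csv <- function(path, period_T = NULL) {
  df <- utils::read.csv(path)
  ids <- unique(df$element_id)
  times <- sort(unique(df$t_s))
  n <- length(ids); m <- length(times)
  o <- order(match(df$t_s, times), match(df$element_id, ids))
  df <- df[o, ]
  tau <- array(0, dim = c(n, m, 3))
  tau[, , 1] <- df$taux_Pa
  tau[, , 2] <- df$tauy_Pa
  tau[, , 3] <- df$tauz_Pa
  areas <- df$area_mm2[seq_len(n)]
  if (is.null(period_T)) period_T <- max(times)
  wss_field(ids, areas, times, tau, period_T)
}
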