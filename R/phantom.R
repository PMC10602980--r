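#' Synthetic pulsatile-flow phantom specification
#'
#' Describes a vessel phantom with analytically known geometry and flow,
#' emulating the target acquisition: ~20 frames per cardiac cycle, VENC
#' 1.5 m/s, low-contrast magnitude background, a systolic-dominated
#' waveform peaking near 0.25 T, and an optional distal temporal lag of the
#' pulse along the vessel axis.  The default grid spacing mirrors the
#' acquired anisotropic resolution (3.6 x 2.4 x 2.6 mm); isotropic fine
#' grids are available for convergence studies.
#'
#' @param shape `"straight-tube"`, `"torus-bend"` or `"y-bifurcation"`
#' @param tube_radius mm (default 6)
#' @param tube_length mm, straight tube / Y parent+daughter length scale
#' @param bend_radius mm, torus bend radius (default 50)
#' @param bend_degrees torus arc angle (default 300)
#' @param bifurcation_angle_deg full angle between the Y daughters
#'   (default 70)
#' @param grid_spacing mm triple (default `c(3.6, 2.4, 2.6)`)
#' @param n_frames frames per cycle (default 20)
#' @param period_T s (default 1)
#' @param waveform list: `type` (`"systolic"`, `"constant"`, `"sine"`),
#'   `peak_frame` (default 6, i.e. ~0.25 T), `peak_mean_velocity` m/s
#'   (default 0.6), `baseline` m/s (default 0.03), `width_frames` pulse
#'   width (default 7)
#' @param venc m/s (default 1.5)
#' @param noise_sigma Rician noise level as a fraction of the tissue
#'   signal ceiling (default 0)
#' @param distal_lag frames of pulse delay accumulated from inlet to
#'   outlet (default 0)
#' @param margin_mm padding between tube and grid edge (default 7)
#' @param seed integer fixing all randomness (default 1)
#' @return an object of class `PhantomSpec`
#' @export
phantom_spec <- function(shape = c("straight-tube", "torus-bend",
                                   "y-bifurcation"),
                         tube_radius = 6, tube_length = 120,
                         bend_radius = 50, bend_degrees = 300,
                         bifurcation_angle_deg = 70,
                         grid_spacing = c(3.6, 2.4, 2.6),
                         n_frames = 20, period_T = 1.0,
                         waveform = list(), venc = 1.5, noise_sigma = 0,
                         distal_lag = 0, margin_mm = 7, seed = 1) {
  shape <- match.arg(shape)
  wf <- utils::modifyList(list(type = "systolic", peak_frame = 6,
                               peak_mean_velocity = 0.6, baseline = 0.03,
                               width_frames = 7), waveform)
  if (wf$peak_mean_velocity > venc)
    stop("PhantomSpec: peak mean velocity must not exceed VENC")
  structure(list(shape = shape, tube_radius = tube_radius,
                 tube_length = tube_length, bend_radius = bend_radius,
                 bend_degrees = bend_degrees,
                 bifurcation_angle_deg = bifurcation_angle_deg,
                 grid_spacing = as.numeric(grid_spacing),
                 n_frames = as.integer(n_frames), period_T = period_T,
                 waveform = wf, venc = venc, noise_sigma = noise_sigma,
                 distal_lag = distal_lag, margin_mm = margin_mm,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

# mean-velocity waveform U(t), vectorized over t (seconds, wrapped to the
# cycle)
waveform_velocity <- function(spec, t) {
  wf <- spec$waveform
  T <- spec$period_T
  tm <- t %% T
  switch(wf$type,
    constant = rep(wf$peak_mean_velocity, length(tm)),
    sine = wf$peak_mean_velocity * sin(2 * pi * tm / T),
    systolic = {
      dt <- T / spec$n_frames
      tpk <- (wf$peak_frame - 1) * dt
      w <- wf$width_frames * dt
      dd <- abs(((tm - tpk + T / 2) %% T) - T / 2)  # circular distance
      bump <- ifelse(dd <= w / 2, 0.5 * (1 + cos(2 * pi * dd / w)), 0)
      wf$baseline + (wf$peak_mean_velocity - wf$baseline) * bump
    },
    stop(sprintf("unknown waveform type '%s'", wf$type)))
}

# geometry query: for points P (n x 3, mm) return radial distance to the
# vessel axis, axial fraction in [0, 1], unit tangent rows and an in-vessel
# domain flag
phantom_geometry <- function(spec, P) {
  R <- spec$tube_radius
  if (spec$shape == "straight-tube") {
    r <- sqrt(P[, 1]^2 + P[, 2]^2)
    sfrac <- P[, 3] / spec$tube_length
    tang <- matrix(rep(c(0, 0, 1), each = nrow(P)), ncol = 3)
    dom <- P[, 3] >= 0 & P[, 3] <= spec$tube_length
  } else if (spec$shape == "torus-bend") {
    th <- atan2(P[, 2], P[, 1]) %% (2 * pi)
    thmax <- spec$bend_degrees * pi / 180
    q <- cbind(spec$bend_radius * cos(th), spec$bend_radius * sin(th), 0)
    r <- sqrt(rowSums((P - q)^2))
    sfrac <- th / thmax
    tang <- cbind(-sin(th), cos(th), 0)
    dom <- th <= thmax
  } else {  # y-bifurcation
    zb <- spec$tube_length * 0.45
    Ld <- spec$tube_length * 0.55
    half <- spec$bifurcation_angle_deg / 2 * pi / 180
    d1 <- c(sin(half), 0, cos(half))
    d2 <- c(-sin(half), 0, cos(half))
    seg_dist <- function(p0, dvec, len) {
      rel <- sweep(P, 2, p0, "-")
      t_ <- pmin(pmax(rel %*% dvec, 0), len)
      perp <- rel - t_ %*% t(dvec)
      list(r = sqrt(rowSums(perp^2)), t = as.numeric(t_))
    }
    par <- seg_dist(c(0, 0, 0), c(0, 0, 1), zb)
    b1 <- seg_dist(c(0, 0, zb), d1, Ld)
    b2 <- seg_dist(c(0, 0, zb), d2, Ld)
    rs <- cbind(par$r, b1$r, b2$r)
    which_br <- max.col(-rs)  # branch with minimal radial distance
    r <- rs[cbind(seq_len(nrow(P)), which_br)]
    s_along <- ifelse(which_br == 1, par$t,
                      zb + ifelse(which_br == 2, b1$t, b2$t))
    sfrac <- s_along / (zb + Ld)
    tang <- matrix(0, nrow(P), 3)
    tang[which_br == 1, ] <- matrix(rep(c(0, 0, 1),
                                        each = sum(which_br == 1)), ncol = 3)
    tang[which_br == 2, ] <- matrix(rep(d1, each = sum(which_br == 2)),
                                    ncol = 3)
    tang[which_br == 3, ] <- matrix(rep(d2, each = sum(which_br == 3)),
                                    ncol = 3)
    dom <- rep(TRUE, nrow(P))
  }
  list(r = r, sfrac = pmin(pmax(sfrac, 0), 1), tangent = tang,
       inside = dom & (r <= R))
}

phantom_grid <- function(spec) {
  m <- spec$margin_mm
  R <- spec$tube_radius
  if (spec$shape == "straight-tube") {
    lo <- c(-R - m, -R - m, -m)
    hi <- c(R + m, R + m, spec$tube_length + m)
  } else if (spec$shape == "torus-bend") {
    ext <- spec$bend_radius + R + m
    lo <- c(-ext, -ext, -R - m)
    hi <- c(ext, ext, R + m)
  } else {
    zb <- spec$tube_length * 0.45
    Ld <- spec$tube_length * 0.55
    half <- spec$bifurcation_angle_deg / 2 * pi / 180
    xex <- Ld * sin(half) + R + m
    lo <- c(-xex, -R - m, -m)
    hi <- c(xex, R + m, zb + Ld * cos(half) + m)
  }
  shape <- pmax(2L, as.integer(ceiling((hi - lo) / spec$grid_spacing)) + 1L)
  voxel_grid(shape, spec$grid_spacing, lo)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# watertight tube mesh around a polyline, parallel-transport frames, fan
# caps at both ends
tube_mesh <- function(points, radius, n_theta = 48) {
  P <- matrix(as.numeric(points), ncol = 3)
  n <- nrow(P)
  # central-difference tangents
  tangents <- matrix(0, n, 3)
  tangents[1, ] <- P[2, ] - P[1, ]
  tangents[n, ] <- P[n, ] - P[n - 1, ]
  if (n > 2) tangents[2:(n - 1), ] <- P[3:n, , drop = FALSE] -
      P[1:(n - 2), , drop = FALSE]
  tangents <- tangents / sqrt(rowSums(tangents^2))
  # initial normal: any vector not parallel to t1
  t1 <- tangents[1, ]
  ref <- if (abs(t1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  nrm <- ref - sum(ref * t1) * t1
  nrm <- nrm / sqrt(sum(nrm^2))
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  verts <- matrix(0, n * n_theta + 2, 3)
  for (i in seq_len(n)) {
    ti <- tangents[i, ]
    if (i > 1) {
      # parallel transport of the frame normal
      tp <- tangents[i - 1, ]
      ax <- c(tp[2] * ti[3] - tp[3] * ti[2], tp[3] * ti[1] - tp[1] * ti[3],
              tp[1] * ti[2] - tp[2] * ti[1])
      s <- sqrt(sum(ax^2))
      if (s > 1e-12) {
        ax <- ax / s
        ang <- atan2(s, sum(tp * ti))
        nrm <- nrm * cos(ang) + c(ax[2] * nrm[3] - ax[3] * nrm[2],
                                  ax[3] * nrm[1] - ax[1] * nrm[3],
                                  ax[1] * nrm[2] - ax[2] * nrm[1]) *
          sin(ang) + ax * sum(ax * nrm) * (1 - cos(ang))
      }
      nrm <- nrm - sum(nrm * ti) * ti
      nrm <- nrm / sqrt(sum(nrm^2))
    }
    bin <- c(ti[2] * nrm[3] - ti[3] * nrm[2], ti[3] * nrm[1] - ti[1] * nrm[3],
             ti[1] * nrm[2] - ti[2] * nrm[1])
    ring <- sweep(outer(cos(theta), nrm) + outer(sin(theta), bin), 1,
                  radius, "*")
    verts[((i - 1) * n_theta + 1):(i * n_theta), ] <- sweep(ring, 2, P[i, ],
                                                            "+")
  }
  c0 <- n * n_theta + 1  # start cap center
  c1 <- n * n_theta + 2  # end cap center
  verts[c0, ] <- P[1, ]
  verts[c1, ] <- P[n, ]
  faces <- list()
  for (i in seq_len(n - 1)) {
    a <- (i - 1) * n_theta + seq_len(n_theta)
    b <- i * n_theta + seq_len(n_theta)
    a2 <- c(a[-1], a[1])
    b2 <- c(b[-1], b[1])
    faces[[i]] <- rbind(cbind(a, b2, b), cbind(a, a2, b2))
  }
  a <- seq_len(n_theta)
  a2 <- c(a[-1], a[1])
  capA <- cbind(rep(c0, n_theta), a2, a)
  b <- (n - 1) * n_theta + seq_len(n_theta)
  b2 <- c(b[-1], b[1])
  capB <- cbind(rep(c1, n_theta), b, b2)
  Fm <- rbind(do.call(rbind, faces), capA, capB)
  surf <- surface_model(verts, Fm)
  if (mesh_volume(surf) < 0) surf$faces <- surf$faces[, c(1, 3, 2)]
  surf
}

phantom_axis_points <- function(spec, step = 1) {
  if (spec$shape == "straight-tube") {
    z <- seq(0, spec$tube_length, by = step)
    cbind(0, 0, z)
  } else if (spec$shape == "torus-bend") {
    thmax <- spec$bend_degrees * pi / 180
    th <- seq(0, thmax, by = step / spec$bend_radius)
    cbind(spec$bend_radius * cos(th), spec$bend_radius * sin(th), 0)
  } else {
    zb <- spec$tube_length * 0.45
    Ld <- spec$tube_length * 0.55
    half <- spec$bifurcation_angle_deg / 2 * pi / 180
    d1 <- c(sin(half), 0, cos(half))
    par <- cbind(0, 0, seq(0, zb, by = step))
    t1 <- seq(step, Ld, by = step)
    rbind(par, sweep(outer(t1, d1), 2, c(0, 0, zb), "+"))
  }
}

#' Generate a synthetic 4D flow dataset with ground truth
#'
#' The velocity field is an axial parabolic (Poiseuille) profile
#' `u(r, t) = 2 U(t - lag(s)) (1 - (r/R)^2)` along the local vessel axis,
#' evaluated at voxel centers; the magnitude image is a low-contrast
#' two-level background (tissue vs lumen) with Rician noise; velocity
#' components get Gaussian noise scaled from `noise_sigma` and VENC, then
#' are clipped to the encodable range.  Everything is deterministic given
#' `spec$seed`.
#'
#' @param spec a [phantom_spec()]
#' @return list with `dataset` (a [flow4d_dataset()]), `truth` (a
#'   `PhantomTruth`: `surface`, `centerline`, `radius`, `curvature_m1`,
#'   `bifurcation_angle_deg`, `waveform` data.frame, `wall_shear` Pa
#'   series, plus per-branch centerlines for the Y phantom) and `spec`
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  grid <- phantom_grid(spec)
  P <- as.matrix(expand.grid(x = grid_axis(grid, 1), y = grid_axis(grid, 2),
                             z = grid_axis(grid, 3)))
  geo <- phantom_geometry(spec, P)
  nvox <- nrow(P)
  nt <- spec$n_frames
  ft <- (seq_len(nt) - 1) * spec$period_T / nt
  dims <- c(grid$shape, nt)
  mag <- array(0, dim = dims)
  vx <- array(0, dim = dims)
  vy <- array(0, dim = dims)
  vz <- array(0, dim = dims)
  lag_s <- spec$distal_lag * spec$period_T / nt
  M0 <- 100
  base_mag <- ifelse(geo$inside, 0.55 * M0, 0.35 * M0)
  prof <- ifelse(geo$inside, 1 - (geo$r / spec$tube_radius)^2, 0)
  with_seed(spec$seed, {
    for (f in seq_len(nt)) {
      U <- waveform_velocity(spec, ft[f] - lag_s * geo$sfrac)
      u <- 2 * U * prof
      vvx <- u * geo$tangent[, 1]
      vvy <- u * geo$tangent[, 2]
      vvz <- u * geo$tangent[, 3]
      m <- base_mag
      if (spec$noise_sigma > 0) {
        sgm <- spec$noise_sigma * M0
        m <- sqrt((m + stats::rnorm(nvox, 0, sgm))^2 +
                    stats::rnorm(nvox, 0, sgm)^2)
        sv <- spec$noise_sigma * spec$venc
        vvx <- vvx + stats::rnorm(nvox, 0, sv)
        vvy <- vvy + stats::rnorm(nvox, 0, sv)
        vvz <- vvz + stats::rnorm(nvox, 0, sv)
      }
      mag[, , , f] <- m
      vx[, , , f] <- vvx
      vy[, , , f] <- vvy
      vz[, , , f] <- vvz
    }
  })
  dataset <- flow4d_dataset(grid, ft, spec$period_T, mag, vx, vy, vz,
                            venc = spec$venc)

  axis_pts <- phantom_axis_points(spec, step = 1)
  truth_line <- centerline(axis_pts,
                           radius = rep(spec$tube_radius, nrow(axis_pts)))
  if (spec$shape == "y-bifurcation") {
    zb <- spec$tube_length * 0.45
    Ld <- spec$tube_length * 0.55
    half <- spec$bifurcation_angle_deg / 2 * pi / 180
    d1 <- c(sin(half), 0, cos(half))
    d2 <- c(-sin(half), 0, cos(half))
    tt <- seq(0, Ld, by = 1)
    parent_line <- centerline(cbind(0, 0, seq(0, zb, by = 1)))
    br1 <- centerline(sweep(outer(tt, d1), 2, c(0, 0, zb), "+"))
    br2 <- centerline(sweep(outer(tt, d2), 2, c(0, 0, zb), "+"))
    fine <- voxel_grid(as.integer(ceiling((grid_bbox(grid)[2, ] -
                                             grid_bbox(grid)[1, ]) / 1.5)) +
                         1L, rep(1.5, 3), grid_bbox(grid)[1, ])
    Pf <- as.matrix(expand.grid(x = grid_axis(fine, 1),
                                y = grid_axis(fine, 2),
                                z = grid_axis(fine, 3)))
    gf <- phantom_geometry(spec, Pf)
    msk <- binary_mask(array(gf$inside, dim = fine$shape), fine)
    surf <- mask_to_surface(msk, smoothing_iterations = 10)
    truth <- list(surface = surf, centerline = truth_line,
                  parent = parent_line, daughters = list(br1, br2),
                  reference_point = c(0, 0, zb),
                  radius = spec$tube_radius, curvature_m1 = 0,
                  bifurcation_angle_deg = spec$bifurcation_angle_deg)
  } else {
    surf <- tube_mesh(axis_pts, spec$tube_radius, n_theta = 48)
    truth <- list(surface = surf, centerline = truth_line,
                  radius = spec$tube_radius,
                  curvature_m1 = if (spec$shape == "torus-bend")
                    1000 / spec$bend_radius else 0,
                  bifurcation_angle_deg = NA_real_)
  }
  U <- waveform_velocity(spec, ft)
  A_m2 <- pi * (spec$tube_radius / 1000)^2
  truth$waveform <- data.frame(t = ft, U = U, Q = U * A_m2)
  mu <- 0.004
  R_m <- spec$tube_radius / 1000
  truth$wall_shear <- 4 * mu * truth$waveform$Q / (pi * R_m^3)
  class(truth) <- "PhantomTruth"
  list(dataset = dataset, truth = truth, spec = spec)
}

#' Closed-form wall-shear field of the straight-tube phantom
#'
#' Poiseuille wall shear `|tau(t)| = 4 mu Q(t) / (pi R^3)`, axial
#' direction, on elements tiling the tube wall.  Only the straight tube
#' has this closed form.
#'
#' @param spec a straight-tube [phantom_spec()]
#' @param fluid a [fluid_properties()]
#' @param n_theta,n_axial wall tiling (default 24 x 20)
#' @return a [wss_field()]
#' @export
phantom_wss <- function(spec, fluid = fluid_properties(), n_theta = 24,
                        n_axial = 20) {
  stopifnot(inherits(spec, "PhantomSpec"))
  if (spec$shape != "straight-tube")
    stop("closed form unavailable: phantom_wss requires a straight-tube spec")
  nt <- spec$n_frames
  ft <- (seq_len(nt) - 1) * spec$period_T / nt
  U <- waveform_velocity(spec, ft)
  R_m <- spec$tube_radius / 1000
  Q <- U * pi * R_m^2
  tau_mag <- 4 * fluid$dynamic_viscosity * Q / (pi * R_m^3)  # signed with Q
  ne <- n_theta * n_axial
  area <- 2 * pi * spec$tube_radius * spec$tube_length / ne  # mm^2
  tau <- array(0, dim = c(ne, nt, 3))
  tau[, , 3] <- matrix(rep(tau_mag, each = ne), nrow = ne)
  wss_field(seq_len(ne), rep(area, ne), ft, tau, spec$period_T)
}

#' Write a phantom to disk (dataset + truth artifacts)
#'
#' NIfTI + JSON sidecar for the 4D dataset, STL for the truth surface,
#' CSV for the truth centerline and waveform.
#'
#' @param phantom result of [make_phantom()]
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_flow4d(phantom$dataset, file.path(dir, "flow4d"))
  write_stl(phantom$truth$surface, file.path(dir, "truth_surface.stl"))
  write_centerline_csv(phantom$truth$centerline,
                       file.path(dir, "truth_centerline.csv"))
  utils::write.csv(phantom$truth$waveform,
                   file.path(dir, "truth_waveform.csv"), row.names = FALSE)
  invisible(dir)
}
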