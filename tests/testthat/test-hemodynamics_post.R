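# dense-quadrature oracle: linear interpolation of the sampled series onto
# a fine grid, then trapezoid
fine_integral <- function(times, y, period, n = 20000) {
  tt <- seq(0, period, length.out = n)
  tc <- c(times, period)
  yc <- c(y, y[1])
  yi <- stats::approx(tc, yc, xout = tt)$y
  sum((yi[-1] + yi[-n]) / 2) * (period / (n - 1))
}

mk_field <- function(tau, times = NULL, period = 1) {
  n <- dim(tau)[1]
  m <- dim(tau)[2]
  if (is.null(times)) times <- (seq_len(m) - 1) * period / m
  wss_field(seq_len(n), rep(1, n), times, tau, period)
}

test_that("TAWSS matches constants, Poiseuille and a dense quadrature oracle", {
  # constant |tau| = 2 Pa
  tau <- array(0, c(3, 8, 3)); tau[, , 1] <- 2
  expect_equal(tawss(mk_field(tau)), rep(2, 3), tolerance = 1e-12)
  # steady Poiseuille closed form 4 mu Q / (pi R^3)
  spec <- phantom_spec("straight-tube", tube_radius = 5,
                       waveform = list(type = "constant",
                                       peak_mean_velocity = 0.3))
  fld <- phantom_wss(spec)
  R <- 0.005; Q <- 0.3 * pi * R^2
  expect_equal(tawss(fld), rep(4 * 0.004 * Q / (pi * R^3),
                               length(fld$element_ids)),
               tolerance = 2e-2 * 4 * 0.004 * Q / (pi * R^3))
  # arbitrary sampled series within 0.5% of the dense-quadrature oracle
  set.seed(41)
  m <- 20
  tau <- array(rnorm(5 * m * 3), c(5, m, 3))
  fld <- mk_field(tau)
  ta <- tawss(fld)
  for (e in 1:5) {
    mag <- sqrt(tau[e, , 1]^2 + tau[e, , 2]^2 + tau[e, , 3]^2)
    expect_equal(ta[e], fine_integral(fld$times, mag, 1), tolerance = 0.005)
  }
  expect_error(wss_field(1:2, c(1, 1), 0.5, array(0, c(2, 1, 3)), 1),
               "at least 2")
})

test_that("OSI spans [0, 0.5] with exact endpoints", {
  # unidirectional shear of any magnitude: OSI = 0
  m <- 12
  tau <- array(0, c(2, m, 3))
  tau[1, , 1] <- abs(rnorm(m)) + 0.1
  tau[2, , 1] <- 3
  expect_equal(osi(mk_field(tau)), c(0, 0), tolerance = 1e-12)
  # half cycle +x, half cycle -x: OSI = 0.5
  tau <- array(0, c(1, 10, 3))
  tau[1, , 1] <- c(rep(1, 5), rep(-1, 5))
  # (periodic closure makes the transition symmetric)
  expect_equal(osi(mk_field(tau)), 0.5, tolerance = 0.06)
  # random fields stay within the bound and match the dense oracle
  set.seed(7)
  tau <- array(rnorm(200 * 15 * 3), c(200, 15, 3))
  fld <- mk_field(tau)
  os <- osi(fld)
  expect_true(all(os >= 0 & os <= 0.5))
  for (e in sample(200, 4)) {
    comp <- vapply(1:3, function(c_)
      fine_integral(fld$times, tau[e, , c_], 1), numeric(1))
    mag <- sqrt(tau[e, , 1]^2 + tau[e, , 2]^2 + tau[e, , 3]^2)
    oracle <- 0.5 * (1 - sqrt(sum(comp^2)) / fine_integral(fld$times, mag, 1))
    expect_equal(os[e], oracle, tolerance = 0.005)
  }
})

test_that("TAWSS/OSI homogeneity and triangle bound", {
  set.seed(13)
  tau <- array(rnorm(50 * 12 * 3), c(50, 12, 3))
  f1 <- mk_field(tau)
  f2 <- mk_field(4 * tau)
  expect_equal(tawss(f2), 4 * tawss(f1), tolerance = 1e-12)
  expect_equal(osi(f2), osi(f1), tolerance = 1e-12)
  # TAWSS >= |time-average of tau| per element
  for (e in 1:50) {
    comp <- vapply(1:3, function(c_)
      fine_integral(f1$times, tau[e, , c_], 1), numeric(1))
    expect_gte(tawss(f1)[e] + 1e-9, sqrt(sum(comp^2)))
  }
})

test_that("extreme regions agree with a sort-based oracle", {
  ex <- extreme_regions(1:100, 0.05)
  expect_identical(sort(ex$upper), 96:100)
  expect_identical(sort(ex$lower), 1:5)
  expect_warning(ex2 <- extreme_regions(rep(3, 10)), "all values equal")
  expect_identical(ex2$upper, 1:10)
  set.seed(55)
  v <- rnorm(437)
  ex <- extreme_regions(v, 0.05)
  qs <- stats::quantile(v, c(0.05, 0.95), names = FALSE, type = 7)
  expect_identical(ex$upper, which(v >= qs[2]))
  expect_identical(ex$lower, which(v <= qs[1]))
  expect_error(extreme_regions(v, 0.6), "fraction")
})

test_that("flow waveforms integrate velocity over lumen planes", {
  # uniform through-plane velocity: Q = U * A on every plane, sd = 0
  g <- voxel_grid(c(11, 11, 21), c(2, 2, 2), c(-10, -10, 0))
  P <- as.matrix(expand.grid(x = grid_axis(g, 1), y = grid_axis(g, 2),
                             z = grid_axis(g, 3)))
  lum <- array(sqrt(P[, 1]^2 + P[, 2]^2) <= 6, g$shape)
  dims <- c(g$shape, 4)
  vz <- array(0, dims)
  for (f in 1:4) vz[, , , f] <- array(0.5 * lum * f / 4, g$shape)
  zero <- array(0, dims)
  ds <- flow4d_dataset(g, (0:3) / 4, 1, array(1, dims), zero, zero, vz)
  mask <- binary_mask(lum, g)
  fw <- flow_waveform(ds, plane_z = c(8, 16, 24, 32, 36), lumen_mask = mask)
  A <- sum(lum[, , 5]) * 4e-6                 # pixel-count area, m^2
  expect_equal(fw$q_mean, 0.5 * (1:4) / 4 * A, tolerance = 1e-12)
  expect_true(all(fw$q_sd < 1e-15))
  # interpolated series passes through the raw samples
  at_raw <- fw$interpolated$q[match(round(fw$times, 9),
                                    round(fw$interpolated$t, 9))]
  expect_equal(at_raw, fw$q_mean, tolerance = 1e-12)
  expect_equal(diff(fw$interpolated$t[1:2]), 0.001, tolerance = 1e-12)
  # parabolic profile with centerline 2U integrates to U * A within 3%
  ph <- make_phantom(phantom_spec("straight-tube", tube_radius = 6,
                                  grid_spacing = rep(2, 3), seed = 1))
  gv <- ph$dataset$grid
  Pv <- as.matrix(expand.grid(x = grid_axis(gv, 1), y = grid_axis(gv, 2),
                              z = grid_axis(gv, 3)))
  truem <- binary_mask(array(sqrt(Pv[, 1]^2 + Pv[, 2]^2) <= 6 &
                               Pv[, 3] >= 0 & Pv[, 3] <= 120, gv$shape), gv)
  fw2 <- flow_waveform(ph$dataset, lumen_mask = truem)
  expect_equal(max(fw2$q_mean), max(ph$truth$waveform$Q), tolerance = 0.03)
  # a plane missing the lumen names itself
  lum2 <- lum
  lum2[, , 19:21] <- FALSE
  mask2 <- binary_mask(lum2, g)
  expect_error(flow_waveform(ds, plane_z = c(8, 16, 24, 32, 40),
                             lumen_mask = mask2), "plane 5")
})

test_that("parabolic profiles have the closed-form shape and flow", {
  q <- 2e-4; R <- 0.01
  expect_equal(parabolic_profile(q, R, 0), 2 * q / (pi * R^2))
  expect_equal(parabolic_profile(q, R, R), 0)
  expect_equal(parabolic_profile(q, R, 2 * R), 0)
  # numerically integrated over the disc within 0.5%
  r <- seq(0, R, length.out = 4000)
  u <- parabolic_profile(q, R, r)
  qnum <- sum(u * 2 * pi * r) * (R / 3999)
  expect_equal(qnum, q, tolerance = 0.005)
  expect_error(parabolic_profile(q, -1, 0), "radius")
})

test_that("Reynolds numbers follow rho U D / mu", {
  fl <- fluid_properties()
  expect_equal(reynolds(fl, 0.1, 0.01), 265)
  expect_equal(reynolds(fl, 0.2, 0.01), 2 * reynolds(fl, 0.1, 0.01))
  set.seed(2)
  for (i in 1:5) {
    rho <- runif(1, 900, 1100); mu <- runif(1, 0.002, 0.006)
    U <- runif(1, 0.05, 2); D <- runif(1, 0.005, 0.04)
    expect_equal(reynolds(fluid_properties(rho, mu), U, D), rho * U * D / mu)
  }
  expect_error(reynolds(fl, -1, 0.01), "must be > 0")
  expect_error(fluid_properties(density = 0), "must be > 0")
})

test_that("WSS CSV round trips in long format", {
  set.seed(66)
  tau <- array(rnorm(4 * 6 * 3), c(4, 6, 3))
  fld <- mk_field(tau)
  td <- withr::local_tempdir()
  f <- file.path(td, "wss.csv")
  write_wss_csv(fld, f)
  back <- read_wss_csv(f, period_T = 1)
  expect_equal(back$tau, fld$tau, tolerance = 1e-9)
  expect_equal(back$times, fld$times, tolerance = 1e-12)
  expect_equal(tawss(back), tawss(fld), tolerance = 1e-9)
})
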