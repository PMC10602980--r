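test_that("extract_centerline follows tube and torus axes with inscribed radii", {
  tube <- fx_tube_mask(radius = 5, length = 40, spacing = 1)
  line <- extract_centerline(tube, rbind(c(0, 0, 2), c(0, 0, 38)))
  mid <- line$arc_length > 5 & line$arc_length < max(line$arc_length) - 5
  off_axis <- sqrt(line$points[mid, 1]^2 + line$points[mid, 2]^2)
  expect_lt(max(off_axis), 1 + 1e-9)            # within one voxel of the axis
  expect_lt(max(abs(line$radius[mid] - 5)), 1 + 1e-9)
  # radius bounded by the distance-transform maximum, equality on the axis
  dtmax <- max(distance_transform(tube$voxels, tube$grid))
  expect_lte(max(line$radius), dtmax)
  expect_equal(max(line$radius[mid]), dtmax)
  # torus-segment mask: path tracks the analytic bend
  g <- voxel_grid(c(46, 46, 9), c(1.5, 1.5, 1.5), c(-34, -34, -6))
  P <- as.matrix(expand.grid(x = grid_axis(g, 1), y = grid_axis(g, 2),
                             z = grid_axis(g, 3)))
  th <- atan2(P[, 2], P[, 1])
  q <- cbind(28 * cos(th), 28 * sin(th), 0)
  inb <- th >= 0 & th <= pi / 2 * 1.6 & sqrt(rowSums((P - q)^2)) <= 5
  tor <- binary_mask(array(inb, g$shape), g)
  p0 <- c(28, 0, 0)
  th1 <- pi / 2 * 1.6
  p1 <- c(28 * cos(th1), 28 * sin(th1), 0)
  tl <- extract_centerline(tor, rbind(p0, p1))
  mid <- tl$arc_length > 6 & tl$arc_length < max(tl$arc_length) - 6
  ring_err <- abs(sqrt(tl$points[mid, 1]^2 + tl$points[mid, 2]^2) - 28)
  expect_lt(max(ring_err), 1.5 + 1e-9)
  expect_lt(max(abs(tl$points[mid, 3])), 1.5 + 1e-9)
  # endpoint far outside the mask is an error
  expect_error(extract_centerline(tube, rbind(c(0, 0, 2), c(30, 30, 2))),
               "outside the mask")
})

test_that("resample_smooth keeps straight lines, damps zig-zag, spaces evenly", {
  straight <- centerline(cbind(0, 0, seq(0, 99, by = 1)))
  sm <- resample_smooth(straight, 3, 0.5, 100)
  expect_lt(max(abs(sm$points[, 1:2])), 1e-9)
  expect_equal(centerline_length(sm), 99, tolerance = 1e-6)
  # spacing 3.0 mm within 1%
  seg <- sqrt(rowSums(diff(sm$points)^2))
  expect_true(all(abs(seg - 3) / 3 < 0.01))
  # zig-zag perturbation amplitude reduced by >= 90% after 100 iterations:
  # alternating +/-1 mm interior offsets about the z axis (endpoints, which
  # the smoother pins, stay on the axis); resampling at the mean segment
  # length keeps the sampled polyline close to the zig-zag itself
  n <- 41
  z <- 3 * (0:(n - 1))
  x <- rep(c(1, -1), length.out = n)
  x[1] <- 0; x[n] <- 0
  zig <- centerline(cbind(x, 0, z))
  seg <- centerline_length(zig) / (n - 1)
  out <- resample_smooth(zig, seg, 0.5, 100)
  expect_lt(max(abs(out$points[, 1])), 0.1 * 1)
  # oracle: the same relaxation run independently on the resampled polyline
  L <- centerline_length(zig)
  nseg <- max(1L, round(L / seg))
  s_new <- seq(0, L, length.out = nseg + 1)
  Pz <- vapply(1:3, function(c_)
    stats::approx(zig$arc_length, zig$points[, c_], xout = s_new)$y,
    numeric(nseg + 1))
  for (it in 1:100) {
    mid <- (Pz[1:(nseg - 1), ] + Pz[3:(nseg + 1), ]) / 2
    Pz[2:nseg, ] <- Pz[2:nseg, ] + 0.5 * (mid - Pz[2:nseg, ])
  }
  expect_equal(out$points, Pz, tolerance = 1e-12)
  expect_error(resample_smooth(straight, 200), "interval")
})

test_that("curvature matches closed forms for circle, line and helix", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  # circle r = 0.2 m = 200 mm -> kappa = 5 / m
  circ <- centerline(cbind(200 * cos(th), 200 * sin(th), 0))
  k <- curvature(circ)
  expect_true(all(abs(k - 5) / 5 < 0.01))
  # straight line -> 0
  expect_true(all(curvature(centerline(cbind(1:50, 2 * (1:50), 0))) == 0))
  # helix a = 0.1 m, b = 0.05 m -> kappa = a / (a^2 + b^2) = 8 / m
  t <- seq(0, 4 * pi, length.out = 400)
  helix <- centerline(cbind(100 * cos(t), 100 * sin(t), 50 * t))
  kh <- curvature(helix)
  interior <- 5:395
  expect_true(all(abs(kh[interior] - 8) / 8 < 0.01))
})

test_that("curvature is rigid-motion and resampling invariant", {
  th <- seq(0, pi, length.out = 60)
  arc <- centerline(cbind(80 * cos(th), 80 * sin(th), 0.3 * th))
  k0 <- stats::median(curvature(arc))
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3)
  moved <- centerline(sweep(arc$points %*% R, 2, c(10, -4, 7), "+"))
  expect_equal(stats::median(curvature(moved)), k0, tolerance = 1e-9)
  dense <- centerline(cbind(80 * cos(seq(0, pi, length.out = 240)),
                            80 * sin(seq(0, pi, length.out = 240)),
                            0.3 * seq(0, pi, length.out = 240)))
  expect_equal(stats::median(curvature(dense)), k0, tolerance = 0.02 * k0)
})

test_that("tortuosity follows L/D - 1 with exact scale invariance", {
  expect_equal(tortuosity(centerline(cbind(0, 0, c(0, 10, 20)))), 0)
  th <- seq(0, pi, length.out = 400)
  semi <- centerline(cbind(30 * cos(th), 30 * sin(th), 0))
  expect_equal(tortuosity(semi), pi / 2 - 1, tolerance = 0.01 * (pi / 2 - 1))
  # brute-force segment-sum oracle on a random polyline
  set.seed(123)
  P <- matrix(cumsum(rnorm(30)), ncol = 3)
  line <- centerline(P)
  L <- sum(sqrt(rowSums(diff(P)^2)))
  D <- sqrt(sum((P[nrow(P), ] - P[1, ])^2))
  expect_equal(tortuosity(line), L / D - 1, tolerance = 1e-12)
  # chi(k * line) = chi(line) exactly
  expect_equal(tortuosity(centerline(3.7 * P)), tortuosity(line),
               tolerance = 1e-12)
  expect_error(tortuosity(centerline(rbind(c(0, 0, 0), c(1, 0, 0),
                                           c(0, 0, 0)))), "coincident")
})

test_that("bifurcation angles recover constructed Y junctions", {
  mk_daughter <- function(dir) {
    t <- seq(0, 30, by = 1.5)
    centerline(sweep(outer(t, dir / sqrt(sum(dir^2))), 2, c(0, 0, 50), "+"))
  }
  parent <- centerline(cbind(0, 0, seq(0, 50, by = 2)))
  # symmetric Y at +/- 30 degrees from the parent axis -> 60 degrees
  d1 <- mk_daughter(c(sin(pi / 6), 0, cos(pi / 6)))
  d2 <- mk_daughter(c(-sin(pi / 6), 0, cos(pi / 6)))
  res <- bifurcation_angle(parent, d1, d2, c(0, 0, 50))
  expect_equal(res$angle_deg, 60, tolerance = 1e-6)
  expect_equal(abs(res$system$bifurcation_plane_normal), c(0, 1, 0),
               tolerance = 1e-9)
  # perpendicular daughters -> 90 degrees
  res90 <- bifurcation_angle(parent, mk_daughter(c(1, 0, 0)),
                             mk_daughter(c(0, 0, 1)), c(0, 0, 50))
  expect_equal(res90$angle_deg, 90, tolerance = 1e-6)
  # parallel daughters: angle 0 with a warning
  expect_warning(
    res0 <- bifurcation_angle(parent, mk_daughter(c(0, 0, 1)),
                              mk_daughter(c(0, 0, 1)), c(0, 0, 50)),
    "parallel")
  expect_equal(res0$angle_deg, 0)
  # daughters must start near the reference point
  far <- centerline(cbind(0, 0, seq(100, 130, by = 2)))
  expect_error(bifurcation_angle(parent, far, d2, c(0, 0, 50)),
               "reference point")
})

test_that("dissected radius is the elementwise lumen sum", {
  expect_equal(dissected_radius(c(3.0, 3.1), c(1.0, 0.9)), c(4.0, 4.0))
  r <- c(2.2, 2.4, 2.1)
  expect_identical(dissected_radius(r, c(0, 0, 0)), r)
  set.seed(9)
  a <- runif(20); b <- runif(20)
  expect_identical(dissected_radius(a, b), a + b)
  expect_error(dissected_radius(1:3, 1:4), "lengths differ")
})

test_that("centerline CSV round trips points, radius and labels", {
  line <- centerline(cbind(1:5, (1:5)^1.5, 0.3 * (1:5)),
                     radius = seq(2, 3, length.out = 5),
                     labels = list(bifurcation = 3L))
  td <- withr::local_tempdir()
  f <- file.path(td, "c.csv")
  write_centerline_csv(line, f)
  back <- read_centerline_csv(f)
  expect_equal(back$points, line$points, tolerance = 1e-9)
  expect_equal(back$radius, line$radius, tolerance = 1e-9)
  expect_equal(back$labels$bifurcation, 3L)
})
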