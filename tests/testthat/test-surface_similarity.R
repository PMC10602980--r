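mk_cyl <- function(radius, length = 60, n_theta = 64, shift = c(0, 0, 0)) {
  pts <- sweep(cbind(0, 0, seq(0, length, by = 2)), 2, shift, "+")
  tube_mesh(pts, radius, n_theta = n_theta)
}

test_that("two-landmark alignment recovers translations and rotations", {
  s <- mk_cyl(4, 50)
  s <- set_landmark(s, "bifurcation", c(0, 0, 0))
  s <- set_landmark(s, "left_iliac_end", c(0, 0, 50))
  # already aligned: identity
  al <- align_by_landmarks(s, s)
  expect_equal(al$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(al$surface$vertices, s$vertices, tolerance = 1e-12)
  # pure translation
  tr <- structure(list(rotation = diag(3), translation = c(10, 0, 0),
                       center = c(0, 0, 0)), class = "AlignmentTransform")
  s2 <- apply_transform(s, tr)
  al <- align_by_landmarks(s2, s)
  expect_equal(al$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(al$surface$vertices, s$vertices, tolerance = 1e-9)
  # rotation about an axis perpendicular to the landmark vector
  ang <- pi / 6
  R <- matrix(c(1, 0, 0, 0, cos(ang), sin(ang), 0, -sin(ang), cos(ang)),
              3, 3)
  s3 <- apply_transform(s, structure(list(rotation = R,
                                          translation = c(3, -2, 5),
                                          center = c(0, 0, 0)),
                                     class = "AlignmentTransform"))
  al <- align_by_landmarks(s3, s)
  expect_lt(max(abs(al$surface$landmarks$bifurcation -
                      s$landmarks$bifurcation)), 1e-6)
  expect_lt(max(abs(al$surface$landmarks$left_iliac_end -
                      s$landmarks$left_iliac_end)), 1e-6)
  expect_lt(max(abs(al$surface$vertices - s$vertices)), 1e-6)
  # missing landmark names the culprit
  s4 <- mk_cyl(4)
  expect_error(align_by_landmarks(s4, s), "bifurcation")
})

test_that("Dice spans identity, disjunction and analytic half overlap", {
  a <- fx_sphere_mask(6, 1)
  expect_equal(dice(a, a), 1)
  b <- binary_mask(array(FALSE, a$grid$shape), a$grid)
  b$voxels[1:2, 1:2, 1:2] <- TRUE
  b$voxels[a$voxels] <- FALSE
  expect_equal(dice(a, b), 0)
  expect_equal(dice(a, b), dice(b, a))
  # unit cubes overlapping on exactly half their volume
  cube <- function(shift) {
    v <- matrix(c(0,0,0, 10,0,0, 10,10,0, 0,10,0,
                  0,0,10, 10,0,10, 10,10,10, 0,10,10),
                ncol = 3, byrow = TRUE)
    f <- matrix(c(1,3,2, 1,4,3, 5,6,7, 5,7,8,
                  1,2,6, 1,6,5, 2,3,7, 2,7,6,
                  3,4,8, 3,8,7, 4,1,5, 4,5,8), ncol = 3, byrow = TRUE)
    surface_model(sweep(v, 2, shift, "+"), f)
  }
  d <- dice(cube(c(0, 0, 0)), cube(c(5, 0, 0)), resolution = 0.5)
  expect_equal(d, 0.5, tolerance = 0.01)
  # both empty: defined as 1 with a warning
  e <- binary_mask(array(FALSE, c(3, 3, 3)), voxel_grid(c(3, 3, 3),
                                                        c(1, 1, 1)))
  expect_warning(expect_equal(dice(e, e), 1), "both masks empty")
})

test_that("point-set Hausdorff equals the O(n^2) double-loop oracle", {
  expect_equal(hausdorff_pointsets(cbind(1:5, 0, 0),
                                   cbind(1:5, 0, 0))$symmetric, 0)
  h <- hausdorff_pointsets(rbind(c(0, 0, 0)),
                           rbind(c(3, 0, 0), c(5, 0, 0)))
  expect_equal(h$forward, 3)
  expect_equal(h$backward, 5)
  expect_equal(h$symmetric, 5)
  oracle_dir <- function(A, B) {
    max(apply(A, 1, function(a)
      min(apply(B, 1, function(b) sqrt(sum((a - b)^2))))))
  }
  set.seed(2024)
  for (rep in 1:20) {
    A <- matrix(rnorm(150), ncol = 3)
    B <- matrix(rnorm(150), ncol = 3)
    h <- hausdorff_pointsets(A, B)
    expect_equal(h$forward, oracle_dir(A, B), tolerance = 1e-12)
    expect_equal(h$backward, oracle_dir(B, A), tolerance = 1e-12)
    expect_equal(h$symmetric, max(h$forward, h$backward), tolerance = 1e-12)
    # symmetry of H
    h2 <- hausdorff_pointsets(B, A)
    expect_equal(h2$symmetric, h$symmetric, tolerance = 1e-12)
  }
  # triangle-type bound on random sets
  for (rep in 1:10) {
    A <- matrix(rnorm(60), ncol = 3)
    B <- matrix(rnorm(60), ncol = 3)
    C <- matrix(rnorm(60), ncol = 3)
    expect_lte(hausdorff_pointsets(A, C)$symmetric,
               hausdorff_pointsets(A, B)$symmetric +
                 hausdorff_pointsets(B, C)$symmetric + 1e-12)
  }
  expect_error(hausdorff_pointsets(matrix(0, 0, 3), cbind(1, 1, 1)),
               "empty")
})

test_that("slice-wise HD identity, annulus and outlier handling", {
  c5 <- mk_cyl(5, 60)
  # surface vs itself: all zero
  hd0 <- slicewise_hd(c5, c5, n_planes = 60)
  expect_equal(max(hd0$per_plane_hd), 0, tolerance = 1e-9)
  expect_equal(hd0$hd_p95, 0, tolerance = 1e-9)
  # coaxial 5 vs 6 mm: 1 mm on every plane (contour-sampling tolerance)
  c6 <- mk_cyl(6, 60, n_theta = 96)
  hd <- slicewise_hd(mk_cyl(5, 60, n_theta = 96), c6, n_planes = 120)
  expect_true(all(abs(hd$per_plane_hd - 1) < 0.1))
  expect_equal(hd$hd_p95, 1, tolerance = 0.1)
  expect_equal(hd$n_planes_skipped, 0)
  # hd_p95 <= max always; an outlier bump on 2% of the length is trimmed
  bump <- mk_cyl(5, 100, n_theta = 96)
  zc <- bump$vertices[, 3]
  band <- zc > 49 & zc < 51
  r <- sqrt(bump$vertices[, 1]^2 + bump$vertices[, 2]^2)
  scale <- ifelse(band & r > 0, (r + 3) / r, 1)
  bump$vertices[, 1:2] <- bump$vertices[, 1:2] * scale
  hdb <- slicewise_hd(mk_cyl(5, 100, n_theta = 96), bump, n_planes = 200)
  expect_gte(max(hdb$per_plane_hd), 2.5)
  expect_lt(hdb$hd_p95, max(hdb$per_plane_hd))
  expect_lte(hdb$hd_p95, max(hdb$per_plane_hd))
  # no overlapping extent errors out
  far <- mk_cyl(5, 20, shift = c(0, 0, 500))
  expect_error(slicewise_hd(c5, far), "no overlapping axial extent")
})

test_that("Dice and slice-wise HD are rigid-motion invariant", {
  a <- mk_cyl(5, 40)
  b <- mk_cyl(6, 40)
  d0 <- dice(a, b, resolution = 1)
  h0 <- slicewise_hd(a, b, n_planes = 50)$hd_p95
  ang <- 0.4
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3)
  tr <- structure(list(rotation = R, translation = c(12, -7, 3),
                       center = c(0, 0, 0)), class = "AlignmentTransform")
  a2 <- apply_transform(a, tr)
  b2 <- apply_transform(b, tr)
  expect_equal(dice(a2, b2, resolution = 1), d0, tolerance = 0.02)
  expect_equal(slicewise_hd(a2, b2, n_planes = 50)$hd_p95, h0,
               tolerance = 0.1)
})

test_that("truncation drops geometry beyond a landmark plane", {
  s <- mk_cyl(5, 80)
  s <- set_landmark(s, "bifurcation", c(5, 0, 40))
  tr <- truncate_at_landmark(s, "bifurcation", keep = "below")
  expect_lte(max(tr$vertices[, 3]), 42)
  expect_gt(nrow(tr$faces), 0)
  expect_error(truncate_at_landmark(s, "nope"), "no landmark")
})
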