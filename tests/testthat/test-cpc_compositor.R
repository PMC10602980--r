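test_that("velocity magnitude matches the per-voxel Pythagorean oracle", {
  g <- voxel_grid(c(8, 8, 8), c(1, 1, 1))
  set.seed(12)
  dims <- c(8, 8, 8, 2)
  vx <- array(runif(prod(dims), -1, 1), dims)
  vy <- array(runif(prod(dims), -1, 1), dims)
  vz <- array(runif(prod(dims), -1, 1), dims)
  vx[1, 1, 1, 1] <- 0.3; vy[1, 1, 1, 1] <- 0.4; vz[1, 1, 1, 1] <- 0
  ds <- flow4d_dataset(g, c(0, 0.5), 1, array(1, dims), vx, vy, vz,
                       venc = 1.5)
  m <- velocity_magnitude(ds, 1)
  expect_equal(m[1, 1, 1], 0.5)
  # brute-force voxel loop oracle on a slab
  for (i in 1:8) for (j in 1:4)
    expect_equal(m[i, j, 3],
                 sqrt(vx[i, j, 3, 1]^2 + vy[i, j, 3, 1]^2 +
                        vz[i, j, 3, 1]^2))
  ds0 <- flow4d_dataset(g, c(0, 0.5), 1, array(1, dims),
                        array(0, dims), array(0, dims), array(0, dims))
  expect_true(all(velocity_magnitude(ds0, 2) == 0))
  expect_error(velocity_magnitude(ds, 3), "out of range")
})

test_that("systolic phase selection brackets the peak and is shift-equivariant", {
  ds <- fx_flow_dataset(n_frames = 20, peak_frame = 6)
  ph <- select_systolic_phases(ds)
  expect_equal(unname(ph[2]), 6)
  expect_lt(ph[1], ph[2])
  expect_gt(ph[3], ph[2])
  # circular shift by k moves all three indices by k
  k <- 3
  ds2 <- ds
  ds2$velocity$vz <- ds$velocity$vz[, , , c((20 - k + 1):20, 1:(20 - k))]
  ph2 <- select_systolic_phases(ds2)
  expect_equal(unname(ph2), unname((ph - 1 + k) %% 20 + 1))
  # flat zero flow is an error
  ds0 <- ds
  ds0$velocity$vz[] <- 0
  expect_error(select_systolic_phases(ds0), "no systolic phase")
  # constant nonzero flow: degenerate adjacent frames with a warning
  dsc <- ds
  dsc$velocity$vz[] <- 0.5
  expect_warning(phc <- select_systolic_phases(dsc), "constant")
  expect_equal(diff(phc), c(1, 1))
})

test_that("phase stacks map velocity affinely above threshold", {
  ds <- fx_flow_dataset(n_frames = 6, peak_frame = 3, peak_U = 0.35,
                        spacing = 2)
  cc <- cpc_config(background_mode = "suppress")
  st <- phase_stack(ds, 3, cc, "transverse", 20, 2)
  expect_s3_class(st, "ImageStack")
  expect_true(all(st$pixels >= 0 & st$pixels <= cc$I_max))
  # doubling velocities (below ceiling) doubles the velocity-mapped pixels
  ds2 <- ds
  for (ch in c("vx", "vy", "vz")) ds2$velocity[[ch]] <- 2 * ds$velocity[[ch]]
  st2 <- phase_stack(ds2, 3, cc, "transverse", 20, 2)
  both <- attr(st, "vmask") & attr(st2, "vmask")
  expect_equal(st2$pixels[both], 2 * st$pixels[both], tolerance = 1e-9)
  # ceiling saturation: velocity at or above v_ceiling maps to I_max
  ds3 <- ds
  ds3$velocity$vz[, , , 3] <- 1.5
  st3 <- phase_stack(ds3, 3, cc, "transverse", 20, 2)
  expect_true(all(abs(st3$pixels - cc$I_max) < 1e-9))
  # just-below-threshold pixels show background, not velocity
  ds4 <- ds
  ds4$velocity$vz[] <- 0
  ds4$velocity$vz[, , , 3] <- 0.249
  st4 <- phase_stack(ds4, 3, cc, "transverse", 20, 2)
  expect_true(all(st4$pixels == 0))   # suppressed background
  cc2 <- cpc_config(background_mode = "retain-magnitude")
  st5 <- phase_stack(ds4, 3, cc2, "transverse", 20, 2)
  expect_true(max(st5$pixels) <= 0.25 * cc2$I_max + 1e-9)
})

test_that("contrast stretch matches a sort-based quantile oracle", {
  # linear doubling case
  st <- image_stack(array(seq(0, 4095 / 2, length.out = 60), c(4, 5, 3)),
                    "transverse", 1, c(1, 1))
  out <- contrast_stretch(st, 0)
  expect_equal(out$pixels, 2 * st$pixels, tolerance = 1e-9)
  # constant image unchanged
  cst <- image_stack(array(1234, c(3, 3, 2)), "transverse", 1, c(1, 1))
  expect_equal(contrast_stretch(cst, 0.01)$pixels, cst$pixels)
  # random image: quantiles from an independent sort-based interpolation
  set.seed(77)
  px <- array(runif(8000, 0, 4095), c(20, 20, 20))
  st <- image_stack(px, "transverse", 1, c(1, 1))
  out <- contrast_stretch(st, 0.01)
  sorted <- sort(as.numeric(px))
  qat <- function(p) {
    h <- (length(sorted) - 1) * p + 1
    lo <- floor(h)
    sorted[lo] + (h - lo) * (sorted[min(lo + 1, length(sorted))] - sorted[lo])
  }
  q1 <- qat(0.01); q99 <- qat(0.99)
  oracle <- pmin(pmax((px - q1) / (q99 - q1) * 4095, 0), 4095)
  expect_equal(out$pixels, oracle, tolerance = 1e-9)
  # about 1% of pixels saturate at each end
  expect_equal(sum(out$pixels == 0) / 8000, 0.01, tolerance = 0.25)
  expect_equal(sum(out$pixels == 4095) / 8000, 0.01, tolerance = 0.25)
  expect_error(contrast_stretch(st, 0.6), "saturation")
})

test_that("compositing blends, stretches and records provenance", {
  cc <- cpc_config(background_mode = "suppress")
  mk <- function(px) {
    s <- image_stack(px, "transverse", 1, c(1, 1))
    attr(s, "vmask") <- px > 0
    s
  }
  set.seed(3)
  px <- array(runif(150, 0, 4095), c(5, 5, 6))
  s <- mk(px)
  # three identical stacks: composite equals the stretched single stack
  for (mode in c("alpha-mean", "pixel-max")) {
    cm <- cpc_config(blend_mode = mode, background_mode = "suppress")
    comp <- composite(list(s, s, s), cm)
    expect_equal(comp$pixels, contrast_stretch(s, cm$stretch_saturation)$pixels,
                 tolerance = 1e-9)
  }
  # single-stack identity
  expect_equal(composite(list(s), cc)$pixels,
               contrast_stretch(s, cc$stretch_saturation)$pixels,
               tolerance = 1e-9)
  # disjoint bright regions: union coverage; pixel-max keeps per-pixel max
  pa <- array(0, c(4, 4, 2)); pa[1:2, , ] <- 3000
  pb <- array(0, c(4, 4, 2)); pb[3, , ] <- 2000
  pc_ <- array(0, c(4, 4, 2)); pc_[4, , ] <- 1000
  sa <- mk(pa); sb <- mk(pb); sc <- mk(pc_)
  cmx <- cpc_config(blend_mode = "pixel-max", background_mode = "suppress",
                    stretch_saturation = 0)
  comp <- composite(list(sa, sb, sc), cmx)
  expect_identical(stack_vmask(comp), pa > 0 | pb > 0 | pc_ > 0)
  # per-pixel max oracle, then the full-range remap (the bright rows tile
  # the whole image, so the stretch maps [min, max] -> [0, I_max])
  oracle <- pmax(pa, pb, pc_)
  oracle <- (oracle - min(oracle)) / (max(oracle) - min(oracle)) * 4095
  expect_equal(comp$pixels, oracle, tolerance = 1e-9)
  # geometry mismatch
  s_bad <- image_stack(array(0, c(3, 4, 2)), "transverse", 1, c(1, 1))
  expect_error(composite(list(sa, s_bad), cc), "stack mismatch")
})

test_that("composite masks obey monotonicity, union and threshold consistency", {
  ds <- fx_flow_dataset(n_frames = 8, peak_frame = 4)
  cc <- cpc_config(background_mode = "suppress")
  frames <- c(3, 4, 5)
  stacks <- lapply(frames, function(f)
    phase_stack(ds, f, cc, "transverse", 15, 2))
  comp <- composite(stacks, cc)
  vm <- stack_vmask(comp)
  # union property
  u <- Reduce(`|`, lapply(stacks, attr, "vmask"))
  expect_identical(vm, u)
  # threshold consistency: every nonzero composite pixel traces to a phase
  expect_true(all(vm[comp$pixels > 0]))
  # raising a voxel's velocity never decreases its blended intensity
  # (monotonicity holds for the velocity map and blend; the final
  # full-range remap is a shared affine rescale)
  ds2 <- ds
  ds2$velocity$vz[, , , 4] <- pmin(ds$velocity$vz[, , , 4] + 0.1, 1.4)
  stacks2 <- lapply(frames, function(f)
    phase_stack(ds2, f, cc, "transverse", 15, 2))
  blend1 <- Reduce(`+`, lapply(stacks, function(s) s$pixels)) / 3
  blend2 <- Reduce(`+`, lapply(stacks2, function(s) s$pixels)) / 3
  expect_true(all(blend2 - blend1 > -1e-9))
  # lowering the velocity threshold never shrinks the mask
  cc_lo <- cpc_config(v_threshold = 0.15, background_mode = "suppress")
  stacks_lo <- lapply(frames, function(f)
    phase_stack(ds, f, cc_lo, "transverse", 15, 2))
  vm_lo <- Reduce(`|`, lapply(stacks_lo, attr, "vmask"))
  expect_true(all(vm_lo[u]))
})

test_that("false-color overlay encodes phase agreement", {
  mk <- function(px) {
    s <- image_stack(px, "transverse", 1, c(1, 1), I_max = 100)
    attr(s, "vmask") <- px > 0
    s
  }
  full <- array(100, c(3, 3, 1))
  none <- array(0, c(3, 3, 1))
  # identical above threshold in all three phases: pure white
  rgb <- false_color_overlay(mk(full), mk(full), mk(full))
  expect_true(all(rgb == 1))
  # PS-only bright region: magenta (R and B, no G)
  rgb <- false_color_overlay(mk(none), mk(full), mk(none))
  expect_true(all(rgb[, , , 1] == 1) && all(rgb[, , , 3] == 1))
  expect_true(all(rgb[, , , 2] == 0))
  # SD-only: green
  rgb <- false_color_overlay(mk(none), mk(none), mk(full))
  expect_true(all(rgb[, , , 2] == 1) && all(rgb[, , , 1] == 0))
  # all-zero stacks: black
  rgb <- false_color_overlay(mk(none), mk(none), mk(none))
  expect_true(all(rgb == 0))
  expect_error(false_color_overlay(mk(full), mk(full),
                                   image_stack(array(0, c(2, 2, 1)),
                                               "transverse", 1, c(1, 1))),
               "mismatch")
})

test_that("cpc_config validates its invariants", {
  expect_error(cpc_config(v_threshold = 0.5, v_ceiling = 0.4), "v_threshold")
  expect_error(cpc_config(stretch_saturation = 0.5), "stretch_saturation")
  expect_error(cpc_config(phases = integer(0)), "phases")
})
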