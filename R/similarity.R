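#' Rigid transform from two landmark pairs
#'
#' Two-landmark alignment: the translation superposes the first landmark
#' pair exactly; the minimal rotation (about the axis perpendicular to
#' both) maps the moving landmark-difference vector onto the fixed one.
#' Roll about the landmark axis is unresolvable from two points and is left
#' at zero.
#'
#' @param moving,fixed [surface_model()]s carrying both named landmarks
#' @param landmark_names character pair
#' @return list with `transform` (class `AlignmentTransform`: `rotation`
#'   3x3, `translation` mm, `center` mm pivot) and `surface` (the moving
#'   surface transformed)
#' @export
align_by_landmarks <- function(moving, fixed,
                               landmark_names = c("bifurcation",
                                                  "left_iliac_end")) {
  for (nm in landmark_names) {
    if (is.null(moving$landmarks[[nm]]))
      stop(sprintf("align_by_landmarks: moving surface lacks landmark '%s'", nm))
    if (is.null(fixed$landmarks[[nm]]))
      stop(sprintf("align_by_landmarks: fixed surface lacks landmark '%s'", nm))
  }
  m1 <- as.numeric(moving$landmarks[[landmark_names[1]]])
  m2 <- as.numeric(moving$landmarks[[landmark_names[2]]])
  f1 <- as.numeric(fixed$landmarks[[landmark_names[1]]])
  f2 <- as.numeric(fixed$landmarks[[landmark_names[2]]])
  a <- m2 - m1
  b <- f2 - f1
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("align_by_landmarks: coincident landmarks")
  a <- a / na; b <- b / nb
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2))
  cth <- sum(a * b)
  R <- diag(3)
  if (s > 1e-12) {
    K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    R <- diag(3) + K + K %*% K * ((1 - cth) / s^2)
  } else if (cth < 0) {
    # antiparallel: rotate pi about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- p - sum(p * a) * a
    u <- u / sqrt(sum(u^2))
    R <- 2 * outer(u, u) - diag(3)
  }
  tr <- structure(list(rotation = R, translation = f1, center = m1),
                  class = "AlignmentTransform")
  list(transform = tr, surface = apply_transform(moving, tr))
}

#' Apply a rigid transform to a surface, centerline or point matrix
#'
#' Points map as `R (p - center) + translation`.
#'
#' @param x a `SurfaceModel`, `Centerline` or n x 3 matrix
#' @param transform an `AlignmentTransform`
#' @return the transformed object
#' @export
apply_transform <- function(x, transform) {
  f <- function(P) sweep(sweep(P, 2, transform$center, "-") %*%
                           t(transform$rotation), 2,
                         transform$translation, "+")
  if (inherits(x, "SurfaceModel")) {
    x$vertices <- f(x$vertices)
    x$landmarks <- lapply(x$landmarks, function(p) as.numeric(f(rbind(p))))
    x
  } else if (inherits(x, "Centerline")) {
    centerline(f(x$points), radius = x$radius, labels = x$labels)
  } else {
    f(matrix(as.numeric(x), ncol = 3))
  }
}

#' Dice similarity coefficient
#'
#' `DSC = 2 |A inter B| / (|A| + |B|)` over voxel cardinalities.  Masks
#' must share a grid; surfaces are voxelized onto a common grid covering
#' both.  Two empty inputs give 1 by convention (with a warning).
#'
#' @param a,b two [binary_mask()]s on one grid, or two [surface_model()]s
#' @param resolution voxelization resolution, mm, for surface inputs
#' @return DSC in `[0, 1]`
#' @export
dice <- function(a, b, resolution = 0.5) {
  if (resolution <= 0) stop("dice: resolution must be > 0")
  if (inherits(a, "SurfaceModel") && inherits(b, "SurfaceModel")) {
    lo <- pmin(apply(a$vertices, 2, min), apply(b$vertices, 2, min)) - 2
    hi <- pmax(apply(a$vertices, 2, max), apply(b$vertices, 2, max)) + 2
    shape <- pmax(2L, as.integer(ceiling((hi - lo) / resolution)) + 1L)
    grid <- voxel_grid(shape, rep(resolution, 3), lo)
    a <- voxelize_surface(a, grid = grid)
    b <- voxelize_surface(b, grid = grid)
  }
  stopifnot(inherits(a, "BinaryMask"), inherits(b, "BinaryMask"))
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("dice: masks must share a grid")
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0) {
    warning("dice: both masks empty; DSC defined as 1")
    return(1)
  }
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Hausdorff distances between two point sets
#'
#' Exact forward, backward and symmetric Hausdorff distances:
#' `h(A,B) = max_a min_b |a - b|`, `H = max(h(A,B), h(B,A))`.
#'
#' @param a,b point matrices (n x d), non-empty, same d
#' @return list `forward`, `backward`, `symmetric` (mm)
#' @export
hausdorff_pointsets <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("hausdorff_pointsets: empty point set")
  fw <- cpp_directed_hd(a, b)
  bw <- cpp_directed_hd(b, a)
  list(forward = fw, backward = bw, symmetric = max(fw, bw))
}

# intersect a triangle mesh with the plane z = z0; returns segments as a
# list of 2 x 2 matrices of (x, y), or NULL when no triangle crosses
mesh_plane_sections <- function(surface, z0) {
  V <- surface$vertices
  Fm <- surface$faces
  z <- matrix(V[Fm, 3], ncol = 3)
  above <- z > z0
  nab <- rowSums(above)
  cross_tri <- which(nab == 1 | nab == 2)
  if (!length(cross_tri)) return(NULL)
  segs <- vector("list", length(cross_tri))
  for (q in seq_along(cross_tri)) {
    f <- Fm[cross_tri[q], ]
    zz <- V[f, 3]
    ab <- zz > z0
    solo <- if (sum(ab) == 1) which(ab) else which(!ab)
    others <- setdiff(1:3, solo)
    p0 <- V[f[solo], ]
    pts <- matrix(0, 2, 2)
    for (k in 1:2) {
      p1 <- V[f[others[k]], ]
      t <- (z0 - p0[3]) / (p1[3] - p0[3])
      pts[k, ] <- p0[1:2] + t * (p1[1:2] - p0[1:2])
    }
    segs[[q]] <- pts
  }
  segs
}

# sample plane-section segments at <= `ds` spacing; returns an n x 2 matrix
sample_sections <- function(segs, ds = 0.1) {
  out <- lapply(segs, function(s) {
    len <- sqrt(sum((s[2, ] - s[1, ])^2))
    n <- max(1L, ceiling(len / ds))
    t <- seq(0, 1, length.out = n + 1)
    cbind(s[1, 1] + t * (s[2, 1] - s[1, 1]),
          s[1, 2] + t * (s[2, 2] - s[1, 2]))
  })
  do.call(rbind, out)
}

#' Slice-wise Hausdorff protocol between two aligned surfaces
#'
#' Intersects both surfaces with `n_planes` equally spaced horizontal
#' (fixed-z) planes across their shared axial extent, computes the exact
#' symmetric 2D Hausdorff distance between the boundary contours on each
#' plane (contours sampled at <= `contour_ds` mm spacing), and reports the
#' per-plane series with mean, SD and the 95th percentile (the outlier-
#' robust summary).  Planes where either surface has no section are skipped
#' and counted.
#'
#' @param a,b aligned [surface_model()]s
#' @param n_planes number of planes (default 1000)
#' @param contour_ds contour sampling step, mm (default 0.1)
#' @return an `HDReport`: list with `per_plane_hd`, `plane_z`, `hd_mean`,
#'   `hd_sd`, `hd_p95`, `forward_hd`, `backward_hd`, `symmetric_hd`,
#'   `n_planes_skipped`
#' @export
slicewise_hd <- function(a, b, n_planes = 1000, contour_ds = 0.1) {
  za <- range(a$vertices[, 3])
  zb <- range(b$vertices[, 3])
  lo <- max(za[1], zb[1])
  hi <- min(za[2], zb[2])
  if (hi <= lo)
    stop("slicewise_hd: surfaces have no overlapping axial extent")
  # keep planes strictly interior so tangent planes at the caps are avoided
  zs <- seq(lo, hi, length.out = n_planes + 2)[2:(n_planes + 1)]
  hd <- rep(NA_real_, n_planes)
  fw <- bw <- rep(NA_real_, n_planes)
  for (i in seq_len(n_planes)) {
    sa <- mesh_plane_sections(a, zs[i])
    sb <- mesh_plane_sections(b, zs[i])
    if (is.null(sa) || is.null(sb)) next
    pa <- sample_sections(sa, contour_ds)
    pb <- sample_sections(sb, contour_ds)
    fw[i] <- cpp_directed_hd(pa, pb)
    bw[i] <- cpp_directed_hd(pb, pa)
    hd[i] <- max(fw[i], bw[i])
  }
  ok <- !is.na(hd)
  if (!any(ok)) stop("slicewise_hd: no plane intersected both surfaces")
  per <- hd[ok]
  structure(list(per_plane_hd = per, plane_z = zs[ok],
                 hd_mean = mean(per), hd_sd = stats::sd(per),
                 hd_p95 = stats::quantile(per, 0.95, names = FALSE,
                                          type = 7),
                 forward_hd = max(fw[ok]), backward_hd = max(bw[ok]),
                 symmetric_hd = max(per),
                 n_planes_skipped = sum(!ok)),
            class = "HDReport")
}

#' @export
print.HDReport <- function(x, ...) {
  cat(sprintf(
    "Slice-wise HD over %d planes (%d skipped): %.2f +/- %.2f mm, p95 %.2f mm, symmetric max %.2f mm\n",
    length(x$per_plane_hd) + x$n_planes_skipped, x$n_planes_skipped,
    x$hd_mean, x$hd_sd, x$hd_p95, x$symmetric_hd))
  invisible(x)
}

#' Truncate a surface at a landmark's axial level
#'
#' Drops all faces whose centroid lies beyond the landmark z (the protocol
#' truncates both models at the bifurcation reference point before the
#' slice-wise comparison).  The cut leaves an open rim: the result is for
#' boundary comparison, not voxelization.
#'
#' @param surface a [surface_model()]
#' @param landmark landmark name or mm point
#' @param keep `"below"` (z smaller, default) or `"above"`
#' @return a [surface_model()]
#' @export
truncate_at_landmark <- function(surface, landmark, keep = c("below",
                                                             "above")) {
  keep <- match.arg(keep)
  p <- if (is.character(landmark)) {
    if (is.null(surface$landmarks[[landmark]]))
      stop(sprintf("truncate_at_landmark: no landmark '%s'", landmark))
    surface$landmarks[[landmark]]
  } else as.numeric(landmark)
  zc <- rowMeans(matrix(surface$vertices[surface$faces, 3], ncol = 3))
  sel <- if (keep == "below") zc <= p[3] else zc >= p[3]
  keep_faces <- surface$faces[sel, , drop = FALSE]
  used <- sort(unique(as.integer(keep_faces)))
  remap <- integer(nrow(surface$vertices))
  remap[used] <- seq_along(used)
  surface_model(surface$vertices[used, , drop = FALSE],
                matrix(remap[keep_faces], ncol = 3),
                landmarks = surface$landmarks)
}

#' JSON similarity report
#'
#' @param dice_value DSC
#' @param hd an `HDReport`
#' @param transform optional `AlignmentTransform`
#' @param path output JSON file
#' @return `path`, invisibly
#' @export
write_similarity_report <- function(dice_value, hd, transform = NULL, path) {
  rep <- list(dice = dice_value, hd_mean = hd$hd_mean, hd_sd = hd$hd_sd,
              hd_p95 = hd$hd_p95, forward_hd = hd$forward_hd,
              backward_hd = hd$backward_hd, symmetric_hd = hd$symmetric_hd,
              n_planes_skipped = hd$n_planes_skipped)
  if (!is.null(transform))
    rep$transform <- list(rotation = transform$rotation,
                          translation = transform$translation,
                          center = transform$center)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
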