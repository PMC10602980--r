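#' Vessel centerline
#'
#' Ordered 3D polyline with arc-length parameterization and (optionally) a
#' per-point maximal-inscribed-sphere radius.
#'
#' @param points n x 3 matrix, mm, consecutive points distinct
#' @param radius optional numeric vector, mm, length n
#' @param labels named list of point indices (e.g. `bifurcation`,
#'   `endpoint`)
#' @return an object of class `Centerline`
#' @export
centerline <- function(points, radius = NULL, labels = list()) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 2) stop("Centerline: need at least 2 points")
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg == 0)) {
    keep <- c(TRUE, seg > 0)
    points <- points[keep, , drop = FALSE]
    if (!is.null(radius)) radius <- radius[keep]
    if (nrow(points) < 2) stop("Centerline: need at least 2 distinct points")
    seg <- sqrt(rowSums(diff(points)^2))
  }
  structure(list(points = points, arc_length = c(0, cumsum(seg)),
                 radius = radius, labels = labels),
            class = "Centerline")
}

#' @export
print.Centerline <- function(x, ...) {
  cat(sprintf("Centerline: %d points, length %.2f mm%s\n", nrow(x$points),
              max(x$arc_length),
              if (is.null(x$radius)) "" else ", with radius"))
  invisible(x)
}

#' Total arc length (mm)
#' @param line a [centerline()]
#' @return mm
#' @export
centerline_length <- function(line) max(line$arc_length)

point_to_voxel <- function(grid, p) {
  idx <- round((as.numeric(p) - grid$origin) / grid$spacing) + 1
  as.integer(pmin(pmax(idx, 1), grid$shape))
}

#' Extract a centerline from a binary mask
#'
#' Minimum-cost path between two endpoints through the lumen, with
#' per-voxel cost `1 / (dt + eps)` where `dt` is the Euclidean distance
#' transform: the path is drawn toward the locus of maximal distance from
#' the wall, the same maximal-inscribed-sphere semantics as Voronoi-based
#' centerline methods.  The per-point `radius` is `dt` at the path point.
#'
#' @param mask a [binary_mask()]
#' @param endpoints 2 x 3 matrix of mm points (must be inside the mask; a
#'   point within `snap_mm` of the mask is snapped to the nearest
#'   foreground voxel)
#' @param eps regularizer, mm (default 0.1)
#' @param snap_mm endpoint snapping tolerance (default 3)
#' @return a [centerline()] with radius
#' @export
extract_centerline <- function(mask, endpoints, eps = 0.1, snap_mm = 3) {
  stopifnot(inherits(mask, "BinaryMask"))
  endpoints <- matrix(as.numeric(endpoints), ncol = 3)
  stopifnot(nrow(endpoints) == 2)
  g <- mask$grid
  fg <- mask$voxels
  fg_idx <- which(fg)
  if (!length(fg_idx)) stop("extract_centerline: empty mask")
  fg_pts <- sweep(sweep(arrayInd(fg_idx, g$shape) - 1, 2, g$spacing, "*"),
                  2, g$origin, "+")
  ev <- matrix(0L, 2, 3)
  for (r in 1:2) {
    v <- point_to_voxel(g, endpoints[r, ])
    if (!fg[v[1], v[2], v[3]]) {
      d2 <- rowSums(sweep(fg_pts, 2, endpoints[r, ], "-")^2)
      j <- which.min(d2)
      if (sqrt(d2[j]) > snap_mm)
        stop(sprintf("extract_centerline: endpoint %d (%.1f, %.1f, %.1f) is outside the mask",
                     r, endpoints[r, 1], endpoints[r, 2], endpoints[r, 3]))
      v <- as.integer(arrayInd(fg_idx[j], g$shape))
    }
    ev[r, ] <- v
  }
  dt <- distance_transform(fg, g)
  cost <- 1 / (dt + eps)

  idx <- which(fg)
  nid <- array(0L, dim = g$shape)
  nid[idx] <- seq_along(idx)
  sh <- g$shape
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]  # 13 forward offsets
  ai <- arrayInd(idx, sh)
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    nb <- sweep(ai, 2, o, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= sh[1] & nb[, 2] >= 1 & nb[, 2] <= sh[2] &
      nb[, 3] >= 1 & nb[, 3] <= sh[3]
    if (!any(ok)) next
    lin_nb <- nb[ok, 1] + sh[1] * (nb[ok, 2] - 1 + sh[2] * (nb[ok, 3] - 1))
    src <- nid[idx[ok]]
    dst <- nid[lin_nb]
    keep <- dst > 0
    if (!any(keep)) next
    step <- sqrt(sum((o * g$spacing)^2))
    from <- c(from, src[keep])
    to <- c(to, dst[keep])
    wt <- c(wt, step * (cost[idx[ok]][keep] + cost[lin_nb[keep]]) / 2)
  }
  gr <- igraph::make_graph(edges = rbind(from, to), n = length(idx),
                           directed = FALSE)
  v1 <- nid[ev[1, 1], ev[1, 2], ev[1, 3]]
  v2 <- nid[ev[2, 1], ev[2, 2], ev[2, 3]]
  sp <- suppressWarnings(igraph::shortest_paths(gr, from = v1, to = v2,
                                                weights = wt,
                                                output = "vpath"))
  vp <- as.integer(sp$vpath[[1]])
  if (length(vp) < 2)
    stop("extract_centerline: no path between the endpoints inside the mask")
  pts_idx <- ai[vp, , drop = FALSE]
  pts <- sweep(sweep(pts_idx - 1, 2, g$spacing, "*"), 2, g$origin, "+")
  centerline(pts, radius = dt[idx[vp]])
}

#' Resample and smooth a centerline
#'
#' Uniform arc-length resampling to (close to) the stated interval, then
#' `iterations` sweeps of endpoint-pinned Laplacian relaxation
#' `p_i <- p_i + factor * ((p_{i-1} + p_{i+1}) / 2 - p_i)` — the standard
#' centerline smoothing semantics ("factor 0.5, 100 iterations").  The
#' radius, if present, is linearly resampled alongside (and untouched by
#' the positional smoothing).
#'
#' @param line a [centerline()]
#' @param interval target spacing, mm (default 3)
#' @param factor relaxation weight per iteration (default 0.5)
#' @param iterations relaxation sweeps (default 100)
#' @return a [centerline()]
#' @export
resample_smooth <- function(line, interval = 3.0, factor = 0.5,
                            iterations = 100) {
  L <- centerline_length(line)
  if (interval >= L)
    stop("resample_smooth: interval must be smaller than the line length")
  nseg <- max(1L, round(L / interval))
  s_new <- seq(0, L, length.out = nseg + 1)
  s_old <- line$arc_length
  P <- vapply(1:3, function(c_)
    stats::approx(s_old, line$points[, c_], xout = s_new)$y,
    numeric(length(s_new)))
  R <- if (is.null(line$radius)) NULL else
    stats::approx(s_old, line$radius, xout = s_new)$y
  n <- nrow(P)
  if (n >= 3 && iterations > 0) {
    for (it in seq_len(iterations)) {
      mid <- (P[1:(n - 2), , drop = FALSE] + P[3:n, , drop = FALSE]) / 2
      P[2:(n - 1), ] <- P[2:(n - 1), , drop = FALSE] +
        factor * (mid - P[2:(n - 1), , drop = FALSE])
    }
  }
  centerline(P, radius = R, labels = line$labels)
}

#' Centerline curvature (Eq. of the osculating circle)
#'
#' `kappa = |c' x c''| / |c'|^3` with derivatives by central finite
#' differences on the arc-length parameterization; endpoint values copy
#' their interior neighbour.  Degenerate (collinear/duplicate) triples give
#' 0.
#'
#' @param line a [centerline()]
#' @return numeric vector of curvatures, 1/m
#' @export
curvature <- function(line) {
  P <- line$points
  s <- line$arc_length
  n <- nrow(P)
  if (n < 3) stop("curvature: need at least 3 points")
  kap <- numeric(n)
  i <- 2:(n - 1)
  h1 <- s[i] - s[i - 1]
  h2 <- s[i + 1] - s[i]
  d1 <- (P[i + 1, , drop = FALSE] - P[i - 1, , drop = FALSE]) / (h1 + h2)
  d2 <- ((P[i + 1, , drop = FALSE] - P[i, , drop = FALSE]) / h2 -
           (P[i, , drop = FALSE] - P[i - 1, , drop = FALSE]) / h1) /
    ((h1 + h2) / 2)
  cr <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
              d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
              d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  num <- sqrt(rowSums(cr^2))
  den <- (sqrt(rowSums(d1^2)))^3
  k <- ifelse(den > 0, num / den, 0)
  kap[i] <- k
  kap[1] <- kap[2]
  kap[n] <- kap[n - 1]
  kap * 1000  # mm^-1 -> m^-1
}

#' Centerline tortuosity
#'
#' `chi = L / D - 1` with `L` the arc length and `D` the Euclidean distance
#' between the endpoints.
#'
#' @param line a [centerline()]
#' @return dimensionless, >= 0
#' @export
tortuosity <- function(line) {
  P <- line$points
  D <- sqrt(sum((P[nrow(P), ] - P[1, ])^2))
  if (D == 0) stop("tortuosity: coincident endpoints (D = 0)")
  max(centerline_length(line) / D - 1, 0)
}

# least-squares direction of the first `span_mm` of a line, oriented away
# from its start
initial_tangent <- function(line, span_mm = 10) {
  s <- line$arc_length
  sel <- s <= span_mm
  if (sum(sel) < 2) sel[1:2] <- TRUE
  P <- line$points[sel, , drop = FALSE]
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr, "-"))
  d <- sv$v[, 1]
  ref <- P[nrow(P), ] - P[1, ]
  if (sum(d * ref) < 0) d <- -d
  d / sqrt(sum(d^2))
}

#' Bifurcation angle between two daughter vessels
#'
#' The bifurcation plane is spanned by the two daughter initial tangents
#' (least-squares direction of the first 10 mm of each) through the
#' reference point; the angle is measured between the in-plane daughter
#' directions, in (0, 180) degrees.
#'
#' @param parent parent [centerline()] (ends near the reference point)
#' @param daughter1,daughter2 daughter [centerline()]s starting near the
#'   reference point
#' @param reference_point mm point of the bifurcation
#' @param tol_mm how far a daughter start may sit from the reference point
#'   (default 10 mm, about 2 coarse voxels)
#' @param span_mm tangent-fitting span (default 10 mm)
#' @return list with `angle_deg` and `system` (a `BifurcationSystem`)
#' @export
bifurcation_angle <- function(parent, daughter1, daughter2, reference_point,
                              tol_mm = 10, span_mm = 10) {
  reference_point <- as.numeric(reference_point)
  for (d in list(daughter1, daughter2)) {
    d0 <- sqrt(sum((d$points[1, ] - reference_point)^2))
    if (d0 > tol_mm)
      stop(sprintf("bifurcation_angle: daughter starts %.1f mm from the reference point (tolerance %.1f mm)",
                   d0, tol_mm))
  }
  t1 <- initial_tangent(daughter1, span_mm)
  t2 <- initial_tangent(daughter2, span_mm)
  pn <- c(t1[2] * t2[3] - t1[3] * t2[2],
          t1[3] * t2[1] - t1[1] * t2[3],
          t1[1] * t2[2] - t1[2] * t2[1])
  pl <- sqrt(sum(pn^2))
  if (pl < 1e-9) {
    warning("bifurcation_angle: daughter directions are parallel; angle 0")
    angle <- 0
    pn <- c(0, 0, 1)
  } else {
    pn <- pn / pl
    angle <- acos(pmin(pmax(sum(t1 * t2), -1), 1)) * 180 / pi
  }
  np <- nrow(parent$points)
  pdir <- parent$points[np, ] - parent$points[max(1, np - 3), ]
  plen <- sqrt(sum(pdir^2))
  pdir <- if (plen > 0) pdir / plen else c(0, 0, 1)
  sys <- structure(list(reference_point = reference_point,
                        parent_direction = pdir,
                        daughter_directions = list(t1, t2),
                        bifurcation_plane_normal = pn),
                   class = "BifurcationSystem")
  list(angle_deg = angle, system = sys)
}

#' Dissected-lumen radius
#'
#' Where a dissection splits the vessel into true and false lumina the
#' effective radius is reported as their sum, `R = R_TL + R_FL`,
#' elementwise along the centerline.
#'
#' @param radius_true,radius_false mm series of equal length
#' @return mm series
#' @export
dissected_radius <- function(radius_true, radius_false) {
  if (length(radius_true) != length(radius_false))
    stop("dissected_radius: series lengths differ")
  radius_true + radius_false
}

#' Write / read a centerline as CSV
#'
#' Columns: `x_mm, y_mm, z_mm, arclength_mm, radius_mm, label`.
#'
#' @param line a [centerline()]
#' @param path CSV file
#' @return `path` invisibly / a `Centerline`
#' @export
write_centerline_csv <- function(line, path) {
  lab <- rep("", nrow(line$points))
  for (nm in names(line$labels)) lab[line$labels[[nm]]] <- nm
  df <- data.frame(x_mm = line$points[, 1], y_mm = line$points[, 2],
                   z_mm = line$points[, 3], arclength_mm = line$arc_length,
                   radius_mm = if (is.null(line$radius)) NA else line$radius,
                   label = lab)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centerline_csv
#' @export
read_centerline_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  radius <- if (all(is.na(df$radius_mm))) NULL else df$radius_mm
  labels <- list()
  if (!is.null(df$label)) {
    has <- which(!is.na(df$label) & df$label != "")
    for (i in has) labels[[df$label[i]]] <- i
  }
  centerline(cbind(df$x_mm, df$y_mm, df$z_mm), radius = radius,
             labels = labels)
}
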