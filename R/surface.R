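#' Triangulated lumen surface
#'
#' @param vertices n x 3 matrix, mm
#' @param faces m x 3 integer matrix of 1-based vertex indices, consistently
#'   oriented (outward normals)
#' @param landmarks named list of mm points (e.g. bifurcation reference
#'   point, left-iliac endpoint); snapped to the nearest vertex by
#'   [set_landmark()]
#' @return an object of class `SurfaceModel`
#' @export
surface_model <- function(vertices, faces, landmarks = list()) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("SurfaceModel: face indices out of range")
  deg <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  if (any(deg)) faces <- faces[!deg, , drop = FALSE]
  structure(list(vertices = vertices, faces = faces, landmarks = landmarks),
            class = "SurfaceModel")
}

#' @export
print.SurfaceModel <- function(x, ...) {
  cat(sprintf("SurfaceModel: %d vertices, %d faces", nrow(x$vertices),
              nrow(x$faces)))
  if (length(x$landmarks))
    cat(sprintf(", landmarks: %s", paste(names(x$landmarks), collapse = ", ")))
  cat("\n")
  invisible(x)
}

edge_table <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Watertightness check
#'
#' A closed, manifold triangulation has every undirected edge shared by
#' exactly two faces.
#'
#' @param surface a [surface_model()]
#' @return `TRUE`/`FALSE`; attribute `open_edges` lists offending edges
#' @export
is_watertight <- function(surface) {
  if (nrow(surface$faces) == 0) return(FALSE)
  tab <- edge_table(surface$faces)
  bad <- names(tab)[tab != 2]
  out <- length(bad) == 0
  attr(out, "open_edges") <- bad
  out
}

#' Signed enclosed volume of a closed surface (mm^3)
#'
#' Divergence-theorem sum over faces; positive for outward orientation.
#'
#' @param surface a [surface_model()]
#' @return volume in mm^3
#' @export
mesh_volume <- function(surface) {
  V <- surface$vertices
  Fm <- surface$faces
  a <- V[Fm[, 1], , drop = FALSE]
  b <- V[Fm[, 2], , drop = FALSE]
  c_ <- V[Fm[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(rowSums(a * cr)) / 6
}

#' Total surface area (mm^2)
#' @param surface a [surface_model()]
#' @return area in mm^2
#' @export
mesh_area <- function(surface) {
  V <- surface$vertices
  Fm <- surface$faces
  u <- V[Fm[, 2], , drop = FALSE] - V[Fm[, 1], , drop = FALSE]
  w <- V[Fm[, 3], , drop = FALSE] - V[Fm[, 1], , drop = FALSE]
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

# volume-constrained Laplacian smoothing: each iteration moves vertices
# toward the mean of their neighbours (uniform weights, factor lambda) and
# then rescales about the centroid to restore the enclosed volume.
smooth_surface <- function(surface, iterations, lambda = 0.5) {
  if (iterations <= 0 || nrow(surface$faces) == 0) return(surface)
  V <- surface$vertices
  nv <- nrow(V)
  e <- rbind(surface$faces[, c(1, 2)], surface$faces[, c(2, 3)],
             surface$faces[, c(3, 1)])
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(nv, nv))
  A@x[] <- 1  # collapse duplicate entries to unit weights
  degree <- Matrix::rowSums(A)
  degree[degree == 0] <- 1
  v0 <- abs(mesh_volume(surface))
  for (it in seq_len(iterations)) {
    nb <- as.matrix(A %*% V) / degree
    V <- V + lambda * (nb - V)
  }
  out <- surface
  out$vertices <- V
  v1 <- abs(mesh_volume(out))
  if (v1 > 0 && v0 > 0) {
    ctr <- colMeans(V)
    out$vertices <- sweep(sweep(V, 2, ctr, "-") * (v0 / v1)^(1 / 3), 2, ctr,
                          "+")
  }
  out
}

#' Iso-surface of a binary mask
#'
#' Extracts the 0.5 level set of the mask with marching tetrahedra and
#' applies the stated iterations of volume-constrained Laplacian smoothing.
#' The result is watertight with outward-oriented faces (asserted).
#'
#' @param mask a [binary_mask()]
#' @param smoothing_iterations count (default 10)
#' @return a [surface_model()]
#' @export
mask_to_surface <- function(mask, smoothing_iterations = 10) {
  stopifnot(inherits(mask, "BinaryMask"))
  if (!any(mask$voxels)) stop("mask_to_surface: empty mask")
  g <- mask$grid
  # pad by one background voxel so surfaces at the grid boundary close
  sh <- g$shape + 2L
  vol <- array(0, dim = sh)
  vol[2:(sh[1] - 1), 2:(sh[2] - 1), 2:(sh[3] - 1)] <-
    as.numeric(mask$voxels)
  res <- cpp_marching_tets(as.numeric(vol), sh, g$spacing,
                           g$origin - g$spacing, 0.5)
  surf <- surface_model(res$vertices, res$faces)
  if (!isTRUE(as.logical(is_watertight(surf))))
    stop("mask_to_surface: extracted surface is not watertight")
  if (mesh_volume(surf) < 0) surf$faces <- surf$faces[, c(1, 3, 2)]
  surf <- smooth_surface(surf, smoothing_iterations)
  surf
}

#' Voxelize a watertight surface
#'
#' Inside/outside parity test at every voxel center of a grid covering the
#' mesh (or a caller-supplied grid).
#'
#' @param surface a [surface_model()] (must be watertight)
#' @param resolution isotropic voxel size, mm (default 0.5); ignored when
#'   `grid` is given
#' @param grid optional [voxel_grid()] to voxelize onto
#' @param margin mm of padding around the mesh bounding box
#' @return a [binary_mask()]
#' @export
voxelize_surface <- function(surface, resolution = 0.5, grid = NULL,
                             margin = 2) {
  stopifnot(inherits(surface, "SurfaceModel"))
  if (resolution <= 0) stop("voxelize_surface: resolution must be > 0")
  wt <- is_watertight(surface)
  if (!isTRUE(as.logical(wt)))
    stop(sprintf("voxelize_surface: surface is not watertight (%d open edges, e.g. %s)",
                 length(attr(wt, "open_edges")),
                 paste(utils::head(attr(wt, "open_edges"), 3), collapse = "; ")))
  if (is.null(grid)) {
    lo <- apply(surface$vertices, 2, min) - margin
    hi <- apply(surface$vertices, 2, max) + margin
    shape <- pmax(2L, as.integer(ceiling((hi - lo) / resolution)) + 1L)
    grid <- voxel_grid(shape, rep(resolution, 3), lo)
  }
  inside <- cpp_raycast_inside(surface$vertices, surface$faces, grid$shape,
                               grid$spacing, grid$origin)
  binary_mask(array(inside, dim = grid$shape), grid)
}

#' Attach a named landmark, snapped to the nearest surface vertex
#'
#' @param surface a [surface_model()]
#' @param name landmark name
#' @param point mm coordinate
#' @return the surface with the landmark set
#' @export
set_landmark <- function(surface, name, point) {
  d2 <- rowSums(sweep(surface$vertices, 2, as.numeric(point), "-")^2)
  surface$landmarks[[name]] <- surface$vertices[which.min(d2), ]
  surface
}

# ---------------------------------------------------------------------------
# STL / PLY io

#' Write a surface as STL
#'
#' @param surface a [surface_model()]
#' @param path output file
#' @param ascii write ASCII STL (default) or binary
#' @return `path`, invisibly
#' @export
write_stl <- function(surface, path, ascii = TRUE) {
  V <- surface$vertices
  Fm <- surface$faces
  u <- V[Fm[, 2], , drop = FALSE] - V[Fm[, 1], , drop = FALSE]
  w <- V[Fm[, 3], , drop = FALSE] - V[Fm[, 1], , drop = FALSE]
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid cpcmra", con)
    for (i in seq_len(nrow(Fm))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1],
                         nrm[i, 2], nrm[i, 3]), con)
      writeLines("    outer loop", con)
      for (k in 1:3)
        writeLines(sprintf("      vertex %.9g %.9g %.9g",
                           V[Fm[i, k], 1], V[Fm[i, k], 2], V[Fm[i, k], 3]),
                   con)
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid cpcmra", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(Fm)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(Fm))) {
      writeBin(as.numeric(c(nrm[i, ], t(V[Fm[i, ], ]))), con, size = 4,
               endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an STL file (ASCII or binary, auto-detected)
#'
#' Duplicate vertices are merged exactly so downstream topology checks see
#' shared edges.
#'
#' @param path STL file
#' @return a [surface_model()]
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_stl: no such file '%s'", path))
  head_raw <- readBin(path, "raw", 80)
  is_ascii <- grepl("^solid", rawToChar(head_raw[1:5]))
  # binary files may also start with "solid"; check size consistency
  if (!is_ascii) {
    tri <- NULL
  }
  if (is_ascii) {
    sz <- file.info(path)$size
    con <- file(path, "rb")
    seek(con, 80)
    ntri_guess <- readBin(con, "integer", 1, size = 4, endian = "little")
    close(con)
    if (length(ntri_guess) == 1 && !is.na(ntri_guess) &&
        sz == 84 + 50 * as.numeric(ntri_guess))
      is_ascii <- FALSE
  }
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, 80)
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    xyz <- matrix(0, nrow = 3 * ntri, ncol = 3)
    for (i in seq_len(ntri)) {
      vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
      xyz[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], ncol = 3,
                                           byrow = TRUE)
      readBin(con, "integer", 1, size = 2, endian = "little")
    }
  }
  key <- paste(xyz[, 1], xyz[, 2], xyz[, 3])
  ids <- match(key, unique(key))
  verts <- xyz[!duplicated(key), , drop = FALSE]
  faces <- matrix(ids, ncol = 3, byrow = TRUE)
  surface_model(verts, faces)
}

#' Write a surface as ASCII PLY
#' @param surface a [surface_model()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_ply <- function(surface, path) {
  V <- surface$vertices
  Fm <- surface$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(Fm)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("3 %d %d %d", Fm[, 1] - 1L, Fm[, 2] - 1L, Fm[, 3] - 1L),
             con)
  invisible(path)
}

#' Read an ASCII PLY file (xyz vertices + triangular faces)
#' @param path PLY file
#' @return a [surface_model()]
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endh <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vl <- lines[(endh + 1):(endh + nv)]
  fl <- lines[(endh + nv + 1):(endh + nv + nf)]
  V <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p)
    as.numeric(p[1:3])))
  Fm <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p)
    as.integer(p[2:4]) + 1L))
  surface_model(V, Fm)
}
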