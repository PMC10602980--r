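# Minimal self-contained NIfTI-1 (.nii, single-file, uncompressed) reader
# and writer.  Only what the pipeline needs: 3D/4D scalar volumes, voxel
# spacing via pixdim, origin via a diagonal sform, datatypes uint8/int16/
# int32/float32/float64, scl_slope/scl_inter honoured on read.  No R NIfTI
# package is available in the target environment, and the fixed 348-byte
# header makes this a small, well-defined contract.

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
                 float64 = 64L)

#' Write a volume as NIfTI-1
#'
#' @param vol 3D or 4D numeric array
#' @param path output file path (`.nii`)
#' @param spacing voxel spacing, mm triple
#' @param origin mm coordinate of the first voxel center
#' @param datatype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`
#' @param dt time step (seconds) recorded in `pixdim[5]` for 4D data
#' @return `path`, invisibly
#' @export
write_nifti <- function(vol, path, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        datatype = "float32", dt = 0) {
  dtcode <- NIFTI_DT[[match.arg(datatype, names(NIFTI_DT))]]
  d <- dim(vol)
  if (length(d) < 3 || length(d) > 4)
    stop("write_nifti: vol must be 3D or 4D")
  ndim <- length(d)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  wi(348L, 4)                                   # sizeof_hdr
  wraw(36)                                      # data_type..dim_info
  dim8 <- rep(1L, 8); dim8[1] <- ndim; dim8[1 + seq_along(d)] <- d
  wi(dim8, 2)                                   # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)                     # intent_p1..3, intent_code
  wi(dtcode, 2)                                 # datatype
  bitpix <- c(`2` = 8L, `4` = 16L, `8` = 32L, `16` = 32L, `64` = 64L)
  wi(bitpix[[as.character(dtcode)]], 2)         # bitpix
  wi(0L, 2)                                     # slice_start
  pd <- rep(0, 8); pd[1] <- 1; pd[2:4] <- spacing; pd[5] <- dt
  wf(pd)                                        # pixdim[8]
  wf(352)                                       # vox_offset
  wf(c(1, 0))                                   # scl_slope, scl_inter
  wi(0L, 2); wraw(2)                            # slice_end, slice_code, xyzt
  wf(c(0, 0, 0, 0))                             # cal_max..toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  wraw(104)                                     # descrip, aux_file
  wi(c(0L, 1L), 2)                              # qform_code=0, sform_code=1
  wf(c(0, 0, 0, 0, 0, 0))                       # quaternion + qoffset
  wf(c(spacing[1], 0, 0, origin[1]))            # srow_x
  wf(c(0, spacing[2], 0, origin[2]))            # srow_y
  wf(c(0, 0, spacing[3], origin[3]))            # srow_z
  wraw(16)                                      # intent_name
  writeBin(charToRaw("n+1"), con); wraw(1)      # magic
  wraw(4)                                       # extension flag
  vals <- as.numeric(vol)
  if (dtcode %in% c(2L, 4L, 8L)) {
    vals <- round(vals)
    sz <- c(`2` = 1L, `4` = 2L, `8` = 4L)[[as.character(dtcode)]]
    writeBin(as.integer(vals), con, size = sz, endian = "little")
  } else {
    writeBin(vals, con, size = if (dtcode == 16L) 4L else 8L,
             endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` file
#' @return list with `data` (3D or 4D array), `spacing`, `origin`, `dt`
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_nifti: no such file '%s'", path))
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  hdrsz <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (hdrsz != 348L) {
    endian <- "big"
    if (hdrsz != 1543569408L)  # 348 byte-swapped
      stop("read_nifti: not a NIfTI-1 file (bad sizeof_hdr)")
  }
  seek(con, 40)
  dim8 <- readBin(con, "integer", 8, size = 2, endian = endian)
  ndim <- dim8[1]
  if (ndim < 3 || ndim > 4) stop("read_nifti: only 3D/4D volumes supported")
  d <- dim8[2:(1 + ndim)]
  seek(con, 70)
  dtcode <- readBin(con, "integer", 1, size = 2, endian = endian)
  seek(con, 76)
  pd <- readBin(con, "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl <- readBin(con, "numeric", 2, size = 4, endian = endian)
  seek(con, 254)
  sform <- readBin(con, "integer", 1, size = 2, endian = endian)
  seek(con, 280)
  srow <- readBin(con, "numeric", 12, size = 4, endian = endian)
  origin <- c(0, 0, 0)
  spacing <- pd[2:4]
  if (sform > 0) {
    origin <- srow[c(4, 8, 12)]
    sp <- c(srow[1], srow[6], srow[11])
    if (all(sp > 0)) spacing <- sp
  }
  seek(con, max(352, round(vox_offset)))
  n <- prod(d)
  data <- switch(as.character(dtcode),
    `2` = readBin(con, "integer", n, size = 1, signed = FALSE,
                  endian = endian),
    `4` = readBin(con, "integer", n, size = 2, endian = endian),
    `8` = readBin(con, "integer", n, size = 4, endian = endian),
    `16` = readBin(con, "numeric", n, size = 4, endian = endian),
    `64` = readBin(con, "numeric", n, size = 8, endian = endian),
    stop(sprintf("read_nifti: unsupported datatype code %d", dtcode)))
  data <- as.numeric(data)
  if (!is.na(scl[1]) && scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    data <- data * scl[1] + scl[2]
  list(data = array(data, dim = d), spacing = spacing, origin = origin,
       dt = pd[5])
}

# file layout of a 4D flow dataset on disk (NIfTI dialect):
#   <dir>/magnitude.nii, velocity_x.nii, velocity_y.nii, velocity_z.nii
#   <dir>/flow4d.json  sidecar: venc_ms, period_s, frame_times_s,
#                      velocity_encoding ("ms" | "phase"), phase_scale
FLOW4D_CHANNELS <- c(magnitude = "magnitude.nii", vx = "velocity_x.nii",
                     vy = "velocity_y.nii", vz = "velocity_z.nii")

#' Write a 4D flow dataset to a directory of NIfTI volumes
#'
#' One 4D NIfTI per channel (magnitude and three velocity components, m/s)
#' plus a JSON sidecar carrying VENC, the cardiac period and the frame
#' times, which NIfTI-1 cannot represent natively.
#'
#' @param dataset a [flow4d_dataset()]
#' @param path output directory (created if needed)
#' @return `path`, invisibly
#' @export
write_flow4d <- function(dataset, path) {
  stopifnot(inherits(dataset, "Flow4DDataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- dataset$grid
  dt <- if (dataset$n_frames > 1) diff(dataset$frame_times)[1] else 0
  write_nifti(dataset$magnitude, file.path(path, FLOW4D_CHANNELS["magnitude"]),
              g$spacing, g$origin, "float32", dt = dt)
  for (ch in c("vx", "vy", "vz"))
    write_nifti(dataset$velocity[[ch]], file.path(path, FLOW4D_CHANNELS[ch]),
                g$spacing, g$origin, "float32", dt = dt)
  sidecar <- list(venc_ms = dataset$venc, period_s = dataset$period_T,
                  frame_times_s = dataset$frame_times,
                  velocity_encoding = "ms")
  jsonlite::write_json(sidecar, file.path(path, "flow4d.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a 4D flow dataset
#'
#' Reads the directory layout written by [write_flow4d()].  When the sidecar
#' declares `velocity_encoding: "phase"`, stored integer phase values `p`
#' are rescaled to velocity as `p / phase_scale * venc` (m/s) at read time;
#' velocity is always held in m/s in memory.
#'
#' @param path dataset directory
#' @param format only `"nifti"` is supported; `"dicom-series"` raises a
#'   documented unsupported-format error (no DICOM codec is available)
#' @return a [flow4d_dataset()]
#' @export
read_flow4d <- function(path, format = c("nifti", "dicom-series")) {
  format <- match.arg(format)
  if (format == "dicom-series")
    stop("read_flow4d: unsupported format 'dicom-series' (no DICOM codec available in this build); use the NIfTI + JSON sidecar layout")
  if (!dir.exists(path)) stop(sprintf("read_flow4d: no such directory '%s'", path))
  for (ch in names(FLOW4D_CHANNELS))
    if (!file.exists(file.path(path, FLOW4D_CHANNELS[ch])))
      stop(sprintf("incomplete dataset: missing channel '%s' (%s)", ch,
                   FLOW4D_CHANNELS[ch]))
  scpath <- file.path(path, "flow4d.json")
  if (!file.exists(scpath)) stop("incomplete dataset: missing flow4d.json sidecar")
  sc <- jsonlite::read_json(scpath, simplifyVector = TRUE)
  vols <- lapply(FLOW4D_CHANNELS, function(f) read_nifti(file.path(path, f)))
  dims <- lapply(vols, function(v) dim(v$data))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("grid mismatch: channels have inconsistent shapes")
  d <- dims[[1]]
  if (length(d) == 3) d <- c(d, 1L)
  venc <- as.numeric(sc$venc_ms)
  conv <- function(v) {
    a <- array(v$data, dim = d)
    if (identical(sc$velocity_encoding, "phase"))
      a <- a / as.numeric(sc$phase_scale) * venc
    a
  }
  grid <- voxel_grid(d[1:3], vols$magnitude$spacing, vols$magnitude$origin)
  flow4d_dataset(grid,
                 frame_times = as.numeric(sc$frame_times_s),
                 period_T = as.numeric(sc$period_s),
                 magnitude = array(vols$magnitude$data, dim = d),
                 vx = conv(vols$vx), vy = conv(vols$vy), vz = conv(vols$vz),
                 venc = venc)
}

#' Write an image stack
#'
#' `"nifti"` writes a single 3D volume (in-plane spacing and slice gap in
#' the header) plus a JSON sidecar with the plane label, `I_max` and origin,
#' so [read_stack()] can restore the object losslessly.  `"pgm-sequence"`
#' writes one ASCII PGM per slice as a geometry-lossy grayscale preview
#' (write-only; intensities rounded to integers, no spatial metadata).
#'
#' @param stack an [image_stack()]
#' @param path `.nii` file (nifti) or directory (pgm-sequence)
#' @param format `"nifti"` or `"pgm-sequence"`
#' @return `path`, invisibly
#' @export
write_stack <- function(stack, path, format = c("nifti", "pgm-sequence")) {
  stopifnot(inherits(stack, "ImageStack"))
  format <- match.arg(format)
  if (format == "nifti") {
    write_nifti(stack$pixels, path,
                spacing = c(stack$in_plane_spacing, stack$slice_gap),
                origin = stack$origin, datatype = "float32")
    sidecar <- list(plane = stack$plane, slice_gap_mm = stack$slice_gap,
                    in_plane_spacing_mm = stack$in_plane_spacing,
                    origin_mm = stack$origin, I_max = stack$I_max)
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    maxv <- max(1L, as.integer(round(stack$I_max)))
    for (s in seq_len(stack$n_slices)) {
      img <- t(round(stack$pixels[, , s]))
      f <- file.path(path, sprintf("slice_%04d.pgm", s))
      lines <- c("P2", sprintf("%d %d", ncol(img), nrow(img)),
                 as.character(maxv),
                 apply(img, 1, paste, collapse = " "))
      writeLines(lines, f)
    }
  }
  invisible(path)
}

#' Read an image stack written by [write_stack()] (nifti format)
#'
#' @param path the `.nii` file
#' @return an [image_stack()]
#' @export
read_stack <- function(path) {
  v <- read_nifti(path)
  scpath <- paste0(path, ".json")
  if (!file.exists(scpath)) stop("read_stack: missing sidecar json")
  sc <- jsonlite::read_json(scpath, simplifyVector = TRUE)
  image_stack(pmin(pmax(v$data, 0), sc$I_max), sc$plane, sc$slice_gap_mm,
              in_plane_spacing = as.numeric(sc$in_plane_spacing_mm),
              origin = as.numeric(sc$origin_mm), I_max = sc$I_max)
}
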