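#' Gradient table for a diffusion acquisition
#'
#' Bundles b-values and gradient directions, and partitions the volumes into
#' the three shells used throughout: non-diffusion-weighted (`b0`), low
#' b-value (`low`, around 100 s/mm^2, acquired for SNR and perfusion control)
#' and high b-value (`high`, the HARDI shell around 1000 s/mm^2).
#'
#' @param bvals Numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs Numeric `n x 3` matrix of gradient directions.  Directions of
#'   diffusion-weighted volumes are re-normalised to unit length.
#' @return An object of class `gradient_table` with elements `bvals`, `bvecs`
#'   and `shell` (factor with levels `b0`, `low`, `high`).
#' @export
gradient_table <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L) stop("'bvecs' must have 3 columns")
  if (length(bvals) != nrow(bvecs))
    stop("direction count does not match b-value count")
  norms <- sqrt(rowSums(bvecs^2))
  dw <- bvals >= 50
  if (any(dw & norms < 1e-6))
    stop("zero gradient direction for a diffusion-weighted volume")
  bvecs[dw, ] <- bvecs[dw, , drop = FALSE] / norms[dw]
  shell <- factor(ifelse(bvals < 50, "b0", ifelse(bvals < 500, "low", "high")),
                  levels = c("b0", "low", "high"))
  if (sum(shell != "high") == 0L)
    stop("at least one b0 or low-b volume is required for normalisation")
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs, shell = shell),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  tab <- table(x$shell)
  cat(sprintf("gradient table: %d volumes (%d b0, %d low-b, %d high-b)\n",
              length(x$bvals), tab[["b0"]], tab[["low"]], tab[["high"]]))
  invisible(x)
}

#' Read / write FSL-style gradient tables
#'
#' `read_gradients()` reads whitespace-separated `bval` (1 x n) and `bvec`
#' (3 x n) text files; `write_gradients()` writes them in the same dialect.
#'
#' @param bval_path,bvec_path Paths to the text files.
#' @return `read_gradients()` returns a [gradient_table()].
#' @export
read_gradients <- function(bval_path, bvec_path) {
  if (!file.exists(bval_path)) stop("bval file not found: ", bval_path)
  if (!file.exists(bvec_path)) stop("bvec file not found: ", bvec_path)
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- scan(bvec_path, quiet = TRUE)
  if (length(bv) != 3L * length(bvals))
    stop("bvec entry count does not match bval count")
  bvecs <- t(matrix(bv, nrow = 3L, byrow = TRUE))
  gradient_table(bvals, bvecs)
}

#' @rdname read_gradients
#' @param gtab A [gradient_table()].
#' @export
write_gradients <- function(gtab, bval_path, bvec_path) {
  writeLines(paste(format(gtab$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  rows <- apply(t(gtab$bvecs), 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = " "))
  writeLines(rows, bvec_path)
  invisible(NULL)
}

#' Diffusion-weighted volume container
#'
#' @param data 4-D numeric array (x, y, z, volume).
#' @param affine 4 x 4 voxel-to-world (mm) matrix, mapping 0-based voxel
#'   indices of voxel centres to world coordinates.
#' @return An object of class `dwi_volume` with `data`, `affine` and
#'   `voxel_size` (mm, column norms of the affine).
#' @export
dwi_volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 4L) stop("'data' must be a 4-D array")
  affine <- .check_affine(affine)
  structure(list(data = data, affine = affine,
                 voxel_size = .voxel_size(affine)),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DWI volume: %d x %d x %d voxels, %d volumes, voxel size %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$voxel_size, 4), collapse = " x ")))
  invisible(x)
}

#' Binary mask container
#'
#' @param data 3-D logical (or 0/1) array.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3-D array")
  affine <- .check_affine(affine)
  structure(list(data = array(as.logical(data), dim(data)), affine = affine),
            class = "binary_mask")
}

.check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("'affine' must be 4 x 4")
  if (abs(det(affine)) < 1e-12) stop("'affine' must be invertible")
  affine
}

.voxel_size <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

# Grids match when shapes agree and affines agree within tolerance.
.same_grid <- function(affine_a, dim_a, affine_b, dim_b, tol = 1e-4) {
  all(dim_a == dim_b) && max(abs(affine_a - affine_b)) <= tol
}

#' Convert between world (mm) coordinates and voxel indices
#'
#' Voxel centres sit at integer 0-based indices under the affine.  The voxel
#' containing a world point is the nearest-centre voxel; points exactly on a
#' boundary resolve to the higher index.
#'
#' @param points `n x 3` matrix (or length-3 vector) of world coordinates.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @return `world_to_voxel()`: `n x 3` integer matrix of 0-based indices;
#'   `voxel_to_world()`: `n x 3` matrix of world coordinates.
#' @export
world_to_voxel <- function(points, affine) {
  points <- rbind(points)
  x <- t(solve(affine, rbind(t(points), 1)))[, 1:3, drop = FALSE]
  storage.mode(x) <- "double"
  matrix(as.integer(floor(x + 0.5)), ncol = 3L)
}

#' @rdname world_to_voxel
#' @param idx `n x 3` matrix of 0-based voxel indices.
#' @export
voxel_to_world <- function(idx, affine) {
  idx <- rbind(idx)
  t(affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
}

# ---- NIfTI I/O -------------------------------------------------------------

.write_nifti <- function(data, affine, path) {
  hdr <- list(pixdim = c(-1, .voxel_size(affine), rep(1, 8 - 1 - 3)),
              srow_x = affine[1, ], srow_y = affine[2, ], srow_z = affine[3, ],
              sform_code = 2L, qform_code = 0L)
  img <- RNifti::asNifti(data, reference = RNifti::niftiHeader(hdr))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4-D diffusion dataset
#'
#' @param image_path NIfTI file with a 4th (volume) dimension.
#' @param bval_path,bvec_path FSL-dialect gradient table text files.
#' @return A list with elements `volume` (a [dwi_volume()]) and `gradients`
#'   (a [gradient_table()]).
#' @export
read_dwi <- function(image_path, bval_path, bvec_path) {
  if (!file.exists(image_path)) stop("image not found: ", image_path)
  img <- RNifti::readNifti(image_path)
  if (length(dim(img)) != 4L)
    stop("expected a 4-D image, got ", length(dim(img)), " dimensions")
  gtab <- read_gradients(bval_path, bvec_path)
  if (length(gtab$bvals) != dim(img)[4])
    stop("image has ", dim(img)[4], " volumes but gradient table has ",
         length(gtab$bvals))
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  vol <- dwi_volume(array(as.numeric(img), dim(img)), matrix(aff, 4, 4))
  list(volume = vol, gradients = gtab)
}

#' @rdname read_dwi
#' @param vol A [dwi_volume()].
#' @param path Output NIfTI path (`.nii` or `.nii.gz`).
#' @export
write_dwi <- function(vol, path) .write_nifti(vol$data, vol$affine, path)

#' Read / write binary masks as NIfTI
#'
#' @param path NIfTI file path.
#' @return `read_mask()` returns a [binary_mask()]; voxels with intensity
#'   greater than 0.5 are inside.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3-D mask image")
  aff <- matrix(structure(RNifti::xform(img), imagedim = NULL, code = NULL), 4, 4)
  binary_mask(array(img > 0.5, dim(img)), aff)
}

#' @rdname read_mask
#' @param mask A [binary_mask()].
#' @export
write_mask <- function(mask, path)
  .write_nifti(array(as.integer(mask$data), dim(mask$data)), mask$affine, path)

# ---- Resampling ------------------------------------------------------------

#' Resample a diffusion volume to an isotropic grid
#'
#' Trilinear interpolation of every volume onto an isotropic grid covering
#' the same world extent, mirroring the common practice of interpolating the
#' raw data (rather than fitted directions) before tracking.
#'
#' @param vol A [dwi_volume()].
#' @param target_mm Target isotropic voxel size in mm (positive, at most four
#'   times the smallest input voxel dimension).
#' @return A [dwi_volume()] with `voxel_size = rep(target_mm, 3)`.
#' @export
resample_isotropic <- function(vol, target_mm) {
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("'target_mm' must be a positive scalar")
  h <- vol$voxel_size
  if (target_mm > min(h) * 4) stop("'target_mm' exceeds 4x the input voxel size")
  d <- dim(vol$data)[1:3]
  nout <- pmax(1L, as.integer(round(d * h / target_mm)))
  # keep the world position of the grid corner (voxel centres at integer
  # indices, so the corner sits half a voxel before centre 0)
  A <- vol$affine
  Aout <- A
  Aout[1:3, 1:3] <- sweep(A[1:3, 1:3, drop = FALSE], 2L, target_mm / h, "*")
  corner <- A %*% c(-0.5, -0.5, -0.5, 1)
  Aout[1:3, 4] <- corner[1:3] - Aout[1:3, 1:3] %*% rep(-0.5, 3)
  # separable source coordinates: output centre k maps to input coordinate
  # (k + 0.5) * target/h - 0.5 along each axis
  idx <- lapply(1:3, function(ax) {
    x <- (seq_len(nout[ax]) - 0.5) * target_mm / h[ax] - 0.5
    x <- pmin(pmax(x, 0), d[ax] - 1)          # clamp at border centres
    i0 <- pmin(floor(x), d[ax] - 1)
    f <- x - i0
    list(i0 = as.integer(i0) + 1L, i1 = as.integer(pmin(i0 + 1, d[ax] - 1)) + 1L,
         f = f)
  })
  nvol <- dim(vol$data)[4]
  out <- array(0, c(nout, nvol))
  wx <- idx[[1]]; wy <- idx[[2]]; wz <- idx[[3]]
  for (v in seq_len(nvol)) {
    vol3 <- vol$data[, , , v]
    gx0 <- vol3[wx$i0, , , drop = FALSE]; gx1 <- vol3[wx$i1, , , drop = FALSE]
    gx <- gx0 * (1 - wx$f) + gx1 * wx$f
    gy0 <- gx[, wy$i0, , drop = FALSE]; gy1 <- gx[, wy$i1, , drop = FALSE]
    gy <- sweep(gy0, 2L, 1 - wy$f, "*") + sweep(gy1, 2L, wy$f, "*")
    gz0 <- gy[, , wz$i0, drop = FALSE]; gz1 <- gy[, , wz$i1, drop = FALSE]
    out[, , , v] <- sweep(gz0, 3L, 1 - wz$f, "*") + sweep(gz1, 3L, wz$f, "*")
  }
  dwi_volume(out, Aout)
}

# ---- Tractogram file I/O ---------------------------------------------------

#' Write / read streamline files
#'
#' Streamlines are written in world mm.  The format is chosen by extension:
#' TrackVis `.trk` (binary, 1000-byte header, points stored in the TrackVis
#' voxel-mm convention with the voxel-to-world matrix in the header) or
#' MRtrix `.tck` (ASCII header, Float32LE point triplets separated by NaN).
#' Coordinates round-trip to better than 1e-3 mm (float32 storage).
#'
#' @param tract A [tractogram()].
#' @param path Output path ending in `.trk` or `.tck`.
#' @export
write_tractogram <- function(tract, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         trk = .write_trk(tract, path),
         tck = .write_tck(tract, path),
         stop("unknown tractogram extension: .", ext))
  invisible(path)
}

#' @rdname write_tractogram
#' @return `read_tractogram()` returns a [tractogram()].
#' @export
read_tractogram <- function(path) {
  if (!file.exists(path)) stop("tractogram not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         trk = .read_trk(path),
         tck = .read_tck(path),
         stop("unknown tractogram extension: .", ext))
}

.write_trk <- function(tract, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  dims <- tract$dim
  vx <- .voxel_size(tract$affine)
  writeChar("TRACK", con, nchars = 5L, eos = NULL); writeBin(as.raw(0L), con)
  writeBin(as.integer(dims), con, size = 2L, endian = "little")
  writeBin(as.numeric(vx), con, size = 4L, endian = "little")
  writeBin(numeric(3L), con, size = 4L, endian = "little")   # origin
  writeBin(0L, con, size = 2L, endian = "little")            # n_scalars
  writeBin(raw(200L), con)                                   # scalar names
  writeBin(0L, con, size = 2L, endian = "little")            # n_properties
  writeBin(raw(200L), con)                                   # property names
  writeBin(as.numeric(t(tract$affine)), con, size = 4L, endian = "little")
  writeBin(raw(444L), con)                                   # reserved
  writeChar("RAS", con, nchars = 3L, eos = NULL); writeBin(as.raw(0L), con)
  writeBin(raw(4L), con)                                     # pad2
  writeBin(numeric(6L), con, size = 4L, endian = "little")   # orientation
  writeBin(raw(2L), con)                                     # pad1
  writeBin(raw(6L), con)                                     # invert/swap
  writeBin(length(tract$streamlines), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")            # version
  writeBin(1000L, con, size = 4L, endian = "little")         # hdr_size
  inv <- solve(tract$affine)
  for (s in tract$streamlines) {
    p <- s$points
    voxmm <- (t(inv %*% rbind(t(p), 1))[, 1:3, drop = FALSE] + 0.5) %*% diag(vx)
    writeBin(nrow(p), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
  }
}

.read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 5L, useBytes = TRUE)
  if (!identical(magic, "TRACK")) stop("not a TrackVis file: ", path)
  readBin(con, "raw", 1L)
  dims <- readBin(con, "integer", 3L, size = 2L, endian = "little")
  vx <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  readBin(con, "numeric", 3L, size = 4L, endian = "little")
  readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  aff <- matrix(readBin(con, "numeric", 16L, size = 4L, endian = "little"),
                4L, 4L, byrow = TRUE)
  readBin(con, "raw", 444L + 4L + 4L)
  readBin(con, "numeric", 6L, size = 4L, endian = "little")
  readBin(con, "raw", 2L + 6L)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  readBin(con, "integer", 2L, size = 4L, endian = "little")
  streamlines <- vector("list", n)
  for (i in seq_len(n)) {
    np <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    pts <- matrix(readBin(con, "numeric", 3L * np, size = 4L,
                          endian = "little"), ncol = 3L, byrow = TRUE)
    idx <- sweep(pts, 2L, vx, "/") - 0.5
    world <- t(aff %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
    streamlines[[i]] <- streamline(world)
  }
  tractogram(streamlines, affine = aff, dim = dims)
}

.write_tck <- function(tract, path) {
  header <- c("mrtrix tracks", "datatype: Float32LE",
              sprintf("count: %d", length(tract$streamlines)))
  body <- paste0(paste(header, collapse = "\n"), "\n")
  offset_line <- function(off) sprintf("file: . %d\nEND\n", off)
  # the offset counts its own digits; iterate once to stabilise
  off <- nchar(body, type = "bytes") + nchar(offset_line(0), type = "bytes")
  off <- nchar(body, type = "bytes") + nchar(offset_line(off), type = "bytes")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(body, offset_line(off)), con, eos = NULL)
  for (s in tract$streamlines) {
    writeBin(as.numeric(t(s$points)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
}

.read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    ch <- character()
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0L) stop("unterminated TCK header")
      if (b == as.raw(10L)) break
      ch <- c(ch, rawToChar(b))
    }
    line <- paste(ch, collapse = "")
    if (identical(line, "END")) break
    lines <- c(lines, line)
  }
  off_line <- grep("^file: ", lines, value = TRUE)
  off <- as.integer(sub("^file: \\. ", "", off_line))
  seek(con, off)
  vals <- readBin(con, "numeric", file.size(path), size = 4L,
                  endian = "little")
  pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  breaks <- which(apply(pts, 1L, function(r) any(is.nan(r) | is.infinite(r))))
  streamlines <- list()
  start <- 1L
  for (b in breaks) {
    if (b > start)
      streamlines[[length(streamlines) + 1L]] <-
        streamline(pts[start:(b - 1L), , drop = FALSE])
    start <- b + 1L
  }
  tractogram(streamlines, affine = diag(4), dim = c(0L, 0L, 0L))
}
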