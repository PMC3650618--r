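#' Acquisition scheme emulating a single-shell HARDI protocol
#'
#' 64 unique gradient directions at b = 1000 s/mm^2 (an evenly spread subset
#' of folded level-2 icosphere vertices, chosen by a deterministic
#' farthest-point rule), six low-b volumes at b = 100 s/mm^2 and two b = 0
#' volumes.
#'
#' @param b_high,b_low High/low shell b-values (s/mm^2).
#' @param n_high Number of high-b directions (default 64).
#' @return A [gradient_table()] with volumes ordered b0, low, high.
#' @export
hardi_scheme <- function(b_high = 1000, b_low = 100, n_high = 64L) {
  cand <- icosphere(2)$vertices
  cand <- t(apply(cand, 1L, antipodal_fold))
  cand <- unique(round(cand, 12L))
  if (n_high > nrow(cand)) stop("at most ", nrow(cand), " unique directions")
  # greedy farthest-point subset on the projective sphere (axial distance)
  sel <- 1L
  while (length(sel) < n_high) {
    dots <- abs(cand %*% t(cand[sel, , drop = FALSE]))
    mind <- apply(dots, 1L, max)       # larger |dot| = closer
    mind[sel] <- Inf
    sel <- c(sel, which.min(mind))
  }
  high <- cand[sel, , drop = FALSE]
  low <- icosphere(0)$vertices
  low <- unique(round(t(apply(low, 1L, antipodal_fold)), 12L))
  bvals <- c(0, 0, rep(b_low, nrow(low)), rep(b_high, n_high))
  bvecs <- rbind(matrix(0, 2L, 3L), low, high)
  gradient_table(bvals, bvecs)
}

#' Declarative synthetic-phantom description
#'
#' A phantom is a voxel grid containing cylindrical fiber bundles (capsules
#' around polyline centerlines) in an isotropic background, plus named ROIs
#' tied to bundle ends.  Bundle voxels carry an axially symmetric tensor
#' compartment along the local centerline tangent; voxels crossed by several
#' bundles split the signal evenly.
#'
#' @param shape Integer grid dimensions (voxels).
#' @param voxel_mm Isotropic voxel size (mm).
#' @param bundles List of bundles, each `list(centerline = n x 3 matrix (mm),
#'   radius = mm, ad = axial, rd = radial diffusivity (um^2/ms))`.
#' @param rois Named list of ROI definitions:
#'   `list(type = "box", min =, max =)` or
#'   `list(type = "sphere", center =, radius =)` in world mm.
#' @param iso_diffusivity Background isotropic diffusivity (um^2/ms).
#' @param snr Rician signal-to-noise ratio at b0 (`Inf` = noiseless),
#'   defined as `s0 / sigma`.
#' @param s0 Baseline signal intensity.
#' @param seed RNG seed for the noise draw.
#' @param scheme A [gradient_table()]; default [hardi_scheme()].
#' @param p Wishart shape parameter of the forward signal model.
#' @param mask_margin Brain mask extends this far (mm) beyond the bundles.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, voxel_mm = 1, bundles, rois = list(),
                         iso_diffusivity = 0.7, snr = Inf, s0 = 100,
                         seed = 1L, scheme = hardi_scheme(), p = 2,
                         mask_margin = 1) {
  if (length(shape) != 3L || any(shape < 1)) stop("'shape' must be 3 positive integers")
  if (voxel_mm <= 0) stop("'voxel_mm' must be positive")
  if (!is.infinite(snr) && snr <= 0) stop("'snr' must be positive")
  if (iso_diffusivity <= 0) stop("diffusivities must be positive")
  for (b in bundles) {
    if (b$radius < voxel_mm / 2) stop("bundle radius must be >= half a voxel")
    if (b$ad <= 0 || b$rd <= 0) stop("diffusivities must be positive")
  }
  structure(list(shape = as.integer(shape), voxel_mm = voxel_mm,
                 bundles = bundles, rois = rois,
                 iso_diffusivity = iso_diffusivity, snr = snr, s0 = s0,
                 seed = as.integer(seed), scheme = scheme, p = p,
                 mask_margin = mask_margin),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom: %s voxels at %g mm, %d bundle(s), %d ROI(s), SNR %s, seed %d\n",
    paste(x$shape, collapse = " x "), x$voxel_mm, length(x$bundles),
    length(x$rois), ifelse(is.infinite(x$snr), "Inf", format(x$snr)),
    x$seed))
  invisible(x)
}

# distance from points (n x 3) to a polyline, plus tangent of nearest segment
.polyline_distance <- function(pts, line) {
  n <- nrow(pts)
  best <- rep(Inf, n)
  tang <- matrix(0, n, 3L)
  for (i in seq_len(nrow(line) - 1L)) {
    a <- line[i, ]; b <- line[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    tt <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2] +
             (pts[, 3] - a[3]) * ab[3]) / len2
    tt <- pmin(pmax(tt, 0), 1)
    dx <- pts[, 1] - (a[1] + tt * ab[1])
    dy <- pts[, 2] - (a[2] + tt * ab[2])
    dz <- pts[, 3] - (a[3] + tt * ab[3])
    d <- sqrt(dx^2 + dy^2 + dz^2)
    upd <- d < best
    if (any(upd)) {
      best[upd] <- d[upd]
      tang[upd, ] <- matrix(ab / sqrt(len2), sum(upd), 3L, byrow = TRUE)
    }
  }
  list(distance = best, tangent = tang)
}

.roi_mask <- function(roi, centers, shape) {
  inside <- switch(roi$type,
    box = centers[, 1] >= roi$min[1] & centers[, 1] <= roi$max[1] &
          centers[, 2] >= roi$min[2] & centers[, 2] <= roi$max[2] &
          centers[, 3] >= roi$min[3] & centers[, 3] <= roi$max[3],
    sphere = sqrt(rowSums(sweep(centers, 2L, roi$center)^2)) <= roi$radius,
    stop("unknown ROI type: ", roi$type))
  array(inside, shape)
}

#' Simulate a diffusion-weighted dataset from a phantom description
#'
#' Per voxel the normalised forward signal is the even mixture over the
#' compartments present,
#' `S/S0 = sum_c f_c (1 + b g' (D_c / p) g)^(-p)`,
#' the same Wishart attenuation law that the deconvolution inverts.  Rician
#' noise is applied per volume as `sqrt((S + e1)^2 + e2^2)` with
#' `e ~ N(0, (s0/snr)^2)`.  Output is bit-reproducible for a given seed.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` ([dwi_volume()]), `gradients`
#'   ([gradient_table()]), `brain` ([binary_mask()]), `rois` (named list of
#'   [binary_mask()]), and `truth` (per-voxel ground truth: `count` array and
#'   `dirs` array of size `shape x 3 x 2`).
#' @export
simulate_dwi <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("'spec' must be a phantom_spec")
  h <- spec$voxel_mm
  shape <- spec$shape
  affine <- diag(c(h, h, h, 1))
  idx <- as.matrix(expand.grid(x = seq_len(shape[1]) - 1L,
                               y = seq_len(shape[2]) - 1L,
                               z = seq_len(shape[3]) - 1L))
  centers <- idx * h
  nvox <- nrow(centers)
  nb <- length(spec$bundles)
  inside <- matrix(FALSE, nvox, max(nb, 1L))
  tangents <- vector("list", nb)
  in_brain <- rep(nb == 0L, nvox)
  for (k in seq_len(nb)) {
    pd <- .polyline_distance(centers, spec$bundles[[k]]$centerline)
    inside[, k] <- pd$distance <= spec$bundles[[k]]$radius
    tangents[[k]] <- pd$tangent
    in_brain <- in_brain |
      pd$distance <= spec$bundles[[k]]$radius + spec$mask_margin
  }
  counts <- rowSums(inside)
  if (nb > 0 && max(counts) > 2L)
    stop("more than two bundles overlap in a voxel")

  gtab <- spec$scheme
  b <- gtab$bvals
  g <- gtab$bvecs
  nvol <- length(b)
  atten_iso <- (1 + b * spec$iso_diffusivity * 1e-3 / spec$p)^(-spec$p)
  S <- matrix(rep(atten_iso, each = nvox), nvox, nvol)
  for (k in seq_len(nb)) {
    vx <- which(inside[, k])
    if (length(vx) == 0L) next
    ad <- spec$bundles[[k]]$ad * 1e-3
    rd <- spec$bundles[[k]]$rd * 1e-3
    tg <- tangents[[k]][vx, , drop = FALSE]
    # g' D g = rd + (ad - rd) (g . t)^2 for an axially symmetric tensor
    dots2 <- (tg %*% t(g))^2
    q <- rd + (ad - rd) * dots2                       # nvx x nvol
    att <- (1 + sweep(q / spec$p, 2L, b, "*"))^(-spec$p)
    f <- 1 / counts[vx]
    prev <- S[vx, , drop = FALSE]
    first <- inside[vx, seq_len(k - 1L), drop = FALSE]
    fresh <- rowSums(first) == 0L                     # first bundle here?
    S[vx[fresh], ] <- att[fresh, , drop = FALSE] * f[fresh]
    S[vx[!fresh], ] <- prev[!fresh, , drop = FALSE] +
      att[!fresh, , drop = FALSE] * f[!fresh]
  }
  S <- S * spec$s0

  if (!is.infinite(spec$snr)) {
    sigma <- spec$s0 / spec$snr
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(spec$seed)
    e1 <- matrix(rnorm(nvox * nvol, 0, sigma), nvox, nvol)
    e2 <- matrix(rnorm(nvox * nvol, 0, sigma), nvox, nvol)
    S <- sqrt((S + e1)^2 + e2^2)
  }

  data <- array(S, c(shape, nvol))
  brain <- array(in_brain, shape)

  dirs <- array(0, c(shape, 3L, 2L))
  cnt <- array(0L, shape)
  for (k in seq_len(nb)) {
    vx <- which(inside[, k])
    for (v in vx) {
      slot <- cnt[idx[v, 1] + 1L, idx[v, 2] + 1L, idx[v, 3] + 1L] + 1L
      if (slot <= 2L) {
        ijk <- idx[v, ] + 1L
        dirs[ijk[1], ijk[2], ijk[3], , slot] <-
          antipodal_fold(tangents[[k]][v, ])
        cnt[ijk[1], ijk[2], ijk[3]] <- slot
      }
    }
  }
  rois <- lapply(spec$rois, .roi_mask, centers = centers, shape = shape)
  rois <- lapply(rois, binary_mask, affine = affine)
  list(volume = dwi_volume(data, affine), gradients = gtab,
       brain = binary_mask(brain, affine), rois = rois,
       truth = list(count = cnt, dirs = dirs))
}

#' Reference phantom geometries
#'
#' Five small phantoms probing distinct behaviours of the pipeline:
#' \describe{
#'   \item{STRAIGHT}{one straight bundle with ROIs at both ends (basic
#'     propagation and track volume);}
#'   \item{CROSS90}{two orthogonal bundles crossing at the centre (crossing
#'     resolution: two peaks per crossing voxel, streamlines do not jump
#'     bundles);}
#'   \item{BRANCH}{a Y-shaped bundle with a 40 degree fork (branching
#'     systems such as the optic radiations);}
#'   \item{CURVE}{a bundle turning 90 degrees over a 10 mm radius arc
#'     (sharp cumulative turns executed through many small steps);}
#'   \item{DISJOINT}{two parallel, non-touching bundles (ground-truth zero
#'     connectivity; negative control for false positives).}
#' }
#'
#' @param snr Rician SNR applied to every phantom (default noiseless).
#' @param seed Noise seed passed to each [phantom_spec()].
#' @return Named list of [phantom_spec()] objects.
#' @export
standard_phantoms <- function(snr = Inf, seed = 1L) {
  seg <- function(from, to) rbind(from, to)
  fib <- function(centerline, radius = 2, ad = 1.5, rd = 0.4)
    list(centerline = centerline, radius = radius, ad = ad, rd = rd)
  box <- function(min, max) list(type = "box", min = min, max = max)

  straight <- phantom_spec(
    shape = c(18, 9, 9), bundles = list(fib(seg(c(2, 4, 4), c(15, 4, 4)))),
    rois = list(A = box(c(1.5, 1.5, 1.5), c(3.5, 6.5, 6.5)),
                B = box(c(13.5, 1.5, 1.5), c(15.5, 6.5, 6.5))),
    snr = snr, seed = seed)

  cross <- phantom_spec(
    shape = c(24, 24, 9),
    bundles = list(fib(seg(c(1, 11.5, 4), c(22, 11.5, 4))),
                   fib(seg(c(11.5, 1, 4), c(11.5, 22, 4)))),
    rois = list(A1 = box(c(0.5, 8.5, 1.5), c(3.5, 14.5, 6.5)),
                A2 = box(c(19.5, 8.5, 1.5), c(22.5, 14.5, 6.5)),
                B1 = box(c(8.5, 0.5, 1.5), c(14.5, 3.5, 6.5)),
                B2 = box(c(8.5, 19.5, 1.5), c(14.5, 22.5, 6.5))),
    snr = snr, seed = seed)

  # 40 degree fork: branches at +/-20 degrees from the stem axis; each
  # bundle runs stem-to-branch-end so at most two compartments overlap
  dy <- 10 * tan(20 * pi / 180)
  branch <- phantom_spec(
    shape = c(25, 17, 9),
    bundles = list(fib(rbind(c(2, 8, 4), c(12, 8, 4), c(22, 8 + dy, 4))),
                   fib(rbind(c(2, 8, 4), c(12, 8, 4), c(22, 8 - dy, 4)))),
    rois = list(STEM = box(c(1.5, 5.5, 1.5), c(3.5, 10.5, 6.5)),
                A_END = box(c(20, 8 + dy - 2.5, 1.5), c(22.5, 8 + dy + 2.5, 6.5)),
                B_END = box(c(20, 8 - dy - 2.5, 1.5), c(22.5, 8 - dy + 2.5, 6.5))),
    snr = snr, seed = seed)

  # quarter circle of radius 10 mm: tangent rotates 90 degrees in total
  theta <- seq(-pi / 2, 0, length.out = 61L)
  arc <- cbind(3 + 10 * cos(theta), 13 + 10 * sin(theta), 4)
  curve <- phantom_spec(
    shape = c(18, 17, 9), bundles = list(fib(arc)),
    rois = list(A = box(c(1.5, 0.5, 1.5), c(5.5, 4.5, 6.5)),
                B = box(c(10.5, 10.5, 1.5), c(15.5, 14.5, 6.5))),
    snr = snr, seed = seed)

  disjoint <- phantom_spec(
    shape = c(18, 17, 9),
    bundles = list(fib(seg(c(2, 4, 4), c(15, 4, 4))),
                   fib(seg(c(2, 12, 4), c(15, 12, 4)))),
    rois = list(A = box(c(13.5, 1.5, 1.5), c(15.5, 6.5, 6.5)),
                B = box(c(13.5, 9.5, 1.5), c(15.5, 14.5, 6.5))),
    snr = snr, seed = seed)

  list(STRAIGHT = straight, CROSS90 = cross, BRANCH = branch,
       CURVE = curve, DISJOINT = disjoint)
}

#' Write a simulated phantom to disk
#'
#' Writes the DWI volume, FSL-style gradient tables, brain mask, ROI masks
#' and the ground-truth direction count, using the same dialects as the
#' reader functions.
#'
#' @param sim Result of [simulate_dwi()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the named vector of written paths.
#' @export
write_phantom <- function(sim, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, paste0(prefix, ...))
  paths <- c(dwi = p("_dwi.nii.gz"), bval = p(".bval"), bvec = p(".bvec"),
             brain = p("_brain.nii.gz"))
  write_dwi(sim$volume, paths[["dwi"]])
  write_gradients(sim$gradients, paths[["bval"]], paths[["bvec"]])
  write_mask(sim$brain, paths[["brain"]])
  for (nm in names(sim$rois)) {
    path <- p("_roi_", nm, ".nii.gz")
    write_mask(sim$rois[[nm]], path)
    paths[paste0("roi_", nm)] <- path
  }
  invisible(paths)
}
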