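#' Streamline tracking configuration
#'
#' Defaults follow the dense deterministic protocol: 64 equidistant seeds
#' per voxel, 0.25 mm Euler steps, propagation stopped when a step would
#' turn by more than 50 degrees or leave the brain mask.  Fractional
#' anisotropy plays no role anywhere in the stopping logic.
#'
#' @param step Euler step length in mm (0 < step <= 1).
#' @param max_turn Maximum per-step turn in degrees (0 < max_turn < 90).
#' @param seeds_per_voxel Seeds per voxel; must be a perfect cube (the seeds
#'   form a regular sub-voxel lattice).
#' @param max_steps Hard cap on steps per direction (guards against cycles).
#' @param min_points Streamlines with fewer points are discarded.
#' @param seed_mode `"per_peak"` launches one bidirectional streamline per
#'   seed per seed-voxel peak (populates branching systems); `"primary"`
#'   launches only along the strongest peak.
#' @param stop_masks Optional named list of [binary_mask()]; propagation
#'   halts upon entering any of them (stop-at-target tracking).
#' @return An object of class `tracking_config`.
#' @export
tracking_config <- function(step = 0.25, max_turn = 50,
                            seeds_per_voxel = 64L, max_steps = 2000L,
                            min_points = 2L,
                            seed_mode = c("per_peak", "primary"),
                            stop_masks = list()) {
  if (!is.numeric(step) || step <= 0 || step > 1)
    stop("'step' must be in (0, 1] mm")
  if (!is.numeric(max_turn) || max_turn <= 0 || max_turn >= 90)
    stop("'max_turn' must be in (0, 90) degrees")
  cbrt <- round(seeds_per_voxel^(1 / 3))
  if (cbrt^3 != seeds_per_voxel)
    stop("'seeds_per_voxel' must be a perfect cube")
  seed_mode <- match.arg(seed_mode)
  structure(list(step = step, max_turn = max_turn,
                 seeds_per_voxel = as.integer(seeds_per_voxel),
                 seeds_per_axis = as.integer(cbrt),
                 max_steps = as.integer(max_steps),
                 min_points = as.integer(min_points),
                 seed_mode = seed_mode, stop_masks = stop_masks),
            class = "tracking_config")
}

#' @export
print.tracking_config <- function(x, ...) {
  cat(sprintf(
    "tracking config: %.3g mm steps, %g deg turn limit, %d seeds/voxel (%s)\n",
    x$step, x$max_turn, x$seeds_per_voxel, x$seed_mode))
  if (length(x$stop_masks))
    cat("  stop masks:", paste(names(x$stop_masks), collapse = ", "), "\n")
  invisible(x)
}

.term_labels <- c("angle", "brain_boundary", "stop_mask", "max_steps",
                  "no_peak")

#' Single streamline container
#'
#' @param points `n x 3` matrix of ordered world-mm coordinates.
#' @param seed Index of the originating seed (or `NA`).
#' @param term_forward,term_backward Termination reasons, one of
#'   `"angle"`, `"brain_boundary"`, `"stop_mask"`, `"max_steps"`,
#'   `"no_peak"` (or `NA`).
#' @return An object of class `streamline`.
#' @export
streamline <- function(points, seed = NA_integer_,
                       term_forward = NA_character_,
                       term_backward = NA_character_) {
  points <- rbind(points)
  structure(list(points = points, seed = seed,
                 term_forward = term_forward,
                 term_backward = term_backward),
            class = "streamline")
}

#' Tractogram container
#'
#' @param streamlines List of [streamline()] objects.
#' @param affine 4 x 4 voxel-to-world matrix of the tracking grid.
#' @param dim Grid dimensions (voxels).
#' @param config The [tracking_config()] used (optional).
#' @return An object of class `tractogram`.
#' @export
tractogram <- function(streamlines, affine, dim, config = NULL) {
  structure(list(streamlines = streamlines, affine = affine,
                 dim = as.integer(dim), config = config),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  n <- length(x$streamlines)
  cat(sprintf("tractogram: %d streamline(s)\n", n))
  if (n > 0L) {
    np <- vapply(x$streamlines, function(s) nrow(s$points), 0L)
    cat(sprintf("  points per streamline: median %g, range %d-%d\n",
                stats::median(np), min(np), max(np)))
  }
  invisible(x)
}

#' @export
summary.tractogram <- function(object, ...) {
  n <- length(object$streamlines)
  term <- table(factor(
    c(vapply(object$streamlines, function(s) s$term_forward, ""),
      vapply(object$streamlines, function(s) s$term_backward, "")),
    levels = .term_labels))
  len <- vapply(object$streamlines, function(s) {
    p <- s$points
    if (nrow(p) < 2L) return(0)
    sum(sqrt(rowSums((p[-1L, , drop = FALSE] -
                        p[-nrow(p), , drop = FALSE])^2)))
  }, 0)
  out <- list(n = n, terminations = term, length_mm = summary(len))
  class(out) <- "summary.tractogram"
  out
}

#' @export
print.summary.tractogram <- function(x, ...) {
  cat(sprintf("tractogram summary: %d streamline(s)\n", x$n))
  cat("  termination reasons (both ends):\n")
  print(x$terminations)
  cat("  streamline length (mm):\n")
  print(x$length_mm)
  invisible(x)
}

#' @export
plot.tractogram <- function(x, plane = c("xy", "xz", "yz"), col = "#33557788",
                            ...) {
  plane <- match.arg(plane)
  ax <- switch(plane, xy = c(1L, 2L), xz = c(1L, 3L), yz = c(2L, 3L))
  lab <- strsplit(plane, "")[[1]]
  pts <- do.call(rbind, lapply(x$streamlines, function(s) s$points[, ax]))
  if (is.null(pts) || nrow(pts) == 0L) {
    plot(0, 0, type = "n", xlab = lab[1], ylab = lab[2],
         main = "empty tractogram")
    return(invisible(x))
  }
  plot(range(pts[, 1]), range(pts[, 2]), type = "n",
       xlab = paste(lab[1], "(mm)"), ylab = paste(lab[2], "(mm)"),
       asp = 1, ...)
  for (s in x$streamlines) lines(s$points[, ax], col = col)
  invisible(x)
}

#' Uniform sub-voxel seed lattice
#'
#' Places `c^3` seeds per brain voxel on a regular lattice at fractional
#' offsets `(k + 0.5)/c - 0.5` (in voxel coordinates) along each axis, so
#' the global seed field has constant spacing `voxel/c` and is continuous
#' across voxel boundaries.  Seed order is deterministic: voxels in
#' column-major order, offsets in x-fastest order.
#'
#' @param brain A [binary_mask()].
#' @param cfg A [tracking_config()].
#' @return `n x 3` matrix of seed points in world mm.
#' @export
generate_seeds <- function(brain, cfg = tracking_config()) {
  vox <- which(brain$data, arr.ind = TRUE)
  if (nrow(vox) == 0L) return(matrix(0, 0L, 3L))
  cc <- cfg$seeds_per_axis
  off <- (seq_len(cc) - 0.5) / cc - 0.5
  lattice <- as.matrix(expand.grid(x = off, y = off, z = off))
  idx <- vox[rep(seq_len(nrow(vox)), each = nrow(lattice)), , drop = FALSE] -
    1L
  idx <- idx + lattice[rep(seq_len(nrow(lattice)), times = nrow(vox)), ,
                       drop = FALSE]
  voxel_to_world(idx, brain$affine)
}

#' Propagate one streamline from a seed point
#'
#' Bidirectional Euler integration through the peak field: at every step the
#' peak most inline with the direction of travel (largest `|d . m|`, ties
#' by PDF value then rank) is chosen and sign-aligned; propagation stops
#' when the required turn exceeds the limit, the brain mask is left, a stop
#' mask is entered, or a voxel offers no peak.
#'
#' @param seed Length-3 world-mm seed point (must lie in the brain mask, in
#'   a voxel with at least one peak).
#' @param peaks A `peak_field` from [pdf_peaks()].
#' @param brain A [binary_mask()] on the same grid.
#' @param cfg A [tracking_config()].
#' @param init_peak Which seed-voxel peak to launch along (default 1).
#' @return A [streamline()].
#' @export
propagate <- function(seed, peaks, brain, cfg = tracking_config(),
                      init_peak = 1L) {
  .check_track_grid(peaks, brain, cfg)
  ijk <- world_to_voxel(seed, peaks$affine)
  d <- peaks$dim
  if (any(ijk < 0L) || any(ijk >= d) ||
      !brain$data[ijk[1] + 1L, ijk[2] + 1L, ijk[3] + 1L])
    stop("seed lies outside the brain mask")
  if (peaks$npeaks[ijk[1] + 1L, ijk[2] + 1L, ijk[3] + 1L] < init_peak)
    return(streamline(matrix(seed, 1L, 3L), seed = 1L,
                      term_forward = "no_peak", term_backward = "no_peak"))
  res <- .track_seeds(matrix(seed, 1L, 3L), peaks, brain, cfg,
                      per_peak = FALSE, init_peak = init_peak,
                      min_points = 1L)
  res$streamlines[[1L]]
}

#' Whole-volume deterministic tractography
#'
#' Seeds every brain voxel with the configured sub-voxel lattice and
#' propagates a bidirectional streamline per seed (per seed-voxel peak by
#' default).  Streamlines shorter than `cfg$min_points` are discarded.
#' Output order is deterministic.
#'
#' @param peaks A `peak_field` from [pdf_peaks()].
#' @param brain A [binary_mask()] on the same grid.
#' @param cfg A [tracking_config()].
#' @return A [tractogram()].
#' @export
track_whole_brain <- function(peaks, brain, cfg = tracking_config()) {
  .check_track_grid(peaks, brain, cfg)
  seeds <- generate_seeds(brain, cfg)
  if (nrow(seeds) == 0L)
    return(tractogram(list(), peaks$affine, peaks$dim, cfg))
  .track_seeds(seeds, peaks, brain, cfg,
               per_peak = cfg$seed_mode == "per_peak", init_peak = 1L,
               min_points = cfg$min_points)
}

.check_track_grid <- function(peaks, brain, cfg) {
  if (!inherits(peaks, "peak_field")) stop("'peaks' must be a peak_field")
  if (!.same_grid(peaks$affine, peaks$dim, brain$affine, dim(brain$data)))
    stop("brain mask grid does not match the peak field")
  for (m in cfg$stop_masks)
    if (!.same_grid(peaks$affine, peaks$dim, m$affine, dim(m$data)))
      stop("stop mask grid does not match the peak field")
}

.track_seeds <- function(seeds, peaks, brain, cfg, per_peak, init_peak,
                         min_points) {
  k <- peaks$k
  dirs <- peaks$dirs
  if (init_peak > 1L) {
    # reorder so the requested peak is launched first
    ord <- c(init_peak, setdiff(seq_len(k), init_peak))
    dirs <- dirs[, , , , ord, drop = FALSE]
  }
  stops <- lapply(cfg$stop_masks, function(m)
    array(as.integer(m$data), dim(m$data)))
  res <- .cpp_track(dirs, peaks$values,
                    array(as.integer(peaks$npeaks), peaks$dim),
                    array(as.integer(brain$data), dim(brain$data)),
                    stops, solve(peaks$affine), seeds,
                    cfg$step, cfg$max_turn, cfg$max_steps, min_points,
                    per_peak)
  sl <- mapply(function(p, s, tf, tb)
    streamline(p, seed = s, term_forward = .term_labels[tf + 1L],
               term_backward = .term_labels[tb + 1L]),
    res$points, res$seed, res$term_forward, res$term_backward,
    SIMPLIFY = FALSE)
  tractogram(sl, peaks$affine, peaks$dim, cfg)
}
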