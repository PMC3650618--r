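#' Filter streamlines by ROI connectivity
#'
#' Keeps a streamline iff it has at least one point in *every* inclusion
#' mask and no point in *any* exclusion mask.  Points are assigned to voxels
#' by nearest-voxel lookup on the tracking grid; streamline order is
#' preserved, so the operation is idempotent and commutes across exclusion
#' masks.
#'
#' @param tract A [tractogram()].
#' @param include Non-empty (optionally named) list of [binary_mask()];
#'   a streamline must touch all of them.
#' @param exclude Optional list of [binary_mask()]; touching any of them
#'   discards the streamline.
#' @return A [tractogram()] with the retained streamlines.
#' @export
filter_streamlines <- function(tract, include, exclude = list()) {
  if (inherits(include, "binary_mask")) include <- list(include)
  if (inherits(exclude, "binary_mask")) exclude <- list(exclude)
  if (length(include) == 0L) stop("'include' must contain at least one mask")
  if (!is.null(names(include)) && !is.null(names(exclude))) {
    shared <- intersect(names(include), names(exclude))
    if (length(shared))
      stop("masks used for both include and exclude: ",
           paste(shared, collapse = ", "))
  }
  for (m in c(include, exclude))
    if (!.same_grid(m$affine, dim(m$data), tract$affine, tract$dim))
      stop("mask grid does not match the tractogram grid")
  keep <- vapply(tract$streamlines, function(s) {
    idx <- world_to_voxel(s$points, tract$affine)
    inb <- idx[, 1] >= 0L & idx[, 1] < tract$dim[1] &
           idx[, 2] >= 0L & idx[, 2] < tract$dim[2] &
           idx[, 3] >= 0L & idx[, 3] < tract$dim[3]
    if (!any(inb)) return(FALSE)
    lin <- idx[inb, 1] + tract$dim[1] *
      (idx[inb, 2] + tract$dim[2] * idx[inb, 3]) + 1L
    for (m in include) if (!any(m$data[lin])) return(FALSE)
    for (m in exclude) if (any(m$data[lin])) return(FALSE)
    TRUE
  }, logical(1L))
  tractogram(tract$streamlines[keep], tract$affine, tract$dim, tract$config)
}

#' Track volume of a streamline bundle
#'
#' The volume (mm^3) of the set of reference-grid voxels visited by at least
#' one streamline point: a binary visitation map times the voxel volume.
#' Invariant to streamline order and duplication.
#'
#' @param tract A [tractogram()].
#' @return Volume in mm^3 (0 for an empty tractogram).
#' @export
track_volume <- function(tract) {
  if (length(tract$streamlines) == 0L) return(0)
  pts <- do.call(rbind, lapply(tract$streamlines, function(s) s$points))
  idx <- world_to_voxel(pts, tract$affine)
  inb <- idx[, 1] >= 0L & idx[, 1] < tract$dim[1] &
         idx[, 2] >= 0L & idx[, 2] < tract$dim[2] &
         idx[, 3] >= 0L & idx[, 3] < tract$dim[3]
  idx <- idx[inb, , drop = FALSE]
  if (nrow(idx) == 0L) return(0)
  lin <- unique(idx[, 1] + tract$dim[1] *
                  (idx[, 2] + tract$dim[2] * idx[, 3]))
  length(lin) * abs(det(tract$affine[1:3, 1:3]))
}

#' Per-pathway summary of a track-volume table
#'
#' Column means and sample (n - 1) standard deviations of a participants x
#' pathways volume table.  Untraceable pathways enter as zero volumes and
#' are *included* in the averages, matching how group summaries of such
#' tables are conventionally reported.
#'
#' @param table Data frame or matrix of track volumes (mm^3), one row per
#'   participant, one numeric column per pathway.  Non-numeric columns
#'   (e.g. participant IDs) are ignored.
#' @return Data frame with columns `pathway`, `mean`, `sd` (unrounded; the
#'   print method shows one decimal).
#' @export
summarize_volumes <- function(table) {
  tab <- as.data.frame(table)
  num <- vapply(tab, is.numeric, logical(1L))
  ids <- grepl("^(participant|id|subject)$", tolower(names(tab)))
  tab <- tab[, num & !ids, drop = FALSE]
  if (ncol(tab) == 0L) stop("no numeric pathway columns")
  if (nrow(tab) < 2L) stop("at least 2 rows are required for a sd")
  if (any(unlist(tab) < 0)) stop("volumes must be non-negative")
  out <- data.frame(pathway = names(tab),
                    mean = vapply(tab, mean, 0),
                    sd = vapply(tab, stats::sd, 0),
                    row.names = NULL)
  class(out) <- c("volume_summary", "data.frame")
  out
}

#' @export
print.volume_summary <- function(x, ...) {
  y <- x
  y$mean <- round(y$mean, 1L)
  y$sd <- round(y$sd, 1L)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Reference track-volume table
#'
#' A 10-participant table of track volumes (mm^3) for the four pathways
#' connecting the two inferior-frontal cortical subdivisions (pars
#' triangularis, pars opercularis) with the putamen and the thalamus.
#' Zeros mark pathways that could not be traced in a participant.  Ships as
#' plain CSV in `inst/extdata/`; used as the worked example for
#' [summarize_volumes()].
#'
#' @return Data frame with a `participant` column and four pathway columns.
#' @export
example_track_volumes <- function() {
  path <- system.file("extdata", "broca_track_volumes.csv",
                      package = "mowtract")
  if (path == "")  # not installed: fall back to source tree layout
    path <- file.path("inst", "extdata", "broca_track_volumes.csv")
  utils::read.csv(path)
}
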