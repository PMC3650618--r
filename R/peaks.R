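#' Extract local maxima of a sphere-sampled PDF
#'
#' Multi-start discrete gradient ascent on the level-3 icosphere vertex
#' graph.  Each of the 42 level-1 vertices (which are also the first 42
#' level-3 vertices) seeds a hill climb that repeatedly moves to the
#' neighbouring vertex with the greatest PDF value while that value exceeds
#' the current one (ties go to the lower vertex index, for determinism).
#' Terminal vertices are folded to the canonical hemisphere, deduplicated
#' within an angular tolerance, sorted by PDF value and truncated.
#'
#' @param pdf Numeric vector of 642 PDF values on the vertices of `tess3`.
#' @param tess3 A level-3 [icosphere()].
#' @param k Maximum number of peaks to keep (default 3).
#' @param dedup Angular tolerance in degrees below which two folded maxima
#'   are duplicates (default 15; the level-3 grid spacing is about 8
#'   degrees, so closer fiber populations are unresolvable anyway).
#' @param iso_ratio Optional peak-to-mean ratio below which the voxel is
#'   declared isotropic (e.g. 1.02); `NULL` (default) disables the filter.
#'   A numerically constant PDF is always declared isotropic.
#' @param starts Integer vertex indices used as ascent starts.
#' @return An object of class `peak_set`: list with `directions` (m x 3,
#'   canonical hemisphere), `values` (descending), and `isotropic` flag.
#'   Isotropic voxels have zero rows.
#' @export
find_maxima <- function(pdf, tess3, k = 3L, dedup = 15, iso_ratio = NULL,
                        starts = 1:42) {
  if (length(pdf) != nrow(tess3$vertices))
    stop("'pdf' length must match the tessellation")
  empty <- structure(list(directions = matrix(0, 0L, 3L), values = numeric(),
                          isotropic = TRUE), class = "peak_set")
  if (max(pdf) - min(pdf) < 1e-12) return(empty)
  if (!is.null(iso_ratio) && max(pdf) / mean(pdf) < iso_ratio) return(empty)

  nb <- .neighbor_matrix(tess3)
  nbv <- matrix(pdf[nb], nrow(nb), ncol(nb))
  best_col <- max.col(nbv, ties.method = "first")  # columns sorted by index
  best_val <- nbv[cbind(seq_len(nrow(nb)), best_col)]
  nxt <- ifelse(best_val > pdf, nb[cbind(seq_len(nrow(nb)), best_col)],
                seq_along(pdf))
  cur <- starts
  for (i in seq_len(length(pdf))) {            # strict ascent: must terminate
    stepped <- nxt[cur]
    if (all(stepped == cur)) break
    cur <- stepped
  }
  term <- sort(unique(cur))
  vals <- pdf[term]
  ord <- order(-vals, term)
  term <- term[ord]; vals <- vals[ord]
  dirs <- t(apply(tess3$vertices[term, , drop = FALSE], 1L, antipodal_fold))
  keep <- integer()
  for (i in seq_along(term)) {
    dup <- FALSE
    for (j in keep) {
      a <- angle_between(dirs[i, ], dirs[j, ])
      if (min(a, 180 - a) < dedup) { dup <- TRUE; break }
    }
    if (!dup) keep <- c(keep, i)
    if (length(keep) >= k) break
  }
  structure(list(directions = dirs[keep, , drop = FALSE],
                 values = vals[keep], isotropic = FALSE),
            class = "peak_set")
}

# padded neighbour matrix (self-padded so pads never win an ascent step);
# cached on the tessellation object via an attribute-free memo environment
.nb_cache <- new.env(parent = emptyenv())
.neighbor_matrix <- function(tess) {
  key <- as.character(tess$level)
  m <- .nb_cache[[key]]
  if (!is.null(m)) return(m)
  deg <- lengths(tess$neighbors)
  m <- matrix(0L, length(deg), max(deg))
  for (i in seq_along(deg))
    m[i, ] <- c(tess$neighbors[[i]], rep(i, max(deg) - deg[i]))
  .nb_cache[[key]] <- m
  m
}

#' @export
print.peak_set <- function(x, ...) {
  if (x$isotropic) {
    cat("peak set: isotropic voxel (no preferred direction)\n")
  } else {
    cat(sprintf("peak set: %d direction(s)\n", nrow(x$directions)))
    for (i in seq_len(nrow(x$directions)))
      cat(sprintf("  [%d] (%+.3f, %+.3f, %+.3f)  value %.4g\n", i,
                  x$directions[i, 1], x$directions[i, 2],
                  x$directions[i, 3], x$values[i]))
  }
  invisible(x)
}

#' Per-voxel peak directions for a whole fitted volume
#'
#' Evaluates the displacement PDF of every fitted voxel and extracts its
#' maxima, producing the direction field that the tracker consumes.
#'
#' @param fit A [mow_fit()].
#' @param cfg A [pdf_config()].
#' @param k,dedup,iso_ratio Passed to [find_maxima()].
#' @param verbose Print progress every 500 voxels.
#' @return An object of class `peak_field`: arrays `dirs`
#'   (`dim x 3 x k`), `values` (`dim x k`), `npeaks` (`dim`), plus the grid
#'   geometry (`affine`, `dim`) and the parameters used.
#' @export
pdf_peaks <- function(fit, cfg = pdf_config(), k = 3L, dedup = 15,
                      iso_ratio = NULL, verbose = FALSE) {
  if (!inherits(fit, "mow_fit")) stop("'fit' must be a mow_fit")
  K <- pdf_kernel(fit$basis, cfg)
  tess3 <- cfg$tess
  d <- fit$dim
  dirs <- array(0, c(d, 3L, k))
  values <- array(0, c(d, k))
  npk <- array(0L, d)
  n <- nrow(fit$weights)
  for (i in seq_len(n)) {
    if (fit$flagged[i]) next
    pdf <- drop(K %*% fit$weights[i, ])
    ps <- find_maxima(pdf, tess3, k = k, dedup = dedup,
                      iso_ratio = iso_ratio)
    m <- nrow(ps$directions)
    ijk <- fit$voxels[i, ] + 1L
    npk[ijk[1], ijk[2], ijk[3]] <- m
    if (m > 0L) {
      dirs[ijk[1], ijk[2], ijk[3], , seq_len(m)] <- t(ps$directions)
      values[ijk[1], ijk[2], ijk[3], seq_len(m)] <- ps$values
    }
    if (verbose && i %% 500L == 0L)
      message(sprintf("peaks for %d / %d voxels", i, n))
  }
  structure(list(dirs = dirs, values = values, npeaks = npk, k = k,
                 dedup = dedup, affine = fit$affine, dim = d),
            class = "peak_field")
}

#' @export
print.peak_field <- function(x, ...) {
  cat(sprintf("peak field: %s voxels, up to %d peaks\n",
              paste(x$dim, collapse = " x "), x$k))
  cat("  voxels by peak count:\n")
  print(table(x$npeaks))
  invisible(x)
}

#' Save / load a peak field as 4-D NIfTI
#'
#' The 4th dimension holds `3k` direction components followed by the `k`
#' PDF values, so tracking can be re-run without re-fitting.
#'
#' @param pf A `peak_field`.
#' @param path NIfTI output path.
#' @export
write_peaks <- function(pf, path) {
  k <- pf$k
  d <- pf$dim
  out <- array(0, c(d, 4L * k))
  for (j in seq_len(k)) {
    out[, , , (3L * (j - 1L) + 1L):(3L * j)] <- pf$dirs[, , , , j]
    out[, , , 3L * k + j] <- pf$values[, , , j]
  }
  .write_nifti(out, pf$affine, path)
}

#' @rdname write_peaks
#' @return `read_peaks()` returns a `peak_field`.
#' @export
read_peaks <- function(path) {
  img <- RNifti::readNifti(path)
  n4 <- dim(img)[4]
  if (n4 %% 4L != 0L) stop("not a peak-field file (4th dim not 4k)")
  k <- n4 %/% 4L
  d <- dim(img)[1:3]
  aff <- matrix(structure(RNifti::xform(img), imagedim = NULL, code = NULL), 4, 4)
  arr <- array(as.numeric(img), dim(img))
  dirs <- array(0, c(d, 3L, k))
  values <- array(0, c(d, k))
  for (j in seq_len(k)) {
    dirs[, , , , j] <- arr[, , , (3L * (j - 1L) + 1L):(3L * j)]
    values[, , , j] <- arr[, , , 3L * k + j]
  }
  npk <- apply(values > 0, 1:3, sum)
  structure(list(dirs = dirs, values = values, npeaks = npk, k = k,
                 dedup = NA_real_, affine = aff, dim = d),
            class = "peak_field")
}
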