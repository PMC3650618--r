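#' Icosphere tessellation of the unit sphere
#'
#' Recursively subdivides a regular icosahedron and re-projects new vertices
#' onto the unit sphere.  Levels 0--3 give 12, 42, 162 and 642 vertices; these
#' are the point sets used throughout the pipeline (42 gradient-ascent starts,
#' 162 Wishart basis directions, 642 displacement-PDF evaluation points).
#'
#' Each subdivision splits every triangular face into four by edge midpoints,
#' so the vertex set of level `k` is contained (bitwise identically) in the
#' vertex set of level `k + 1`, and the whole set is closed under negation.
#'
#' @param level Non-negative integer subdivision depth (at most 4).
#' @return An object of class `icosphere` with components:
#'   \describe{
#'     \item{level}{the subdivision depth;}
#'     \item{vertices}{an `n x 3` matrix of unit vectors;}
#'     \item{faces}{an `m x 3` integer matrix of triangle vertex indices;}
#'     \item{neighbors}{a list of integer vectors, the edge-connected
#'       neighbours of each vertex.}
#'   }
#' @examples
#' tess <- icosphere(1)
#' nrow(tess$vertices)  # 42
#' @export
icosphere <- function(level) {
  if (length(level) != 1L || !is.finite(level) || level != round(level))
    stop("'level' must be a single integer")
  if (level < 0L) stop("'level' must be non-negative")
  if (level > 4L) stop("'level' must be at most 4")
  level <- as.integer(level)

  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))

  if (level > 0L) {
    for (i in seq_len(level)) {
      sub <- .subdivide(v, f)
      v <- sub$vertices
      f <- sub$faces
    }
  }
  neighbors <- .face_adjacency(f, nrow(v))
  structure(list(level = level, vertices = v, faces = f,
                 neighbors = neighbors),
            class = "icosphere")
}

# One midpoint subdivision pass.  Midpoints are deduplicated by their
# (sorted) parent edge, so no coordinate rounding is involved and the
# parent vertices keep their indices.
.subdivide <- function(v, f) {
  cache <- new.env(parent = emptyenv())
  verts <- vector("list", nrow(f) * 3L)
  nv <- nrow(v)
  midpoint <- function(a, b) {
    key <- paste(min(a, b), max(a, b), sep = "_")
    idx <- cache[[key]]
    if (!is.null(idx)) return(idx)
    m <- (v[a, ] + v[b, ]) / 2
    m <- m / sqrt(sum(m^2))
    nv <<- nv + 1L
    verts[[nv - nrow(v)]] <<- m
    cache[[key]] <- nv
    nv
  }
  newf <- matrix(0L, nrow(f) * 4L, 3L)
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1L]; b <- f[i, 2L]; c <- f[i, 3L]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    newf[4L * i - 3L, ] <- c(a, ab, ca)
    newf[4L * i - 2L, ] <- c(b, bc, ab)
    newf[4L * i - 1L, ] <- c(c, ca, bc)
    newf[4L * i, ]      <- c(ab, bc, ca)
  }
  list(vertices = rbind(v, do.call(rbind, verts[seq_len(nv - nrow(v))])),
       faces = newf)
}

.face_adjacency <- function(f, n) {
  edges <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  edges <- rbind(edges, edges[, 2:1])
  lapply(seq_len(n), function(i) sort(unique(edges[edges[, 1L] == i, 2L])))
}

#' @export
print.icosphere <- function(x, ...) {
  cat(sprintf("icosphere tessellation: level %d, %d vertices, %d faces\n",
              x$level, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Angle between two unit vectors
#'
#' @param u,v Unit 3-vectors (checked to within 1e-6).
#' @return The angle in degrees, in `[0, 180]`.
#' @examples
#' angle_between(c(1, 0, 0), c(0, 1, 0))  # 90
#' @export
angle_between <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) stop("zero-norm input")
  if (abs(nu - 1) > 1e-6 || abs(nv - 1) > 1e-6)
    stop("inputs must be unit vectors")
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Fold a direction into the canonical hemisphere
#'
#' Fiber orientations are axes, not signed vectors: `u` and `-u` describe the
#' same fiber population.  This folds a unit vector to the representative
#' whose last nonzero coordinate is positive, which is total, deterministic
#' and idempotent.
#'
#' @param u A unit 3-vector.
#' @return `u` or `-u`, in the canonical hemisphere.
#' @examples
#' antipodal_fold(c(0, 0, -1))  # c(0, 0, 1)
#' @export
antipodal_fold <- function(u) {
  nz <- which(u != 0)
  if (length(nz) == 0L) stop("zero vector cannot be folded")
  if (u[nz[length(nz)]] < 0) -u else u
}
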