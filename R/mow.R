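#' Wishart basis dictionary for spherical deconvolution
#'
#' Builds the dictionary of reference diffusion tensors used by the
#' mixture-of-Wisharts signal model.  Each atom is a symmetric
#' positive-definite tensor with the prototypical single-fiber eigenvalues
#' (default 1.5, 0.4, 0.4 um^2/ms) whose principal eigenvector is one of the
#' 162 vertices of a level-2 icosphere, so the dictionary covers orientation
#' space evenly.  The atoms are the *expected* tensors `p * Sigma` of Wishart
#' distributions with shape parameter `p`, which keeps the stated eigenvalues
#' interpretable as a typical fiber tensor.
#'
#' @param tess A level-2 [icosphere()] (162 vertices).
#' @param eigenvalues Length-3 positive eigenvalues in um^2/ms, largest
#'   first; the second and third belong to the minor axes.
#' @param p Wishart shape parameter (>= 1, dimensionless).
#' @return An object of class `wishart_basis` with elements `dirs`
#'   (162 x 3), `eigenvalues`, `p` and `tensors` (3 x 3 x 162 array in
#'   mm^2/s).
#' @export
wishart_basis <- function(tess = icosphere(2), eigenvalues = c(1.5, 0.4, 0.4),
                          p = 2) {
  if (!inherits(tess, "icosphere") || nrow(tess$vertices) != 162L)
    stop("'tess' must be a level-2 icosphere (162 vertices)")
  if (length(eigenvalues) != 3L || any(eigenvalues <= 0))
    stop("'eigenvalues' must be 3 positive values")
  if (p < 1) stop("'p' must be at least 1")
  ev_mm <- eigenvalues * 1e-3              # um^2/ms -> mm^2/s
  dirs <- tess$vertices
  n <- nrow(dirs)
  tensors <- array(0, c(3L, 3L, n))
  for (j in seq_len(n)) {
    v <- dirs[j, ]
    # deterministic minor frame: the least-aligned coordinate axis seeds e2
    a <- diag(3)[, which.min(abs(v))]
    e2 <- a - sum(a * v) * v; e2 <- e2 / sqrt(sum(e2^2))
    e3 <- c(v[2] * e2[3] - v[3] * e2[2],
            v[3] * e2[1] - v[1] * e2[3],
            v[1] * e2[2] - v[2] * e2[1])
    tensors[, , j] <- ev_mm[1] * tcrossprod(v) + ev_mm[2] * tcrossprod(e2) +
      ev_mm[3] * tcrossprod(e3)
  }
  structure(list(dirs = dirs, eigenvalues = eigenvalues, p = p,
                 tensors = tensors),
            class = "wishart_basis")
}

#' @export
print.wishart_basis <- function(x, ...) {
  cat(sprintf(
    "Wishart basis: %d atoms, eigenvalues (%s) um^2/ms, shape p = %g\n",
    nrow(x$dirs), paste(x$eigenvalues, collapse = ", "), x$p))
  invisible(x)
}

#' Design matrix of the Wishart deconvolution
#'
#' The Laplace-transform signal model of a Wishart tensor distribution gives
#' the closed-form attenuation `(1 + b g' (D/p) g)^(-p)` per atom, so the
#' normalised signal is linear in the mixture weights.  Rows are the
#' diffusion-weighted volumes (b0 volumes are the normaliser and are
#' excluded); columns are the 162 atoms.
#'
#' @param gtab A [gradient_table()].
#' @param basis A [wishart_basis()].
#' @return Matrix of size `sum(b > 0)` x 162 with entries in `(0, 1]`, with
#'   attribute `rows` giving the volume indices used.
#' @export
design_matrix <- function(gtab, basis) {
  rows <- which(gtab$shell != "b0")
  b <- gtab$bvals[rows]
  g <- gtab$bvecs[rows, , drop = FALSE]
  n <- dim(basis$tensors)[3]
  A <- matrix(0, length(rows), n)
  for (j in seq_len(n)) {
    q <- rowSums((g %*% basis$tensors[, , j]) * g)   # g' D g
    A[, j] <- (1 + b * q / basis$p)^(-basis$p)
  }
  attr(A, "rows") <- rows
  A
}

#' Non-negative least-squares weights for one voxel
#'
#' Solves `min || A w - s ||` subject to `w >= 0` (Lawson--Hanson active
#' set, via [pracma::lsqnonneg()]).  Non-finite signals yield a flagged
#' all-zero weight vector rather than an error; negative normalised values
#' are clipped to zero.
#'
#' @param signal Normalised signal vector (same length as `nrow(A)`).
#' @param A Design matrix from [design_matrix()].
#' @return Numeric weight vector (length `ncol(A)`) with attributes `flagged`
#'   (logical) and `clipped` (number of clipped entries).
#' @export
fit_weights <- function(signal, A) {
  if (any(!is.finite(signal)) || all(signal == 0)) {
    w <- numeric(ncol(A))
    attr(w, "flagged") <- TRUE
    attr(w, "clipped") <- 0L
    return(w)
  }
  clipped <- sum(signal < 0)
  signal <- pmax(signal, 0)
  w <- pracma::lsqnonneg(A, signal)$x
  attr(w, "flagged") <- FALSE
  attr(w, "clipped") <- clipped
  w
}

#' Displacement-PDF evaluation settings
#'
#' The fitted Wishart mixture implies a displacement probability density that
#' is a mixture of zero-mean Gaussians; it is probed on a sphere of radius
#' `r` at the effective diffusion time `t = Delta - delta/3`.  Peak
#' *locations* are insensitive to `r` and `t` for a fixed-eigenvalue basis,
#' so these defaults matter only for absolute density values.
#'
#' @param t Effective diffusion time in ms (default 20).
#' @param r Displacement probe radius in um (default 12).
#' @param tess A level-3 [icosphere()]; its 642 vertices are the evaluation
#'   directions.
#' @return An object of class `pdf_config`.
#' @export
pdf_config <- function(t = 20, r = 12, tess = icosphere(3)) {
  if (!is.numeric(t) || t <= 0) stop("'t' must be positive")
  if (!is.numeric(r) || r <= 0) stop("'r' must be positive")
  if (!inherits(tess, "icosphere") || nrow(tess$vertices) != 642L)
    stop("'tess' must be a level-3 icosphere (642 vertices)")
  structure(list(t = t, r = r, tess = tess), class = "pdf_config")
}

#' Kernel mapping mixture weights to PDF values
#'
#' Precomputes the 642 x 162 matrix `K` with
#' `K[k, j] = (4 pi t)^(-3/2) |D_j|^(-1/2) exp(-r^2 u_k' D_j^{-1} u_k / (4t))`
#' (r in mm, D in mm^2/s, t in s) so that a voxel's PDF on the sphere is the
#' single matrix product `K %*% w`.
#'
#' @param basis A [wishart_basis()].
#' @param cfg A [pdf_config()].
#' @return The kernel matrix, with the configuration attached as attributes.
#' @export
pdf_kernel <- function(basis, cfg = pdf_config()) {
  t_s <- cfg$t * 1e-3
  r_mm <- cfg$r * 1e-3
  U <- cfg$tess$vertices
  n <- dim(basis$tensors)[3]
  K <- matrix(0, nrow(U), n)
  for (j in seq_len(n)) {
    D <- basis$tensors[, , j]
    Dinv <- solve(D)
    q <- rowSums((U %*% Dinv) * U)
    K[, j] <- (4 * pi * t_s)^(-1.5) / sqrt(det(D)) *
      exp(-r_mm^2 * q / (4 * t_s))
  }
  attr(K, "cfg") <- cfg
  K
}

#' Evaluate the displacement PDF of one voxel
#'
#' @param w Non-negative weight vector (length 162).
#' @param basis A [wishart_basis()].
#' @param cfg A [pdf_config()].
#' @param kernel Optional precomputed [pdf_kernel()] (recomputed otherwise).
#' @return Numeric vector of 642 non-negative density values, one per vertex
#'   of the evaluation tessellation.
#' @export
evaluate_pdf <- function(w, basis, cfg = pdf_config(), kernel = NULL) {
  if (any(w < 0)) stop("weights must be non-negative")
  if (is.null(kernel)) kernel <- pdf_kernel(basis, cfg)
  drop(kernel %*% w)
}

# ---- whole-volume model fit ------------------------------------------------

#' Fit the mixture-of-Wisharts model to a diffusion volume
#'
#' The central fitting routine.  For every voxel inside the brain mask the
#' signal is normalised by the mean b0 intensity and deconvolved against the
#' Wishart dictionary by non-negative least squares, yielding a sparse vector
#' of 162 orientation weights per voxel.
#'
#' @param vol A [dwi_volume()].
#' @param gtab The matching [gradient_table()].
#' @param mask Optional [binary_mask()] restricting the fit (default: all
#'   voxels with positive mean b0 signal).
#' @param basis A [wishart_basis()].
#' @param verbose Print progress every 500 voxels.
#' @return An object of class `mow_fit` with the per-voxel weight matrix
#'   (`weights`, voxels x 162), the voxel index map (`voxels`, n x 3,
#'   0-based), fit diagnostics, and the grid geometry needed downstream.
#'   Supports `print()`, `summary()`, `coef()`, `fitted()`, `residuals()`
#'   and `predict()` (normalised signal or sphere PDF).
#' @export
mow_fit <- function(vol, gtab, mask = NULL, basis = wishart_basis(),
                    verbose = FALSE) {
  if (!inherits(vol, "dwi_volume")) stop("'vol' must be a dwi_volume")
  if (dim(vol$data)[4] != length(gtab$bvals))
    stop("volume count does not match the gradient table")
  d <- dim(vol$data)[1:3]
  b0 <- which(gtab$shell == "b0")
  if (length(b0) == 0L) b0 <- which(gtab$shell == "low")
  s0 <- apply(vol$data[, , , b0, drop = FALSE], 1:3, mean)
  if (is.null(mask)) {
    mask_arr <- s0 > 0
  } else {
    if (!.same_grid(mask$affine, dim(mask$data), vol$affine, d))
      stop("mask grid does not match the volume grid")
    mask_arr <- mask$data
  }
  A <- design_matrix(gtab, basis)
  rows <- attr(A, "rows")
  vox <- which(mask_arr, arr.ind = TRUE)
  n <- nrow(vox)
  W <- matrix(0, n, ncol(A))
  S <- matrix(NA_real_, n, nrow(A))
  flagged <- logical(n)
  clipped <- 0L
  rss <- numeric(n)
  for (i in seq_len(n)) {
    s <- vol$data[vox[i, 1], vox[i, 2], vox[i, 3], rows]
    s0i <- s0[vox[i, 1], vox[i, 2], vox[i, 3]]
    s <- if (s0i > 0) s / s0i else rep(NA_real_, length(s))
    w <- fit_weights(s, A)
    W[i, ] <- w
    flagged[i] <- attr(w, "flagged")
    clipped <- clipped + attr(w, "clipped")
    if (!flagged[i]) {
      S[i, ] <- pmax(s, 0)
      rss[i] <- sum((A %*% w - S[i, ])^2)
    } else rss[i] <- NA_real_
    if (verbose && i %% 500L == 0L)
      message(sprintf("fitted %d / %d voxels", i, n))
  }
  if (clipped > 0L)
    warning(clipped, " negative normalised signal values clipped to zero")
  structure(list(weights = W, voxels = unname(vox) - 1L, flagged = flagged,
                 signal = S, rss = rss, n_clipped = clipped, basis = basis,
                 gtab = gtab, design = A, dim = d, affine = vol$affine,
                 mask = mask_arr, call = match.call()),
            class = "mow_fit")
}

#' @export
print.mow_fit <- function(x, ...) {
  cat("Mixture-of-Wisharts deconvolution fit\n")
  cat(sprintf("  grid: %s voxels (%d fitted, %d flagged)\n",
              paste(x$dim, collapse = " x "), nrow(x$weights),
              sum(x$flagged)))
  cat(sprintf("  dictionary: %d atoms, p = %g\n", ncol(x$weights),
              x$basis$p))
  invisible(x)
}

#' @export
summary.mow_fit <- function(object, ...) {
  ok <- !object$flagged
  nz <- rowSums(object$weights[ok, , drop = FALSE] > 0)
  out <- list(
    n_voxels = nrow(object$weights),
    n_flagged = sum(object$flagged),
    n_clipped = object$n_clipped,
    sparsity = summary(nz),
    rmse = sqrt(mean(object$rss[ok]) / nrow(object$design)))
  class(out) <- "summary.mow_fit"
  out
}

#' @export
print.summary.mow_fit <- function(x, ...) {
  cat("Mixture-of-Wisharts fit summary\n")
  cat(sprintf("  voxels fitted: %d (%d flagged degenerate)\n",
              x$n_voxels, x$n_flagged))
  cat(sprintf("  clipped negative signal values: %d\n", x$n_clipped))
  cat(sprintf("  per-voxel RMSE of normalised signal: %.4g\n", x$rmse))
  cat("  active atoms per voxel:\n")
  print(x$sparsity)
  invisible(x)
}

#' @export
coef.mow_fit <- function(object, ...) object$weights

#' @export
fitted.mow_fit <- function(object, ...)
  object$weights %*% t(object$design)

#' @export
residuals.mow_fit <- function(object, ...) {
  if (is.null(object$signal))
    stop("this fit object carries no signal (reloaded from disk?)")
  object$signal - fitted(object)
}

#' Predict from a mixture-of-Wisharts fit
#'
#' @param object A [mow_fit()].
#' @param type `"signal"` for the fitted normalised attenuation (voxels x
#'   diffusion-weighted volumes) or `"pdf"` for the displacement PDF sampled
#'   on the 642-point sphere (voxels x 642).
#' @param cfg A [pdf_config()] (used for `type = "pdf"`).
#' @param ... Unused.
#' @export
predict.mow_fit <- function(object, type = c("signal", "pdf"),
                            cfg = pdf_config(), ...) {
  type <- match.arg(type)
  if (type == "signal") return(fitted(object))
  K <- pdf_kernel(object$basis, cfg)
  object$weights %*% t(K)
}
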