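# Shared, lazily built fixtures.  The expensive per-phantom fits are reused
# across test files; everything is deterministic (noise seeds are fixed in
# the phantom specs).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(build)()
  .fixtures[[name]]
}

# simulate + fit + peaks for one of the standard phantoms
phantom_pipeline <- function(name, snr = Inf, mask = NULL) {
  key <- paste0(name, "_snr", snr)
  fixture(key, function() {
    sim <- simulate_dwi(standard_phantoms(snr = snr, seed = 7L)[[name]])
    fit_mask <- if (is.null(mask)) sim$brain else mask
    fit <- mow_fit(sim$volume, sim$gradients, fit_mask)
    peaks <- pdf_peaks(fit)
    list(sim = sim, fit = fit, peaks = peaks)
  })
}

# oblique single-fiber bundle (axis not on any icosphere vertex), fitted on
# the bundle voxels only; used for orientation-recovery scoring
oblique_bundle <- function(snr = Inf) {
  key <- paste0("oblique_snr", snr)
  fixture(key, function() {
    d <- c(2, 1, 0.5); d <- d / sqrt(sum(d^2))
    spec <- phantom_spec(
      shape = c(26, 16, 12),
      bundles = list(list(centerline = rbind(c(2, 3, 3), c(2, 3, 3) + 20 * d),
                          radius = 3, ad = 1.5, rd = 0.4)),
      snr = snr, seed = 11L)
    sim <- simulate_dwi(spec)
    bundle <- binary_mask(sim$truth$count >= 1L, sim$volume$affine)
    fit <- mow_fit(sim$volume, sim$gradients, bundle)
    peaks <- pdf_peaks(fit)
    list(sim = sim, fit = fit, peaks = peaks, bundle = bundle, axis = d)
  })
}

# angular error between two axes (antipodally symmetric), degrees
axis_angle <- function(u, v) {
  a <- angle_between(u, v)
  min(a, 180 - a)
}

# per-voxel top-peak angular error against the stored ground truth
peak_errors <- function(peaks, truth, voxels) {
  apply(voxels, 1L, function(ijk) {
    p <- peaks$dirs[ijk[1], ijk[2], ijk[3], , 1]
    if (sum(p^2) == 0) return(NA_real_)
    axis_angle(p, truth$dirs[ijk[1], ijk[2], ijk[3], , 1])
  })
}

# random sparse Wishart-mixture weight vectors (spiky + heavier tail)
random_mixture_weights <- function(n_atoms, rng) {
  w <- numeric(n_atoms)
  k <- sample(1:3, 1L)
  w[sample.int(n_atoms, k)] <- runif(k, 0.5, 2)
  w + runif(n_atoms, 0, 0.02)
}

# exact mean of a Rician(nu, sigma) magnitude:
# E[M] = sigma sqrt(pi/2) exp(-x/2) [(1+x) I0(x/2) + x I1(x/2)], x = nu^2/(2 sigma^2);
# scaled Bessels absorb the exp(-x/2) factor without overflow
rician_mean <- function(nu, sigma) {
  x <- nu^2 / (2 * sigma^2)
  sigma * sqrt(pi / 2) * ((1 + x) * besselI(x / 2, 0, expon.scaled = TRUE) +
                            x * besselI(x / 2, 1, expon.scaled = TRUE))
}

# brute-force NNLS by support enumeration (oracle for small dictionaries)
nnls_enumerate <- function(A, s) {
  p <- ncol(A)
  best <- list(rss = sum(s^2), w = numeric(p))   # empty support
  for (mask in seq_len(2^p - 1L)) {
    sup <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0L)
    ws <- tryCatch(qr.solve(A[, sup, drop = FALSE], s),
                   error = function(e) NULL)
    if (is.null(ws) || any(ws < -1e-10)) next
    w <- numeric(p); w[sup] <- pmax(ws, 0)
    rss <- sum((A %*% w - s)^2)
    if (rss < best$rss - 1e-12) best <- list(rss = rss, w = w)
  }
  best
}
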