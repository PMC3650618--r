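test_that("basis tensors have the prescribed spectrum and orientation", {
  basis <- wishart_basis()
  expect_identical(dim(basis$tensors), c(3L, 3L, 162L))
  for (j in seq(1, 162, by = 7)) {
    D <- basis$tensors[, , j] * 1e3          # back to um^2/ms
    ev <- eigen(D, symmetric = TRUE)
    expect_lt(max(abs(sort(ev$values) - c(0.4, 0.4, 1.5))), 1e-9)
    expect_lt(axis_angle(ev$vectors[, 1], basis$dirs[j, ]), 1e-6)
    expect_equal(sum(diag(D)), 2.3)
    expect_equal(det(D), 0.24, tolerance = 1e-12)
  }
  # atom aligned with z is exactly diagonal
  jz <- which(apply(basis$dirs, 1L, function(v) axis_angle(v, c(0, 0, 1))) <
                1e-9)[1]
  expect_lt(max(abs(basis$tensors[, , jz] * 1e3 - diag(c(0.4, 0.4, 1.5)))),
            1e-9)
  expect_error(wishart_basis(icosphere(1)), "level-2")
  expect_error(wishart_basis(p = 0.5), "at least 1")
})

test_that("design matrix implements the Laplace-transform attenuation", {
  basis <- wishart_basis()
  gtab <- hardi_scheme()
  A <- design_matrix(gtab, basis)
  expect_identical(dim(A), c(70L, 162L))
  expect_true(all(A > 0 & A <= 1))
  # spot-check one entry against the scalar formula
  i <- 40L; j <- 101L
  row <- attr(A, "rows")[i]
  g <- gtab$bvecs[row, ]
  q <- drop(g %*% basis$tensors[, , j] %*% g)
  expect_equal(A[i, j], (1 + gtab$bvals[row] * q / 2)^-2, tolerance = 1e-12)
})

test_that("NNLS recovers single- and two-atom synthetic signals", {
  basis <- wishart_basis()
  gtab <- hardi_scheme()
  A <- design_matrix(gtab, basis)
  set.seed(21)
  for (j in sample.int(162, 5)) {
    w <- fit_weights(A[, j], A)
    expect_true(all(w >= 0))
    expect_lt(sqrt(sum((A %*% w - A[, j])^2)), 1e-8)
    # recovered orientation: strongest atom within one grid spacing
    expect_lt(axis_angle(basis$dirs[which.max(w), ], basis$dirs[j, ]), 10)
  }
  # two orthogonal atoms
  j1 <- which.max(abs(basis$dirs %*% c(1, 0, 0)))
  j2 <- which.max(abs(basis$dirs %*% c(0, 1, 0)))
  s <- 0.5 * (A[, j1] + A[, j2])
  w <- fit_weights(s, A)
  top <- order(w, decreasing = TRUE)[1:2]
  angs <- sapply(top, function(t) min(axis_angle(basis$dirs[t, ],
                                                 basis$dirs[j1, ]),
                                      axis_angle(basis$dirs[t, ],
                                                 basis$dirs[j2, ])))
  expect_lt(max(angs), 10)
})

test_that("flat (unattenuated) signal fits better with spread weights than any single atom", {
  basis <- wishart_basis()
  A <- design_matrix(hardi_scheme(), basis)
  s <- rep(1, nrow(A))
  w <- fit_weights(s, A)
  rss <- sum((A %*% w - s)^2)
  single_best <- min(sapply(seq_len(ncol(A)), function(j) {
    cj <- sum(A[, j] * s) / sum(A[, j]^2)
    sum((cj * A[, j] - s)^2)
  }))
  expect_lt(rss, single_best)
  expect_lte(sqrt(rss), sqrt(sum(s^2)))          # never worse than w = 0
})

test_that("degenerate voxel signals are flagged, not fatal", {
  A <- design_matrix(hardi_scheme(), wishart_basis())
  w <- fit_weights(rep(NA_real_, nrow(A)), A)
  expect_true(attr(w, "flagged"))
  expect_equal(as.numeric(w), numeric(ncol(A)))
  s <- rep(0.5, nrow(A)); s[3] <- -0.1
  w2 <- fit_weights(s, A)
  expect_identical(attr(w2, "clipped"), 1L)
})

test_that("NNLS satisfies KKT conditions and matches an enumeration oracle", {
  basis <- wishart_basis()
  A_full <- design_matrix(hardi_scheme(), basis)
  set.seed(33)
  for (rep in 1:10) {
    atoms <- sample.int(162, 8)
    A <- A_full[, atoms]
    w_true <- numeric(8); w_true[sample.int(8, 2)] <- runif(2, 0.3, 1)
    s <- drop(A %*% w_true) + rnorm(nrow(A), 0, 0.02)
    w <- fit_weights(s, A)
    # KKT: non-negativity; zero gradient on the support, non-negative off it
    g <- drop(crossprod(A, A %*% w - pmax(s, 0)))
    expect_true(all(w >= 0))
    expect_lt(max(abs(g[w > 0])), 1e-6)
    expect_gt(min(g[w == 0]), -1e-6)
    # optimal residual equals the brute-force support enumeration
    oracle <- nnls_enumerate(A, pmax(s, 0))
    expect_equal(sum((A %*% w - pmax(s, 0))^2), oracle$rss,
                 tolerance = 1e-8)
  }
})

test_that("the displacement PDF is positive, antipodally symmetric and atom-peaked", {
  basis <- wishart_basis()
  cfg <- pdf_config()
  K <- pdf_kernel(basis, cfg)
  t3 <- cfg$tess
  # antipodal vertex pairing
  V <- t3$vertices
  pair <- vapply(seq_len(nrow(V)), function(i)
    which.min(colSums((t(V) + V[i, ])^2)), 0L)
  jz <- which(apply(basis$dirs, 1L, function(v)
    axis_angle(v, c(0, 0, 1))) < 1e-9)[1]
  w <- numeric(162); w[jz] <- 1
  pdf <- evaluate_pdf(w, basis, cfg, K)
  expect_true(all(pdf > 0))
  expect_identical(max(abs(pdf - pdf[pair])), 0)
  peak <- V[which.max(pdf), ]
  expect_lt(axis_angle(peak, c(0, 0, 1)), 1e-9)
  # uniform weights give a near-isotropic profile
  pdfu <- evaluate_pdf(rep(1, 162), basis, cfg, K)
  expect_lt(max(pdfu) / min(pdfu), 1.05)
  expect_error(pdf_config(t = -1), "positive")
  expect_error(evaluate_pdf(c(-1, rep(0, 161)), basis, cfg, K),
               "non-negative")
})

test_that("peak locations are insensitive to the diffusion time", {
  basis <- wishart_basis()
  set.seed(44)
  w <- random_mixture_weights(162, NULL)
  # the dominant orientation must not move as the probe time varies;
  # weak secondary grid maxima may appear or vanish with the contrast
  locs <- lapply(c(15, 20, 30, 40), function(tt) {
    cfg <- pdf_config(t = tt)
    pdf <- evaluate_pdf(w, basis, cfg)
    find_maxima(pdf, cfg$tess)$directions[1, ]
  })
  for (l in locs[-1]) expect_lt(axis_angle(l, locs[[1]]), 8)
})

test_that("mow_fit returns a well-formed model object with methods", {
  px <- phantom_pipeline("STRAIGHT")
  fit <- px$fit
  expect_s3_class(fit, "mow_fit")
  expect_true(all(coef(fit) >= 0))
  expect_identical(nrow(coef(fit)), sum(px$sim$brain$data))
  f <- fitted(fit)
  expect_identical(dim(f), c(nrow(coef(fit)), 70L))
  expect_true(all(f > 0))
  pdfs <- predict(fit, type = "pdf")
  expect_identical(dim(pdfs), c(nrow(coef(fit)), 642L))
  expect_true(all(pdfs > 0))
  r <- residuals(fit)
  expect_identical(dim(r), dim(f))
  expect_equal(rowSums(r^2), fit$rss)
  sm <- summary(fit)
  # noiseless data: tiny residual (the isotropic background is approximated
  # by weight spread, so the fit is close but not exact there)
  expect_lt(sm$rmse, 1e-2)
  expect_output(print(fit), "Mixture-of-Wisharts")
  expect_output(print(sm), "active atoms")
})
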