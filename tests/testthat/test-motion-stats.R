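mk_traj <- function(pts) {
  structure(list(points = pts, observed = matrix(TRUE, dim(pts)[1], dim(pts)[2]),
                 timestamps = (seq_len(dim(pts)[1]) - 1) / 30,
                 grid = NULL, kept_nodes = seq_len(dim(pts)[2])),
            class = "grid_trajectory")
}

random_traj <- function(nf = 8, nn = 36, sd = 1) {
  base <- matrix(rnorm(nn * 3, sd = 3), nn, 3)
  pts <- array(NA_real_, c(nf, nn, 3))
  for (f in 1:nf) pts[f, , ] <- base + matrix(rnorm(nn * 3, sd = sd), nn, 3)
  mk_traj(pts)
}

test_that("motion matrices express frames relative to the rest configuration", {
  base <- matrix(rnorm(36 * 3), 36, 3)
  static <- aperm(array(base, c(36, 3, 4)), c(3, 1, 2))
  mm <- build_motion_matrix(mk_traj(static))
  expect_true(all(mm$X == 0))
  expect_equal(mm$rest, base)
  # one node moving +1 mm in z at frame 2: exactly one nonzero entry that row
  pts <- static
  pts[2, 7, 3] <- pts[2, 7, 3] + 1
  mm2 <- build_motion_matrix(mk_traj(pts))
  expect_equal(sum(mm2$X != 0), 1)
  expect_equal(mm2$X[2, (7 - 1) * 3 + 3], 1)
  # round trip through the flattening
  set.seed(2)
  tr <- random_traj()
  mm3 <- build_motion_matrix(tr)
  for (f in c(1, 5, 8))
    expect_equal(velogrid:::unflatten_config(mm3$X[f, ]) + mm3$rest,
                 tr$points[f, , ], ignore_attr = TRUE)
  # missing entries are refused
  bad <- tr; bad$points[3, 5, 2] <- NA
  expect_error(build_motion_matrix(bad), "non-rectangular")
})

test_that("PCA matches an independent eigendecomposition oracle", {
  set.seed(23)
  tr <- random_traj(nf = 30)
  mm <- build_motion_matrix(tr)
  p <- fit_pca(mm, k = 12)
  # oracle: eigendecomposition of the sample covariance matrix
  C <- cov(mm$X)
  ev <- eigen(C, symmetric = TRUE)
  expect_equal(p$eigenvalues, ev$values[1:12], tolerance = 1e-8)
  expect_equal(p$total_variance, sum(diag(C)), tolerance = 1e-8)
  # loading subspace alignment (up to sign)
  for (j in 1:5)
    expect_equal(abs(sum(p$loadings[j, ] * ev$vectors[, j])), 1, tolerance = 1e-6)
  # orthonormality
  expect_lt(max(abs(p$loadings %*% t(p$loadings) - diag(12))), 1e-9)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  # full-rank reconstruction identity
  k_full <- min(29, 108)
  pf <- fit_pca(mm, k = k_full)
  recon <- matrix(pf$mean, 30, 108, byrow = TRUE) + pf$scores %*% pf$loadings
  expect_lt(max(abs(recon - mm$X)), 1e-8)
  expect_equal(sum(pf$eigenvalues), pf$total_variance, tolerance = 1e-8)
})

test_that("rank-one motion is captured entirely by the first component", {
  set.seed(31)
  v <- rnorm(108); v <- v / sqrt(sum(v^2))
  amp <- rnorm(10, sd = 2)
  base <- matrix(rnorm(36 * 3), 36, 3)
  pts <- array(NA_real_, c(10, 36, 3))
  for (f in 1:10)
    pts[f, , ] <- base + velogrid:::unflatten_config(amp[f] * v)
  mm <- build_motion_matrix(mk_traj(pts))
  expect_warning(p <- fit_pca(mm, k = 12), "rank deficiency")
  expect_equal(p$eigenvalues[1] / p$total_variance, 1, tolerance = 1e-9)
  expect_gte(abs(sum(p$loadings[1, ] * v)), 0.999)
  # mode-shape reconstruction: score zero gives the mean shape; observed
  # scores reproduce the observed frames on rank-one data
  sh0 <- reconstruct_mode_shape(p, 1, 0)
  expect_equal(sh0, p$rest + velogrid:::unflatten_config(p$mean),
               ignore_attr = TRUE)
  for (f in c(2, 7)) {
    sh <- reconstruct_mode_shape(p, 1, p$scores[f, 1])
    expect_equal(sh, pts[f, , ], tolerance = 1e-8, ignore_attr = TRUE)
  }
  # orthonormal loadings make the shape path an isometry in score
  s <- 1.73
  expect_equal(sqrt(sum((reconstruct_mode_shape(p, 1, s) - sh0)^2)), s,
               tolerance = 1e-9)
})

test_that("isotropic noise yields no spurious dominant mode", {
  set.seed(57)
  tr <- random_traj(nf = 25, sd = 1)
  p <- fit_pca(build_motion_matrix(tr), k = 12)
  # eigenvalues sorted, positive, and the top one far from absorbing all
  # variance for isotropic data
  expect_true(all(p$eigenvalues >= 0))
  expect_lt(p$eigenvalues[1] / p$total_variance, 0.3)
})

test_that("Mann-Whitney matches enumeration and handles its edge cases", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  # identical samples: central U, p near 1
  r2 <- suppressWarnings(mann_whitney(c(5, 5, 5), c(5, 5, 5)))
  expect_equal(r2$U, 4.5)
  expect_gte(r2$p, 0.99)
  set.seed(61)
  for (i in 1:10) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- rnorm(n1); b <- rnorm(n2, mean = runif(1, -1, 1))
    got <- mann_whitney(a, b)
    want <- mw_enumerate(a, b)
    expect_equal(got$U, want$U)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_gte(got$U, 0); expect_lte(got$U, n1 * n2)
  }
})

test_that("the discriminant separates what is separable and only that", {
  # linearly separable clusters: perfect resubstitution
  set.seed(71)
  a <- cbind(rnorm(40, -4), rnorm(40, 0))
  b <- cbind(rnorm(40, 4), rnorm(40, 0))
  d <- discriminant_classify(rbind(a, b), rep(c("m", "f"), each = 40))
  expect_equal(d$accuracy, 100)
  # 2-point-per-class toy set: closed-form midpoint rule
  x <- rbind(c(0, 0), c(0, 2), c(4, 0), c(4, 2))
  dt <- discriminant_classify(x, c("A", "A", "B", "B"))
  expect_equal(as.character(dt$predicted), c("A", "A", "B", "B"))
  # boundary at x = 2: weights orthogonal to the class-mean difference axis
  expect_equal(dt$weights[2], 0, tolerance = 1e-9)
  # accuracy invariant to affine rescaling of the two axes
  sc <- cbind(rbind(a, b)[, 1] * 30 + 5, rbind(a, b)[, 2] * 0.01 - 2)
  d2 <- discriminant_classify(sc, rep(c("m", "f"), each = 40))
  expect_equal(d2$accuracy, d$accuracy)
  expect_error(discriminant_classify(a, rep("m", 40)), "two classes")
})

test_that("the discriminant agrees with an established LDA implementation", {
  set.seed(83)
  x <- rbind(cbind(rnorm(60, 0.5), rnorm(60)), cbind(rnorm(60, -0.5), rnorm(60)))
  lab <- rep(c("m", "f"), each = 60)
  d <- discriminant_classify(x, lab)
  ref <- MASS::lda(x, grouping = lab)
  ref_pred <- predict(ref, x)$class
  expect_equal(as.character(d$predicted), as.character(ref_pred))
})

test_that("leave-one-subject-out accuracy is reported when subjects are given", {
  set.seed(91)
  n_sub <- 8
  lab <- rep(c("m", "f"), each = 4 * 25)
  subj <- rep(sprintf("s%02d", 1:n_sub), each = 25)
  x <- cbind(rnorm(200, ifelse(lab == "m", 1, -1)), rnorm(200))
  d <- discriminant_classify(x, lab, subjects = subj)
  expect_false(is.na(d$accuracy_loso))
  expect_gte(d$accuracy_loso, 50)
  expect_lte(d$accuracy_loso, 100)
})
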