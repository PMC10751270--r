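# Build landmarks whose 10%-expanded bounding box is exactly the P x P patch
# centered at ((P-1)/2, (P-1)/2), so align_crop's transform is the identity.
identity_landmarks <- function(P) {
  tmpl <- unclass(face_template68())
  span <- apply(tmpl, 2, function(v) diff(range(v)))
  s <- (P / 1.1) / max(span)
  pts <- tmpl * s
  ctr <- (apply(pts, 2, max) + apply(pts, 2, min)) / 2
  pts <- sweep(pts, 2, ctr) + (P - 1) / 2
  landmarks68(pts)
}

test_that("align_crop: identity case, translation absorption, transform oracle", {
  P <- 64L
  set.seed(5)
  img <- matrix(runif(P * P), P, P)
  lms <- identity_landmarks(P)
  patch <- align_crop(img, lms, P)
  expect_equal(patch$transform$scale, 1, tolerance = 1e-12)
  expect_equal(patch$pixels, img, tolerance = 1e-12)

  # translating image content and landmarks together changes nothing
  big <- matrix(0.5, P + 20, P + 20)
  big[1:P, 1:P] <- img
  big2 <- matrix(0.5, P + 20, P + 20)
  big2[1:P, 11:(P + 10)] <- img
  p1 <- align_crop(big, lms, P)
  lms_t <- landmarks68(cbind(lms[, 1] + 10, lms[, 2]))
  p2 <- align_crop(big2, lms_t, P)
  expect_equal(p1$pixels, p2$pixels, tolerance = 1e-12)

  # re-apply-transform oracle: the returned transform maps raw landmarks to
  # the patch landmarks, and the mapped bounding box spans P/1.1 of the patch
  for (i in 1:5) {
    rl <- random_landmarks(scale = runif(1, 10, 25), center = c(60, 55))
    cv <- matrix(runif(120 * 120), 120, 120)
    pp <- align_crop(cv, rl, 96)
    tr <- pp$transform
    mapped <- cbind((rl[, 1] - tr$cx_src) * tr$scale + tr$cx_dst,
                    (rl[, 2] - tr$cy_src) * tr$scale + tr$cy_dst)
    expect_equal(unclass(pp$landmarks), mapped, ignore_attr = TRUE)
    span <- max(apply(mapped, 2, function(v) diff(range(v))))
    expect_equal(span, 96 / 1.1, tolerance = 1e-8)
  }
})

test_that("align_crop rejects landmarks entirely outside the image", {
  img <- matrix(0, 50, 50)
  far <- landmarks68(unclass(random_landmarks(center = c(500, 500))))
  expect_error(align_crop(img, far, 64), "outside")
})

test_that("HOG: flat patch, step edge, length formula, intensity shift", {
  expect_equal(hog_features(matrix(0.7, 64, 64)), rep(0, 1568))
  # length formula (P=64, cell=8, block=2, orientations=8)
  set.seed(6)
  rnd <- matrix(runif(64 * 64), 64, 64)
  v <- hog_features(rnd, orientations = 8, cell = 8, block = 2)
  expect_length(v, (8 - 2 + 1)^2 * 2^2 * 8)
  expect_true(all(v >= 0))
  # vertical step edge: gradient points along x, orientation 0
  step <- matrix(0, 64, 64); step[, 33:64] <- 1
  hv <- hog_features(step, orientations = 8, cell = 8, block = 2)
  by_orient <- rowsum(hv, rep(1:8, times = length(hv) / 8))
  expect_gte(by_orient[1] / sum(by_orient), 0.9)
  # per-pixel gradient-binning oracle on the unnormalized tally
  gx <- cbind(step[, 2] - step[, 1],
              (step[, 3:64] - step[, 1:62]) / 2,
              step[, 64] - step[, 63])
  gy <- rbind(step[2, ] - step[1, ],
              (step[3:64, ] - step[1:62, ]) / 2,
              step[64, ] - step[63, ])
  theta <- atan2(gy, gx) %% pi
  bins <- pmin(floor(theta / (pi / 8)), 7)
  mag <- sqrt(gx^2 + gy^2)
  expect_gte(sum(mag[bins == 0]) / sum(mag), 0.9)
  # adding a constant to all intensities leaves HOG unchanged
  expect_equal(hog_features(rnd), hog_features(rnd + 0.17))
})

test_that("HOG pipeline is deterministic end to end", {
  set.seed(7)
  img <- matrix(runif(80 * 80), 80, 80)
  lms <- random_landmarks(scale = 11, center = c(40, 40))
  f1 <- hog_features(align_crop(img, lms, 64))
  f2 <- hog_features(align_crop(img, lms, 64))
  expect_identical(f1, f2)
})

test_that("PCA: eigendecomposition oracle, rank-1 data, exact reconstruction", {
  set.seed(8)
  # points on a line in 3-space
  dir3 <- c(1, -2, 2) / 3
  X1 <- outer(rnorm(40), dir3) + matrix(1, 40, 1) %*% c(5, 6, 7)
  b1 <- fit_pca(X1, retained_variance = 0.99)
  expect_equal(b1$k, 1)
  expect_equal(abs(sum(b1$components[1, ] * dir3)), 1, tolerance = 1e-8)

  X <- matrix(rnorm(50 * 20), 50, 20)
  full <- fit_pca(X, retained_variance = 1.0)
  rec <- pca_reconstruct(full, pca_project(full, X))
  expect_equal(rec, X, tolerance = 1e-8, ignore_attr = TRUE)

  # independent eigendecomposition of the covariance matrix
  ev <- eigen(cov(X), symmetric = TRUE)
  b <- fit_pca(X, retained_variance = 0.95)
  expect_equal(b$explained_variance,
               (ev$values / sum(ev$values))[seq_len(b$k)], tolerance = 1e-8)
  for (j in seq_len(b$k)) {
    expect_equal(abs(sum(b$components[j, ] * ev$vectors[, j])), 1,
                 tolerance = 1e-8)
  }
  expect_error(fit_pca(matrix(3, 10, 4)), "zero-variance")
})

test_that("PCA projection: closed form, round trip, decorrelated scores", {
  set.seed(9)
  X <- matrix(rnorm(60 * 12), 60, 12)
  b <- fit_pca(X, retained_variance = 1.0)
  expect_equal(pca_project(b, b$mean), rep(0, b$k), ignore_attr = TRUE)
  expect_equal(pca_reconstruct(b, pca_project(b, X[3, ])), X[3, ],
               tolerance = 1e-8, ignore_attr = TRUE)
  x <- rnorm(12)
  expect_equal(pca_project(b, x),
               drop((x - b$mean) %*% t(b$components)), ignore_attr = TRUE)
  S <- pca_project(b, X)
  C <- cor(S)
  expect_lt(max(abs(C[upper.tri(C)])), 1e-6)
  expect_error(pca_project(b, rnorm(5)), "dimension")
})
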