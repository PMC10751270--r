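test_that("separable AU labels are fit perfectly on the training set", {
  fix <- separable_feature_fixture()
  for (alg in c("svm", "xgb")) {
    det <- train_au_detector(fix$X, fix$au_labels, algorithm = alg, seed = 3)
    probs <- fexkit:::predict_au_matrix(det, fix$X)
    for (au in au_names12()) {
      expect_equal(f1_binary(probs[, au] >= 0.5, fix$au_labels[, au]), 1,
                   info = paste(alg, au))
    }
  }
})

test_that("retraining with a fixed seed reproduces identical model bytes", {
  fix <- separable_feature_fixture()
  for (alg in c("svm", "xgb")) {
    d1 <- train_au_detector(fix$X, fix$au_labels, algorithm = alg, seed = 11)
    d2 <- train_au_detector(fix$X, fix$au_labels, algorithm = alg, seed = 11)
    expect_identical(serialize(d1, NULL), serialize(d2, NULL))
  }
})

test_that("single-class AU labels fail with the AU named", {
  fix <- separable_feature_fixture()
  L <- fix$au_labels
  L[, "AU09"] <- 0
  expect_error(train_au_detector(fix$X, L), "AU09")
})

test_that("linear-variant probability is monotone in the decision margin", {
  fix <- separable_feature_fixture()
  det <- train_au_detector(fix$X, fix$au_labels, algorithm = "svm", seed = 1)
  set.seed(10)
  Xnew <- matrix(rnorm(200 * 5), 200, 5)
  for (au in c("AU01", "AU12", "AU26")) {
    m <- det$models[[au]]
    expect_gte(unname(m$platt["a"]), 0)
    margin <- drop(Xnew %*% m$w) + m$b
    p <- fexkit:::predict_linear_binary(m, Xnew)
    ord <- order(margin)
    expect_true(all(diff(p[ord]) >= -1e-12))
  }
})

test_that("held-out F1 under independent labels collapses to the rate baseline", {
  # permutation-null oracle: with labels independent of the features, the
  # mean held-out F1 over 20 seeds must sit inside the simulated 95% band of
  # a label-independent Bernoulli predictor matched in predicted rate
  n <- 160
  f1s <- numeric(20)
  qhat <- numeric(20)
  p_pos <- 0.4
  for (s in 1:20) {
    set.seed(100 + s)
    X <- matrix(rnorm(n * 5), n, 5)
    y <- rbinom(n, 1, p_pos)
    tr <- 1:(n / 2); te <- (n / 2 + 1):n
    if (length(unique(y[tr])) < 2) y[tr[1:2]] <- c(0, 1)
    m <- fexkit:::fit_linear_binary(X[tr, ], y[tr])
    pred <- fexkit:::predict_linear_binary(m, X[te, ]) >= 0.5
    qhat[s] <- mean(pred)
    f1s[s] <- if (any(y[te] == 1)) f1_binary(pred, y[te]) else NA
  }
  obs <- mean(f1s, na.rm = TRUE)
  set.seed(999)
  null_means <- replicate(400, {
    mean(vapply(1:20, function(s) {
      yte <- rbinom(80, 1, p_pos)
      pr <- rbinom(80, 1, mean(qhat))
      if (!any(yte == 1)) return(NA_real_)
      tp <- sum(pr & yte)
      if (tp == 0) 0 else 2 * tp / (2 * tp + sum(pr & !yte) + sum(!pr & yte))
    }, numeric(1)), na.rm = TRUE)
  })
  expect_gte(obs, quantile(null_means, 0.025) - 0.05)
  expect_lte(obs, quantile(null_means, 0.975) + 0.05)
})

test_that("emotion classifier: separable accuracy and normalized probabilities", {
  set.seed(12)
  emos <- emotion_names()
  centers <- matrix(rnorm(7 * 5, sd = 6), 7, 5)
  y <- rep(emos, each = 30)
  X <- centers[rep(1:7, each = 30), ] + matrix(rnorm(210 * 5, sd = 0.3), 210, 5)
  det <- train_emotion_detector(X, y, seed = 4)
  P <- fexkit:::predict_emotion_matrix(det, X)
  expect_equal(emos[max.col(P)], y)   # training accuracy 1.0
  rnd <- matrix(rnorm(1000 * 5, sd = 4), 1000, 5)
  Pr <- fexkit:::predict_emotion_matrix(det, rnd)
  expect_equal(rowSums(Pr), rep(1, 1000), tolerance = 1e-6)
  expect_true(all(Pr >= 0 & Pr <= 1))
  expect_error(train_emotion_detector(X, rep("anger", 210)), "two emotion classes")
})

test_that("bundle detects on raw features and rejects mismatched preprocessing", {
  fix <- separable_feature_fixture()
  cfg <- detector_config(patch_size = 64)
  # treat the fixture features as a tiny HOG space
  bundle <- fit_detector(config = cfg, seed = 5, features = fix$X,
                         au_labels = fix$au_labels,
                         emotion_labels = fix$emotions)
  p <- detect_aus(bundle, features = fix$X[1, ])
  expect_named(p, au_names12())
  expect_true(all(p >= 0 & p <= 1))
  # all-zero feature vector: finite probabilities, no error
  p0 <- detect_aus(bundle, features = rep(0, 5))
  expect_true(all(is.finite(p0)))
  e0 <- detect_emotions(bundle, features = rep(0, 5))
  expect_equal(sum(e0), 1, tolerance = 1e-6)
  # a patch whose size disagrees with the bundle's config is refused
  img <- matrix(runif(96 * 96), 96, 96)
  patch <- align_crop(img, random_landmarks(scale = 12, center = c(48, 48)), 96)
  expect_error(detect_aus(bundle, image = patch), "patch size")
  expect_error(detect_aus(bundle, features = rnorm(3)), "dimension")
})

test_that("bundle serialization round-trips bit-exactly", {
  fix <- separable_feature_fixture()
  bundle <- fit_detector(config = detector_config(), seed = 6,
                         features = fix$X, au_labels = fix$au_labels,
                         emotion_labels = fix$emotions)
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(path))
  write_bundle(bundle, path)
  back <- read_bundle(path)
  expect_identical(serialize(bundle, NULL), serialize(back, NULL))
})
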