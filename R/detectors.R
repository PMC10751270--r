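#' @title AU and emotion detectors
#' @name detectors
#' @description
#' Shallow classifiers on the PCA-compressed HOG features: one independent
#' binary classifier per action unit (linear max-margin or gradient-boosted
#' trees) and a seven-class linear emotion classifier, plus the training
#' harness that assembles everything into a serializable detector bundle.
NULL

# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Platt-style probability calibration: logistic fit of regularized targets on
# decision values. Targets use the (N+1)/(N+2) smoothing so separable data do
# not drive the slope to infinity. Returns c(a, c) with a >= 0 enforced by
# the caller flipping the margin orientation.
platt_fit <- function(margin, y) {
  npos <- sum(y == 1); nneg <- sum(y == 0)
  t_pos <- (npos + 1) / (npos + 2)
  t_neg <- 1 / (nneg + 2)
  tgt <- ifelse(y == 1, t_pos, t_neg)
  fit <- suppressWarnings(stats::glm(tgt ~ margin, family = stats::binomial()))
  cf <- stats::coef(fit)
  c(a = unname(cf[2]), c = unname(cf[1]))
}

# Fit one binary linear SVM with inverse-frequency class weights; returns a
# flat parameter list (weights, offset, Platt link) so serialization is a
# plain numeric dump. Margins are oriented so that larger margin means
# higher probability of the positive class.
fit_linear_binary <- function(X, y, cost = 1) {
  yf <- factor(y, levels = c(0, 1))
  cw <- length(y) / (2 * table(yf))
  fit <- e1071::svm(X, yf, kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = cw)
  w <- drop(crossprod(fit$SV, fit$coefs))
  b <- -fit$rho
  margin <- drop(X %*% w) + b
  pl <- platt_fit(margin, y)
  if (is.na(pl["a"])) pl <- c(a = 0, c = stats::qlogis(mean(y == 1)))
  if (pl["a"] < 0) {       # orient so probability is increasing in margin
    w <- -w; b <- -b
    pl["a"] <- -pl["a"]
  }
  list(type = "linear_svm", w = w, b = b, platt = pl)
}

predict_linear_binary <- function(model, X) {
  margin <- drop(X %*% model$w) + model$b
  stats::plogis(model$platt["a"] * margin + model$platt["c"])
}

fit_xgb_binary <- function(X, y, seed, nrounds = 150) {
  spw <- sum(y == 0) / max(1, sum(y == 1))
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  params <- list(objective = "binary:logistic", max_depth = 4, eta = 0.3,
                 nthread = 1, seed = seed, scale_pos_weight = spw)
  bst <- xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                            verbose = 0)
  list(type = "xgb", raw = xgboost::xgb.save.raw(bst), nrounds = nrounds)
}

predict_xgb_binary <- function(model, X) {
  bst <- xgboost::xgb.load.raw(model$raw)
  as.numeric(stats::predict(bst, xgboost::xgb.DMatrix(X)))
}

#' Train the 12 per-AU binary classifiers
#'
#' One independent binary model per action unit on the PCA score matrix.
#' The gradient-boosted variant (`"xgb"`, the default) emits calibrated
#' probabilities directly; the linear max-margin variant (`"svm"`) maps its
#' margin through a monotone logistic (Platt) link fitted on the training
#' margins. Class imbalance is handled by inverse-frequency weights.
#'
#' @param scores `n x k` feature (PCA score) matrix.
#' @param labels `n x 12` binary matrix with columns named as
#'   [au_names12()].
#' @param algorithm `"xgb"` or `"svm"`.
#' @param seed Integer seed controlling all stochastic training steps.
#' @return An object of class `"au_detector"`: per-AU parameter lists plus
#'   metadata.
#' @export
train_au_detector <- function(scores, labels, algorithm = c("xgb", "svm"),
                              seed = 1) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(scores)
  L <- as.matrix(labels)
  if (is.null(colnames(L))) colnames(L) <- au_names12()
  if (!identical(sort(colnames(L)), sort(au_names12())))
    stop("train_au_detector: label columns must be the 12 detection AUs")
  L <- L[, au_names12(), drop = FALSE]
  models <- vector("list", 12L)
  names(models) <- au_names12()
  for (au in au_names12()) {
    y <- as.numeric(L[, au] > 0)
    if (length(unique(y)) < 2L)
      stop(sprintf("train_au_detector: %s has a single class in the labels", au))
    models[[au]] <- with_seed(seed, {
      if (algorithm == "xgb") fit_xgb_binary(X, y, seed = seed)
      else fit_linear_binary(X, y)
    })
  }
  structure(list(models = models, algorithm = algorithm, seed = seed,
                 n = nrow(X), k = ncol(X)),
            class = "au_detector")
}

# Probability matrix (n x 12) from an au_detector on a score matrix.
predict_au_matrix <- function(det, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (ncol(X) != det$k)
    stop("au detector: feature dimension does not match training")
  out <- vapply(det$models, function(m) {
    p <- if (m$type == "xgb") predict_xgb_binary(m, X)
         else predict_linear_binary(m, X)
    pmin(1, pmax(0, p))
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(det$models)))
  out
}

#' Train the seven-class emotion classifier
#'
#' A multiclass linear classifier built from one-vs-rest linear support
#' vector machines with Platt-calibrated per-class probabilities, normalized
#' to sum to one.
#'
#' @param scores `n x k` feature matrix.
#' @param labels Factor or character vector over [emotion_names()] (at least
#'   two classes present).
#' @param seed Integer seed.
#' @return An object of class `"emotion_detector"`.
#' @export
train_emotion_detector <- function(scores, labels, seed = 1) {
  X <- as.matrix(scores)
  y <- as.character(labels)
  present <- intersect(emotion_names(), unique(y))
  if (length(present) < 2L)
    stop("train_emotion_detector: need at least two emotion classes")
  if (length(setdiff(unique(y), emotion_names())))
    stop("train_emotion_detector: unknown emotion label(s)")
  models <- lapply(present, function(cl)
    with_seed(seed, fit_linear_binary(X, as.numeric(y == cl))))
  names(models) <- present
  structure(list(models = models, classes = present, seed = seed,
                 n = nrow(X), k = ncol(X)),
            class = "emotion_detector")
}

# Probability matrix (n x 7) over all emotion categories, rows sum to 1.
predict_emotion_matrix <- function(det, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (ncol(X) != det$k)
    stop("emotion detector: feature dimension does not match training")
  raw <- matrix(0, nrow(X), length(emotion_names()),
                dimnames = list(NULL, emotion_names()))
  for (cl in det$classes)
    raw[, cl] <- predict_linear_binary(det$models[[cl]], X)
  tot <- rowSums(raw)
  zero <- tot <= 0
  raw[zero, ] <- 1 / ncol(raw)
  raw[!zero, ] <- raw[!zero, , drop = FALSE] / tot[!zero]
  raw
}

#' Extract pipeline features for a set of faces
#'
#' Runs [align_crop()] and [hog_features()] with the given configuration for
#' each image/landmark pair.
#'
#' @param images List of grayscale matrices in `[0, 1]`.
#' @param landmarks List of [landmarks68()] in each image's pixel frame.
#' @param config A [detector_config()].
#' @return An `n x d` HOG feature matrix.
#' @export
extract_face_features <- function(images, landmarks, config = detector_config()) {
  stopifnot(length(images) == length(landmarks))
  feats <- lapply(seq_along(images), function(i) {
    patch <- align_crop(images[[i]], landmarks[[i]], config$patch_size)
    hog_features(patch, orientations = config$hog_orientations,
                 cell = config$hog_cell, block = config$hog_block)
  })
  do.call(rbind, feats)
}

#' Fit a full detector bundle
#'
#' The end-to-end training harness: HOG features within the landmark hull,
#' PCA compression, 12 per-AU classifiers and the emotion classifier, all
#' wrapped with the preprocessing configuration and training metadata into a
#' single serializable bundle.
#'
#' @param dataset A list of records with fields `image`, `landmarks`,
#'   `au_binary` (named 12-vector) and `emotion` (label) — e.g. the output of
#'   [make_dataset()] — or `NULL` if `features` is supplied directly.
#' @param config A [detector_config()].
#' @param algorithm AU classifier algorithm, `"xgb"` (default) or `"svm"`.
#' @param seed Integer seed.
#' @param features Optional precomputed `n x d` HOG matrix (bypasses image
#'   processing; must match `config`).
#' @param au_labels,emotion_labels Labels to use with `features`.
#' @return An object of class `"detector_bundle"` with elements `config`,
#'   `pca`, `au`, `emotion`, and `meta`.
#' @export
fit_detector <- function(dataset = NULL, config = detector_config(),
                         algorithm = c("xgb", "svm"), seed = 1,
                         features = NULL, au_labels = NULL,
                         emotion_labels = NULL) {
  algorithm <- match.arg(algorithm)
  if (is.null(features)) {
    stopifnot(is.list(dataset), length(dataset) >= 2)
    features <- extract_face_features(lapply(dataset, `[[`, "image"),
                                      lapply(dataset, `[[`, "landmarks"),
                                      config)
    au_labels <- do.call(rbind, lapply(dataset, `[[`, "au_binary"))
    colnames(au_labels) <- au_names12()
    emotion_labels <- vapply(dataset, `[[`, character(1), "emotion")
  }
  pca <- fit_pca(features, config$pca_retained_variance)
  scores <- pca_project(pca, features)
  au <- train_au_detector(scores, au_labels, algorithm = algorithm, seed = seed)
  emo <- train_emotion_detector(scores, emotion_labels, seed = seed)
  structure(list(config = config, pca = pca, au = au, emotion = emo,
                 meta = list(seed = seed, n = nrow(features),
                             algorithm = algorithm,
                             trained = "fexkit detector bundle v1")),
            class = "detector_bundle")
}

#' @export
print.detector_bundle <- function(x, ...) {
  cat("Detector bundle\n")
  cat(sprintf("  preprocessing: %dpx patch, HOG %d orientations / %dpx cells / %d-cell blocks\n",
              x$config$patch_size, x$config$hog_orientations,
              x$config$hog_cell, x$config$hog_block))
  cat(sprintf("  PCA: %d components (%.0f%% variance retained)\n",
              x$pca$k, 100 * x$config$pca_retained_variance))
  cat(sprintf("  AU classifiers: 12 x %s; emotion: one-vs-rest linear SVM\n",
              x$au$algorithm))
  cat(sprintf("  trained on n = %d faces, seed %d\n", x$meta$n, x$meta$seed))
  invisible(x)
}

# Resolve detector inputs to a PCA score matrix. Accepts raw HOG features or
# an image + landmarks pair processed under the bundle's own configuration.
bundle_scores <- function(bundle, image = NULL, landmarks = NULL,
                          features = NULL) {
  if (is.null(features)) {
    if (is.null(image) || (is.null(landmarks) && !inherits(image, "face_patch")))
      stop("provide either `features`, a face_patch, or both `image` and `landmarks`")
    if (inherits(image, "face_patch")) {
      if (nrow(image$pixels) != bundle$config$patch_size)
        stop("patch size does not match the bundle's preprocessing configuration")
      features <- hog_features(image, bundle$config$hog_orientations,
                               bundle$config$hog_cell, bundle$config$hog_block)
    } else {
      features <- extract_face_features(list(image), list(landmarks),
                                        bundle$config)
    }
  }
  X <- if (is.null(dim(features))) matrix(features, nrow = 1) else as.matrix(features)
  if (ncol(X) == length(bundle$pca$mean)) return(pca_project(bundle$pca, X))
  if (ncol(X) == bundle$pca$k) return(X)   # already projected
  stop("feature dimension matches neither the bundle's HOG length nor its PCA rank")
}

#' Detect action units
#'
#' @param bundle A fitted [fit_detector()] bundle.
#' @param image Grayscale matrix (with `landmarks`) or a [align_crop()]
#'   patch.
#' @param landmarks [landmarks68()] when `image` is a full image.
#' @param features Optional precomputed HOG vector/matrix or PCA scores.
#' @return For a single face, a named probability vector over the 12 AUs;
#'   for a feature matrix, an `n x 12` matrix. Thresholding at 0.5 gives the
#'   binary calls used for F1 scoring.
#' @export
detect_aus <- function(bundle, image = NULL, landmarks = NULL, features = NULL) {
  stopifnot(inherits(bundle, "detector_bundle"))
  S <- bundle_scores(bundle, image, landmarks, features)
  P <- predict_au_matrix(bundle$au, S)
  if (nrow(P) == 1L) drop(P)[au_names12()] else P
}

#' Detect emotions
#'
#' @inheritParams detect_aus
#' @return A named probability vector over the seven emotion categories
#'   (summing to 1), or an `n x 7` matrix for batch input.
#' @export
detect_emotions <- function(bundle, image = NULL, landmarks = NULL,
                            features = NULL) {
  stopifnot(inherits(bundle, "detector_bundle"))
  S <- bundle_scores(bundle, image, landmarks, features)
  P <- predict_emotion_matrix(bundle$emotion, S)
  if (nrow(P) == 1L) drop(P)[emotion_names()] else P
}

#' Serialize / restore a detector bundle
#'
#' The bundle is written as a single versioned archive; a write/read round
#' trip restores it bit-exactly (`serialize()`-identical).
#'
#' @param bundle A [fit_detector()] bundle.
#' @param path File path.
#' @return `read_bundle()` returns the bundle; `write_bundle()` returns
#'   `path` invisibly.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "detector_bundle"))
  saveRDS(bundle, path, version = 3, compress = "gzip")
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  bundle <- readRDS(path)
  if (!inherits(bundle, "detector_bundle"))
    stop("read_bundle: file does not contain a detector bundle")
  bundle
}
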