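#' @title AU-to-landmark generative face model
#' @name facemodel
#' @description
#' A linear generative model of how facial action unit (AU) activations deform
#' a neutral 68-point face: `landmarks(au) = template + reshape(W %*% au)`.
#' The model can be fitted from paired AU/landmark data by per-coordinate
#' ordinary least squares, used to generate landmarks for arbitrary AU
#' combinations, rendered as a stylized anonymous face with optional muscle
#' heatmaps, and morphed between expressions. It is also the geometry engine
#' behind the synthetic data generator.
#'
#' Landmark vectors are length 136, stacked as all x coordinates (points
#' 0-67) followed by all y coordinates. The template lives in a normalized
#' frame: centroid at the origin, interocular distance 1, y increasing
#' downward.
NULL

#' The 12 detectable action units
#'
#' @return Character vector of AU column labels, `AU01` ... `AU26`.
#' @export
au_names12 <- function() {
  c("AU01", "AU02", "AU04", "AU05", "AU06", "AU09",
    "AU12", "AU15", "AU17", "AU20", "AU25", "AU26")
}

#' The seven emotion categories
#'
#' @return Character vector: anger, disgust, fear, happiness, sadness,
#'   surprise, neutral.
#' @export
emotion_names <- function() {
  c("anger", "disgust", "fear", "happiness", "sadness", "surprise", "neutral")
}

#' Neutral 68-point face template
#'
#' A hand-designed neutral face in the normalized frame (centroid at origin,
#' interocular distance 1, y down). Eye centers sit one interocular unit
#' apart; brows, nose, mouth and jaw are placed at conventional proportions.
#'
#' @return A [landmarks68()] matrix.
#' @export
face_template68 <- function() {
  pts <- matrix(0, 68, 2)
  # jaw 0-16: elliptical arc from left cheekbone through chin to right
  t <- ((0:16) - 8) / 8
  pts[1:17, 1] <- 1.1 * sin(t * pi / 2)
  pts[1:17, 2] <- -0.05 + 1.4 * cos(t * pi / 2)
  # brows 17-21 (right, lateral->medial) and 22-26 (left, medial->lateral)
  bx <- c(0.85, 0.68, 0.50, 0.33, 0.18)
  by <- c(-0.25, -0.31, -0.33, -0.31, -0.27)
  pts[18:22, 1] <- -bx;       pts[18:22, 2] <- by
  pts[23:27, 1] <- rev(bx);   pts[23:27, 2] <- rev(by)
  # nose bridge 27-30 and base 31-35
  pts[28:31, 1] <- 0
  pts[28:31, 2] <- c(-0.15, 0.02, 0.19, 0.36)
  pts[32:36, 1] <- c(-0.18, -0.09, 0, 0.09, 0.18)
  pts[32:36, 2] <- c(0.44, 0.47, 0.49, 0.47, 0.44)
  # eyes 36-41 (right, from outer corner) and 42-47 (left, from inner corner)
  eye <- function(cx) cbind(cx + c(-0.17, -0.08, 0.08, 0.17, 0.08, -0.08),
                            c(0, -0.06, -0.06, 0, 0.06, 0.06))
  pts[37:42, ] <- eye(-0.5)
  pts[43:48, ] <- eye(0.5)
  # mouth: outer lips 48-59, inner 60-67
  pts[49:60, 1] <- c(-0.35, -0.22, -0.10, 0, 0.10, 0.22, 0.35,
                     0.22, 0.10, 0, -0.10, -0.22)
  pts[49:60, 2] <- c(0.75, 0.68, 0.65, 0.66, 0.65, 0.68, 0.75,
                     0.84, 0.88, 0.89, 0.88, 0.84)
  pts[61:68, 1] <- c(-0.28, -0.10, 0, 0.10, 0.28, 0.10, 0, -0.10)
  pts[61:68, 2] <- c(0.75, 0.72, 0.73, 0.72, 0.75, 0.79, 0.80, 0.79)
  pts <- sweep(pts, 2, colMeans(pts))
  lms <- landmarks68(pts)
  # exact unit interocular distance
  landmarks68(unclass(lms) / interocular_distance(lms))
}

#' Construct an AU face model
#'
#' @param template A [landmarks68()] neutral face in the normalized frame.
#' @param W A `136 x K` deformation matrix: column k is the landmark
#'   displacement (x-block then y-block) per unit activation of AU k.
#' @param au_names Length-K character vector naming the columns of `W`.
#' @param activation_range Expected activation scale per AU (informational).
#' @return An object of class `"au_face_model"`.
#' @export
au_face_model <- function(template, W, au_names,
                          activation_range = c(0, 1)) {
  template <- as_landmarks68(template)
  W <- as.matrix(W)
  if (nrow(W) != 136L) stop("au_face_model: W must have 136 rows")
  if (ncol(W) != length(au_names))
    stop("au_face_model: ncol(W) must match au_names")
  if (length(au_names) < 12L)
    stop("au_face_model: at least the 12 detection AUs are required")
  colnames(W) <- au_names
  structure(list(template = template, W = W, au_names = au_names,
                 activation_range = activation_range),
            class = "au_face_model")
}

#' @export
print.au_face_model <- function(x, ...) {
  cat("AU-to-landmark face model\n")
  cat("  AUs (K =", length(x$au_names), "):",
      paste(x$au_names, collapse = " "), "\n")
  cat("  template: 68 points, normalized frame (interocular = 1)\n")
  cat("  mean |deformation| per unit activation:",
      sprintf("%.3f", mean(abs(x$W))), "\n")
  invisible(x)
}

#' @export
coef.au_face_model <- function(object, ...) object$W

# Displacement columns of the packaged default model, in the normalized
# frame (units of interocular distance, y down so negative dy is upward).
default_deformations <- function() {
  W <- matrix(0, 136, 12, dimnames = list(NULL, au_names12()))
  put <- function(W, au, idx, dx = 0, dy = 0) {
    W[idx, au] <- W[idx, au] + dx
    W[idx + 68L, au] <- W[idx + 68L, au] + dy
    W
  }
  # AU1 inner brow raiser
  W <- put(W, "AU01", c(22, 23), dy = -0.16)
  W <- put(W, "AU01", c(21, 24), dy = -0.09)
  # AU2 outer brow raiser
  W <- put(W, "AU02", c(18, 27), dy = -0.15)
  W <- put(W, "AU02", c(19, 26), dy = -0.09)
  # AU4 brow lowerer (down and medial)
  W <- put(W, "AU04", 18:27, dy = 0.11)
  W <- put(W, "AU04", c(21, 22), dx = 0.05)
  W <- put(W, "AU04", c(23, 24), dx = -0.05)
  # AU5 upper lid raiser (eye aperture widens)
  W <- put(W, "AU05", c(38, 39, 44, 45), dy = -0.10)
  W <- put(W, "AU05", c(37, 40, 43, 46), dy = -0.03)
  # AU6 cheek raiser (lower lid pushed up, slight squint)
  W <- put(W, "AU06", c(41, 42, 47, 48), dy = -0.15)
  W <- put(W, "AU06", c(37, 40, 43, 46), dy = -0.02)
  # AU9 nose wrinkler (base drawn up, nostrils flare, brows pulled down)
  W <- put(W, "AU09", 32:36, dy = -0.15)
  W <- put(W, "AU09", 32, dx = -0.07)
  W <- put(W, "AU09", 36, dx = 0.07)
  W <- put(W, "AU09", 28:31, dy = -0.06)
  W <- put(W, "AU09", c(22, 23), dy = 0.06)
  # AU12 lip corner puller (smile: out and up)
  W <- put(W, "AU12", c(49, 61), dx = -0.13, dy = -0.11)
  W <- put(W, "AU12", c(55, 65), dx = 0.13, dy = -0.11)
  W <- put(W, "AU12", c(50, 60), dx = -0.06, dy = -0.05)
  W <- put(W, "AU12", c(54, 56), dx = 0.06, dy = -0.05)
  # AU15 lip corner depressor
  W <- put(W, "AU15", c(49, 61), dy = 0.11)
  W <- put(W, "AU15", c(55, 65), dy = 0.11)
  W <- put(W, "AU15", c(50, 54), dy = 0.05)
  # AU17 chin raiser
  W <- put(W, "AU17", 8:10, dy = -0.10)
  W <- put(W, "AU17", c(57, 58, 59, 66, 67, 68), dy = -0.06)
  # AU20 lip stretcher (out, slightly down)
  W <- put(W, "AU20", c(49, 61), dx = -0.20, dy = 0.03)
  W <- put(W, "AU20", c(55, 65), dx = 0.20, dy = 0.03)
  W <- put(W, "AU20", c(50, 60), dx = -0.09)
  W <- put(W, "AU20", c(54, 56), dx = 0.09)
  # AU25 lips part (mouth opening becomes visible)
  W <- put(W, "AU25", 62:64, dy = -0.11)
  W <- put(W, "AU25", 66:68, dy = 0.13)
  W <- put(W, "AU25", 51:53, dy = -0.05)
  W <- put(W, "AU25", 57:59, dy = 0.05)
  # AU26 jaw drop
  W <- put(W, "AU26", 7:11, dy = 0.15)
  W <- put(W, "AU26", 9, dy = 0.05)
  W <- put(W, "AU26", c(56, 57, 58, 59, 60), dy = 0.10)
  W <- put(W, "AU26", 66:68, dy = 0.08)
  W
}

#' Packaged default face model
#'
#' The neutral template of [face_template68()] paired with hand-designed
#' deformation directions for the 12 detectable AUs (e.g. AU12 pulls the
#' mouth corners outward and upward, AU26 drops the jaw). Deformation
#' magnitudes are expressed in interocular-distance units per unit
#' activation.
#'
#' @return An [au_face_model()].
#' @examples
#' m <- default_face_model()
#' smile <- generate_landmarks(m, c(AU06 = 1, AU12 = 1))
#' @export
default_face_model <- function() {
  au_face_model(face_template68(), default_deformations(), au_names12())
}

#' Fit an AU face model by per-coordinate least squares
#'
#' Regresses normalized landmark coordinates on AU activations. If rows with
#' all-zero activations are present, the template is their mean shape and the
#' deformation matrix is the no-intercept OLS solution of
#' `(landmarks - template) ~ activations`; otherwise an intercept is fitted
#' and becomes the template.
#'
#' @param au_matrix `n x K` activation matrix (column names become AU names).
#' @param landmark_matrix `n x 136` landmark rows (x-block then y-block),
#'   already normalized (e.g. via [procrustes_normalize()]).
#' @param au_names Optional AU names; defaults to `colnames(au_matrix)`.
#' @return An [au_face_model()].
#' @export
fit_face_model <- function(au_matrix, landmark_matrix, au_names = NULL) {
  X <- as.matrix(au_matrix)
  Y <- as.matrix(landmark_matrix)
  if (nrow(X) != nrow(Y)) stop("fit_face_model: row mismatch")
  if (ncol(Y) != 136L) stop("fit_face_model: landmarks must have 136 columns")
  K <- ncol(X)
  if (nrow(X) <= K) stop("fit_face_model: need more rows than AUs")
  if (is.null(au_names)) au_names <- colnames(X)
  if (is.null(au_names)) au_names <- paste0("AU", seq_len(K))
  qx <- qr(X)
  if (qx$rank < K) {
    dep <- au_names[qx$pivot[(qx$rank + 1L):K]]
    stop(sprintf("fit_face_model: AU matrix is rank deficient; dependent columns: %s",
                 paste(dep, collapse = ", ")))
  }
  zero_rows <- rowSums(abs(X)) == 0
  if (any(zero_rows)) {
    template_v <- colMeans(Y[zero_rows, , drop = FALSE])
    D <- sweep(Y, 2, template_v)
    B <- qr.coef(qx, D)                     # K x 136
  } else {
    Xi <- cbind(`(Intercept)` = 1, X)
    B_all <- qr.coef(qr(Xi), Y)             # (K+1) x 136
    template_v <- B_all[1, ]
    B <- B_all[-1, , drop = FALSE]
  }
  au_face_model(matrix(template_v, 68, 2), t(B), au_names)
}

#' Normalize landmark rows by translation and scale
#'
#' Centers each 136-vector landmark row at the origin and rescales it to unit
#' interocular distance (optionally to unit centroid size). Rotation is not
#' removed: head-rotation robustness is evaluated explicitly rather than
#' silently corrected.
#'
#' @param landmark_matrix `n x 136` matrix (x-block then y-block).
#' @return Matrix of the same shape in the normalized frame.
#' @export
procrustes_normalize <- function(landmark_matrix) {
  Y <- as.matrix(landmark_matrix)
  t(apply(Y, 1, function(v) {
    p <- matrix(v, 68, 2)
    p <- sweep(p, 2, colMeans(p))
    as.vector(p / interocular_distance(landmarks68(p)))
  }))
}

#' Generate landmarks from AU activations
#'
#' `template + reshape(W %*% au)`: linear, so displacements are additive in
#' the activation vector and a zero vector reproduces the template exactly.
#'
#' @param model An [au_face_model()].
#' @param au Numeric activation vector of length K, or a named vector whose
#'   names are matched against the model's AU names (missing AUs are 0).
#' @return A [landmarks68()] in the model's normalized frame.
#' @export
generate_landmarks <- function(model, au) {
  stopifnot(inherits(model, "au_face_model"))
  au <- expand_au(model, au)
  v <- c(model$template[, 1], model$template[, 2]) + as.vector(model$W %*% au)
  landmarks68(matrix(v, 68, 2))
}

expand_au <- function(model, au) {
  K <- length(model$au_names)
  if (!is.null(names(au))) {
    unknown <- setdiff(names(au), model$au_names)
    if (length(unknown))
      stop(sprintf("unknown AU name(s): %s", paste(unknown, collapse = ", ")))
    full <- stats::setNames(numeric(K), model$au_names)
    full[names(au)] <- au
    au <- full
  }
  if (length(au) != K)
    stop(sprintf("activation vector must have length %d", K))
  if (!all(is.finite(au))) stop("activation vector must be finite")
  as.numeric(au)
}

#' @export
predict.au_face_model <- function(object, au, ...) generate_landmarks(object, au)

#' Muscle heatmap anchors
#'
#' Hand-curated anchor landmarks and falloff scales locating each AU's
#' muscle group on the template: brows for AU1/2/4, upper lids for AU5,
#' cheeks (below the lower lids) for AU6, the nose root for AU9, mouth
#' corners for AU12/15/20, the chin for AU17/26 and the lips for AU25.
#'
#' @return A data frame with columns `au`, `landmark` (1-based index),
#'   `dx`, `dy` (offset from the anchor, normalized units) and `sigma`
#'   (radial falloff, normalized units).
#' @export
default_heatmap_spec <- function() {
  d <- rbind(
    data.frame(au = "AU01", landmark = c(22, 23), dx = 0, dy = -0.05),
    data.frame(au = "AU02", landmark = c(18, 27), dx = 0, dy = -0.05),
    data.frame(au = "AU04", landmark = c(21, 24), dx = 0, dy = 0.03),
    data.frame(au = "AU05", landmark = c(39, 44), dx = 0, dy = -0.04),
    data.frame(au = "AU06", landmark = c(41, 47), dx = c(-0.1, 0.1), dy = 0.15),
    data.frame(au = "AU09", landmark = 28, dx = 0, dy = 0),
    data.frame(au = "AU12", landmark = c(49, 55), dx = c(-0.05, 0.05), dy = 0),
    data.frame(au = "AU15", landmark = c(49, 55), dx = 0, dy = 0.06),
    data.frame(au = "AU17", landmark = 9, dx = 0, dy = -0.15),
    data.frame(au = "AU20", landmark = c(49, 55), dx = c(-0.08, 0.08), dy = 0.02),
    data.frame(au = "AU25", landmark = c(52, 58), dx = 0, dy = 0),
    data.frame(au = "AU26", landmark = 9, dx = 0, dy = -0.05))
  d$sigma <- 0.12
  d
}

#' Render a stylized face from AU activations
#'
#' Generates landmarks with [generate_landmarks()], places them on the canvas
#' and rasterizes a stylized anonymous face (polyline jaw/brows/nose, filled
#' eyes and mouth). With a heatmap spec, each active AU additionally brightens
#' the canvas around its muscle anchors in proportion to its activation,
#' truncated at three falloff scales so the overlay has finite support.
#' Rendering is fully deterministic: identical inputs give identical pixels.
#'
#' @param model An [au_face_model()].
#' @param au Activation vector (as in [generate_landmarks()]).
#' @param heatmap `NULL` for no overlay, or a spec like
#'   [default_heatmap_spec()].
#' @param canvas `(rows, cols)` canvas size in pixels.
#' @return A `rows x cols` numeric matrix in `[0, 1]` of class
#'   `"face_raster"`, with the pixel-frame landmarks in attribute
#'   `"landmarks"`.
#' @export
plot_face <- function(model, au = 0, heatmap = NULL, canvas = c(256, 256)) {
  stopifnot(inherits(model, "au_face_model"), all(canvas >= 8))
  if (identical(au, 0)) au <- numeric(length(model$au_names))
  au <- expand_au(model, au)
  lms <- generate_landmarks(model, au)
  tr <- canvas_transform(canvas)
  lms_px <- apply_canvas_transform(lms, tr)
  img <- render_face_raster(lms_px, canvas)
  if (!is.null(heatmap)) {
    img <- overlay_heatmap(img, model, au, heatmap, tr)
  }
  structure(img, landmarks = landmarks68(lms_px), class = c("face_raster", "matrix", "array"))
}

overlay_heatmap <- function(img, model, au, spec, tr) {
  names(au) <- model$au_names
  active <- spec[spec$au %in% model$au_names & au[spec$au] > 0, , drop = FALSE]
  if (nrow(active) == 0L) return(img)
  tmpl <- model$template
  nr <- nrow(img); nc <- ncol(img)
  for (i in seq_len(nrow(active))) {
    a <- active[i, ]
    cx <- (tmpl[a$landmark, 1] + a$dx) * tr$scale + tr$cx
    cy <- (tmpl[a$landmark, 2] + a$dy) * tr$scale + tr$cy
    sg <- a$sigma * tr$scale
    act <- min(1, au[[a$au]])
    r0 <- max(1L, floor(cy - 3 * sg) + 1L); r1 <- min(nr, ceiling(cy + 3 * sg) + 1L)
    c0 <- max(1L, floor(cx - 3 * sg) + 1L); c1 <- min(nc, ceiling(cx + 3 * sg) + 1L)
    if (r0 > r1 || c0 > c1) next
    rows <- r0:r1; cols <- c0:c1
    px <- rep(cols - 1, each = length(rows))
    py <- rep(rows - 1, times = length(cols))
    d2 <- (px - cx)^2 + (py - cy)^2
    wgt <- act * exp(-d2 / (2 * sg^2))
    wgt[d2 > (3 * sg)^2] <- 0
    w <- matrix(0.65 * wgt, nrow = length(rows))
    sub <- img[rows, cols, drop = FALSE]
    img[rows, cols] <- sub * (1 - w) + 0.98 * w
  }
  img
}

#' @export
plot.face_raster <- function(x, ...) {
  op <- graphics::par(mar = c(0, 0, 0, 0)); on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(unclass(x)), 0, 0, 1, 1)
  invisible(x)
}

#' Morph one expression into another
#'
#' Linearly interpolates the activation vector between `start_au` and
#' `end_au` over `n_frames` frames and renders each with [plot_face()]. The
#' endpoint frames equal the static renders of the endpoints, and landmark
#' trajectories are affine in the frame index.
#'
#' @param model An [au_face_model()].
#' @param start_au,end_au Activation vectors (named vectors allowed).
#' @param n_frames Number of frames, at least 2.
#' @inheritParams plot_face
#' @return A list of `"face_raster"` frames with the interpolated activation
#'   matrix in attribute `"au_path"`.
#' @export
animate_face <- function(model, start_au, end_au, n_frames = 10,
                         heatmap = NULL, canvas = c(256, 256)) {
  if (n_frames < 2) stop("animate_face: n_frames must be at least 2")
  a <- expand_au(model, start_au)
  b <- expand_au(model, end_au)
  path <- t(vapply(seq_len(n_frames), function(i) {
    w <- (i - 1) / (n_frames - 1)
    a + w * (b - a)
  }, numeric(length(a))))
  colnames(path) <- model$au_names
  frames <- lapply(seq_len(n_frames), function(i)
    plot_face(model, path[i, ], heatmap = heatmap, canvas = canvas))
  attr(frames, "au_path") <- path
  frames
}
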