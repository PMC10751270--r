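#' @title Landmark, box and pose types
#' @name geometry
#' @description
#' The geometric backbone of the toolkit: face bounding boxes, the standard
#' 68-point facial landmark scheme, and head pose angles, plus the utilities
#' (interocular distance, convex-hull masks, region boxes) that the feature
#' extraction, robustness and evaluation stages consume.
#'
#' Conventions: pixel coordinates are 0-based with x increasing rightward and
#' y increasing downward; a pixel at matrix position `[r, c]` has its center at
#' `(x, y) = (c - 1, r - 1)`. Boxes are `(x, y, w, h)` with `(x, y)` the
#' top-left corner. Pixels whose centers lie on a hull boundary count as
#' inside.
NULL

#' Face bounding box
#'
#' @param x,y Top-left corner in pixels (0-based).
#' @param w,h Width and height in pixels; must be strictly positive.
#' @param score Detection confidence in `[0, 1]`.
#' @return An object of class `"bbox"`: a named list with fields
#'   `x`, `y`, `w`, `h`, `score`.
#' @examples
#' bbox(10, 20, 100, 120, score = 0.9)
#' @export
bbox <- function(x, y, w, h, score = 1) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(w), is.numeric(h))
  if (!is.finite(w) || !is.finite(h) || w <= 0 || h <= 0)
    stop("bbox: width and height must be finite and strictly positive")
  if (!is.finite(score) || score < 0 || score > 1)
    stop("bbox: score must lie in [0, 1]")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 w = as.numeric(w), h = as.numeric(h),
                 score = as.numeric(score)),
            class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox x=%.2f y=%.2f w=%.2f h=%.2f score=%.3f>\n",
              x$x, x$y, x$w, x$h, x$score))
  invisible(x)
}

# Region index sets of the 68-point scheme, 1-based (the conventional scheme
# numbers points 0-67; R storage is 1-based so region k here holds indices
# k0 + 1). The sets partition 1:68.
landmark_regions <- function() {
  list(jaw        = 1:17,   # 0-16
       brow_right = 18:22,  # 17-21
       brow_left  = 23:27,  # 22-26
       nose       = 28:36,  # 27-35
       eye_right  = 37:42,  # 36-41
       eye_left   = 43:48,  # 42-47
       mouth      = 49:68)  # 48-67
}

#' 68-point facial landmark set
#'
#' Validates and classes a 68 x 2 matrix of pixel coordinates following the
#' standard scheme: jaw 0-16, right brow 17-21, left brow 22-26, nose 27-35,
#' right eye 36-41, left eye 42-47, mouth 48-67 (0-based point numbers; rows
#' 1-68 of the matrix).
#'
#' @param points A 68 x 2 numeric matrix (columns x, y) or a length-136 vector
#'   ordered as all x then all y.
#' @return A 68 x 2 matrix of class `"landmarks68"` with columns `x`, `y`.
#' @examples
#' lms <- landmarks68(cbind(runif(68, 0, 100), runif(68, 0, 100)))
#' interocular_distance(lms)
#' @export
landmarks68 <- function(points) {
  if (is.numeric(points) && is.null(dim(points)) && length(points) == 136L)
    points <- matrix(points, ncol = 2L)
  points <- as.matrix(points)
  if (!is.numeric(points) || nrow(points) != 68L || ncol(points) != 2L)
    stop("landmarks68: expected 68 (x, y) points")
  if (!all(is.finite(points)))
    stop("landmarks68: all coordinates must be finite")
  storage.mode(points) <- "double"
  dimnames(points) <- list(NULL, c("x", "y"))
  class(points) <- c("landmarks68", "matrix", "array")
  points
}

as_landmarks68 <- function(x) {
  if (inherits(x, "landmarks68")) x else landmarks68(x)
}

#' @export
print.landmarks68 <- function(x, ...) {
  cat("<landmarks68>  68 points, x in [",
      sprintf("%.1f, %.1f", min(x[, 1]), max(x[, 1])),
      "], y in [", sprintf("%.1f, %.1f", min(x[, 2]), max(x[, 2])), "]\n")
  invisible(x)
}

#' Head pose angles
#'
#' @param pitch,roll,yaw Rotation angles in degrees about the x, y and z axes.
#' @return An object of class `"head_pose"`.
#' @export
head_pose <- function(pitch = 0, roll = 0, yaw = 0) {
  v <- c(pitch = as.numeric(pitch), roll = as.numeric(roll),
         yaw = as.numeric(yaw))
  if (!all(is.finite(v))) stop("head_pose: angles must be finite (degrees)")
  structure(as.list(v), class = "head_pose")
}

#' Interocular distance of a landmark set
#'
#' The Euclidean distance between the two eye centers, where each eye center
#' is the mean of its six eye landmarks (points 36-41 and 42-47 in 0-based
#' numbering). This is the normalizer used by the landmark error metric.
#' The eye-center definition (rather than outer corners) is deliberate: it is
#' stable under per-point jitter.
#'
#' @param lms A [landmarks68()] object or 68 x 2 matrix.
#' @return A positive scalar, in the units of the landmark coordinates.
#' @export
interocular_distance <- function(lms) {
  lms <- as_landmarks68(lms)
  reg <- landmark_regions()
  c_r <- colMeans(lms[reg$eye_right, , drop = FALSE])
  c_l <- colMeans(lms[reg$eye_left, , drop = FALSE])
  d <- sqrt(sum((c_r - c_l)^2))
  if (!is.finite(d) || d <= 0)
    stop("interocular_distance: eye centers coincide; degenerate geometry")
  d
}

# Orient polygon vertices counter-clockwise in the y-down pixel frame.
# Returns the vertex matrix reordered so the signed area is non-negative.
orient_ccw <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  a <- sum(x * y2 - x2 * y) / 2
  if (a < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

# Points-in-convex-polygon, boundary inclusive. px, py vectors; poly CCW.
points_in_convex <- function(px, py, poly, eps = 1e-9) {
  inside <- rep(TRUE, length(px))
  n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- poly[j, 1] - poly[i, 1]
    ey <- poly[j, 2] - poly[i, 2]
    cr <- ex * (py - poly[i, 2]) - ey * (px - poly[i, 1])
    inside <- inside & (cr >= -eps)
    if (!any(inside)) break
  }
  inside
}

#' Convex hull mask of a landmark set
#'
#' Rasterizes the convex hull of the 68 landmark points into a binary mask:
#' a pixel is `TRUE` exactly when its center lies inside or on the hull,
#' clipped to the image. This is the mask used to restrict HOG features to the
#' face region.
#'
#' @param lms A [landmarks68()] object or 68 x 2 matrix, in pixel coordinates
#'   of the target image.
#' @param image_shape Integer vector `(rows, cols)`.
#' @return A logical `rows x cols` matrix.
#' @export
convex_hull_mask <- function(lms, image_shape) {
  lms <- as_landmarks68(lms)
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 1L))
  hull_idx <- grDevices::chull(lms[, 1], lms[, 2])
  if (length(hull_idx) < 3L)
    stop("convex_hull_mask: landmarks are collinear; degenerate geometry")
  poly <- orient_ccw(lms[hull_idx, , drop = FALSE])
  nr <- image_shape[1]; nc <- image_shape[2]
  px <- rep(seq_len(nc) - 1, each = nr)   # x = col - 1
  py <- rep(seq_len(nr) - 1, times = nc)  # y = row - 1
  matrix(points_in_convex(px, py, poly), nrow = nr, ncol = nc)
}

# Landmark index sets for occludable regions. The eyes region deliberately
# includes the brows: the brow action units (1, 2, 4) live there and an eye
# mask that spares brows would not lesion them.
region_indices <- function(region) {
  reg <- landmark_regions()
  switch(region,
         eyes  = c(reg$eye_right, reg$eye_left, reg$brow_right, reg$brow_left),
         nose  = reg$nose,
         mouth = reg$mouth,
         stop(sprintf("region_box: unknown region '%s' (use eyes, nose or mouth)",
                      region)))
}

#' Axis-aligned box around a landmark region
#'
#' Tight box around the named region's landmarks (eyes includes the brows),
#' expanded by `pad` pixels on every side and clipped to the image when
#' `image_shape` is supplied. Used to place occlusion masks.
#'
#' @param lms A [landmarks68()] object or 68 x 2 matrix.
#' @param region One of `"eyes"`, `"nose"`, `"mouth"`.
#' @param pad Non-negative padding in pixels.
#' @param image_shape Optional `(rows, cols)` to clip against.
#' @return A [bbox()].
#' @export
region_box <- function(lms, region = c("eyes", "nose", "mouth"), pad = 0,
                       image_shape = NULL) {
  region <- match.arg(region)
  stopifnot(pad >= 0)
  lms <- as_landmarks68(lms)
  pts <- lms[region_indices(region), , drop = FALSE]
  x0 <- min(pts[, 1]) - pad
  y0 <- min(pts[, 2]) - pad
  x1 <- max(pts[, 1]) + pad
  y1 <- max(pts[, 2]) + pad
  if (!is.null(image_shape)) {
    nr <- image_shape[1]; nc <- image_shape[2]
    x0 <- max(x0, 0); y0 <- max(y0, 0)
    x1 <- min(x1, nc - 1); y1 <- min(y1, nr - 1)
    if (x1 <= x0 || y1 <= y0)
      stop("region_box: region falls entirely outside the image")
  }
  bbox(x0, y0, x1 - x0, y1 - y0, score = 1)
}
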