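#' @title Robustness perturbations
#' @name robustness
#' @description
#' The image perturbations used to probe detector robustness: global
#' luminance scaling, landmark-guided black-mask occlusion of the eyes, nose
#' or mouth, and in-plane rotation about the face center. All operate on
#' grayscale matrices with intensities in `[0, 1]`.
NULL

#' Perturb image luminance
#'
#' Multiplies all intensities by a brightness factor drawn uniformly from
#' `[0.1, 0.8]` (level `"low"`) or `[1.2, 1.9]` (level `"high"`), then clips
#' to `[0, 1]`. The drawn factor is returned for audit; a fixed `factor`
#' bypasses sampling (test hook).
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param level `"low"` or `"high"`.
#' @param seed Integer seed for the factor draw.
#' @param factor Optional fixed factor overriding the draw.
#' @return List with `image` (perturbed) and `factor`.
#' @export
perturb_brightness <- function(image, level = c("low", "high"), seed = 1,
                               factor = NULL) {
  level <- match.arg(level)
  if (is.null(factor)) {
    rng <- if (level == "low") c(0.1, 0.8) else c(1.2, 1.9)
    factor <- with_seed(seed, stats::runif(1, rng[1], rng[2]))
  }
  out <- pmin(pmax(image * factor, 0), 1)
  list(image = out, factor = factor)
}

#' Occlude a facial region with a black mask
#'
#' Sets every pixel inside the padded [region_box()] of the named region to
#' zero; all other pixels are untouched. The eyes region includes the brows.
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param lms [landmarks68()] in the image's pixel frame.
#' @param region `"eyes"`, `"nose"` or `"mouth"`.
#' @param pad Mask padding in pixels (default 2).
#' @return The occluded image.
#' @export
occlude <- function(image, lms, region = c("eyes", "nose", "mouth"), pad = 2) {
  region <- match.arg(region)
  box <- tryCatch(region_box(lms, region, pad = pad,
                             image_shape = dim(image)),
                  error = function(e) NULL)
  if (is.null(box)) {
    warning("occlude: region box empty after clipping; image unchanged")
    return(image)
  }
  # pixel centers at (col-1, row-1); mask centers inside [x, x+w] x [y, y+h]
  c0 <- max(1L, ceiling(box$x) + 1L)
  c1 <- min(ncol(image), floor(box$x + box$w) + 1L)
  r0 <- max(1L, ceiling(box$y) + 1L)
  r1 <- min(nrow(image), floor(box$y + box$h) + 1L)
  if (c0 > c1 || r0 > r1) {
    warning("occlude: region box empty after clipping; image unchanged")
    return(image)
  }
  image[r0:r1, c0:c1] <- 0
  image
}

#' Rotate a face image and its landmarks in-plane
#'
#' Rotates pixels and landmarks consistently by `degrees` (counter-clockwise
#' in the y-down pixel frame) about the landmark centroid. Pixels sampled
#' from outside the source image are filled with the median border intensity
#' (or `fill` if given). This is an in-plane stand-in for out-of-plane head
#' rotation, and is labeled as such wherever results are reported.
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param lms [landmarks68()].
#' @param degrees Rotation angle; the conventional evaluation grid is
#'   0, 15, 30, 45 but any angle is accepted.
#' @param fill Out-of-frame fill intensity; default is the median of the
#'   image border.
#' @return List with `image` and `landmarks`, both rotated.
#' @export
rotate_face <- function(image, lms, degrees, fill = NULL) {
  lms <- as_landmarks68(lms)
  th <- degrees * pi / 180
  ct <- cos(th); st <- sin(th)
  cx <- mean(lms[, 1]); cy <- mean(lms[, 2])
  if (is.null(fill)) {
    border <- c(image[1, ], image[nrow(image), ], image[, 1], image[, ncol(image)])
    fill <- stats::median(border)
  }
  # forward-rotate landmarks
  dx <- lms[, 1] - cx; dy <- lms[, 2] - cy
  lms_r <- landmarks68(cbind(cx + ct * dx - st * dy,
                             cy + st * dx + ct * dy))
  # inverse-map pixels
  nr <- nrow(image); nc <- ncol(image)
  gx <- rep(seq_len(nc) - 1, each = nr)
  gy <- rep(seq_len(nr) - 1, times = nc)
  rx <- gx - cx; ry <- gy - cy
  sx <- cx + ct * rx + st * ry
  sy <- cy - st * rx + ct * ry
  vals <- bilinear_sample(image, sx, sy, fill = fill)
  out <- matrix(vals, nrow = nr, ncol = nc)
  list(image = out, landmarks = lms_r)
}
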