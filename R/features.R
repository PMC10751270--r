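#' @title HOG/PCA preprocessing front end
#' @name features
#' @description
#' The preprocessing stages of the AU and emotion pipeline: standardize a
#' face region into a fixed-size grayscale patch, extract histogram of
#' oriented gradients (HOG) features restricted to the landmark convex hull,
#' and compress the feature space with principal components analysis. The
#' whole path is deterministic: the same image, landmarks and parameters give
#' a bit-identical feature vector.
NULL

#' Detector preprocessing configuration
#'
#' Default values follow the conventional HOG setup: a 112 x 112 patch,
#' 8 x 8 pixel cells, 2 x 2 cell blocks with L2-Hys normalization, and 8
#' unsigned orientation bins; PCA keeps 95% of the training variance.
#'
#' @param patch_size Patch side in pixels (>= 32, divisible by `hog_cell`).
#' @param hog_orientations Number of unsigned orientation bins (>= 2).
#' @param hog_cell Cell side in pixels.
#' @param hog_block Block side in cells.
#' @param pca_retained_variance Fraction of variance the PCA basis retains.
#' @return A named list of class `"detector_config"`.
#' @export
detector_config <- function(patch_size = 112L, hog_orientations = 8L,
                            hog_cell = 8L, hog_block = 2L,
                            pca_retained_variance = 0.95) {
  stopifnot(patch_size >= 32, patch_size %% hog_cell == 0,
            hog_orientations >= 2, hog_block >= 1,
            pca_retained_variance > 0, pca_retained_variance <= 1)
  structure(list(patch_size = as.integer(patch_size),
                 hog_orientations = as.integer(hog_orientations),
                 hog_cell = as.integer(hog_cell),
                 hog_block = as.integer(hog_block),
                 pca_retained_variance = pca_retained_variance),
            class = "detector_config")
}

# Bilinear sampling of image at (x, y) pixel-center coordinates; outside -> fill.
bilinear_sample <- function(image, x, y, fill = 0) {
  nr <- nrow(image); nc <- ncol(image)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  get_px <- function(xi, yi) {
    ok <- xi >= 0 & xi <= nc - 1 & yi >= 0 & yi <= nr - 1
    v <- rep(fill, length(xi))
    v[ok] <- image[cbind(yi[ok] + 1, xi[ok] + 1)]
    v
  }
  v00 <- get_px(x0, y0); v10 <- get_px(x0 + 1, y0)
  v01 <- get_px(x0, y0 + 1); v11 <- get_px(x0 + 1, y0 + 1)
  (v00 * (1 - fx) + v10 * fx) * (1 - fy) + (v01 * (1 - fx) + v11 * fx) * fy
}

#' Standardize a face region into a fixed-size patch
#'
#' Applies a similarity transform (uniform scale plus translation, no
#' rotation) that maps the landmark bounding box, expanded by 10%, onto a
#' `P x P` patch, resampling the image bilinearly. The landmarks are carried
#' through the same transform and their convex hull becomes the patch mask;
#' the masked view zeroes every pixel outside the hull.
#'
#' @param image Grayscale matrix with intensities in `[0, 1]`.
#' @param lms [landmarks68()] in the image's pixel frame.
#' @param patch_size Patch side `P` (>= 32).
#' @return An object of class `"face_patch"`: list with `pixels` (the aligned
#'   crop), `masked` (hull-masked view), `hull_mask`, `landmarks`
#'   (patch-frame), and `transform` (`scale`, `cx_src`, `cy_src`, `cx_dst`,
#'   `cy_dst` such that `p_dst = (p_src - c_src) * scale + c_dst`).
#' @export
align_crop <- function(image, lms, patch_size = 112L) {
  stopifnot(is.matrix(image), patch_size >= 32)
  lms <- as_landmarks68(lms)
  P <- as.integer(patch_size)
  x0 <- min(lms[, 1]); x1 <- max(lms[, 1])
  y0 <- min(lms[, 2]); y1 <- max(lms[, 2])
  if (x1 < 0 || y1 < 0 || x0 > ncol(image) - 1 || y0 > nrow(image) - 1)
    stop("align_crop: landmark hull lies entirely outside the image")
  we <- (x1 - x0) * 1.1
  he <- (y1 - y0) * 1.1
  if (we <= 0 && he <= 0) stop("align_crop: degenerate landmark box")
  s <- P / max(we, he)
  cx_src <- (x0 + x1) / 2; cy_src <- (y0 + y1) / 2
  cx_dst <- (P - 1) / 2;   cy_dst <- (P - 1) / 2
  # inverse map patch pixel centers to source coordinates
  gx <- rep(seq_len(P) - 1, each = P)    # x = col - 1
  gy <- rep(seq_len(P) - 1, times = P)   # y = row - 1
  sx <- (gx - cx_dst) / s + cx_src
  sy <- (gy - cy_dst) / s + cy_src
  vals <- bilinear_sample(image, sx, sy, fill = 0)
  pixels <- matrix(vals, nrow = P, ncol = P)  # filled column-wise: col = x + 1
  lms_p <- landmarks68(cbind((lms[, 1] - cx_src) * s + cx_dst,
                             (lms[, 2] - cy_src) * s + cy_dst))
  mask <- convex_hull_mask(lms_p, c(P, P))
  structure(list(pixels = pixels,
                 masked = pixels * mask,
                 hull_mask = mask,
                 landmarks = lms_p,
                 transform = list(scale = s, cx_src = cx_src, cy_src = cy_src,
                                  cx_dst = cx_dst, cy_dst = cy_dst)),
            class = "face_patch")
}

#' @export
print.face_patch <- function(x, ...) {
  cat(sprintf("<face_patch %dx%d, scale %.3f, %.0f%% of pixels in hull>\n",
              nrow(x$pixels), ncol(x$pixels), x$transform$scale,
              100 * mean(x$hull_mask)))
  invisible(x)
}

#' Histogram of oriented gradients over a hull-masked patch
#'
#' Standard unsigned-gradient HOG: central-difference gradients, orientation
#' folded to `[0, pi)` and hard-assigned to one of `orientations` bins,
#' magnitude-weighted 'cell' histograms, and overlapping `block x block` cell
#' blocks normalized with L2-Hys (L2 norm, clip at 0.2, renormalize). Pixels
#' outside the convex hull are zeroed before the gradient computation, which
#' intentionally leaves a gradient edge along the hull boundary (the face
#' outline). The output length is
#' `(P/cell - block + 1)^2 * block^2 * orientations` and does not depend on
#' the image content.
#'
#' @param patch A [align_crop()] patch, or a plain numeric matrix (used
#'   unmasked).
#' @param orientations Number of unsigned orientation bins.
#' @param cell Cell side in pixels (must divide the patch side).
#' @param block Block side in cells.
#' @return A non-negative numeric feature vector.
#' @export
hog_features <- function(patch, orientations = 8L, cell = 8L, block = 2L) {
  img <- if (inherits(patch, "face_patch")) patch$masked else as.matrix(patch)
  P <- nrow(img)
  stopifnot(ncol(img) == P, P %% cell == 0, orientations >= 2)
  cps <- P %/% cell                      # cells per side
  if (block > cps) stop("hog_features: block larger than the cell grid")
  # central differences with replicated borders
  left  <- img[, c(1, seq_len(P - 1))]
  right <- img[, c(seq_len(P - 1) + 1, P)]
  up    <- img[c(1, seq_len(P - 1)), ]
  down  <- img[c(seq_len(P - 1) + 1, P), ]
  gx <- (right - left) / 2
  gy <- (down - up) / 2
  mag <- sqrt(gx^2 + gy^2)
  theta <- atan2(gy, gx) %% pi           # unsigned orientation in [0, pi)
  bin <- pmin(floor(theta / (pi / orientations)), orientations - 1)
  # cell id per pixel (row-major over the cell grid)
  rows <- row(img) - 1L; cols <- col(img) - 1L
  cell_id <- (rows %/% cell) * cps + (cols %/% cell)   # 0 .. cps^2-1
  idx <- cell_id * orientations + bin + 1L
  hist <- numeric(cps * cps * orientations)
  acc <- rowsum(as.vector(mag), as.vector(idx))
  hist[as.integer(rownames(acc))] <- acc
  # hist laid out as [cell0 bins, cell1 bins, ...] with cell index row-major
  ch <- matrix(hist, nrow = orientations)              # orientations x cells
  nb <- cps - block + 1L
  out <- numeric(nb * nb * block * block * orientations)
  pos <- 1L
  blk_len <- block * block * orientations
  for (bi in 0:(nb - 1L)) {
    for (bj in 0:(nb - 1L)) {
      cells <- as.vector(outer(bj:(bj + block - 1L),
                               (bi:(bi + block - 1L)) * cps, `+`)) + 1L
      v <- as.vector(ch[, cells])
      nrm <- sqrt(sum(v^2) + 1e-10)
      v <- pmin(v / nrm, 0.2)
      nrm2 <- sqrt(sum(v^2) + 1e-10)
      out[pos:(pos + blk_len - 1L)] <- v / nrm2
      pos <- pos + blk_len
    }
  }
  out
}

#' Fit a PCA basis by retained variance
#'
#' Principal components of the sample covariance (via [stats::prcomp()]);
#' the basis keeps the smallest number of leading components whose cumulative
#' explained-variance fraction reaches `retained_variance`.
#'
#' @param feature_matrix `n x d` matrix, `n >= 2`.
#' @param retained_variance Fraction in `(0, 1]`.
#' @return An object of class `"pca_basis"`: list with `mean` (length d),
#'   `components` (`k x d`, orthonormal rows), `explained_variance`
#'   (per-component fractions, non-increasing) and `k`.
#' @export
fit_pca <- function(feature_matrix, retained_variance = 0.95) {
  X <- as.matrix(feature_matrix)
  stopifnot(nrow(X) >= 2, retained_variance > 0, retained_variance <= 1)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  var_tot <- sum(pc$sdev^2)
  if (var_tot <= 0) stop("fit_pca: zero-variance input; degenerate data")
  evr <- pc$sdev^2 / var_tot
  k <- which(cumsum(evr) >= retained_variance - 1e-12)[1]
  if (is.na(k)) k <- length(evr)
  structure(list(mean = pc$center,
                 components = t(pc$rotation[, seq_len(k), drop = FALSE]),
                 explained_variance = evr[seq_len(k)],
                 k = k,
                 retained_variance = retained_variance),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("PCA basis: %d components over %d features (%.1f%% variance)\n",
              x$k, length(x$mean), 100 * sum(x$explained_variance)))
  invisible(x)
}

#' Project features onto a PCA basis
#'
#' Centered projection: `(x - mean) %*% t(components)`. At
#' `retained_variance = 1` projecting and reconstructing a training row is
#' exact.
#'
#' @param basis A [fit_pca()] basis.
#' @param features A vector of length d or an `n x d` matrix.
#' @return A score vector of length k or an `n x k` matrix.
#' @export
pca_project <- function(basis, features) {
  stopifnot(inherits(basis, "pca_basis"))
  one <- is.null(dim(features))
  X <- if (one) matrix(features, nrow = 1) else as.matrix(features)
  if (ncol(X) != length(basis$mean))
    stop(sprintf("pca_project: feature dimension %d does not match basis dimension %d",
                 ncol(X), length(basis$mean)))
  S <- sweep(X, 2, basis$mean) %*% t(basis$components)
  if (one) drop(S) else S
}

#' Reconstruct features from PCA scores
#'
#' @param basis A [fit_pca()] basis.
#' @param scores Score vector or `n x k` matrix.
#' @return Reconstructed features in the original space.
#' @export
pca_reconstruct <- function(basis, scores) {
  stopifnot(inherits(basis, "pca_basis"))
  one <- is.null(dim(scores))
  S <- if (one) matrix(scores, nrow = 1) else as.matrix(scores)
  X <- sweep(S %*% basis$components, 2, basis$mean, `+`)
  if (one) drop(X) else X
}
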