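# Independent oracles used by the tests. These deliberately use different
# algorithms from the package implementations they check.

# Even-odd ray-crossing point-in-polygon test (the package uses a convex
# half-plane test). Boundary points are resolved separately.
oracle_point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-segment check (boundary counts as inside)
    cr <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    if (abs(cr) < eps &&
        px >= min(xi, xj) - eps && px <= max(xi, xj) + eps &&
        py >= min(yi, yj) - eps && py <= max(yi, yj) + eps) return(TRUE)
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Brute-force average precision: for every prefix of the score-ranked
# predictions, re-run greedy matching from scratch to get one PR point, then
# integrate the interpolated curve point by point.
oracle_average_precision <- function(pred, gt, iou_threshold = 0.5) {
  box_iou <- function(a, b) {
    ix <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
    iy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
    inter <- ix * iy
    inter / (a$w * a$h + b$w * b$h - inter)
  }
  ord <- order(-pred$score)
  pred <- pred[ord, , drop = FALSE]
  npred <- nrow(pred)
  prec <- numeric(npred); rec <- numeric(npred)
  for (k in seq_len(npred)) {
    matched <- rep(FALSE, nrow(gt))
    tp <- 0
    for (i in seq_len(k)) {
      best <- 0; best_iou <- -1
      for (j in seq_len(nrow(gt))) {
        if (matched[j] || gt$image[j] != pred$image[i]) next
        v <- box_iou(pred[i, ], gt[j, ])
        if (v > best_iou) { best_iou <- v; best <- j }
      }
      if (best > 0 && best_iou >= iou_threshold) {
        matched[best] <- TRUE
        tp <- tp + 1
      }
    }
    prec[k] <- tp / k
    rec[k] <- tp / nrow(gt)
  }
  ap <- 0
  prev_r <- 0
  for (k in seq_len(npred)) {
    p_interp <- max(prec[k:npred])
    ap <- ap + (rec[k] - prev_r) * p_interp
    prev_r <- rec[k]
  }
  ap
}

# Random valid boxes for AP fuzzing.
random_detection_instance <- function(n_gt, n_pred, n_images = 2) {
  rbox <- function(n, scored) {
    d <- data.frame(image = sample.int(n_images, n, replace = TRUE),
                    x = runif(n, 0, 20), y = runif(n, 0, 20),
                    w = runif(n, 2, 12), h = runif(n, 2, 12))
    if (scored) d$score <- runif(n)
    d
  }
  list(gt = rbox(n_gt, FALSE), pred = rbox(n_pred, TRUE))
}

# Random plausible landmark set: template jittered, scaled and translated.
random_landmarks <- function(scale = 30, jitter = 1, center = c(50, 50)) {
  tmpl <- unclass(fexkit::face_template68())
  pts <- tmpl * scale + matrix(rnorm(136, 0, jitter), 68, 2)
  pts[, 1] <- pts[, 1] + center[1]
  pts[, 2] <- pts[, 2] + center[2]
  fexkit::landmarks68(pts)
}
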