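# Internal deterministic rasterizer for stylized faces.
#
# Images are numeric matrices in [0, 1], row = y, col = x, pixel centers at
# (col - 1, row - 1). Everything here is pure arithmetic on the landmark
# polylines so that the same landmarks always produce bit-identical rasters.

# Blend anti-aliased coverage of one line segment into `img` (darkest wins).
# Coverage falls off linearly from 1 at the segment to 0 at distance `radius`.
draw_segment <- function(img, x1, y1, x2, y2, value = 0.05, radius = 0.9) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- max(1L, floor(min(y1, y2) - radius) + 1L)
  r1 <- min(nr, ceiling(max(y1, y2) + radius) + 1L)
  c0 <- max(1L, floor(min(x1, x2) - radius) + 1L)
  c1 <- min(nc, ceiling(max(x1, x2) + radius) + 1L)
  if (r0 > r1 || c0 > c1) return(img)
  rows <- r0:r1; cols <- c0:c1
  px <- rep(cols - 1, each = length(rows))
  py <- rep(rows - 1, times = length(cols))
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) rep(0, length(px)) else
    pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  d <- sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
  cov <- pmin(1, pmax(0, 1 - d / radius))
  sub <- img[rows, cols, drop = FALSE]
  blended <- sub * (1 - cov) + value * cov
  img[rows, cols] <- pmin(sub, blended)
  img
}

draw_polyline <- function(img, pts, value = 0.05, closed = FALSE, radius = 0.9) {
  n <- nrow(pts)
  idx <- if (closed) c(seq_len(n), 1L) else seq_len(n)
  for (i in seq_len(length(idx) - 1L)) {
    a <- idx[i]; b <- idx[i + 1L]
    img <- draw_segment(img, pts[a, 1], pts[a, 2], pts[b, 1], pts[b, 2],
                        value = value, radius = radius)
  }
  img
}

# Fill a polygon (boundary inclusive) with `value`, taking the darker pixel.
fill_polygon <- function(img, pts, value = 0.1) {
  nr <- nrow(img); nc <- ncol(img)
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(hull) < 3L) return(img)
  poly <- orient_ccw(pts[hull, , drop = FALSE])
  r0 <- max(1L, floor(min(pts[, 2])) + 1L)
  r1 <- min(nr, ceiling(max(pts[, 2])) + 1L)
  c0 <- max(1L, floor(min(pts[, 1])) + 1L)
  c1 <- min(nc, ceiling(max(pts[, 1])) + 1L)
  if (r0 > r1 || c0 > c1) return(img)
  rows <- r0:r1; cols <- c0:c1
  px <- rep(cols - 1, each = length(rows))
  py <- rep(rows - 1, times = length(cols))
  inside <- points_in_convex(px, py, poly)
  sub <- img[rows, cols, drop = FALSE]
  sub[matrix(inside, nrow = length(rows))] <-
    pmin(sub[matrix(inside, nrow = length(rows))], value)
  img[rows, cols] <- sub
  img
}

# Brighten a polygon interior toward `value` (lightest wins); used for the
# mouth opening so parted lips expose a bright tooth region with strong
# gradient contrast against the dark lips.
fill_bright_polygon <- function(img, pts, value = 0.85) {
  nr <- nrow(img); nc <- ncol(img)
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(hull) < 3L) return(img)
  poly <- orient_ccw(pts[hull, , drop = FALSE])
  r0 <- max(1L, floor(min(pts[, 2])) + 1L); r1 <- min(nr, ceiling(max(pts[, 2])) + 1L)
  c0 <- max(1L, floor(min(pts[, 1])) + 1L); c1 <- min(nc, ceiling(max(pts[, 1])) + 1L)
  if (r0 > r1 || c0 > c1) return(img)
  rows <- r0:r1; cols <- c0:c1
  px <- rep(cols - 1, each = length(rows))
  py <- rep(rows - 1, times = length(cols))
  inside <- matrix(points_in_convex(px, py, poly), nrow = length(rows))
  sub <- img[rows, cols, drop = FALSE]
  sub[inside] <- pmax(sub[inside], value)
  img[rows, cols] <- sub
  img
}

# Render a stylized face from 68 landmarks already in pixel coordinates.
# Mid-gray background; dark polylines for jaw/brows/nose; filled eye and
# mouth polygons so the raster has usable gradients for HOG.
render_face_raster <- function(lms_px, canvas, background = 0.5) {
  img <- matrix(background, nrow = canvas[1], ncol = canvas[2])
  reg <- landmark_regions()
  img <- draw_polyline(img, lms_px[reg$jaw, , drop = FALSE], value = 0.05)
  img <- draw_polyline(img, lms_px[reg$brow_right, , drop = FALSE], value = 0.05)
  img <- draw_polyline(img, lms_px[reg$brow_left, , drop = FALSE], value = 0.05)
  img <- draw_polyline(img, lms_px[28:31, , drop = FALSE], value = 0.05)  # bridge 27-30
  img <- draw_polyline(img, lms_px[32:36, , drop = FALSE], value = 0.05)  # base 31-35
  img <- fill_polygon(img, lms_px[reg$eye_right, , drop = FALSE], value = 0.12)
  img <- fill_polygon(img, lms_px[reg$eye_left, , drop = FALSE], value = 0.12)
  img <- fill_polygon(img, lms_px[49:60, , drop = FALSE], value = 0.30)   # outer lips
  img <- fill_bright_polygon(img, lms_px[61:68, , drop = FALSE], value = 0.85)  # mouth opening (teeth)
  img <- draw_polyline(img, lms_px[49:60, , drop = FALSE], value = 0.05, closed = TRUE)
  img
}

# Canvas placement shared by plot_face() and the synthetic generator: the
# normalized face frame (centroid 0, interocular distance 1) is scaled by
# min(canvas)/3.5 and centered on the canvas.
canvas_transform <- function(canvas) {
  s <- min(canvas) / 3.5
  list(scale = s,
       cx = (canvas[2] - 1) / 2,
       cy = (canvas[1] - 1) / 2)
}

apply_canvas_transform <- function(lms, tr) {
  out <- cbind(lms[, 1] * tr$scale + tr$cx, lms[, 2] * tr$scale + tr$cy)
  colnames(out) <- c("x", "y")
  out
}
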