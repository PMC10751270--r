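test_that("interocular distance: closed forms, invariances and recomputation", {
  # 3-4-5 triangle between the two eye centers
  pts <- matrix(0, 68, 2)
  pts[43:48, 1] <- 3; pts[43:48, 2] <- 4
  pts[1, ] <- c(-1, -1)  # avoid all-coincident non-eye points mattering
  expect_equal(interocular_distance(landmarks68(pts)), 5)

  set.seed(1)
  for (i in 1:20) {
    lms <- random_landmarks()
    d <- interocular_distance(lms)
    # direct re-evaluation oracle
    c_r <- colMeans(lms[37:42, ]); c_l <- colMeans(lms[43:48, ])
    expect_equal(d, sqrt(sum((c_r - c_l)^2)))
    # translation invariance
    shift <- landmarks68(sweep(unclass(lms), 2, c(runif(1, -9, 9), runif(1, -9, 9)), `+`))
    expect_equal(interocular_distance(shift), d)
    # rotation invariance
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    expect_equal(interocular_distance(landmarks68(unclass(lms) %*% R)), d)
    # linear scaling
    s <- runif(1, 0.2, 4)
    expect_equal(interocular_distance(landmarks68(unclass(lms) * s)), s * d)
  }
})

test_that("interocular distance rejects coincident eye centers", {
  pts <- matrix(rep(c(1, 2), each = 68), 68, 2)
  expect_error(interocular_distance(landmarks68(pts)), "degenerate")
})

test_that("landmark validation enforces shape and finiteness", {
  expect_error(landmarks68(matrix(0, 67, 2)), "68")
  bad <- matrix(0, 68, 2); bad[5, 1] <- NA
  expect_error(landmarks68(bad), "finite")
  reg <- fexkit:::landmark_regions()
  expect_equal(sort(unname(unlist(reg))), 1:68)  # regions partition the point set
})

test_that("convex hull mask matches a per-pixel point-in-polygon oracle", {
  set.seed(2)
  for (i in 1:5) {
    lms <- random_landmarks(scale = 8, jitter = 0.7, center = c(15, 14))
    mask <- convex_hull_mask(lms, c(30, 32))
    hull <- grDevices::chull(lms[, 1], lms[, 2])
    poly <- lms[hull, , drop = FALSE]
    oracle <- matrix(FALSE, 30, 32)
    for (r in seq_len(30)) {
      for (cc in seq_len(32)) {
        oracle[r, cc] <- oracle_point_in_polygon(cc - 1, r - 1, poly)
      }
    }
    expect_identical(mask, oracle)
  }
})

test_that("hull mask contains the landmarks and ignores point order", {
  set.seed(3)
  lms <- random_landmarks(scale = 10, jitter = 0.5, center = c(20, 20))
  pts <- round(unclass(lms))
  pts <- pmax(pts, 0); pts <- pmin(pts, 39)
  mask <- convex_hull_mask(landmarks68(pts), c(40, 40))
  for (i in 1:68) expect_true(mask[pts[i, 2] + 1, pts[i, 1] + 1])
  perm <- landmarks68(pts[sample(68), ])
  expect_equal(sum(convex_hull_mask(perm, c(40, 40))), sum(mask))
})

test_that("hull mask of an axis-aligned square has the square's area", {
  # 68 points on the boundary of [5.5, 15.5]^2 -> pixel centers 6..15
  side <- seq(5.5, 15.5, length.out = 18)
  pts <- rbind(cbind(side, 5.5), cbind(side, 15.5),
               cbind(5.5, side[2:17]), cbind(15.5, side[2:17]))
  mask <- convex_hull_mask(landmarks68(pts), c(25, 25))
  expect_equal(sum(mask), 100)
})

test_that("collinear landmarks are rejected as degenerate", {
  pts <- cbind(seq_len(68), 2 * seq_len(68) + 1)
  expect_error(convex_hull_mask(landmarks68(pts), c(10, 10)), "collinear")
})

test_that("region boxes: worked examples, oracle, and containment", {
  # mouth spanning x in [10, 30], y in [40, 50]
  pts <- matrix(5, 68, 2)
  pts[43:48, ] <- 6  # keep eyes distinct
  pts[49:68, 1] <- seq(10, 30, length.out = 20)
  pts[49:68, 2] <- rep(c(40, 50), 10)
  b <- region_box(landmarks68(pts), "mouth", pad = 0)
  expect_equal(c(b$x, b$y, b$w, b$h), c(10, 40, 20, 10))
  b5 <- region_box(landmarks68(pts), "mouth", pad = 5)
  expect_equal(c(b5$x, b5$y, b5$w, b5$h), c(5, 35, 30, 20))

  idx <- list(eyes = c(37:48, 18:27), nose = 28:36, mouth = 49:68)
  set.seed(4)
  for (i in 1:10) {
    lms <- random_landmarks()
    all_box <- c(min(lms[, 1]), min(lms[, 2]), max(lms[, 1]), max(lms[, 2]))
    for (region in names(idx)) {
      b <- region_box(lms, region, pad = 0)
      pts_r <- lms[idx[[region]], , drop = FALSE]
      expect_equal(c(b$x, b$y, b$x + b$w, b$y + b$h),
                   c(min(pts_r[, 1]), min(pts_r[, 2]),
                     max(pts_r[, 1]), max(pts_r[, 2])))
      expect_gte(b$x, all_box[1]); expect_gte(b$y, all_box[2])
      expect_lte(b$x + b$w, all_box[3]); expect_lte(b$y + b$h, all_box[4])
    }
  }
  expect_error(region_box(random_landmarks(), "chin"), "'arg'")
})

test_that("bounding box and pose types enforce their invariants", {
  expect_error(bbox(0, 0, -1, 5), "positive")
  expect_error(bbox(0, 0, 1, 5, score = 1.5), "\\[0, 1\\]")
  expect_error(head_pose(pitch = Inf), "finite")
  p <- head_pose(1, -2, 30)
  expect_equal(unlist(p), c(pitch = 1, roll = -2, yaw = 30))
})
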