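#' @title Evaluation metrics
#' @name metrics
#' @description
#' The benchmark metrics used to evaluate the detection stages: box
#' intersection-over-union and average precision for face detection,
#' interocular-normalized landmark error, per-axis head-pose mean absolute
#' error, and the F1 score for binary AU/emotion calls.
NULL

as_box_df <- function(x) {
  if (inherits(x, "bbox")) x <- data.frame(x = x$x, y = x$y, w = x$w, h = x$h,
                                           score = x$score)
  x <- as.data.frame(x)
  stopifnot(all(c("x", "y", "w", "h") %in% names(x)))
  if (any(x$w <= 0) || any(x$h <= 0)) stop("boxes must have positive size")
  x
}

#' Intersection over union of two boxes
#'
#' @param a,b [bbox()] objects or lists/rows with fields `x`, `y`, `w`, `h`.
#' @return Overlap fraction in `[0, 1]`.
#' @export
iou <- function(a, b) {
  ix <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- ix * iy
  union <- a$w * a$h + b$w * b$h - inter
  inter / union
}

#' Average precision of scored detections
#'
#' Benchmark-style evaluation: predictions are sorted by descending score (ties
#' broken by input order), each is greedily matched to the highest-IoU
#' unmatched ground-truth box of the same image at IoU at or above the
#' threshold, and the area under the resulting precision-recall curve is
#' computed with all-points interpolation (precision at each recall level is
#' the maximum precision at any equal-or-higher recall).
#'
#' @param pred Data frame of predictions: columns `image`, `x`, `y`, `w`,
#'   `h`, `score`.
#' @param gt Data frame of ground truth boxes: columns `image`, `x`, `y`,
#'   `w`, `h`. Must be non-empty.
#' @param iou_threshold Match threshold, default 0.5.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(pred, gt, iou_threshold = 0.5) {
  gt <- as_box_df(gt)
  if (nrow(gt) == 0L) stop("average_precision: empty ground truth; metric undefined")
  if (is.null(gt$image)) gt$image <- 1
  if (is.null(pred) || nrow(as.data.frame(pred)) == 0L) return(0)
  pred <- as_box_df(pred)
  if (is.null(pred$image)) pred$image <- 1
  stopifnot(!is.null(pred$score))
  ord <- order(-pred$score)             # stable: ties keep input order
  pred <- pred[ord, , drop = FALSE]
  matched <- rep(FALSE, nrow(gt))
  tp <- logical(nrow(pred))
  for (i in seq_len(nrow(pred))) {
    cand <- which(gt$image == pred$image[i] & !matched)
    if (!length(cand)) next
    ious <- vapply(cand, function(j) iou(pred[i, ], gt[j, ]), numeric(1))
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      tp[i] <- TRUE
      matched[cand[best]] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  prec <- cum_tp / seq_along(tp)
  rec <- cum_tp / nrow(gt)
  # all-points interpolation: running max of precision from the right
  prec_i <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec)) * prec_i)
}

#' Interocular-normalized landmark error
#'
#' Root mean squared error over the 68 point-wise Euclidean distances between
#' predicted and ground-truth landmarks, divided by the ground truth's
#' interocular distance.
#'
#' @param pred,gt [landmarks68()] objects or 68 x 2 matrices.
#' @return Non-negative normalized error.
#' @export
landmark_nme <- function(pred, gt) {
  pred <- as_landmarks68(pred); gt <- as_landmarks68(gt)
  d2 <- rowSums((unclass(pred) - unclass(gt))^2)
  sqrt(mean(d2)) / interocular_distance(gt)
}

#' Head pose mean absolute error
#'
#' @param pred,gt Lists of [head_pose()] objects (equal length), or
#'   data frames/matrices with columns pitch, roll, yaw.
#' @return Named vector: `pitch`, `roll`, `yaw` MAE in degrees, and their
#'   `average`.
#' @export
pose_mae <- function(pred, gt) {
  to_mat <- function(x) {
    if (is.list(x) && all(vapply(x, inherits, logical(1), "head_pose")))
      x <- do.call(rbind, lapply(x, function(p) unlist(p)))
    m <- as.matrix(as.data.frame(x))[, c("pitch", "roll", "yaw"), drop = FALSE]
    m
  }
  p <- to_mat(pred); g <- to_mat(gt)
  if (nrow(p) != nrow(g) || nrow(p) < 1)
    stop("pose_mae: prediction and ground truth lengths differ or are empty")
  mae <- colMeans(abs(p - g))
  c(mae, average = mean(mae))
}

#' F1 score for binary calls
#'
#' `2TP / (2TP + FP + FN)`; defined as 0 when there are no true positives.
#' Requires at least one positive in the ground truth.
#'
#' @param pred,gt Binary (0/1 or logical) vectors of equal length.
#' @return F1 in `[0, 1]`.
#' @export
f1_binary <- function(pred, gt) {
  pred <- as.numeric(pred) > 0
  gt <- as.numeric(gt) > 0
  if (length(pred) != length(gt)) stop("f1_binary: length mismatch")
  if (!any(gt)) stop("f1_binary: no positives in ground truth; metric undefined")
  tp <- sum(pred & gt); fp <- sum(pred & !gt); fn <- sum(!pred & gt)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Per-AU F1 of a detector on labeled records
#'
#' Runs the bundle over a labeled synthetic dataset (optionally perturbing
#' each image first) and scores each AU's binary call at threshold 0.5.
#'
#' @param bundle A [fit_detector()] bundle.
#' @param records A [make_dataset()] list.
#' @param perturb Optional `function(image, landmarks)` returning a perturbed
#'   image (or a list with `image` and `landmarks`) applied before feature
#'   extraction.
#' @param threshold Probability threshold for the binary call.
#' @return Named vector of per-AU F1 scores (NA for AUs with no positive
#'   ground truth).
#' @export
evaluate_au_f1 <- function(bundle, records, perturb = NULL, threshold = 0.5) {
  images <- lapply(records, `[[`, "image")
  lms <- lapply(records, `[[`, "landmarks")
  if (!is.null(perturb)) {
    for (i in seq_along(images)) {
      out <- perturb(images[[i]], lms[[i]])
      if (is.list(out) && !is.null(out$image)) {
        images[[i]] <- out$image
        if (!is.null(out$landmarks)) lms[[i]] <- out$landmarks
      } else images[[i]] <- out
    }
  }
  feats <- extract_face_features(images, lms, bundle$config)
  probs <- detect_aus(bundle, features = feats)
  truth <- do.call(rbind, lapply(records, `[[`, "au_binary"))
  colnames(truth) <- au_names12()
  vapply(au_names12(), function(au) {
    if (!any(truth[, au] > 0)) return(NA_real_)
    f1_binary(probs[, au] >= threshold, truth[, au])
  }, numeric(1))
}

#' Macro-F1 of the emotion detector on labeled records
#'
#' One-vs-rest F1 per emotion category (argmax call), averaged over the
#' categories present in the ground truth.
#'
#' @inheritParams evaluate_au_f1
#' @return List with `per_class` F1 vector and `macro_f1`.
#' @export
evaluate_emotion_f1 <- function(bundle, records, perturb = NULL) {
  images <- lapply(records, `[[`, "image")
  lms <- lapply(records, `[[`, "landmarks")
  if (!is.null(perturb)) {
    for (i in seq_along(images)) {
      out <- perturb(images[[i]], lms[[i]])
      images[[i]] <- if (is.list(out) && !is.null(out$image)) out$image else out
    }
  }
  feats <- extract_face_features(images, lms, bundle$config)
  probs <- detect_emotions(bundle, features = feats)
  call <- emotion_names()[max.col(probs, ties.method = "first")]
  truth <- vapply(records, `[[`, character(1), "emotion")
  present <- intersect(emotion_names(), unique(truth))
  per <- vapply(present, function(cl) f1_binary(call == cl, truth == cl),
                numeric(1))
  list(per_class = per, macro_f1 = mean(per))
}
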