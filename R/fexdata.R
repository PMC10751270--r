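#' @title The Fex frames-by-features container
#' @name fexdata
#' @description
#' A data frame subclass holding per-frame facial expression detections —
#' face box, 68 landmarks, head pose, AU probabilities and emotion
#' probabilities — with a session label per row (by default the input video
#' identifier). Sessions drive aggregation (`extract_summary`), intersubject
#' correlation (`isc`), mass-univariate regression (`fex_regress`) and
#' cross-validated decoding (`predict`).
NULL

fex_column_groups <- function() {
  list(faceboxes = c("FaceRectX", "FaceRectY", "FaceRectWidth",
                     "FaceRectHeight", "FaceScore"),
       landmarks = c(paste0("x_", 0:67), paste0("y_", 0:67)),
       poses     = c("Pitch", "Roll", "Yaw"),
       aus       = au_names12(),
       emotions  = emotion_names())
}

fex_feature_columns <- function() unlist(fex_column_groups(), use.names = FALSE)

#' Construct or validate a Fex table
#'
#' @param data A data frame with columns `frame`, `input`, the feature
#'   columns (faceboxes `FaceRectX/Y/Width/Height/Score`, landmarks
#'   `x_0..x_67, y_0..y_67`, poses `Pitch/Roll/Yaw`, the 12 AU columns and
#'   7 emotion columns) and optionally `session` (defaults to `input`).
#' @return The data frame with class `"fex"`.
#' @export
as_fex <- function(data) {
  data <- as.data.frame(data)
  needed <- c("frame", "input", fex_feature_columns())
  missing <- setdiff(needed, names(data))
  if (length(missing))
    stop(sprintf("as_fex: missing column(s): %s%s",
                 paste(utils::head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) ", ..." else ""))
  if (is.null(data$session)) data$session <- data$input
  data$session <- as.character(data$session)
  if (anyNA(data$session)) stop("as_fex: session labels must cover all rows")
  class(data) <- c("fex", "data.frame")
  data
}

#' @rdname as_fex
#' @export
is_fex <- function(data) inherits(data, "fex")

#' @export
print.fex <- function(x, ...) {
  cat(sprintf("Fex table: %d frames x %d columns, %d session(s)\n",
              nrow(x), ncol(x), length(unique(x$session))))
  cat("  sessions:", paste(utils::head(unique(x$session), 8), collapse = " "),
      if (length(unique(x$session)) > 8) "..." else "", "\n")
  invisible(x)
}

#' Select a feature column group
#'
#' @param fex A [as_fex()] table (or a summary table with suffixed names).
#' @param group One of `"faceboxes"`, `"landmarks"`, `"poses"`, `"aus"`,
#'   `"emotions"`.
#' @return The data frame restricted to that group's columns (prefix-matched
#'   on summary tables whose columns carry a `_stat` suffix).
#' @export
fex_group <- function(fex, group = c("aus", "emotions", "poses",
                                     "landmarks", "faceboxes")) {
  group <- match.arg(group)
  cols <- fex_column_groups()[[group]]
  hit <- names(fex)[names(fex) %in% cols]
  if (!length(hit)) {
    pat <- paste0("^(", paste(cols, collapse = "|"), ")_(mean|std|min|max)$")
    hit <- grep(pat, names(fex), value = TRUE)
  }
  if (!length(hit)) stop(sprintf("fex_group: no '%s' columns present", group))
  fex[, hit, drop = FALSE]
}

#' Relabel sessions
#'
#' Maps existing session labels to new ones; labels absent from the mapping
#' pass through unchanged. Mapping several labels to one merges those
#' sessions.
#'
#' @param fex A Fex table.
#' @param mapping Named character vector or list: `old label -> new label`.
#' @return The relabeled Fex table.
#' @examples
#' \dontrun{
#' fx <- update_sessions(fx, c("001" = "good_news", "002" = "bad_news"))
#' }
#' @export
update_sessions <- function(fex, mapping) {
  stopifnot(is_fex(fex))
  mapping <- unlist(mapping)
  if (length(mapping) == 0) return(fex)
  miss <- setdiff(names(mapping), unique(fex$session))
  if (length(miss))
    message("update_sessions: label(s) not present, ignored: ",
            paste(miss, collapse = ", "))
  hit <- fex$session %in% names(mapping)
  fex$session[hit] <- as.character(mapping[fex$session[hit]])
  fex
}

#' Per-session summary statistics
#'
#' One row per session; each feature column contributes one column per
#' requested statistic, named `<feature>_<stat>`. `extract_mean()` is the
#' mean-only shorthand.
#'
#' @param fex A Fex table.
#' @param stats Subset of `c("mean", "std", "min", "max")`.
#' @return A data frame with a `session` column followed by the
#'   feature-by-statistic columns.
#' @export
extract_summary <- function(fex, stats = c("mean", "std", "min", "max")) {
  stopifnot(is_fex(fex))
  stats <- match.arg(stats, several.ok = TRUE)
  funs <- list(mean = mean, std = stats::sd, min = min, max = max)[stats]
  sessions <- unique(fex$session)
  feats <- fex_feature_columns()
  out <- lapply(sessions, function(s) {
    sub <- fex[fex$session == s, feats, drop = FALSE]
    if (nrow(sub) == 0) stop(sprintf("extract_summary: session '%s' is empty", s))
    vals <- unlist(lapply(names(funs), function(st)
      stats::setNames(vapply(sub, funs[[st]], numeric(1)),
                      paste0(feats, "_", st))))
    as.data.frame(as.list(vals), check.names = FALSE)
  })
  cbind(data.frame(session = sessions), do.call(rbind, out))
}

#' @rdname extract_summary
#' @export
extract_mean <- function(fex) extract_summary(fex, stats = "mean")

#' Intersubject (intervideo) correlation of one feature channel
#'
#' Pairwise correlation of the named feature's time series across sessions.
#' Series of unequal length are truncated to the shortest (with a warning);
#' missing frames are dropped pairwise. A zero-variance series yields `NA`
#' entries (undefined correlation), not 0.
#'
#' @param fex A Fex table with at least two sessions.
#' @param col Feature column name (e.g. `"happiness"`).
#' @param method `"pearson"` or `"spearman"`.
#' @return A symmetric session-by-session correlation matrix with unit
#'   diagonal.
#' @export
isc <- function(fex, col, method = c("pearson", "spearman")) {
  stopifnot(is_fex(fex))
  method <- match.arg(method)
  if (!col %in% names(fex)) stop(sprintf("isc: no column '%s'", col))
  sessions <- unique(fex$session)
  if (length(sessions) < 2) stop("isc: need at least two sessions")
  series <- lapply(sessions, function(s) {
    sub <- fex[fex$session == s, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    sub[[col]]
  })
  lens <- lengths(series)
  if (length(unique(lens)) > 1) {
    warning(sprintf("isc: unequal series lengths (%d-%d); truncating to %d frames",
                    min(lens), max(lens), min(lens)))
  }
  n <- min(lens)
  if (n < 3) stop("isc: sessions must have at least 3 frames after alignment")
  M <- vapply(series, function(v) v[seq_len(n)], numeric(n))
  colnames(M) <- sessions
  degenerate <- apply(M, 2, function(v) stats::sd(v, na.rm = TRUE) == 0)
  if (any(degenerate))
    warning("isc: zero-variance series; correlations reported as NA for: ",
            paste(sessions[degenerate], collapse = ", "))
  C <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs",
                                   method = method))
  C[degenerate, ] <- NA_real_
  C[, degenerate] <- NA_real_
  diag(C) <- 1
  C
}

#' Mass-univariate regression over a feature group
#'
#' Fits the same ordinary-least-squares design independently to every column
#' of the outcome group and collects per-outcome betas, standard errors,
#' t statistics and two-tailed p values with shared residual degrees of
#' freedom `n - p`. With `X = "sessions"` and numeric session labels (the
#' contrast-code idiom, e.g. good = 1, bad = -1) the labels are used directly
#' as the regressor, so a +/-1 contrast with an intercept reproduces the
#' pooled two-sample t test; non-numeric labels are expanded to treatment
#' dummies.
#'
#' @param fex A Fex table.
#' @param X `"sessions"` or a character vector of predictor column names.
#' @param y Outcome group name (e.g. `"aus"`) or outcome column names.
#' @param fit_intercept Include an intercept column.
#' @param p_adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   correction across outcomes, applied per predictor row.
#' @return An object of class `"fex_regression"`: list with `beta`, `se`,
#'   `t`, `p` (predictor-by-outcome matrices), `df` and `residuals`.
#' @export
fex_regress <- function(fex, X = "sessions", y = "aus", fit_intercept = TRUE,
                        p_adjust = c("none", "BH")) {
  stopifnot(is_fex(fex))
  p_adjust <- match.arg(p_adjust)
  if (identical(X, "sessions")) {
    labs <- fex$session
    num <- suppressWarnings(as.numeric(labs))
    if (!anyNA(num)) {
      design <- matrix(num, ncol = 1, dimnames = list(NULL, "sessions"))
    } else {
      f <- factor(labs)
      design <- stats::model.matrix(~ f)[, -1, drop = FALSE]
      colnames(design) <- paste0("session_", levels(f)[-1])
    }
  } else {
    stopifnot(all(X %in% names(fex)))
    design <- as.matrix(fex[, X, drop = FALSE])
  }
  if (fit_intercept) design <- cbind(`(Intercept)` = 1, design)
  ycols <- if (length(y) == 1 && y %in% names(fex_column_groups()))
    fex_column_groups()[[y]] else y
  stopifnot(all(ycols %in% names(fex)))
  Y <- as.matrix(fex[, ycols, drop = FALSE])
  n <- nrow(design); p <- ncol(design)
  if (n <= p) stop("fex_regress: need more rows than predictors")
  qx <- qr(design)
  if (qx$rank < p) {
    dep <- colnames(design)[qx$pivot[(qx$rank + 1):p]]
    stop(sprintf("fex_regress: design is rank deficient; dependent column(s): %s",
                 paste(dep, collapse = ", ")))
  }
  beta <- qr.coef(qx, Y)
  fitted <- design %*% beta
  resid <- Y - fitted
  df <- n - p
  rss <- colSums(resid^2)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(outer(diag(xtx_inv), sigma2))
  dimnames(se) <- dimnames(beta)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  if (p_adjust == "BH")
    pval <- t(apply(pval, 1, stats::p.adjust, method = "BH"))
  structure(list(beta = beta, se = se, t = tval, p = pval, df = df,
                 residuals = resid, design = design),
            class = "fex_regression")
}

#' @export
print.fex_regression <- function(x, ...) {
  cat(sprintf("Mass-univariate OLS: %d outcome(s), %d predictor(s), df = %d\n",
              ncol(x$beta), nrow(x$beta), x$df))
  last <- nrow(x$t)
  show <- utils::head(order(x$p[last, ]), 6)
  cat(sprintf("  top effects for '%s':\n", rownames(x$t)[last]))
  for (j in show)
    cat(sprintf("    %-10s beta=% .4f t=% .2f p=%.3g\n",
                colnames(x$t)[j], x$beta[last, j], x$t[last, j], x$p[last, j]))
  invisible(x)
}

#' @export
coef.fex_regression <- function(object, ...) object$beta

#' Cross-validated decoding of sessions from features
#'
#' Decodes the session label from a feature group with k-fold
#' cross-validation grouped by video: all frames of one input stay in the
#' same fold, so temporally autocorrelated frames never leak across the
#' train/test boundary. Videos are dealt to folds round-robin within each
#' class (after a seeded shuffle) to keep folds class-balanced. The final
#' decoder is refit on all data and its coefficient vector is exposed for
#' face reconstruction via [plot_face()].
#'
#' @param object A Fex table.
#' @param X Feature group name or column names.
#' @param y Must be `"sessions"` (the decoded label).
#' @param model `"lda"` (default), `"svm"` or `"logistic"`.
#' @param folds Number of folds (at most the number of videos).
#' @param seed Integer seed for the fold shuffle.
#' @param ... Unused.
#' @return An object of class `"fex_decoder"`: list with `accuracy` (mean
#'   held-out accuracy), `fold_accuracy`, `fold_assignment` (video -> fold),
#'   `decoder` (refit on all data), `coef` (named coefficient vector) and
#'   `model`.
#' @export
predict.fex <- function(object, X = "aus", y = "sessions",
                        model = c("lda", "svm", "logistic"), folds = 5,
                        seed = 1, ...) {
  stopifnot(is_fex(object))
  model <- match.arg(model)
  if (!identical(y, "sessions"))
    stop("predict.fex: decoding target must be \"sessions\"")
  xcols <- if (length(X) == 1 && X %in% names(fex_column_groups()))
    fex_column_groups()[[X]] else X
  stopifnot(all(xcols %in% names(object)))
  Xm <- as.matrix(object[, xcols, drop = FALSE])
  lab <- factor(object$session)
  if (nlevels(lab) < 2) stop("predict.fex: need at least two session classes")
  vids <- object$input
  vid_class <- tapply(as.character(lab), vids, function(v) v[1])
  if (folds > length(vid_class))
    stop("predict.fex: more folds than videos")
  assign_fold <- with_seed(seed, {
    fa <- stats::setNames(integer(length(vid_class)), names(vid_class))
    for (cl in unique(vid_class)) {
      members <- sample(names(vid_class)[vid_class == cl])
      fa[members] <- rep(seq_len(folds), length.out = length(members))
    }
    fa
  })
  fit_fun <- switch(model,
    lda = function(x, g) MASS::lda(x, grouping = g),
    svm = function(x, g) e1071::svm(x, g, kernel = "linear", scale = FALSE),
    logistic = function(x, g) {
      if (nlevels(droplevels(g)) != 2)
        stop("logistic decoder requires exactly two classes")
      suppressWarnings(stats::glm.fit(cbind(1, x), as.numeric(g) - 1,
                                      family = stats::binomial()))
    })
  pred_fun <- switch(model,
    lda = function(fit, x) as.character(stats::predict(fit, x)$class),
    svm = function(fit, x) as.character(stats::predict(fit, x)),
    logistic = function(fit, x) {
      p <- stats::plogis(drop(cbind(1, x) %*% fit$coefficients))
      levels(lab)[1 + (p > 0.5)]
    })
  fold_acc <- vapply(seq_len(folds), function(k) {
    test_vids <- names(assign_fold)[assign_fold == k]
    te <- vids %in% test_vids
    if (!any(te) || all(te)) return(NA_real_)
    fit <- fit_fun(Xm[!te, , drop = FALSE], droplevels(lab[!te]))
    mean(pred_fun(fit, Xm[te, , drop = FALSE]) == as.character(lab[te]))
  }, numeric(1))
  final <- fit_fun(Xm, lab)
  coefv <- switch(model,
    lda = stats::setNames(drop(final$scaling[, 1]), xcols),
    svm = stats::setNames(drop(crossprod(final$SV, final$coefs)), xcols),
    logistic = stats::setNames(final$coefficients[-1], xcols))
  structure(list(accuracy = mean(fold_acc, na.rm = TRUE),
                 fold_accuracy = fold_acc,
                 fold_assignment = assign_fold,
                 decoder = final, coef = coefv, model = model,
                 classes = levels(lab)),
            class = "fex_decoder")
}

#' @export
print.fex_decoder <- function(x, ...) {
  cat(sprintf("Fex decoder (%s): %d-fold video-grouped CV accuracy %.3f (folds: %s)\n",
              x$model, length(x$fold_accuracy), x$accuracy,
              paste(sprintf("%.2f", x$fold_accuracy), collapse = " ")))
  invisible(x)
}

#' @export
coef.fex_decoder <- function(object, ...) object$coef

#' Read / write a Fex table as CSV
#'
#' The CSV dialect has a header row and the columns
#' `frame,input,FaceRectX,...,x_0..x_67,y_0..y_67,Pitch,Roll,Yaw,AU01..AU26,
#' anger..neutral,session`, UTF-8. Numbers are written with full (17
#' significant digit) precision so a write/read round trip reproduces the
#' table exactly.
#'
#' @param fex A Fex table.
#' @param path File path.
#' @return `read_fex()` returns a [as_fex()] table; `write_fex()` returns
#'   `path` invisibly.
#' @export
write_fex <- function(fex, path) {
  stopifnot(is_fex(fex))
  cols <- c("frame", "input", fex_feature_columns(), "session")
  df <- as.data.frame(fex)[, cols]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_fex
#' @export
read_fex <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                        colClasses = c(input = "character",
                                       session = "character"))
  as_fex(df)
}
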