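#' @title Synthetic labeled-face generator
#' @name synth
#' @description
#' Generates stylized labeled face images from the AU-to-landmark face model
#' (ground-truth boxes, landmarks, AU occurrences/intensities and emotion
#' labels), and condition-structured Fex time series, so that training,
#' detection, robustness and statistical analysis are all testable at desk
#' scale without external datasets. Every output is fully reproducible from
#' its recipe and seed.
NULL

#' Canonical AU-to-emotion map
#'
#' An EMFACS-style convention restricted to the 12 detectable AUs:
#' happiness \{6, 12\}; sadness \{1, 4, 15\}; surprise \{1, 2, 5, 26\};
#' fear \{1, 2, 4, 5, 20, 26\}; anger \{4, 5, 17\}; disgust \{9, 15, 25\};
#' neutral = no active AUs. This is a package convention for the synthetic
#' world, not a claim about any benchmark corpus.
#'
#' @return Named list mapping each emotion to its AU label set.
#' @export
au_emotion_map <- function() {
  list(happiness = c("AU06", "AU12"),
       sadness   = c("AU01", "AU04", "AU15"),
       surprise  = c("AU01", "AU02", "AU05", "AU26"),
       fear      = c("AU01", "AU02", "AU04", "AU05", "AU20", "AU26"),
       anger     = c("AU04", "AU05", "AU17"),
       disgust   = c("AU09", "AU15", "AU25"),
       neutral   = character(0))
}

#' Label an AU pattern with an emotion
#'
#' Returns the emotion whose AU set exactly matches the active pattern, or
#' `"neutral"` when no prototype matches (including the empty pattern).
#'
#' @param au_binary Named binary vector over [au_names12()].
#' @return Emotion label.
#' @export
label_emotion <- function(au_binary) {
  active <- sort(au_names12()[au_binary[au_names12()] > 0])
  for (emo in names(au_emotion_map())) {
    if (identical(active, sort(au_emotion_map()[[emo]]))) return(emo)
  }
  "neutral"
}

#' Synthetic dataset recipe
#'
#' Defines the data-generating conditions for [make_dataset()]. Faces are a
#' mixture of emotion-prototype expressions (the AU pattern of a uniformly
#' drawn emotion, intensities from `intensity_range`) and free expressions
#' with independent per-AU Bernoulli occurrences. Landmarks get Gaussian
#' pixel noise; an optional multiplicative brightness jitter is applied to
#' the rendered canvas.
#'
#' @param n_faces Number of faces.
#' @param seed Integer seed; recorded in every output.
#' @param au_p Per-AU Bernoulli occurrence probability (scalar or named
#'   12-vector) for free expressions.
#' @param intensity_range Range of activation intensities for active AUs.
#' @param p_emotion Fraction of faces drawn as emotion prototypes.
#' @param landmark_sigma SD of Gaussian landmark noise, in pixels.
#' @param canvas `(rows, cols)` canvas size.
#' @param brightness_range Multiplicative jitter range (default none).
#' @return A list of class `"synth_recipe"`.
#' @export
synth_recipe <- function(n_faces = 200, seed = 1, au_p = 0.25,
                         intensity_range = c(0.5, 1), p_emotion = 0.6,
                         landmark_sigma = 0.5, canvas = c(112, 112),
                         brightness_range = c(1, 1)) {
  if (length(au_p) == 1L) au_p <- stats::setNames(rep(au_p, 12), au_names12())
  stopifnot(all(au_p >= 0), all(au_p <= 1), landmark_sigma >= 0,
            p_emotion >= 0, p_emotion <= 1, length(canvas) == 2,
            all(canvas >= 48))
  structure(list(n_faces = as.integer(n_faces), seed = as.integer(seed),
                 au_p = au_p[au_names12()],
                 intensity_range = intensity_range, p_emotion = p_emotion,
                 landmark_sigma = landmark_sigma,
                 canvas = as.integer(canvas),
                 brightness_range = brightness_range),
            class = "synth_recipe")
}

#' @export
print.synth_recipe <- function(x, ...) {
  cat(sprintf("Synthetic face recipe: n = %d, seed = %d\n", x$n_faces, x$seed))
  cat(sprintf("  %.0f%% emotion prototypes, free AUs Bernoulli(p = %.2f), intensities [%.2f, %.2f]\n",
              100 * x$p_emotion, mean(x$au_p),
              x$intensity_range[1], x$intensity_range[2]))
  cat(sprintf("  canvas %dx%d, landmark noise sd %.2f px\n",
              x$canvas[1], x$canvas[2], x$landmark_sigma))
  invisible(x)
}

#' Sample independent AU activation vectors
#'
#' The Bernoulli-occurrence component of the recipe's activation law: each AU
#' occurs independently with its recipe probability and, when active, draws
#' an intensity uniformly from the recipe's intensity range.
#'
#' @param recipe A [synth_recipe()].
#' @param n Number of vectors (default `recipe$n_faces`).
#' @param seed Seed (default `recipe$seed`).
#' @return List with `intensity` (`n x 12`) and `binary` (`n x 12`,
#'   `binary = intensity > 0`).
#' @export
sample_au_vectors <- function(recipe, n = recipe$n_faces, seed = recipe$seed) {
  with_seed(seed, {
    occ <- matrix(stats::runif(n * 12), n, 12) <
      matrix(recipe$au_p, n, 12, byrow = TRUE)
    val <- matrix(stats::runif(n * 12, recipe$intensity_range[1],
                               recipe$intensity_range[2]), n, 12)
    intensity <- occ * val
    dimnames(intensity) <- list(NULL, au_names12())
    list(intensity = intensity,
         binary = matrix(as.numeric(intensity > 0), n, 12,
                         dimnames = list(NULL, au_names12())))
  })
}

# Draw one face's AU intensity vector under the recipe's mixture law.
sample_one_au <- function(recipe) {
  au <- stats::setNames(numeric(12), au_names12())
  if (stats::runif(1) < recipe$p_emotion) {
    emo <- sample(names(au_emotion_map()), 1)
    members <- au_emotion_map()[[emo]]
    if (length(members))
      au[members] <- stats::runif(length(members), recipe$intensity_range[1],
                                  recipe$intensity_range[2])
  } else {
    occ <- stats::runif(12) < recipe$au_p
    au[occ] <- stats::runif(sum(occ), recipe$intensity_range[1],
                            recipe$intensity_range[2])
  }
  au
}

#' Generate a labeled synthetic face dataset
#'
#' For each face: draw an AU intensity vector under the recipe's mixture law,
#' generate landmarks through the face model, place them on the canvas, add
#' Gaussian landmark noise, rasterize the stylized face from the noisy
#' landmarks, apply brightness jitter, and record the ground truth (tight
#' box, landmarks, AU intensities/occurrences, emotion label via
#' [label_emotion()], applied nuisance parameters). Regenerating with the
#' same recipe is bit-identical.
#'
#' @param recipe A [synth_recipe()].
#' @param model An [au_face_model()]; default [default_face_model()].
#' @return A list of records (class `"synth_dataset"`), each with fields
#'   `image`, `box`, `landmarks`, `au_intensity`, `au_binary`, `emotion`,
#'   `brightness`, `seed`.
#' @export
make_dataset <- function(recipe, model = default_face_model()) {
  stopifnot(inherits(recipe, "synth_recipe"), inherits(model, "au_face_model"))
  tr <- canvas_transform(recipe$canvas)
  # face spans ~3.1 normalized units; guard against unusably small canvases
  if (tr$scale < 14)
    stop("make_dataset: canvas too small for the face scale")
  records <- with_seed(recipe$seed, {
    lapply(seq_len(recipe$n_faces), function(i) {
      au <- sample_one_au(recipe)
      lms <- generate_landmarks(model, au)
      lms_px <- apply_canvas_transform(lms, tr)
      if (recipe$landmark_sigma > 0)
        lms_px <- lms_px + matrix(stats::rnorm(136, 0, recipe$landmark_sigma),
                                  68, 2)
      lms_px <- landmarks68(lms_px)
      img <- render_face_raster(lms_px, recipe$canvas)
      bf <- if (diff(recipe$brightness_range) > 0 ||
                any(recipe$brightness_range != 1))
        stats::runif(1, recipe$brightness_range[1], recipe$brightness_range[2])
      else 1
      if (bf != 1) img <- pmin(1, pmax(0, img * bf))
      binary <- stats::setNames(as.numeric(au > 0), au_names12())
      box <- bbox(min(lms_px[, 1]), min(lms_px[, 2]),
                  max(lms_px[, 1]) - min(lms_px[, 1]),
                  max(lms_px[, 2]) - min(lms_px[, 2]))
      list(image = img, box = box, landmarks = lms_px,
           au_intensity = au, au_binary = binary,
           emotion = label_emotion(binary),
           brightness = bf, seed = recipe$seed)
    })
  })
  structure(records, class = c("synth_dataset", "list"), recipe = recipe)
}

#' @export
print.synth_dataset <- function(x, ...) {
  emo <- table(vapply(x, `[[`, character(1), "emotion"))
  cat(sprintf("Synthetic face dataset: %d records, canvas %dx%d\n",
              length(x), nrow(x[[1]]$image), ncol(x[[1]]$image)))
  cat("  emotions:", paste(sprintf("%s=%d", names(emo), emo), collapse = " "), "\n")
  invisible(x)
}

#' Generate a condition-structured Fex time series
#'
#' Emulates per-frame detector output for two experimental conditions
#' (`"good"` and `"bad"` news): every AU probability channel fluctuates
#' around the maximal-uncertainty baseline 0.5 with smooth first-order
#' autoregressive noise, and the condition effect shifts the named AUs in the
#' `"good"` condition (by default raising AU06, AU12 and AU25). Emotion
#' columns are derived from the AU channels through the canonical map (plus
#' noise) and normalized to sum to one; pose, box and landmark columns carry
#' no condition signal.
#'
#' @param n_videos_per_condition Videos per condition.
#' @param n_frames Frames per video.
#' @param effect_spec Named vector of mean shifts added to the `"good"`
#'   condition's AU channels.
#' @param noise_sd Innovation SD of the per-video AR(1) temporal noise.
#' @param shared_noise_sd Innovation SD of a per-condition AR(1) time course
#'   added to every video of that condition; this shared structure is what
#'   makes intervideo correlations cluster by condition.
#' @param ar_coef AR(1) coefficient of both noise components.
#' @param seed Integer seed.
#' @return A [fex()] table with sessions set to the video identifiers and a
#'   `condition` attribute mapping videos to conditions.
#' @export
make_fex_timeseries <- function(n_videos_per_condition = 10, n_frames = 300,
                                effect_spec = c(AU06 = 0.20, AU12 = 0.25,
                                                AU25 = 0.20),
                                noise_sd = 0.08, shared_noise_sd = 0.05,
                                ar_coef = 0.7, seed = 1) {
  stopifnot(n_videos_per_condition >= 1, n_frames >= 3)
  if (length(setdiff(names(effect_spec), au_names12())))
    stop("make_fex_timeseries: effect_spec names must be detection AUs")
  conditions <- c("good", "bad")
  tmpl <- face_template68()
  tr <- canvas_transform(c(112L, 112L))
  tmpl_px <- apply_canvas_transform(tmpl, tr)
  ar1 <- function(n, sd) {
    if (sd == 0) return(numeric(n))
    x <- numeric(n)
    x[1] <- stats::rnorm(1, 0, sd / sqrt(1 - ar_coef^2))
    for (t in 2:n) x[t] <- ar_coef * x[t - 1] + stats::rnorm(1, 0, sd)
    x
  }
  rows <- with_seed(seed, {
    out <- list()
    vid <- 0L
    for (cond in conditions) {
      shared <- vapply(au_names12(), function(a) ar1(n_frames, shared_noise_sd),
                       numeric(n_frames))
      for (v in seq_len(n_videos_per_condition)) {
        vid <- vid + 1L
        id <- sprintf("%s_%02d", cond, v)
        mu <- stats::setNames(rep(0.5, 12), au_names12())
        if (cond == "good") mu[names(effect_spec)] <- mu[names(effect_spec)] + effect_spec
        target <- mu
        if (any(target < 0 | target > 1)) {
          warning("make_fex_timeseries: effect pushes AU means outside [0, 1]; clipping")
          target <- pmin(1, pmax(0, target))
        }
        aus <- vapply(au_names12(), function(a)
          pmin(1, pmax(0, target[a] + shared[, a] + ar1(n_frames, noise_sd))),
          numeric(n_frames))
        emo_raw <- vapply(emotion_names(), function(e) {
          members <- au_emotion_map()[[e]]
          base <- if (length(members)) rowMeans(aus[, members, drop = FALSE]) else
            1 - apply(aus, 1, max)
          pmax(0, base + stats::rnorm(n_frames, 0, 0.05))
        }, numeric(n_frames))
        emo <- emo_raw / pmax(rowSums(emo_raw), 1e-12)
        lm_noise <- matrix(stats::rnorm(n_frames * 136, 0, 0.5), n_frames, 136)
        lms <- matrix(rep(c(tmpl_px[, 1], tmpl_px[, 2]), each = n_frames),
                      n_frames, 136) + lm_noise
        df <- data.frame(frame = seq_len(n_frames) - 1L, input = id)
        df$FaceRectX <- min(tmpl_px[, 1]) + stats::rnorm(n_frames, 0, 0.5)
        df$FaceRectY <- min(tmpl_px[, 2]) + stats::rnorm(n_frames, 0, 0.5)
        df$FaceRectWidth <- diff(range(tmpl_px[, 1])) + stats::rnorm(n_frames, 0, 0.5)
        df$FaceRectHeight <- diff(range(tmpl_px[, 2])) + stats::rnorm(n_frames, 0, 0.5)
        df$FaceScore <- pmin(1, pmax(0, 0.98 + stats::rnorm(n_frames, 0, 0.01)))
        lm_df <- as.data.frame(lms)
        names(lm_df) <- c(paste0("x_", 0:67), paste0("y_", 0:67))
        df <- cbind(df, lm_df)
        df$Pitch <- stats::rnorm(n_frames, 0, 2)
        df$Roll <- stats::rnorm(n_frames, 0, 2)
        df$Yaw <- stats::rnorm(n_frames, 0, 2)
        df <- cbind(df, as.data.frame(aus))
        df <- cbind(df, as.data.frame(emo))
        df$session <- id
        out[[vid]] <- df
      }
    }
    out
  })
  fx <- as_fex(do.call(rbind, rows))
  attr(fx, "condition") <- stats::setNames(
    rep(conditions, each = n_videos_per_condition),
    unique(vapply(rows, function(d) d$input[1], character(1))))
  fx
}
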