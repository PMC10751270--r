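# Shared heavyweight fixtures, built once per test run.
#
# The end-to-end detector experiment (train on one synthetic recipe, test on
# an independent one) is used by several acceptance properties; building it
# once here keeps the suite inside a sensible runtime.

.fexkit_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fexkit_cache)) {
    assign(key, builder(), envir = .fexkit_cache)
  }
  get(key, envir = .fexkit_cache)
}

# Full-scale experiment: train recipe seed 7 (n = 2000), test recipe seed 8
# (n = 400), default generator conditions.
e2e_experiment <- function() {
  cached("e2e", function() {
    train <- fexkit::make_dataset(fexkit::synth_recipe(n_faces = 2000, seed = 7))
    test <- fexkit::make_dataset(fexkit::synth_recipe(n_faces = 400, seed = 8))
    bundle <- fexkit::fit_detector(train, seed = 7)
    test_features <- fexkit::extract_face_features(
      lapply(test, `[[`, "image"), lapply(test, `[[`, "landmarks"),
      bundle$config)
    list(train = train, test = test, bundle = bundle,
         test_features = test_features,
         base_f1 = fexkit::evaluate_au_f1(bundle, test))
  })
}

# Small feature-space fixture for classifier unit tests (no images involved):
# 5 informative dimensions, AU labels tied to thresholded coordinates.
separable_feature_fixture <- function(n = 240, seed = 42) {
  cached(paste0("sep", n, "_", seed), function() {
    set.seed(seed)
    X <- matrix(rnorm(n * 5), n, 5)
    X <- X[apply(abs(X) > 0.25, 1, all), , drop = FALSE]  # margin gap
    n <- nrow(X)
    aus <- fexkit::au_names12()
    L <- sapply(seq_along(aus), function(j) as.numeric(X[, (j %% 5) + 1] > 0))
    colnames(L) <- aus
    emotions <- fexkit::emotion_names()
    emo <- emotions[1 + (floor(3 * (X[, 1] + 2) / 4) %% 7)]
    list(X = X, au_labels = L, emotions = emo, n = n)
  })
}
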