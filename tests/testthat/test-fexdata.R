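# Small two-video Fex fixture with controllable values.
small_fex <- function(n_videos = 4, n_frames = 30, seed = 21, ...) {
  make_fex_timeseries(n_videos_per_condition = n_videos / 2,
                      n_frames = n_frames, seed = seed, ...)
}

test_that("session relabeling: mapping, pass-through, merging", {
  fx <- small_fex()
  old <- unique(fx$session)
  m <- stats::setNames(c("good", "bad"), old[1:2])
  fx2 <- update_sessions(fx, m)
  expect_setequal(unique(fx2$session), c("good", "bad", old[3:4]))
  expect_identical(update_sessions(fx, c())$session, fx$session)
  merged <- update_sessions(fx, stats::setNames(c("one", "one"), old[1:2]))
  expect_equal(sum(merged$session == "one"),
               sum(fx$session %in% old[1:2]))
  expect_message(update_sessions(fx, c(nope = "x")), "not present")
})

test_that("per-session summaries match direct group-by recomputation", {
  fx <- small_fex()
  fx$AU01 <- 0.25  # constant channel
  s <- extract_summary(fx)
  expect_equal(nrow(s), 4)
  expect_true(all(s$AU01_mean == 0.25 & s$AU01_std == 0 &
                  s$AU01_min == 0.25 & s$AU01_max == 0.25))
  for (colname in c("AU12", "happiness", "Pitch")) {
    for (st in c("mean", "std", "min", "max")) {
      f <- list(mean = mean, std = sd, min = min, max = max)[[st]]
      direct <- tapply(fx[[colname]], fx$session, f)
      expect_equal(s[[paste0(colname, "_", st)]],
                   as.vector(direct[s$session]), tolerance = 1e-12)
    }
  }
  m <- extract_mean(fx)
  expect_identical(m$AU12_mean, s$AU12_mean)
  expect_named(fex_group(m, "aus"), paste0(au_names12(), "_mean"))
})

test_that("feature column groups are disjoint and exhaustive", {
  g <- fexkit:::fex_column_groups()
  all_cols <- unlist(g, use.names = FALSE)
  expect_identical(anyDuplicated(all_cols), 0L)
  fx <- small_fex()
  expect_setequal(setdiff(names(fx), c("frame", "input", "session")), all_cols)
  for (nm in names(g)) expect_named(fex_group(fx, nm), g[[nm]])
})

test_that("intersubject correlation equals direct pairwise correlation", {
  fx <- small_fex(n_videos = 6, n_frames = 40)
  C <- isc(fx, "happiness")
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, 6))
  expect_true(all(C >= -1 & C <= 1))
  M <- sapply(unique(fx$session), function(s)
    fx$happiness[fx$session == s][1:40])
  expect_equal(unname(C), unname(cor(M)), tolerance = 1e-12)
  # identical and negated series
  fx$sadness[fx$session == unique(fx$session)[2]] <-
    fx$sadness[fx$session == unique(fx$session)[1]]
  C2 <- isc(fx, "sadness")
  expect_equal(C2[1, 2], 1)
  fx$fear[fx$session == unique(fx$session)[2]] <-
    -fx$fear[fx$session == unique(fx$session)[1]]
  expect_equal(isc(fx, "fear")[1, 2], -1)
  # spearman is invariant under a monotone transform of one series
  fx3 <- fx
  fx3$anger <- exp(fx3$anger)
  expect_equal(isc(fx3, "anger", method = "spearman"),
               isc(fx, "anger", method = "spearman"))
})

test_that("isc truncates unequal series and flags zero variance", {
  fx <- small_fex()
  fx_short <- rbind(fx[fx$session != fx$session[1], ],
                    fx[fx$session == fx$session[1], ][1:10, ])
  fx_short <- as_fex(fx_short)
  expect_warning(C <- isc(fx_short, "happiness"), "truncating")
  expect_equal(dim(C), c(4, 4))
  fx$disgust[fx$session == unique(fx$session)[3]] <- 0.5
  expect_warning(C3 <- isc(fx, "disgust"), "zero-variance")
  expect_true(all(is.na(C3[3, -3])))
  expect_false(anyNA(C3[-3, -3]))
})

test_that("regression with a +/-1 contrast reproduces the two-sample t test", {
  fx <- small_fex(n_videos = 6, n_frames = 50)
  cond <- attr(fx, "condition")
  fx <- update_sessions(fx, stats::setNames(ifelse(cond == "good", "1", "-1"),
                                            names(cond)))
  r <- fex_regress(fx, X = "sessions", y = "aus", fit_intercept = TRUE)
  for (au in c("AU06", "AU12", "AU01")) {
    y <- fx[[au]]
    g <- fx$session == "1"
    n1 <- sum(g); n2 <- sum(!g)
    sp2 <- ((n1 - 1) * var(y[g]) + (n2 - 1) * var(y[!g])) / (n1 + n2 - 2)
    t_pooled <- (mean(y[g]) - mean(y[!g])) / sqrt(sp2 * (1 / n1 + 1 / n2))
    # the contrast codes are +/-1, so the slope t equals the pooled t
    expect_equal(unname(r$t["sessions", au]), t_pooled, tolerance = 1e-10)
    expect_equal(unname(r$p["sessions", au]),
                 2 * pt(abs(t_pooled), n1 + n2 - 2, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  expect_equal(r$df, nrow(fx) - 2)
  expect_equal(r$t, r$beta / r$se)
  # residuals orthogonal to the design
  expect_lt(max(abs(crossprod(r$design, r$residuals))), 1e-8)
})

test_that("noise-free linear outcomes are fit exactly", {
  fx <- small_fex()
  fx$AU01 <- 2 * fx$Pitch - 3 * fx$Roll + 1
  r <- fex_regress(fx, X = c("Pitch", "Roll"), y = "AU01")
  expect_equal(unname(r$beta[, "AU01"]), c(1, 2, -3), tolerance = 1e-10)
  expect_lt(max(abs(r$residuals)), 1e-10)
  fx$Yaw <- fx$Pitch
  expect_error(fex_regress(fx, X = c("Pitch", "Yaw"), y = "AU01"),
               "rank deficient")
})

test_that("null regressions have a calibrated false-positive rate", {
  set.seed(3)
  n <- 40
  x <- rep(c(1, -1), each = n / 2)
  Y <- matrix(rnorm(n * 500), n, 500)
  X <- cbind(1, x)
  qx <- qr(X)
  beta <- qr.coef(qx, Y)
  res <- Y - X %*% beta
  se <- sqrt(colSums(res^2) / (n - 2) * chol2inv(qr.R(qx))[2, 2])
  tstat <- beta[2, ] / se
  p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  expect_gte(mean(p < 0.05), 0.03)
  expect_lte(mean(p < 0.05), 0.07)
  # and the package path agrees with this direct computation
  fx <- small_fex(n_videos = 2, n_frames = 20)
  set.seed(33)
  fx$AU04 <- rnorm(40)
  fx <- update_sessions(fx, stats::setNames(c("1", "-1"), unique(fx$session)))
  r <- fex_regress(fx, X = "sessions", y = "AU04")
  y <- fx$AU04; g <- fx$session == "1"
  sp2 <- ((sum(g) - 1) * var(y[g]) + (sum(!g) - 1) * var(y[!g])) / (40 - 2)
  expect_equal(unname(r$t["sessions", 1]),
               (mean(y[g]) - mean(y[!g])) / sqrt(sp2 * (2 / 20)),
               tolerance = 1e-10)
})

test_that("video-grouped decoding: separability, determinism, no leakage", {
  fx <- make_fex_timeseries(n_videos_per_condition = 5, n_frames = 40,
                            effect_spec = c(AU06 = 0.35, AU12 = 0.4),
                            noise_sd = 0.02, seed = 5)
  fx <- update_sessions(fx, attr(fx, "condition"))
  d <- predict(fx, X = "aus", folds = 5, seed = 2)
  expect_equal(d$accuracy, 1)   # near-noiseless conditions separate perfectly
  d2 <- predict(fx, X = "aus", folds = 5, seed = 2)
  expect_identical(d$fold_assignment, d2$fold_assignment)
  expect_identical(d$accuracy, d2$accuracy)
  # structural leakage check: each video sits in exactly one fold
  expect_equal(sort(names(d$fold_assignment)), sort(unique(fx$input)))
  expect_true(all(table(d$fold_assignment) >= 1))
  expect_named(d$coef, au_names12())
  expect_error(predict(fx, X = "aus", folds = 99), "folds")
})

test_that("decoding shuffled video labels stays inside the chance band", {
  accs <- numeric(20)
  fx <- make_fex_timeseries(n_videos_per_condition = 4, n_frames = 30, seed = 6)
  vids <- unique(fx$input)
  for (s in 1:20) {
    set.seed(200 + s)
    lab <- sample(rep(c("a", "b"), length.out = length(vids)))
    fxs <- update_sessions(fx, stats::setNames(lab, vids))
    accs[s] <- predict(fxs, X = "aus", folds = 4, seed = s)$accuracy
  }
  # binomial 95% band around 0.5 treating each video in each seed as a trial
  half_width <- 1.96 * sqrt(0.25 / (20 * length(vids)))
  expect_gt(mean(accs), 0.5 - half_width - 0.05)
  expect_lt(mean(accs), 0.5 + half_width + 0.05)
})

test_that("the Fex CSV dialect round-trips exactly", {
  fx <- small_fex()
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_fex(fx, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_identical(header, c("frame", "input", fexkit:::fex_feature_columns(),
                             "session"))
  back <- read_fex(path)
  for (cn in fexkit:::fex_feature_columns())
    expect_identical(back[[cn]], fx[[cn]])
  expect_identical(back$input, fx$input)
  expect_identical(back$session, fx$session)
})
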