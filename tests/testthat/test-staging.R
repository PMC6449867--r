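test_that("the LD boundary matches the closed-form two-Gaussian discriminant", {
  set.seed(51)
  n <- 400
  mu1 <- rep(0, 30); mu2 <- c(6, rep(0, 29))   # separation 6 along feature 1
  X <- rbind(matrix(rnorm(n * 30), n, 30),
             sweep(matrix(rnorm(n * 30), n, 30), 2, mu2, "+"))
  y <- hypnogram(rep(c("W", "N2"), each = n), "raw")
  model <- train_ld(epoch_feature_matrix(X), y, "s2", lambda = 0)
  ## sweep along the mu1-mu2 axis; the sign change must sit near the midpoint
  probe <- seq(2, 4, by = 0.005)
  P <- matrix(0, length(probe), 30); P[, 1] <- probe
  pred <- predict_stages(model, P)$hypnogram$labels
  boundary <- probe[which(pred == "S")[1]]
  expect_lt(abs(boundary - 3), 0.1)
})

test_that("training validates its inputs", {
  X <- epoch_feature_matrix(matrix(rnorm(20 * 30), 20, 30))
  y_one <- hypnogram(rep("W", 20), "raw")
  expect_error(train_ld(X, y_one, "s2"), class = "somnostage_data_error")
  err <- tryCatch(train_ld(X, y_one, "s2"), error = identity)
  expect_match(conditionMessage(err), "S")    # names the absent class
  y_bad <- hypnogram(rep(c("W", "N2"), 5), "raw")
  expect_error(train_ld(X, y_bad, "s2"), class = "somnostage_data_error")
  expect_error(train_ld(X, hypnogram(rep(c("W", "N2"), 10), "raw"),
                        "s2", lambda = 2),
               class = "somnostage_argument_error")
})

test_that("training is deterministic and unaffected by duplicating the set", {
  set.seed(52)
  X <- epoch_feature_matrix(matrix(rnorm(60 * 30), 60, 30))
  y <- hypnogram(rep(c("W", "N2", "REM"), each = 20), "raw")
  m1 <- train_ld(X, y, "s3")
  m2 <- train_ld(X, y, "s3")
  expect_identical(m1$class_means, m2$class_means)
  ## duplicated training data: same priors and (up to the N - 1 / N - K
  ## denominators in scale and covariance) the same classifier
  m3 <- train_ld(list(X, X), list(y, y), "s3")
  expect_equal(m3$priors, m1$priors)
  expect_equal(m3$class_means, m1$class_means, tolerance = 0.02)
  Xte <- matrix(rnorm(50 * 30), 50, 30)
  expect_equal(predict_stages(m3, Xte)$hypnogram$labels,
               predict_stages(m1, Xte)$hypnogram$labels)
})

test_that("prediction assigns class means to their class and normalizes posteriors", {
  set.seed(53)
  X <- epoch_feature_matrix(matrix(rnorm(90 * 30), 90, 30) +
                            rep(c(0, 8, 16), each = 30))
  y <- hypnogram(rep(c("W", "N2", "REM"), each = 30), "raw")
  model <- train_ld(X, y, "s3", priors = "uniform")
  ## un-normalized class means: invert the model normalization
  M <- sweep(sweep(model$class_means, 2, model$scale, "*"), 2, model$center, "+")
  pred <- predict_stages(model, M)
  expect_equal(pred$hypnogram$labels, model$classes)
  expect_true(all(abs(rowSums(pred$posterior) - 1) < 1e-12))
  expect_error(predict_stages(model, matrix(0, 2, 10)),
               class = "somnostage_argument_error")
})

test_that("exact discriminant ties break toward W", {
  ## symmetric two-class model: a point equidistant from both means
  model <- structure(list(
    classes = c("W", "S"), system_id = "s2",
    class_means = rbind(W = c(-1, rep(0, 29)), S = c(1, rep(0, 29))),
    pooled_covariance = diag(30), cov_inverse = diag(30),
    priors = c(W = 0.5, S = 0.5), shrinkage = 0,
    center = rep(0, 30), scale = rep(1, 30),
    feature_names = all_feature_names()), class = "ld_model")
  pred <- predict_stages(model, matrix(0, 1, 30))
  expect_equal(pred$hypnogram$labels, "W")
})

test_that("prediction is invariant to a common affine rescaling of a feature", {
  set.seed(54)
  Xtr <- matrix(rnorm(80 * 30), 80, 30); Xtr[1:40, 3] <- Xtr[1:40, 3] + 2
  y <- hypnogram(rep(c("W", "N2"), each = 40), "raw")
  Xte <- matrix(rnorm(25 * 30), 25, 30)
  base <- predict_stages(train_ld(epoch_feature_matrix(Xtr), y, "s2"),
                         Xte)$hypnogram$labels
  for (j in c(1, 3, 17)) {
    Xtr2 <- Xtr; Xte2 <- Xte
    Xtr2[, j] <- 100 * Xtr2[, j] - 7
    Xte2[, j] <- 100 * Xte2[, j] - 7
    got <- predict_stages(train_ld(epoch_feature_matrix(Xtr2), y, "s2"),
                          Xte2)$hypnogram$labels
    expect_equal(got, base)
  }
})

test_that("training followed by prediction separates linearly separable classes", {
  sub <- toy_subject(rep(c("W", "REM", "N1", "N2", "N3"), each = 12), seed = 55)
  model <- train_ld(sub$features, sub$hypnogram, "s4")
  pred <- predict_stages(model, sub$features)
  ref <- map_stages(sub$hypnogram, "s4")
  expect_equal(pred$hypnogram$labels, ref$labels)   # 100% training accuracy
})

test_that("the shrinkage-free model agrees with an independent LDA fit", {
  skip_if_not_installed("MASS")
  set.seed(56)
  n <- 300
  X <- rbind(matrix(rnorm(n * 30), n, 30),
             sweep(matrix(rnorm(n * 30), n, 30), 2, rep(1.2, 30), "+"))
  y <- rep(c("W", "N2"), each = n)
  model <- train_ld(epoch_feature_matrix(X), hypnogram(y, "raw"), "s2",
                    lambda = 0)
  fit <- MASS::lda(X, grouping = ifelse(y == "W", "W", "S"))
  Xte <- matrix(rnorm(200 * 30), 200, 30) + 0.6
  ours <- predict_stages(model, Xte)$hypnogram$labels
  theirs <- as.character(predict(fit, Xte)$class)
  expect_gt(mean(ours == theirs), 0.99)
})

test_that("models survive a JSON round trip", {
  set.seed(57)
  X <- epoch_feature_matrix(matrix(rnorm(60 * 30), 60, 30) +
                            rep(c(0, 5, 10), each = 20))
  y <- hypnogram(rep(c("W", "N2", "REM"), each = 20), "raw")
  model <- train_ld(X, y, "s3")
  p <- withr::local_tempfile(fileext = ".json")
  write_ld_model(model, p)
  model2 <- read_ld_model(p)
  expect_equal(model2$class_means, model$class_means, tolerance = 1e-12)
  expect_equal(model2$priors, model$priors, tolerance = 1e-12)
  Xte <- matrix(rnorm(40 * 30), 40, 30)
  expect_equal(predict_stages(model2, Xte)$hypnogram$labels,
               predict_stages(model, Xte)$hypnogram$labels)
})

test_that("feature assembly imputes degenerate cells with recording medians", {
  set.seed(58)
  night <- quick_night(minutes = 3)
  ex <- extract_features(night$audio, night$imu)
  X <- ex$features
  expect_equal(dim(X$values), c(6L, 30L))
  expect_true(all(is.finite(X$values)))
  ## determinism: identical inputs give identical matrices
  ex2 <- extract_features(night$audio, night$imu)
  expect_identical(ex2$features$values, X$values)
})

test_that("assembly flags and fills epochs with no detected breaths", {
  night <- quick_night(minutes = 3)
  ex <- extract_features(night$audio, night$imu)
  ## breaths emptied: every interval feature must be flagged yet finite
  empty <- breath_series(numeric(0), numeric(0), threshold = 1)
  X <- assemble_features(empty, envelope(night$audio), ex$beats, night$imu,
                         ex$positions, ex$grid)
  expect_true(all(X$imputed_flags[, 1:7]))
  expect_true(all(is.finite(X$values)))
})
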