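#' Per-epoch feature matrix
#'
#' One 30-dimensional feature vector per 30-second epoch: 13 respiratory,
#' 13 cardiac and 4 movement features.
#'
#' @param values n_epochs x 30 numeric matrix.
#' @param imputed logical matrix of the same shape flagging cells that were
#'   degenerate and filled with the recording median.
#' @param subject_id optional identifier.
#' @return an object of class `epoch_feature_matrix`.
#' @export
epoch_feature_matrix <- function(values, imputed = NULL, subject_id = NA_character_) {
  values <- as.matrix(values)
  nm <- all_feature_names()
  if (ncol(values) != length(nm))
    abort_argument(sprintf("feature matrix must have %d columns", length(nm)))
  if (!all(is.finite(values)))
    abort_argument("feature matrix must be finite after imputation")
  colnames(values) <- nm
  if (is.null(imputed)) imputed <- matrix(FALSE, nrow(values), ncol(values))
  structure(list(values = values, feature_names = nm,
                 imputed_flags = imputed, subject_id = subject_id),
            class = "epoch_feature_matrix")
}

#' @export
print.epoch_feature_matrix <- function(x, ...) {
  cat(sprintf("<epoch_feature_matrix> %d epochs x %d features (%s), %.1f%% imputed\n",
              nrow(x$values), ncol(x$values), x$subject_id,
              100 * mean(x$imputed_flags)))
  invisible(x)
}

#' Feature names of the 30-dimensional epoch vector
#' @return character vector of length 30.
#' @export
all_feature_names <- function() {
  c(respiratory_feature_names, cardiac_feature_names, movement_feature_names)
}

#' Assemble the per-epoch feature matrix
#'
#' Concatenates the 13 respiratory, 13 cardiac and 4 movement features for
#' every epoch of the grid. Cells flagged degenerate by the per-epoch
#' extractors (no events in the window) are imputed with the recording
#' median of that feature (0 when a feature is degenerate everywhere) and
#' marked in `imputed_flags`.
#'
#' @param breaths a [breath_series()].
#' @param env the `envelope_series` breaths were detected on.
#' @param beats a [beat_series()].
#' @param imu an [imu_recording()].
#' @param positions a `position_series`.
#' @param grid an `epoch_grid`; all sources must cover it.
#' @param config a [somnostage_config()] (feature window tunables).
#' @param subject_id optional identifier.
#' @return an [epoch_feature_matrix()].
#' @export
assemble_features <- function(breaths, env, beats, imu, positions, grid,
                              config = somnostage_config(),
                              subject_id = NA_character_) {
  n <- grid$n_epochs
  if (n < 1L) abort_argument("epoch grid is empty")
  if (duration(imu) + 1e-9 < 30 * n)
    abort_data("IMU recording does not cover the epoch grid")
  gravity <- stats::median(sqrt(rowSums(imu$accel^2)))
  vals <- matrix(NA_real_, n, 30L)
  flags <- matrix(FALSE, n, 30L)
  for (k in seq_len(n)) {
    r <- respiratory_features(breaths, env, k - 1L, grid,
                              context_s = config$resp$context_s,
                              bb_bounds_s = config$resp$bb_bounds_s)
    cfeat <- cardiac_features(beats, k - 1L, grid,
                              context_s = config$cardiac$context_s,
                              spectral_context_s = config$cardiac$spectral_context_s)
    m <- movement_features(imu, positions, k - 1L, grid, gravity = gravity)
    vals[k, ] <- c(r$values, cfeat$values, m$values)
    flags[k, ] <- c(r$imputed, cfeat$imputed, m$imputed)
  }
  for (j in seq_len(ncol(vals))) {
    bad <- flags[, j]
    if (any(bad)) {
      fill <- if (all(bad)) 0 else stats::median(vals[!bad, j])
      vals[bad, j] <- fill
    }
  }
  epoch_feature_matrix(vals, flags, subject_id)
}

#' Train the linear discriminant sleep-stage classifier
#'
#' Gaussian linear discriminant with a pooled within-class covariance.
#' Features are normalized by training-set location/scale (global, not
#' per subject). The pooled covariance is shrunk toward its diagonal,
#' `(1 - lambda) * S + lambda * diag(S)`, to keep it well conditioned with
#' 30 features and rare classes. Priors default to training class
#' frequencies.
#'
#' @param X an [epoch_feature_matrix()] or list of them.
#' @param y a [hypnogram()] (raw or already in `system`) or list matching `X`.
#' @param system a [stage_system()] or id string.
#' @param lambda shrinkage weight in `[0, 1]` (default 0.1).
#' @param priors `"empirical"` (class frequencies) or `"uniform"`.
#' @return an `ld_model` with class means, shrunken pooled covariance and
#'   its inverse, priors, normalization and class labels.
#' @export
train_ld <- function(X, y, system = "s2", lambda = 0.1,
                     priors = c("empirical", "uniform")) {
  priors <- match.arg(priors)
  if (is.character(system)) system <- stage_system(system)
  if (inherits(X, "epoch_feature_matrix")) X <- list(X)
  if (inherits(y, "hypnogram")) y <- list(y)
  if (length(X) != length(y))
    abort_argument("`X` and `y` must have the same length")
  if (lambda < 0 || lambda > 1) abort_argument("`lambda` must be in [0, 1]")
  mats <- lapply(X, function(m) if (inherits(m, "epoch_feature_matrix")) m$values else as.matrix(m))
  labs <- mapply(function(m, h) {
    h <- map_stages(h, system)
    if (length(h$labels) != nrow(m))
      abort_data("feature matrix and hypnogram disagree on epoch count")
    h$labels
  }, mats, y, SIMPLIFY = FALSE)
  Xp <- do.call(rbind, mats)
  yp <- unlist(labs)
  classes <- system$classes
  missing <- setdiff(classes, unique(yp))
  if (length(missing))
    abort_data(sprintf("class absent from training data: %s",
                       paste(missing, collapse = ", ")))
  if (length(unique(yp)) < 2L)
    abort_data("training data must contain at least 2 classes")

  center <- colMeans(Xp)
  scale <- apply(Xp, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  Z <- sweep(sweep(Xp, 2, center), 2, scale, "/")

  p <- ncol(Z)
  means <- matrix(NA_real_, length(classes), p,
                  dimnames = list(classes, colnames(Xp)))
  S <- matrix(0, p, p)
  for (cl in classes) {
    Zc <- Z[yp == cl, , drop = FALSE]
    means[cl, ] <- colMeans(Zc)
    Zc <- sweep(Zc, 2, means[cl, ])
    S <- S + crossprod(Zc)
  }
  S <- S / (nrow(Z) - length(classes))
  S <- (1 - lambda) * S + lambda * diag(diag(S), p)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch))
    stop(errorCondition(
      "pooled covariance is singular despite shrinkage",
      class = c("somnostage_numeric_error", "somnostage_error")))
  Sinv <- chol2inv(ch)

  pri <- if (priors == "empirical") {
    as.numeric(table(factor(yp, levels = classes))) / length(yp)
  } else rep(1 / length(classes), length(classes))
  names(pri) <- classes

  structure(list(classes = classes, system_id = system$id,
                 class_means = means, pooled_covariance = S,
                 cov_inverse = Sinv, priors = pri, shrinkage = lambda,
                 center = center, scale = scale,
                 feature_names = colnames(Xp) %||% all_feature_names()),
            class = "ld_model")
}

#' @export
print.ld_model <- function(x, ...) {
  cat(sprintf("<ld_model> system '%s', classes: %s; shrinkage %.2f\n",
              x$system_id, paste(x$classes, collapse = ", "), x$shrinkage))
  invisible(x)
}

#' Predict sleep stages for a feature matrix
#'
#' Evaluates the linear discriminant scores
#' `delta_k(x) = x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k` on
#' normalized features and assigns each epoch to the arg-max class.
#' Posteriors are the softmax of the scores. Ties are broken toward W,
#' then by class order.
#'
#' @param model an `ld_model` from [train_ld()].
#' @param X an [epoch_feature_matrix()] or numeric matrix with matching
#'   columns.
#' @return a list with `hypnogram` (predicted labels in the model's stage
#'   system) and `posterior` (n x K matrix, rows summing to 1).
#' @export
predict_stages <- function(model, X) {
  stopifnot(inherits(model, "ld_model"))
  M <- if (inherits(X, "epoch_feature_matrix")) X$values else as.matrix(X)
  if (ncol(M) != length(model$center))
    abort_argument(sprintf("feature matrix has %d columns; model expects %d",
                           ncol(M), length(model$center)))
  Z <- sweep(sweep(M, 2, model$center), 2, model$scale, "/")
  A <- model$cov_inverse %*% t(model$class_means)          # p x K
  const <- -0.5 * colSums(t(model$class_means) * A) + log(model$priors)
  delta <- sweep(Z %*% A, 2, const, "+")
  ## classes are ordered W-first, so which.max's first-match rule implements
  ## the tie-break toward W then earlier class order
  idx <- apply(delta, 1, which.max)
  post <- exp(delta - apply(delta, 1, max))
  post <- post / rowSums(post)
  colnames(post) <- model$classes
  list(hypnogram = hypnogram(model$classes[idx], model$system_id),
       posterior = post)
}

#' Serialize / load a trained model as JSON
#' @param model an `ld_model`.
#' @param path file path.
#' @return `path` invisibly; `read_ld_model()` returns the `ld_model`.
#' @export
write_ld_model <- function(model, path) {
  stopifnot(inherits(model, "ld_model"))
  obj <- list(classes = model$classes, system_id = model$system_id,
              class_means = model$class_means,
              pooled_covariance = model$pooled_covariance,
              priors = model$priors, shrinkage = model$shrinkage,
              center = model$center, scale = model$scale,
              feature_names = model$feature_names)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_ld_model
#' @export
read_ld_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  S <- as.matrix(obj$pooled_covariance)
  means <- as.matrix(obj$class_means)
  dimnames(means) <- list(obj$classes, obj$feature_names)
  pri <- as.numeric(obj$priors); names(pri) <- obj$classes
  structure(list(classes = obj$classes, system_id = obj$system_id,
                 class_means = means, pooled_covariance = S,
                 cov_inverse = chol2inv(chol(S)), priors = pri,
                 shrinkage = obj$shrinkage,
                 center = as.numeric(obj$center), scale = as.numeric(obj$scale),
                 feature_names = obj$feature_names),
            class = "ld_model")
}
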