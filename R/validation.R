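#' Unweighted Cohen's kappa
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' `p_o` the observed agreement and `p_e` the chance agreement expected
#' from the two raters' marginal label frequencies. When `p_e = 1` (both
#' raters constant on the same label) the coefficient is degenerate:
#' 1 is returned for perfect agreement, otherwise 0 with a warning.
#'
#' @param ref,pred equal-length label vectors over a shared alphabet.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(ref, pred) {
  if (length(ref) != length(pred))
    abort_argument("`ref` and `pred` must have equal length")
  if (!length(ref)) abort_argument("empty label vectors")
  lev <- union(unique(as.character(ref)), unique(as.character(pred)))
  tab <- table(factor(ref, levels = lev), factor(pred, levels = lev))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps * 8) {
    if (p_o == 1) return(1)
    warning("degenerate marginals (chance agreement = 1); returning 0")
    return(0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Agreement report between a reference and a predicted hypnogram
#'
#' Confusion matrix (reference rows x predicted columns), per-stage
#' accuracy (percentage of each reference stage correctly classified),
#' overall accuracy and unweighted Cohen kappa.
#'
#' @param ref,pred [hypnogram()]s (or label vectors) in the same alphabet.
#' @param classes label set; defaults to the reference alphabet.
#' @return an `agreement_report`.
#' @export
agreement_report <- function(ref, pred, classes = NULL) {
  r <- if (inherits(ref, "hypnogram")) ref$labels else as.character(ref)
  p <- if (inherits(pred, "hypnogram")) pred$labels else as.character(pred)
  if (length(r) != length(p))
    abort_argument("reference and prediction must have equal length")
  if (is.null(classes)) {
    classes <- if (inherits(ref, "hypnogram")) stage_alphabets[[ref$alphabet_id]]
               else sort(union(unique(r), unique(p)))
  }
  cm <- table(reference = factor(r, levels = classes),
              predicted = factor(p, levels = classes))
  per_stage <- 100 * diag(cm) / rowSums(cm)    # NaN for absent stages
  structure(list(confusion_matrix = unclass(cm),
                 per_stage_accuracy = per_stage,
                 overall_accuracy = 100 * sum(diag(cm)) / sum(cm),
                 kappa = cohen_kappa(r, p),
                 n_epochs = length(r)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d epochs, overall accuracy %.1f%%, kappa %.3f\n",
              x$n_epochs, x$overall_accuracy, x$kappa))
  print(round(x$per_stage_accuracy, 1))
  invisible(x)
}

#' Leave-one-out cross validation of the stage classifier
#'
#' For each subject, trains the linear discriminant on all other subjects
#' and predicts the held-out subject, until every subject has been tested
#' once. Per-stage accuracy is averaged over folds (a stage absent from a
#' fold's reference, or a fold whose training set lacks a class, is
#' excluded from that stage's average); a pooled confusion matrix over all
#' epochs is also reported.
#'
#' @param cohort list of subjects, each a list with elements `features`
#'   (an [epoch_feature_matrix()]) and `hypnogram` (raw [hypnogram()]).
#' @param system a [stage_system()] or id string.
#' @param lambda,priors passed to [train_ld()].
#' @return a `loocv_result` with `folds` (per-subject predictions and
#'   reports), `pooled` (pooled `agreement_report`),
#'   `per_stage_accuracy_mean` (fold average), `kappa_pooled`,
#'   `kappa_mean` (mean of per-subject kappas) and `skipped_folds`.
#' @export
loocv <- function(cohort, system = "s2", lambda = 0.1, priors = "empirical") {
  if (length(cohort) < 3L)
    abort_argument("leave-one-out cross validation needs at least 3 subjects")
  if (is.character(system)) system <- stage_system(system)
  n <- length(cohort)
  folds <- vector("list", n)
  skipped <- character(0)
  ids <- vapply(seq_len(n), function(i)
    cohort[[i]]$features$subject_id %||% NA_character_, character(1))
  ids <- ifelse(is.na(ids), paste0("subject", seq_len(n)), ids)
  for (i in seq_len(n)) {
    train <- cohort[-i]
    model <- tryCatch(
      train_ld(lapply(train, `[[`, "features"),
               lapply(train, `[[`, "hypnogram"),
               system, lambda = lambda, priors = priors),
      somnostage_error = function(e) e)
    if (inherits(model, "error")) {
      skipped <- c(skipped, ids[i])
      warning(sprintf("fold %s skipped: %s", ids[i], conditionMessage(model)))
      next
    }
    pred <- predict_stages(model, cohort[[i]]$features)
    ref <- map_stages(cohort[[i]]$hypnogram, system)
    folds[[i]] <- list(subject = ids[i], predicted = pred$hypnogram,
                       reference = ref, posterior = pred$posterior,
                       report = agreement_report(ref, pred$hypnogram,
                                                 classes = system$classes))
  }
  done <- !vapply(folds, is.null, logical(1))
  if (!any(done)) abort_data("every cross-validation fold failed")
  acc <- do.call(rbind, lapply(folds[done],
                               function(f) f$report$per_stage_accuracy))
  per_stage_mean <- colMeans(acc, na.rm = TRUE)
  ref_all <- unlist(lapply(folds[done], function(f) f$reference$labels))
  pred_all <- unlist(lapply(folds[done], function(f) f$predicted$labels))
  pooled <- agreement_report(ref_all, pred_all, classes = system$classes)
  kappas <- vapply(folds[done], function(f) f$report$kappa, numeric(1))
  structure(list(system_id = system$id, folds = folds[done],
                 pooled = pooled, per_stage_accuracy_mean = per_stage_mean,
                 overall_accuracy_mean = mean(vapply(
                   folds[done], function(f) f$report$overall_accuracy, numeric(1))),
                 kappa_pooled = pooled$kappa, kappa_mean = mean(kappas),
                 skipped_folds = skipped),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> system '%s', %d folds: pooled accuracy %.1f%%, kappa %.3f\n",
              x$system_id, length(x$folds), x$pooled$overall_accuracy,
              x$kappa_pooled))
  invisible(x)
}

#' Sleep summary of a 2-stage hypnogram
#'
#' Total sleep time (TST), total wake time (TWT), time in bed, sleep
#' efficiency `SE = 100 * TST / time_in_bed` and wake after sleep onset
#' (WASO, wake minutes after the first epoch scored sleep; 0 for an
#' all-wake night). Epochs contribute 0.5 min each.
#'
#' @param h a [hypnogram()] in the 2-stage (`s2`) alphabet.
#' @param onset_rule `"first"` (sleep onset = first S epoch, default) or
#'   `"first3"` (first of 3 consecutive S epochs).
#' @return a `sleep_summary` list with `SE` (percent), `TST`, `TWT`,
#'   `WASO`, `time_in_bed` (minutes).
#' @export
sleep_summary <- function(h, onset_rule = c("first", "first3")) {
  stopifnot(inherits(h, "hypnogram"))
  onset_rule <- match.arg(onset_rule)
  if (!length(h$labels)) abort_argument("empty hypnogram")
  if (h$alphabet_id != "s2")
    abort_argument("sleep_summary expects a 2-stage (s2) hypnogram; use map_stages()")
  s <- h$labels == "S"
  tst <- 0.5 * sum(s)
  twt <- 0.5 * sum(!s)
  tib <- 0.5 * length(s)
  onset <- if (onset_rule == "first") {
    which(s)[1]
  } else {
    runs <- which(s & c(s[-1], FALSE) & c(s[-(1:2)], FALSE, FALSE))
    runs[1]
  }
  waso <- if (is.na(onset %||% NA)) 0 else 0.5 * sum(!s[seq_along(s) > onset])
  structure(list(SE = 100 * tst / tib, TST = tst, TWT = twt,
                 WASO = waso, time_in_bed = tib),
            class = "sleep_summary")
}

#' @export
print.sleep_summary <- function(x, ...) {
  cat(sprintf("<sleep_summary> SE %.1f%% | TST %.1f | TWT %.1f | WASO %.1f | TIB %.1f min\n",
              x$SE, x$TST, x$TWT, x$WASO, x$time_in_bed))
  invisible(x)
}

#' Sleep-efficiency group
#'
#' Bins a sleep efficiency into the screening groups 0--39%, 40--59%,
#' 60--79% and >=80%. Boundaries belong to the upper group (SE = 40 is in
#' 40--59).
#'
#' @param se sleep efficiency percentage in `[0, 100]`.
#' @return factor with levels `"0-39" "40-59" "60-79" ">=80"`.
#' @export
se_group <- function(se) {
  if (any(!is.finite(se)) || any(se < 0 | se > 100))
    abort_argument("`se` must be within [0, 100]")
  cut(se, breaks = c(-Inf, 40, 60, 80, Inf), right = FALSE,
      labels = c("0-39", "40-59", "60-79", ">=80"))
}

#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over the continuous scores against fixed
#' binary labels; the AUC is the trapezoidal area under the resulting
#' TPR/FPR curve (ties handled by grouping equal scores, which makes the
#' area equal the Mann-Whitney probability with ties counted 1/2).
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector, `TRUE` = positive.
#' @return a list with `fpr`, `tpr`, `thresholds` and `auc`; `auc` is `NA`
#'   when either class is empty.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    abort_argument("`scores` and `labels` must have equal length")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(grp, fromLast = TRUE)      # last index of each tie group
  tpr <- c(0, tp[last] / max(n_pos, 1L))
  fpr <- c(0, fp[last] / max(n_neg, 1L))
  auc <- if (n_pos == 0L || n_neg == 0L) NA_real_ else
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, s[last]), auc = auc)
}

#' Sleep-efficiency group screening metrics
#'
#' Binary screening at one SE threshold: subjects with estimated
#' `SE >= threshold` are called positive and compared with the reference
#' (PSG) grouping. Reports sensitivity, specificity, PPV, NPV (percent),
#' Cohen kappa on the binary labels, and the ROC/AUC obtained by sweeping
#' the decision threshold over the estimated SE against the fixed
#' reference membership.
#'
#' @param est_se,psg_se paired per-subject sleep efficiencies (percent).
#' @param threshold one of 40, 60, 80.
#' @return a `screening_report`; rates that are undefined (no subject on
#'   one side of the reference threshold) are `NA`.
#' @export
screening_metrics <- function(est_se, psg_se, threshold) {
  if (length(est_se) != length(psg_se))
    abort_argument("`est_se` and `psg_se` must be paired")
  if (!threshold %in% c(40, 60, 80))
    abort_argument("`threshold` must be one of 40, 60, 80")
  est_pos <- est_se >= threshold
  ref_pos <- psg_se >= threshold
  tp <- sum(est_pos & ref_pos);  fp <- sum(est_pos & !ref_pos)
  fn <- sum(!est_pos & ref_pos); tn <- sum(!est_pos & !ref_pos)
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  kap <- if (length(unique(ref_pos)) < 2L && !identical(est_pos, ref_pos))
    NA_real_ else suppressWarnings(cohen_kappa(ref_pos, est_pos))
  roc <- roc_curve(est_se, ref_pos)
  structure(list(threshold = threshold,
                 sensitivity = rate(tp, tp + fn),
                 specificity = rate(tn, tn + fp),
                 PPV = rate(tp, tp + fp), NPV = rate(tn, tn + fn),
                 kappa = kap, auc = roc$auc, roc = roc,
                 table = matrix(c(tp, fn, fp, tn), 2, 2,
                                dimnames = list(est = c("pos", "neg"),
                                                ref = c("pos", "neg")))),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf(
    "<screening_report> SE >= %d%%: sens %.1f%%, spec %.1f%%, PPV %.1f%%, NPV %.1f%%, kappa %.3f, AUC %.3f\n",
    x$threshold, x$sensitivity, x$specificity, x$PPV, x$NPV, x$kappa, x$auc))
  invisible(x)
}

#' Correlation and paired-difference summary
#'
#' Compares estimated against reference values (e.g. SE_est vs SE_PSG):
#' coefficient of determination of the least-squares fit, and paired
#' t statistics of the differences (mean, SD, 95% CI, p).
#'
#' @param est,ref paired numeric vectors of length >= 3.
#' @return a list with `r2`, `mean_diff`, `sd_diff`, `ci95`, `p_value`, `n`.
#' @export
correlation_summary <- function(est, ref) {
  if (length(est) != length(ref)) abort_argument("`est` and `ref` must be paired")
  if (length(est) < 3L) abort_argument("need at least 3 pairs")
  r2 <- if (stats::sd(est) == 0 || stats::sd(ref) == 0) NA_real_
        else stats::cor(est, ref)^2
  d <- est - ref
  tt <- if (stats::sd(d) == 0) NULL else stats::t.test(d)
  list(r2 = r2, mean_diff = mean(d), sd_diff = stats::sd(d),
       ci95 = if (is.null(tt)) c(mean(d), mean(d)) else as.numeric(tt$conf.int),
       p_value = if (is.null(tt)) NA_real_ else tt$p.value,
       n = length(est))
}
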