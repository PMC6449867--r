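## Independent oracles used across test files. These deliberately use the
## most transparent (brute-force) formulation of each rule, never the
## package's own code paths.

## fraction of truth events with a detection within tol seconds
event_recall <- function(truth, detected, tol) {
  if (!length(truth)) return(NA_real_)
  mean(vapply(truth, function(t) any(abs(detected - t) <= tol), logical(1)))
}

## per-truth-event time error of the nearest detection
nearest_error <- function(truth, detected) {
  vapply(truth, function(t) detected[which.min(abs(detected - t))] - t,
         numeric(1))
}

## brute-force Cohen kappa straight from the contingency definition
kappa_bruteforce <- function(ref, pred) {
  lev <- union(unique(ref), unique(pred))
  n <- length(ref)
  p_o <- sum(ref == pred) / n
  p_e <- 0
  for (l in lev)
    p_e <- p_e + (sum(ref == l) / n) * (sum(pred == l) / n)
  (p_o - p_e) / (1 - p_e)
}

## Mann-Whitney formulation of the AUC (ties count 1/2)
auc_mann_whitney <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

## exhaustive run-finding oracle for breath detection: maximal runs of
## envelope values above thr with duration inside [dmin, dmax]
breath_runs_oracle <- function(values, times, hop, thr, dmin, dmax) {
  above <- values > thr
  onsets <- numeric(0)
  i <- 1L
  while (i <= length(above)) {
    if (above[i]) {
      j <- i
      while (j < length(above) && above[j + 1L]) j <- j + 1L
      dur <- (j - i + 1L) * hop
      if (dur >= dmin && dur <= dmax) onsets <- c(onsets, times[i])
      i <- j + 1L
    } else i <- i + 1L
  }
  onsets
}

## transparent repeated-minimal-gap pairing oracle (O(n^3)): at each step
## scan every unused pair, take the smallest in-window gap (ties: earliest
## first peak), until no valid pair remains; beats at first peaks
pairing_oracle <- function(peaks, window = c(0.15, 0.45)) {
  used <- logical(length(peaks))
  beats <- numeric(0)
  repeat {
    best <- NULL; best_gap <- Inf
    for (i in seq_along(peaks)) {
      if (used[i]) next
      for (j in seq_along(peaks)) {
        if (j <= i || used[j]) next
        gap <- peaks[j] - peaks[i]
        if (gap >= window[1] && gap <= window[2] &&
            (gap < best_gap - 1e-12 ||
             (abs(gap - best_gap) <= 1e-12 && peaks[i] < peaks[best[1]]))) {
          best <- c(i, j); best_gap <- gap
        }
      }
    }
    if (is.null(best)) break
    used[best] <- TRUE
    beats <- c(beats, peaks[best[1]])
  }
  sort(beats)
}

## simulated nights for unit tests: short, fixed seed
quick_night <- function(minutes = 5, seed = 7, ...) {
  simulate_night(sim_config(night_minutes = minutes, ...), seed = seed)
}

## separable toy cohort for classifier tests: class means far apart, all
## 30 features present
toy_subject <- function(labels, seed, spread = 6) {
  set.seed(seed)
  raw_means <- list(W = 0, REM = spread, N1 = 2 * spread,
                    N2 = 3 * spread, N3 = 4 * spread)
  X <- t(vapply(labels, function(l) stats::rnorm(30, raw_means[[l]], 1),
                numeric(30)))
  list(features = epoch_feature_matrix(X, subject_id = paste0("toy", seed)),
       hypnogram = hypnogram(labels, "raw"),
       subject_id = paste0("toy", seed))
}
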