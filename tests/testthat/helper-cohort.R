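## The end-to-end synthetic study cohort: 10 subjects, 2-h nights, default
## physiology and SNR, wake-bias spread across the cohort. Built once per
## test run and shared by the end-to-end tests (generation + extraction is
## the expensive part).
.cohort_cache <- new.env(parent = emptyenv())

study_cohort <- function() {
  if (is.null(.cohort_cache$cohort)) {
    .cohort_cache$cohort <- build_cohort(10, sim_config(), seed = 1234)
  }
  .cohort_cache$cohort
}

## matched-event interval error: |estimated BB - true BB| over consecutive
## truth events that both matched a detection within tol
interval_mae <- function(truth, detected, tol) {
  nearest <- vapply(truth, function(t) detected[which.min(abs(detected - t))],
                    numeric(1))
  ok <- abs(nearest - truth) <= tol
  both <- ok[-length(ok)] & ok[-1]
  mean(abs(diff(nearest)[both] - diff(truth)[both]))
}

interval_rmse <- function(truth, detected, tol) {
  nearest <- vapply(truth, function(t) detected[which.min(abs(detected - t))],
                    numeric(1))
  ok <- abs(nearest - truth) <= tol
  both <- ok[-length(ok)] & ok[-1]
  sqrt(mean((diff(nearest)[both] - diff(truth)[both])^2))
}
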