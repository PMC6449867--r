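## Stage alphabets. "raw" is the manual scoring alphabet (one label per
## 30-s epoch); the three reduced systems regroup it for classification:
##   s2: wake vs sleep; s3: wake / REM / NREM; s4: wake / REM / light / deep.
stage_alphabets <- list(
  raw = c("W", "REM", "N1", "N2", "N3"),
  s2  = c("W", "S"),
  s3  = c("W", "REM", "NREM"),
  s4  = c("W", "REM", "LS", "DS"))

stage_mappings <- list(
  s2 = c(W = "W", REM = "S", N1 = "S", N2 = "S", N3 = "S"),
  s3 = c(W = "W", REM = "REM", N1 = "NREM", N2 = "NREM", N3 = "NREM"),
  s4 = c(W = "W", REM = "REM", N1 = "LS", N2 = "LS", N3 = "DS"))

#' Stage system definition
#'
#' Returns one of the three reduced sleep-stage systems: `"s2"` (wake W /
#' sleep S), `"s3"` (W / REM / NREM) or `"s4"` (W / REM / light sleep LS /
#' deep sleep DS), together with the total mapping from the raw scoring
#' alphabet `{W, REM, N1, N2, N3}`.
#'
#' @param id one of `"s2"`, `"s3"`, `"s4"`.
#' @return a list with `id`, `classes` (ordered label set, W first) and
#'   `raw_mapping` (named character, raw label -> class).
#' @export
stage_system <- function(id = c("s2", "s3", "s4")) {
  id <- match.arg(id)
  structure(list(id = id, classes = stage_alphabets[[id]],
                 raw_mapping = stage_mappings[[id]]),
            class = "stage_system")
}

#' Hypnogram container
#'
#' A sequence of sleep-stage labels, one per fixed 30-second epoch.
#'
#' @param labels character vector of stage labels.
#' @param alphabet_id one of `"raw"`, `"s2"`, `"s3"`, `"s4"`.
#' @param epoch_seconds epoch length; fixed at 30 s (AASM convention).
#' @return an object of class `hypnogram`.
#' @export
hypnogram <- function(labels, alphabet_id = "raw", epoch_seconds = 30) {
  if (!alphabet_id %in% names(stage_alphabets))
    abort_argument(sprintf("unknown stage alphabet: %s", alphabet_id))
  if (epoch_seconds != 30)
    abort_argument("epoch_seconds is fixed at 30")
  labels <- as.character(labels)
  bad <- which(!labels %in% stage_alphabets[[alphabet_id]])
  if (length(bad))
    abort_data(sprintf(
      "label(s) outside alphabet '%s' at epoch index(es): %s (first offending label '%s')",
      alphabet_id, paste(utils::head(bad, 5L), collapse = ", "), labels[bad[1]]))
  structure(list(labels = labels, alphabet_id = alphabet_id,
                 epoch_seconds = 30), class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs (%.1f min), alphabet '%s'\n",
              length(x$labels), length(x$labels) * 0.5, x$alphabet_id))
  print(table(factor(x$labels, levels = stage_alphabets[[x$alphabet_id]])))
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$labels)

#' Read / write a hypnogram
#'
#' Accepts either one label per line or a CSV with columns `epoch,label`
#' (the writer emits the CSV form, so write-then-read is the identity).
#'
#' @param path file path.
#' @param alphabet_id alphabet the labels must belong to.
#' @return a [hypnogram()].
#' @export
read_hypnogram <- function(path, alphabet_id = "raw") {
  if (!file.exists(path))
    abort_format(sprintf("hypnogram file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    abort_data(sprintf("empty hypnogram file: %s", path))
  if (any(grepl(",", lines, fixed = TRUE))) {
    d <- utils::read.csv(path, colClasses = c("integer", "character"))
    if (!all(c("epoch", "label") %in% names(d)))
      abort_format(sprintf("hypnogram CSV %s must have columns epoch,label", path))
    labels <- d$label[order(d$epoch)]
  } else {
    labels <- trimws(lines)
  }
  hypnogram(labels, alphabet_id)
}

#' @rdname read_hypnogram
#' @param h a [hypnogram()] to write.
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  d <- data.frame(epoch = seq_along(h$labels) - 1L, label = h$labels)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map a raw hypnogram into a reduced stage system
#'
#' Relabels every epoch by the system's raw mapping (e.g. N2 becomes S in
#' the 2-stage, NREM in the 3-stage and LS in the 4-stage system). A
#' hypnogram already in the target system is returned unchanged.
#'
#' @param h a [hypnogram()] in the raw alphabet.
#' @param system a [stage_system()] or system id string.
#' @return a [hypnogram()] in the system's alphabet, same epoch count.
#' @export
map_stages <- function(h, system) {
  stopifnot(inherits(h, "hypnogram"))
  if (is.character(system)) system <- stage_system(system)
  if (h$alphabet_id == system$id) return(h)
  if (h$alphabet_id != "raw")
    abort_data(sprintf("cannot map alphabet '%s' into system '%s'",
                       h$alphabet_id, system$id))
  mapped <- unname(system$raw_mapping[h$labels])
  if (anyNA(mapped))
    abort_data("unmapped label in hypnogram")
  hypnogram(mapped, system$id)
}

#' Epoch grid
#'
#' The shared 30-second scoring grid: epoch `k` (0-based) covers the
#' half-open interval `[30k, 30(k+1))` seconds from the recording start.
#' A trailing partial epoch is discarded.
#'
#' @param duration_s recording duration in seconds (> 0).
#' @return an object of class `epoch_grid` with `n_epochs` and
#'   `epoch_seconds`.
#' @export
align_to_epochs <- function(duration_s) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    abort_argument("`duration_s` must be a single positive number")
  structure(list(n_epochs = as.integer(floor(duration_s / 30 + 1e-9)),
                 epoch_seconds = 30), class = "epoch_grid")
}

#' @rdname align_to_epochs
#' @param n_epochs number of epochs.
#' @export
epoch_grid <- function(n_epochs) {
  structure(list(n_epochs = as.integer(n_epochs), epoch_seconds = 30),
            class = "epoch_grid")
}

## [start, end) of 0-based epoch k, in seconds
epoch_bounds <- function(grid, k) c(start = 30 * k, end = 30 * (k + 1))
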