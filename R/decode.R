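#' Build population spike-count vectors for decoding
#'
#' For each trial, the spike count of a fixed random subset of neurons
#' (default 50) over the raster window, labelled by the trial's stimulus
#' pattern.
#'
#' @param raster A [spike_raster()] whose trials carry pattern labels.
#' @param n_sample Number of neurons in the subset.
#' @param neurons Optional explicit neuron ids (overrides random sampling).
#' @param seed Seed for the neuron subset.
#' @return A list with `counts` (trials x neurons integer matrix), `labels`
#'   (pattern per trial) and `neurons` (the subset used).
#' @export
population_vectors <- function(raster, n_sample = 50, neurons = NULL,
                               seed = 1) {
  pat <- attr(raster, "trial_patterns")
  if (is.null(pat)) {
    if (!"pattern" %in% names(raster))
      abort("raster carries no pattern labels.")
    pat <- dplyr::arrange(dplyr::distinct(tibble::as_tibble(raster),
                                          .data$trial, .data$pattern),
                          .data$trial)
    full <- rep(NA_integer_, raster_n_trials(raster))
    full[pat$trial] <- pat$pattern
    pat <- full
    if (anyNA(pat))
      abort("some trials have no spikes and no recorded pattern label; supply `trial_patterns` to `spike_raster()`.")
  }
  if (is.null(neurons)) {
    neurons <- with_seed(seed,
      sort(sample(raster_n_neurons(raster), n_sample)))
  }
  win <- raster_window(raster)
  ev <- tibble::as_tibble(raster)
  ev <- ev[ev$t_ms >= win[1] & ev$t_ms < win[2] &
             ev$neuron %in% neurons, , drop = FALSE]
  counts <- matrix(0L, nrow = raster_n_trials(raster),
                   ncol = length(neurons),
                   dimnames = list(NULL, paste0("n", neurons)))
  if (nrow(ev) > 0) {
    idx <- cbind(ev$trial, match(ev$neuron, neurons))
    agg <- dplyr::count(tibble::tibble(trial = idx[, 1], col = idx[, 2]),
                        .data$trial, .data$col)
    counts[cbind(agg$trial, agg$col)] <- agg$n
  }
  list(counts = counts, labels = as.integer(pat), neurons = neurons)
}

#' Decode stimulus patterns from population vectors
#'
#' Trains and tests a k-nearest-neighbour classifier (Euclidean distance on
#' spike counts, majority vote) with stratified cross-validation, and
#' reports held-out accuracy.
#'
#' @param counts Trials x neurons count matrix (e.g. from
#'   [population_vectors()]).
#' @param labels Integer pattern label per trial.
#' @param k Number of neighbours (default 5).
#' @param folds Number of stratified folds (default 5).
#' @param seed Seed for fold assignment.
#' @return A list of class `decode_result`: `accuracy` (mean held-out),
#'   `fold_accuracy`, `chance` (1 / number of classes), `confusion`
#'   (tibble `truth`, `predicted`, `n`), `k`, `folds`.
#' @export
decode_patterns <- function(counts, labels, k = 5, folds = 5, seed = 1) {
  labels <- as.integer(labels)
  stopifnot(nrow(counts) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    abort("decoding needs at least 2 classes.")
  tab <- table(labels)
  if (any(tab < folds))
    abort(sprintf("every class needs at least %d members for %d-fold stratified CV.",
                  folds, folds),
          class = "gabashunt_stratification_error")

  fold_of <- with_seed(seed, {
    fo <- integer(length(labels))
    for (cl in classes) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fo[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fo
  })

  preds <- integer(length(labels))
  for (f in seq_len(folds)) {
    te <- fold_of == f
    pr <- class::knn(train = counts[!te, , drop = FALSE],
                     test = counts[te, , drop = FALSE],
                     cl = factor(labels[!te], levels = classes), k = k)
    preds[te] <- classes[as.integer(pr)]
  }
  fold_acc <- vapply(seq_len(folds), function(f)
    mean(preds[fold_of == f] == labels[fold_of == f]), numeric(1))
  conf <- dplyr::count(tibble::tibble(truth = labels, predicted = preds),
                       .data$truth, .data$predicted)
  structure(list(accuracy = mean(preds == labels),
                 fold_accuracy = fold_acc,
                 chance = 1 / length(classes),
                 confusion = conf, k = k, folds = folds),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode_result> accuracy %.3f (chance %.3f), k = %d, %d-fold stratified CV\n",
              x$accuracy, x$chance, x$k, x$folds))
  invisible(x)
}

#' @rdname tidy.egaba_fit
#' @method glance decode_result
#' @export
glance.decode_result <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, chance = x$chance, k = x$k,
                 folds = x$folds)
}
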