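## Snapshot-ensemble training under cosine annealing with warm restarts.
##
## A single model instance is trained for T epochs with SGD + momentum;
## the learning rate follows a half-cosine decay within each of M cycles
## of length T/M and resets to the maximum at each cycle start. The
## weights at the end of each cycle (i.e. at the learning-rate minimum)
## are kept as one snapshot, yielding an M-member ensemble from one run.
## Ensemble predictions are the arithmetic mean of the member outputs.

#' Cosine-annealing-with-restarts schedule parameters
#'
#' @param a0 maximum learning rate.
#' @param total_epochs total epochs T.
#' @param n_cycles number of cycles/snapshots M; must divide T.
#' @return a `smad_schedule` list.
#' @export
schedule_params <- function(a0 = 0.1, total_epochs = 200L, n_cycles = 10L) {
  stopifnot(a0 > 0, n_cycles >= 1, total_epochs >= n_cycles)
  if (total_epochs %% n_cycles != 0)
    stop("total_epochs must be a multiple of n_cycles")
  structure(list(a0 = a0, total_epochs = as.integer(total_epochs),
                 n_cycles = as.integer(n_cycles)),
            class = "smad_schedule")
}

#' Cosine-annealing learning rate with warm restarts
#'
#' The learning rate at epoch `t` (1-based) is
#' \deqn{a(t) = \frac{a_0}{2}\left[\cos\!\left(\frac{\pi\,((t-1) \bmod
#'   T/M)}{T/M}\right) + 1\right]}
#' so each cycle of length T/M starts at the maximum `a0` and decays
#' along a half-cosine, restarting at every cycle boundary.
#'
#' @param t epoch index (1..T), vectorized.
#' @param a0 maximum learning rate.
#' @param total_epochs total epochs T.
#' @param n_cycles number of cycles M.
#' @return learning rate(s) in (0, a0].
#' @export
cosine_annealing_lr <- function(t, a0 = 0.1, total_epochs = 200L,
                                n_cycles = 10L) {
  if (total_epochs %% n_cycles != 0)
    stop("total_epochs must be a multiple of n_cycles")
  if (any(t < 1) || any(t > total_epochs))
    stop("epoch index out of range 1..", total_epochs)
  cl <- total_epochs / n_cycles
  (a0 / 2) * (cos(pi * ((t - 1) %% cl) / cl) + 1)
}

#' Split a dataset into training and test sets
#'
#' The training set has `round(fraction * N)` members. Stratified
#' splitting (the default) preserves class proportions to within one
#' sequence per class.
#'
#' @param ids identifier vector.
#' @param labels class labels parallel to `ids` (required when
#'   `stratified`).
#' @param fraction training fraction (default 0.75).
#' @param seed RNG seed for the shuffle.
#' @param stratified preserve class proportions.
#' @return list with `train_ids`, `test_ids`, `train_idx`, `test_idx`,
#'   `fraction`, `seed`.
#' @export
split_dataset <- function(ids, labels = NULL, fraction = 0.75, seed = NULL,
                          stratified = TRUE) {
  n <- length(ids)
  stopifnot(n >= 4, fraction > 0, fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  n_train <- as.integer(round(fraction * n))
  if (stratified) {
    if (is.null(labels) || length(labels) != n)
      stop("stratified splitting requires labels")
    labels <- as.character(labels)
    if (any(table(labels) < 2))
      stop("every class needs at least 2 members for a stratified split")
    classes <- names(sort(table(labels), decreasing = TRUE))
    take <- setNames(as.integer(round(fraction * table(labels)[classes])),
                     classes)
    # reconcile per-class rounding with the overall round(fraction * N)
    excess <- sum(take) - n_train
    take[1] <- take[1] - excess
    train_idx <- integer(0)
    for (cl in classes) {
      i <- which(labels == cl)
      train_idx <- c(train_idx, sample(i, take[cl]))
    }
    train_idx <- sort(train_idx)
  } else {
    train_idx <- sort(sample.int(n, n_train))
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train_ids = ids[train_idx], test_ids = ids[test_idx],
       train_idx = train_idx, test_idx = test_idx,
       fraction = fraction, seed = seed)
}

#' Train a snapshot ensemble
#'
#' Trains one model for `schedule$total_epochs` epochs of mini-batch SGD
#' (momentum 0.9 by default) under the cosine-annealing-with-restarts
#' schedule, copying the weights out at the end of each cycle. The M
#' snapshots form the ensemble.
#'
#' @param spec a [model_spec()]; dense sizes derived from the training
#'   size unless fixed in the spec.
#' @param x a `smad_onehot` training batch.
#' @param labels `"SMAD2"`/`"SMAD3"` labels (taken from `x$labels` when
#'   omitted).
#' @param schedule a [schedule_params()].
#' @param batch_size mini-batch size.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty applied to weight matrices (not biases
#'   or batch-norm parameters) during the SGD update.
#' @param clip_norm global gradient-norm clipping threshold (0 disables);
#'   stabilizes backpropagation through the recurrent layer.
#' @param seed seed controlling weight init, shuffling and dropout.
#' @param verbose print per-epoch loss.
#' @return a `smad_ensemble`: `spec`, list of `snapshots` (parameter
#'   sets), and a `manifest` with the learning-rate and loss traces.
#' @export
train_snapshot_ensemble <- function(spec, x, labels = NULL,
                                    schedule = schedule_params(),
                                    batch_size = 16L, momentum = 0.9,
                                    weight_decay = 1e-4, clip_norm = 1,
                                    seed = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "smad_model_spec"),
            inherits(schedule, "smad_schedule"))
  arr <- as_input_array(x)
  if (is.null(labels)) labels <- x$labels
  if (is.null(labels)) stop("training requires labels")
  y <- encode_labels(labels)
  if (length(unique(y)) < 2)
    stop("training labels contain a single class")
  n_train <- dim(arr)[1]
  model <- build_model(spec, n_train = n_train, seed = seed)
  lr <- cosine_annealing_lr(seq_len(schedule$total_epochs),
                            a0 = schedule$a0,
                            total_epochs = schedule$total_epochs,
                            n_cycles = schedule$n_cycles)
  cycle_len <- schedule$total_epochs %/% schedule$n_cycles
  fit <- .nn_train(model$params, unclass(model$spec), arr, y, lr,
                   as.integer(batch_size), momentum, weight_decay,
                   clip_norm, cycle_len, verbose)
  if (any(!is.finite(fit$loss)))
    warning("training loss diverged; consider lowering a0")
  structure(list(
    spec = model$spec,
    snapshots = fit$snapshots,
    manifest = list(schedule = unclass(schedule), lr = lr,
                    loss = as.numeric(fit$loss), seed = seed,
                    batch_size = as.integer(batch_size),
                    momentum = momentum, weight_decay = weight_decay,
                    clip_norm = clip_norm, n_train = n_train)),
    class = "smad_ensemble")
}

#' @export
print.smad_ensemble <- function(x, ...) {
  cat("<smad_ensemble> ", x$spec$arch, ", ", length(x$snapshots),
      " snapshot(s)\n", sep = "")
  m <- x$manifest
  cat(" schedule: a0=", m$schedule$a0, " T=", m$schedule$total_epochs,
      " M=", m$schedule$n_cycles, "\n", sep = "")
  cat(" final training loss:", round(tail(m$loss, 1), 4), "\n")
  invisible(x)
}

# one snapshot viewed as a standalone model
snapshot_model <- function(ensemble, i) {
  structure(list(spec = ensemble$spec, params = ensemble$snapshots[[i]],
                 n_train = ensemble$manifest$n_train),
            class = "smad_model")
}

#' Per-snapshot prediction matrix
#'
#' One column of probabilities per snapshot; useful for caching when the
#' ensemble is evaluated over many member subsets.
#'
#' @param ensemble a `smad_ensemble`.
#' @param x a `smad_onehot` batch or array.
#' @return numeric matrix, `n_sequences x n_snapshots`.
#' @export
predict_snapshots <- function(ensemble, x) {
  stopifnot(inherits(ensemble, "smad_ensemble"))
  vapply(seq_along(ensemble$snapshots),
         function(i) predict_proba(snapshot_model(ensemble, i), x),
         numeric(dim(as_input_array(x))[1]))
}

#' Ensemble prediction
#'
#' Arithmetic mean of the per-snapshot probabilities over the chosen
#' subset of members (all by default).
#'
#' @param ensemble a `smad_ensemble`.
#' @param x a `smad_onehot` batch or array.
#' @param subset optional integer indices of the snapshots to average.
#' @return numeric vector of probabilities.
#' @export
predict_ensemble <- function(ensemble, x, subset = NULL) {
  stopifnot(inherits(ensemble, "smad_ensemble"))
  M <- length(ensemble$snapshots)
  if (is.null(subset)) subset <- seq_len(M)
  subset <- as.integer(subset)
  if (length(subset) == 0) stop("snapshot subset is empty")
  if (any(subset < 1 | subset > M)) stop("snapshot index out of range")
  P <- vapply(subset,
              function(i) predict_proba(snapshot_model(ensemble, i), x),
              numeric(dim(as_input_array(x))[1]))
  rowMeans(matrix(P, ncol = length(subset)))
}
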