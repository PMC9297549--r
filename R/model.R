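## Model specification and construction for the two sequence classifiers.
##
## Both architectures start with a narrow convolution (kernel 5) acting as
## a local motif detector over the 5-channel one-hot input. The CNN adds a
## second, wide convolution stack (kernel 32) to capture longer-range
## patterns; the CNN-LSTM instead feeds the pooled feature maps to a
## 32-cell LSTM and classifies from its final hidden state. In both cases
## the features are batch normalized and passed through two ReLU dense
## layers (sized by the minimal-capacity rule below, separated by a 0.2
## dropout) into a single sigmoid output unit.

#' Minimal dense-layer sizes for a two-hidden-layer classifier
#'
#' Implements the two-hidden-layer sizing rule of Huang (2003) for the
#' minimum number of hidden neurons sufficient to realize an arbitrary
#' labeling of `n_train` samples with `m_outputs` outputs:
#' \deqn{d_1 = \lceil \sqrt{(m+2)N} + 2\sqrt{N/(m+2)} \rceil,\quad
#'       d_2 = \lceil m\sqrt{N/(m+2)} \rceil}
#' with \eqn{N} the training-set size and \eqn{m} the output count.
#'
#' @param n_train number of training samples.
#' @param m_outputs number of output units (1 for binary classification).
#' @return integer vector `c(dense1, dense2)`.
#' @export
compute_dense_sizes <- function(n_train, m_outputs = 1L) {
  if (n_train < 1 || m_outputs < 1) stop("n_train and m_outputs must be >= 1")
  N <- as.numeric(n_train); m <- as.numeric(m_outputs)
  d1 <- ceiling(sqrt((m + 2) * N) + 2 * sqrt(N / (m + 2)))
  d2 <- ceiling(m * sqrt(N / (m + 2)))
  c(as.integer(d1), as.integer(d2))
}

#' Specify a classifier architecture
#'
#' @param arch `"cnn"` or `"cnn_lstm"`.
#' @param input_width sequence width in bp (default 200).
#' @param n_channels one-hot channels (5: A,T,C,G,N).
#' @param conv1_kernel kernel length of the motif-detector convolution.
#' @param conv1_filters number of filters in the first convolution.
#' @param pool_size max-pooling width/stride.
#' @param conv2_kernel,conv2_filters second convolution stack (CNN only);
#'   the wide 32-bp kernel captures patterns beyond single motifs.
#' @param lstm_units LSTM cells (CNN-LSTM only).
#' @param dense1_units,dense2_units dense-layer sizes; left `NULL` to be
#'   derived from the training-set size via [compute_dense_sizes()] at
#'   build time.
#' @param dropout dropout ratio between the two dense layers.
#' @return a `smad_model_spec` list.
#' @export
model_spec <- function(arch = c("cnn", "cnn_lstm"), input_width = 200L,
                       n_channels = 5L, conv1_kernel = 5L,
                       conv1_filters = 16L, pool_size = 2L,
                       conv2_kernel = 32L, conv2_filters = 16L,
                       lstm_units = 32L, dense1_units = NULL,
                       dense2_units = NULL, dropout = 0.2) {
  arch <- match.arg(arch)
  spec <- list(arch = arch, input_width = as.integer(input_width),
               n_channels = as.integer(n_channels),
               conv1_kernel = as.integer(conv1_kernel),
               conv1_filters = as.integer(conv1_filters),
               pool_size = as.integer(pool_size),
               conv2_kernel = as.integer(conv2_kernel),
               conv2_filters = as.integer(conv2_filters),
               lstm_units = as.integer(lstm_units),
               dense1_units = dense1_units, dense2_units = dense2_units,
               dropout = dropout)
  class(spec) <- "smad_model_spec"
  validate_spec_dims(spec)
  spec
}

# width arithmetic for "valid" convolutions and non-overlapping pooling;
# errors carry the computed minimum width so callers can fix their input
validate_spec_dims <- function(spec) {
  L1 <- spec$input_width - spec$conv1_kernel + 1L
  P1 <- L1 %/% spec$pool_size
  if (P1 < 1)
    stop("input width ", spec$input_width, " too small; minimum is ",
         spec$conv1_kernel + spec$pool_size - 1L)
  if (spec$arch == "cnn") {
    L2 <- P1 - spec$conv2_kernel + 1L
    if (L2 %/% spec$pool_size < 1) {
      min_P1 <- spec$conv2_kernel + spec$pool_size - 1L
      min_w <- min_P1 * spec$pool_size + spec$conv1_kernel - 1L
      stop("input width ", spec$input_width, " too small for conv2 kernel ",
           spec$conv2_kernel, "; minimum input width is ", min_w)
    }
  }
  invisible(spec)
}

# flattened feature dimension entering batch normalization
feature_dim <- function(spec) {
  L1 <- spec$input_width - spec$conv1_kernel + 1L
  P1 <- L1 %/% spec$pool_size
  if (spec$arch == "cnn_lstm") return(spec$lstm_units)
  L2 <- P1 - spec$conv2_kernel + 1L
  P2 <- L2 %/% spec$pool_size
  P2 * spec$conv2_filters
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

init_params <- function(spec) {
  kC <- spec$conv1_kernel * spec$n_channels
  f1 <- spec$conv1_filters
  D <- feature_dim(spec)
  p <- list(conv1_W = glorot(kC, f1), conv1_b = numeric(f1))
  if (spec$arch == "cnn_lstm") {
    H <- spec$lstm_units
    p$lstm_Wx <- glorot(f1, 4L * H)
    p$lstm_Wh <- glorot(H, 4L * H)
    b <- numeric(4L * H)
    # chrono-style gate bias: the LSTM integrates over T_seq pooled
    # positions, so the forget gate must start near 1 (bias ~ log T_seq)
    # or features seen early in the sequence decay out of the final
    # state before it is read
    T_seq <- (spec$input_width - spec$conv1_kernel + 1L) %/% spec$pool_size
    b[(H + 1L):(2L * H)] <- log(T_seq)          # forget gate
    b[1L:H] <- -log(T_seq)                      # input gate
    p$lstm_b <- b
  } else {
    k2C <- spec$conv2_kernel * f1
    p$conv2_W <- glorot(k2C, spec$conv2_filters)
    p$conv2_b <- numeric(spec$conv2_filters)
  }
  p$bn_gamma <- rep(1, D); p$bn_beta <- numeric(D)
  p$bn_mean <- numeric(D); p$bn_var <- rep(1, D)
  p$dense1_W <- glorot(D, spec$dense1_units)
  p$dense1_b <- numeric(spec$dense1_units)
  p$dense2_W <- glorot(spec$dense1_units, spec$dense2_units)
  p$dense2_b <- numeric(spec$dense2_units)
  p$out_W <- glorot(spec$dense2_units, 1L)
  p$out_b <- numeric(1L)
  p
}

#' Build an untrained model
#'
#' Fills in the dense-layer sizes (from `n_train` via
#' [compute_dense_sizes()] when the spec leaves them `NULL`) and
#' initializes weights (Glorot-uniform; LSTM forget-gate bias 1).
#'
#' @param spec a [model_spec()].
#' @param n_train training-set size used for the dense sizing rule.
#' @param seed optional seed for weight initialization.
#' @return a `smad_model` list with `spec` and `params`.
#' @export
build_model <- function(spec, n_train, seed = NULL) {
  stopifnot(inherits(spec, "smad_model_spec"))
  if (is.null(spec$dense1_units) || is.null(spec$dense2_units)) {
    d <- compute_dense_sizes(n_train)
    spec$dense1_units <- d[1]; spec$dense2_units <- d[2]
  }
  spec$dense1_units <- as.integer(spec$dense1_units)
  spec$dense2_units <- as.integer(spec$dense2_units)
  validate_spec_dims(spec)
  if (!is.null(seed)) set.seed(seed)
  structure(list(spec = spec, params = init_params(spec),
                 n_train = n_train),
            class = "smad_model")
}

#' Ordered layer manifest of an architecture
#'
#' Lists the layer sequence of a spec (or built model) as compact
#' strings, e.g. `"conv k5"`, `"lstm u32"`, usable as a structural
#' regression check.
#'
#' @param x a `smad_model_spec` or `smad_model`.
#' @return character vector of layers in order.
#' @export
layer_manifest <- function(x) {
  spec <- if (inherits(x, "smad_model")) x$spec else x
  stopifnot(inherits(spec, "smad_model_spec"))
  if (spec$arch == "cnn") {
    c(paste0("conv k", spec$conv1_kernel), "pool",
      paste0("conv k", spec$conv2_kernel), "pool",
      "flatten", "batchnorm", "dense", "dropout", "dense", "dense-sigmoid")
  } else {
    c(paste0("conv k", spec$conv1_kernel), "pool",
      paste0("lstm u", spec$lstm_units),
      "batchnorm", "dense", "dropout", "dense", "dense-sigmoid")
  }
}

#' Number of trainable parameters implied by a spec
#'
#' Pure arithmetic on the spec (batch-norm running statistics excluded);
#' matches the element count of a built model's weight tensors.
#'
#' @param spec a `smad_model_spec` with dense sizes filled in.
#' @return integer parameter count.
#' @export
count_parameters <- function(spec) {
  stopifnot(!is.null(spec$dense1_units), !is.null(spec$dense2_units))
  f1 <- spec$conv1_filters
  D <- feature_dim(spec)
  n <- spec$conv1_kernel * spec$n_channels * f1 + f1
  if (spec$arch == "cnn_lstm") {
    H <- spec$lstm_units
    n <- n + (f1 + H) * 4 * H + 4 * H
  } else {
    n <- n + spec$conv2_kernel * f1 * spec$conv2_filters + spec$conv2_filters
  }
  n <- n + 2 * D                                        # gamma, beta
  n <- n + D * spec$dense1_units + spec$dense1_units
  n <- n + spec$dense1_units * spec$dense2_units + spec$dense2_units
  n <- n + spec$dense2_units + 1
  as.integer(n)
}

#' @export
print.smad_model <- function(x, ...) {
  cat("<smad_model> ", x$spec$arch, "\n", sep = "")
  cat(" layers:", paste(layer_manifest(x), collapse = " -> "), "\n")
  cat(" parameters:", count_parameters(x$spec), "\n")
  invisible(x)
}

# accept smad_onehot or a bare N x L x 5 array
as_input_array <- function(x) {
  if (inherits(x, "smad_onehot")) return(x$x)
  if (is.array(x) && length(dim(x)) == 3) return(x)
  stop("expected a smad_onehot object or an N x L x 5 array")
}

#' Predict class probabilities for a single model
#'
#' Deterministic forward pass (dropout inactive, batch normalization
#' using running statistics). Output is the probability of the positive
#' class SMAD3.
#'
#' @param model a `smad_model` (built, possibly trained).
#' @param x a `smad_onehot` batch or `N x L x 5` array.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "smad_model"))
  arr <- as_input_array(x)
  if (dim(arr)[2] != model$spec$input_width ||
      dim(arr)[3] != model$spec$n_channels)
    stop("input shape ", paste(dim(arr), collapse = "x"),
         " does not match spec ", model$spec$input_width, "x",
         model$spec$n_channels)
  as.numeric(.nn_predict(model$params, unclass(model$spec), arr))
}
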