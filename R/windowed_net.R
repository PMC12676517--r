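#' Windowed network configuration
#'
#' Hyperparameters of the spectral classifier: the input spectrum is cut
#' into overlapping windows, each window feeds a small dense block (ReLU),
#' the block outputs are concatenated into a dense head with dropout, and a
#' single sigmoid unit emits the disease probability. This windowed dense
#' design mimics a sparse 1-D convolutional network while keeping the
#' parameter count small for short-spectrum cohorts.
#'
#' @param window Window size in grid points (default 50).
#' @param stride Stride between window starts (default 25, i.e. 50% overlap).
#' @param block_units Units in each per-window dense block (default 8).
#' @param head_units Units in the merged dense head (default 16).
#' @param dropout Bernoulli drop probability in \[0, 1) (default 0.3;
#'   applied in the dense head unless `dropout_site = "input"`).
#' @param epochs Training epochs (default 200, no early stopping).
#' @param batch_size Mini-batch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param output `"sigmoid"` (default; required for training) or `"linear"`
#'   (raw pre-activation output, useful for analytically tractable nets).
#' @param dropout_site `"head"` (default) or `"input"`.
#' @param seed Integer seed controlling weight initialization, batch order
#'   and dropout masks.
#' @return An object of class `net_config`.
#' @export
net_config <- function(window = 50L, stride = 25L, block_units = 8L,
                       head_units = 16L, dropout = 0.3, epochs = 200L,
                       batch_size = 32L, learning_rate = 1e-3,
                       output = c("sigmoid", "linear"),
                       dropout_site = c("head", "input"), seed = 1L) {
  cfg <- list(window = as.integer(window), stride = as.integer(stride),
              block_units = as.integer(block_units),
              head_units = as.integer(head_units),
              dropout = dropout, epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate,
              output = match.arg(output),
              dropout_site = match.arg(dropout_site),
              seed = as.integer(seed))
  if (cfg$stride < 1L || cfg$window < cfg$stride)
    stop("need 1 <= stride <= window")
  if (!(cfg$dropout >= 0 && cfg$dropout < 1))
    stop("dropout must lie in [0, 1)")
  if (cfg$epochs < 1L || cfg$batch_size < 1L)
    stop("epochs and batch_size must be >= 1")
  class(cfg) <- "net_config"
  cfg
}

#' Overlapping window index ranges
#'
#' Returns the 1-based inclusive index ranges `[1 + i*s, i*s + w]` for
#' `i = 0 .. floor((n - w)/s)`. If the last regular window does not reach
#' the end of the grid, a final tail window anchored at `n - w + 1` is
#' appended so that no grid point is dropped.
#'
#' @param n Grid length.
#' @param w Window size (`w <= n`).
#' @param s Stride.
#' @return Integer matrix with columns `start`, `end`; one row per window.
#' @export
window_slices <- function(n, w, s) {
  n <- as.integer(n); w <- as.integer(w); s <- as.integer(s)
  if (w > n) stop("window size ", w, " exceeds grid length ", n)
  if (s < 1L || s > w) stop("need 1 <= stride <= window")
  starts <- seq.int(1L, by = s, length.out = (n - w) %/% s + 1L)
  if (starts[length(starts)] + w - 1L < n) starts <- c(starts, n - w + 1L)
  cbind(start = starts, end = starts + w - 1L)
}

init_weights <- function(windows, w, block_units, head_units) {
  K <- nrow(windows)
  he <- function(fan_in, nr, nc)
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  list(
    W_blocks = lapply(seq_len(K), function(k) he(w, w, block_units)),
    b_blocks = lapply(seq_len(K), function(k) matrix(0, 1, block_units)),
    W_head = he(K * block_units, K * block_units, head_units),
    b_head = matrix(0, 1, head_units),
    W_out = matrix(stats::rnorm(head_units, 0, sqrt(1 / head_units)),
                   head_units, 1),
    b_out = 0)
}

#' Build an (untrained) windowed network
#'
#' Instantiates the architecture for a grid of `n` points and initializes
#' weights from the configured seed (He initialization for the ReLU
#' layers). The returned object is untrained; see [train_net()].
#'
#' @param config A [net_config()].
#' @param n Grid length the network accepts.
#' @return An object of class `windowed_net`.
#' @export
build_net <- function(config, n) {
  stopifnot(inherits(config, "net_config"))
  windows <- window_slices(n, config$window, config$stride)
  set.seed(config$seed)
  weights <- init_weights(windows, config$window, config$block_units,
                          config$head_units)
  structure(
    list(config = config, n = as.integer(n), windows = windows,
         weights = weights, trained = FALSE, loss = numeric(0)),
    class = "windowed_net")
}

#' Number of trainable parameters
#' @param net A `windowed_net`.
#' @return Integer parameter count.
#' @export
n_params <- function(net) {
  w <- net$weights
  sum(vapply(w$W_blocks, length, 0L)) + sum(vapply(w$b_blocks, length, 0L)) +
    length(w$W_head) + length(w$b_head) + length(w$W_out) + 1L
}

#' @export
print.windowed_net <- function(x, ...) {
  cat("<windowed_net> ", nrow(x$windows), " windows of ", x$config$window,
      " points (stride ", x$config$stride, ") on a ", x$n, "-point grid\n",
      sep = "")
  cat("  ", n_params(x), " parameters; dropout ", x$config$dropout, " (",
      x$config$dropout_site, "); ",
      if (x$trained) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

as_intensity_matrix <- function(data, n) {
  X <- if (inherits(data, "spectrum_set")) data$intensities else as.matrix(data)
  if (ncol(X) != n)
    stop("data has ", ncol(X), " grid points but the network expects ", n)
  X
}

#' Train a windowed network
#'
#' Minimizes binary cross-entropy by mini-batch Adam for exactly
#' `config$epochs` epochs (no early stopping), with dropout active during
#' training. Fully reproducible: weights, batch order and dropout masks all
#' derive from `config$seed`.
#'
#' @param net An untrained (or trained) `windowed_net`.
#' @param data A `spectrum_set` or numeric matrix (spectra in rows).
#' @param labels Factor or character vector of `control`/`disease` per
#'   spectrum (disease is the positive class), or a 0/1 numeric vector.
#' @return The trained `windowed_net`, with `loss` holding the per-epoch
#'   mean training loss.
#' @export
train_net <- function(net, data, labels) {
  stopifnot(inherits(net, "windowed_net"))
  cfg <- net$config
  if (cfg$output != "sigmoid")
    stop("training requires output = 'sigmoid'")
  X <- as_intensity_matrix(data, net$n)
  y <- if (is.numeric(labels)) as.numeric(labels)
       else as.numeric(factor(labels, levels = c("control", "disease"))) - 1
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("labels must be control/disease (or 0/1)")
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes")
  set.seed(cfg$seed + 1L)  # training stream, distinct from init stream
  fit <- cpp_net_train(X, y, net$windows - 1L, net$weights,
                       cfg$dropout,
                       if (cfg$dropout_site == "head") 0L else 1L,
                       cfg$epochs, cfg$batch_size, cfg$learning_rate,
                       TRUE)
  net$weights <- fit$weights
  net$loss <- as.numeric(fit$loss)
  net$trained <- TRUE
  net
}

#' Fit a windowed network in one call
#'
#' Convenience wrapper: [build_net()] for the data's grid then
#' [train_net()].
#'
#' @param data A `spectrum_set` or numeric matrix.
#' @param labels Per-spectrum class labels (see [train_net()]).
#' @param config A [net_config()].
#' @return A trained `windowed_net`.
#' @export
windowed_net <- function(data, labels, config = net_config()) {
  n <- if (inherits(data, "spectrum_set")) length(data$wavenumbers)
       else ncol(data)
  train_net(build_net(config, n), data, labels)
}

#' Set network weights explicitly
#'
#' Replaces the parameter store with user-supplied weights (same shapes as
#' the initialized ones) and marks the network trained. Intended for
#' constructing analytically tractable networks, e.g. a single linear unit
#' whose dropout distribution can be enumerated exactly.
#'
#' @param net A `windowed_net`.
#' @param weights List with elements `W_blocks`, `b_blocks`, `W_head`,
#'   `b_head`, `W_out`, `b_out` matching the network's shapes.
#' @return The modified `windowed_net`.
#' @export
set_net_weights <- function(net, weights) {
  stopifnot(inherits(net, "windowed_net"))
  old <- net$weights
  need <- c("W_blocks", "b_blocks", "W_head", "b_head", "W_out", "b_out")
  if (!all(need %in% names(weights)))
    stop("weights must have elements: ", paste(need, collapse = ", "))
  same_dim <- function(a, b) identical(dim(as.matrix(a)), dim(as.matrix(b)))
  ok <- length(weights$W_blocks) == length(old$W_blocks) &&
    all(mapply(same_dim, weights$W_blocks, old$W_blocks)) &&
    same_dim(weights$W_head, old$W_head) && same_dim(weights$W_out, old$W_out)
  if (!ok) stop("weight shapes do not match the network architecture")
  for (nm in need) net$weights[[nm]] <- weights[[nm]]
  net$trained <- TRUE
  net
}

#' Predict disease probabilities
#'
#' Deterministic prediction disables dropout (activations at the dropout
#' site are scaled by the keep probability, the classical weight-scaling
#' rule); `stochastic = TRUE` performs one Bernoulli-masked forward pass,
#' the primitive Monte Carlo dropout builds on.
#'
#' @param object A trained `windowed_net`.
#' @param data A `spectrum_set` or numeric matrix.
#' @param stochastic Logical; sample a dropout mask for this pass.
#' @param ... Unused.
#' @return Numeric vector of probabilities (or raw outputs for a
#'   linear-output net), named by spectrum id when available.
#' @export
predict.windowed_net <- function(object, data, stochastic = FALSE, ...) {
  if (!object$trained)
    warning("predicting from an untrained network")
  X <- as_intensity_matrix(data, object$n)
  cfg <- object$config
  out <- as.numeric(cpp_net_forward(
    X, object$windows - 1L, object$weights, cfg$dropout,
    if (cfg$dropout_site == "head") 0L else 1L,
    isTRUE(stochastic), cfg$output == "sigmoid"))
  names(out) <- rownames(X)
  out
}
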