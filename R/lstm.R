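#' Configuration of the stacked-LSTM segment classifier
#'
#' Four LSTM layers, each pair separated by a temporal max-pooling
#' layer (three pools in total); the first three layers return the full
#' sequence, the last only its final state, which a dense sigmoid layer
#' reduces to one output per label. Gates use the logistic function;
#' the cell/candidate activation is tanh by default (selectable), with
#' a recurrent dropout of 0.25; training uses Adam at learning rate
#' 1e-4 with mean-squared error against one-hot targets.
#'
#' @param layer_units integer vector of 4 non-increasing unit counts.
#' @param pool_size temporal max-pool factor between LSTM layers.
#' @param n_labels number of output labels (>= 2).
#' @param recurrent_dropout recurrent-state dropout fraction in \[0,1).
#' @param learning_rate Adam learning rate.
#' @param activation cell/candidate activation: `"tanh"` (the classical
#'   cell equations; default — the all-logistic variant is prone to
#'   cell-state saturation because its candidate values are strictly
#'   positive) or `"sigmoid"`.
#' @param epochs,batch_size,patience training loop controls; training
#'   early-stops after `patience` epochs without validation improvement.
#' @param validation_fraction fraction of the training set held out for
#'   early stopping.
#' @param seed integer seed governing initialization, shuffling and
#'   dropout.
#' @return an object of class `lstm_config`.
#' @export
lstm_config <- function(layer_units = c(64, 32, 16, 8), pool_size = 4,
                        n_labels = 2, recurrent_dropout = 0.25,
                        learning_rate = 1e-4, activation = c("tanh", "sigmoid"),
                        epochs = 30, batch_size = 32, patience = 5,
                        validation_fraction = 0.1, seed = 1) {
  activation <- match.arg(activation)
  stopifnot(length(layer_units) == 4, all(diff(layer_units) <= 0),
            all(layer_units >= 1), pool_size >= 2, n_labels >= 2,
            recurrent_dropout >= 0, recurrent_dropout < 1,
            learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(list(layer_units = as.integer(layer_units),
                 pool_size = as.integer(pool_size),
                 n_labels = as.integer(n_labels),
                 recurrent_dropout = recurrent_dropout,
                 learning_rate = learning_rate, activation = activation,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "lstm_config")
}

#' Desk-scale LSTM preset
#'
#' A reduced model for CPU-scale experiments on the synthetic recordings
#' (4 channels at 100 Hz, 2-s segments): units 16/8/8/4 and a larger
#' learning rate so the small model converges in tens of epochs.
#'
#' @param n_labels number of labels.
#' @param seed integer seed.
#' @param ... overrides passed to [lstm_config()].
#' @export
lstm_config_desk <- function(n_labels = 2, seed = 1, ...) {
  args <- list(layer_units = c(16L, 8L, 8L, 4L), pool_size = 4L,
               n_labels = n_labels, learning_rate = 3e-3, epochs = 20,
               patience = 8, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(lstm_config, args)
}

act_code <- function(activation) if (activation == "tanh") 0L else 1L

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Build (initialize) a stacked-LSTM model
#'
#' Allocates Glorot-uniform gate weights (column blocks ordered
#' input/forget/output/candidate, with the forget bias initialized to 1)
#' and records a structure report listing every layer. The time axis is
#' floor-divided by the pool size at each of the three pools; building
#' fails if it collapses to zero.
#'
#' @param config an `lstm_config`.
#' @param input_shape `c(time_steps, channels)` of one segment.
#' @return an object of class `lstm_model` with elements `params`
#'   (flat list of weight matrices), `config`, `input_shape`, and
#'   `structure` (data.frame of layers).
#' @export
build_lstm_model <- function(config, input_shape) {
  stopifnot(inherits(config, "lstm_config"), length(input_shape) == 2)
  t_steps <- as.integer(input_shape[1]); n_ch <- as.integer(input_shape[2])
  units <- config$layer_units
  p <- config$pool_size
  set.seed(config$seed)
  params <- list()
  d <- n_ch
  t_axis <- t_steps
  rows <- list()
  for (l in 1:4) {
    u <- units[l]
    b <- rep(0, 4 * u)
    b[(u + 1):(2 * u)] <- 1            # forget-gate bias
    params <- c(params, list(glorot(d, 4 * u), glorot(u, 4 * u),
                             matrix(b, 1)))
    rows[[length(rows) + 1]] <- data.frame(
      kind = "lstm", units = u, time_steps = t_axis,
      returns_sequence = l < 4)
    if (l < 4) {
      t_axis <- t_axis %/% p
      if (t_axis < 1)
        stop("time axis collapsed to zero: reduce pool_size or lengthen segments")
      rows[[length(rows) + 1]] <- data.frame(
        kind = "maxpool", units = u, time_steps = t_axis,
        returns_sequence = TRUE)
    }
    d <- u
  }
  params <- c(params, list(glorot(units[4], config$n_labels),
                           matrix(0, 1, config$n_labels)))
  rows[[length(rows) + 1]] <- data.frame(
    kind = "dense", units = config$n_labels, time_steps = 1L,
    returns_sequence = FALSE)
  structure(list(params = params, config = config,
                 input_shape = c(t_steps, n_ch),
                 structure = do.call(rbind, rows),
                 history = NULL),
            class = "lstm_model")
}

#' @export
print.lstm_model <- function(x, ...) {
  cat("Stacked-LSTM segment classifier\n")
  print(x$structure, row.names = FALSE)
  if (!is.null(x$history))
    cat(sprintf("trained %d epochs, best validation loss %.4f\n",
                length(x$history$train_loss), min(x$history$val_loss)))
  invisible(x)
}

as_batch_array <- function(x) {
  # accept (B, C, T) array or a single C x T matrix
  if (is.matrix(x)) x <- array(x, c(1, nrow(x), ncol(x)))
  stopifnot(length(dim(x)) == 3)
  x
}

one_hot <- function(labels, n_labels) {
  y <- matrix(0, length(labels), n_labels)
  y[cbind(seq_along(labels), labels + 1L)] <- 1
  y
}

#' Train the stacked LSTM on a balanced segment set
#'
#' Targets are one-hot (each label has its own output set to zero or
#' one) under mean-squared-error loss; optimization is Adam. A held-out
#' slice of the training set drives early stopping. Deterministic for a
#' fixed seed.
#'
#' @param model an `lstm_model` from [build_lstm_model()].
#' @param x numeric array `(n, channels, time_steps)` of segments.
#' @param labels integer labels in `0:(n_labels-1)`.
#' @param verbose print per-epoch losses.
#' @return the trained `lstm_model` with a `history` element
#'   (per-epoch train/validation loss).
#' @export
train_lstm <- function(model, x, labels, verbose = FALSE) {
  stopifnot(inherits(model, "lstm_model"))
  cfg <- model$config
  x <- as_batch_array(x)
  n <- dim(x)[1]
  if (n == 0) stop("empty training set")
  stopifnot(length(labels) == n, dim(x)[2] == model$input_shape[2],
            dim(x)[3] == model$input_shape[1])
  y <- one_hot(as.integer(labels), cfg$n_labels)

  set.seed(cfg$seed)
  n_val <- max(1L, floor(cfg$validation_fraction * n))
  val_idx <- sample(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  fit <- lstm_train_cpp(model$params,
                        x[tr_idx, , , drop = FALSE], y[tr_idx, , drop = FALSE],
                        x[val_idx, , , drop = FALSE], y[val_idx, , drop = FALSE],
                        cfg$pool_size, act_code(cfg$activation),
                        cfg$recurrent_dropout, cfg$learning_rate,
                        cfg$epochs, cfg$batch_size, cfg$patience, verbose)
  if (!all(is.finite(unlist(fit$train_loss))))
    stop("non-finite training loss: diverged")
  model$params <- fit$params
  model$history <- list(train_loss = as.numeric(fit$train_loss),
                        val_loss = as.numeric(fit$val_loss),
                        epochs_run = fit$epochs_run)
  model
}

#' Classify segments with a trained LSTM
#'
#' Pure inference (dropout disabled): returns one sigmoid output per
#' label for each segment.
#'
#' @param model a trained `lstm_model`.
#' @param x a single channels x time matrix or an `(n, channels, time)`
#'   array.
#' @return numeric matrix `n x n_labels` of values in \[0, 1\].
#' @export
predict_segment <- function(model, x) {
  stopifnot(inherits(model, "lstm_model"))
  x <- as_batch_array(x)
  stopifnot(dim(x)[2] == model$input_shape[2],
            dim(x)[3] == model$input_shape[1])
  lstm_predict_cpp(model$params, x, model$config$pool_size,
                   act_code(model$config$activation))
}

#' One step of the LSTM cell recurrence
#'
#' The reference (pure R) recurrence: input, forget and output gates are
#' `sigmoid(x U + h_prev W + b)`; the candidate is
#' `act(x U_g + h_prev W_g + b_g)`; the cell state updates as
#' `C = f * C_prev + i * C_tilde` and the hidden state as
#' `h = act(C) * o`. Serves as the independent oracle for the compiled
#' training path.
#'
#' @param x input row vector (length = input width).
#' @param h_prev,c_prev previous hidden / cell state vectors (length =
#'   units).
#' @param params list with `U`, `W`, `b`, each a list of four elements
#'   named `i`, `f`, `o`, `g` (input weights, recurrent weights, bias).
#' @param activation `"tanh"` (classical equations) or `"sigmoid"`.
#' @return list with `h` and `c`, the new states.
#' @export
lstm_cell_step <- function(x, h_prev, c_prev, params,
                           activation = c("tanh", "sigmoid")) {
  activation <- match.arg(activation)
  act <- if (activation == "tanh") tanh else stats::plogis
  gate <- function(gname, squash) {
    squash(drop(x %*% params$U[[gname]] + h_prev %*% params$W[[gname]]) +
             params$b[[gname]])
  }
  i <- gate("i", stats::plogis)
  f <- gate("f", stats::plogis)
  o <- gate("o", stats::plogis)
  g <- gate("g", act)
  c_new <- f * c_prev + i * g
  h_new <- act(c_new) * o
  list(h = h_new, c = c_new)
}

#' @rdname build_lstm_model
#' @param model an `lstm_model`.
#' @return `lstm_structure_report`: data.frame with one row per layer
#'   (`kind`, `units`, `time_steps`, `returns_sequence`).
#' @export
lstm_structure_report <- function(model) {
  stopifnot(inherits(model, "lstm_model"))
  model$structure
}
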