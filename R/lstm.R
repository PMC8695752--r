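#' Closed-form parameter counts for the sequence model
#'
#' The LSTM layer has `4 * (units * (units + n_channels) + units)` weights
#' (four gate blocks, each with input kernel, recurrent kernel and bias);
#' the per-timestep affine map has `units * width + width`; the output map
#' has `input_length * width + 1`.
#'
#' @param units LSTM hidden width.
#' @param input_length padded sequence length (timesteps).
#' @param n_channels input channels per timestep (default 3).
#' @param per_step_dense_width width of the per-timestep affine map.
#' @return named list with `lstm`, `per_step_dense`, `output`, `total`.
#' @export
lstm_param_count <- function(units, input_length, n_channels = 3L,
                             per_step_dense_width = 1L) {
  u <- units; w <- per_step_dense_width
  lstm <- 4L * (u * (u + n_channels) + u)
  dense <- u * w + w
  out <- input_length * w + 1L
  list(lstm = lstm, per_step_dense = dense, output = out,
       total = lstm + dense + out)
}

glorot_uniform <- function(fan_in, fan_out, n = fan_in * fan_out) {
  l <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(n, -l, l), fan_in, fan_out)
}

init_weights <- function(units, input_length, n_channels, width) {
  u <- units
  Wh <- do.call(cbind, lapply(1:4, function(k) {
    a <- matrix(rnorm(u * u), u, u)
    qr.Q(qr(a))
  }))
  list(
    Wx = glorot_uniform(n_channels, 4L * u),
    Wh = Wh,
    b = c(rep(0, u), rep(1, u), rep(0, 2L * u)),  # forget-gate bias 1
    Wd = glorot_uniform(u, width),
    bd = rep(0, width),
    Wo = as.numeric(glorot_uniform(input_length * width, 1L)),
    bo = 0
  )
}

#' Build an untrained LSTM classifier
#'
#' Architecture: an LSTM layer returning its full hidden sequence, a
#' per-timestep affine map to `per_step_dense_width` features, a flatten
#' step, and an affine map to a single sigmoid output. Initialisation:
#' Glorot-uniform kernels, orthogonal recurrent kernels, zero biases with
#' the forget-gate bias at 1. Initialisation randomness is governed by
#' `cfg$seed`.
#'
#' @param cfg a [model_config()].
#' @param input_length padded sequence length the model accepts.
#' @param n_channels input channels per timestep (default 3).
#' @return an object of class `lstm_model`.
#' @export
build_model <- function(cfg, input_length, n_channels = 3L) {
  stopifnot(inherits(cfg, "model_config"))
  if (input_length < 1) stop("input_length must be >= 1", call. = FALSE)
  set.seed(cfg$seed)
  w <- init_weights(cfg$units, input_length, n_channels,
                    cfg$per_step_dense_width)
  structure(
    list(config = cfg, weights = w, input_length = as.integer(input_length),
         n_channels = as.integer(n_channels), trained = FALSE,
         history = NULL, norm_stats = NULL),
    class = "lstm_model")
}

#' @export
print.lstm_model <- function(x, ...) {
  pc <- lstm_param_count(x$config$units, x$input_length, x$n_channels,
                         x$config$per_step_dense_width)
  cat(sprintf(
    "LSTM classifier: %d units, input %d x %d, %s (%s parameters)\n",
    x$config$units, x$input_length, x$n_channels,
    if (x$trained) sprintf("trained %d epochs", nrow(x$history)) else
      "untrained",
    format(pc$total, big.mark = ",")))
  invisible(x)
}

count_parameters <- function(model) {
  sum(vapply(model$weights, length, numeric(1)))
}

# mask matrix (n x T) from valid lengths; all-ones when masking is off
make_mask <- function(n, T, valid_lengths = NULL, pad_side = "end") {
  if (is.null(valid_lengths)) return(matrix(1, n, T))
  m <- matrix(0, n, T)
  for (i in seq_len(n)) {
    v <- min(valid_lengths[i], T)
    idx <- if (pad_side == "end") seq_len(v) else seq(T - v + 1L, T)
    m[i, idx] <- 1
  }
  m
}

apply_norm <- function(x, stats) {
  for (c in seq_len(dim(x)[3]))
    x[, , c] <- (x[, , c] - stats$mean[c]) / stats$sd[c]
  x
}

#' Train the LSTM classifier
#'
#' Runs exactly `cfg$epochs` passes over seed-shuffled minibatches of
#' `cfg$batch_size`, minimising mean absolute error between the sigmoid
#' output and the binary label with Adam (default hyperparameters:
#' `learning_rate` 1e-3, beta1 0.9, beta2 0.999, epsilon 1e-7). Training is
#' deterministic given the config seed and single-threaded numerics.
#'
#' @param model an untrained (or previously trained) `lstm_model`.
#' @param train_set list with `x` (array n x timesteps x channels), `y`
#'   (binary labels), optionally `valid_lengths`; see [stack_tensors()].
#' @param val_set optional validation set in the same layout.
#' @param epochs optional override of `cfg$epochs`.
#' @return the `lstm_model` with trained weights and a `history` data frame
#'   (`epoch,train_loss,train_acc[,val_loss,val_acc]`); train-set history
#'   entries are running minibatch averages.
#' @export
train_model <- function(model, train_set, val_set = NULL, epochs = NULL) {
  stopifnot(inherits(model, "lstm_model"))
  cfg <- model$config
  if (!is.null(epochs)) {
    if (epochs < 1) stop("epochs must be a positive integer", call. = FALSE)
    cfg$epochs <- as.integer(epochs)
  }
  x <- train_set$x
  y <- train_set$y
  if (is.null(x) || length(y) == 0L)
    stop("training set is empty", call. = FALSE)
  n <- dim(x)[1]
  if (dim(x)[2] != model$input_length)
    stop(sprintf("sequence length mismatch: model expects %d, got %d",
                 model$input_length, dim(x)[2]), call. = FALSE)

  if (cfg$normalize) {
    st <- list(mean = apply(x, 3, mean), sd = pmax(apply(x, 3, sd), 1e-8))
    model$norm_stats <- st
    x <- apply_norm(x, st)
  }
  vl <- if (cfg$mask_padding) train_set$valid_lengths else NULL
  mask <- make_mask(n, dim(x)[2], vl)

  set.seed(cfg$seed + 1L)  # distinct stream from weight init
  shuffle <- t(vapply(seq_len(cfg$epochs),
                      function(e) sample.int(n) - 1L, integer(n)))

  xv <- yv <- mv <- NULL
  if (!is.null(val_set) && length(val_set$y) > 0L) {
    xv <- val_set$x
    if (cfg$normalize) xv <- apply_norm(xv, model$norm_stats)
    yv <- as.numeric(val_set$y)
    vvl <- if (cfg$mask_padding) val_set$valid_lengths else NULL
    mv <- make_mask(dim(xv)[1], dim(xv)[2], vvl)
  }

  fit <- lstm_train_cpp(
    x, as.numeric(y), mask, model$weights,
    matrix(as.integer(shuffle), nrow = cfg$epochs), cfg$epochs,
    cfg$batch_size, cfg$learning_rate, 0.9, 0.999, 1e-7,
    cfg$classification_threshold,
    if (is.null(xv)) NULL else xv,
    if (is.null(yv)) NULL else yv,
    if (is.null(mv)) NULL else mv)

  h <- as.data.frame(fit$history)
  names(h) <- if (ncol(h) == 4L)
    c("train_loss", "train_acc", "val_loss", "val_acc") else
    c("train_loss", "train_acc")
  h <- cbind(epoch = seq_len(nrow(h)), h)

  model$weights <- fit$weights
  model$trained <- TRUE
  model$history <- h
  model$config <- cfg
  model
}

#' Predict death probabilities
#'
#' @param model a trained `lstm_model`.
#' @param newdata list with `x` (array n x timesteps x channels) and
#'   optionally `valid_lengths`, or a bare array.
#' @return numeric vector of probabilities in `[0, 1]`, named by patient id
#'   when `newdata$ids` is present.
#' @export
predict_proba <- function(model, newdata) {
  stopifnot(inherits(model, "lstm_model"))
  if (is.array(newdata) && !is.list(newdata)) newdata <- list(x = newdata)
  x <- newdata$x
  if (length(dim(x)) != 3L)
    stop("newdata$x must be an n x timesteps x channels array", call. = FALSE)
  if (dim(x)[2] != model$input_length)
    stop(sprintf("sequence length mismatch: model expects %d, got %d",
                 model$input_length, dim(x)[2]), call. = FALSE)
  if (model$config$normalize) {
    if (is.null(model$norm_stats))
      stop("model was configured to normalize but has no training statistics",
           call. = FALSE)
    x <- apply_norm(x, model$norm_stats)
  }
  vl <- if (model$config$mask_padding) newdata$valid_lengths else NULL
  mask <- make_mask(dim(x)[1], dim(x)[2], vl)
  p <- as.numeric(lstm_predict_cpp(x, mask, model$weights))
  if (!is.null(newdata$ids)) names(p) <- newdata$ids
  p
}

#' Threshold probabilities into binary predictions
#'
#' Predicts death (1) when the probability is greater than or equal to the
#' threshold; the tie at exactly the threshold is classified as death.
#'
#' @param probabilities numeric vector in `[0, 1]`.
#' @param threshold cutoff strictly inside (0, 1); default 0.5.
#' @return integer vector of 0/1 predictions (names preserved).
#' @export
classify <- function(probabilities, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)", call. = FALSE)
  stats::setNames(as.integer(probabilities >= threshold),
                  names(probabilities))
}

#' Export a training history as CSV
#' @param model a trained `lstm_model`.
#' @param path output path.
#' @export
write_history_csv <- function(model, path) {
  stopifnot(inherits(model, "lstm_model"), model$trained)
  write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a trained model (weights as RDS-free plain JSON)
#'
#' Weights are written as a JSON sidecar-style file holding the model
#' configuration, seed, normalisation statistics and all weight arrays, so
#' a checkpoint is a portable text artifact.
#'
#' @param model a `lstm_model`.
#' @param path output path (`.json`).
#' @export
save_model_json <- function(model, path) {
  obj <- list(config = unclass(model$config),
              input_length = model$input_length,
              n_channels = model$n_channels,
              trained = model$trained,
              norm_stats = model$norm_stats,
              weights = model$weights,
              history = model$history)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model_json
#' @export
load_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  cfg$units <- as.integer(cfg$units)
  cfg <- do.call(model_config, cfg[names(cfg) %in% names(formals(model_config))])
  w <- obj$weights
  w$Wx <- as.matrix(w$Wx); w$Wh <- as.matrix(w$Wh)
  w$Wd <- as.matrix(w$Wd)
  w$b <- as.numeric(w$b); w$bd <- as.numeric(w$bd)
  w$Wo <- as.numeric(w$Wo); w$bo <- as.numeric(w$bo)
  m <- structure(
    list(config = cfg, weights = w,
         input_length = as.integer(obj$input_length),
         n_channels = as.integer(obj$n_channels),
         trained = isTRUE(obj$trained),
         history = if (!is.null(obj$history)) as.data.frame(obj$history),
         norm_stats = if (!is.null(obj$norm_stats))
           lapply(obj$norm_stats, as.numeric)),
    class = "lstm_model")
  m
}
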