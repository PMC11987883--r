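#' Configuration of the CLA-PTNet farrowing-onset regressor
#'
#' CLA-PTNet maps a fixed-length activity window to the remaining time (in
#' minutes) until farrowing onset. The network stacks three blocks: CBE
#' (1-D convolutions with batch normalization and ELU for local features),
#' LDE (an LSTM with dropout and ELU for long-range temporal dependencies)
#' and PTW-SA (position-aware time-weighted self-attention, the model's
#' core), followed by pooling and a fully connected head.
#'
#' @param seq_len Window length `t` in points (72 = 6 h at 5-min steps).
#' @param cbe_channels Integer vector of convolution output channels, one
#'   entry per CBE layer.
#' @param cbe_kernel_sizes Odd kernel sizes, same length as `cbe_channels`;
#'   odd kernels with symmetric padding keep the sequence length.
#' @param lstm_hidden Hidden dimension `d` of the LSTM.
#' @param lstm_layers Number of stacked LSTM layers.
#' @param dropout Dropout probability in the LDE block (training mode only).
#' @param attention_scale `"sqrt_d"` (standard scaled dot-product scoring,
#'   default) or `"d"` (divide attention scores by `d` itself).
#' @param pooling `"mean"` over the `t` attention output rows (default) or
#'   `"last"` row only.
#' @param loss `"mse"` (default) or `"mae"` training loss.
#' @param learning_rate,batch_size,epochs Adam optimizer settings.
#' @param lr_decay Multiplicative learning-rate decay per epoch.
#' @param patience Early-stopping patience on validation MAE (epochs);
#'   `Inf` disables early stopping.
#' @param seed Seed driving initialization, shuffling and dropout.
#' @return A `claptnet_config` list.
#' @export
claptnet_config <- function(seq_len = 72L,
                            cbe_channels = c(16L, 16L),
                            cbe_kernel_sizes = c(7L, 5L),
                            lstm_hidden = 32L,
                            lstm_layers = 1L,
                            dropout = 0.1,
                            attention_scale = c("sqrt_d", "d"),
                            pooling = c("mean", "last"),
                            loss = c("mse", "mae"),
                            learning_rate = 2.5e-3,
                            lr_decay = 0.96,
                            batch_size = 64L,
                            epochs = 75L,
                            patience = Inf,
                            seed = 1L) {
  attention_scale <- match.arg(attention_scale)
  pooling <- match.arg(pooling)
  loss <- match.arg(loss)
  check_count(seq_len, "seq_len")
  if (length(cbe_channels) != length(cbe_kernel_sizes) ||
      length(cbe_channels) == 0L) {
    fc_abort("`cbe_channels` and `cbe_kernel_sizes` must be non-empty and of equal length.",
             class = "farrowcast_config_error")
  }
  if (any(cbe_kernel_sizes %% 2L == 0L)) {
    fc_abort("`cbe_kernel_sizes` must be odd (length-preserving convolutions).",
             class = "farrowcast_config_error")
  }
  check_count(lstm_hidden, "lstm_hidden")
  check_count(lstm_layers, "lstm_layers")
  check_scalar_number(dropout, "dropout", min = 0)
  if (dropout >= 1) {
    fc_abort("`dropout` must lie in [0, 1).", class = "farrowcast_config_error")
  }
  check_scalar_number(learning_rate, "learning_rate", min = 0, allow_zero = FALSE)
  check_scalar_number(lr_decay, "lr_decay", min = 0, allow_zero = FALSE)
  check_count(batch_size, "batch_size")
  check_count(epochs, "epochs")
  check_count(seed, "seed", min = 0L)
  structure(
    list(seq_len = as.integer(seq_len),
         cbe_channels = as.integer(cbe_channels),
         cbe_kernel_sizes = as.integer(cbe_kernel_sizes),
         lstm_hidden = as.integer(lstm_hidden),
         lstm_layers = as.integer(lstm_layers),
         dropout = dropout,
         attention_scale = attention_scale,
         pooling = pooling,
         loss = loss,
         learning_rate = learning_rate,
         lr_decay = lr_decay,
         batch_size = as.integer(batch_size),
         epochs = as.integer(epochs),
         patience = patience,
         seed = as.integer(seed)),
    class = "claptnet_config"
  )
}

# Glorot-uniform style initialization; forget-gate biases start at +1.
claptnet_init_params <- function(cfg) {
  gl <- function(n_in, n_out, dims = c(n_in, n_out)) {
    r <- sqrt(6 / (n_in + n_out))
    array(runif(prod(dims), -r, r), dims)
  }
  conv <- list()
  c_in <- 1L
  for (l in seq_along(cfg$cbe_channels)) {
    k <- cfg$cbe_kernel_sizes[l]
    c_out <- cfg$cbe_channels[l]
    conv[[l]] <- list(W = gl(k * c_in, c_out, c(k, c_in, c_out)),
                      b = numeric(c_out),
                      gamma = rep(1, c_out),
                      beta = numeric(c_out))
    c_in <- c_out
  }
  d <- cfg$lstm_hidden
  lstm <- list()
  in_dim <- cfg$cbe_channels[length(cfg$cbe_channels)]
  for (l in seq_len(cfg$lstm_layers)) {
    b <- numeric(4 * d)
    b[(d + 1):(2 * d)] <- 1  # forget gate bias
    lstm[[l]] <- list(Wx = gl(in_dim, 4 * d), Wh = gl(d, 4 * d), b = b)
    in_dim <- d
  }
  t <- cfg$seq_len
  attn <- list(P = matrix(rnorm(t * d, 0, 0.02), t, d),
               Wq = gl(d, d), Wk = gl(d, d), Wv = gl(d, d),
               w_time = rep(1, t))
  head <- list(W = gl(d, 1L), b = 0)
  list(conv = conv, lstm = lstm, attn = attn, head = head)
}

claptnet_init_buffers <- function(cfg) {
  list(bn = lapply(cfg$cbe_channels, function(c_out) {
    list(mean = numeric(c_out), var = rep(1, c_out))
  }))
}

#' Initialize an untrained CLA-PTNet model
#'
#' @param config A [claptnet_config()].
#' @return An object of class `claptnet` holding parameters, batch-norm
#'   buffers and (identity) normalization statistics; train it with
#'   [claptnet_fit()] or use it directly for forward passes.
#' @export
claptnet_init <- function(config = claptnet_config()) {
  stopifnot(inherits(config, "claptnet_config"))
  params <- with_seed(config$seed, claptnet_init_params(config))
  structure(
    list(config = config,
         params = params,
         buffers = claptnet_init_buffers(config),
         norm = list(x_mean = 0, x_sd = 1, y_scale = 1),
         history = tibble::tibble(epoch = integer(), train_loss = numeric(),
                                  val_mae = numeric()),
         trained = FALSE),
    class = "claptnet"
  )
}

#' @export
print.claptnet <- function(x, ...) {
  cat(sprintf("<claptnet> t=%d, conv channels [%s], LSTM d=%d x%d, %s pooling (%s)\n",
              x$config$seq_len, paste(x$config$cbe_channels, collapse = ","),
              x$config$lstm_hidden, x$config$lstm_layers, x$config$pooling,
              if (x$trained) sprintf("trained, %d epochs", nrow(x$history))
              else "untrained"))
  cat(sprintf("  %d trainable parameters\n", claptnet_n_params(x)))
  invisible(x)
}

claptnet_n_params <- function(model) {
  sum(vapply(flatten_params(model$params), length, integer(1)))
}

windows_to_matrix <- function(windows, seq_len) {
  if (is.matrix(windows)) {
    x <- windows
  } else if (is.data.frame(windows) && "window" %in% names(windows)) {
    x <- do.call(rbind, windows$window)
  } else if (is.numeric(windows)) {
    x <- matrix(windows, nrow = 1L)
  } else {
    fc_abort("`windows` must be a windows tibble, a matrix or a numeric vector.")
  }
  if (ncol(x) != seq_len) {
    fc_abort(sprintf("window length %d does not match the model's seq_len %d.",
                     ncol(x), seq_len))
  }
  x
}

#' Forward pass of CLA-PTNet in evaluation mode
#'
#' Runs the full CBE -> LDE -> PTW-SA -> pooling -> fully-connected pipeline
#' deterministically (batch-norm running statistics, no dropout) and
#' returns predicted minutes to onset.
#'
#' @param model A `claptnet` object.
#' @param windows A windows tibble from [make_windows()], a numeric matrix
#'   (rows = windows), or a single numeric window.
#' @return Numeric vector of predicted minutes to farrowing onset.
#' @export
claptnet_forward <- function(model, windows) {
  stopifnot(inherits(model, "claptnet"))
  x <- windows_to_matrix(windows, model$config$seq_len)
  xs <- (x - model$norm$x_mean) / model$norm$x_sd
  fw <- claptnet_forward_pass(xs, model$params, model$buffers, model$config,
                              training = FALSE)
  fw$yhat * model$norm$y_scale
}

#' @export
predict.claptnet <- function(object, newdata, ...) {
  pred <- claptnet_forward(object, newdata)
  if (is.data.frame(newdata) && "label" %in% names(newdata)) {
    out <- newdata[setdiff(names(newdata), "window")]
    out$prediction <- pred
    tibble::as_tibble(out)
  } else {
    tibble::tibble(prediction = pred)
  }
}

batch_loss_grad <- function(yhat, y, loss) {
  n <- length(y)
  if (loss == "mse") {
    list(loss = mean((yhat - y)^2), dy = 2 * (yhat - y) / n)
  } else {
    list(loss = mean(abs(yhat - y)), dy = sign(yhat - y) / n)
  }
}

#' Train CLA-PTNet on a windowed remaining-time dataset
#'
#' Seeded, reproducible mini-batch training with Adam. Input windows are
#' standardized with statistics computed from the training set only, and
#' labels are rescaled to unit range by the maximum training label; both
#' sets of statistics are frozen inside the returned model. Optionally
#' monitors validation MAE (in minutes) for early stopping, restoring the
#' best parameters seen.
#'
#' @param model A `claptnet` from [claptnet_init()].
#' @param train_windows Windows tibble ([make_windows()]) with `label`.
#' @param val_windows Optional validation windows tibble.
#' @param verbose Print per-epoch progress.
#' @return The trained `claptnet`; `$history` holds per-epoch train loss
#'   (on the scaled objective) and validation MAE in minutes.
#' @export
claptnet_fit <- function(model, train_windows, val_windows = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(model, "claptnet"))
  cfg <- model$config
  if (is.data.frame(train_windows) && nrow(train_windows) == 0L) {
    fc_abort("training set is empty.")
  }
  x <- windows_to_matrix(train_windows, cfg$seq_len)
  y <- train_windows$label
  if (is.null(y)) fc_abort("`train_windows` must carry a `label` column.")

  model$norm <- list(x_mean = mean(x), x_sd = max(sd(x), 1e-8),
                     y_scale = max(max(y), 1))
  xs <- (x - model$norm$x_mean) / model$norm$x_sd
  ys <- y / model$norm$y_scale

  has_val <- !is.null(val_windows) && nrow(val_windows) > 0L
  if (has_val) {
    xv <- windows_to_matrix(val_windows, cfg$seq_len)
    yv <- val_windows$label
  }

  params <- model$params
  buffers <- model$buffers
  flat <- flatten_params(params)
  opt <- adam_init(flat)
  n <- nrow(xs)
  history <- vector("list", cfg$epochs)
  best <- list(val = Inf, flat = flat, buffers = buffers, epoch = 0L)
  bad_epochs <- 0L

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr_epoch <- cfg$learning_rate * cfg$lr_decay^(epoch - 1)
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        xb <- xs[idx, , drop = FALSE]
        yb <- ys[idx]
        fw <- claptnet_forward_pass(xb, params, buffers, cfg, training = TRUE)
        buffers <- fw$buffers
        lg <- batch_loss_grad(fw$yhat, yb, cfg$loss)
        epoch_loss <- epoch_loss + lg$loss * length(idx)
        grads <- claptnet_backward_pass(lg$dy, params, cfg, fw$cache)
        upd <- adam_update(flat, flatten_params(grads), opt, lr = lr_epoch)
        flat <- upd$flat
        opt <- upd$state
        params <- assign_flat(params, flat)
      }
      epoch_loss <- epoch_loss / n

      val_mae <- NA_real_
      if (has_val) {
        eval_model <- model
        eval_model$params <- params
        eval_model$buffers <- buffers
        pv <- claptnet_forward(eval_model, xv)
        val_mae <- mean(abs(pv - yv))
        if (val_mae < best$val) {
          best <- list(val = val_mae, flat = flat, buffers = buffers,
                       epoch = epoch)
          bad_epochs <- 0L
        } else {
          bad_epochs <- bad_epochs + 1L
        }
      }
      history[[epoch]] <- tibble::tibble(epoch = epoch,
                                         train_loss = epoch_loss,
                                         val_mae = val_mae)
      if (verbose) {
        message(sprintf("epoch %3d  train %s %.5f  val MAE %s",
                        epoch, cfg$loss, epoch_loss,
                        if (is.na(val_mae)) "-" else sprintf("%.1f min", val_mae)))
      }
      if (has_val && is.finite(cfg$patience) && bad_epochs >= cfg$patience) break
    }
  })

  if (has_val && is.finite(best$val)) {
    flat <- best$flat
    buffers <- best$buffers
  }
  model$params <- assign_flat(model$params, flat)
  model$buffers <- buffers
  model$history <- dplyr::bind_rows(history[!vapply(history, is.null, logical(1))])
  model$trained <- TRUE
  model
}

#' Save / load a CLA-PTNet checkpoint
#'
#' Single-file archive holding the configuration, all parameter arrays,
#' batch-norm buffers, normalization statistics and training history.
#'
#' @param model A `claptnet`.
#' @param path File path.
#' @return `save_claptnet()` returns `path` invisibly; `load_claptnet()`
#'   the restored model.
#' @export
save_claptnet <- function(model, path) {
  stopifnot(inherits(model, "claptnet"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_claptnet
#' @export
load_claptnet <- function(path) {
  obj <- readRDS(path)
  obj$config <- structure(obj$config, class = "claptnet_config")
  structure(obj, class = "claptnet")
}

# ---- building-block surfaces ----------------------------------------------

#' Position-aware time-weighted self-attention on one hidden sequence
#'
#' The core attention variant: a learnable positional-encoding matrix `P`
#' is added to the hidden states (`H' = H + P`), queries/keys/values are
#' linear projections of `H'`, each key row `i` is rescaled by a learnable
#' time weight `w_time[i]`, scores are row-softmax-normalized after
#' division by the scale, and the output is the weight matrix times `V`.
#' With `P = 0` and `w_time = 1` this reduces exactly to textbook scaled
#' dot-product self-attention.
#'
#' @param H Hidden-state matrix `t x d`.
#' @param P Positional-encoding matrix `t x d`.
#' @param w_q,w_k,w_v Projection matrices `d x d`.
#' @param w_time Time-weight vector of length `t`.
#' @param scale `"sqrt_d"` or `"d"`.
#' @return List with `output` (`t x d`) and `weights` (`t x t` attention
#'   matrix; every row sums to 1).
#' @export
#' @examples
#' H <- matrix(rnorm(5 * 4), 5, 4)
#' a <- ptwsa(H, P = matrix(0, 5, 4), diag(4), diag(4), diag(4),
#'            w_time = rep(1, 5))
#' rowSums(a$weights)
ptwsa <- function(H, P, w_q, w_k, w_v, w_time, scale = c("sqrt_d", "d")) {
  scale <- match.arg(scale)
  H <- as.matrix(H)
  t <- nrow(H); d <- ncol(H)
  stopifnot(identical(dim(P), c(t, d)),
            identical(dim(w_q), c(d, d)), identical(dim(w_k), c(d, d)),
            identical(dim(w_v), c(d, d)), length(w_time) == t)
  if (!all(is.finite(c(H, P, w_q, w_k, w_v, w_time)))) {
    fc_abort("non-finite attention parameters.")
  }
  sc <- switch(scale, sqrt_d = sqrt(d), d = d)
  Hp <- H + P
  Q <- Hp %*% w_q
  K <- Hp %*% w_k
  V <- Hp %*% w_v
  Kp <- K * w_time
  W <- softmax_rows(Q %*% t(Kp) / sc)
  list(output = W %*% V, weights = W)
}

#' CBE block forward pass (convolution, batch norm, ELU)
#'
#' Advanced building-block API: runs a batch of raw windows through the
#' model's convolutional feature extractor. Length-preserving by
#' construction (odd kernels, symmetric zero padding).
#'
#' @param model A `claptnet`.
#' @param x Numeric matrix `batch x t` (raw, unstandardized values are
#'   accepted; no input normalization is applied here).
#' @param training Use batch statistics (`TRUE`) or the stored running
#'   statistics (`FALSE`).
#' @return Feature array `batch x t x c`.
#' @export
cbe_forward <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "claptnet"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$config$seq_len) {
    fc_abort(sprintf("input length %d does not match seq_len %d.",
                     ncol(x), model$config$seq_len))
  }
  cbe_block_forward(x, model$params$conv, model$buffers$bn, training)$out
}

#' LDE block forward pass (LSTM, ELU, dropout)
#'
#' Advanced building-block API: encodes a feature sequence with the model's
#' LSTM stack. Dropout is applied only in training mode, so evaluation-mode
#' calls are deterministic.
#'
#' @param model A `claptnet`.
#' @param features Array `batch x t x c` (e.g. from [cbe_forward()]).
#' @param training Apply dropout.
#' @return Hidden-state array `batch x t x d`.
#' @export
lde_forward <- function(model, features, training = FALSE) {
  stopifnot(inherits(model, "claptnet"))
  if (length(dim(features)) != 3L) {
    fc_abort("`features` must be a batch x t x c array.")
  }
  lde_block_forward(features, model$params$lstm,
                    model$config$dropout, training)$out
}

# ---- broom-style methods ---------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy summary of CLA-PTNet parameter groups
#'
#' @param x A `claptnet`.
#' @param ... Unused.
#' @return A tibble with one row per parameter array: `term`, `block`,
#'   `n_params`, `l2_norm`.
#' @method tidy claptnet
#' @export
tidy.claptnet <- function(x, ...) {
  flat <- flatten_params(x$params)
  tibble::tibble(
    term = names(flat),
    block = sub("\\..*$", "", names(flat)),
    n_params = vapply(flat, length, integer(1)),
    l2_norm = vapply(flat, function(v) sqrt(sum(v^2)), numeric(1))
  )
}

#' One-row summary of a CLA-PTNet fit
#'
#' @param x A `claptnet`.
#' @param ... Unused.
#' @return A tibble with `n_params`, `epochs_trained`, `final_train_loss`,
#'   `best_val_mae` (minutes, `NA` if no validation set was used).
#' @method glance claptnet
#' @export
glance.claptnet <- function(x, ...) {
  tibble::tibble(
    n_params = claptnet_n_params(x),
    epochs_trained = nrow(x$history),
    final_train_loss = if (nrow(x$history)) utils::tail(x$history$train_loss, 1) else NA_real_,
    best_val_mae = if (nrow(x$history) && any(is.finite(x$history$val_mae))) {
      min(x$history$val_mae, na.rm = TRUE)
    } else {
      NA_real_
    }
  )
}
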