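# The 1d-CNN classifier. Filters of size F0 x 1 span the whole frequency
# axis and slide only along time with stride 1 and same-padding, so the
# convolutional layer is exactly a linear map R^F0 -> R^N applied to every
# time frame: one GEMM per batch. The rest of the network is a max-pool
# along time, a flatten (n3 = T1 * N), one ReLU dense layer (n4) and a
# sigmoid output. Forward, backward and the Adadelta optimizer are written
# directly in base matrix algebra; training is deterministic given the
# config seed on a fixed BLAS.

#' 1d-CNN configuration
#'
#' Defaults are the canonical operating point: 128 frequency-spanning
#' filters, max-pool kernel 5 / stride 4 / padding 4, 128 hidden neurons,
#' 50 epochs of Adadelta with batch 80 and a learning rate decaying
#' exponentially from 1 to 0.01.
#'
#' @param N Number of convolution filters (depth of layer 1).
#' @param pool_k Max-pool kernel length along time.
#' @param pool_s Max-pool stride along time.
#' @param pool_p Max-pool padding (equal to `pool_s` canonically; only used
#'   by the `"explicit"` pooling convention).
#' @param n4 Width of the hidden dense layer.
#' @param epochs,batch Training epochs and mini-batch size.
#' @param lr_start,lr_end Learning-rate schedule endpoints; the rate decays
#'   exponentially across epochs from `lr_start` to `lr_end`.
#' @param rho,eps Adadelta decay rate and conditioner.
#' @param seed Seed for weight initialization and batch shuffling.
#' @param pool_convention `"same"` (default): pooled length `ceil(T0/s)`,
#'   the usual same-padding convention; `"explicit"`: the textbook
#'   `floor((T0 + 2p - k)/s) + 1` using `pool_p` literally.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(N = 128L, pool_k = 5L, pool_s = 4L, pool_p = 4L,
                       n4 = 128L, epochs = 50L, batch = 80L,
                       lr_start = 1, lr_end = 0.01,
                       rho = 0.95, eps = 1e-7, seed = 1L,
                       pool_convention = c("same", "explicit")) {
  pool_convention <- match.arg(pool_convention)
  stopifnot(N >= 1L, pool_k >= 1L, pool_s >= 1L, pool_p >= 0L,
            n4 >= 1L, epochs >= 1L, batch >= 1L,
            lr_start > 0, lr_end > 0, rho > 0, rho < 1, eps > 0)
  structure(
    list(N = as.integer(N), pool_k = as.integer(pool_k),
         pool_s = as.integer(pool_s), pool_p = as.integer(pool_p),
         n4 = as.integer(n4), epochs = as.integer(epochs),
         batch = as.integer(batch), lr_start = lr_start, lr_end = lr_end,
         rho = rho, eps = eps, seed = as.integer(seed),
         pool_convention = pool_convention),
    class = "cnn_config"
  )
}

#' Temporal length after max-pooling
#'
#' @param T0 Input length along time.
#' @param k,s,p Pool kernel, stride, padding.
#' @param convention `"same"` gives `ceil(T0/s)` (padding implied by the
#'   output size); `"explicit"` gives `floor((T0 + 2p - k)/s) + 1`.
#' @return Integer pooled length `T1`.
#' @export
#' @examples
#' pooled_length(125, 5, 4, 4)  # 32
pooled_length <- function(T0, k, s, p = s,
                          convention = c("same", "explicit")) {
  convention <- match.arg(convention)
  stopifnot(T0 >= 1L, k >= 1L, s >= 1L, p >= 0L)
  if (convention == "same") as.integer(ceiling(T0 / s))
  else as.integer((T0 + 2L * p - k) %/% s + 1L)
}

# Window start positions (1-based, may stick out of [1, T0]; out-of-range
# positions act as -Inf padding, i.e. windows are clipped to valid frames).
pool_windows <- function(T0, k, s, p, convention) {
  t1 <- pooled_length(T0, k, s, p, convention)
  starts <- if (convention == "same") {
    pad_total <- max((t1 - 1L) * s + k - T0, 0L)
    (seq_len(t1) - 1L) * s + 1L - pad_total %/% 2L
  } else {
    (seq_len(t1) - 1L) * s + 1L - p
  }
  lapply(starts, function(a) seq(max(1L, a), min(T0, a + k - 1L)))
}

glorot <- function(nrow, ncol) {
  limit <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -limit, limit), nrow, ncol)
}

#' Build a 1d-CNN model
#'
#' Instantiates the architecture for a given input geometry and seeds the
#' weights (Glorot-uniform, zero biases). Layers: (1) convolution, `N`
#' filters of size `F0 x 1`, stride 1, ReLU; (2) max-pool `(1, pool_k)`,
#' stride `(1, pool_s)`; (3) flatten to `n3 = T1 * N`; (4) dense `n4`,
#' ReLU; output dense 1, sigmoid.
#'
#' @param config A [cnn_config()].
#' @param F0,T0 Input spectrogram geometry (frequency bins x time frames),
#'   defaults 513 x 125.
#' @return A list of class `cnn_model` with the weight tensors (`W1`, `b1`,
#'   `W3`, `b3`, `W4`, `b4`), geometry (`F0`, `T0`, `T1`, `n3`), pooling
#'   windows, the config, and an empty training trace.
#' @export
build_model <- function(config, F0 = 513L, T0 = 125L) {
  stopifnot(inherits(config, "cnn_config"), F0 >= 1L, T0 >= 1L)
  wins <- pool_windows(T0, config$pool_k, config$pool_s, config$pool_p,
                       config$pool_convention)
  t1 <- length(wins)
  n3 <- t1 * config$N
  weights <- with_seed(config$seed, {
    list(W1 = glorot(config$N, F0), b1 = numeric(config$N),
         W3 = glorot(config$n4, n3), b3 = numeric(config$n4),
         W4 = glorot(1L, config$n4), b4 = 0)
  })
  structure(
    c(weights,
      list(F0 = as.integer(F0), T0 = as.integer(T0), T1 = t1, n3 = n3,
           windows = wins, config = config, loss_trace = numeric(0))),
    class = "cnn_model"
  )
}

#' Trainable parameter counts
#'
#' Counted from the actual weight tensors; layer 3 (flatten) has none.
#'
#' @param model A `cnn_model`.
#' @return List with `conv`, `hidden`, `output` and `total` counts.
#' @export
count_params <- function(model) {
  conv <- length(model$W1) + length(model$b1)
  hidden <- length(model$W3) + length(model$b3)
  output <- length(model$W4) + length(model$b4)
  list(conv = conv, hidden = hidden, output = output,
       total = conv + hidden + output)
}

#' @export
print.cnn_model <- function(x, ...) {
  p <- count_params(x)
  cat(sprintf(paste0(
    "<cnn_model %dx%d -> conv N=%d -> pool k=%d s=%d -> T1=%d ",
    "-> n3=%d -> n4=%d -> 1; %d params>\n"),
    x$F0, x$T0, x$config$N, x$config$pool_k, x$config$pool_s,
    x$T1, x$n3, x$config$n4, p$total))
  invisible(x)
}

# Forward pass on a batch. X is F0 x (T0*B), columns ordered sample-major
# (time frame fastest). Returns probabilities and, if keep = TRUE, the
# cache needed for the backward pass.
cnn_forward <- function(model, X, B, keep = FALSE) {
  N <- model$config$N; T0 <- model$T0; T1 <- model$T1
  Z1 <- model$W1 %*% X + model$b1
  A1 <- Z1 * (Z1 > 0)

  P_ <- matrix(0, N, T1 * B)
  AT <- if (keep) matrix(1L, N, T1 * B) else NULL
  b0_T0 <- (seq_len(B) - 1L) * T0
  for (j in seq_len(T1)) {
    win <- model$windows[[j]]
    best <- A1[, b0_T0 + win[1L], drop = FALSE]
    arg <- if (keep) matrix(win[1L], N, B) else NULL
    for (t in win[-1L]) {
      cur <- A1[, b0_T0 + t, drop = FALSE]
      upd <- cur > best
      best[upd] <- cur[upd]
      if (keep) arg[upd] <- t
    }
    cols_out <- (seq_len(B) - 1L) * T1 + j
    P_[, cols_out] <- best
    if (keep) AT[, cols_out] <- arg
  }
  F3 <- P_
  dim(F3) <- c(model$n3, B)

  Z3 <- model$W3 %*% F3 + model$b3
  A3 <- Z3 * (Z3 > 0)
  Z4 <- model$W4 %*% A3 + model$b4
  P <- as.numeric(1 / (1 + exp(-Z4)))
  if (!keep) return(list(p = P))
  list(p = P, Z1 = Z1, AT = AT, F3 = F3, Z3 = Z3, A3 = A3, X = X)
}

# Binary cross-entropy loss and gradients for one batch.
cnn_loss_grads <- function(model, X, y, B) {
  fw <- cnn_forward(model, X, B, keep = TRUE)
  p <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))

  N <- model$config$N; T0 <- model$T0; T1 <- model$T1
  dZ4 <- matrix((fw$p - y) / B, 1L, B)
  dW4 <- tcrossprod(dZ4, fw$A3)
  db4 <- sum(dZ4)
  dA3 <- crossprod(model$W4, dZ4)
  dZ3 <- dA3 * (fw$Z3 > 0)
  dW3 <- tcrossprod(dZ3, fw$F3)
  db3 <- rowSums(dZ3)
  dF3 <- crossprod(model$W3, dZ3)

  dP_ <- dF3
  dim(dP_) <- c(N, T1 * B)
  dA1 <- matrix(0, N, T0 * B)
  rowm <- matrix(seq_len(N), N, B)
  bcol <- matrix(rep((seq_len(B) - 1L) * T0, each = N), N, B)
  for (j in seq_len(T1)) {
    cols_out <- (seq_len(B) - 1L) * T1 + j
    # flatten to vector indexing: an N x 2 integer matrix would otherwise
    # be taken as (row, col) matrix subscripts
    lin <- as.vector((bcol + AT_sub(fw$AT, cols_out) - 1L) * N + rowm)
    dA1[lin] <- dA1[lin] + as.vector(dP_[, cols_out])
  }
  dZ1 <- dA1 * (fw$Z1 > 0)
  dW1 <- tcrossprod(dZ1, fw$X)
  db1 <- rowSums(dZ1)

  list(loss = loss,
       grads = list(W1 = dW1, b1 = db1, W3 = dW3, b3 = db3,
                    W4 = dW4, b4 = db4))
}

AT_sub <- function(AT, cols) AT[, cols, drop = FALSE]

WEIGHT_NAMES <- c("W1", "b1", "W3", "b3", "W4", "b4")

#' Train a 1d-CNN
#'
#' Mini-batch Adadelta on binary cross-entropy. The learning rate decays
#' exponentially across epochs, `lr(e) = lr_start * (lr_end/lr_start) ^
#' ((e-1)/(epochs-1))`; batch order is reshuffled each epoch from the
#' config seed, so a run is fully reproducible.
#'
#' @param model A `cnn_model` from [build_model()].
#' @param x Sample array `F0 x T0 x L` of normalized log-spectrograms, or a
#'   `crop_features` object (then `y` defaults to its labels).
#' @param y Binary sample labels (each crop inherits its speaker's label).
#' @param verbose Print the per-epoch loss.
#' @return The trained `cnn_model`; `$loss_trace` holds the mean training
#'   loss per epoch.
#' @export
train_model <- function(model, x, y = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"))
  if (inherits(x, "crop_features")) {
    if (is.null(y)) y <- x$meta$label
    x <- x$x
  }
  stopifnot(length(dim(x)) == 3L)
  if (dim(x)[1L] != model$F0 || dim(x)[2L] != model$T0) {
    stop("sample geometry ", dim(x)[1L], "x", dim(x)[2L],
         " does not match model ", model$F0, "x", model$T0)
  }
  L <- dim(x)[3L]
  if (L == 0L) stop("empty training set")
  stopifnot(length(y) == L, all(y %in% c(0, 1)))

  cfg <- model$config
  T0 <- model$T0
  Xall <- x
  dim(Xall) <- c(model$F0, T0 * L)

  state <- lapply(WEIGHT_NAMES, function(nm) {
    w <- model[[nm]]
    list(Eg = w * 0, Ed = w * 0)
  })
  names(state) <- WEIGHT_NAMES

  trace <- numeric(cfg$epochs)
  for (e in seq_len(cfg$epochs)) {
    lr <- if (cfg$epochs == 1L) cfg$lr_start else
      cfg$lr_start * (cfg$lr_end / cfg$lr_start)^((e - 1) / (cfg$epochs - 1))
    ord <- with_seed(derive_seed(cfg$seed, "shuffle", e), sample.int(L))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch))
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      B <- length(idx)
      cols <- as.vector(outer(seq_len(T0), (idx - 1L) * T0, "+"))
      lg <- cnn_loss_grads(model, Xall[, cols, drop = FALSE], y[idx], B)
      if (!is.finite(lg$loss)) {
        stop("training diverged (non-finite loss) at epoch ", e)
      }
      losses[bi] <- lg$loss
      for (nm in WEIGHT_NAMES) {
        g <- lg$grads[[nm]]
        st <- state[[nm]]
        st$Eg <- cfg$rho * st$Eg + (1 - cfg$rho) * g^2
        dx <- -sqrt(st$Ed + cfg$eps) / sqrt(st$Eg + cfg$eps) * g
        st$Ed <- cfg$rho * st$Ed + (1 - cfg$rho) * dx^2
        state[[nm]] <- st
        model[[nm]] <- model[[nm]] + lr * dx
      }
    }
    trace[e] <- mean(losses)
    if (verbose) {
      message(sprintf("epoch %3d  lr %.4f  loss %.5f", e, lr, trace[e]))
    }
  }
  model$loss_trace <- trace
  model
}

#' Per-sample depression probabilities
#'
#' @param model A trained `cnn_model`.
#' @param x Sample array `F0 x T0 x L` or a `crop_features` object.
#' @param batch Prediction batch size (memory knob only).
#' @return Numeric vector of `L` probabilities in `[0, 1]`, in input order.
#' @export
predict_samples <- function(model, x, batch = 256L) {
  if (inherits(x, "crop_features")) x <- x$x
  stopifnot(length(dim(x)) == 3L)
  if (dim(x)[1L] != model$F0 || dim(x)[2L] != model$T0) {
    stop("sample geometry ", dim(x)[1L], "x", dim(x)[2L],
         " does not match model ", model$F0, "x", model$T0)
  }
  L <- dim(x)[3L]
  T0 <- model$T0
  Xall <- x
  dim(Xall) <- c(model$F0, T0 * L)
  p <- numeric(L)
  for (start in seq(1L, L, by = batch)) {
    idx <- start:min(L, start + batch - 1L)
    cols <- as.vector(outer(seq_len(T0), (idx - 1L) * T0, "+"))
    p[idx] <- cnn_forward(model, Xall[, cols, drop = FALSE],
                          length(idx))$p
  }
  p
}
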