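# Convolutional classifier for 36 x 32 grayscale pair maps.
#
# Convolutions and pooling run in direct compiled kernels (src/): each
# sample's activation block is small enough to stay cache-resident, so no
# patch matrices are materialized. Activations for a batch of B samples
# with C channels are stored as an (H*W) x (C*B) matrix, channels fastest
# within a sample.

conv_geom <- function(H, W, k) {
  Hout <- H - k + 1L
  Wout <- W - k + 1L
  npatch <- Hout * Wout
  i <- rep(seq_len(Hout), times = Wout)
  j <- rep(seq_len(Wout), each = Hout)
  di <- rep(0:(k - 1L), times = k)
  dj <- rep(0:(k - 1L), each = k)
  idx <- outer(i, di, "+") + (outer(j, dj, "+") - 1L) * H   # npatch x k^2
  storage.mode(idx) <- "integer"
  list(H = H, W = W, k = k, k2 = k * k, Hout = Hout, Wout = Wout,
       npatch = npatch, idx = idx)
}

conv_fwd <- function(X, W, b, g, Cin, Cout, B) {
  conv_fwd_cb(X, W, b, g$H, g$W, g$k, Cin, Cout, B)   # (npatch) x (Cout*B)
}

conv_bwd <- function(dY, X_in, W, g, Cin, Cout, B, input_grad = TRUE) {
  gr <- conv_grad_cb(X_in, dY, g$H, g$W, g$k, Cin, Cout, B)
  dX <- if (input_grad) conv_dx_cb(dY, W, g$H, g$W, g$k, Cin, Cout, B)
  list(dX = dX, dW = gr$dW, db = gr$db)
}

pool_fwd <- function(X, g, CB) {
  maxpool_cb(X, g$idx)
}

pool_bwd <- function(dY, amax, g, CB) {
  maxpool_bwd_cb(dY, amax, g$idx, g$H * g$W)
}

#' CNN model configuration
#'
#' Three 6 x 6 convolutions (stride 1, no padding, shared channel count),
#' each followed by ReLU, with 3 x 3 stride-1 max pooling after the second
#' and third convolutions, then a fully connected layer and softmax over
#' (interaction, non-interaction). On a 36 x 32 input the spatial sizes
#' are 31x27, 26x22, 24x20, 19x15, 17x13, giving a flattened length of
#' `channels * 221` (14,144 at the default 64 channels).
#'
#' @param channels Channel count of all three convolutions (default 64;
#'   the hyperparameter search uses \{2, 4, 8, 16, 32, 64\}).
#' @param input_dim Input height and width (fixed 36 x 32 pair maps).
#' @return List of class `"cnn_config"`.
#' @export
cnn_config <- function(channels = 64L, input_dim = c(36L, 32L)) {
  channels <- as.integer(channels)
  if (!channels %in% c(2L, 4L, 8L, 16L, 32L, 64L)) {
    warning("channel count ", channels, " is outside the usual search set {2,4,...,64}")
  }
  structure(list(channels = channels, input_dim = as.integer(input_dim),
                 conv_kernel = 6L, pool_kernel = 3L),
            class = "cnn_config")
}

#' Layer-by-layer output shapes of the network
#'
#' @param config A [cnn_config()].
#' @return Data frame with one row per layer (`layer`, `height`, `width`,
#'   `channels`) ending with the flattened length.
#' @export
cnn_shapes <- function(config = cnn_config()) {
  H <- config$input_dim[1]; W <- config$input_dim[2]
  k <- config$conv_kernel; p <- config$pool_kernel; ch <- config$channels
  dims <- list(input = c(H, W, 1L))
  step <- function(hw, d) c(hw[1] - d + 1L, hw[2] - d + 1L)
  hw <- c(H, W)
  hw <- step(hw, k); dims$conv1 <- c(hw, ch)
  hw <- step(hw, k); dims$conv2 <- c(hw, ch)
  hw <- step(hw, p); dims$pool1 <- c(hw, ch)
  hw <- step(hw, k); dims$conv3 <- c(hw, ch)
  hw <- step(hw, p); dims$pool2 <- c(hw, ch)
  out <- data.frame(layer = names(dims),
                    height = vapply(dims, `[`, integer(1), 1L),
                    width = vapply(dims, `[`, integer(1), 2L),
                    channels = vapply(dims, `[`, integer(1), 3L),
                    row.names = NULL)
  attr(out, "flat_length") <- out$height[nrow(out)] * out$width[nrow(out)] * ch
  out
}

init_weight <- function(nrow, ncol, fan_in) {
  s <- 1 / sqrt(fan_in)
  matrix(stats::runif(nrow * ncol, -s, s), nrow, ncol)
}

#' Build an untrained CNN
#'
#' Weights use the standard uniform fan-in initialization
#' `U(-1/sqrt(fan_in), 1/sqrt(fan_in))` under the recorded seed.
#'
#' @param config A [cnn_config()].
#' @param seed Integer seed for weight initialization.
#' @return List of class `"ppi_cnn"` holding `config`, `params`, the
#'   precomputed layer geometry, and the seed.
#' @export
build_cnn <- function(config = cnn_config(), seed = 1L) {
  ch <- config$channels
  k2 <- config$conv_kernel^2
  shp <- cnn_shapes(config)
  flat <- attr(shp, "flat_length")
  g1 <- conv_geom(shp$height[1], shp$width[1], config$conv_kernel)
  g2 <- conv_geom(shp$height[2], shp$width[2], config$conv_kernel)
  gp1 <- conv_geom(shp$height[3], shp$width[3], config$pool_kernel)
  g3 <- conv_geom(shp$height[4], shp$width[4], config$conv_kernel)
  gp2 <- conv_geom(shp$height[5], shp$width[5], config$pool_kernel)
  params <- with_seed(seed, list(
    W1 = init_weight(k2, ch, k2), b1 = stats::runif(ch, -1/sqrt(k2), 1/sqrt(k2)),
    W2 = init_weight(k2 * ch, ch, k2 * ch), b2 = stats::runif(ch, -1/sqrt(k2*ch), 1/sqrt(k2*ch)),
    W3 = init_weight(k2 * ch, ch, k2 * ch), b3 = stats::runif(ch, -1/sqrt(k2*ch), 1/sqrt(k2*ch)),
    Wfc = init_weight(2L, flat, flat), bfc = stats::runif(2L, -1/sqrt(flat), 1/sqrt(flat))))
  structure(list(config = config, params = params, seed = seed,
                 geom = list(g1 = g1, g2 = g2, gp1 = gp1, g3 = g3, gp2 = gp2),
                 flat_length = flat),
            class = "ppi_cnn")
}

as_input_matrix <- function(x) {
  if (is.matrix(x) && nrow(x) == 1152L) return(x)
  d <- dim(x)
  if (length(d) == 2L) {                  # single 36 x 32 map
    stopifnot(all(d == c(36L, 32L)))
    return(matrix(as.vector(x), 1152L, 1L))
  }
  stopifnot(length(d) == 3L, d[1] == 36L, d[2] == 32L)
  dim(x) <- c(1152L, d[3])
  x
}

cnn_forward <- function(model, X, cache = FALSE) {
  p <- model$params; g <- model$geom; ch <- model$config$channels
  B <- ncol(X)
  Z1 <- conv_fwd(X, p$W1, p$b1, g$g1, 1L, ch, B)
  A1 <- pmax(Z1, 0)
  Z2 <- conv_fwd(A1, p$W2, p$b2, g$g2, ch, ch, B)
  A2 <- pmax(Z2, 0)
  p1 <- pool_fwd(A2, g$gp1, ch * B)
  Z3 <- conv_fwd(p1$out, p$W3, p$b3, g$g3, ch, ch, B)
  A3 <- pmax(Z3, 0)
  p2 <- pool_fwd(A3, g$gp2, ch * B)
  Xf <- p2$out
  dim(Xf) <- c(model$flat_length, B)
  logits <- p$Wfc %*% Xf + p$bfc
  m <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, m))
  probs <- sweep(e, 2L, colSums(e), "/")            # 2 x B, row 1 = interaction
  out <- list(probs = probs)
  if (cache) {
    out$cache <- list(X0 = X, Z1 = Z1, A1 = A1, Z2 = Z2,
                      pool1 = p1, Z3 = Z3, pool2 = p2,
                      Xf = Xf, B = B)
  }
  out
}

cnn_backward <- function(model, cache, dlogits) {
  p <- model$params; g <- model$geom; ch <- model$config$channels
  B <- cache$B
  grads <- list()
  grads$Wfc <- dlogits %*% t(cache$Xf)
  grads$bfc <- rowSums(dlogits)
  dXf <- t(p$Wfc) %*% dlogits
  dim(dXf) <- c(g$gp2$npatch, ch * B)
  dA3 <- pool_bwd(dXf, cache$pool2$amax, g$gp2, ch * B)
  dZ3 <- dA3 * (cache$Z3 > 0)
  b3 <- conv_bwd(dZ3, cache$pool1$out, p$W3, g$g3, ch, ch, B)
  grads$W3 <- b3$dW; grads$b3 <- b3$db
  dA2 <- pool_bwd(b3$dX, cache$pool1$amax, g$gp1, ch * B)
  dZ2 <- dA2 * (cache$Z2 > 0)
  b2 <- conv_bwd(dZ2, cache$A1, p$W2, g$g2, ch, ch, B)
  grads$W2 <- b2$dW; grads$b2 <- b2$db
  dZ1 <- b2$dX * (cache$Z1 > 0)
  b1 <- conv_bwd(dZ1, cache$X0, p$W1, g$g1, 1L, ch, B, input_grad = FALSE)
  grads$W1 <- b1$dW; grads$b1 <- b1$db
  grads
}

# Cross-entropy over softmax outputs; labels are 1 (interaction, class
# row 1) or 0 (non-interaction, class row 2).
ce_loss <- function(probs, y) {
  r <- ifelse(y == 1L, 1L, 2L)
  -mean(log(pmax(probs[cbind(r, seq_along(y))], 1e-300)))
}

#' Training configuration
#'
#' @param lr Adam learning rate (searched in `[1e-5, 1e-3]`).
#' @param batch_size Mini-batch size (default 128).
#' @param max_epochs Epoch cap (default 100).
#' @param patience Early-stopping patience on validation loss (default
#'   10): training stops once the validation loss has not strictly
#'   improved for this many consecutive epochs, and the best-validation
#'   weights are restored.
#' @param seed Seed controlling shuffling (and any other training
#'   randomness).
#' @return List of class `"cnn_train_config"`.
#' @export
cnn_train_config <- function(lr = 5e-4, batch_size = 128L, max_epochs = 100L,
                             patience = 10L, seed = 1L) {
  stopifnot(lr > 0, batch_size > 0, patience < max_epochs)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "cnn_train_config")
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train a CNN with Adam and early stopping
#'
#' Mini-batch training with per-batch averaged cross-entropy, Adam
#' updates, and early stopping on the validation loss: if the validation
#' loss does not strictly improve for `patience` consecutive epochs,
#' training stops and the best-validation checkpoint is restored.
#'
#' @param model A [build_cnn()] model.
#' @param x,y Training maps (36 x 32 x n array) and binary labels.
#' @param val_x,val_y Validation maps and labels.
#' @param tc A [cnn_train_config()].
#' @param verbose Print per-epoch losses.
#' @return The trained model, with `history` (per-epoch train/validation
#'   loss), `stopped_epoch` and `best_epoch` attached.
#' @export
cnn_train <- function(model, x, y, val_x, val_y,
                      tc = cnn_train_config(), verbose = FALSE) {
  X <- as_input_matrix(x)
  Xv <- as_input_matrix(val_x)
  n <- ncol(X)
  if (!n || !ncol(Xv)) ppi_stop("empty training or validation set")
  stopifnot(length(y) == n, length(val_y) == ncol(Xv))
  state <- list(m = lapply(model$params, function(p) p * 0),
                v = lapply(model$params, function(p) p * 0))
  best <- Inf; best_params <- model$params; best_epoch <- 0L
  wait <- 0L; t_step <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  with_seed(tc$seed, {
    for (epoch in seq_len(tc$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = tc$batch_size)
      batch_losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        sel <- ord[starts[bi]:min(starts[bi] + tc$batch_size - 1L, n)]
        fw <- cnn_forward(model, X[, sel, drop = FALSE], cache = TRUE)
        loss <- ce_loss(fw$probs, y[sel])
        if (!is.finite(loss)) {
          ppi_stop("non-finite training loss at epoch %d, batch %d (lr = %g)",
                   epoch, bi, tc$lr)
        }
        batch_losses[bi] <- loss
        onehot <- rbind(as.numeric(y[sel] == 1L), as.numeric(y[sel] != 1L))
        dlogits <- (fw$probs - onehot) / length(sel)
        grads <- cnn_backward(model, fw$cache, dlogits)
        t_step <- t_step + 1L
        upd <- adam_step(model$params, grads, state, tc$lr, t_step)
        model$params <- upd$params
        state <- upd$state
      }
      val_probs <- predict_probs(model, Xv)
      val_loss <- ce_loss(t(val_probs), val_y)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = mean(batch_losses),
                                     val_loss = val_loss))
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        mean(batch_losses), val_loss))
      }
      if (val_loss < best) {
        best <- val_loss; best_params <- model$params
        best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= tc$patience) break
      }
    }
  })
  model$params <- best_params
  model$history <- hist
  model$best_epoch <- best_epoch
  model$stopped_epoch <- nrow(hist)
  model$train_config <- tc
  model
}

predict_probs <- function(model, X, batch_size = 256L) {
  n <- ncol(X)
  out <- matrix(NA_real_, n, 2L,
                dimnames = list(NULL, c("interaction", "non_interaction")))
  for (s in seq(1L, n, by = batch_size)) {
    sel <- s:min(s + batch_size - 1L, n)
    out[sel, ] <- t(cnn_forward(model, X[, sel, drop = FALSE])$probs)
  }
  out
}

#' Predict interaction probabilities
#'
#' @param object A trained `"ppi_cnn"`.
#' @param x Maps (36 x 32 x n array, single map, or 1152 x n matrix).
#' @param type `"prob"` for the interaction probability vector, `"matrix"`
#'   for both class probabilities.
#' @param ... Unused.
#' @return Numeric vector (or n x 2 matrix) of probabilities.
#' @export
predict.ppi_cnn <- function(object, x, type = c("prob", "matrix"), ...) {
  type <- match.arg(type)
  probs <- predict_probs(object, as_input_matrix(x))
  if (type == "prob") probs[, "interaction"] else probs
}
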