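# A small inception-style 1-D convolutional network, written directly in
# vectorized base R (BLAS matrix products). Input: n x 40 x C arrays
# (sequence one-hot plus factor channels); output: n x 20 per-position
# editing efficiencies through a sigmoid head. Loss: mean-squared error
# masked to target-base positions.
#
# Layout notes: an (i, t, c) element of an R array sits at row i + (t-1)*n of
# matrix(X, n*T, C), which is what makes the convolution a plain matmul.

SEQ_LEN <- 40L
OUT_LEN <- 20L

#' Initialize a convolutional efficiency network
#'
#' Parallel convolution branches (one per kernel width, 'same' zero padding)
#' over the 40-bp axis, ReLU, channel concatenation, width-2 max pooling
#' (40 -> 20), then a dense sigmoid layer emitting 20 per-position outputs.
#'
#' @param n_channels Input channels (4 sequence + k factors).
#' @param control A [be_training_control()].
#' @param seed RNG seed for weight initialization.
#' @return List of class `be_cnn` holding weights and architecture.
#' @export
cnn_init <- function(n_channels, control = be_training_control(), seed = 1L) {
  widths <- control$kernel_widths
  F <- control$filters
  with_seed(seed, {
    branches <- lapply(widths, function(w) {
      sd <- sqrt(2 / (w * n_channels))
      list(W = array(stats::rnorm(w * n_channels * F, sd = sd),
                     dim = c(w, n_channels, F)),
           b = numeric(F))
    })
    n_hidden <- OUT_LEN * length(widths) * F
    list_structure <- list(
      branches = branches,
      Wd = matrix(stats::rnorm(n_hidden * OUT_LEN, sd = sqrt(1 / n_hidden)),
                  n_hidden, OUT_LEN),
      bd = numeric(OUT_LEN),
      widths = widths, filters = F, n_channels = n_channels,
      loss = control$loss
    )
    structure(list_structure, class = "be_cnn")
  })
}

# Forward pass; returns predictions and (optionally) the cache for backprop.
cnn_forward <- function(net, X, cache = FALSE) {
  n <- dim(X)[1]
  F <- net$filters
  nb <- length(net$widths)
  A_all <- array(0, c(n, SEQ_LEN, nb * F))
  Zs <- if (cache) vector("list", nb) else NULL
  for (bi in seq_len(nb)) {
    w <- net$widths[bi]
    lp <- (w - 1L) %/% 2L
    Wb <- net$branches[[bi]]$W
    Z <- array(rep(net$branches[[bi]]$b, each = n * SEQ_LEN),
               c(n, SEQ_LEN, F))
    for (d in seq_len(w)) {
      src <- (1:SEQ_LEN) - lp + d - 1L
      tt <- which(src >= 1L & src <= SEQ_LEN)
      ss <- src[tt]
      M <- matrix(X[, ss, , drop = FALSE], n * length(tt), net$n_channels)
      Z[, tt, ] <- Z[, tt, , drop = FALSE] +
        array(M %*% matrix(Wb[d, , ], net$n_channels, F), c(n, length(tt), F))
    }
    if (cache) Zs[[bi]] <- Z
    A_all[, , (bi - 1) * F + seq_len(F)] <- pmax(Z, 0)
  }
  odd <- A_all[, seq(1, SEQ_LEN, 2), , drop = FALSE]
  even <- A_all[, seq(2, SEQ_LEN, 2), , drop = FALSE]
  take_odd <- odd >= even
  P <- ifelse(take_odd, odd, even)
  Pf <- matrix(P, n, OUT_LEN * nb * F)
  logits <- Pf %*% net$Wd + rep(net$bd, each = n)
  yhat <- 1 / (1 + exp(-logits))
  out <- list(yhat = yhat)
  if (cache) {
    out$X <- X; out$Zs <- Zs; out$take_odd <- take_odd
    out$Pf <- Pf; out$logits <- logits
  }
  out
}

# Masked loss and output gradient. Y and mask are n x 20; masked-out entries
# never contribute.
cnn_loss <- function(net, yhat, Y, mask) {
  m <- sum(mask)
  if (net$loss == "logit_mse") {
    eps <- 1e-6
    ly <- stats::qlogis(pmin(pmax(Y, eps), 1 - eps))
    lh <- stats::qlogis(pmin(pmax(yhat, eps), 1 - eps))
    list(loss = sum(mask * (lh - ly)^2) / m,
         dyhat = 2 * mask * (lh - ly) / (m * pmax(yhat * (1 - yhat), eps)))
  } else {
    list(loss = sum(mask * (yhat - Y)^2) / m,
         dyhat = 2 * mask * (yhat - Y) / m)
  }
}

# Backward pass: gradients for every parameter.
cnn_backward <- function(net, fw, dyhat) {
  n <- nrow(dyhat)
  F <- net$filters
  nb <- length(net$widths)
  dlogits <- dyhat * fw$yhat * (1 - fw$yhat)
  gWd <- crossprod(fw$Pf, dlogits)
  gbd <- colSums(dlogits)
  dPf <- dlogits %*% t(net$Wd)
  dP <- array(dPf, c(n, OUT_LEN, nb * F))
  dA <- array(0, c(n, SEQ_LEN, nb * F))
  dA[, seq(1, SEQ_LEN, 2), ] <- dP * fw$take_odd
  dA[, seq(2, SEQ_LEN, 2), ] <- dP * (!fw$take_odd)
  grads <- list(Wd = gWd, bd = gbd, branches = vector("list", nb))
  for (bi in seq_len(nb)) {
    w <- net$widths[bi]
    lp <- (w - 1L) %/% 2L
    Z <- fw$Zs[[bi]]
    dZ <- dA[, , (bi - 1) * F + seq_len(F), drop = FALSE] * (Z > 0)
    gW <- array(0, dim(net$branches[[bi]]$W))
    gb <- colSums(matrix(dZ, n * SEQ_LEN, F))
    for (d in seq_len(w)) {
      src <- (1:SEQ_LEN) - lp + d - 1L
      tt <- which(src >= 1L & src <= SEQ_LEN)
      ss <- src[tt]
      M <- matrix(fw$X[, ss, , drop = FALSE], n * length(tt), net$n_channels)
      dZm <- matrix(dZ[, tt, , drop = FALSE], n * length(tt), F)
      gW[d, , ] <- crossprod(M, dZm)
    }
    grads$branches[[bi]] <- list(W = gW, b = gb)
  }
  grads
}

# One Adam update over the flattened parameter list. State carries first and
# second moments plus the step counter.
adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(param, grad, key) {
    if (is.null(state$m[[key]])) {
      state$m[[key]] <- param * 0
      state$v[[key]] <- param * 0
    }
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * grad
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * grad^2
    mh <- state$m[[key]] / (1 - beta1^state$t)
    vh <- state$v[[key]] / (1 - beta2^state$t)
    param - lr * mh / (sqrt(vh) + eps)
  }
  net$Wd <- upd(net$Wd, grads$Wd, "Wd")
  net$bd <- upd(net$bd, grads$bd, "bd")
  for (bi in seq_along(net$branches)) {
    net$branches[[bi]]$W <- upd(net$branches[[bi]]$W,
                                grads$branches[[bi]]$W, paste0("W", bi))
    net$branches[[bi]]$b <- upd(net$branches[[bi]]$b,
                                grads$branches[[bi]]$b, paste0("b", bi))
  }
  list(net = net, state = state)
}

#' Fit the convolutional network by minibatch Adam with early stopping
#'
#' @param X n x 40 x C input array.
#' @param Y,mask n x 20 matrices of labels and target-position indicators.
#' @param control A [be_training_control()].
#' @param val_idx Indices held out for per-epoch validation loss (early
#'   stopping with the control's patience); `NULL` disables early stopping.
#' @param seed RNG seed (weight init and minibatch order).
#' @param net Optional pre-initialized network (for warm starts).
#' @return List: `net` (the weights at the best validation epoch), `history`
#'   data.frame of per-epoch train/validation loss, `epochs_run`.
#' @export
cnn_fit <- function(X, Y, mask, control = be_training_control(),
                    val_idx = NULL, seed = 1L, net = NULL) {
  n <- dim(X)[1]
  if (is.null(net)) net <- cnn_init(dim(X)[3], control, seed = seed)
  train_idx <- setdiff(seq_len(n), val_idx)
  state <- new.env(parent = emptyenv())
  state$t <- 0L; state$m <- list(); state$v <- list()
  best <- list(loss = Inf, net = net, epoch = 0L)
  history <- list()
  wait <- 0L
  with_seed(seed + 1L, {
    for (epoch in seq_len(control$epochs)) {
      ord <- sample(train_idx)
      nb <- ceiling(length(ord) / control$batch_size)
      tr_loss <- 0
      for (b in seq_len(nb)) {
        idx <- ord[((b - 1) * control$batch_size + 1):min(b * control$batch_size,
                                                          length(ord))]
        fw <- cnn_forward(net, X[idx, , , drop = FALSE], cache = TRUE)
        ls <- cnn_loss(net, fw$yhat, Y[idx, , drop = FALSE],
                       mask[idx, , drop = FALSE])
        tr_loss <- tr_loss + ls$loss * length(idx)
        grads <- cnn_backward(net, fw, ls$dyhat)
        res <- adam_step(net, grads, state, control$learning_rate)
        net <- res$net
      }
      tr_loss <- tr_loss / length(train_idx)
      if (!is.null(val_idx) && length(val_idx) > 0) {
        fw <- cnn_forward(net, X[val_idx, , , drop = FALSE])
        vl <- cnn_loss(net, fw$yhat, Y[val_idx, , drop = FALSE],
                       mask[val_idx, , drop = FALSE])$loss
      } else {
        vl <- tr_loss
      }
      history[[epoch]] <- data.frame(epoch = epoch, train_loss = tr_loss,
                                     val_loss = vl)
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, net = net, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (!is.null(val_idx) && wait >= control$patience) break
      }
    }
  })
  list(net = best$net, history = do.call(rbind, history),
       epochs_run = length(history), best_epoch = best$epoch,
       best_val_loss = best$loss)
}
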