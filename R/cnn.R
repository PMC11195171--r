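# Convolutional neural network for spectrogram classification, implemented
# natively: compiled im2col/pooling data-movement kernels feed one BLAS
# matrix product per layer; batch normalization, dropout, Adam and the
# training loop live in R. Architecture: conv 3x3 x24 + ReLU, batchnorm,
# conv 3x3 x48 + ReLU, maxpool 2x2 (stride 1), batchnorm, fully connected
# 64, dropout, fully connected 2; softmax cross-entropy loss.
#
# Activation layout: matrices with rows indexing (h, w, image) -- h
# fastest -- and one column per channel.

# K: (3, 3, C, K_out) -> (9*C) x K_out matching the im2col column order
kern2mat <- function(K) {
  d <- dim(K)
  matrix(aperm(K, c(3L, 2L, 1L, 4L)), 9L * d[3L], d[4L])
}
mat2kern <- function(Km, C, K_out) {
  aperm(array(Km, c(C, 3L, 3L, K_out)), c(3L, 2L, 1L, 4L))
}

# Batchnorm over a (rows x channels) matrix. Returns normalized matrix and
# cache; updates running moments when training.
bn_forward <- function(Xm, bn, train, momentum = 0.1, eps = 1e-5) {
  if (train) {
    mom <- col_moments_nc(Xm, eps)
    mu <- mom$mu
    invstd <- mom$invstd
    bn$run_mean <- (1 - momentum) * bn$run_mean + momentum * mom$mu
    bn$run_var <- (1 - momentum) * bn$run_var + momentum * mom$var
  } else {
    mu <- bn$run_mean
    invstd <- 1 / sqrt(bn$run_var + eps)
  }
  ap <- bn_apply_nc(Xm, mu, invstd, bn$gamma, bn$beta)
  list(out = ap$out, xhat = ap$xhat, invstd = invstd, bn = bn)
}

bn_backward <- function(cache, gamma, dY) {
  bn_bwd_nc(dY, cache$xhat, cache$invstd, gamma)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Initialize the spectrogram CNN
#'
#' Builds the network used for context decoding: two 3x3 stride-1
#' convolutional layers with 24 and 48 kernels and ReLU activations, each
#' followed by batch normalization (the second after 2x2 max pooling), a
#' 64-unit fully connected layer with dropout, and a 2-unit output layer.
#'
#' @param input_dim `c(H, W)` spectrogram dimensions (freq x time).
#' @param seed integer seed for the He-normal weight initialization.
#' @param n_kernels1,n_kernels2 kernels in the two convolutional layers.
#' @param fc_units hidden units of the first fully connected layer.
#' @param n_classes output classes.
#' @param pool_stride max-pool stride (default 1; 2 gives the conventional
#'   halving variant).
#' @param dropout dropout rate on the hidden fully connected layer.
#' @return object of class `cnn_model`.
#' @export
cnn_init <- function(input_dim, seed = 1, n_kernels1 = 24L, n_kernels2 = 48L,
                     fc_units = 64L, n_classes = 2L, pool_stride = 1L,
                     dropout = 0.5) {
  H <- as.integer(input_dim[1L]); W <- as.integer(input_dim[2L])
  if (H < 6L || W < 6L)
    stop("input too small for two 3x3 convolutions and 2x2 pooling: ",
         H, "x", W)
  H3 <- (H - 4L - 2L) %/% pool_stride + 1L
  W3 <- (W - 4L - 2L) %/% pool_stride + 1L
  D <- H3 * W3 * n_kernels2
  with_seed(seed, {
    he <- function(fan_in, dims) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
    params <- list(
      K1 = he(9, c(3L, 3L, 1L, n_kernels1)), b1 = numeric(n_kernels1),
      g1 = rep(1, n_kernels1), be1 = numeric(n_kernels1),
      K2 = he(9 * n_kernels1, c(3L, 3L, n_kernels1, n_kernels2)),
      b2 = numeric(n_kernels2),
      g2 = rep(1, n_kernels2), be2 = numeric(n_kernels2),
      Wf1 = matrix(rnorm(D * fc_units, 0, sqrt(2 / D)), D, fc_units),
      bf1 = numeric(fc_units),
      Wf2 = matrix(rnorm(fc_units * n_classes, 0, sqrt(2 / fc_units)),
                   fc_units, n_classes),
      bf2 = numeric(n_classes))
    structure(list(params = params,
                   bn1 = list(run_mean = numeric(n_kernels1),
                              run_var = rep(1, n_kernels1)),
                   bn2 = list(run_mean = numeric(n_kernels2),
                              run_var = rep(1, n_kernels2)),
                   input_dim = c(H, W), pool_stride = as.integer(pool_stride),
                   dropout = dropout, flat_dim = D,
                   n_kernels = c(n_kernels1, n_kernels2),
                   fc_units = fc_units, n_classes = n_classes),
              class = "cnn_model")
  })
}

#' Audit the CNN architecture
#'
#' Reports kernel counts and sizes, strides and layer widths for
#' conformance checks.
#'
#' @param model a `cnn_model`.
#' @return list describing each layer.
#' @export
cnn_shape_audit <- function(model) {
  p <- model$params
  list(conv1 = list(kernels = dim(p$K1)[4L], size = dim(p$K1)[1:2], stride = c(1L, 1L)),
       conv2 = list(kernels = dim(p$K2)[4L], size = dim(p$K2)[1:2], stride = c(1L, 1L)),
       pool = list(size = c(2L, 2L), stride = rep(model$pool_stride, 2L)),
       fc1 = list(units = ncol(p$Wf1)),
       dropout = model$dropout,
       fc2 = list(units = ncol(p$Wf2)))
}

# Forward pass; X: array (H, W, N). Returns logits (N x classes) and, when
# `train`, the caches needed for backprop. Dropout uses the ambient RNG.
cnn_forward <- function(model, X, train = FALSE) {
  if (length(dim(X)) == 4L) X <- array(X, dim(X)[c(1:2, 4L)])
  p <- model$params
  d <- dim(X)
  H <- d[1L]; W <- d[2L]; N <- d[3L]
  stopifnot(H == model$input_dim[1L], W == model$input_dim[2L])
  H1 <- H - 2L; W1 <- W - 2L
  H2 <- H1 - 2L; W2 <- W1 - 2L
  s <- model$pool_stride
  H3 <- (H2 - 2L) %/% s + 1L; W3 <- (W2 - 2L) %/% s + 1L

  Xm <- matrix(X, H * W * N, 1L)
  M1 <- im2col3_nc(Xm, H, W, N)
  A1 <- bias_relu_nc(M1 %*% kern2mat(p$K1), p$b1)
  n1 <- bn_forward(A1, c(model$bn1, list(gamma = p$g1, beta = p$be1)), train)
  if (train) model$bn1 <- n1$bn[c("run_mean", "run_var")]

  M2 <- im2col3_nc(n1$out, H1, W1, N)
  A2 <- bias_relu_nc(M2 %*% kern2mat(p$K2), p$b2)

  pl <- pool2_fwd_nc(A2, H2, W2, N, s)
  n2 <- bn_forward(pl$out, c(model$bn2, list(gamma = p$g2, beta = p$be2)), train)
  if (train) model$bn2 <- n2$bn[c("run_mean", "run_var")]
  flat <- nc_to_flat(n2$out, H3, W3, N)

  Z1 <- sweep(flat %*% p$Wf1, 2L, p$bf1, "+")
  A3 <- Z1 * (Z1 > 0)
  if (train && model$dropout > 0) {
    mask <- matrix((runif(length(A3)) >= model$dropout) / (1 - model$dropout),
                   nrow(A3), ncol(A3))
    A3d <- A3 * mask
  } else {
    mask <- NULL
    A3d <- A3
  }
  Z2 <- sweep(A3d %*% p$Wf2, 2L, p$bf2, "+")

  list(logits = Z2, model = model,
       cache = if (train) list(M1 = M1, A1 = A1, n1 = n1, M2 = M2,
                               A2 = A2, pl = pl, n2 = n2, flat = flat,
                               Z1 = Z1, mask = mask, A3d = A3d,
                               dims = c(H = H, W = W, N = N, H1 = H1,
                                        W1 = W1, H2 = H2, W2 = W2,
                                        H3 = H3, W3 = W3)) else NULL)
}

# Backward pass from logits; y: integer class labels (1-based).
cnn_backward <- function(model, fwd, y) {
  p <- model$params
  cc <- fwd$cache
  dm <- cc$dims
  N <- dm[["N"]]
  P <- softmax_rows(fwd$logits)
  Y <- matrix(0, N, model$n_classes)
  Y[cbind(seq_len(N), y)] <- 1
  dZ2 <- (P - Y) / N

  dWf2 <- crossprod(cc$A3d, dZ2)
  dbf2 <- colSums(dZ2)
  dA3 <- tcrossprod(dZ2, p$Wf2)
  if (!is.null(cc$mask)) dA3 <- dA3 * cc$mask
  dZ1 <- relu_mask_nc(dA3, cc$Z1)
  dWf1 <- crossprod(cc$flat, dZ1)
  dbf1 <- colSums(dZ1)
  dflat <- tcrossprod(dZ1, p$Wf1)

  dB2 <- flat_to_nc(dflat, dm[["H3"]], dm[["W3"]], N, dim(p$K2)[4L])
  bnb2 <- bn_backward(cc$n2, p$g2, dB2)
  dA2 <- pool2_bwd_nc(bnb2$dX, cc$pl$which, dm[["H2"]], dm[["W2"]], N,
                      model$pool_stride)
  dZ2c <- relu_mask_nc(dA2, cc$A2)
  dK2 <- mat2kern(crossprod(cc$M2, dZ2c), dim(p$K2)[3L], dim(p$K2)[4L])
  db2 <- colSums(dZ2c)
  dM2 <- tcrossprod(dZ2c, kern2mat(p$K2))
  dB1 <- col2im3_nc(dM2, dm[["H1"]], dm[["W1"]], N, dim(p$K1)[4L])

  bnb1 <- bn_backward(cc$n1, p$g1, dB1)
  dZ1c <- relu_mask_nc(bnb1$dX, cc$A1)
  dK1 <- mat2kern(crossprod(cc$M1, dZ1c), 1L, dim(p$K1)[4L])
  db1 <- colSums(dZ1c)
  # gradient w.r.t. the input image is not needed (first layer)

  list(K1 = dK1, b1 = db1, g1 = bnb1$dgamma, be1 = bnb1$dbeta,
       K2 = dK2, b2 = db2, g2 = bnb2$dgamma, be2 = bnb2$dbeta,
       Wf1 = dWf1, bf1 = dbf1, Wf2 = dWf2, bf2 = dbf2)
}

cnn_loss <- function(logits, y) {
  P <- softmax_rows(logits)
  -mean(log(pmax(P[cbind(seq_len(nrow(P)), y)], 1e-12)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the spectrogram CNN
#'
#' Minibatch Adam on softmax cross-entropy. After each epoch the model is
#' evaluated on the validation set; the parameters with the best validation
#' accuracy seen so far are retained and returned (epoch-wise model
#' selection).
#'
#' @param model a `cnn_model` from [cnn_init()].
#' @param x training spectrograms, array (H, W, N) normalized to `[0, 1]`.
#' @param y training labels, integer (1-based) or factor of length N.
#' @param x_val,y_val validation set in the same format.
#' @param epochs training epochs (default 40).
#' @param batch_size minibatch size (default 20).
#' @param lr Adam learning rate.
#' @param eval_train also evaluate training-set accuracy each epoch (for
#'   diagnostics; validation accuracy is always tracked for model
#'   selection).
#' @return the trained `cnn_model` with `history` (per-epoch train loss,
#'   train/validation accuracy) and `best_epoch` attached.
#' @export
cnn_train <- function(model, x, y, x_val, y_val, epochs = 40L,
                      batch_size = 20L, lr = 1e-3, eval_train = FALSE) {
  y <- as.integer(as.factor(y))
  y_val <- as.integer(as.factor(y_val))
  N <- dim(x)[3L]
  stopifnot(length(y) == N)
  best <- list(acc = -Inf, params = model$params,
               bn1 = model$bn1, bn2 = model$bn2, epoch = 0L)
  state <- adam_init(model$params)
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(N)
    losses <- numeric(0)
    for (start in seq(1L, N, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, N)]
      if (length(idx) < 2L) next                 # batchnorm needs > 1 item
      fwd <- cnn_forward(model, x[, , idx, drop = FALSE], train = TRUE)
      model <- fwd$model
      losses <- c(losses, cnn_loss(fwd$logits, y[idx]))
      grads <- cnn_backward(model, fwd, y[idx])
      upd <- adam_step(model$params, grads, state, lr = lr)
      model$params <- upd$params
      state <- upd$state
    }
    tr_acc <- if (eval_train) mean(cnn_predict(model, x) == y) else NA_real_
    va_acc <- mean(cnn_predict(model, x_val) == y_val)
    hist[[ep]] <- data.frame(epoch = ep, loss = mean(losses),
                             train_acc = tr_acc, val_acc = va_acc)
    if (va_acc > best$acc) {
      best <- list(acc = va_acc, params = model$params,
                   bn1 = model$bn1, bn2 = model$bn2, epoch = ep)
    }
  }
  model$params <- best$params
  model$bn1 <- best$bn1
  model$bn2 <- best$bn2
  model$history <- do.call(rbind, hist)
  model$best_epoch <- best$epoch
  model
}

#' Predict classes with a trained CNN
#'
#' @param model a trained `cnn_model`.
#' @param x array (H, W, N) of normalized spectrograms.
#' @param prob return the class-2 softmax probability instead of labels.
#' @return integer class labels (1-based) or probabilities.
#' @export
cnn_predict <- function(model, x, prob = FALSE) {
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  n <- dim(x)[3L]
  out <- integer(n)
  pr <- numeric(n)
  # predict in chunks to bound transient im2col memory
  for (start in seq(1L, n, by = 64L)) {
    idx <- start:min(start + 63L, n)
    fwd <- cnn_forward(model, x[, , idx, drop = FALSE], train = FALSE)
    P <- softmax_rows(fwd$logits)
    out[idx] <- max.col(P, ties.method = "first")
    pr[idx] <- P[, ncol(P)]
  }
  if (prob) pr else out
}

#' @export
print.cnn_model <- function(x, ...) {
  a <- cnn_shape_audit(x)
  cat("<cnn_model> input ", paste(x$input_dim, collapse = "x"),
      ": conv3x3x", a$conv1$kernels, " -> bn -> conv3x3x", a$conv2$kernels,
      " -> maxpool2x2/s", a$pool$stride[1L], " -> bn -> fc", a$fc1$units,
      " -> dropout(", x$dropout, ") -> fc", a$fc2$units, "\n", sep = "")
  if (!is.null(x$best_epoch))
    cat("  best validation epoch:", x$best_epoch, "\n")
  invisible(x)
}
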