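#' CNN hyperparameter configuration
#'
#' The published stack uses receptive fields of 5, 5 and 2 with 20, 50 and
#' 500 filters, stride 1, learning rate 0.001, batch size 1000 (whole-map
#' fusion, Architecture 1) or 100 (per-channel fusion, Architecture 2) and
#' 300 / 150 epochs respectively.  The `"desk"` profile (filters 8/16/64,
#' 20 epochs, batch 8, momentum 0.9) is a scaled-down configuration for
#' testing on synthetic data at n ~ 60: the published batch sizes exceed a
#' desk-scale dataset outright, so the desk batch is sized to give a
#' meaningful number of SGD updates; the full profiles remain the
#' documented defaults.
#'
#' Unstated details default to: plain SGD (momentum 0), dropout rate 0.5
#' applied only before the fully connected layer, 2x2 stride-2 max pooling,
#' valid (no) padding.  The desk profile alone uses momentum 0.9: plain SGD
#' at rate 0.001 is calibrated for hundreds of epochs, and the 20-epoch
#' profile compensates with standard momentum rather than a changed rate.
#'
#' @param profile `"arch1"`, `"arch2"` or `"desk"`; sets the defaults below.
#' @param kernel_sizes receptive fields of the three conv stages.
#' @param filters number of filters per conv stage.
#' @param learning_rate SGD learning rate.
#' @param batch_size mini-batch size.
#' @param epochs training epochs.
#' @param dropout_rate dropout probability before the dense layer.
#' @param momentum SGD momentum (0 = plain SGD).
#' @param n_classes number of output classes l.
#' @param seed integer controlling initialization, shuffling and dropout.
#' @return list of class `CNNConfig`.
#' @export
cnn_config <- function(profile = c("arch1", "arch2", "desk"),
                       kernel_sizes = c(5L, 5L, 2L),
                       filters = NULL, learning_rate = 0.001,
                       batch_size = NULL, epochs = NULL,
                       dropout_rate = 0.5, momentum = 0,
                       n_classes = 6L, seed = 1L) {
  profile <- match.arg(profile)
  def <- switch(profile,
    arch1 = list(filters = c(20L, 50L, 500L), batch_size = 1000L, epochs = 300L),
    arch2 = list(filters = c(20L, 50L, 500L), batch_size = 100L,  epochs = 150L),
    desk  = list(filters = c(8L, 16L, 64L),   batch_size = 8L,    epochs = 20L,
                 momentum = 0.9))
  if (is.null(filters)) filters <- def$filters
  if (is.null(batch_size)) batch_size <- def$batch_size
  if (is.null(epochs)) epochs <- def$epochs
  if (missing(momentum) && !is.null(def$momentum)) momentum <- def$momentum
  stopifnot(length(kernel_sizes) == 3, length(filters) == 3,
            all(kernel_sizes >= 1), all(filters >= 1),
            learning_rate > 0, batch_size >= 1, epochs >= 1,
            dropout_rate >= 0, dropout_rate < 1, n_classes >= 2)
  structure(list(profile = profile,
                 kernel_sizes = as.integer(kernel_sizes),
                 filters = as.integer(filters), stride = 1L,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 dropout_rate = dropout_rate, momentum = momentum,
                 n_classes = as.integer(n_classes),
                 seed = as.integer(seed),
                 bn_eps = 1e-5, bn_momentum = 0.9),
            class = "CNNConfig")
}

# ---- internal layer engine ------------------------------------------------
# Activations travel as matrices (prod(shape) x N), rows flattened
# column-major over (H, W, C).  Each layer carries its in/out shape and any
# precomputed index tables; caches live in the layer during a fwd/bwd pair.

.im2col_index <- function(h, w, cin, k) {
  hout <- h - k + 1L; wout <- w - k + 1L
  g <- expand.grid(dh = 0:(k - 1L), dw = 0:(k - 1L), c = 0:(cin - 1L))
  p <- expand.grid(oh = 1:hout, ow = 0:(wout - 1L))
  # idx[kk, p]: linear index of input element feeding patch p, kernel pos kk
  outer(g$dh + g$dw * h + g$c * (h * w),
        p$oh + p$ow * h, `+`)
}

.layer_conv <- function(in_shape, k, cout) {
  h <- in_shape[1]; w <- in_shape[2]; cin <- in_shape[3]
  if (h < k || w < k) {
    stop(sprintf("input %dx%d too small for conv with receptive field %d",
                 h, w, k))
  }
  K <- k * k * cin
  list(type = "conv", in_shape = in_shape,
       out_shape = c(h - k + 1L, w - k + 1L, cout),
       k = k, K = K, P = (h - k + 1L) * (w - k + 1L),
       idx = as.vector(.im2col_index(h, w, cin, k)),
       W = matrix(stats::rnorm(K * cout, sd = sqrt(2 / K)), K, cout),
       b = numeric(cout))
}

.layer_bn <- function(in_shape) {
  C <- in_shape[3]
  list(type = "bn", in_shape = in_shape, out_shape = in_shape, C = C,
       plane = prod(in_shape[1:2]),
       gamma = rep(1, C), beta = numeric(C),
       run_mean = numeric(C), run_var = rep(1, C))
}

.layer_relu <- function(in_shape) {
  list(type = "relu", in_shape = in_shape, out_shape = in_shape)
}

.layer_pool <- function(in_shape) {
  h <- in_shape[1]; w <- in_shape[2]; C <- in_shape[3]
  hout <- h %/% 2L; wout <- w %/% 2L
  if (hout < 1L || wout < 1L) {
    stop(sprintf("input %dx%d too small for 2x2 max pooling", h, w))
  }
  p <- expand.grid(oh = 1:hout, ow = 1:wout, c = 1:C)
  base <- (2L * p$oh - 1L) + (2L * p$ow - 2L) * h + (p$c - 1L) * h * w
  list(type = "pool", in_shape = in_shape, out_shape = c(hout, wout, C),
       idx = rbind(base, base + 1L, base + h, base + h + 1L))
}

.layer_dropout <- function(in_shape, rate) {
  list(type = "dropout", in_shape = in_shape, out_shape = in_shape,
       rate = rate)
}

.layer_dense <- function(in_shape, units) {
  D <- as.integer(prod(in_shape))
  list(type = "dense", in_shape = in_shape, out_shape = c(units),
       D = D, W = matrix(stats::rnorm(D * units, sd = sqrt(2 / D)), D, units),
       b = numeric(units))
}

.forward_layer <- function(ly, A, train) {
  N <- ncol(A)
  switch(ly$type,
    conv = {
      out <- matrix(0, ly$P * ncol(ly$W), N)
      if (train) cache <- vector("list", N)
      bP <- rep(ly$b, each = ly$P)
      for (n in seq_len(N)) {
        Pm <- matrix(A[ly$idx, n], ly$K, ly$P)
        out[, n] <- crossprod(Pm, ly$W) + bP
        if (train) cache[[n]] <- Pm
      }
      if (train) ly$cache <- cache
      list(ly = ly, A = out)
    },
    bn = {
      out <- A
      if (train) {
        xhat <- A; inv_std <- numeric(ly$C); mcount <- ly$plane * N
        for (cc in seq_len(ly$C)) {
          rows <- (cc - 1L) * ly$plane + seq_len(ly$plane)
          v <- A[rows, , drop = FALSE]
          mu <- mean(v); va <- mean((v - mu)^2)
          is <- 1 / sqrt(va + 1e-5)
          xh <- (v - mu) * is
          xhat[rows, ] <- xh
          inv_std[cc] <- is
          out[rows, ] <- ly$gamma[cc] * xh + ly$beta[cc]
          ly$run_mean[cc] <- 0.9 * ly$run_mean[cc] + 0.1 * mu
          ly$run_var[cc] <- 0.9 * ly$run_var[cc] + 0.1 * va
        }
        ly$cache <- list(xhat = xhat, inv_std = inv_std, m = mcount)
      } else {
        for (cc in seq_len(ly$C)) {
          rows <- (cc - 1L) * ly$plane + seq_len(ly$plane)
          is <- 1 / sqrt(ly$run_var[cc] + 1e-5)
          out[rows, ] <- ly$gamma[cc] * (A[rows, , drop = FALSE] -
                                           ly$run_mean[cc]) * is + ly$beta[cc]
        }
      }
      list(ly = ly, A = out)
    },
    relu = {
      out <- pmax(A, 0)
      if (train) ly$cache <- A > 0
      list(ly = ly, A = out)
    },
    pool = {
      Pout <- ncol(ly$idx)
      best <- matrix(A[ly$idx[1L, ], ], Pout, N)
      arg <- matrix(1L, Pout, N)
      for (q in 2:4) {
        v <- matrix(A[ly$idx[q, ], ], Pout, N)
        upd <- v > best
        best[upd] <- v[upd]; arg[upd] <- q
      }
      if (train) ly$cache <- arg
      list(ly = ly, A = best)
    },
    dropout = {
      if (train && ly$rate > 0) {
        mask <- matrix(stats::runif(length(A)) >= ly$rate,
                       nrow(A), N) / (1 - ly$rate)
        ly$cache <- mask
        list(ly = ly, A = A * mask)
      } else {
        ly$cache <- NULL
        list(ly = ly, A = A)
      }
    },
    dense = {
      out <- crossprod(ly$W, A) + ly$b
      if (train) ly$cache <- A
      list(ly = ly, A = out)
    })
}

.backward_layer <- function(ly, dA) {
  N <- ncol(dA)
  switch(ly$type,
    conv = {
      cout <- ncol(ly$W)
      dW <- matrix(0, ly$K, cout); db <- numeric(cout)
      dIn <- matrix(0, prod(ly$in_shape), N)
      grp <- ly$idx  # duplicated input indices across patches
      for (n in seq_len(N)) {
        dO <- matrix(dA[, n], ly$P, cout)
        Pm <- ly$cache[[n]]
        dW <- dW + Pm %*% dO
        db <- db + colSums(dO)
        dPm <- ly$W %*% t(dO)                 # K x P
        rs <- rowsum(as.vector(dPm), grp)
        dIn[as.integer(rownames(rs)), n] <- rs
      }
      ly$grad <- list(W = dW, b = db); ly$cache <- NULL
      list(ly = ly, dA = dIn)
    },
    bn = {
      xhat <- ly$cache$xhat; m <- ly$cache$m
      dIn <- dA
      dgamma <- numeric(ly$C); dbeta <- numeric(ly$C)
      for (cc in seq_len(ly$C)) {
        rows <- (cc - 1L) * ly$plane + seq_len(ly$plane)
        dy <- dA[rows, , drop = FALSE]
        xh <- xhat[rows, , drop = FALSE]
        dgamma[cc] <- sum(dy * xh); dbeta[cc] <- sum(dy)
        dIn[rows, ] <- (ly$gamma[cc] * ly$cache$inv_std[cc] / m) *
          (m * dy - dbeta[cc] - xh * dgamma[cc])
      }
      ly$grad <- list(gamma = dgamma, beta = dbeta); ly$cache <- NULL
      list(ly = ly, dA = dIn)
    },
    relu = {
      dIn <- dA * ly$cache
      ly$cache <- NULL
      list(ly = ly, dA = dIn)
    },
    pool = {
      arg <- ly$cache
      dIn <- matrix(0, prod(ly$in_shape), N)
      for (q in 1:4) {
        contrib <- dA * (arg == q)
        dIn[ly$idx[q, ], ] <- dIn[ly$idx[q, ], ] + contrib
      }
      ly$cache <- NULL
      list(ly = ly, dA = dIn)
    },
    dropout = {
      if (!is.null(ly$cache)) dA <- dA * ly$cache
      ly$cache <- NULL
      list(ly = ly, dA = dA)
    },
    dense = {
      A <- ly$cache
      ly$grad <- list(W = A %*% t(dA), b = rowSums(dA))
      ly$cache <- NULL
      list(ly = ly, dA = ly$W %*% dA)
    })
}

.forward_net <- function(model, A, train) {
  for (i in seq_along(model$layers)) {
    r <- .forward_layer(model$layers[[i]], A, train)
    model$layers[[i]] <- r$ly
    A <- r$A
  }
  list(model = model, logits = A)
}

.softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(e))
}

#' Validate the layer-stack geometry for an input size
#'
#' Symbolic shape arithmetic for the fixed stack
#' conv5 -> pool2 -> conv5 -> conv2 (valid padding, stride 1): returns the
#' spatial side lengths after each stage or raises the same error
#' [build_cnn()] would.
#'
#' @param input_shape integer vector (H, W, channels).
#' @param config a [cnn_config()].
#' @return integer vector of spatial sizes (input, conv1, pool, conv2, conv3).
#' @export
validate_cnn_shape <- function(input_shape, config = cnn_config("desk")) {
  input_shape <- as.integer(input_shape)
  h <- input_shape[1]
  k <- config$kernel_sizes
  t1 <- h - k[1] + 1L
  if (t1 < 1L) stop(sprintf("conv layer 1 (field %d) needs input >= %d, got %d",
                            k[1], k[1], h))
  t2 <- t1 %/% 2L
  if (t2 < 1L) stop("max pool needs input >= 2 after conv layer 1")
  t3 <- t2 - k[2] + 1L
  if (t3 < 1L) stop(sprintf("conv layer 2 (field %d) needs %d after pooling, got %d",
                            k[2], k[2], t2))
  t4 <- t3 - k[3] + 1L
  if (t4 < 1L) stop(sprintf("conv layer 3 (field %d) needs %d, got %d",
                            k[3], k[3], t3))
  c(h, t1, t2, t3, t4)
}

#' Build the convolutional network
#'
#' Fixed stack (valid padding, stride 1):
#' conv(k1) -> batch norm -> ReLU -> max pool 2x2 ->
#' conv(k2) -> batch norm -> ReLU ->
#' conv(k3) -> batch norm -> ReLU -> dropout -> dense(l) (+ softmax at the
#' loss/prediction stage).  A single pooling stage keeps the three map
#' geometries (19x19, 20x20, 23x23) and their single-channel variants all
#' valid for the 5/5/2 receptive fields.  Weight initialization is seeded.
#'
#' @param input_shape integer (H, W, channels), e.g. `c(19, 19, 23)` for XA.
#' @param config a [cnn_config()].
#' @return a `cnn_model` (untrained).
#' @export
build_cnn <- function(input_shape, config = cnn_config("desk")) {
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 3)
  validate_cnn_shape(input_shape, config)
  k <- config$kernel_sizes; f <- config$filters
  model <- withr::with_seed(config$seed, {
    layers <- list()
    shp <- input_shape
    add <- function(ly) { layers[[length(layers) + 1L]] <<- ly; ly$out_shape }
    shp <- add(.layer_conv(shp, k[1], f[1]))
    shp <- add(.layer_bn(shp))
    shp <- add(.layer_relu(shp))
    shp <- add(.layer_pool(shp))
    shp <- add(.layer_conv(shp, k[2], f[2]))
    shp <- add(.layer_bn(shp))
    shp <- add(.layer_relu(shp))
    shp <- add(.layer_conv(shp, k[3], f[3]))
    shp <- add(.layer_bn(shp))
    shp <- add(.layer_relu(shp))
    shp <- add(.layer_dropout(shp, config$dropout_rate))
    shp <- add(.layer_dense(shp, config$n_classes))
    list(layers = layers, input_shape = input_shape,
         n_classes = config$n_classes, config = config, trained = FALSE)
  })
  class(model) <- "cnn_model"
  model
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("cnn_model: input (%s), %d classes, %strained\n",
              paste(x$input_shape, collapse = ","), x$n_classes,
              if (x$trained) "" else "un"))
  invisible(x)
}

# stack a list of (H,W,C) arrays into the (prod, N) activation matrix
.as_batch <- function(x, input_shape) {
  if (is.list(x)) {
    N <- length(x)
    A <- matrix(0, prod(input_shape), N)
    for (n in seq_len(N)) {
      xi <- x[[n]]
      if (!identical(dim(xi), as.integer(input_shape))) {
        stop(sprintf("sample %d has shape (%s), model expects (%s)", n,
                     paste(dim(xi), collapse = ","),
                     paste(input_shape, collapse = ",")))
      }
      A[, n] <- as.vector(xi)
    }
    A
  } else if (is.array(x) && length(dim(x)) == 4L) {
    if (!identical(dim(x)[1:3], as.integer(input_shape))) {
      stop("batch array shape does not match model input shape")
    }
    matrix(x, prod(input_shape), dim(x)[4])
  } else stop("x must be a list of 3D arrays or a 4D array (H, W, C, N)")
}

.sgd_step <- function(model, lr, momentum) {
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (is.null(ly$grad)) next
    for (p in names(ly$grad)) {
      vname <- paste0("vel_", p)
      v <- if (is.null(ly[[vname]])) 0 else ly[[vname]]
      v <- momentum * v - lr * ly$grad[[p]]
      ly[[vname]] <- v
      ly[[p]] <- ly[[p]] + v
    }
    ly$grad <- NULL
    model$layers[[i]] <- ly
  }
  model
}

.eval_metrics <- function(model, A, y) {
  probs <- .softmax_cols(.forward_net(model, A, train = FALSE)$logits)
  pred <- apply(probs, 2, which.max)
  eps <- 1e-12
  ll <- -mean(log(pmax(probs[cbind(y, seq_along(y))], eps)))
  c(acc = mean(pred == y), loss = ll)
}

#' Train a CNN by mini-batch SGD on the softmax cross-entropy
#'
#' All randomness (shuffling, dropout) is driven by `config$seed`, so a
#' repeated call with identical inputs reproduces the parameters and the
#' history bit for bit.  Per-epoch train (and optional test) accuracy and
#' loss are recorded in evaluation mode (running batch-norm statistics, no
#' dropout).
#'
#' @param model an untrained [build_cnn()] model.
#' @param x training feature maps: list of 3D arrays or a 4D array.
#' @param y integer class labels in 1..n_classes.
#' @param x_test,y_test optional held-out data monitored per epoch.
#' @param verbose print a line every `verbose` epochs (0 = silent).
#' @return list with `model` (trained) and `history` (`TrainingHistory`
#'   data frame: epoch, train_acc, test_acc, train_loss, test_loss).
#' @export
train_cnn <- function(model, x, y, x_test = NULL, y_test = NULL, verbose = 0) {
  stopifnot(inherits(model, "cnn_model"))
  cfg <- model$config
  A <- .as_batch(x, model$input_shape)
  y <- as.integer(y)
  N <- ncol(A)
  stopifnot(length(y) == N, all(y >= 1), all(y <= model$n_classes))
  missing_cls <- setdiff(seq_len(model$n_classes), unique(y))
  if (length(missing_cls)) {
    stop("training data has no samples for class(es): ",
         paste(missing_cls, collapse = ", "))
  }
  A_test <- if (!is.null(x_test)) .as_batch(x_test, model$input_shape)
  hist <- matrix(NA_real_, cfg$epochs, 4,
                 dimnames = list(NULL, c("train_acc", "test_acc",
                                         "train_loss", "test_loss")))
  model <- withr::with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(N)
      for (start in seq(1L, N, by = cfg$batch_size)) {
        bi <- ord[start:min(start + cfg$batch_size - 1L, N)]
        fw <- .forward_net(model, A[, bi, drop = FALSE], train = TRUE)
        model <- fw$model
        probs <- .softmax_cols(fw$logits)
        loss <- -mean(log(pmax(probs[cbind(y[bi], seq_along(bi))], 1e-12)))
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d (diverged; lower the learning rate)", ep))
        }
        dlogits <- probs
        dlogits[cbind(y[bi], seq_along(bi))] <-
          dlogits[cbind(y[bi], seq_along(bi))] - 1
        dA <- dlogits / length(bi)
        for (i in rev(seq_along(model$layers))) {
          bw <- .backward_layer(model$layers[[i]], dA)
          model$layers[[i]] <- bw$ly
          dA <- bw$dA
        }
        model <- .sgd_step(model, cfg$learning_rate, cfg$momentum)
      }
      tr <- .eval_metrics(model, A, y)
      hist[ep, c(1, 3)] <- tr
      if (!is.null(A_test)) hist[ep, c(2, 4)] <- .eval_metrics(model, A_test, y_test)
      if (verbose > 0 && ep %% verbose == 0) {
        cat(sprintf("epoch %3d  train acc %.3f loss %.4f\n",
                    ep, tr["acc"], tr["loss"]))
      }
    }
    model
  })
  model$trained <- TRUE
  history <- data.frame(epoch = seq_len(cfg$epochs), hist)
  class(history) <- c("TrainingHistory", "data.frame")
  list(model = model, history = history)
}

#' Class probabilities from a trained CNN
#'
#' Evaluation-mode forward pass (running batch-norm statistics, dropout
#' off) followed by softmax normalization; batching does not affect the
#' result.
#'
#' @param model a trained `cnn_model`.
#' @param x list of 3D arrays or a 4D array of feature maps.
#' @return N x l matrix; rows are probability vectors (non-negative,
#'   summing to 1).
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "cnn_model"))
  A <- .as_batch(x, model$input_shape)
  t(.softmax_cols(.forward_net(model, A, train = FALSE)$logits))
}
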