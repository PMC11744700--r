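#' @name mlp
#' @title Built-in fully connected neural network
#'
#' @description
#' A small, dependency-free neural-network engine written in base R matrix
#' code. It exists for two reasons: the four-layer ReLU network is the
#' reference regressor/classifier of this package, and integrated-gradient
#' attribution needs exact analytic gradients of the network output with
#' respect to its *inputs*, which the engine provides in closed form from the
#' same backpropagation pass used for training. Weights use He-scaled normal
#' initialization; training is mini-batch Adam with early stopping on a
#' validation split. All randomness (init, shuffling, split) derives from the
#' seed given at construction, so fitting is exactly reproducible.
NULL

.relu <- function(x) x * (x > 0)

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# new network: input_dim -> hidden[1] -> hidden[2] -> hidden[3] -> output_dim
# (four weight layers, ReLU after each hidden layer, linear output)
.mlp_new <- function(input_dim, hidden, output_dim, seed) {
  stopifnot(length(hidden) == 3, all(hidden >= 1), input_dim >= 1,
            output_dim >= 1)
  dims <- c(input_dim, hidden, output_dim)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  W <- b <- vector("list", 4)
  for (l in 1:4) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1], 0,
                                  sqrt(2 / dims[l])),
                     nrow = dims[l], ncol = dims[l + 1])
    b[[l]] <- rep(0, dims[l + 1])
  }
  list(W = W, b = b, dims = dims, seed = as.integer(seed))
}

# forward pass; X is n x input_dim. Returns list of pre-activations and
# activations (A[[1]] = X, A[[5]] = linear output).
.mlp_forward <- function(net, X) {
  A <- vector("list", 5)
  Z <- vector("list", 4)
  A[[1]] <- X
  for (l in 1:4) {
    Z[[l]] <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    A[[l + 1]] <- if (l < 4) .relu(Z[[l]]) else Z[[l]]
  }
  list(A = A, Z = Z)
}

# backward pass from an output-side gradient dOut (n x output_dim).
# Returns weight/bias gradients and the gradient w.r.t. the input rows.
.mlp_backward <- function(net, fw, dOut) {
  gW <- gb <- vector("list", 4)
  delta <- dOut
  for (l in 4:1) {
    gW[[l]] <- crossprod(fw$A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(net$W[[l]])) * (fw$Z[[l - 1]] > 0)
    } else {
      dX <- delta %*% t(net$W[[1]])
    }
  }
  list(gW = gW, gb = gb, dX = dX)
}

# mini-batch Adam with early stopping on a held-out validation fraction.
# Returns the trained net plus per-epoch mean training loss and val loss.
.mlp_fit <- function(net, X, Y, task = c("regression", "classification"),
                     lr = 1e-3, batch = 32, epochs = 500, patience = 25,
                     val_frac = 0.1, seed = net$seed) {
  task <- match.arg(task)
  n <- nrow(X)
  stopifnot(n >= 2, nrow(Y) == n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) + 1L)

  n_val <- max(1L, floor(val_frac * n))
  if (n - n_val < 2) n_val <- 0L
  perm <- sample.int(n)
  val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(perm, val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
  Xva <- X[val_idx, , drop = FALSE]; Yva <- Y[val_idx, , drop = FALSE]

  mW <- vW <- lapply(net$W, function(w) w * 0)
  mb <- vb <- lapply(net$b, function(bb) bb * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0

  loss_of <- function(out, Yref) {
    if (task == "regression") mean((out - Yref)^2)
    else {
      p <- .softmax(out)
      -mean(log(pmax(rowSums(p * Yref), 1e-12)))
    }
  }
  out_grad <- function(out, Yref) {
    m <- nrow(Yref)
    if (task == "regression") 2 * (out - Yref) / m
    else (.softmax(out) - Yref) / m
  }

  best <- list(W = net$W, b = net$b, val = Inf, epoch = 0L)
  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))
  ntr <- nrow(Xtr)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(ntr)
    ep_losses <- c()
    for (start in seq(1, ntr, by = batch)) {
      idx <- ord[start:min(start + batch - 1, ntr)]
      Xb <- Xtr[idx, , drop = FALSE]; Yb <- Ytr[idx, , drop = FALSE]
      fw <- .mlp_forward(net, Xb)
      out <- fw$A[[5]]
      ep_losses <- c(ep_losses, loss_of(out, Yb))
      gr <- .mlp_backward(net, fw, out_grad(out, Yb))
      t_step <- t_step + 1
      for (l in 1:4) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gr$gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gr$gW[[l]]^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gr$gb[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gr$gb[[l]]^2
        mhatW <- mW[[l]] / (1 - beta1^t_step)
        vhatW <- vW[[l]] / (1 - beta2^t_step)
        mhatb <- mb[[l]] / (1 - beta1^t_step)
        vhatb <- vb[[l]] / (1 - beta2^t_step)
        net$W[[l]] <- net$W[[l]] - lr * mhatW / (sqrt(vhatW) + eps)
        net$b[[l]] <- net$b[[l]] - lr * mhatb / (sqrt(vhatb) + eps)
      }
    }
    val_loss <- if (n_val > 0) {
      loss_of(.mlp_forward(net, Xva)$A[[5]], Yva)
    } else mean(ep_losses)
    trace <- rbind(trace, data.frame(epoch = ep,
                                     train_loss = mean(ep_losses),
                                     val_loss = val_loss))
    if (val_loss < best$val - 1e-9) {
      best <- list(W = net$W, b = net$b, val = val_loss, epoch = ep)
    } else if (ep - best$epoch >= patience) {
      break
    }
  }
  net$W <- best$W
  net$b <- best$b
  list(net = net, trace = trace)
}

# raw network output for X (n x input_dim): linear outputs / logits
.mlp_out <- function(net, X) .mlp_forward(net, X)$A[[5]]

# gradient of one output unit (regression output or class score) w.r.t. each
# input row. X is n x input_dim; returns n x input_dim.
# For classification, `on` selects the class; `of` chooses the softmax
# probability ("prob") or the raw logit ("logit") as the differentiated
# quantity.
.mlp_input_gradient <- function(net, X, on = 1L,
                                of = c("value", "prob", "logit")) {
  of <- match.arg(of)
  fw <- .mlp_forward(net, X)
  out <- fw$A[[5]]
  K <- ncol(out)
  seed_mat <- matrix(0, nrow(X), K)
  if (of == "prob") {
    p <- .softmax(out)
    # d p_on / d z_j = p_on (1[j==on] - p_j)
    seed_mat <- -p * p[, on]
    seed_mat[, on] <- seed_mat[, on] + p[, on]
  } else {
    seed_mat[, on] <- 1
  }
  .mlp_backward(net, fw, seed_mat)$dX
}
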