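## Minimal feedforward neural network for spectral decoloring, implemented
## with dense matrix algebra: leaky-ReLU hidden layers, linear output,
## mean squared error loss, plain SGD with the stepped learning-rate decay
## lr(epoch) = lr0 * 0.9^(epoch/2), optional inverted dropout.

# He-normal initialization of all layers; widths = c(d_in, hidden..., 1)
.init_mlp <- function(widths, seed, leakySlope) {
  .with_seed(seed, {
    L <- length(widths) - 1L
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      W[[l]] <- matrix(rnorm(widths[l] * widths[l + 1L],
                             sd = sqrt(2 / widths[l])),
                       widths[l], widths[l + 1L])
      b[[l]] <- rep(0, widths[l + 1L])
    }
    list(W = W, b = b, widths = widths, leakySlope = leakySlope)
  })
}

# forward pass; returns activations for backprop
.mlp_forward <- function(net, X, dropMasks = NULL) {
  L <- length(net$W)
  a <- X
  acts <- vector("list", L + 1L)
  acts[[1L]] <- a
  for (l in seq_len(L)) {
    z <- a %*% net$W[[l]] + rep(net$b[[l]], each = nrow(a))
    if (l < L) {
      z <- ifelse(z > 0, z, net$leakySlope * z)
      if (!is.null(dropMasks)) z <- z * dropMasks[[l]]
    }
    a <- z
    acts[[l + 1L]] <- a
  }
  list(out = a, acts = acts)
}

# one SGD step on a batch; returns updated net and the batch loss
.mlp_step <- function(net, X, y, lr, dropout) {
  L <- length(net$W)
  n <- nrow(X)
  dropMasks <- NULL
  if (dropout > 0) {
    dropMasks <- lapply(seq_len(L - 1L), function(l)
      matrix((runif(n * ncol(net$W[[l]])) >= dropout) / (1 - dropout),
             n, ncol(net$W[[l]])))
  }
  fw <- .mlp_forward(net, X, dropMasks)
  err <- fw$out - y                      # d loss / d out, x n/2
  loss <- mean(err^2)
  delta <- 2 * err / n
  for (l in rev(seq_len(L))) {
    a_prev <- fw$acts[[l]]
    gW <- crossprod(a_prev, delta)
    gb <- colSums(delta)
    if (l > 1L) {
      back <- delta %*% t(net$W[[l]])
      z <- fw$acts[[l]]                  # post-activation of layer l-1
      grad_act <- ifelse(z > 0, 1, net$leakySlope)
      if (!is.null(dropMasks)) grad_act <- grad_act * dropMasks[[l - 1L]]
      delta <- back * grad_act
    }
    net$W[[l]] <- net$W[[l]] - lr * gW
    net$b[[l]] <- net$b[[l]] - lr * gb
  }
  list(net = net, loss = loss)
}

# full training loop
.train_mlp <- function(X, y, cfg) {
  widths <- nnLayerWidths(cfg, ncol(X))
  net <- .init_mlp(widths, cfg$seed, cfg$leakySlope)
  y <- matrix(y, ncol = 1L)
  n <- nrow(X)
  bs <- as.integer(min(cfg$batchSize, n))
  losses <- numeric(cfg$epochs)
  .with_seed(.child_seed(cfg$seed, 23L), {
    for (epoch in seq_len(cfg$epochs) - 1L) {
      lr <- cfg$lr0 * cfg$lrDecayPerEpoch^epoch
      ord <- if (bs < n) sample.int(n) else seq_len(n)
      starts <- seq(1L, n, by = bs)
      eloss <- 0
      for (s in starts) {
        rows <- ord[s:min(s + bs - 1L, n)]
        st <- .mlp_step(net, X[rows, , drop = FALSE],
                        y[rows, , drop = FALSE], lr, cfg$dropout)
        net <- st$net
        eloss <- eloss + st$loss * length(rows)
      }
      losses[epoch + 1L] <- eloss / n
    }
  })
  c(net, list(loss = losses))
}
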