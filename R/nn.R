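# Small neural-network trainers used by the ann/rnn/cnn classifier
# configurations. All are plain-R matrix implementations trained with Adam;
# the ann/rnn objectives are mean absolute error against one-hot targets
# with an L2 weight penalty (a portable stand-in for Bayesian-regularized
# batch training), the cnn uses cross-entropy.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mh <- state$m[[k]] / (1 - beta1^state$t)
    vh <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

one_hot <- function(y, levels) {
  Y <- matrix(0, length(y), length(levels))
  Y[cbind(seq_along(y), match(y, levels))] <- 1
  Y
}

# ---- MLP: logistic-sigmoid hidden layer, softmax output, MAE + L2 -------

mlp_train <- function(X, y, hidden = 10, epochs = 100, lr = 0.01,
                      l2 = 1e-4, seed = 1) {
  levels <- sort(unique(y))
  Y <- one_hot(y, levels)
  d <- ncol(X); K <- length(levels); n <- nrow(X)
  params <- with_seed(seed, function() list(
    W1 = matrix(rnorm(d * hidden, sd = 0.3), d, hidden),
    b1 = rep(0, hidden),
    W2 = matrix(rnorm(hidden * K, sd = 0.3), hidden, K),
    b2 = rep(0, K)))
  st <- adam_init(params)
  for (ep in seq_len(epochs)) {
    Z1 <- X %*% params$W1 + rep(params$b1, each = n)
    A1 <- 1 / (1 + exp(-Z1))
    Z2 <- A1 %*% params$W2 + rep(params$b2, each = n)
    P <- softmax_rows(Z2)
    dP <- -sign(Y - P) / (n * K)
    dZ2 <- P * (dP - rowSums(dP * P))
    grads <- list(
      W1 = NULL, b1 = NULL,
      W2 = t(A1) %*% dZ2 + 2 * l2 * params$W2,
      b2 = colSums(dZ2))
    dA1 <- dZ2 %*% t(params$W2)
    dZ1 <- dA1 * A1 * (1 - A1)
    grads$W1 <- t(X) %*% dZ1 + 2 * l2 * params$W1
    grads$b1 <- colSums(dZ1)
    upd <- adam_step(params, grads, st, lr)
    params <- upd$params; st <- upd$state
  }
  list(params = params, levels = levels)
}

mlp_predict <- function(model, X) {
  n <- nrow(X)
  A1 <- 1 / (1 + exp(-(X %*% model$params$W1 +
                       rep(model$params$b1, each = n))))
  P <- softmax_rows(A1 %*% model$params$W2 + rep(model$params$b2, each = n))
  model$levels[max.col(P, ties.method = "first")]
}

# ---- RNN: tanh hidden with delays 1:2, linear output, MAE + L2 ----------
# Input: n x T x D array (the 160-dim feature row presented as a length-8
# sequence of per-component channel slices).

rnn_train <- function(Xseq, y, hidden = 10, epochs = 100, lr = 0.01,
                      l2 = 1e-4, seed = 1) {
  levels <- sort(unique(y))
  Y <- one_hot(y, levels)
  n <- dim(Xseq)[1]; Tn <- dim(Xseq)[2]; D <- dim(Xseq)[3]
  K <- length(levels)
  params <- with_seed(seed, function() list(
    Wx = matrix(rnorm(D * hidden, sd = 0.3), D, hidden),
    Wh1 = matrix(rnorm(hidden^2, sd = 0.1), hidden, hidden),
    Wh2 = matrix(rnorm(hidden^2, sd = 0.1), hidden, hidden),
    bh = rep(0, hidden),
    Wo = matrix(rnorm(hidden * K, sd = 0.3), hidden, K),
    bo = rep(0, K)))
  st <- adam_init(params)
  zero <- matrix(0, n, hidden)
  for (ep in seq_len(epochs)) {
    H <- vector("list", Tn)
    h1 <- zero; h2 <- zero
    for (t in seq_len(Tn)) {
      Z <- Xseq[, t, ] %*% params$Wx + h1 %*% params$Wh1 +
        h2 %*% params$Wh2 + rep(params$bh, each = n)
      H[[t]] <- tanh(Z)
      h2 <- h1; h1 <- H[[t]]
    }
    Yhat <- H[[Tn]] %*% params$Wo + rep(params$bo, each = n)
    dY <- -sign(Y - Yhat) / (n * K)
    grads <- list(Wx = params$Wx * 0, Wh1 = params$Wh1 * 0,
                  Wh2 = params$Wh2 * 0, bh = params$bh * 0,
                  Wo = t(H[[Tn]]) %*% dY + 2 * l2 * params$Wo,
                  bo = colSums(dY))
    dH <- vector("list", Tn)
    for (t in seq_len(Tn)) dH[[t]] <- zero
    dH[[Tn]] <- dY %*% t(params$Wo)
    for (t in rev(seq_len(Tn))) {
      dZ <- dH[[t]] * (1 - H[[t]]^2)
      grads$Wx <- grads$Wx + t(Xseq[, t, ]) %*% dZ
      grads$bh <- grads$bh + colSums(dZ)
      hp1 <- if (t >= 2) H[[t - 1]] else zero
      hp2 <- if (t >= 3) H[[t - 2]] else zero
      grads$Wh1 <- grads$Wh1 + t(hp1) %*% dZ
      grads$Wh2 <- grads$Wh2 + t(hp2) %*% dZ
      if (t >= 2) dH[[t - 1]] <- dH[[t - 1]] + dZ %*% t(params$Wh1)
      if (t >= 3) dH[[t - 2]] <- dH[[t - 2]] + dZ %*% t(params$Wh2)
    }
    grads$Wx <- grads$Wx + 2 * l2 * params$Wx
    grads$Wh1 <- grads$Wh1 + 2 * l2 * params$Wh1
    grads$Wh2 <- grads$Wh2 + 2 * l2 * params$Wh2
    upd <- adam_step(params, grads, st, lr)
    params <- upd$params; st <- upd$state
  }
  list(params = params, levels = levels, hidden = hidden)
}

rnn_predict <- function(model, Xseq) {
  n <- dim(Xseq)[1]; Tn <- dim(Xseq)[2]
  p <- model$params
  h1 <- h2 <- matrix(0, n, model$hidden)
  for (t in seq_len(Tn)) {
    h <- tanh(Xseq[, t, ] %*% p$Wx + h1 %*% p$Wh1 + h2 %*% p$Wh2 +
              rep(p$bh, each = n))
    h2 <- h1; h1 <- h
  }
  Yhat <- h1 %*% p$Wo + rep(p$bo, each = n)
  model$levels[max.col(Yhat, ties.method = "first")]
}

# ---- CNN ----------------------------------------------------------------
# conv(same, stride 1) -> batchnorm -> leaky ReLU -> dropout, twice, then
# two fully connected layers with a softmax classification output.
# Implemented with im2col so the whole batch is one matrix product.

im2col <- function(A, kh, kw) {
  d <- dim(A); n <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  Ap <- array(0, c(n, H + 2 * ph, W + 2 * pw, C))
  Ap[, ph + seq_len(H), pw + seq_len(W), ] <- A
  P <- matrix(0, n * H * W, kh * kw * C)
  off <- 0
  for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    blk <- Ap[, di + seq_len(H) - 1, dj + seq_len(W) - 1, , drop = FALSE]
    P[, off + seq_len(C)] <- matrix(blk, n * H * W, C)
    off <- off + C
  }
  P
}

col2im <- function(dP, n, H, W, C, kh, kw) {
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  dAp <- array(0, c(n, H + 2 * ph, W + 2 * pw, C))
  off <- 0
  for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    blk <- array(dP[, off + seq_len(C)], c(n, H, W, C))
    dAp[, di + seq_len(H) - 1, dj + seq_len(W) - 1, ] <-
      dAp[, di + seq_len(H) - 1, dj + seq_len(W) - 1, , drop = FALSE] + blk
    off <- off + C
  }
  dAp[, ph + seq_len(H), pw + seq_len(W), , drop = FALSE]
}

# largest odd kernel extent that fits the requested size and the map
clamp_kernel <- function(requested, map_dim) {
  k <- min(requested, map_dim)
  if (k %% 2 == 0) k <- k - 1
  max(k, 1)
}

cnn_train <- function(Xmap, y, filters = 96, kernel = c(11, 11),
                      dropout = 0.25, fc_width = 32, epochs = 100,
                      batch = 64, lr = 1e-3, lr_drop_period = 125,
                      lr_drop_factor = 0.2, leaky = 0.01, seed = 1) {
  levels <- sort(unique(y))
  n <- dim(Xmap)[1]; H <- dim(Xmap)[2]; W <- dim(Xmap)[3]
  K <- length(levels)
  kh <- clamp_kernel(kernel[1], H); kw <- clamp_kernel(kernel[2], W)
  F1 <- filters
  flat <- H * W * F1
  params <- with_seed(seed, function() list(
    K1 = matrix(rnorm(kh * kw * 1 * F1, sd = sqrt(2 / (kh * kw))),
                kh * kw, F1),
    c1 = rep(0, F1), g1 = rep(1, F1), be1 = rep(0, F1),
    K2 = matrix(rnorm(kh * kw * F1 * F1, sd = sqrt(2 / (kh * kw * F1))),
                kh * kw * F1, F1),
    c2 = rep(0, F1), g2 = rep(1, F1), be2 = rep(0, F1),
    W3 = matrix(rnorm(flat * fc_width, sd = sqrt(2 / flat)), flat, fc_width),
    b3 = rep(0, fc_width),
    W4 = matrix(rnorm(fc_width * K, sd = sqrt(2 / fc_width)), fc_width, K),
    b4 = rep(0, K)))
  run <- list(m1 = rep(0, F1), v1 = rep(1, F1),
              m2 = rep(0, F1), v2 = rep(1, F1))
  st <- adam_init(params)
  Yall <- one_hot(y, levels)
  with_seed(seed + 1, function() {
    for (ep in seq_len(epochs)) {
      rate <- lr * lr_drop_factor^floor((ep - 1) / lr_drop_period)
      ord <- sample.int(n)
      for (b0 in seq(1, n, by = batch)) {
        idx <- ord[b0:min(b0 + batch - 1, n)]
        nb <- length(idx)
        A0 <- array(Xmap[idx, , , drop = FALSE], c(nb, H, W, 1))
        Y <- Yall[idx, , drop = FALSE]
        # block 1
        P1 <- im2col(A0, kh, kw)
        Z1 <- P1 %*% params$K1 + rep(params$c1, each = nb * H * W)
        mu1 <- colMeans(matrix(Z1, ncol = F1))
        va1 <- colMeans(matrix(Z1, ncol = F1)^2) - mu1^2
        run$m1 <<- 0.9 * run$m1 + 0.1 * mu1
        run$v1 <<- 0.9 * run$v1 + 0.1 * va1
        Zh1 <- sweep(sweep(Z1, 2, mu1), 2, sqrt(va1 + 1e-5), "/")
        B1 <- sweep(sweep(Zh1, 2, params$g1, "*"), 2, params$be1, "+")
        R1 <- ifelse(B1 > 0, B1, leaky * B1)
        M1 <- matrix(stats::rbinom(length(R1), 1, 1 - dropout) /
                       (1 - dropout), nrow(R1), ncol(R1))
        D1 <- R1 * M1
        A1 <- array(D1, c(nb, H, W, F1))
        # block 2
        P2 <- im2col(A1, kh, kw)
        Z2 <- P2 %*% params$K2 + rep(params$c2, each = nb * H * W)
        mu2 <- colMeans(matrix(Z2, ncol = F1))
        va2 <- colMeans(matrix(Z2, ncol = F1)^2) - mu2^2
        run$m2 <<- 0.9 * run$m2 + 0.1 * mu2
        run$v2 <<- 0.9 * run$v2 + 0.1 * va2
        Zh2 <- sweep(sweep(Z2, 2, mu2), 2, sqrt(va2 + 1e-5), "/")
        B2 <- sweep(sweep(Zh2, 2, params$g2, "*"), 2, params$be2, "+")
        R2 <- ifelse(B2 > 0, B2, leaky * B2)
        M2 <- matrix(stats::rbinom(length(R2), 1, 1 - dropout) /
                       (1 - dropout), nrow(R2), ncol(R2))
        D2 <- R2 * M2
        Xf <- matrix(array(D2, c(nb, H, W, F1)), nb, flat)
        # head
        A3 <- Xf %*% params$W3 + rep(params$b3, each = nb)
        R3 <- ifelse(A3 > 0, A3, leaky * A3)
        Z4 <- R3 %*% params$W4 + rep(params$b4, each = nb)
        Pr <- softmax_rows(Z4)
        # backward (cross-entropy)
        dZ4 <- (Pr - Y) / nb
        gW4 <- t(R3) %*% dZ4; gb4 <- colSums(dZ4)
        dR3 <- dZ4 %*% t(params$W4)
        dA3 <- dR3 * ifelse(A3 > 0, 1, leaky)
        gW3 <- t(Xf) %*% dA3; gb3 <- colSums(dA3)
        dXf <- dA3 %*% t(params$W3)
        dD2 <- matrix(array(dXf, c(nb, H, W, F1)), nb * H * W, F1)
        dR2 <- dD2 * M2
        dB2 <- dR2 * ifelse(B2 > 0, 1, leaky)
        bn2 <- bn_backward(dB2, Zh2, params$g2, va2)
        gg2 <- colSums(dB2 * Zh2); gbe2 <- colSums(dB2)
        gK2 <- t(P2) %*% bn2; gc2 <- colSums(bn2)
        dP2 <- bn2 %*% t(params$K2)
        dA1 <- col2im(dP2, nb, H, W, F1, kh, kw)
        dD1 <- matrix(dA1, nb * H * W, F1)
        dR1 <- dD1 * M1
        dB1 <- dR1 * ifelse(B1 > 0, 1, leaky)
        bn1 <- bn_backward(dB1, Zh1, params$g1, va1)
        gg1 <- colSums(dB1 * Zh1); gbe1 <- colSums(dB1)
        gK1 <- t(P1) %*% bn1; gc1 <- colSums(bn1)
        grads <- list(K1 = gK1, c1 = gc1, g1 = gg1, be1 = gbe1,
                      K2 = gK2, c2 = gc2, g2 = gg2, be2 = gbe2,
                      W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
        upd <- adam_step(params, grads, st, rate)
        params <<- upd$params; st <<- upd$state
      }
    }
  })
  list(params = params, run = run, levels = levels, H = H, W = W,
       kh = kh, kw = kw, filters = F1, leaky = leaky)
}

bn_backward <- function(dB, Zh, gamma, va) {
  m <- nrow(dB)
  dZh <- sweep(dB, 2, gamma, "*")
  term <- dZh - rep(colMeans(dZh), each = m) -
    Zh * rep(colMeans(dZh * Zh), each = m)
  sweep(term, 2, sqrt(va + 1e-5), "/")
}

cnn_predict <- function(model, Xmap) {
  n <- dim(Xmap)[1]; H <- model$H; W <- model$W; F1 <- model$filters
  p <- model$params; leaky <- model$leaky
  A0 <- array(Xmap, c(n, H, W, 1))
  P1 <- im2col(A0, model$kh, model$kw)
  Z1 <- P1 %*% p$K1 + rep(p$c1, each = n * H * W)
  Zh1 <- sweep(sweep(Z1, 2, model$run$m1), 2, sqrt(model$run$v1 + 1e-5), "/")
  B1 <- sweep(sweep(Zh1, 2, p$g1, "*"), 2, p$be1, "+")
  A1 <- array(ifelse(B1 > 0, B1, leaky * B1), c(n, H, W, F1))
  P2 <- im2col(A1, model$kh, model$kw)
  Z2 <- P2 %*% p$K2 + rep(p$c2, each = n * H * W)
  Zh2 <- sweep(sweep(Z2, 2, model$run$m2), 2, sqrt(model$run$v2 + 1e-5), "/")
  B2 <- sweep(sweep(Zh2, 2, p$g2, "*"), 2, p$be2, "+")
  Xf <- matrix(array(ifelse(B2 > 0, B2, leaky * B2), c(n, H, W, F1)),
               n, H * W * F1)
  A3 <- Xf %*% p$W3 + rep(p$b3, each = n)
  R3 <- ifelse(A3 > 0, A3, leaky * A3)
  Pr <- softmax_rows(R3 %*% p$W4 + rep(p$b4, each = n))
  model$levels[max.col(Pr, ties.method = "first")]
}
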