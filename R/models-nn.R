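# Small seeded neural-network engines trained with Adam on mean-squared
# error. Inputs arrive standardized; the response is standardized by the
# caller. Weights are plain matrices, so fits are deterministic given the
# RNG state set by fit_droplet_model().

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

relu <- function(x) x * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- multilayer perceptron -------------------------------------------------
# Two hidden rectified layers by default (64, 32), linear scalar output.
mlp_fit <- function(X, y, hidden = c(64, 32), epochs = 100, lr = 1e-3,
                    batch = 32) {
  n <- nrow(X)
  sizes <- c(ncol(X), hidden, 1L)
  L <- length(sizes) - 1L
  params <- list()
  for (l in seq_len(L)) {
    params[[paste0("W", l)]] <- matrix(
      stats::rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
      sizes[l], sizes[l + 1]
    )
    params[[paste0("b", l)]] <- numeric(sizes[l + 1])
  }
  st <- adam_new(params)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = batch)
    for (s in starts) {
      rows <- ord[s:min(s + batch - 1, n)]
      Xb <- X[rows, , drop = FALSE]
      yb <- y[rows]
      B <- length(rows)

      acts <- vector("list", L + 1)
      acts[[1]] <- Xb
      for (l in seq_len(L)) {
        z <- sweep(acts[[l]] %*% params[[paste0("W", l)]], 2,
                   params[[paste0("b", l)]], "+")
        acts[[l + 1]] <- if (l < L) relu(z) else z
      }
      delta <- 2 * (drop(acts[[L + 1]]) - yb) / B
      delta <- matrix(delta, B, 1)
      grads <- list()
      for (l in rev(seq_len(L))) {
        grads[[paste0("W", l)]] <- crossprod(acts[[l]], delta)
        grads[[paste0("b", l)]] <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(params[[paste0("W", l)]])) * (acts[[l]] > 0)
        }
      }
      upd <- adam_step(params, grads, st, lr)
      params <- upd$params
      st <- upd$state
    }
  }
  list(params = params, sizes = sizes)
}

mlp_predict <- function(fit, X) {
  L <- length(fit$sizes) - 1L
  a <- X
  for (l in seq_len(L)) {
    z <- sweep(a %*% fit$params[[paste0("W", l)]], 2,
               fit$params[[paste0("b", l)]], "+")
    a <- if (l < L) relu(z) else z
  }
  drop(a)
}

# ---- single-step LSTM ------------------------------------------------------
# Each record is a length-1 sequence of the five-feature vector: one LSTM
# cell step from zero initial state, then a linear scalar head. The
# recurrent weights participate in the forward pass (multiplying the zero
# initial hidden state) so the cell is a faithful one-step unroll; their
# gradients are identically zero with sequence length 1.
lstm_fit <- function(X, y, units = 32, epochs = 100, lr = 1e-3, batch = 32) {
  n <- nrow(X); p <- ncol(X)
  gates <- c("i", "f", "o", "g")
  params <- list()
  for (gt in gates) {
    params[[paste0("W", gt)]] <- matrix(stats::rnorm(p * units, sd = sqrt(1 / p)),
                                        p, units)
    params[[paste0("U", gt)]] <- matrix(stats::rnorm(units * units,
                                                     sd = sqrt(1 / units)),
                                        units, units)
    params[[paste0("b", gt)]] <- numeric(units)
  }
  params$bf <- params$bf + 1 # customary forget-gate bias
  params$Wy <- matrix(stats::rnorm(units, sd = sqrt(1 / units)), units, 1)
  params$by <- 0

  st <- adam_new(params)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = batch)
    for (s in starts) {
      rows <- ord[s:min(s + batch - 1, n)]
      Xb <- X[rows, , drop = FALSE]
      yb <- y[rows]
      B <- length(rows)
      h0 <- matrix(0, B, units)

      gi <- sigmoid(sweep(Xb %*% params$Wi + h0 %*% params$Ui, 2, params$bi, "+"))
      gf <- sigmoid(sweep(Xb %*% params$Wf + h0 %*% params$Uf, 2, params$bf, "+"))
      go <- sigmoid(sweep(Xb %*% params$Wo + h0 %*% params$Uo, 2, params$bo, "+"))
      gg <- tanh(sweep(Xb %*% params$Wg + h0 %*% params$Ug, 2, params$bg, "+"))
      cc <- gi * gg                 # f * c0 vanishes (c0 = 0)
      hc <- tanh(cc)
      h <- go * hc
      yhat <- drop(h %*% params$Wy) + params$by

      dy <- matrix(2 * (yhat - yb) / B, B, 1)
      dh <- dy %*% t(params$Wy)
      do_ <- dh * hc
      dc <- dh * go * (1 - hc^2)
      di <- dc * gg
      dg <- dc * gi
      dZi <- di * gi * (1 - gi)
      dZo <- do_ * go * (1 - go)
      dZg <- dg * (1 - gg^2)
      zero <- matrix(0, p, units)
      zu <- matrix(0, units, units)
      grads <- list(
        Wi = crossprod(Xb, dZi), Ui = zu, bi = colSums(dZi),
        Wf = zero, Uf = zu, bf = numeric(units),
        Wo = crossprod(Xb, dZo), Uo = zu, bo = colSums(dZo),
        Wg = crossprod(Xb, dZg), Ug = zu, bg = colSums(dZg),
        Wy = crossprod(h, dy), by = sum(dy)
      )
      upd <- adam_step(params, grads, st, lr)
      params <- upd$params
      st <- upd$state
    }
  }
  list(params = params, units = units)
}

lstm_predict <- function(fit, X) {
  p <- fit$params
  B <- nrow(X)
  h0 <- matrix(0, B, fit$units)
  gi <- sigmoid(sweep(X %*% p$Wi + h0 %*% p$Ui, 2, p$bi, "+"))
  go <- sigmoid(sweep(X %*% p$Wo + h0 %*% p$Uo, 2, p$bo, "+"))
  gg <- tanh(sweep(X %*% p$Wg + h0 %*% p$Ug, 2, p$bg, "+"))
  h <- go * tanh(gi * gg)
  drop(h %*% p$Wy) + p$by
}
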