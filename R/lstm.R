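# Bidirectional LSTM regression engine.
#
# Minimal, self-contained implementation of stacked bidirectional LSTM layers
# with per-position linear readout, masked mean-squared-error loss, full
# backpropagation through time and Adam updates. Batches are dense arrays
# (batch x time x features); padded positions are carried through the
# recurrence unchanged (Keras-style masking) and excluded from the loss.
# Gate order throughout: input, forget, cell candidate, output.

sigmoid <- function(x) 1 / (1 + exp(-x))

act_fun <- function(kind) {
  switch(kind,
         relu = list(f = function(x) pmax(x, 0), df = function(x, y) (x > 0) * 1),
         tanh = list(f = tanh, df = function(x, y) 1 - y^2),
         stop("unknown activation: ", kind))
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

lstm_cell_init <- function(input_dim, hidden) {
  b <- numeric(4 * hidden)
  b[(hidden + 1):(2 * hidden)] <- 1  # forget-gate bias: remember by default
  list(Wx = glorot(input_dim, 4 * hidden),
       Wh = glorot(hidden, 4 * hidden),
       b = b)
}

bilstm_init <- function(input_dim, widths) {
  layers <- list()
  d <- input_dim
  for (h in widths) {
    layers[[length(layers) + 1]] <- list(fwd = lstm_cell_init(d, h),
                                         bwd = lstm_cell_init(d, h))
    d <- 2 * h
  }
  layers
}

# one LSTM direction over a padded batch
# X: (B, L, D); M: (B, L) in {0,1}; returns H (B, L, Hdim) plus caches
lstm_dir_forward <- function(X, M, par, act, reverse = FALSE) {
  B <- dim(X)[1]; L <- dim(X)[2]
  H <- ncol(par$Wh)
  Hdim <- H / 4L
  order_t <- if (reverse) L:1 else 1:L
  Hout <- array(0, c(B, L, Hdim))
  cache <- list(I = array(0, c(B, L, Hdim)), Fg = array(0, c(B, L, Hdim)),
                G = array(0, c(B, L, Hdim)), O = array(0, c(B, L, Hdim)),
                Zg = array(0, c(B, L, Hdim)), Cpre = array(0, c(B, L, Hdim)),
                Hprev = array(0, c(B, L, Hdim)), Cprev = array(0, c(B, L, Hdim)))
  h <- matrix(0, B, Hdim)
  cc <- matrix(0, B, Hdim)
  bmat <- matrix(par$b, B, 4 * Hdim, byrow = TRUE)
  g1 <- 1:Hdim; g2 <- Hdim + g1; g3 <- 2 * Hdim + g1; g4 <- 3 * Hdim + g1
  for (t in order_t) {
    xt <- X[, t, , drop = FALSE]
    dim(xt) <- c(B, dim(X)[3])
    z <- xt %*% par$Wx + h %*% par$Wh + bmat
    gi <- sigmoid(z[, g1, drop = FALSE])
    gf <- sigmoid(z[, g2, drop = FALSE])
    zg <- z[, g3, drop = FALSE]
    gg <- act$f(zg)
    go <- sigmoid(z[, g4, drop = FALSE])
    cpre <- gf * cc + gi * gg
    hnew <- go * act$f(cpre)
    m <- M[, t]
    cache$I[, t, ] <- gi; cache$Fg[, t, ] <- gf; cache$G[, t, ] <- gg
    cache$O[, t, ] <- go; cache$Zg[, t, ] <- zg; cache$Cpre[, t, ] <- cpre
    cache$Hprev[, t, ] <- h; cache$Cprev[, t, ] <- cc
    h <- m * hnew + (1 - m) * h
    cc <- m * cpre + (1 - m) * cc
    Hout[, t, ] <- h
  }
  list(H = Hout, cache = cache)
}

# backprop for one direction; dH is the gradient w.r.t. this direction's
# post-mask outputs. Returns parameter grads and dX.
lstm_dir_backward <- function(X, M, par, act, fwd, dH, reverse = FALSE) {
  B <- dim(X)[1]; L <- dim(X)[2]; D <- dim(X)[3]
  Hdim <- ncol(par$Wh) / 4L
  order_t <- if (reverse) L:1 else 1:L
  ca <- fwd$cache
  dWx <- par$Wx * 0; dWh <- par$Wh * 0; db <- par$b * 0
  dX <- array(0, c(B, L, D))
  dh_rec <- matrix(0, B, Hdim)
  dc_rec <- matrix(0, B, Hdim)
  for (t in rev(order_t)) {
    m <- M[, t]
    dh_total <- matrix(dH[, t, ], B, Hdim) + dh_rec
    dh_new <- dh_total * m
    dh_carry <- dh_total * (1 - m)
    dc_new <- dc_rec * m
    dc_carry <- dc_rec * (1 - m)
    gi <- matrix(ca$I[, t, ], B, Hdim); gf <- matrix(ca$Fg[, t, ], B, Hdim)
    gg <- matrix(ca$G[, t, ], B, Hdim); go <- matrix(ca$O[, t, ], B, Hdim)
    zg <- matrix(ca$Zg[, t, ], B, Hdim)
    cpre <- matrix(ca$Cpre[, t, ], B, Hdim)
    hprev <- matrix(ca$Hprev[, t, ], B, Hdim)
    cprev <- matrix(ca$Cprev[, t, ], B, Hdim)
    hc <- act$f(cpre)
    do_ <- dh_new * hc
    dc <- dc_new + dh_new * go * act$df(cpre, hc)
    di <- dc * gg
    df <- dc * cprev
    dg <- dc * gi
    dzi <- di * gi * (1 - gi)
    dzf <- df * gf * (1 - gf)
    dzg <- dg * act$df(zg, gg)
    dzo <- do_ * go * (1 - go)
    dz <- cbind(dzi, dzf, dzg, dzo)
    xt <- matrix(X[, t, ], B, D)
    dWx <- dWx + crossprod(xt, dz)
    dWh <- dWh + crossprod(hprev, dz)
    db <- db + colSums(dz)
    dX[, t, ] <- dX[, t, ] + dz %*% t(par$Wx)
    dh_rec <- dz %*% t(par$Wh) + dh_carry
    dc_rec <- dc * gf + dc_carry
  }
  list(Wx = dWx, Wh = dWh, b = db, dX = dX)
}

bilstm_forward <- function(X, M, layers, act) {
  acts <- list()
  inp <- X
  for (li in seq_along(layers)) {
    f <- lstm_dir_forward(inp, M, layers[[li]]$fwd, act, reverse = FALSE)
    b <- lstm_dir_forward(inp, M, layers[[li]]$bwd, act, reverse = TRUE)
    B <- dim(inp)[1]; L <- dim(inp)[2]
    Hdim <- dim(f$H)[3]
    out <- array(0, c(B, L, 2 * Hdim))
    out[, , 1:Hdim] <- f$H
    out[, , Hdim + 1:Hdim] <- b$H
    acts[[li]] <- list(input = inp, fwd = f, bwd = b)
    inp <- out
  }
  list(output = inp, acts = acts)
}

bilstm_backward <- function(M, layers, act, acts, dOut) {
  grads <- vector("list", length(layers))
  d <- dOut
  for (li in rev(seq_along(layers))) {
    a <- acts[[li]]
    Hdim <- dim(a$fwd$H)[3]
    B <- dim(d)[1]; L <- dim(d)[2]
    dF <- array(d[, , 1:Hdim], c(B, L, Hdim))
    dB <- array(d[, , Hdim + 1:Hdim], c(B, L, Hdim))
    gf <- lstm_dir_backward(a$input, M, layers[[li]]$fwd, act, a$fwd, dF,
                            reverse = FALSE)
    gb <- lstm_dir_backward(a$input, M, layers[[li]]$bwd, act, a$bwd, dB,
                            reverse = TRUE)
    grads[[li]] <- list(fwd = gf[c("Wx", "Wh", "b")], bwd = gb[c("Wx", "Wh", "b")])
    d <- gf$dX + gb$dX
  }
  grads
}

# full network: stacked biLSTM + per-position linear head
net_forward <- function(X, M, net) {
  act <- act_fun(net$activation)
  bi <- bilstm_forward(X, M, net$layers, act)
  B <- dim(X)[1]; L <- dim(X)[2]
  Hlast <- dim(bi$output)[3]
  flat <- matrix(bi$output, B * L, Hlast)
  yhat <- matrix(flat %*% net$Wout + net$bout, B, L)
  list(yhat = yhat, bi = bi)
}

# masked MSE loss and full gradient; M masks the recurrence (sequence
# validity), W masks the loss (valid AND observed target)
net_loss_grad <- function(X, M, Y, net, W = M) {
  act <- act_fun(net$activation)
  fw <- net_forward(X, M, net)
  n_obs <- sum(W)
  if (n_obs == 0) stop("all positions are masked out of the loss")
  resid <- (fw$yhat - Y) * W
  loss <- sum(resid^2) / n_obs
  dyhat <- 2 * resid / n_obs
  B <- dim(X)[1]; L <- dim(X)[2]
  Hlast <- dim(fw$bi$output)[3]
  flat <- matrix(fw$bi$output, B * L, Hlast)
  dflat <- matrix(as.vector(dyhat), ncol = 1)
  dWout <- crossprod(flat, dflat)
  dbout <- sum(dflat)
  dOut <- array(dflat %*% t(net$Wout), c(B, L, Hlast))
  lgrads <- bilstm_backward(M, net$layers, act, fw$bi$acts, dOut)
  list(loss = loss,
       grads = list(layers = lgrads, Wout = dWout, bout = dbout))
}

# ---- generic nested-list parameter algebra (for Adam and clipping) ----

map2_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- map2_params(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

map_params <- function(a, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- map_params(a[[i]], f)
    out
  } else f(a)
}

sum_params <- function(a, f) {
  if (is.list(a)) sum(vapply(a, sum_params, numeric(1), f = f)) else f(a)
}

clip_global_norm <- function(grads, max_norm) {
  total <- sqrt(sum_params(grads, function(g) sum(g^2)))
  if (is.finite(total) && total > max_norm) {
    grads <- map_params(grads, function(g) g * (max_norm / total))
  }
  grads
}

adam_init <- function(params) {
  list(m = map_params(params, function(p) p * 0),
       v = map_params(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map2_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- map2_params(state$m, state$v, function(m, v) {
    lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
  params <- map2_params(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

net_params <- function(net) list(layers = net$layers, Wout = net$Wout, bout = net$bout)

net_set_params <- function(net, params) {
  net$layers <- params$layers
  net$Wout <- params$Wout
  net$bout <- params$bout
  net
}
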