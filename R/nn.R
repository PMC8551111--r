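# Neural sequence predictors with a bivariate-Gaussian head.
#
# All network kinds share a three-weight-layer skeleton 6 -> 64 -> 128 -> 5
# (deep kinds insert a second 128 -> 128 hidden layer) and differ in the
# middle layer(s): identity (LN), ReLU (NN/DNN), tanh recurrence
# (RNN/DRNN), or an LSTM cell (LSTM/DLSTM). The 5-vector emitted by the
# head parameterizes a bivariate Gaussian over the target's next-step
# displacement: mu = (h1, h2), sigma = exp(h3, h4), rho = tanh(h5), which
# guarantees sigma > 0 and |rho| < 1 for any real h.
#
# Forward and backward passes are implemented directly on base-R matrices.
# Sequences are stored time-major: a (T*B) x d matrix whose rows
# (t-1)*B + 1 ... t*B hold the batch at step t, so dense layers are a
# single matrix product and recurrent layers slice per step.

MODEL_KINDS <- c("L", "C", "LN", "NN", "RNN", "LSTM", "DNN", "DRNN", "DLSTM")
NETWORK_KINDS <- setdiff(MODEL_KINDS, c("L", "C"))
RECURRENT_KINDS <- c("RNN", "LSTM", "DRNN", "DLSTM")

is_recurrent <- function(kind) kind %in% RECURRENT_KINDS

#' Model specification
#'
#' @param kind one of `"L"`, `"C"` (parameter-free extrapolators) or
#'   `"LN"`, `"NN"`, `"RNN"`, `"LSTM"`, `"DNN"`, `"DRNN"`, `"DLSTM"`
#'   (trainable networks).
#' @param epochs training epochs (default 100; the checkpoint with the
#'   lowest training NLL is retained).
#' @param learning_rate Adam learning rate (default 3e-4).
#' @param batch_size 16: time-steps per batch for feedforward kinds, trials
#'   per batch for recurrent kinds.
#' @param seed integer seed controlling initialization and shuffling.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(kind, epochs = 100L, learning_rate = 3e-4,
                       batch_size = 16L, seed = 1L) {
  kind <- match.arg(kind, MODEL_KINDS)
  structure(list(kind = kind, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "model_spec")
}

build_arch <- function(kind) {
  dense <- function(n_in, n_out, act) list(type = "dense", n_in = n_in,
                                           n_out = n_out, act = act)
  rnn  <- function(n_in, n_out) list(type = "rnn", n_in = n_in, n_out = n_out)
  lstm <- function(n_in, n_out) list(type = "lstm", n_in = n_in, n_out = n_out)
  head <- dense(128, 5, "identity")
  switch(kind,
    LN    = list(dense(6, 64, "identity"), dense(64, 128, "identity"), head),
    NN    = list(dense(6, 64, "relu"), dense(64, 128, "relu"), head),
    RNN   = list(dense(6, 64, "identity"), rnn(64, 128), head),
    LSTM  = list(dense(6, 64, "identity"), lstm(64, 128), head),
    DNN   = list(dense(6, 64, "relu"), dense(64, 128, "relu"),
                 dense(128, 128, "relu"), head),
    DRNN  = list(dense(6, 64, "identity"), rnn(64, 128), rnn(128, 128), head),
    DLSTM = list(dense(6, 64, "identity"), lstm(64, 128), lstm(128, 128), head),
    stop("kind '", kind, "' has no network architecture", call. = FALSE))
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_params <- function(arch) {
  lapply(arch, function(l) {
    switch(l$type,
      dense = list(W = glorot(l$n_in, l$n_out), b = numeric(l$n_out)),
      rnn   = list(Wx = glorot(l$n_in, l$n_out), Wh = glorot(l$n_out, l$n_out),
                   b = numeric(l$n_out)),
      lstm  = list(Wx = glorot(l$n_in, 4 * l$n_out),
                   Wh = glorot(l$n_out, 4 * l$n_out),
                   b = numeric(4 * l$n_out)))
  })
}

#' Number of trainable parameters of a network kind
#' @param kind a network kind name or a `cp_model`.
#' @return integer parameter count.
#' @export
n_params <- function(kind) {
  arch <- if (inherits(kind, "cp_model")) kind$arch else build_arch(kind)
  sum(vapply(init_params(arch), function(p)
    sum(vapply(p, length, integer(1))), numeric(1)))
}

zero_state <- function(arch, B) {
  lapply(arch, function(l) {
    switch(l$type,
      dense = NULL,
      rnn = list(h = matrix(0, B, l$n_out)),
      lstm = list(h = matrix(0, B, l$n_out), c = matrix(0, B, l$n_out)))
  })
}

add_bias <- function(M, b) M + rep(b, each = nrow(M))
sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass over a time-major sequence batch.
# X: (T*B) x d_in, state: per-layer list or NULL (zeros).
# Returns out (T*B) x 5, caches (if keep_cache), and the final state.
seq_forward <- function(arch, params, X, B, T_len, state = NULL,
                        keep_cache = FALSE) {
  if (is.null(state)) state <- zero_state(arch, B)
  caches <- vector("list", length(arch))
  cur <- X
  for (li in seq_along(arch)) {
    l <- arch[[li]]; p <- params[[li]]
    if (l$type == "dense") {
      pre <- add_bias(cur %*% p$W, p$b)
      out <- if (l$act == "relu") pmax(pre, 0) else pre
      if (keep_cache) caches[[li]] <- list(X = cur, pre = if (l$act == "relu") pre else NULL)
      cur <- out
    } else if (l$type == "rnn") {
      n <- l$n_out
      Xw <- add_bias(cur %*% p$Wx, p$b)
      H <- matrix(0, nrow(cur), n)
      h <- state[[li]]$h
      h0 <- h
      for (t in seq_len(T_len)) {
        idx <- ((t - 1L) * B + 1L):(t * B)
        h <- tanh(Xw[idx, , drop = FALSE] + h %*% p$Wh)
        H[idx, ] <- h
      }
      if (keep_cache) caches[[li]] <- list(X = cur, H = H, h0 = h0)
      state[[li]]$h <- h
      cur <- H
    } else { # lstm
      n <- l$n_out
      Ax <- add_bias(cur %*% p$Wx, p$b)
      N <- nrow(cur)
      I <- matrix(0, N, n); F_ <- I; O <- I; G <- I; C <- I; TC <- I
      H <- matrix(0, N, n)
      h <- state[[li]]$h; cc <- state[[li]]$c
      h0 <- h; c0 <- cc
      for (t in seq_len(T_len)) {
        idx <- ((t - 1L) * B + 1L):(t * B)
        A <- Ax[idx, , drop = FALSE] + h %*% p$Wh
        i_ <- sigmoid(A[, 1:n, drop = FALSE])
        f_ <- sigmoid(A[, n + 1:n, drop = FALSE])
        o_ <- sigmoid(A[, 2 * n + 1:n, drop = FALSE])
        g_ <- tanh(A[, 3 * n + 1:n, drop = FALSE])
        cc <- f_ * cc + i_ * g_
        tc <- tanh(cc)
        h <- o_ * tc
        I[idx, ] <- i_; F_[idx, ] <- f_; O[idx, ] <- o_; G[idx, ] <- g_
        C[idx, ] <- cc; TC[idx, ] <- tc; H[idx, ] <- h
      }
      if (keep_cache)
        caches[[li]] <- list(X = cur, I = I, F = F_, O = O, G = G, C = C,
                             TC = TC, H = H, h0 = h0, c0 = c0)
      state[[li]]$h <- h; state[[li]]$c <- cc
      cur <- H
    }
  }
  list(out = cur, caches = caches, state = state)
}

# Backward pass matching seq_forward. dOut: gradient w.r.t. the head output
# (already scaled, zero rows at padded steps). Returns per-layer gradients.
seq_backward <- function(arch, params, caches, dOut, B, T_len) {
  grads <- vector("list", length(arch))
  d <- dOut
  for (li in rev(seq_along(arch))) {
    l <- arch[[li]]; p <- params[[li]]; cc <- caches[[li]]
    if (l$type == "dense") {
      dpre <- if (l$act == "relu") d * (cc$pre > 0) else d
      grads[[li]] <- list(W = crossprod(cc$X, dpre), b = colSums(dpre))
      d <- tcrossprod(dpre, p$W)
    } else if (l$type == "rnn") {
      n <- l$n_out
      dPre <- matrix(0, nrow(d), n)
      dWh <- matrix(0, n, n)
      dh_carry <- matrix(0, B, n)
      for (t in rev(seq_len(T_len))) {
        idx <- ((t - 1L) * B + 1L):(t * B)
        h_t <- cc$H[idx, , drop = FALSE]
        h_prev <- if (t == 1L) cc$h0 else cc$H[idx - B, , drop = FALSE]
        dh <- d[idx, , drop = FALSE] + dh_carry
        dpre <- dh * (1 - h_t^2)
        dPre[idx, ] <- dpre
        dWh <- dWh + crossprod(h_prev, dpre)
        dh_carry <- tcrossprod(dpre, p$Wh)
      }
      grads[[li]] <- list(Wx = crossprod(cc$X, dPre), Wh = dWh,
                          b = colSums(dPre))
      d <- tcrossprod(dPre, p$Wx)
    } else { # lstm
      n <- l$n_out
      dA_big <- matrix(0, nrow(d), 4 * n)
      dWh <- matrix(0, n, 4 * n)
      dh_carry <- matrix(0, B, n); dc_carry <- matrix(0, B, n)
      for (t in rev(seq_len(T_len))) {
        idx <- ((t - 1L) * B + 1L):(t * B)
        i_ <- cc$I[idx, , drop = FALSE]; f_ <- cc$F[idx, , drop = FALSE]
        o_ <- cc$O[idx, , drop = FALSE]; g_ <- cc$G[idx, , drop = FALSE]
        tc <- cc$TC[idx, , drop = FALSE]
        c_prev <- if (t == 1L) cc$c0 else cc$C[idx - B, , drop = FALSE]
        h_prev <- if (t == 1L) cc$h0 else cc$H[idx - B, , drop = FALSE]
        dh <- d[idx, , drop = FALSE] + dh_carry
        do_ <- dh * tc
        dc <- dh * o_ * (1 - tc^2) + dc_carry
        di <- dc * g_; dg <- dc * i_; df <- dc * c_prev
        dc_carry <- dc * f_
        dA <- cbind(di * i_ * (1 - i_), df * f_ * (1 - f_),
                    do_ * o_ * (1 - o_), dg * (1 - g_^2))
        dA_big[idx, ] <- dA
        dWh <- dWh + crossprod(h_prev, dA)
        dh_carry <- tcrossprod(dA, p$Wh)
      }
      grads[[li]] <- list(Wx = crossprod(cc$X, dA_big), Wh = dWh,
                          b = colSums(dA_big))
      d <- tcrossprod(dA_big, p$Wx)
    }
  }
  grads
}

#' Map a raw 5-vector head output to bivariate-Gaussian parameters
#'
#' `mu = (h1, h2)`, `sigma = exp(h3, h4)`, `rho = tanh(h5)`: valid
#' (`sigma > 0`, `|rho| < 1`) for any real input.
#'
#' @param h numeric 5-vector, or an n x 5 matrix treated row-wise.
#' @return list with `mu`, `sigma` (each 2-vector / n x 2 matrix) and `rho`.
#' @export
gauss_head <- function(h) {
  if (is.null(dim(h))) h <- matrix(h, 1)
  stopifnot(ncol(h) == 5)
  out <- list(mu = h[, 1:2, drop = FALSE],
              sigma = exp(h[, 3:4, drop = FALSE]),
              rho = tanh(h[, 5]))
  if (nrow(h) == 1) {
    out$mu <- drop(out$mu); out$sigma <- drop(out$sigma)
  }
  out
}

#' Bivariate-Gaussian negative log-likelihood
#'
#' `-log N(y | mu, sigma, rho)`, the per-step training loss of the network
#' predictors.
#'
#' @param pred a prediction as returned by [gauss_head()] (fields `mu`,
#'   `sigma`, `rho`).
#' @param y observed 2-D displacement.
#' @return the negative log density (scalar).
#' @export
#' @examples
#' nll_loss(list(mu = c(0, 0), sigma = c(1, 1), rho = 0), c(0, 0)) # log(2*pi)
nll_loss <- function(pred, y) {
  s <- pred$sigma; r <- pred$rho; mu <- pred$mu
  stopifnot(all(s > 0), abs(r) < 1)
  h <- c(mu[1], mu[2], log(s[1]), log(s[2]), atanh(r))
  nll_h(matrix(h, 1), matrix(y, 1))$nll
}

# NLL and gradient w.r.t. the raw head output h (N x 5), vectorized.
nll_h <- function(H, Y) {
  mu1 <- H[, 1]; mu2 <- H[, 2]
  s1 <- exp(H[, 3]); s2 <- exp(H[, 4]); r <- tanh(H[, 5])
  u <- (Y[, 1] - mu1) / s1
  v <- (Y[, 2] - mu2) / s2
  cc <- 1 - r^2
  Q <- u^2 - 2 * r * u * v + v^2
  nll <- log(2 * pi) + H[, 3] + H[, 4] + 0.5 * log(cc) + Q / (2 * cc)
  grad <- cbind(-(u - r * v) / (s1 * cc),
                -(v - r * u) / (s2 * cc),
                1 - u * (u - r * v) / cc,
                1 - v * (v - r * u) / cc,
                -r - u * v + r * Q / cc)
  list(nll = nll, grad = grad)
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  zeros <- function(x) if (is.list(x)) lapply(x, zeros) else x * 0
  list(m = zeros(params), v = zeros(params), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  out <- upd(params, grads, st$m, st$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = st$t))
}
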