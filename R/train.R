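# Input construction and training loop.

#' Build model input/target pairs from a trial set
#'
#' At the 20 Hz analysis rate, the model input at step t is the 6-vector
#' `x_t = (v_a, v_d, r)`: attacker velocity, defender (pursuer) velocity
#' (cm per 50 ms step) and the range vector from defender to attacker (cm).
#' The target `y_t` is the attacker displacement from t to t+1. Pairs never
#' cross trial boundaries. A trial of n samples yields n - 2 pairs
#' (velocity needs a predecessor, the target a successor).
#'
#' @param ts a `trialset`; raw 120 Hz trials are decimated to `rate`.
#' @param rate analysis rate in Hz (default 20).
#' @return list with one element per usable trial: `trial_id`,
#'   `defender_participant`, `condition`, `X` (m x 6), `Y` (m x 2), and the
#'   decimated positions `pa`, `pd` (n x 2). Trials too short to yield a
#'   pair are skipped with a message.
#' @export
build_inputs <- function(ts, rate = 20) {
  out <- list(); skipped <- 0L
  for (tr in ts$trials) {
    tr2 <- if (tr$sample_rate == rate) tr else downsample(tr, rate)
    n <- nrow(tr2$attacker_xy)
    if (n < 3) { skipped <- skipped + 1L; next }
    pa <- tr2$attacker_xy; pd <- tr2$defender_xy
    da <- diff(pa); dd <- diff(pd)
    idx <- 2:(n - 1)                      # steps with velocity and successor
    X <- cbind(da[idx - 1, 1], da[idx - 1, 2],   # v_a at t
               dd[idx - 1, 1], dd[idx - 1, 2],   # v_d at t
               pa[idx, 1] - pd[idx, 1],          # r_x
               pa[idx, 2] - pd[idx, 2])          # r_y
    Y <- da[idx, , drop = FALSE]                 # displacement t -> t+1
    out[[length(out) + 1L]] <- list(
      trial_id = tr2$trial_id,
      defender_participant = tr2$defender_participant,
      condition = tr2$condition, X = X, Y = Y, pa = pa, pd = pd)
  }
  if (skipped > 0)
    message(skipped, " trial(s) too short at ", rate, " Hz were skipped")
  out
}

#' Construct an untrained model object
#'
#' For `"L"` / `"C"` this is the complete (parameter-free) model; for
#' network kinds the parameters are freshly initialized from `spec$seed`
#' and the model can be used for forward passes or passed to training.
#'
#' @param spec a [model_spec()] or a kind name.
#' @return object of class `cp_model`.
#' @export
make_model <- function(spec) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "model_spec"))
  m <- list(kind = spec$kind, spec = spec, arch = NULL, params = NULL,
            history = numeric(0), fold = NA_character_)
  if (spec$kind %in% NETWORK_KINDS) {
    set.seed(spec$seed)
    m$arch <- build_arch(spec$kind)
    m$params <- init_params(m$arch)
  }
  structure(m, class = "cp_model")
}

#' @export
print.cp_model <- function(x, ...) {
  cat(sprintf("<%s model%s%s>\n", x$kind,
              if (length(x$history)) sprintf(", trained %d epochs (best NLL %.4f)",
                                             length(x$history), min(x$history)) else "",
              if (!is.na(x$fold)) paste0(", fold ", x$fold) else ""))
  invisible(x)
}

#' Single forward step of a model
#'
#' @param model a `cp_model` of a network kind.
#' @param x 6-vector state input.
#' @param state hidden state from the previous call (recurrent kinds;
#'   `NULL` = zeros). Ignored for feedforward kinds.
#' @return list with `pred` (a [gauss_head()] prediction) and `state`.
#' @export
model_forward <- function(model, x, state = NULL) {
  stopifnot(inherits(model, "cp_model"), model$kind %in% NETWORK_KINDS)
  fw <- seq_forward(model$arch, model$params, matrix(x, 1), B = 1L,
                    T_len = 1L, state = state)
  list(pred = gauss_head(fw$out), state = fw$state)
}

#' Predict a whole trial sequence (teacher forcing)
#'
#' Runs the model over a T x 6 input matrix, threading the hidden state
#' from zeros at the trial start (recurrent kinds).
#'
#' @param model a network `cp_model`.
#' @param X T x 6 input matrix (one trial, from [build_inputs()]).
#' @return list with `mu` (T x 2), `sigma` (T x 2), `rho` (length T).
#' @export
predict_sequence <- function(model, X) {
  stopifnot(inherits(model, "cp_model"), model$kind %in% NETWORK_KINDS)
  fw <- seq_forward(model$arch, model$params, X, B = 1L, T_len = nrow(X))
  list(mu = fw$out[, 1:2, drop = FALSE],
       sigma = exp(fw$out[, 3:4, drop = FALSE]),
       rho = tanh(fw$out[, 5]))
}

#' Train a network predictor
#'
#' Minimizes the bivariate-Gaussian negative log-likelihood of next-step
#' attacker displacements with Adam (learning rate 3e-4, batch size 16).
#' Feedforward kinds batch over shuffled time-steps; recurrent kinds batch
#' over shuffled trials with full-sequence unrolling, zero initial state
#' per trial, and right-padding masked out of the loss. The per-epoch mean
#' NLL is recorded and the parameters from the best epoch are retained.
#' Fully reproducible given `spec$seed`.
#'
#' @param spec a [model_spec()] with a network `kind`.
#' @param ts a `trialset` (or a prebuilt [build_inputs()] list).
#' @param rate analysis rate (Hz).
#' @param verbose print per-epoch NLL.
#' @return a trained `cp_model` with `history` (per-epoch mean NLL).
#' @export
train_model <- function(spec, ts, rate = 20, verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$kind %in% NETWORK_KINDS)
    stop("kind '", spec$kind, "' has no trainable parameters", call. = FALSE)
  inputs <- if (inherits(ts, "trialset")) build_inputs(ts, rate) else ts
  if (!length(inputs)) stop("empty training set", call. = FALSE)

  set.seed(spec$seed)
  arch <- build_arch(spec$kind)
  params <- init_params(arch)
  opt <- adam_init(params)
  lr <- spec$learning_rate; bs <- spec$batch_size
  recurrent <- is_recurrent(spec$kind)
  history <- numeric(spec$epochs)
  best <- list(nll = Inf, params = params, epoch = 0L)

  if (!recurrent) {
    X <- do.call(rbind, lapply(inputs, `[[`, "X"))
    Y <- do.call(rbind, lapply(inputs, `[[`, "Y"))
    N <- nrow(X)
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(N)
      tot <- 0
      for (b0 in seq(1L, N, by = bs)) {
        sel <- ord[b0:min(b0 + bs - 1L, N)]
        Xb <- X[sel, , drop = FALSE]; Yb <- Y[sel, , drop = FALSE]
        fw <- seq_forward(arch, params, Xb, B = length(sel), T_len = 1L,
                          keep_cache = TRUE)
        lg <- nll_h(fw$out, Yb)
        tot <- tot + sum(lg$nll)
        grads <- seq_backward(arch, params, fw$caches,
                              lg$grad / length(sel), B = length(sel), T_len = 1L)
        st <- adam_step(params, grads, opt, lr)
        params <- st$params; opt <- st$state
      }
      history[ep] <- tot / N
      if (history[ep] < best$nll)
        best <- list(nll = history[ep], params = params, epoch = ep)
      if (verbose) message(sprintf("epoch %d: NLL %.5f", ep, history[ep]))
    }
  } else {
    n_tr <- length(inputs)
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n_tr)
      tot <- 0; n_steps <- 0L
      for (b0 in seq(1L, n_tr, by = bs)) {
        sel <- ord[b0:min(b0 + bs - 1L, n_tr)]
        B <- length(sel)
        lens <- vapply(inputs[sel], function(z) nrow(z$X), integer(1))
        T_len <- max(lens)
        Xb <- matrix(0, T_len * B, 6); Yb <- matrix(0, T_len * B, 2)
        mask <- logical(T_len * B)
        for (k in seq_len(B)) {
          z <- inputs[[sel[k]]]
          rows <- (seq_len(lens[k]) - 1L) * B + k   # time-major layout
          Xb[rows, ] <- z$X; Yb[rows, ] <- z$Y; mask[rows] <- TRUE
        }
        fw <- seq_forward(arch, params, Xb, B = B, T_len = T_len,
                          keep_cache = TRUE)
        lg <- nll_h(fw$out, Yb)
        nv <- sum(mask)
        tot <- tot + sum(lg$nll[mask]); n_steps <- n_steps + nv
        dOut <- lg$grad
        dOut[!mask, ] <- 0
        grads <- seq_backward(arch, params, fw$caches, dOut / nv,
                              B = B, T_len = T_len)
        st <- adam_step(params, grads, opt, lr)
        params <- st$params; opt <- st$state
      }
      history[ep] <- tot / n_steps
      if (history[ep] < best$nll)
        best <- list(nll = history[ep], params = params, epoch = ep)
      if (verbose) message(sprintf("epoch %d: NLL %.5f", ep, history[ep]))
    }
  }

  structure(list(kind = spec$kind, spec = spec, arch = arch,
                 params = best$params, history = history,
                 best_epoch = best$epoch, fold = NA_character_),
            class = "cp_model")
}
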