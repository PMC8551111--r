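# extrapolators, input construction, Gaussian head, NLL, networks, training

test_that("build_inputs produces (v_a, v_d, r) with n-2 pairs per trial", {
  n <- 101
  pa <- cbind(seq(0, 2, length.out = n), seq(5, 3, length.out = n))
  pd <- cbind(rep(0, n), rep(0, n))
  tr <- chase_trial("b", pa, pd, condition = "square", sample_rate = 20,
                    outcome = "timeout")
  z <- build_inputs(trialset(list(tr)))[[1]]
  expect_equal(nrow(z$X), 99)
  expect_equal(ncol(z$X), 6)
  # range vector points from defender to attacker
  expect_equal(z$X[1, 5:6], pa[2, ] - pd[2, ])
  # stationary attacker -> zero targets
  pa2 <- matrix(rep(c(1, 2), each = 10), ncol = 2)
  tr2 <- chase_trial("s", pa2, pa2 * 0, condition = "square",
                     sample_rate = 20, outcome = "timeout")
  z2 <- build_inputs(trialset(list(tr2)))[[1]]
  expect_true(all(z2$Y == 0))
  # too-short trials are skipped with a message
  tr3 <- chase_trial("short", pa2[1:2, ], pa2[1:2, ] * 0,
                     condition = "square", sample_rate = 20,
                     outcome = "timeout")
  expect_message(out <- build_inputs(trialset(list(tr3))), "skipped")
  expect_length(out, 0)
})

test_that("linear extrapolation repeats the last displacement", {
  expect_equal(linear_extrapolate(c(0, 0), c(1, 0)), c(2, 0))
  expect_equal(linear_extrapolate(c(1, 1), c(1, 1)), c(1, 1))
  expect_equal(linear_extrapolate(c(0, 0), c(1, 1)), c(2, 2))
})

test_that("curvilinear extrapolation rotates by the last angular change", {
  # +90 degree turn continues turning left
  expect_equal(curvilinear_extrapolate(c(0, 0), c(1, 0), c(1, 1)), c(0, 1))
  # degenerate cases
  expect_equal(curvilinear_extrapolate(c(0, 0), c(1, 0), c(1, 0)), c(1, 0))
  expect_equal(curvilinear_extrapolate(c(1, 0), c(1, 0), c(2, 0)), c(3, 0))
  # collinear -> identical to linear (property)
  set.seed(11)
  for (k in 1:1000) {
    p0 <- rnorm(2); d <- rnorm(2); a <- runif(2, 0.1, 2)
    p1 <- p0 + a[1] * d; p2 <- p1 + a[2] * d
    expect_equal(curvilinear_extrapolate(p0, p1, p2),
                 linear_extrapolate(p1, p2), tolerance = 1e-12)
  }
  # circular motion stays on the circle and hits the next sample
  set.seed(12)
  for (k in 1:200) {
    R <- runif(1, 0.5, 5); th0 <- runif(1, 0, 2 * pi)
    dth <- runif(1, 0.01, 1); ctr <- rnorm(2)
    p <- t(sapply(0:3, function(j)
      ctr + R * c(cos(th0 + j * dth), sin(th0 + j * dth))))
    pr <- curvilinear_extrapolate(p[1, ], p[2, ], p[3, ])
    expect_lt(max(abs(pr - p[4, ])), 1e-9)
    expect_lt(abs(sqrt(sum((pr - ctr)^2)) - R), 1e-9)
  }
})

test_that("the Gaussian head transform is always valid", {
  z <- gauss_head(rep(0, 5))
  expect_equal(z$mu, c(0, 0))
  expect_equal(z$sigma, c(1, 1))
  expect_equal(z$rho, 0)
  set.seed(4)
  H <- matrix(rnorm(500, sd = 5), ncol = 5)
  g <- gauss_head(H)
  expect_true(all(g$sigma > 0))
  expect_true(all(abs(g$rho) < 1))
})

test_that("NLL equals log(2*pi) at the mean and is unimodal", {
  p <- list(mu = c(0, 0), sigma = c(1, 1), rho = 0)
  expect_equal(nll_loss(p, c(0, 0)), log(2 * pi))
  l0 <- nll_loss(p, c(0.5, 0))
  expect_gt(l0, nll_loss(p, c(0.2, 0)))
  expect_gt(nll_loss(p, c(0, 2)), nll_loss(p, c(0, 1)))
})

test_that("NLL gradients match central finite differences", {
  set.seed(21)
  worst <- 0
  for (k in 1:100) {
    h <- rnorm(5); y <- rnorm(2)
    g <- chasepred:::nll_h(matrix(h, 1), matrix(y, 1))$grad
    for (j in 1:5) {
      e <- rep(0, 5); e[j] <- 1e-5
      num <- (chasepred:::nll_h(matrix(h + e, 1), matrix(y, 1))$nll -
              chasepred:::nll_h(matrix(h - e, 1), matrix(y, 1))$nll) / 2e-5
      worst <- max(worst, abs(num - g[j]))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("a 1-unit LSTM with zero weights matches the hand-computed cell", {
  arch <- list(list(type = "lstm", n_in = 1, n_out = 1))
  params <- list(list(Wx = matrix(0, 1, 4), Wh = matrix(0, 1, 4),
                      b = c(0, 0, 0, 1)))
  out <- chasepred:::seq_forward(arch, params, matrix(0, 1, 1),
                                 B = 1, T_len = 1)
  # i = f = o = sigmoid(0) = 0.5, c = 0.5 * tanh(1), h = 0.5 * tanh(c)
  expect_equal(out$out[1, 1], 0.5 * tanh(0.5 * tanh(1)), tolerance = 1e-12)
  expect_equal(out$state[[1]]$c[1, 1], 0.5 * tanh(1))
})

test_that("trainable parameter counts match the fixed dimensions", {
  # closed-form oracle from the layer dimensions
  dense <- function(i, o) i * o + o
  rnn <- function(i, o) i * o + o * o + o
  lstm <- function(i, o) 4 * (i * o + o * o + o)
  expect_equal(n_params("LN"), dense(6, 64) + dense(64, 128) + dense(128, 5))
  expect_equal(n_params("LN"), 9413)
  expect_equal(n_params("NN"), 9413)
  expect_equal(n_params("RNN"), dense(6, 64) + rnn(64, 128) + dense(128, 5))
  expect_equal(n_params("LSTM"), dense(6, 64) + lstm(64, 128) + dense(128, 5))
  expect_equal(n_params("DNN"), 9413 - dense(128, 5) +
                 dense(128, 128) + dense(128, 5))
  expect_equal(n_params("DRNN"), n_params("RNN") + rnn(128, 128))
  expect_equal(n_params("DLSTM"), n_params("LSTM") + lstm(128, 128))
})

test_that("network gradients match finite differences end to end", {
  set.seed(31)
  for (kind in c("NN", "LSTM")) {
    arch <- chasepred:::build_arch(kind)
    params <- chasepred:::init_params(arch)
    B <- 2; T_len <- 3
    X <- matrix(rnorm(T_len * B * 6, sd = 0.5), T_len * B, 6)
    Y <- matrix(rnorm(T_len * B * 2, sd = 0.3), T_len * B, 2)
    fw <- chasepred:::seq_forward(arch, params, X, B = B, T_len = T_len,
                                  keep_cache = TRUE)
    gr <- chasepred:::seq_backward(arch, params, fw$caches,
                                   chasepred:::nll_h(fw$out, Y)$grad,
                                   B = B, T_len = T_len)
    loss <- function(pp) {
      f <- chasepred:::seq_forward(arch, pp, X, B = B, T_len = T_len)
      sum(chasepred:::nll_h(f$out, Y)$nll)
    }
    worst <- 0
    for (li in seq_along(params)) for (nm in names(params[[li]])) {
      idx <- sample(length(params[[li]][[nm]]), 3)
      for (ii in idx) {
        pp <- params
        pp[[li]][[nm]][ii] <- pp[[li]][[nm]][ii] + 1e-5
        up <- loss(pp)
        pp[[li]][[nm]][ii] <- pp[[li]][[nm]][ii] - 2e-5
        dn <- loss(pp)
        worst <- max(worst, abs((up - dn) / 2e-5 - gr[[li]][[nm]][ii]))
      }
    }
    expect_lt(worst, 1e-6)
  }
})

# synthetic random-walk inputs, no simulator involved
fake_inputs <- function(n_trials, len, seed) {
  set.seed(seed)
  lapply(seq_len(n_trials), function(k) {
    pa <- apply(matrix(rnorm((len + 2) * 2, sd = 0.2), ncol = 2), 2, cumsum)
    pd <- apply(matrix(rnorm((len + 2) * 2, sd = 0.2), ncol = 2), 2, cumsum)
    da <- diff(pa); dd <- diff(pd)
    idx <- 2:(len + 1)
    list(trial_id = paste0("f", k), defender_participant = "P01",
         condition = "square",
         X = cbind(da[idx - 1, ], dd[idx - 1, ], pa[idx, ] - pd[idx, ]),
         Y = da[idx, , drop = FALSE], pa = pa, pd = pd)
  })
}

test_that("training reduces the NLL and is reproducible", {
  inputs <- fake_inputs(4, 50, seed = 5)
  improved <- 0
  for (s in 1:10) {
    m <- train_model(model_spec("LN", epochs = 2, seed = s), inputs)
    if (m$history[2] <= m$history[1]) improved <- improved + 1
  }
  expect_gte(improved, 8)

  m1 <- train_model(model_spec("NN", epochs = 2, seed = 7), inputs)
  m2 <- train_model(model_spec("NN", epochs = 2, seed = 7), inputs)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)

  mr1 <- train_model(model_spec("RNN", epochs = 2, seed = 7), inputs)
  mr2 <- train_model(model_spec("RNN", epochs = 2, seed = 7), inputs)
  expect_identical(mr1$params, mr2$params)
  expect_true(all(is.finite(mr1$history)))

  expect_error(train_model(model_spec("NN", epochs = 1), list()), "empty")
  expect_error(train_model(model_spec("L"), inputs), "trainable")
})

test_that("the NN learns a deterministic constant-velocity rule", {
  # attacker always moves at a fixed velocity: the trivial linear rule
  mk <- function(k) {
    n <- 60
    v <- c(0.2, -0.1)
    p0 <- c(runif(1, -2, 2), runif(1, 2, 5))
    pa <- cbind(p0[1] + (0:(n - 1)) * v[1], p0[2] + (0:(n - 1)) * v[2])
    pd <- cbind(rep(0, n), rep(-3, n))
    list(trial_id = paste0("cv", k), defender_participant = "P01",
         condition = "square",
         X = cbind(matrix(rep(v, each = n - 2), ncol = 2),
                   matrix(0, n - 2, 2),
                   pa[2:(n - 1), ] - pd[2:(n - 1), ]),
         Y = matrix(rep(v, each = n - 2), ncol = 2),
         pa = pa, pd = pd)
  }
  set.seed(8)
  inputs <- lapply(1:10, mk)
  m <- train_model(model_spec("NN", epochs = 40, seed = 1), inputs)
  os <- one_step_eval(m, inputs)
  expect_lt(median(os$error), 5)
})

test_that("model_forward is deterministic and threads recurrent state", {
  m <- make_model(model_spec("LSTM", seed = 2))
  x <- c(0.1, -0.2, 0, 0.1, 1, 2)
  a <- model_forward(m, x)
  b <- model_forward(m, x)
  expect_identical(a$pred, b$pred)
  # feeding the state forward changes the second prediction
  c2 <- model_forward(m, x, state = a$state)
  expect_false(identical(a$pred, c2$pred))
})
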